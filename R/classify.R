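#' Linear support-vector-machine decision scores
#'
#' Fits a linear-kernel SVM to a labeled feature matrix (0 =
#' contralateral/normal, 1 = ipsilateral/abnormal) and returns the signed
#' decision-function value of every point, oriented so that larger scores
#' mean more abnormal.  Features are z-scored before fitting; columns with
#' zero variance are dropped from standardization (kept at 0).  Deterministic
#' given the data and \code{c_reg}.
#'
#' @param x numeric matrix or data.frame of features (n x d).
#' @param y binary labels (0/1, logical, or a 2-level factor).
#' @param c_reg SVM cost parameter.
#' @param newdata optional matrix of points to score instead of \code{x}
#'   (standardized with the training moments).
#' @return numeric vector of decision scores.
#' @export
train_linear_svm <- function(x, y, c_reg = 1, newdata = NULL) {
  x <- as.matrix(x)
  y <- as.integer(as.factor(y)) - 1L
  if (length(unique(y)) < 2) stop("training needs both classes present")
  mu <- colMeans(x)
  sg <- apply(x, 2, stats::sd)
  sg[sg == 0] <- 1
  xs <- scale(x, mu, sg)
  fit <- e1071::svm(xs, factor(y, levels = c(0, 1)), kernel = "linear",
                    cost = c_reg, scale = FALSE)
  xn <- if (is.null(newdata)) xs else scale(as.matrix(newdata), mu, sg)
  dv <- attr(stats::predict(fit, xn, decision.values = TRUE),
             "decision.values")
  score <- as.numeric(dv)
  # libsvm orients the decision value toward the first label it encounters;
  # normalize so the positive (abnormal) class scores high
  if (grepl("^0/1$", colnames(dv)[1])) score <- -score
  score
}

#' ROC curve, AUC and operating point
#'
#' Builds the ROC curve over all unique decision-score thresholds (predict
#' positive when score >= threshold; tied scores enter together), integrates
#' the AUC by the trapezoidal rule — which under this tie convention equals
#' the pairwise concordance probability (Mann-Whitney identity) exactly —
#' and selects the operating point maximizing (sensitivity + specificity)/2,
#' breaking ties toward higher sensitivity.
#'
#' @param scores numeric decision scores (larger = more abnormal).
#' @param labels binary labels (0 = negative/normal, 1 = positive/abnormal).
#' @return a \code{roc_result}: data.frame \code{curve} (threshold,
#'   sensitivity, specificity), \code{auc}, \code{op_threshold},
#'   \code{op_sensitivity}, \code{op_specificity}.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) < 2) stop("ROC evaluation needs both classes")
  stopifnot(length(scores) == length(y))
  thr <- sort(unique(scores))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, 0)
  spec <- vapply(thr, function(t) sum(scores < t & y == 0) / n0, 0)
  # curve endpoints: everything positive / nothing positive
  sens <- c(1, sens, 0); spec <- c(0, spec, 1)
  thr <- c(-Inf, thr, Inf)
  fpr <- 1 - spec
  auc <- sum(-diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  bal <- (sens + spec) / 2
  best <- which(bal == max(bal))
  best <- best[which.max(sens[best])]
  structure(list(curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec),
                 auc = auc, op_threshold = thr[best],
                 op_sensitivity = sens[best], op_specificity = spec[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f | operating point: sens = %.3f spec = %.3f (thr %.4g)\n",
              x$auc, x$op_sensitivity, x$op_specificity, x$op_threshold))
  invisible(x)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration of the permutation distribution of the U statistic for
#' small samples (both groups <= \code{exact_max}), normal approximation with
#' tie correction and continuity correction otherwise.  The two-sided exact
#' p-value doubles the smaller tail (capped at 1), matching the usual exact
#' convention for the symmetric null distribution.
#'
#' @param a,b numeric samples (both nonempty).
#' @param exact_max enumerate exactly when both groups are at most this size.
#' @return list with \code{u} (U statistic of the first group),
#'   \code{p_value} and \code{method}.
#' @export
mann_whitney_two_sided <- function(a, b, exact_max = 8) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na <= exact_max && nb <= exact_max) {
    idx <- utils::combn(na + nb, na)
    us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    # symmetric two-sided: double the smaller tail
    p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
    return(list(u = u_obs, p_value = min(1, p), method = "exact enumeration"))
  }
  n <- na + nb
  ties <- table(pooled)
  mu <- na * nb / 2
  sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(list(u = u_obs, p_value = 1,
                             method = "normal approximation"))
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sig2)
  list(u = u_obs, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}

#' Per-rat classification pipeline: one-channel vs four-channel
#'
#' Reproduces the comparison between single-channel circular polarimetry
#' (features: dep and delta of one designated channel) and the four-channel
#' method (16 features: per-channel metrics plus their statistical moments).
#' Contralateral points are labeled negative, ipsilateral positive.  The
#' default scheme scores the training points themselves (resubstitution, the
#' apparent in-sample ROC); stratified k-fold cross-validation is available
#' and recommended when generalization matters.
#'
#' @param features feature table from \code{\link{feature_table}} (or a
#'   measurement table from \code{\link{generate_scan}}, converted
#'   automatically).
#' @param mode \code{"one_channel"} or \code{"four_channel"}.
#' @param scheme \code{"resubstitution"} or \code{"k_fold"}.
#' @param channel designated channel for one-channel mode (1..4).
#' @param c_reg SVM cost.
#' @param k folds for \code{"k_fold"}.
#' @param fold_seed seed for the stratified fold assignment.
#' @return named list of \code{roc_result}, one per rat_id.
#' @export
evaluate_pipeline <- function(features, mode = c("one_channel", "four_channel"),
                              scheme = c("resubstitution", "k_fold"),
                              channel = 1, c_reg = 1, k = 5, fold_seed = 1) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  if ("channel" %in% names(features)) {
    if (max(features$channel) == 1L) {
      # single-channel scan: only the one-channel classifier applies
      if (mode != "one_channel" || channel != 1)
        stop("single-channel measurements support only one_channel mode, channel 1")
      features <- data.frame(rat_id = features$rat_id, side = features$side,
                             point_index = features$point_index,
                             dep1 = features$dep, delta1 = features$delta)
    } else {
      features <- feature_table(features)
    }
  }
  cols <- if (mode == "one_channel") {
    paste0(c("dep", "delta"), channel)
  } else {
    c(paste0("dep", 1:4), paste0("delta", 1:4),
      paste0("dep_z", 1:4), paste0("delta_z", 1:4))
  }
  out <- lapply(split(features, features$rat_id), function(d) {
    x <- as.matrix(d[, cols, drop = FALSE])
    y <- as.integer(d$side == "ipsi")
    if (scheme == "resubstitution") {
      sc <- train_linear_svm(x, y, c_reg)
    } else {
      sc <- rep(NA_real_, nrow(x))
      folds <- local({
        set.seed(fold_seed)
        f <- rep(NA_integer_, length(y))
        for (cl in unique(y)) {
          i <- which(y == cl)
          f[i] <- sample(rep_len(seq_len(k), length(i)))
        }
        f
      })
      for (fi in seq_len(k)) {
        te <- folds == fi
        sc[te] <- train_linear_svm(x[!te, , drop = FALSE], y[!te], c_reg,
                                   newdata = x[te, , drop = FALSE])
      }
    }
    roc_auc(sc, y)
  })
  out
}
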