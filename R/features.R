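#' Statistical moments across the four measurement channels
#'
#' The four-channel probe samples the two polarization metrics at four
#' adjacent spots; the first- to fourth-order statistical moments of the four
#' values summarize the local spatial texture: \code{z1} the mean, \code{z2}
#' the standard deviation, \code{z3} the skewness and \code{z4} the kurtosis.
#' With \code{convention = "sample_sd"} (default) \code{z2 =
#' sqrt((1/3) sum (c_j - z1)^2)} and the higher moments normalize by
#' \code{z2^3} and \code{z2^4}; \code{convention = "population"} uses the
#' \code{1/4} divisor instead (exposed for sensitivity analysis; the two
#' differ by fixed factors).  For n = 4 samples the kurtosis obeys the
#' algebraic bound \code{z4 >= 9/16} under the default convention
#' (\code{z4 >= 1} under the population convention).
#'
#' When all four values coincide (\code{z2 = 0}) the skewness and kurtosis
#' are undefined: they are returned as \code{NA} with \code{degenerate =
#' TRUE}; \code{\link{build_feature_vector}} imputes them as 0 and 1 with a
#' flag so the sample is preserved for classification.
#'
#' @param c4 numeric vector of exactly 4 finite channel values.
#' @param convention \code{"sample_sd"} or \code{"population"}.
#' @return list with \code{z1, z2, z3, z4, degenerate}.
#' @export
channel_moments <- function(c4, convention = c("sample_sd", "population")) {
  convention <- match.arg(convention)
  if (length(c4) != 4 || !all(is.finite(c4)))
    stop("channel_moments needs exactly 4 finite values")
  z1 <- mean(c4)
  d <- c4 - z1
  z2 <- if (convention == "sample_sd") sqrt(sum(d^2) / 3) else
    sqrt(sum(d^2) / 4)
  if (z2 == 0)
    return(list(z1 = z1, z2 = 0, z3 = NA_real_, z4 = NA_real_,
                degenerate = TRUE))
  list(z1 = z1,
       z2 = z2,
       z3 = sum(d^3) / 4 / z2^3,
       z4 = sum(d^4) / 4 / z2^4,
       degenerate = FALSE)
}

#' Assemble the 16-value feature vector of one scan point
#'
#' Fixed ordering: the per-channel metrics \code{dep1..dep4, delta1..delta4},
#' then the moment block \code{dep_z1..dep_z4, delta_z1..delta_z4}.  The
#' moment block is invariant under any permutation of the channels; the first
#' eight entries are not.  Undefined moments (all channels identical) are
#' imputed as skewness 0 and kurtosis 1, and the returned vector carries a
#' \code{"degenerate"} attribute naming the affected metric(s).
#'
#' @param dep,delta numeric vectors of 4 per-channel metric values.
#' @param convention moment convention, see \code{\link{channel_moments}}.
#' @return named numeric vector of length 16.
#' @export
build_feature_vector <- function(dep, delta,
                                 convention = c("sample_sd", "population")) {
  convention <- match.arg(convention)
  if (length(dep) != 4 || length(delta) != 4 ||
      anyNA(dep) || anyNA(delta))
    stop("incomplete measurement: need 4 channels of dep and delta")
  impute <- function(m) {
    if (m$degenerate) c(m$z1, m$z2, 0, 1) else c(m$z1, m$z2, m$z3, m$z4)
  }
  md <- channel_moments(dep, convention)
  mt <- channel_moments(delta, convention)
  out <- c(dep, delta, impute(md), impute(mt))
  names(out) <- c(paste0("dep", 1:4), paste0("delta", 1:4),
                  paste0("dep_z", 1:4), paste0("delta_z", 1:4))
  flags <- c(if (md$degenerate) "dep", if (mt$degenerate) "delta")
  if (length(flags)) attr(out, "degenerate") <- flags
  out
}

#' Feature table from a scan measurement table
#'
#' Turns a long measurement table (one row per point x channel, as produced
#' by \code{\link{generate_scan}}) into a wide feature table with one row per
#' scan point: metadata columns, the 16 features and a \code{degenerate}
#' flag column.
#'
#' @param records data.frame with columns \code{rat_id, side, point_index,
#'   x_um, y_um, channel, dep, delta}.
#' @param convention moment convention.
#' @return data.frame, one row per (rat_id, side, point_index).
#' @export
feature_table <- function(records, convention = c("sample_sd", "population")) {
  convention <- match.arg(convention)
  need <- c("rat_id", "side", "point_index", "channel", "dep", "delta")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  records <- records[order(records$rat_id, records$side,
                           records$point_index, records$channel), ]
  key <- paste(records$rat_id, records$side, records$point_index, sep = "\r")
  if (any(tabulate(factor(key)) != 4) ||
      any(records$channel != rep(1:4, length.out = nrow(records))))
    stop("each point needs exactly 4 channels (1..4)")
  first <- seq(1, nrow(records), by = 4)
  D <- matrix(records$dep, ncol = 4, byrow = TRUE)
  Tm <- matrix(records$delta, ncol = 4, byrow = TRUE)
  if (anyNA(D) || anyNA(Tm)) stop("incomplete measurement: NA metric values")
  div <- if (convention == "sample_sd") 3 else 4
  mom <- function(M) {
    z1 <- rowMeans(M)
    d <- M - z1
    z2 <- sqrt(rowSums(d^2) / div)
    degen <- z2 == 0
    z3 <- ifelse(degen, 0, rowSums(d^3) / 4 / z2^3)
    z4 <- ifelse(degen, 1, rowSums(d^4) / 4 / z2^4)
    list(m = cbind(z1, z2, z3, z4), degen = degen)
  }
  md <- mom(D); mt <- mom(Tm)
  out <- data.frame(rat_id = records$rat_id[first],
                    side = records$side[first],
                    point_index = records$point_index[first],
                    x_um = if ("x_um" %in% names(records))
                      rowMeans(matrix(records$x_um, ncol = 4, byrow = TRUE))
                      else NA_real_,
                    y_um = if ("y_um" %in% names(records))
                      rowMeans(matrix(records$y_um, ncol = 4, byrow = TRUE))
                      else NA_real_,
                    degenerate = md$degen | mt$degen)
  feat <- cbind(D, Tm, md$m, mt$m)
  colnames(feat) <- c(paste0("dep", 1:4), paste0("delta", 1:4),
                      paste0("dep_z", 1:4), paste0("delta_z", 1:4))
  out <- cbind(out, as.data.frame(feat))
  rownames(out) <- NULL
  out
}
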