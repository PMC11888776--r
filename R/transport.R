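# Polarized Monte Carlo photon transport through a scattering slab.
#
# Photons are processed in fixed-size chunks, each with its own deterministic
# RNG substream derived from the run seed, so extending a run with more
# photons never reshuffles the photons already simulated.  Within a chunk all
# photons advance in vectorized lock-step.  Polarization is tracked with the
# meridian-plane method: each packet carries a unit reference vector
# perpendicular to its direction that defines the Q > 0 axis of its Stokes
# vector; at every scattering event the Stokes vector is rotated into the
# scattering frame, multiplied by the single-scattering Mueller matrix built
# from the exact amplitude series, renormalized, and the reference vector is
# replaced by the scattered-frame parallel axis.

# ---- small row-wise 3-vector helpers -------------------------------------

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vnormalize <- function(a) a / sqrt(rowSums(a^2))

# rotation angle from frame vector `from` to `to` about direction u
frame_angle <- function(from, to, u) {
  atan2(rowSums(to * vcross(u, from)), rowSums(to * from))
}

# ---- Watson axial distribution -------------------------------------------

#' Sample axis directions from a Watson axial distribution
#'
#' Density proportional to \code{exp(kappa (a . mu)^2)} over the sphere;
#' axes are returned with the hemisphere sign chosen at random (the
#' distribution is axial).  \code{kappa = Inf} returns the mean axis exactly,
#' \code{kappa = 0} is isotropic.
#'
#' @param n number of axes.
#' @param mean_axis unit mean axis.
#' @param kappa concentration parameter, >= 0 or Inf.
#' @return n x 3 matrix of unit vectors.
#' @export
rwatson <- function(n, mean_axis, kappa) {
  mu <- mean_axis / sqrt(sum(mean_axis^2))
  if (is.infinite(kappa)) return(matrix(mu, n, 3, byrow = TRUE))
  tg <- seq(-1, 1, length.out = 4097)
  d <- exp(kappa * (tg^2 - 1))
  cdf <- cumsum((d[-1] + d[-length(d)]) / 2)
  cdf <- c(0, cdf / cdf[length(cdf)])
  u <- stats::runif(n)
  j <- findInterval(u, cdf, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1), length(tg) - 1)
  frac <- (u - cdf[j]) / pmax(cdf[j + 1] - cdf[j], 1e-300)
  t <- tg[j] + frac * (tg[j + 1] - tg[j])
  phi <- stats::runif(n, 0, 2 * pi)
  # orthonormal pair perpendicular to mu
  ref <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- ref - sum(ref * mu) * mu; p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(mu[2] * p1[3] - mu[3] * p1[2],
          mu[3] * p1[1] - mu[1] * p1[3],
          mu[1] * p1[2] - mu[2] * p1[1])
  st <- sqrt(pmax(0, 1 - t^2))
  outer(t, mu) + st * (outer(cos(phi), p1) + outer(sin(phi), p2))
}

# ---- per-population precomputation ---------------------------------------

.prepare_populations <- function(model) {
  lapply(model$populations, function(p) {
    if (p$type == "sphere") {
      p$coef <- mie_coefficients(p$x, p$m)
      thg <- seq(0, pi, length.out = 721)
      amp <- mie_amplitudes(thg, p$x, p$m, p$coef)
      m11 <- (Mod(amp$S1)^2 + Mod(amp$S2)^2) / 2
      m12 <- (Mod(amp$S2)^2 - Mod(amp$S1)^2) / 2
      p$pmax <- 1.05 * max(m11 + abs(m12))
    } else {
      p$nmax <- ceiling(p$x + 4 * p$x^(1 / 3) + 2)
      G <- max(96L, 8L * p$nmax)
      p$theta_grid <- 2 * pi * seq(0, G - 1) / G
      nvec <- 0:p$nmax
      p$Cg <- cos(outer(nvec, p$theta_grid))   # (nmax+1) x G
      p$Sg <- sin(outer(nvec, p$theta_grid))
      p$w <- c(1, rep(2, p$nmax))
      p$ws <- c(0, rep(2, p$nmax))
      # Bernstein-type safety factor: |T|^2 is a trig polynomial of degree
      # 2 nmax, so the grid maximum underestimates the true maximum by at
      # most 1/cos(pi nmax / G)
      p$safety <- 1.02 / cos(pi * p$nmax / G)
    }
    p
  })
}

# ---- scattering kernels (vectorized over photons) ------------------------

# Cylinder event: draws axes, rejection-samples the azimuthal scattering
# angle Theta on the cone from the polarized phase function, applies the
# amplitude-series Mueller matrix and updates direction + reference frame.
.scatter_cylinder <- function(u, vref, S, pop, max_rounds = 5000L) {
  n <- nrow(u)
  axis <- rwatson(n, pop$mean_axis, pop$kappa)
  cd <- rowSums(u * axis)
  flip <- cd < 0
  axis[flip, ] <- -axis[flip, , drop = FALSE]
  cd <- abs(cd)
  # near-axial incidence is geometrically degenerate; such events are
  # vanishingly rare and are treated as forward (no-op)
  ok <- cd < 1 - 1e-6
  if (!all(ok)) {
    res <- .scatter_cylinder(u[ok, , drop = FALSE], vref[ok, , drop = FALSE],
                             S[ok, , drop = FALSE], pop, max_rounds)
    u[ok, ] <- res$u; vref[ok, ] <- res$vref; S[ok, ] <- res$S
    return(list(u = u, vref = vref, S = S))
  }
  sz <- sqrt(pmax(0, 1 - cd^2))
  zeta <- pmax(acos(pmin(cd, 1)), 1e-6)
  # the amplitude series varies smoothly with incidence angle: evaluate the
  # coefficient sets on a ~0.06 degree grid of unique incidence-angle bins
  # (the cone geometry itself stays exact); each binned matrix is still an
  # exact Mueller-Jones matrix, so pure states stay pure
  nb_zeta <- 1440L
  ib <- pmin(pmax(round(zeta / (pi / 2) * nb_zeta), 1L), nb_zeta)
  ub <- sort(unique(ib))
  map <- match(ib, ub)
  cfu <- cylinder_coefficients(ub * (pi / 2) / nb_zeta, pop$x, pop$m,
                               nmax = pop$nmax)
  # unpolarized phase function on the Theta grid -> per-bin envelope
  m11g <- (Mod(cfu$bI %*% ((pop$w) * pop$Cg))^2 +
           Mod(cfu$aII %*% ((pop$w) * pop$Cg))^2 +
           Mod(cfu$aI %*% ((pop$ws) * pop$Sg))^2 +
           Mod(cfu$bII %*% ((pop$ws) * pop$Sg))^2) / 2
  envu <- m11g[, 1]
  for (g in 2:ncol(m11g)) envu <- pmax(envu, m11g[, g])
  cf <- list(bI = cfu$bI[map, , drop = FALSE],
             aI = cfu$aI[map, , drop = FALSE],
             aII = cfu$aII[map, , drop = FALSE],
             bII = cfu$bII[map, , drop = FALSE], nmax = cfu$nmax)
  env <- 2 * pop$safety * envu[map]  # p <= 2 m11 for any physical state
  # rotate Stokes into the incidence frame (parallel = plane of axis and u)
  epar_i <- vnormalize(axis - cd * u)
  psi <- frame_angle(vref, epar_i, u)
  S_loc <- rotate_stokes_rows(S, psi)
  # rejection sampling of Theta
  Theta <- numeric(n)
  todo <- seq_len(n)
  amp_row1 <- function(idx, th) {
    a <- cylinder_amplitudes(th, coef = list(bI = cf$bI[idx, , drop = FALSE],
                                             aI = cf$aI[idx, , drop = FALSE],
                                             aII = cf$aII[idx, , drop = FALSE],
                                             bII = cf$bII[idx, , drop = FALSE],
                                             nmax = cf$nmax))
    e <- mueller_from_amplitudes(a$T1, a$T2, a$T3, a$T4)
    list(p = e$m11 * S_loc[idx, 1] + e$m12 * S_loc[idx, 2] +
           e$m13 * S_loc[idx, 3] + e$m14 * S_loc[idx, 4], amp = a)
  }
  rounds <- 0L
  while (length(todo)) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop("cylinder phase-function rejection sampling failed (bound exceeded)")
    cand <- stats::runif(length(todo), 0, 2 * pi)
    p <- amp_row1(todo, cand)$p
    acc <- stats::runif(length(todo)) * env[todo] < p
    Theta[todo[acc]] <- cand[acc]
    todo <- todo[!acc]
  }
  a <- cylinder_amplitudes(Theta, coef = cf)
  e <- mueller_from_amplitudes(a$T1, a$T2, a$T3, a$T4)
  S_new <- mueller_apply_rows(e, S_loc)
  bad <- S_new[, 1] <= 0
  if (any(bad)) S_new[bad, ] <- S_loc[bad, , drop = FALSE]  # numerical guard
  S_new <- S_new / S_new[, 1]
  # new direction on the cone about the axis
  that <- (u - cd * axis) / sz
  bhat <- vcross(axis, that)
  u_new <- cd * axis + sz * (cos(Theta) * that + sin(Theta) * bhat)
  u_new <- vnormalize(u_new)
  vref_new <- vnormalize(axis - rowSums(axis * u_new) * u_new)
  list(u = u_new, vref = vref_new, S = S_new)
}

# Sphere event: joint rejection sampling of (theta, phi) from the polarized
# Mie phase function, then meridian-plane update.
.scatter_sphere <- function(u, vref, S, pop, max_rounds = 5000L) {
  n <- nrow(u)
  theta <- numeric(n); phi <- numeric(n)
  todo <- seq_len(n)
  q <- sqrt(S[, 2]^2 + S[, 3]^2)
  rounds <- 0L
  while (length(todo)) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop("sphere phase-function rejection sampling failed (bound exceeded)")
    ct <- stats::runif(length(todo), -1, 1)
    th <- acos(ct)
    ph <- stats::runif(length(todo), 0, 2 * pi)
    amp <- mie_amplitudes(th, coef = pop$coef)
    m11 <- (Mod(amp$S1)^2 + Mod(amp$S2)^2) / 2
    m12 <- (Mod(amp$S2)^2 - Mod(amp$S1)^2) / 2
    p <- m11 + m12 * (S[todo, 2] * cos(2 * ph) + S[todo, 3] * sin(2 * ph))
    acc <- stats::runif(length(todo)) * pop$pmax < p
    theta[todo[acc]] <- th[acc]
    phi[todo[acc]] <- ph[acc]
    todo <- todo[!acc]
  }
  S_loc <- rotate_stokes_rows(S, phi)
  amp <- mie_amplitudes(theta, coef = pop$coef)
  e <- mueller_from_amplitudes(amp$S2, amp$S1, rep(0 + 0i, n), rep(0 + 0i, n))
  S_new <- mueller_apply_rows(e, S_loc)
  S_new <- S_new / S_new[, 1]
  epar <- vref * cos(phi) + vcross(u, vref) * sin(phi)
  u_new <- u * cos(theta) + epar * sin(theta)
  vref_new <- epar * cos(theta) - u * sin(theta)
  list(u = vnormalize(u_new), vref = vnormalize(vref_new), S = S_new)
}

# ---- photon packets -------------------------------------------------------

#' Photon packet ensemble
#'
#' Container for vectorized packet state: positions (um), unit directions,
#' unit reference vectors (perpendicular to direction; the Q > 0 axis of each
#' packet's Stokes vector), Stokes rows normalized to s0 = 1, and survival
#' weights.
#'
#' @param n number of packets.
#' @param direction,reference,stokes,position,weight optional initial state
#'   (matrices are recycled from single rows).
#' @return a \code{photon_packets} list.
#' @export
photon_packets <- function(n, direction = c(0, 0, 1), reference = c(1, 0, 0),
                           stokes = c(1, 0, 0, 1), position = c(0, 0, 0),
                           weight = 1) {
  asrows <- function(v, k) {
    m <- if (is.matrix(v)) v else matrix(v, n, k, byrow = TRUE)
    stopifnot(nrow(m) == n, ncol(m) == k)
    m
  }
  u <- asrows(direction, 3); r <- asrows(reference, 3)
  u <- vnormalize(u); r <- vnormalize(r)
  if (max(abs(rowSums(u * r))) > 1e-10)
    stop("reference vectors must be perpendicular to directions")
  S <- asrows(stokes, 4)
  S <- S / S[, 1]
  structure(list(n = n, position = asrows(position, 3), direction = u,
                 reference = r, stokes = S, weight = rep_len(weight, n)),
            class = "photon_packets")
}

#' Single scattering event
#'
#' Applies one scattering event to every packet: a scatterer type is selected
#' with probability proportional to the partial scattering coefficients, a
#' cylinder axis is drawn from the population's orientation distribution (the
#' scattered direction stays on the cone about the axis), or a sphere
#' scattering angle pair is drawn from the polarized Mie phase function; the
#' Stokes vectors are rotated through the scattering frames and multiplied by
#' the single-scattering Mueller matrix.  A model with zero total scattering
#' coefficient returns the packets unchanged.
#'
#' @param packets a \code{photon_packets} ensemble.
#' @param model a \code{tissue_model}.
#' @param prepared internal: pre-tabulated populations.
#' @return the updated \code{photon_packets}.
#' @export
scatter_event <- function(packets, model, prepared = NULL) {
  if (model$mu_s_um <= 0) return(packets)
  pops <- if (is.null(prepared)) .prepare_populations(model) else prepared
  mus <- vapply(model$populations, `[[`, 0, "mu_s_um")
  pick <- sample.int(length(pops), packets$n, replace = TRUE, prob = mus)
  u <- packets$direction; vr <- packets$reference; S <- packets$stokes
  for (j in seq_along(pops)) {
    idx <- which(pick == j)
    if (!length(idx)) next
    fn <- if (pops[[j]]$type == "cylinder") .scatter_cylinder else .scatter_sphere
    res <- fn(u[idx, , drop = FALSE], vr[idx, , drop = FALSE],
              S[idx, , drop = FALSE], pops[[j]])
    u[idx, ] <- res$u; vr[idx, ] <- res$vref; S[idx, ] <- res$S
  }
  packets$direction <- u; packets$reference <- vr; packets$stokes <- S
  packets
}

# rotate detected Stokes rows into the laboratory frame (reference = lab x
# axis projected perpendicular to each exit direction)
.to_lab_frame <- function(u, vref, S) {
  ex <- cbind(1 - u[, 1]^2, -u[, 1] * u[, 2], -u[, 1] * u[, 3])
  ex <- vnormalize(ex)
  rotate_stokes_rows(S, frame_angle(vref, ex, u))
}

.chunk_seed <- function(seed, i) (seed * 48271 + i * 1299721) %% 2147483647

# ---- main driver ----------------------------------------------------------

#' Polarized Monte Carlo transport through the slab
#'
#' Launches \code{n_photons} packets at normal incidence with the given input
#' Stokes state, propagates them with exponential free paths, continuous
#' absorption weighting and Russian roulette, and accumulates the packets that
#' exit the far face within \code{acceptance_half_angle} of the forward
#' normal.  Returns the ensemble mean output Stokes vector in the laboratory
#' frame and the depolarization / retardance metrics relative to the launched
#' state, with batch-based Monte Carlo standard errors.  Fully reproducible
#' given \code{seed}; photons are simulated in chunks with per-chunk RNG
#' substreams so results for the first photons do not depend on the total
#' count.
#'
#' @param model a \code{tissue_model}.
#' @param input_state launched Stokes state (default right-circular).
#' @param n_photons number of packets (>= 1).
#' @param acceptance_half_angle detector acceptance about the forward normal,
#'   radians (default 10 degrees).
#' @param seed integer seed.
#' @param chunk_size photons per RNG substream chunk.
#' @param roulette_threshold weight below which Russian roulette fires
#'   (survival probability 0.1); 0 disables.
#' @param n_batches batches for standard-error estimation.
#' @param keep_exit keep all far-face exit directions/weights (used by
#'   \code{\link{scattering_pattern}}).
#' @return a \code{detector_result} list: counts, mean output Stokes,
#'   \code{dep}, \code{delta} (+ \code{dep_se}, \code{delta_se}), energy
#'   bookkeeping, and optionally the exit records.
#' @export
run_forward <- function(model, input_state = stokes(1, 0, 0, 1),
                        n_photons = 1e4, acceptance_half_angle = 10 * pi / 180,
                        seed = 1, chunk_size = 16384L,
                        roulette_threshold = 1e-4, n_batches = 10L,
                        keep_exit = FALSE) {
  stopifnot(n_photons >= 1)
  s_in <- as.numeric(stokes(as.numeric(input_state)))
  s_in <- s_in / s_in[1]
  pops <- .prepare_populations(model)
  mus <- model$mu_s_um
  mua <- model$mu_a_um
  d <- model$slab_thickness_um
  cos_acc <- cos(acceptance_half_angle)
  n_chunks <- ceiling(n_photons / chunk_size)
  batch_sum <- matrix(0, n_batches, 4)
  batch_n <- numeric(n_batches)
  energy <- c(detected = 0, transmitted = 0, reflected = 0, absorbed = 0,
              terminated = 0, stuck = 0)
  exit_rec <- if (keep_exit) vector("list", n_chunks) else NULL
  launched <- 0
  for (ic in seq_len(n_chunks)) {
    nc <- min(chunk_size, n_photons - (ic - 1L) * chunk_size)
    set.seed(.chunk_seed(seed, ic))
    gidx <- (ic - 1L) * chunk_size + seq_len(nc)   # global photon indices
    z <- numeric(nc)
    u <- matrix(rep(c(0, 0, 1), each = nc), nc)
    vref <- matrix(rep(c(1, 0, 0), each = nc), nc)
    S <- matrix(rep(s_in, each = nc), nc)
    w <- rep(1, nc)
    alive <- rep(TRUE, nc)
    launched <- launched + nc
    iter <- 0L
    while (any(alive)) {
      iter <- iter + 1L
      if (iter > 10000L) { # pathological stragglers
        energy["stuck"] <- energy["stuck"] + sum(w[alive])
        break
      }
      ia <- which(alive)
      na <- length(ia)
      len <- if (mus > 0) stats::rexp(na) / mus else rep(Inf, na)
      uz <- u[ia, 3]
      znew <- z[ia] + uz * len
      out_top <- znew >= d & uz > 0
      out_bot <- znew < 0 & uz < 0
      sideways <- !out_top & !out_bot & !is.finite(len)
      # --- exits ---
      for (top in c(TRUE, FALSE)) {
        sel <- if (top) out_top else out_bot
        if (!any(sel)) next
        ii <- ia[sel]
        lb <- if (top) (d - z[ii]) / u[ii, 3] else -z[ii] / u[ii, 3]
        wexit <- w[ii] * exp(-mua * lb)
        energy["absorbed"] <- energy["absorbed"] + sum(w[ii] - wexit)
        if (top) {
          energy["transmitted"] <- energy["transmitted"] + sum(wexit)
          det <- u[ii, 3] >= cos_acc
          if (any(det)) {
            jj <- ii[det]
            s_lab <- .to_lab_frame(u[jj, , drop = FALSE],
                                   vref[jj, , drop = FALSE],
                                   S[jj, , drop = FALSE])
            b <- factor((gidx[jj] - 1L) %% n_batches + 1L,
                        levels = seq_len(n_batches))
            ws <- s_lab * wexit[det]
            for (k in 1:4) {
              agg <- tapply(ws[, k], b, sum)
              batch_sum[, k] <- batch_sum[, k] + ifelse(is.na(agg), 0, agg)
            }
            batch_n <- batch_n + tabulate(b, n_batches)
            energy["detected"] <- energy["detected"] + sum(wexit[det])
          }
          if (keep_exit) {
            exit_rec[[ic]] <- rbind(exit_rec[[ic]],
                                    cbind(u[ii, , drop = FALSE], wexit))
          }
        } else {
          energy["reflected"] <- energy["reflected"] + sum(wexit)
        }
        alive[ii] <- FALSE
      }
      if (any(sideways)) { # mu_s = 0 and traveling parallel to the faces
        ii <- ia[sideways]
        energy["stuck"] <- energy["stuck"] + sum(w[ii])
        alive[ii] <- FALSE
      }
      # --- interior scattering ---
      ins <- which(alive[ia]) # relative to ia
      ii <- ia[ins]
      if (!length(ii)) next
      wnew <- w[ii] * exp(-mua * len[ins])
      energy["absorbed"] <- energy["absorbed"] + sum(w[ii] - wnew)
      w[ii] <- wnew
      z[ii] <- znew[ins]
      mus_frac <- vapply(model$populations, `[[`, 0, "mu_s_um")
      pick <- sample.int(length(pops), length(ii), replace = TRUE,
                         prob = mus_frac)
      for (j in seq_along(pops)) {
        sel <- which(pick == j)
        if (!length(sel)) next
        kk <- ii[sel]
        fn <- if (pops[[j]]$type == "cylinder") .scatter_cylinder
              else .scatter_sphere
        res <- fn(u[kk, , drop = FALSE], vref[kk, , drop = FALSE],
                  S[kk, , drop = FALSE], pops[[j]])
        u[kk, ] <- res$u; vref[kk, ] <- res$vref; S[kk, ] <- res$S
      }
      # --- Russian roulette ---
      if (roulette_threshold > 0) {
        rr <- which(alive & w < roulette_threshold)
        if (length(rr)) {
          live <- stats::runif(length(rr)) < 0.1
          # net weight removed by roulette: killed weight minus the weight
          # boost of survivors, so the energy balance closes exactly
          energy["terminated"] <- energy["terminated"] + sum(w[rr[!live]]) -
            9 * sum(w[rr[live]])
          alive[rr[!live]] <- FALSE
          w[rr[live]] <- w[rr[live]] / 0.1
        }
      }
    }
  }
  n_det <- sum(batch_n)
  tot <- colSums(batch_sum)
  flagged <- n_det == 0
  if (!flagged) {
    mean_s <- tot / tot[1]
    dep <- depolarization(s_in, mean_s)
    delta <- retardance_angle(s_in, mean_s)
    bs <- batch_sum[batch_n > 0, , drop = FALSE]
    bdep <- apply(bs, 1, function(r) depolarization(s_in, r / r[1]))
    bdel <- apply(bs, 1, function(r) retardance_angle(s_in, r / r[1]))
    nb <- nrow(bs)
    dep_se <- stats::sd(bdep) / sqrt(nb)
    delta_se <- stats::sd(bdel) / sqrt(nb)
  } else {
    mean_s <- rep(NA_real_, 4); dep <- delta <- dep_se <- delta_se <- NA_real_
  }
  structure(list(n_launched = launched, n_detected = n_det,
                 mean_out_stokes = mean_s, dep = as.numeric(dep),
                 delta = delta, dep_se = dep_se, delta_se = delta_se,
                 input_state = s_in,
                 acceptance_half_angle = acceptance_half_angle,
                 energy = energy, flagged = flagged,
                 exit = if (keep_exit) do.call(rbind, exit_rec) else NULL,
                 seed = seed),
            class = "detector_result")
}

#' @export
print.detector_result <- function(x, ...) {
  cat(sprintf("<detector_result> %d / %d detected | dep = %.4f (se %.4f) | delta = %.4f (se %.4f)\n",
              x$n_detected, x$n_launched, x$dep, x$dep_se, x$delta, x$delta_se))
  invisible(x)
}

#' Forward-hemisphere scattering pattern
#'
#' Histogram of far-face exit directions weighted by intensity, over direction
#' cosines (ux, uy), together with an anisotropy metric: the ratio of the
#' second angular moments of the exit directions along and across the mean
#' cylinder axis (projected onto the slab plane).  Aligned cylinders produce
#' strongly anisotropic patterns under linear illumination and isotropic ones
#' under circular illumination.
#'
#' @inheritParams run_forward
#' @param n_bins histogram bins per axis.
#' @param axis in-plane reference axis for the anisotropy metric (defaults to
#'   the mean axis of the first cylinder population, or x).
#' @return list with \code{grid} (n_bins x n_bins intensity), \code{breaks},
#'   \code{anisotropy}, \code{anisotropy_se} (batch-based) and the underlying
#'   \code{detector_result}.
#' @export
scattering_pattern <- function(model, input_state = stokes(1, 0, 0, 1),
                               n_photons = 1e4, seed = 1, n_bins = 41,
                               axis = NULL, ...) {
  res <- run_forward(model, input_state, n_photons, seed = seed,
                     acceptance_half_angle = pi / 2 - 1e-9,
                     keep_exit = TRUE, ...)
  ex <- res$exit
  if (is.null(ex) || nrow(ex) == 0)
    return(list(grid = matrix(0, n_bins, n_bins), breaks = NULL,
                anisotropy = NA_real_, result = res))
  if (is.null(axis)) {
    cyl <- Filter(function(p) p$type == "cylinder", model$populations)
    axis <- if (length(cyl)) cyl[[1]]$mean_axis else c(1, 0, 0)
  }
  a2 <- axis[1:2] / sqrt(sum(axis[1:2]^2))
  br <- seq(-1, 1, length.out = n_bins + 1)
  ix <- cut(ex[, 1], br, labels = FALSE, include.lowest = TRUE)
  iy <- cut(ex[, 2], br, labels = FALSE, include.lowest = TRUE)
  gv <- numeric(n_bins * n_bins)
  agg <- rowsum(ex[, 4], (iy - 1L) * n_bins + ix)
  gv[as.integer(rownames(agg))] <- agg
  grid <- matrix(gv, n_bins, n_bins)
  along <- ex[, 1] * a2[1] + ex[, 2] * a2[2]
  across <- -ex[, 1] * a2[2] + ex[, 2] * a2[1]
  wts <- ex[, 4]
  aniso_of <- function(sel) {
    sum(wts[sel] * along[sel]^2) / sum(wts[sel] * across[sel]^2)
  }
  anis <- aniso_of(rep(TRUE, length(wts)))
  nb <- 10L
  bidx <- (seq_along(wts) - 1L) %% nb + 1L
  banis <- vapply(seq_len(nb), function(b) aniso_of(bidx == b), 0)
  list(grid = grid, breaks = br, anisotropy = anis,
       anisotropy_se = stats::sd(banis) / sqrt(nb), result = res)
}
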