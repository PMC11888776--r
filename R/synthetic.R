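#' Zig-zag scan geometry
#'
#' Serpentine (zig-zag) raster over a rectangular region: points sit at the
#' centers of a step-sized grid, odd rows traversed left-to-right and even
#' rows right-to-left.  The default one-channel geometry is the 3 x 4 mm
#' region at 500 um steps (6 x 8 = 48 points per hemisphere side); the
#' four-channel variant samples 64 points from a 4 x 4 mm region.  The four
#' channels form a 2 x 2 square of spots with \code{channel_offset_um} pitch
#' centered on the nominal point.
#'
#' Coordinates are in um with the origin at the region corner, x rightward
#' and y downward.
#'
#' @param region_mm c(width, height) of the scanned region, mm.
#' @param step_um scan step, um.
#' @param spot_diameter_um illumination spot diameter, um (metadata).
#' @param channel_offset_um pitch between adjacent channel spots, um.
#' @param n_channels 1 or 4.
#' @return a \code{scan_geometry} list with the point table \code{points}
#'   (point_index, x_um, y_um in serpentine order).
#' @export
scan_geometry <- function(region_mm = c(3, 4), step_um = 500,
                          spot_diameter_um = 500, channel_offset_um = 125,
                          n_channels = 4) {
  stopifnot(step_um > 0, all(region_mm > 0), n_channels %in% c(1, 4))
  nx <- round(region_mm[1] * 1000 / step_um)
  ny <- round(region_mm[2] * 1000 / step_um)
  if (nx < 1 || ny < 1) stop("region smaller than one step")
  rows <- lapply(seq_len(ny), function(iy) {
    xs <- (seq_len(nx) - 0.5) * step_um
    if (iy %% 2 == 0) xs <- rev(xs)      # serpentine
    data.frame(x_um = xs, y_um = (iy - 0.5) * step_um)
  })
  pts <- do.call(rbind, rows)
  pts$point_index <- seq_len(nrow(pts))
  off <- channel_offset_um / 2
  ch_off <- data.frame(channel = 1:4,
                       dx_um = c(-off, off, -off, off),
                       dy_um = c(-off, -off, off, off))
  if (n_channels == 1) ch_off <- data.frame(channel = 1, dx_um = 0, dy_um = 0)
  structure(list(region_mm = region_mm, step_um = step_um,
                 spot_diameter_um = spot_diameter_um,
                 channel_offset_um = channel_offset_um,
                 n_channels = n_channels, n_points = nrow(pts),
                 points = pts[, c("point_index", "x_um", "y_um")],
                 channel_offsets = ch_off),
            class = "scan_geometry")
}

#' @rdname scan_geometry
#' @export
geometry_one_channel <- function() scan_geometry(c(3, 4), n_channels = 1)

#' @rdname scan_geometry
#' @export
geometry_four_channel <- function() scan_geometry(c(4, 4), n_channels = 4)

#' Spatial injury field of the ischemic hemisphere
#'
#' Injury severity in [0, 1] with a Gaussian fall-off from the ischemic core:
#' \code{severity(p) = core_severity * exp(-(|p - core| / decay)^2)}.
#' Severity is monotone non-increasing with distance from the core, emulating
#' the core-to-penumbra gradient; the contralateral side always has severity
#' 0.
#'
#' @param core_center_mm position of the ischemic core in region coordinates.
#' @param core_severity peak severity in [0, 1].
#' @param decay_length_mm gradient length scale, mm.
#' @return an \code{injury_field}; call \code{severity_at(field, x_um, y_um)}.
#' @export
injury_field <- function(core_center_mm = c(1.3, 1.6), core_severity = 1,
                         decay_length_mm = 1.4) {
  stopifnot(core_severity >= 0, core_severity <= 1, decay_length_mm > 0)
  structure(list(core_center_mm = core_center_mm,
                 core_severity = core_severity,
                 decay_length_mm = decay_length_mm),
            class = "injury_field")
}

#' @rdname injury_field
#' @param field an \code{injury_field}.
#' @param x_um,y_um positions, um.
#' @export
severity_at <- function(field, x_um, y_um) {
  d2 <- ((x_um / 1000 - field$core_center_mm[1])^2 +
           (y_um / 1000 - field$core_center_mm[2])^2)
  field$core_severity * exp(-d2 / field$decay_length_mm^2)
}

#' Parameters of the parametric scan generator
#'
#' The parametric backend draws (dep, delta) per channel from Gaussians whose
#' means interpolate between the contralateral level and the full-severity
#' ipsilateral level according to the local severity at each channel spot,
#' with compound-symmetric inter-channel correlation.  The level anchors are
#' the package's forward-model endpoints for normal and ischemic tissue
#' (dep 0.14 -> 0.35, delta 0.25 -> 0.33); the spreads (0.05) are calibration
#' choices that place the single-channel classifier near AUC 0.8 under the
#' default injury field — calibration targets, not measured truths.
#'
#' @param dep_contra,delta_contra contralateral means.
#' @param dep_ipsi,delta_ipsi full-severity ipsilateral means.
#' @param dep_sd,delta_sd biological point-to-point spreads.
#' @param channel_cor inter-channel correlation of the biological component
#'   at 125 um spacing, in [-1, 1].
#' @param noise_sd additive per-channel measurement noise.
#' @param backend \code{"parametric"} or \code{"mc_driven"} (run the photon
#'   transport per point on the severity-interpolated tissue model).
#' @param mc_photons photons per point for the MC backend.
#' @return a \code{generator_params} list.
#' @export
generator_params <- function(dep_contra = 0.14, delta_contra = 0.25,
                             dep_ipsi = 0.35, delta_ipsi = 0.33,
                             dep_sd = 0.05, delta_sd = 0.05,
                             channel_cor = 0.5, noise_sd = 0.01,
                             backend = c("parametric", "mc_driven"),
                             mc_photons = 2000) {
  backend <- match.arg(backend)
  stopifnot(dep_sd > 0, delta_sd > 0, channel_cor >= -1, channel_cor <= 1,
            noise_sd >= 0)
  structure(list(dep_contra = dep_contra, delta_contra = delta_contra,
                 dep_ipsi = dep_ipsi, delta_ipsi = delta_ipsi,
                 dep_sd = dep_sd, delta_sd = delta_sd,
                 channel_cor = channel_cor, noise_sd = noise_sd,
                 backend = backend, mc_photons = mc_photons),
            class = "generator_params")
}

# correlated 4-channel deviations: compound symmetry, unit marginal variance
.chol4 <- function(rho) {
  S <- matrix(rho, 4, 4); diag(S) <- 1
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12) stop("invalid inter-channel correlation matrix")
  chol(S + diag(4) * 1e-12)
}

#' Generate a synthetic two-hemisphere scan dataset
#'
#' Emulates one rat: both hemisphere sides are scanned with the same
#' geometry; the ipsilateral side carries the injury field, the contralateral
#' side is statistically identical to severity 0 everywhere.  Each channel
#' spot sees the severity at its own offset position, so the injury gradient
#' induces real inter-channel texture.  Output Stokes vectors are synthesized
#' from the metric pair assuming a right-circular probe beam (the linear
#' component is placed along s1).  Reproducible given \code{seed}; records
#' are returned in serpentine acquisition order.
#'
#' @param geometry a \code{scan_geometry}.
#' @param field an \code{injury_field}.
#' @param params a \code{generator_params}.
#' @param rat_id identifier stored in the records.
#' @param seed integer seed.
#' @return data.frame with columns rat_id, side, point_index, x_um, y_um,
#'   channel, s0..s3, dep, delta.
#' @export
generate_scan <- function(geometry = geometry_four_channel(),
                          field = injury_field(),
                          params = generator_params(),
                          rat_id = "rat1", seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  L <- .chol4(params$channel_cor)
  ch <- geometry$channel_offsets
  nch <- nrow(ch)
  out <- list()
  for (side in c("contra", "ipsi")) {
    pts <- geometry$points
    # channel spot positions and local severities
    xs <- outer(pts$x_um, ch$dx_um, `+`)
    ys <- outer(pts$y_um, ch$dy_um, `+`)
    sev <- if (side == "ipsi") severity_at(field, xs, ys) else xs * 0
    if (params$backend == "parametric") {
      mu_dep <- params$dep_contra + sev * (params$dep_ipsi - params$dep_contra)
      mu_del <- params$delta_contra +
        sev * (params$delta_ipsi - params$delta_contra)
      zd <- matrix(stats::rnorm(nrow(pts) * 4), ncol = 4) %*% L
      zt <- matrix(stats::rnorm(nrow(pts) * 4), ncol = 4) %*% L
      dep <- mu_dep + params$dep_sd * zd[, seq_len(nch), drop = FALSE] +
        stats::rnorm(length(mu_dep), sd = params$noise_sd)
      del <- mu_del + params$delta_sd * zt[, seq_len(nch), drop = FALSE] +
        stats::rnorm(length(mu_del), sd = params$noise_sd)
    } else {
      dep <- del <- matrix(NA_real_, nrow(pts), nch)
      for (i in seq_len(nrow(pts))) for (j in seq_len(nch)) {
        mdl <- interpolate_model(sev[i, j])
        pseed <- ((seed %% 100000) * 10007 +
                    (i * nch + j) * 17 + (side == "ipsi")) %% 2147483647
        r <- run_forward(mdl, n_photons = params$mc_photons, seed = pseed)
        dep[i, j] <- r$dep + stats::rnorm(1, sd = params$noise_sd)
        del[i, j] <- r$delta + stats::rnorm(1, sd = params$noise_sd)
      }
    }
    for (j in seq_len(nch)) {
      dopo <- pmax(0, pmin(1, 1 - dep[, j]))
      out[[length(out) + 1L]] <- data.frame(
        rat_id = rat_id, side = side, point_index = pts$point_index,
        x_um = xs[, j], y_um = ys[, j], channel = ch$channel[j],
        s0 = 1, s1 = dopo * sin(del[, j]), s2 = 0, s3 = dopo * cos(del[, j]),
        dep = dep[, j], delta = del[, j])
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$side, c("contra", "ipsi")), res$point_index,
                   res$channel), ]
  rownames(res) <- NULL
  res
}

#' Simulated polarimeter traces for a list of Stokes vectors
#'
#' Feeds the polarimeter stage: one rotating-retarder trace per input state,
#' with optional additive Gaussian intensity noise.  Noiseless traces
#' round-trip through \code{\link{demodulate}} to the inputs at 1e-10.
#'
#' @param stokes_list list of Stokes vectors (or a single one).
#' @param noise_sd additive intensity noise SD.
#' @param angles retarder angle grid.
#' @return list of \code{polarimeter_trace} objects.
#' @export
generate_trace_dataset <- function(stokes_list, noise_sd = 0,
                                   angles = qwp_angles()) {
  if (!is.list(stokes_list)) stokes_list <- list(stokes_list)
  lapply(stokes_list, forward_trace, angles = angles, noise_sd = noise_sd)
}

#' Write a measurement table as CSV
#'
#' @param records measurement data.frame from \code{\link{generate_scan}}.
#' @param path output CSV path.
#' @export
write_scan_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# save/restore the global RNG state so generators are pure given `seed`
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
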