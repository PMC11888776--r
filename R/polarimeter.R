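#' Retarder angles for a rotating quarter-wave-plate sweep
#'
#' The default acquisition measures intensity every 15 degrees while the wave
#' plate rotates through half a turn.  The grid is half-open: 12 samples at
#' 0, 15, ..., 165 degrees; a 13th sample at 180 degrees would duplicate the
#' one at 0 and bias the discrete Fourier sums.
#'
#' @param n number of samples over the half turn (>= 12 for exact inversion).
#' @param offset angle of the first sample, radians.
#' @return numeric vector of fast-axis angles in radians, strictly increasing.
#' @export
qwp_angles <- function(n = 12, offset = 0) {
  if (n < 12) stop("at least 12 samples are needed to resolve the 4theta harmonic")
  offset + seq(0, pi, length.out = n + 1)[-(n + 1)]
}

#' Forward model of a rotating-retarder Stokes polarimeter
#'
#' Detected intensity when a beam with Stokes vector \code{s} passes a
#' rotating retarder (fast axis \code{angles[k]}, retardance \code{retardance})
#' followed by a fixed linear analyzer:
#' \code{I(theta) = [P(analyzer) . Ret(retardance, theta) . s]_1}.
#' With the analyzer horizontal and a quarter-wave retarder this reduces to the
#' classical form \code{I = (A + B sin 2theta + C cos 4theta + D sin 4theta)/2}
#' with \code{A = s0 + s1/2}, \code{B = -s3}, \code{C = s1/2}, \code{D = s2/2}
#' under this package's sign conventions.
#'
#' @param s input Stokes vector.
#' @param angles retarder fast-axis angles, radians (default the 12-point grid).
#' @param analyzer_axis fixed analyzer orientation, radians.
#' @param retardance retarder retardance, radians (pi/2 nominal; perturb to
#'   model a calibration offset).
#' @param noise_sd additive Gaussian intensity noise (0 = ideal).
#' @param noise one of \code{"gaussian"} or \code{"poisson"}; for Poisson the
#'   trace is treated as mean counts scaled by \code{1/noise_sd^2}.
#' @return a \code{polarimeter_trace}: data.frame with columns \code{angle}
#'   (radians) and \code{intensity}, plus attributes \code{analyzer_axis} and
#'   \code{retardance}.
#' @export
forward_trace <- function(s, angles = qwp_angles(), analyzer_axis = 0,
                          retardance = pi / 2, noise_sd = 0,
                          noise = c("gaussian", "poisson")) {
  noise <- match.arg(noise)
  s <- as.numeric(s)
  pol <- unclass(mueller_linear_polarizer(analyzer_axis))
  intens <- vapply(angles, function(th) {
    (pol %*% (unclass(mueller_retarder(retardance, th)) %*% s))[1]
  }, numeric(1))
  if (noise_sd > 0) {
    intens <- if (noise == "gaussian") {
      intens + stats::rnorm(length(intens), sd = noise_sd)
    } else {
      # shot noise: interpret intensity as mean photon count n0 = I/noise_sd^2
      g <- 1 / noise_sd^2
      stats::rpois(length(intens), lambda = pmax(intens, 0) * g) / g
    }
  }
  polarimeter_trace(angles, intens, analyzer_axis = analyzer_axis,
                    retardance = retardance)
}

#' @rdname forward_trace
#' @param intensities detected intensities matching \code{angles}.
#' @export
polarimeter_trace <- function(angles, intensities, analyzer_axis = 0,
                              retardance = pi / 2) {
  if (length(angles) != length(intensities))
    stop("angles and intensities must have equal length")
  if (is.unsorted(angles, strictly = TRUE))
    stop("retarder angles must be strictly increasing")
  structure(data.frame(angle = angles, intensity = intensities),
            analyzer_axis = analyzer_axis, retardance = retardance,
            class = c("polarimeter_trace", "data.frame"))
}

#' Fourier demodulation of a rotating-retarder trace
#'
#' Computes the discrete Fourier coefficients of the intensity trace at DC,
#' 2theta and 4theta and inverts the closed-form relations to the Stokes
#' vector.  Requires at least 12 equally spaced angles spanning a half turn
#' (anything less aliases the 4theta harmonic).  On noiseless traces the
#' round trip \code{forward_trace |> demodulate} reproduces the input to
#' better than 1e-10.
#'
#' @param trace a \code{polarimeter_trace} (or data.frame with \code{angle},
#'   \code{intensity}).
#' @param retardance retarder retardance used in the inversion, radians.
#' @param analyzer_axis analyzer orientation; defaults to the value stored in
#'   the trace.
#' @return a \code{stokes} vector.
#' @export
demodulate <- function(trace, retardance = NULL, analyzer_axis = NULL) {
  th <- trace$angle
  I <- trace$intensity
  n <- length(th)
  if (n < 12) stop("demodulate: fewer than 12 samples (4theta harmonic aliases)")
  dth <- diff(th)
  if (max(abs(dth - pi / n)) > 1e-9 * pi)
    stop("demodulate: angles must be uniformly spaced over a half turn")
  if (is.null(retardance)) {
    retardance <- attr(trace, "retardance")
    if (is.null(retardance)) retardance <- pi / 2
  }
  if (is.null(analyzer_axis)) {
    analyzer_axis <- attr(trace, "analyzer_axis")
    if (is.null(analyzer_axis)) analyzer_axis <- 0
  }
  # work in the analyzer frame: theta' = theta - a, s' = R(a) s
  psi <- 2 * (th - analyzer_axis)
  a_hat <- 2 * mean(I)
  b_hat <- (4 / n) * sum(I * sin(psi))
  c_hat <- (4 / n) * sum(I * cos(2 * psi))
  d_hat <- (4 / n) * sum(I * sin(2 * psi))
  cr <- cos(retardance); sr <- sin(retardance)
  if (abs(sr) < 1e-12 || abs(1 - cr) < 1e-12)
    stop("demodulate: retardance leaves s3 or the 4theta harmonic unobservable")
  s1 <- 2 * c_hat / (1 - cr)
  s2 <- 2 * d_hat / (1 - cr)
  s3 <- -b_hat / sr
  s0 <- a_hat - s1 * (1 + cr) / 2
  sv <- mueller_apply(mueller_rotator(-analyzer_axis), c(s0, s1, s2, s3))
  structure(as.numeric(sv), class = "stokes")
}

#' Read / write polarimeter traces as CSV
#'
#' Interchange format: columns \code{angle_deg, intensity}; analyzer axis and
#' retardance are carried as commented header lines.
#'
#' @param trace a \code{polarimeter_trace}.
#' @param path CSV file path.
#' @return \code{read_trace_csv} returns a \code{polarimeter_trace}.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# analyzer_axis_deg: %.10g",
                     attr(trace, "analyzer_axis") * 180 / pi), con)
  writeLines(sprintf("# retardance_deg: %.10g",
                     attr(trace, "retardance") * 180 / pi), con)
  writeLines("angle_deg,intensity", con)
  writeLines(sprintf("%.12g,%.12g", trace$angle * 180 / pi, trace$intensity),
             con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(default)
    as.numeric(sub(".*: *", "", m[1])) * pi / 180
  }
  d <- utils::read.csv(text = lines[!grepl("^#", lines)])
  polarimeter_trace(d$angle_deg * pi / 180, d$intensity,
                    analyzer_axis = get("analyzer_axis_deg", 0),
                    retardance = get("retardance_deg", pi / 2))
}
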