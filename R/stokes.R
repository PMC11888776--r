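#' Construct a Stokes vector
#'
#' A Stokes vector \code{(s0, s1, s2, s3)} describes the intensity and
#' polarization state of a beam: \code{s0} is total intensity, \code{s1} the
#' horizontal/vertical linear balance, \code{s2} the +45/-45 linear balance and
#' \code{s3} the circular component.  Throughout this package \code{s3 = +s0}
#' denotes right-circular polarization as seen by an observer looking toward
#' the source.
#'
#' Physical states satisfy \code{s1^2 + s2^2 + s3^2 <= s0^2}.  Vectors coming
#' out of noisy demodulation may violate the bound slightly; by default this is
#' tolerated up to a relative slack of \code{1e-9} and rejected beyond it.
#' With \code{clip = TRUE} a super-physical polarized part is rescaled onto the
#' unit Poincare sphere (DOP = 1) and a message is emitted, so that silent
#' repair never happens.
#'
#' @param s0,s1,s2,s3 numeric components; alternatively pass a length-4 vector
#'   as \code{s0}.
#' @param clip logical; rescale a super-physical polarized part back to
#'   DOP = 1 (off by default, logged when it fires).
#' @param tol relative tolerance on the physicality bound.
#' @return a numeric vector of length 4 with class \code{"stokes"}.
#' @examples
#' stokes(1, 0, 0, 1)     # right-circular
#' stokes(c(1, 1, 0, 0))  # horizontal linear
#' @export
stokes <- function(s0, s1 = NULL, s2 = NULL, s3 = NULL, clip = FALSE,
                   tol = 1e-9) {
  if (is.null(s1)) {
    v <- as.numeric(s0)
    if (length(v) != 4L) stop("a Stokes vector has exactly 4 components")
  } else {
    v <- c(s0, s1, s2, s3)
  }
  if (!all(is.finite(v))) stop("Stokes components must be finite")
  if (v[1] < 0) stop("s0 (total intensity) must be >= 0")
  p2 <- sum(v[2:4]^2)
  if (p2 > v[1]^2 * (1 + tol)) {
    if (clip) {
      message(sprintf(
        "stokes(): clipping super-physical state (DOP = %.6f) to DOP = 1",
        sqrt(p2) / v[1]))
      v[2:4] <- v[2:4] * (v[1] / sqrt(p2))
    } else {
      stop(sprintf(
        "non-physical Stokes vector: DOP = %.6g > 1 (use clip = TRUE to rescale)",
        sqrt(p2) / v[1]))
    }
  }
  structure(v, class = "stokes")
}

#' @export
print.stokes <- function(x, ...) {
  cat(sprintf("<stokes> s0=%.6g s1=%.6g s2=%.6g s3=%.6g (DOP=%.4f)\n",
              x[1], x[2], x[3], x[4],
              if (x[1] > 0) sqrt(sum(x[2:4]^2)) / x[1] else NA_real_))
  invisible(x)
}

#' Degree of polarization
#'
#' \code{DOP = sqrt(s1^2 + s2^2 + s3^2) / s0}: the polarized fraction of the
#' total intensity.
#'
#' @param s Stokes vector (numeric length 4 or \code{stokes}).
#' @return scalar in \code{[0, 1]} for physical states.
#' @export
degree_of_polarization <- function(s) {
  s <- as.numeric(s)
  if (s[1] <= 0) stop("degree_of_polarization: zero or negative intensity")
  sqrt(sum(s[2:4]^2)) / s[1]
}

#' Depolarization metric
#'
#' \code{dep = 1 - DOP_out / DOP_in}, the fractional loss of polarization
#' between the beam entering and leaving the sample.  The raw value is
#' returned: measurement noise can make \code{DOP_out > DOP_in}, in which case
#' \code{dep} is negative and a \code{"flagged"} attribute is set rather than
#' clipping, so that downstream statistics see the real noise.
#'
#' @param s_in,s_out input and output Stokes vectors.
#' @return scalar; \code{attr(, "flagged")} is TRUE when outside \code{[0,1]}.
#' @export
depolarization <- function(s_in, s_out) {
  dop_in <- degree_of_polarization(s_in)
  if (dop_in <= 0) stop("depolarization: unpolarized input (DOP_in = 0)")
  dep <- 1 - degree_of_polarization(s_out) / dop_in
  if (dep < 0 || dep > 1) attr(dep, "flagged") <- TRUE
  dep
}

#' Poincare-sphere retardance angle
#'
#' The angle in \code{[0, pi]} between the polarized parts
#' \code{(s1, s2, s3)} of the input and output states on the Poincare sphere.
#' This is the "retardance" metric used in tissue circular polarimetry; it is
#' an input/output state rotation angle, not a retarder decomposition.
#'
#' @param s_in,s_out input and output Stokes vectors.
#' @return angle in radians.
#' @export
retardance_angle <- function(s_in, s_out) {
  a <- as.numeric(s_in)[2:4]
  b <- as.numeric(s_out)[2:4]
  if (all(a == 0) || all(b == 0))
    stop("retardance_angle: zero polarized part on one side")
  # atan2 form: exact 0 for identical states, accurate at small angles
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  atan2(sqrt(sum(cr^2)), sum(a * b))
}

#' Serialize / deserialize Stokes vectors as JSON
#'
#' Plain-text interchange format: a JSON array \code{[s0, s1, s2, s3]} (or an
#' array of such arrays).
#'
#' @param s a \code{stokes} vector or list of them.
#' @param path file path; if missing, the JSON string is returned.
#' @return \code{stokes_to_json}: JSON string or (invisibly) the path;
#'   \code{stokes_from_json}: a \code{stokes} vector or list of them.
#' @export
stokes_to_json <- function(s, path = NULL) {
  x <- if (is.list(s)) lapply(s, as.numeric) else as.numeric(s)
  txt <- jsonlite::toJSON(x, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' @rdname stokes_to_json
#' @param json JSON string or path to a JSON file.
#' @export
stokes_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  if (is.matrix(x)) return(apply(x, 1, stokes, simplify = FALSE))
  if (is.list(x)) return(lapply(x, stokes))
  stokes(x)
}
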