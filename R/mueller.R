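#' Mueller matrices of ideal polarization elements
#'
#' Standard 4x4 Mueller forms in the (I, Q, U, V) convention of this package
#' (Q > 0 along the reference axis, V > 0 right-circular looking toward the
#' source).  \code{mueller_rotator(theta)} rotates the reference frame by
#' \code{theta} (right-handed about the propagation direction):
#' a beam polarized along the old axis acquires \code{Q' = Q cos 2theta}.
#' Composition is ordinary matrix product, applied left of the Stokes vector.
#'
#' @param theta frame rotation angle, radians.
#' @return 4x4 numeric matrix of class \code{"mueller"}.
#' @export
mueller_rotator <- function(theta) {
  c2 <- cos(2 * theta); s2 <- sin(2 * theta)
  m <- matrix(c(1, 0, 0, 0,
                0, c2, s2, 0,
                0, -s2, c2, 0,
                0, 0, 0, 1), 4, 4, byrow = TRUE)
  structure(m, class = "mueller")
}

#' @rdname mueller_rotator
#' @param ret retardance, radians (pi/2 for a quarter-wave plate).
#' @param fast_axis fast-axis orientation, radians from the reference axis.
#' @export
mueller_retarder <- function(ret, fast_axis = 0) {
  m0 <- matrix(c(1, 0, 0, 0,
                 0, 1, 0, 0,
                 0, 0, cos(ret), sin(ret),
                 0, 0, -sin(ret), cos(ret)), 4, 4, byrow = TRUE)
  m <- unclass(mueller_rotator(-fast_axis)) %*% m0 %*%
    unclass(mueller_rotator(fast_axis))
  structure(m, class = "mueller")
}

#' @rdname mueller_rotator
#' @param axis transmission-axis orientation of the linear polarizer, radians.
#' @export
mueller_linear_polarizer <- function(axis = 0) {
  p0 <- 0.5 * matrix(c(1, 1, 0, 0,
                       1, 1, 0, 0,
                       0, 0, 0, 0,
                       0, 0, 0, 0), 4, 4, byrow = TRUE)
  m <- unclass(mueller_rotator(-axis)) %*% p0 %*%
    unclass(mueller_rotator(axis))
  structure(m, class = "mueller")
}

#' Apply a Mueller matrix to a Stokes vector
#'
#' @param m 4x4 Mueller matrix.
#' @param s Stokes vector (validation of the result is skipped: element
#'   matrices such as polarizers legitimately produce s0 = 0).
#' @return numeric length-4 vector of class \code{"stokes"}.
#' @export
mueller_apply <- function(m, s) {
  v <- as.numeric(unclass(m) %*% as.numeric(s))
  structure(v, class = "stokes")
}

#' Mueller matrix from a 2x2 amplitude (Jones) scattering matrix
#'
#' Given the amplitude relation \code{Epar_s = t1 Epar_i + t4 Eperp_i},
#' \code{Eperp_s = t3 Epar_i + t2 Eperp_i} in the parallel/perpendicular basis
#' of a scattering plane, returns the 16 Mueller elements.  All four inputs
#' may be complex vectors of equal length, in which case each element of the
#' returned list is a vector (used by the vectorized transport code); scalars
#' yield a 4x4 matrix via \code{amplitude_mueller_matrix}.
#'
#' @param t1,t2,t3,t4 complex amplitude elements (co-parallel, co-perpendicular
#'   and the two cross-polarized couplings).
#' @return named list of 16 numeric vectors \code{m11 .. m44}.
#' @export
mueller_from_amplitudes <- function(t1, t2, t3, t4) {
  a11 <- Re(t1 * Conj(t1)); a22 <- Re(t2 * Conj(t2))
  a33 <- Re(t3 * Conj(t3)); a44 <- Re(t4 * Conj(t4))
  t14 <- t1 * Conj(t4); t32 <- t3 * Conj(t2)
  t13 <- t1 * Conj(t3); t42 <- t4 * Conj(t2)
  t12 <- t1 * Conj(t2); t43 <- t4 * Conj(t3)
  list(
    m11 = (a11 + a22 + a33 + a44) / 2,
    m12 = (a11 - a22 + a33 - a44) / 2,
    m13 = Re(t14 + t32),
    m14 = Im(t14 + t32),
    m21 = (a11 + a44 - a33 - a22) / 2,
    m22 = (a11 - a44 - a33 + a22) / 2,
    m23 = Re(t14 - t32),
    m24 = Im(t14 - t32),
    m31 = Re(t13 + t42),
    m32 = Re(t13 - t42),
    m33 = Re(t12 + t43),
    m34 = Im(t12 - t43),
    m41 = -Im(t13 + t42),
    m42 = -Im(t13 - t42),
    m43 = -Im(t12 + t43),
    m44 = Re(t12 - t43)
  )
}

#' @rdname mueller_from_amplitudes
#' @export
amplitude_mueller_matrix <- function(t1, t2, t3, t4) {
  e <- mueller_from_amplitudes(t1[1], t2[1], t3[1], t4[1])
  m <- matrix(unlist(e), 4, 4, byrow = TRUE)
  structure(m, class = "mueller")
}

# Apply Mueller elements (lists of vectors, one entry per photon) to a matrix
# of Stokes rows. Internal hot path of the transport code.
mueller_apply_rows <- function(e, s) {
  cbind(e$m11 * s[, 1] + e$m12 * s[, 2] + e$m13 * s[, 3] + e$m14 * s[, 4],
        e$m21 * s[, 1] + e$m22 * s[, 2] + e$m23 * s[, 3] + e$m24 * s[, 4],
        e$m31 * s[, 1] + e$m32 * s[, 2] + e$m33 * s[, 3] + e$m34 * s[, 4],
        e$m41 * s[, 1] + e$m42 * s[, 2] + e$m43 * s[, 3] + e$m44 * s[, 4])
}

# Frame rotation of Stokes rows by per-photon angles (vectorized rotator).
rotate_stokes_rows <- function(s, psi) {
  c2 <- cos(2 * psi); s2 <- sin(2 * psi)
  cbind(s[, 1],
        c2 * s[, 2] + s2 * s[, 3],
        -s2 * s[, 2] + c2 * s[, 3],
        s[, 4])
}
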