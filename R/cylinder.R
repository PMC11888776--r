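#' Scattering coefficients of an obliquely illuminated infinite cylinder
#'
#' Classical Bessel-series solution for a plane wave striking an infinitely
#' long homogeneous dielectric cylinder.  \code{zeta} is the angle between the
#' propagation direction and the cylinder axis, so \code{zeta = pi/2} is
#' perpendicular (normal) incidence.  Scattered directions lie on the cone of
#' half-angle \code{zeta} about the axis; the azimuthal position on the cone is
#' the scattering angle \code{Theta} (\code{Theta = 0} forward).
#'
#' The returned coefficient sets follow the usual case-I (E parallel to the
#' axis/incidence plane) and case-II (E perpendicular) decomposition:
#' \code{bI}, \code{aI} for case I and \code{aII}, \code{bII} for case II,
#' each a complex vector over harmonic order \code{n = 0 .. nmax} with
#' \code{nmax = ceiling(x + 4 x^(1/3) + 2)}.  At perpendicular incidence the
#' cross coefficients \code{aI}, \code{bII} vanish identically.
#'
#' All arguments may be vectors (recycled to a common length); the result
#' matrices then have one row per input, which is what the vectorized photon
#' transport uses.
#'
#' @param zeta incidence angle from the cylinder axis, radians in (0, pi/2].
#' @param x size parameter \code{2 pi a n_medium / lambda}, > 0.
#' @param m relative refractive index (cylinder / medium).
#' @return list of complex matrices \code{bI, aI, aII, bII}
#'   (\code{length(zeta)} x \code{nmax + 1}), plus \code{nmax}.
#' @export
cylinder_coefficients <- function(zeta, x, m, nmax = NULL) {
  if (any(x <= 0)) stop("size parameter must be > 0")
  if (any(zeta <= 0 | zeta > pi / 2 + 1e-12))
    stop("incidence angle zeta must lie in (0, pi/2]")
  if (is.null(nmax)) nmax <- ceiling(max(x) + 4 * max(x)^(1 / 3) + 2)
  k <- max(length(zeta), length(x), length(m))
  zeta <- rep_len(zeta, k); x <- rep_len(x, k); m <- rep_len(m, k)
  cz <- cos(zeta); sz <- sin(zeta)
  xi <- x * sz
  eta <- x * sqrt(m^2 - cz^2)
  nn <- nmax + 2  # need orders 0 .. nmax+1 for derivatives
  Jxi <- matrix(0, k, nn); Jeta <- matrix(0, k, nn); Yxi <- matrix(0, k, nn)
  for (n in 0:(nn - 1)) {
    Jxi[, n + 1] <- besselJ(xi, n)
    Jeta[, n + 1] <- besselJ(eta, n)
    Yxi[, n + 1] <- besselY(xi, n)
  }
  Hxi <- matrix(complex(real = Jxi, imaginary = Yxi), k, nn)
  idx <- seq_len(nmax + 1)                 # orders 0..nmax
  ns <- matrix(rep(0:nmax, each = k), k)
  # derivatives: f'_n = (f_{n-1} - f_{n+1})/2 with f_{-1} = -f_1
  deriv <- function(f) {
    lower <- cbind(-f[, 2, drop = FALSE], f[, idx[-length(idx)], drop = FALSE])
    (lower - f[, idx + 1, drop = FALSE]) / 2
  }
  dJxi <- deriv(Jxi); dJeta <- deriv(Jeta); dHxi <- deriv(Hxi)
  Jxi <- Jxi[, idx, drop = FALSE]; Jeta <- Jeta[, idx, drop = FALSE]
  Hxi <- Hxi[, idx, drop = FALSE]
  An <- 1i * xi * (xi * dJeta * Jxi - eta * Jeta * dJxi)
  Bn <- xi * (m^2 * xi * dJeta * Jxi - eta * Jeta * dJxi)
  Cn <- ns * cz * eta * Jeta * Jxi * (xi^2 / eta^2 - 1)
  Dn <- ns * cz * eta * Jeta * Hxi * (xi^2 / eta^2 - 1)
  Vn <- xi * (m^2 * xi * dJeta * Hxi - eta * Jeta * dHxi)
  Wn <- 1i * xi * (eta * Jeta * dHxi - xi * dJeta * Hxi)
  den <- Wn * Vn + 1i * Dn^2
  if (any(!is.finite(Mod(den))) || any(Mod(den) == 0))
    stop("cylinder series did not converge (pathological parameters)")
  list(bI = (Wn * Bn + 1i * Dn * Cn) / den,
       aI = (Cn * Vn - Bn * Dn) / den,
       aII = -(An * Vn - 1i * Cn * Dn) / den,
       bII = -1i * (Cn * Wn + An * Dn) / den,
       nmax = nmax)
}

#' Amplitude-matrix elements of the infinite cylinder
#'
#' Evaluates the four scattering amplitudes \code{T1} (parallel-parallel),
#' \code{T2} (perpendicular-perpendicular) and the cross couplings \code{T3},
#' \code{T4} at azimuthal scattering angle(s) \code{Theta} on the cone.  The
#' parallel direction is taken in the plane containing the cylinder axis and
#' the respective (incident or scattered) propagation direction.
#'
#' @param Theta azimuthal scattering angle(s), radians (0 = forward).
#' @inheritParams cylinder_coefficients
#' @param coef optional precomputed \code{cylinder_coefficients}; when given
#'   with k rows, \code{Theta} must have length k (one angle per row) unless
#'   k = 1.
#' @return list of complex vectors/matrices \code{T1, T2, T3, T4}.
#' @export
cylinder_amplitudes <- function(Theta, zeta = pi / 2, x, m, coef = NULL) {
  if (is.null(coef)) coef <- cylinder_coefficients(zeta, x, m)
  k <- nrow(coef$bI)
  n <- 0:coef$nmax
  if (k == 1L) {
    # one coefficient row, many angles; harmonic symmetry collapses the
    # two-sided sums to cosine (co-polarized) and sine (cross) series
    w <- c(1, rep(2, coef$nmax))
    ws <- c(0, rep(2, coef$nmax))
    Cn <- cos(outer(Theta, n))
    Sn <- sin(outer(Theta, n))
    T1 <- as.vector(Cn %*% (w * as.vector(coef$bI)))
    T2 <- as.vector(Cn %*% (w * as.vector(coef$aII)))
    T3 <- -1i * as.vector(Sn %*% (ws * as.vector(coef$aI)))
    T4 <- -1i * as.vector(Sn %*% (ws * as.vector(coef$bII)))
  } else {
    if (length(Theta) != k) stop("need one Theta per coefficient row")
    # per-photon angles: accumulate over harmonic order with Chebyshev
    # recurrences for cos(n Theta), sin(n Theta) (hot path of the transport)
    c1 <- cos(Theta); s1 <- sin(Theta)
    cn1 <- rep(1, k); sn1 <- rep(0, k)   # n - 1 terms
    cn <- c1; sn <- s1                   # current n terms
    T1 <- coef$bI[, 1]; T2 <- coef$aII[, 1]
    T3 <- complex(k); T4 <- complex(k)
    for (nn in seq_len(coef$nmax)) {
      T1 <- T1 + 2 * coef$bI[, nn + 1] * cn
      T2 <- T2 + 2 * coef$aII[, nn + 1] * cn
      T3 <- T3 + 2 * coef$aI[, nn + 1] * sn
      T4 <- T4 + 2 * coef$bII[, nn + 1] * sn
      cnew <- 2 * c1 * cn - cn1; snew <- 2 * c1 * sn - sn1
      cn1 <- cn; sn1 <- sn; cn <- cnew; sn <- snew
    }
    T3 <- -1i * T3; T4 <- -1i * T4
  }
  list(T1 = T1, T2 = T2, T3 = T3, T4 = T4)
}

#' Single-scattering Mueller matrix of the cylinder
#'
#' @inheritParams cylinder_amplitudes
#' @return 4x4 \code{mueller} matrix at the first \code{Theta}.
#' @export
cylinder_mueller <- function(Theta, zeta = pi / 2, x, m) {
  amp <- cylinder_amplitudes(Theta[1], zeta, x, m)
  amplitude_mueller_matrix(amp$T1, amp$T2, amp$T3, amp$T4)
}

#' Cylinder scattering and extinction efficiencies
#'
#' Efficiencies per unit length, normalized by the geometric width \code{2a}:
#' \code{qext} from the forward amplitude (optical theorem) and \code{qsca}
#' from the term-by-term coefficient sums, for each polarization case and
#' their unpolarized mean.  For a non-absorbing cylinder the two agree, which
#' the tests use as an internal consistency oracle.
#'
#' @inheritParams cylinder_coefficients
#' @return list with \code{qext_I, qsca_I, qext_II, qsca_II, qext, qsca}.
#' @export
cylinder_efficiencies <- function(zeta, x, m) {
  cf <- cylinder_coefficients(zeta, x, m)
  w <- c(1, rep(2, cf$nmax))
  qext_I <- (2 / x) * Re(sum(w * cf$bI))
  qext_II <- (2 / x) * Re(sum(w * cf$aII))
  qsca_I <- (2 / x) * sum(w * (Mod(cf$bI)^2 + Mod(cf$aI)^2))
  qsca_II <- (2 / x) * sum(w * (Mod(cf$aII)^2 + Mod(cf$bII)^2))
  list(qext_I = qext_I, qsca_I = qsca_I,
       qext_II = qext_II, qsca_II = qsca_II,
       qext = (qext_I + qext_II) / 2, qsca = (qsca_I + qsca_II) / 2)
}
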