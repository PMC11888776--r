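#' Mie scattering series for a homogeneous sphere
#'
#' Standard Lorenz-Mie solution used for the quasi-spherical background
#' scatterers of the tissue model (organelles, membranous debris).  The series
#' is truncated at the Wiscombe-style order \code{ceiling(x + 4 x^(1/3) + 2)}.
#'
#' @param x size parameter \code{2 pi a n_medium / lambda} (dimensionless, > 0).
#' @param m relative refractive index (sphere / medium), real.
#' @return \code{mie_coefficients}: list with complex vectors \code{a}, \code{b}
#'   of length \code{nmax}.
#' @export
mie_coefficients <- function(x, m) {
  if (x <= 0) stop("size parameter must be > 0")
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  # logarithmic derivative D_n(mx) by downward recurrence
  mx <- m * x
  nd <- max(nmax + 15, ceiling(abs(mx)) + 15)
  D <- numeric(nd + 1)
  for (n in nd:1) D[n] <- n / mx - 1 / (D[n + 1] + n / mx)
  # Riccati-Bessel psi, chi by upward recurrence
  psi <- numeric(nmax + 1); chi <- numeric(nmax + 1)
  psi0 <- sin(x); chi0 <- cos(x)
  psi[1] <- sin(x) / x - cos(x)       # psi_1
  chi[1] <- cos(x) / x + sin(x)       # chi_1
  if (nmax >= 2) {
    for (n in 2:nmax) {
      psi[n] <- (2 * n - 1) / x * psi[n - 1] - (if (n == 2) psi0 else psi[n - 2])
      chi[n] <- (2 * n - 1) / x * chi[n - 1] - (if (n == 2) chi0 else chi[n - 2])
    }
  }
  psi <- c(psi0, psi)[1:(nmax + 1)]   # psi_0 .. psi_nmax
  chi <- c(chi0, chi)[1:(nmax + 1)]
  xi <- complex(real = psi, imaginary = -chi)
  n <- seq_len(nmax)
  psin <- psi[n + 1]; psin1 <- psi[n]
  xin <- xi[n + 1]; xin1 <- xi[n]
  Dn <- D[n + 1]  # slot k of the downward recurrence holds D_{k-1}(mx)
  fa <- Dn / m + n / x
  fb <- Dn * m + n / x
  a <- (fa * psin - psin1) / (fa * xin - xin1)
  b <- (fb * psin - psin1) / (fb * xin - xin1)
  list(a = a, b = b, nmax = nmax, x = x, m = m)
}

#' @rdname mie_coefficients
#' @param theta scattering angle(s), radians in \code{[0, pi]}.
#' @param coef optional precomputed \code{mie_coefficients(x, m)}.
#' @return \code{mie_amplitudes}: list with complex vectors \code{S1}
#'   (perpendicular) and \code{S2} (parallel) at each \code{theta}.
#' @export
mie_amplitudes <- function(theta, x, m, coef = NULL) {
  if (is.null(coef)) coef <- mie_coefficients(x, m)
  nmax <- coef$nmax
  mu <- cos(theta)
  S1 <- complex(length(mu)); S2 <- complex(length(mu))
  pi0 <- rep(0, length(mu)); pi1 <- rep(1, length(mu))
  for (n in seq_len(nmax)) {
    tau <- n * mu * pi1 - (n + 1) * pi0
    f <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + f * (coef$a[n] * pi1 + coef$b[n] * tau)
    S2 <- S2 + f * (coef$a[n] * tau + coef$b[n] * pi1)
    pin <- ((2 * n + 1) * mu * pi1 - (n + 1) * pi0) / n
    pi0 <- pi1; pi1 <- pin
  }
  list(S1 = S1, S2 = S2)
}

#' Single-scattering Mueller matrix of a sphere
#'
#' Assembled from the Mie amplitudes in the scattering-plane basis
#' (parallel = in-plane).  Off-diagonal polarization mixing vanishes at
#' \code{theta = 0} by forward symmetry.
#'
#' @inheritParams mie_amplitudes
#' @return 4x4 \code{mueller} matrix (single angle) .
#' @export
sphere_mueller <- function(theta, x, m, coef = NULL) {
  amp <- mie_amplitudes(theta[1], x, m, coef)
  amplitude_mueller_matrix(amp$S2, amp$S1, 0 + 0i, 0 + 0i)
}

#' Mie efficiencies
#'
#' @inheritParams mie_coefficients
#' @return list with \code{qext}, \code{qsca} and asymmetry parameter \code{g}.
#' @export
mie_efficiencies <- function(x, m) {
  cf <- mie_coefficients(x, m)
  n <- seq_len(cf$nmax)
  qext <- (2 / x^2) * sum((2 * n + 1) * Re(cf$a + cf$b))
  qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(cf$a)^2 + Mod(cf$b)^2))
  a <- cf$a; b <- cf$b
  a1 <- c(a[-1], 0); b1 <- c(b[-1], 0)
  g <- (4 / (x^2 * qsca)) *
    sum(n * (n + 2) / (n + 1) * Re(a * Conj(a1) + b * Conj(b1)) +
          (2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  list(qext = qext, qsca = qsca, g = g)
}
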