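## Analytic complex Lindhard response of the homogeneous electron gas.
## This is the closed-form oracle against which the discrete chi0 of a
## jellium model is checked; it is never used inside the response code.

#' Complex Lindhard density-density response function
#'
#' Closed form of the T = 0 non-interacting response of the homogeneous
#' electron gas at complex frequency `z = E + i eta` (hartree atomic
#' units, spin-degenerate):
#' \deqn{\chi^0(q, z) = \frac{J(z - q^2/2) - J(z + q^2/2)}{2 \pi^2 q^3},
#'   \quad J(a) = a T + \frac{T^2 - a^2}{2}
#'   \ln\frac{a + T}{a - T}, \quad T = k_F q.}
#' Static small-q limit: `-k_F / pi^2` (minus the density of states at the
#' Fermi level).
#'
#' @param q momentum transfer magnitude (a.u., > 0).
#' @param energy energy loss E in eV (vectorised).
#' @param eta broadening in eV (> 0).
#' @param density electron density (per cubic bohr); `kf` overrides it.
#' @param kf Fermi momentum (a.u.), default computed from `density`.
#' @return complex vector, chi0 per unit volume in atomic units.
#' @export
#' @examples
#' kf <- (9 * pi / 4)^(1 / 3) / 2    # r_s = 2
#' lindhard_chi0(0.5, energy = 10, eta = 0.3, kf = kf)
lindhard_chi0 <- function(q, energy, eta, density = NULL, kf = NULL) {
  stopifnot(q > 0, eta > 0)
  if (is.null(kf)) {
    if (is.null(density)) stop("supply `density` or `kf`")
    kf <- (3 * pi^2 * density)^(1 / 3)
  }
  z <- complex(real = ev_to_ha(energy), imaginary = ev_to_ha(eta))
  tt <- kf * q
  J <- function(a) a * tt + ((tt^2 - a^2) / 2) * log((a + tt) / (a - tt))
  (J(z - q^2 / 2) - J(z + q^2 / 2)) / (2 * pi^2 * q^3)
}

#' Analytic RPA energy loss function of the electron gas
#'
#' ELF computed from the closed-form Lindhard response through the scalar
#' RPA screening `chi = chi0 / (1 - v_q chi0)`, `v_q = 4 pi / q^2`:
#' `ELF = -(4 pi / q^2) Im chi`.  Used as the oracle for the jellium ELF.
#'
#' @inheritParams lindhard_chi0
#' @return numeric vector of ELF values (dimensionless).
#' @export
lindhard_elf <- function(q, energy, eta, density = NULL, kf = NULL) {
  chi0 <- lindhard_chi0(q, energy, eta, density = density, kf = kf)
  vq <- 4 * pi / q^2
  -vq * Im(chi0 / (1 - vq * chi0))
}
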