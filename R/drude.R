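## Parametric Drude-type ELF surfaces: damped-oscillator stand-ins for
## measured or ab initio energy loss functions.

#' Set of Drude oscillator peaks
#'
#' Each peak contributes
#' `A_i * gamma_i * E / ((E^2 - E_i(q)^2)^2 + gamma_i^2 E^2)` to the ELF.
#' The normalisation `int_0^Inf E * ELF_i dE = pi/2 * A_i` holds exactly
#' for every position and width, so the weight `A_i` is the squared plasma
#' frequency (eV^2) carried by peak i and the total weight fixes the f-sum
#' rule of the surface.
#'
#' @param position peak positions E_i at q = 0 (eV, > 0).
#' @param width damping widths gamma_i (eV, > 0).
#' @param weight oscillator weights A_i = omega_{p,i}^2 (eV^2, > 0).
#' @param dispersion `"none"` for q-independent peaks or `"quadratic"` for
#'   the free-electron ridge `E_i(q) = E_i + q^2/2` (q in a.u., the shift
#'   converted to eV).
#' @return An object of class `drude_peaks`.
#' @export
#' @examples
#' drude_peaks(21.4, 10, 450, dispersion = "quadratic")
drude_peaks <- function(position, width, weight,
                        dispersion = c("none", "quadratic")) {
  dispersion <- match.arg(dispersion)
  n <- length(position)
  stopifnot(length(width) == n, length(weight) == n,
            all(position > 0), all(width > 0), all(weight > 0))
  structure(list(position = as.numeric(position),
                 width = as.numeric(width),
                 weight = as.numeric(weight),
                 dispersion = dispersion),
            class = "drude_peaks")
}

#' @export
print.drude_peaks <- function(x, ...) {
  cat(sprintf("<drude_peaks: %d peak(s), dispersion = %s>\n",
              length(x$position), x$dispersion))
  for (i in seq_along(x$position))
    cat(sprintf("  E = %.2f eV, gamma = %.2f eV, weight = %.2f eV^2\n",
                x$position[i], x$width[i], x$weight[i]))
  cat(sprintf("  total weight (omega_p^2) = %.2f eV^2  (omega_p = %.2f eV)\n",
              sum(x$weight), sqrt(sum(x$weight))))
  invisible(x)
}

#' Build a Drude ELF surface on an (E, q) grid
#'
#' @param peaks a [drude_peaks()] set.
#' @param energy_grid energy losses in eV (uniform spacing).
#' @param q_grid momentum transfers in a.u.
#' @param optical_q optical-limit marker, default the smallest grid q.
#' @return An [elf_surface()].
#' @export
#' @examples
#' s <- make_drude_elf(drude_peaks(21.4, 10, 450),
#'                     energy_grid = seq(0.15, 150, by = 0.15),
#'                     q_grid = seq(0.1, 2, length.out = 20))
#' range(elf_fsum(s)) / (pi / 2)   # ~ 450 at every q
make_drude_elf <- function(peaks, energy_grid, q_grid,
                           optical_q = min(q_grid)) {
  stopifnot(inherits(peaks, "drude_peaks"))
  energy_grid <- as.numeric(energy_grid)
  q_grid <- as.numeric(q_grid)
  vals <- matrix(0, length(energy_grid), length(q_grid))
  for (i in seq_along(peaks$position)) {
    ei0 <- peaks$position[i]
    g <- peaks$width[i]
    a <- peaks$weight[i]
    for (j in seq_along(q_grid)) {
      eiq <- if (peaks$dispersion == "quadratic")
        ei0 + ha_to_ev(q_grid[j]^2 / 2) else ei0
      vals[, j] <- vals[, j] +
        a * g * energy_grid /
        ((energy_grid^2 - eiq^2)^2 + g^2 * energy_grid^2)
    }
  }
  elf_surface(energy_grid, q_grid, vals, optical_q = optical_q,
              provenance = list(generator = "make_drude_elf",
                                dispersion = peaks$dispersion,
                                total_weight = sum(peaks$weight)))
}
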