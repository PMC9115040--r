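## Born-approximation inelastic observables from an ELF surface:
## DDCS, SDCS, total inelastic cross section / IMFP, stopping power,
## and per-molecular-orbital channel SDCS.

#' Kinematic integration limits of the momentum-transfer integral
#'
#' Momentum conservation for an incident electron of kinetic energy T
#' losing energy E:
#' `q_min/max = sqrt(2m) (sqrt(T) -/+ sqrt(T - E))` in atomic units
#' (m = 1).  The closed forms satisfy `q_min * q_max = 2 m E` identically.
#'
#' @param T incident kinetic energy (eV, scalar).
#' @param E energy loss (eV), vectorised; must satisfy `0 <= E <= T`.
#' @return An object of class `kinematic_limits`: data frame with columns
#'   `T`, `E` (eV) and `q_min`, `q_max` (a.u.).
#' @export
#' @examples
#' kinematic_limits(100, c(0, 10, 50, 100))
kinematic_limits <- function(T, E) {
  stopifnot(length(T) == 1, T > 0)
  if (any(E < 0) || any(E > T + 1e-12))
    stop("energy loss must satisfy 0 <= E <= T")
  t_au <- ev_to_ha(T)
  e_au <- ev_to_ha(pmin(E, T))
  root <- sqrt(pmax(t_au - e_au, 0))
  q_max <- sqrt(2) * (sqrt(t_au) + root)
  ## q_min through the product identity q_min q_max = 2 m E: algebraically
  ## identical to sqrt(2)(sqrt(T) - sqrt(T - E)) but free of cancellation
  out <- data.frame(T = T, E = E,
                    q_min = 2 * e_au / q_max,
                    q_max = q_max)
  class(out) <- c("kinematic_limits", "data.frame")
  out
}

#' Double-differential inelastic cross section
#'
#' `d2S / (dE dq) = ELF(E, q) / (pi a0 T q)` (plane-wave Born
#' approximation).  Returned per nanometre of path, per eV of energy loss
#' and per atomic unit of momentum transfer.
#'
#' @param elf an [elf_surface()].
#' @param T incident kinetic energy (eV).
#' @param E energy loss (eV), vectorised.
#' @param q momentum transfer (a.u.), vectorised with `E`.
#' @return numeric vector, units 1/(nm eV a.u.).
#' @export
ddcs <- function(elf, T, E, q) {
  stopifnot(T > 0, all(q > 0))
  vals <- as.numeric(elf_lookup(elf, E, q))
  au <- vals / (pi * ev_to_ha(T) * q)
  au / (.BOHR_NM * .HA_EV)
}

## trapezoid weights for arbitrary increasing nodes
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

## Evaluate SDCS integrand columns for a list of surfaces under the shared
## extrapolation policy: inside the tabulated q range every surface is
## interpolated bilinearly; beyond it the first surface (the total) is
## extended log-log and the extension is distributed over the remaining
## surfaces in proportion to their share of the total at the last tabulated
## q.  With a single surface this reduces to the plain policy.
.sdcs_matrix <- function(surfaces, T, energy_grid, n_q) {
  tot <- surfaces[[1]]
  nE <- length(energy_grid)
  ns <- length(surfaces)
  out <- matrix(0, nE, ns)
  extrap_frac <- numeric(nE)
  t_au <- ev_to_ha(T)
  qg_max <- max(tot$q_grid)
  for (ie in seq_len(nE)) {
    E <- energy_grid[ie]
    if (E <= 0 || E >= T) next
    kl <- kinematic_limits(T, E)
    if (kl$q_max <= kl$q_min) next
    x <- seq(log(kl$q_min), log(kl$q_max), length.out = n_q)
    qn <- exp(x)
    inside <- qn <= qg_max + 1e-12
    ftot <- elf_lookup(tot, rep(E, n_q), qn)
    vals <- matrix(0, n_q, ns)
    vals[, 1] <- ftot
    if (ns > 1) {
      if (any(inside))
        for (s in 2:ns)
          vals[inside, s] <- elf_lookup(surfaces[[s]], rep(E, sum(inside)),
                                        qn[inside])
      if (any(!inside)) {
        last_tot <- elf_lookup(tot, E, qg_max)
        for (s in 2:ns) {
          f_s <- if (last_tot > 0)
            elf_lookup(surfaces[[s]], E, qg_max) / last_tot else 0
          vals[!inside, s] <- f_s * ftot[!inside]
        }
      }
    }
    ## d Sigma / dE = (1/(pi a0 T)) int ELF(E, q) dlnq   (a0 = 1 a.u.)
    ints <- apply(vals, 2, function(y) .trapz(x, y))
    out[ie, ] <- ints / (pi * t_au) / (.BOHR_NM * .HA_EV)
    if (any(!inside) && ints[1] > 0) {
      y <- ftot; y[inside] <- 0
      extrap_frac[ie] <- .trapz(x, y) / .trapz(x, ftot)
    }
  }
  attr(out, "extrap_frac") <- extrap_frac
  out
}

#' Single-differential inelastic cross section
#'
#' `dSigma/dE (E; T) = (1/(pi a0 T)) int_{q_min}^{q_max} ELF(E, q) / q dq`,
#' integrated by the trapezoidal rule on a logarithmic q grid between the
#' kinematic limits.  Grid energies above T are excluded with a warning.
#'
#' @param elf an [elf_surface()].
#' @param T incident kinetic energy (eV).
#' @param energy_grid energy losses at which to evaluate (eV); defaults to
#'   the surface's native grid.
#' @param n_q number of logarithmic quadrature nodes in q (default 200).
#' @return data frame of class `sdcs_curve` with columns `energy` (eV),
#'   `value` (1/(nm eV)) and `extrap_frac` (fraction of the q integral
#'   obtained beyond the tabulated q range); attribute `T`.
#' @export
#' @examples
#' s <- make_drude_elf(drude_peaks(21.4, 10, 450),
#'                     seq(0.5, 200, by = 0.5), seq(0.1, 3, length.out = 15))
#' head(sdcs(s, T = 100))
sdcs <- function(elf, T, energy_grid = elf$energy_grid, n_q = 200) {
  stopifnot(T > 0)
  drop_n <- sum(energy_grid > T)
  if (drop_n > 0) {
    warning(sprintf("%d energy grid point(s) above T = %g eV excluded",
                    drop_n, T))
    energy_grid <- energy_grid[energy_grid <= T]
  }
  m <- .sdcs_matrix(list(elf), T, energy_grid, n_q)
  out <- data.frame(energy = energy_grid, value = m[, 1],
                    extrap_frac = attr(m, "extrap_frac"))
  attr(out, "T") <- T
  attr(out, "units") <- "1/(nm eV)"
  class(out) <- c("sdcs_curve", "data.frame")
  out
}

## maximum energy loss: E_max = min[(T + E_gap)/2, T - E_F]
.e_max <- function(T, E_gap, E_F) pmin((T + E_gap) / 2, T - E_F)

.xs_one <- function(elf, T, emin, emax, n_q, energy_nodes) {
  if (emax <= emin) return(c(sigma = 0, stopping = 0, extrap = 0))
  if (is.null(energy_nodes)) {
    inner <- elf$energy_grid[elf$energy_grid > emin & elf$energy_grid < emax]
    nodes <- unique(sort(c(emin, inner, emax)))
  } else {
    nodes <- unique(sort(pmin(pmax(energy_nodes, emin), emax)))
    if (length(nodes) < 2) return(c(sigma = 0, stopping = 0, extrap = 0))
  }
  m <- .sdcs_matrix(list(elf), T, nodes, n_q)
  v <- m[, 1]
  sig <- .trapz(nodes, v)
  stp <- .trapz(nodes, nodes * v)
  ef <- attr(m, "extrap_frac")
  wext <- if (sig > 0) .trapz(nodes, v * ef) / sig else 0
  c(sigma = sig, stopping = stp, extrap = wext)
}

## shared driver returning the full per-T table
.xs_table <- function(elf, T_grid, emin_mode, E_gap, E_F, n_q, energy_nodes) {
  emin_mode <- match.arg(emin_mode, c("zero", "gap"))
  stopifnot(all(T_grid > 0))
  emin <- if (emin_mode == "gap") E_gap else 0
  rows <- t(vapply(T_grid, function(T)
    .xs_one(elf, T, emin, .e_max(T, E_gap, E_F), n_q, energy_nodes),
    c(sigma = 0, stopping = 0, extrap = 0)))
  out <- data.frame(T = T_grid,
                    sigma_total = rows[, "sigma"],
                    imfp = ifelse(rows[, "sigma"] > 0,
                                  1 / rows[, "sigma"], Inf),
                    stopping = rows[, "stopping"],
                    extrap_frac = rows[, "extrap"])
  attr(out, "emin_mode") <- emin_mode
  attr(out, "E_gap") <- E_gap
  attr(out, "E_F") <- E_F
  attr(out, "units") <- c(sigma_total = "1/nm", imfp = "nm",
                          stopping = "eV/nm")
  attr(out, "imfp_infinite") <- any(rows[, "sigma"] == 0)
  class(out) <- c("xs_table", "data.frame")
  out
}

#' Total inelastic cross section and inelastic mean free path
#'
#' `Sigma(T) = int_{E_min}^{E_max} dSigma/dE dE` with
#' `E_max = min[(T + E_gap)/2, T - E_F]`; the inverse of `Sigma` is the
#' IMFP.  `Sigma` is expressed per unit path length (1/nm), folding the
#' target density that the ELF already carries.
#'
#' @param elf an [elf_surface()].
#' @param T_grid incident kinetic energies (eV).
#' @param emin_mode `"zero"` (default; excitations are allowed below the
#'   gap threshold) or `"gap"` (`E_min = E_gap`).
#' @param E_gap,E_F band gap and Fermi energy of the target (eV), used by
#'   the `E_max` convention and by `emin_mode = "gap"`.
#' @param n_q logarithmic quadrature nodes in q.
#' @param energy_nodes optional override of the energy-integration nodes
#'   (eV); default is the surface's native grid restricted to the limits.
#' @return data frame of class `xs_table` with columns `T`, `sigma_total`
#'   (1/nm), `imfp` (nm), `stopping` (eV/nm), `extrap_frac`.  When
#'   `Sigma = 0` the IMFP is reported as `Inf` and the attribute
#'   `imfp_infinite` is set.
#' @export
total_cross_section <- function(elf, T_grid, emin_mode = "zero",
                                E_gap = 0, E_F = 0, n_q = 200,
                                energy_nodes = NULL) {
  .xs_table(elf, T_grid, emin_mode, E_gap, E_F, n_q, energy_nodes)
}

#' Electronic stopping power
#'
#' `S_e(T) = int_{E_min}^{E_max} E dSigma/dE dE` (eV/nm) over the same
#' limits as [total_cross_section()].
#'
#' @inheritParams total_cross_section
#' @return data frame of class `xs_table`; see [total_cross_section()].
#' @export
stopping_power <- function(elf, T_grid, emin_mode = "zero",
                           E_gap = 0, E_F = 0, n_q = 200,
                           energy_nodes = NULL) {
  .xs_table(elf, T_grid, emin_mode, E_gap, E_F, n_q, energy_nodes)
}

#' Per-channel single-differential cross sections
#'
#' Applies the SDCS integral to each molecular-orbital channel surface.
#' Inside the tabulated q range every channel is integrated independently;
#' beyond it the total surface is extended (log-log) and shared among
#' channels in proportion to their weight at the largest tabulated q, so
#' the channel curves sum to the total curve exactly.
#'
#' @param channel_elfs an `mo_channel_set` from [mo_channel_elf()], or a
#'   named list of [elf_surface()] channels (the total is then their sum).
#' @param T incident kinetic energy (eV).
#' @param energy_grid energy losses (eV); default the channels' grid.
#' @param n_q logarithmic quadrature nodes in q.
#' @return data frame of class `sdcs_channel_set`: columns `energy`,
#'   `total`, and one column per channel (1/(nm eV)); attribute `T`.
#' @export
channel_cross_sections <- function(channel_elfs, T, energy_grid = NULL,
                                   n_q = 200) {
  if (inherits(channel_elfs, "mo_channel_set")) {
    channels <- channel_elfs$channels
    total <- channel_elfs$total
  } else {
    channels <- channel_elfs
    total <- elf_surface_sum(channels)
  }
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be named")
  for (s in channels) {
    if (!isTRUE(all.equal(s$energy_grid, total$energy_grid)) ||
        !isTRUE(all.equal(s$q_grid, total$q_grid)))
      stop("channel surfaces must share the total's (E, q) grids")
  }
  if (is.null(energy_grid)) energy_grid <- total$energy_grid
  energy_grid <- energy_grid[energy_grid <= T]
  m <- .sdcs_matrix(c(list(total), channels), T, energy_grid, n_q)
  out <- data.frame(energy = energy_grid, total = m[, 1])
  for (i in seq_along(channels)) out[[names(channels)[i]]] <- m[, i + 1]
  attr(out, "T") <- T
  attr(out, "units") <- "1/(nm eV)"
  class(out) <- c("sdcs_channel_set", "data.frame")
  out
}
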