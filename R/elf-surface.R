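## ELF(E, q) surfaces: container, validation and the interpolation policy
## used by the cross-section integrals.

#' Energy loss function surface
#'
#' Container for ELF(E, q) tabulated on a uniform energy-loss grid (eV) and
#' a strictly increasing momentum-transfer grid (atomic units).  The first
#' q column at or nearest `optical_q` is the optical-limit column.
#'
#' @param energy_grid energy-loss values in eV, uniformly spaced,
#'   strictly increasing.
#' @param q_grid momentum-transfer magnitudes in a.u., strictly increasing.
#' @param values matrix `length(energy_grid) x length(q_grid)`,
#'   non-negative.
#' @param optical_q the q value treated as the optical limit (defaults to
#'   the smallest grid q).
#' @param provenance free-text metadata list.
#' @param nonneg enforce non-negative values (default).  Partition
#'   channels of a total ELF may carry negative interference terms and
#'   are stored with `nonneg = FALSE`.
#' @return An object of class `elf_surface`.
#' @export
elf_surface <- function(energy_grid, q_grid, values,
                        optical_q = min(q_grid), provenance = list(),
                        nonneg = TRUE) {
  energy_grid <- as.numeric(energy_grid)
  q_grid <- as.numeric(q_grid)
  values <- as.matrix(values)
  if (any(diff(energy_grid) <= 0)) stop("`energy_grid` must be strictly increasing")
  if (length(q_grid) > 1 && any(diff(q_grid) <= 0))
    stop("`q_grid` must be strictly increasing")
  de <- diff(energy_grid)
  if (length(de) && max(abs(de - de[1])) > 1e-8 * de[1])
    stop("`energy_grid` spacing is not uniform")
  if (!all(dim(values) == c(length(energy_grid), length(q_grid))))
    stop("`values` must be length(energy_grid) x length(q_grid)")
  if (nonneg && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative ELF value at energy row %d, q column %d",
                 bad[1], bad[2]))
  }
  structure(list(energy_grid = energy_grid, q_grid = q_grid,
                 values = values, optical_q = optical_q,
                 provenance = provenance),
            class = "elf_surface")
}

#' @export
print.elf_surface <- function(x, ...) {
  cat(sprintf("<elf_surface: %d x %d (E x q)>\n",
              length(x$energy_grid), length(x$q_grid)))
  cat(sprintf("  E: %.3g .. %.4g eV (dE = %.4g), q: %.3g .. %.3g a.u. (optical q = %.3g)\n",
              min(x$energy_grid), max(x$energy_grid),
              if (length(x$energy_grid) > 1) diff(x$energy_grid)[1] else NA,
              min(x$q_grid), max(x$q_grid), x$optical_q))
  cat(sprintf("  max ELF = %.4g\n", max(x$values)))
  invisible(x)
}

#' Evaluate an ELF surface at arbitrary (E, q)
#'
#' Bilinear interpolation inside the tabulated grid.  Outside it, the
#' policy mirrors how sparse ab initio Bethe surfaces are used in practice:
#' below the smallest tabulated q the optical column is held constant
#' (the optical limit is itself approximated by the smallest computed q);
#' above the largest tabulated q the ELF is extrapolated linearly in
#' log(ELF) versus log(q) from the last two columns, floored at zero;
#' below the first energy row the ELF is interpolated linearly from
#' ELF(0) = 0; above the last energy row it is zero.
#'
#' @param surface an [elf_surface()].
#' @param energy energies in eV (vector).
#' @param q momentum transfers in a.u. (vector, recycled against `energy`).
#' @return numeric vector of ELF values.
#' @export
elf_lookup <- function(surface, energy, q) {
  n <- max(length(energy), length(q))
  energy <- rep_len(as.numeric(energy), n)
  q <- rep_len(as.numeric(q), n)
  eg <- surface$energy_grid
  qg <- surface$q_grid
  v <- surface$values
  ne <- length(eg); nq <- length(qg)

  ## energy bracketing (with the (0, 0) anchor below the grid)
  ei <- findInterval(energy, eg)
  out <- numeric(n)

  row_at <- function(qq, rows) {
    ## interpolate one q-location for given row indices; rows may be 0
    ## (anchor below grid) -> value 0
    val_row <- function(r) {
      if (r == 0) return(rep(0, length(qq)))
      rv <- v[r, ]
      lo <- findInterval(qq, qg)
      lo[lo < 1] <- 1
      res <- numeric(length(qq))
      inside <- qq <= qg[nq] + 1e-12
      li <- lo[inside]; li[li >= nq] <- nq - 1L
      if (nq == 1) {
        res[inside] <- rv[1]
      } else {
        t <- (qq[inside] - qg[li]) / (qg[li + 1] - qg[li])
        t[t < 0] <- 0                       # below smallest q: hold optical
        res[inside] <- rv[li] * (1 - t) + rv[li + 1] * t
      }
      if (any(!inside)) {
        ## log-log linear extension from the last two columns
        if (nq == 1) {
          res[!inside] <- 0
        } else {
          y1 <- rv[nq - 1]; y2 <- rv[nq]
          if (y1 <= 0 || y2 <= 0) {
            res[!inside] <- 0
          } else {
            ## never extrapolate upward: a rising last column means the
            ## Bethe ridge is still inside the grid, where a power-law
            ## extension is meaningless
            slope <- min(0, log(y2 / y1) / log(qg[nq] / qg[nq - 1]))
            res[!inside] <- y2 * exp(slope * log(qq[!inside] / qg[nq]))
          }
        }
      }
      res
    }
    val_row(rows)
  }

  ## process grouped by energy bracket for vector efficiency
  for (grp in split(seq_len(n), ei)) {
    r0 <- ei[grp[1]]
    qq <- q[grp]
    if (r0 >= ne) { out[grp] <- 0; next }      # above last row -> 0
    vlo <- row_at(qq, r0)
    vhi <- row_at(qq, r0 + 1L)
    elo <- if (r0 == 0) 0 else eg[r0]
    ehi <- eg[r0 + 1L]
    t <- (energy[grp] - elo) / (ehi - elo)
    out[grp] <- vlo * (1 - t) + vhi * t
  }
  ## interpolation is linear in the tabulated values, so partition
  ## channels (which may be locally negative) stay exactly additive;
  ## only energies below zero are forced to zero.
  out[energy < 0] <- 0
  out
}

#' Sum a set of ELF surfaces sharing grids
#'
#' @param surfaces list of [elf_surface()] objects on identical grids.
#' @return an [elf_surface()] whose values are the element-wise sum.
#' @export
elf_surface_sum <- function(surfaces) {
  stopifnot(length(surfaces) >= 1)
  s1 <- surfaces[[1]]
  for (s in surfaces[-1]) {
    if (!isTRUE(all.equal(s$energy_grid, s1$energy_grid)) ||
        !isTRUE(all.equal(s$q_grid, s1$q_grid)))
      stop("surfaces are tabulated on different grids")
  }
  vals <- Reduce(`+`, lapply(surfaces, `[[`, "values"))
  elf_surface(s1$energy_grid, s1$q_grid, vals, optical_q = s1$optical_q,
              provenance = list(generator = "elf_surface_sum"),
              nonneg = FALSE)
}

#' f-sum rule integral of an ELF surface
#'
#' Computes `int E * ELF(E, q) dE` per q column by the trapezoidal rule on
#' the native energy grid.  For a surface normalised to a squared plasma
#' frequency `wp2` (eV^2) the exact value is `pi/2 * wp2` at every q.
#'
#' @param surface an [elf_surface()].
#' @return numeric vector, one integral (eV^2) per q column.
#' @export
elf_fsum <- function(surface) {
  e <- surface$energy_grid
  f <- surface$values * e
  de <- diff(e)
  apply(f, 2, function(col) sum((col[-1] + col[-length(col)]) / 2 * de))
}
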