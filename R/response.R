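## RPA linear response: non-interacting chi0_{GG'}(E, q), the Dyson
## equation with the Coulomb kernel, and the macroscopic ELF with and
## without local-field effects.
##
## chi0_{GG'}(E,q) = (1/(N_k V_uc)) sum_{n,m,k} (f_{n,k} - f_{m,k+q})
##                   U^G_{nm,k}(q) conj(U^G'_{nm,k}(q))
##                   / (E - (E_{m,k+q} - E_{n,k}) + i eta)
## with dimensionless cell-normalized overlaps U (a Kronecker delta for
## plane waves), i.e. the response per unit crystal volume, so that
## eps = 1 - v chi0 is dimensionless.  Terms with equal occupations
## contribute zero and are skipped, so the sum runs only over
## occupied<->empty pairs.

## ---- q commensurability and k-point folding --------------------------

## Resolve a momentum transfer against the model's k-mesh.  q must connect
## mesh points: q_frac * kmesh integer.  Returns cartesian q, the k' index
## map kto (and inverse), and the integer G-shift per k that folds k+q
## back into the mesh.
.q_setup <- function(model, q, qdir = c(1, 0, 0)) {
  stopifnot(q > 0)
  qdir <- qdir / sqrt(sum(qdir^2))
  q_cart <- q * qdir
  n <- model$kmesh
  q_frac <- q_cart * model$alat / (2 * pi)
  qn <- q_frac * n
  if (max(abs(qn - round(qn))) > 1e-6) {
    step <- 2 * pi / (n * model$alat)
    near <- sqrt(sum((round(qn) / n * 2 * pi / model$alat)^2))
    stop(sprintf(paste0(
      "q = %.6g a.u. along (%g,%g,%g) is not commensurate with the ",
      "%dx%dx%d k-mesh (mesh step %.6g a.u. per axis); nearest ",
      "commensurate magnitude is %.6g a.u."),
      q, qdir[1], qdir[2], qdir[3], n[1], n[2], n[3], min(step), near))
  }
  qn <- round(qn)
  kint <- round(sweep(model$kpoints, 2, n, "*"))
  key <- kint[, 1] + n[1] * (kint[, 2] + n[2] * kint[, 3])
  ksum <- sweep(kint, 2, qn, "+")
  k2int <- cbind(ksum[, 1] %% n[1], ksum[, 2] %% n[2], ksum[, 3] %% n[3])
  key2 <- k2int[, 1] + n[1] * (k2int[, 2] + n[2] * k2int[, 3])
  kto <- match(key2, key)
  gshift <- cbind((ksum[, 1] - k2int[, 1]) %/% n[1],
                  (ksum[, 2] - k2int[, 2]) %/% n[2],
                  (ksum[, 3] - k2int[, 3]) %/% n[3])
  kfrom <- integer(length(kto)); kfrom[kto] <- seq_along(kto)
  list(q = q, q_cart = q_cart, qdir = qdir, kto = kto, kfrom = kfrom,
       gshift = gshift)
}

## ---- electron-hole pair terms ---------------------------------------

## Enumerate all pair terms (n,k) -> (m,k+q) with df != 0 and their matrix
## elements in the basis `gv`.  Returns:
##   omega   transition energies E_m(k+q) - E_n(k)  (Ha)
##   df      occupation differences f_{n,k} - f_{m,k+q}
##   e_occ   energy of the occupied state of each term (Ha)
##   n, m, ik  indices (ik indexes model$kpoints)
##   U       either a dense complex (nG x T) matrix, or for jellium the
##           integer diagonal index d (U^G is a Kronecker delta).
.chi0_terms <- function(model, qs, gv) {
  t <- if (model$type == "jellium") .chi0_terms_jellium(model, qs, gv)
  else .chi0_terms_lcao(model, qs, gv)
  ## per-crystal-volume normalization: chi0 carries 1/(N_k V_uc) with
  ## dimensionless cell-normalized overlaps, so that eps = 1 - v chi0 is
  ## dimensionless and jellium reproduces the Lindhard function
  t$norm <- t$n_k * model$cell_volume
  t
}

.chi0_terms_jellium <- function(model, qs, gv) {
  occ <- model$occupations
  en <- model$band_energies
  nb <- nrow(occ)
  gkey <- .gkey(gv)

  build <- function(nn, mm, iks) {
    ik2 <- qs$kto[iks]
    df <- occ[cbind(nn, iks)] - occ[cbind(mm, ik2)]
    keep <- abs(df) > 1e-12
    nn <- nn[keep]; mm <- mm[keep]; iks <- iks[keep]; ik2 <- ik2[keep]
    df <- df[keep]
    dg <- model$band_g[mm, , drop = FALSE] - model$band_g[nn, , drop = FALSE] -
      qs$gshift[iks, , drop = FALSE]
    d <- match(.gkey(dg), gkey)
    keep <- !is.na(d)
    list(n = nn[keep], m = mm[keep], ik = iks[keep], df = df[keep],
         d = d[keep],
         omega = en[cbind(mm[keep], ik2[keep])] - en[cbind(nn[keep], iks[keep])],
         e_occ = ifelse(df[keep] > 0,
                        en[cbind(nn[keep], iks[keep])],
                        en[cbind(mm[keep], ik2[keep])]))
  }

  occA <- which(occ > 0, arr.ind = TRUE)          # occupied (n, ik)
  a <- build(rep(occA[, 1], each = nb),
             rep_len(seq_len(nb), nrow(occA) * nb),
             rep(occA[, 2], each = nb))
  ## de-excitation direction: n empty at k, m occupied at k+q
  occB <- which(occ > 0, arr.ind = TRUE)          # occupied (m, ik2)
  ikB <- qs$kfrom[occB[, 2]]
  b <- build(rep_len(seq_len(nb), nrow(occB) * nb),
             rep(occB[, 1], each = nb),
             rep(ikB, each = nb))
  ## `build` filtered df != 0, so occupied->occupied appears in neither;
  ## empty->occupied appears only in b (a requires f_n > 0).
  b_only <- occ[cbind(b$n, b$ik)] == 0
  res <- list(kind = "kron",
              n = c(a$n, b$n[b_only]), m = c(a$m, b$m[b_only]),
              ik = c(a$ik, b$ik[b_only]),
              df = c(a$df, b$df[b_only]),
              d = c(a$d, b$d[b_only]),
              omega = c(a$omega, b$omega[b_only]),
              e_occ = c(a$e_occ, b$e_occ[b_only]),
              n_k = nrow(model$kpoints), n_g = nrow(gv))
  res
}

.chi0_terms_lcao <- function(model, qs, gv) {
  occ <- model$occupations
  en <- model$band_energies
  nb <- nrow(occ)
  nk <- nrow(model$kpoints)
  wg <- model$wf_g
  wkey <- .gkey(wg)
  nG <- nrow(gv)

  Us <- list(); ns <- list(); ms <- list(); iks <- list()
  dfs <- list(); oms <- list(); eos <- list()
  ti <- 0L
  for (ik in seq_len(nk)) {
    ik2 <- qs$kto[ik]
    C1 <- model$pw_coeffs[, , ik, drop = FALSE][, , 1]
    C2 <- model$pw_coeffs[, , ik2, drop = FALSE][, , 1]
    nrm <- colSums(Mod(C1)^2)
    if (any(abs(nrm - 1) > 1e-8))
      stop("plane-wave coefficients are not normalised; states must be ",
           "normalised before matrix elements are taken")
    df <- outer(occ[, ik], occ[, ik2], "-")
    sel <- which(abs(df) > 1e-12, arr.ind = TRUE)
    if (nrow(sel) == 0) next
    ## U[r, t]: matrix elements for every pair t = (n, m) and basis row r
    Umat <- matrix(0+0i, nG, nrow(sel))
    for (r in seq_len(nG)) {
      tg <- sweep(wg, 2, gv[r, ] + qs$gshift[ik, ], "+")
      idx <- match(.gkey(tg), wkey)
      C2s <- matrix(0+0i, nrow(wg), nb)
      ok <- !is.na(idx)
      C2s[ok, ] <- C2[idx[ok], , drop = FALSE]
      Ur <- Conj(t(C1)) %*% C2s            # Ur[n, m]
      Umat[r, ] <- Ur[sel]
    }
    ti <- ti + 1L
    Us[[ti]] <- Umat
    ns[[ti]] <- sel[, 1]; ms[[ti]] <- sel[, 2]
    iks[[ti]] <- rep(ik, nrow(sel))
    dfs[[ti]] <- df[sel]
    oms[[ti]] <- en[cbind(sel[, 2], rep(ik2, nrow(sel)))] -
      en[cbind(sel[, 1], rep(ik, nrow(sel)))]
    eos[[ti]] <- ifelse(df[sel] > 0,
                        en[cbind(sel[, 1], rep(ik, nrow(sel)))],
                        en[cbind(sel[, 2], rep(ik2, nrow(sel)))])
  }
  list(kind = "dense",
       U = if (ti) do.call(cbind, Us) else matrix(0+0i, nG, 0),
       n = unlist(ns), m = unlist(ms), ik = unlist(iks),
       df = unlist(dfs), omega = unlist(oms), e_occ = unlist(eos),
       n_k = nk, n_g = nG)
}

## assemble chi0 matrix at one energy (Ha) from a term set
.chi0_matrix <- function(terms, e_ha, eta_ha) {
  w <- terms$df / (e_ha - terms$omega + 1i * eta_ha) / terms$norm
  nG <- terms$n_g
  if (terms$kind == "kron") {
    m <- matrix(0+0i, nG, nG)
    if (length(w)) {
      dsum <- rowsum(cbind(Re(w), Im(w)), terms$d)
      idx <- as.integer(rownames(dsum))
      m[cbind(idx, idx)] <- complex(real = dsum[, 1], imaginary = dsum[, 2])
    }
    m
  } else {
    if (!length(w)) return(matrix(0+0i, nG, nG))
    Uw <- sweep(terms$U, 2, w, "*")
    Uw %*% Conj(t(terms$U))
  }
}

## ---- public response API --------------------------------------------

.check_eta <- function(eta, energy_grid) {
  if (eta <= 0) stop("`eta` must be > 0 (eta = 0 is rejected)")
  if (length(energy_grid) > 1) {
    de <- min(diff(energy_grid))
    if (eta < 2 * de - 1e-12)
      warning(sprintf(paste0(
        "eta = %.3g eV is below twice the energy resolution (2 dE = %.3g ",
        "eV); spectra may show discretisation ripple"), eta, 2 * de))
  }
  invisible(TRUE)
}

#' Non-interacting response matrices chi0(E, q)
#'
#' Builds the independent-particle (Kohn-Sham) density-density response in
#' the plane-wave basis `gvectors` for every energy on the grid.  Only
#' occupied/empty pairs enter the sum; terms with equal occupations are
#' skipped exactly.
#'
#' @param model a [ks_model()].
#' @param q momentum-transfer magnitude (a.u.).  Must connect k-mesh
#'   points; otherwise an error names the nearest commensurate magnitude.
#' @param energy_grid energy losses in eV.
#' @param eta Lorentzian broadening in eV; values below twice the grid
#'   spacing trigger a warning.
#' @param qdir direction of q (default the x axis; the response of the
#'   target systems is treated as isotropic).
#' @param gvectors basis for the response matrix; defaults to the model's
#'   G list.  Pass `matrix(0L, 1, 3)` for a head-only (1x1) response.
#' @return An object of class `response_set`: a list of
#'   `response_matrix` objects (fields `q`, `energy`, `matrix`, `kind`,
#'   `gvectors`).
#' @export
chi0 <- function(model, q, energy_grid, eta = 0.3, qdir = c(1, 0, 0),
                 gvectors = model$gvectors) {
  .check_eta(eta, energy_grid)
  gvectors <- as.matrix(gvectors)
  qs <- .q_setup(model, q, qdir)
  terms <- .chi0_terms(model, qs, gvectors)
  eta_ha <- ev_to_ha(eta)
  out <- lapply(energy_grid, function(e) {
    structure(list(q = q, energy = e,
                   matrix = .chi0_matrix(terms, ev_to_ha(e), eta_ha),
                   kind = "noninteracting", gvectors = gvectors),
              class = "response_matrix")
  })
  structure(out, class = "response_set", q = q, eta = eta,
            energy_grid = energy_grid)
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix (%s): %dx%d at E = %.3f eV, q = %.3f a.u.>\n",
              x$kind, nrow(x$matrix), ncol(x$matrix), x$energy, x$q))
  invisible(x)
}

#' Plane-wave matrix elements between Kohn-Sham states
#'
#' The dimensionless overlap
#' `U^G_{nm,k}(q) = int Psi*_{n,k} exp(-i(G+q)r) Psi_{m,k+q} d3r` over the
#' unit cell with cell-normalised states, evaluated analytically: a
#' Kronecker delta for plane-wave (jellium) models and a coefficient
#' convolution for LCAO-style models.  This is the overlap entering the
#' per-volume response sum.
#'
#' @param model a [ks_model()].
#' @param k_index index of the k-point (row of `model$kpoints`).
#' @param q momentum-transfer magnitude (a.u.).
#' @param n,m band indices at k and at the folded k + q.
#' @param qdir direction of q.
#' @param gvectors G rows at which to evaluate; default the model basis.
#' @return complex vector over the rows of `gvectors`.
#' @export
plane_wave_matrix_elements <- function(model, k_index, q, n, m,
                                       qdir = c(1, 0, 0),
                                       gvectors = model$gvectors) {
  gvectors <- as.matrix(gvectors)
  qs <- .q_setup(model, q, qdir)
  ik2 <- qs$kto[k_index]
  gs <- qs$gshift[k_index, ]
  if (model$type == "jellium") {
    dg <- model$band_g[m, ] - model$band_g[n, ] - gs
    as.numeric(.gkey(gvectors) == .gkey(matrix(dg, 1))) + 0i
  } else {
    C1 <- model$pw_coeffs[, n, k_index]
    C2 <- model$pw_coeffs[, m, ik2]
    if (abs(sum(Mod(C1)^2) - 1) > 1e-8 || abs(sum(Mod(C2)^2) - 1) > 1e-8)
      stop("states are not normalised")
    wkey <- .gkey(model$wf_g)
    vapply(seq_len(nrow(gvectors)), function(r) {
      tg <- sweep(model$wf_g, 2, gvectors[r, ] + gs, "+")
      idx <- match(.gkey(tg), wkey)
      ok <- !is.na(idx)
      sum(Conj(C1[ok]) * C2[idx[ok]])
    }, complex(1))
  }
}

#' Diagonal Coulomb kernel in a plane-wave basis
#'
#' RPA interaction kernel `K_{GG'} = 4 pi delta_{GG'} / |q + G|^2` (atomic
#' units).
#'
#' @param model a [ks_model()] (supplies the reciprocal lattice scale).
#' @param q momentum-transfer magnitude (a.u.).
#' @param qdir direction of q.
#' @param gvectors G rows of the basis; default the model's list.
#' @return An object of class `kernel_matrix` with the diagonal `matrix`.
#' @export
coulomb_kernel <- function(model, q, qdir = c(1, 0, 0),
                           gvectors = model$gvectors) {
  gvectors <- as.matrix(gvectors)
  b <- 2 * pi / model$alat
  qdir <- qdir / sqrt(sum(qdir^2))
  qg <- sweep(gvectors * b, 2, q * qdir, "+")
  n2 <- rowSums(qg^2)
  if (any(n2 < 1e-12))
    stop(sprintf(paste0(
      "q = %.6g a.u. coincides with a reciprocal lattice vector ",
      "(|q + G| = 0 for G row %d): the Coulomb kernel diverges; choose a ",
      "q that is not an integer multiple of 2*pi/alat = %.6g along the ",
      "chosen direction"), q, which.min(n2), b))
  d <- 4 * pi / n2
  structure(list(q = q, matrix = diag(d, nrow = length(d)),
                 gvectors = gvectors),
            class = "kernel_matrix")
}

## reciprocal condition number of [I - K chi0]-type systems.  The identity
## sets the natural scale, so the denominator is floored at 1: an almost
## zero matrix (the scalar plasmon-pole case) is singular even though its
## relative spread of singular values is trivial.
.rcond_complex <- function(a) {
  s <- svd(a, nu = 0, nv = 0)$d
  min(s) / max(s, 1)
}

#' Solve the RPA Dyson equation for the interacting response
#'
#' `chi = chi0 [I - K chi0]^{-1}`, computed through a linear solve of the
#' equivalent system `(I - chi0 K) chi = chi0` (no explicit inverse).
#'
#' @param chi0_mat a `response_matrix` of kind `"noninteracting"` (as the
#'   elements of [chi0()]'s result), or a bare complex matrix.
#' @param kernel a [coulomb_kernel()] result or bare diagonal matrix.
#' @param rcond_tol reciprocal-condition-number tolerance below which the
#'   system is declared singular (a plasmon pole at real energy with too
#'   small a broadening).
#' @return a `response_matrix` of kind `"interacting"` (or a bare matrix if
#'   a bare matrix was supplied).
#' @export
dyson_solve <- function(chi0_mat, kernel, rcond_tol = 1e-12) {
  x0 <- if (inherits(chi0_mat, "response_matrix")) chi0_mat$matrix else chi0_mat
  km <- if (inherits(kernel, "kernel_matrix")) kernel$matrix else kernel
  if (!all(dim(x0) == dim(km))) stop("chi0 and kernel are not conformable")
  a <- diag(nrow(x0)) - x0 %*% km
  rc <- .rcond_complex(a)
  if (rc < rcond_tol)
    stop(sprintf(paste0("[I - K chi0] is singular within tolerance ",
                        "(rcond = %.3g): plasmon pole at real energy; ",
                        "increase eta"), rc))
  x <- solve(a, x0)
  if (inherits(chi0_mat, "response_matrix")) {
    structure(list(q = chi0_mat$q, energy = chi0_mat$energy, matrix = x,
                   kind = "interacting", gvectors = chi0_mat$gvectors),
              class = "response_matrix")
  } else x
}

## shared driver: ELF column at one q for a vector of energies
.elf_column <- function(model, q, energy_grid, eta, qdir, gvectors, lfe,
                        rcond_tol = 1e-12) {
  qs <- .q_setup(model, q, qdir)
  gv <- if (lfe) as.matrix(gvectors) else matrix(0L, 1, 3)
  terms <- .chi0_terms(model, qs, gv)
  kern <- coulomb_kernel(model, q, qdir, gv)$matrix
  eta_ha <- ev_to_ha(eta)
  vq <- 4 * pi / q^2
  vapply(energy_grid, function(e) {
    x0 <- .chi0_matrix(terms, ev_to_ha(e), eta_ha)
    if (lfe) {
      a <- diag(nrow(x0)) - x0 %*% kern
      rc <- .rcond_complex(a)
      if (rc < rcond_tol)
        stop(sprintf("singular screening at E = %.3f eV (rcond = %.3g)",
                     e, rc))
      chi00 <- solve(a, x0)[1, 1]
      -vq * Im(chi00)
    } else {
      eps00 <- 1 - vq * x0[1, 1]
      Im(-1 / eps00)
    }
  }, numeric(1))
}

#' Macroscopic ELF including local-field effects
#'
#' `ELF(E, q) = -(4 pi / q^2) Im chi_00(E, q)` with chi from the full
#' G x G' RPA Dyson solve.  Crystal local fields enter through the
#' off-diagonal response components.
#'
#' @inheritParams chi0
#' @param direction_average if `TRUE`, average the ELF over the three
#'   axis directions of q.
#' @return numeric vector of ELF values over `energy_grid`.
#' @export
elf_with_lfe <- function(model, q, energy_grid, eta = 0.3,
                         qdir = c(1, 0, 0), gvectors = model$gvectors,
                         direction_average = FALSE) {
  .check_eta(eta, energy_grid)
  if (direction_average) {
    dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    cols <- lapply(dirs, function(d)
      .elf_column(model, q, energy_grid, eta, d, gvectors, lfe = TRUE))
    Reduce(`+`, cols) / 3
  } else {
    .elf_column(model, q, energy_grid, eta, qdir, gvectors, lfe = TRUE)
  }
}

#' Macroscopic ELF without local-field effects
#'
#' Head-only screening: `ELF_NLFE = Im[-1/eps_00]` with
#' `eps_00 = 1 - (4 pi / q^2) chi0_00`; the off-diagonal coupling of the
#' dielectric matrix is ignored.  Identical to [elf_with_lfe()] for
#' homogeneous models.
#'
#' @inheritParams elf_with_lfe
#' @return numeric vector of ELF values over `energy_grid`.
#' @export
elf_without_lfe <- function(model, q, energy_grid, eta = 0.3,
                            qdir = c(1, 0, 0),
                            direction_average = FALSE) {
  .check_eta(eta, energy_grid)
  if (direction_average) {
    dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    cols <- lapply(dirs, function(d)
      .elf_column(model, q, energy_grid, eta, d, NULL, lfe = FALSE))
    Reduce(`+`, cols) / 3
  } else {
    .elf_column(model, q, energy_grid, eta, qdir, NULL, lfe = FALSE)
  }
}

#' Assemble an ELF surface from a model
#'
#' Computes ELF columns over a q grid and stacks them into an
#' [elf_surface()].  Values more negative than `-1e-8` (beyond broadening
#' round-off) raise an error; small negative round-off is clipped to zero.
#'
#' @inheritParams elf_with_lfe
#' @param q_grid momentum-transfer magnitudes (a.u.), each commensurate
#'   with the model k-mesh.
#' @param lfe include local-field effects (default `TRUE`).
#' @return an [elf_surface()].
#' @export
elf_surface_from_model <- function(model, q_grid, energy_grid, eta = 0.3,
                                   lfe = TRUE, qdir = c(1, 0, 0),
                                   direction_average = FALSE) {
  cols <- vapply(q_grid, function(q) {
    if (lfe) elf_with_lfe(model, q, energy_grid, eta, qdir,
                          direction_average = direction_average)
    else elf_without_lfe(model, q, energy_grid, eta, qdir,
                         direction_average = direction_average)
  }, numeric(length(energy_grid)))
  cols <- matrix(cols, nrow = length(energy_grid))
  ## finite basis + Lorentzian broadening can overshoot slightly below
  ## zero near the edge of the model's momentum support; clip that, but
  ## treat anything larger as a sign error
  neg <- min(cols)
  if (neg < -0.01 * max(abs(cols), 1e-300))
    stop(sprintf("ELF is negative beyond broadening round-off (min %.3g)",
                 neg))
  cols[cols < 0] <- 0
  elf_surface(energy_grid, q_grid, cols,
              provenance = list(generator = "elf_surface_from_model",
                                lfe = lfe, eta = eta,
                                model = model$provenance$generator))
}
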