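## Toy periodic Kohn-Sham models: containers and generators.
##
## A ks_model holds everything the response machinery needs: a cubic cell,
## a Gamma-centred k-mesh, a reciprocal-lattice vector list, band energies
## and occupations, and a rule (plane-wave labels or LCAO-style plane-wave
## expansion coefficients) from which the plane-wave matrix elements
## U^G_{nm,k}(q) are evaluated analytically.

#' Construct a toy periodic Kohn-Sham model
#'
#' Low-level constructor; most users will call [make_jellium()] or
#' [make_toy_water()].  Energies are stored in hartree, the cell is cubic
#' with lattice constant `alat` bohr, k-points are fractional coordinates on
#' a Gamma-centred `kmesh` grid with equal weights.
#'
#' @param type `"jellium"` (bands labelled by reciprocal vectors, exact
#'   plane-wave eigenstates) or `"lcao"` (states expanded in plane waves
#'   with explicit coefficients).
#' @param alat cubic lattice constant (bohr).
#' @param kmesh integer vector of length 3.
#' @param gvectors integer matrix (rows = reciprocal vectors in units of
#'   2*pi/alat) used as the response-matrix basis; first row must be 0.
#' @param band_energies `n_bands x N_k` matrix (hartree).
#' @param occupations `n_bands x N_k` matrix, values in `[0, 2]` (spin
#'   factor folded into the occupation, see Details).
#' @param fermi_energy,band_gap scalars (hartree).
#' @param band_g for jellium models: `n_bands x 3` integer matrix mapping
#'   each band to its plane-wave label.
#' @param wf_g,pw_coeffs for LCAO models: integer matrix of wavefunction
#'   plane-wave components and a complex array `(nrow(wf_g), n_bands, N_k)`
#'   of expansion coefficients (columns orthonormal per k).
#' @param orbitals optional data frame with columns `atom`, `species`, `l`
#'   labelling atomic orbitals; `orbital_coeffs` is the matching complex
#'   array `(nrow(orbitals), n_bands, N_k)`, normalised per state.
#' @param orbital_coeffs see `orbitals`.
#' @param provenance free-text list stored with the model.
#'
#' @details Occupation numbers carry the spin degeneracy explicitly:
#' a fully occupied band has f = 2.  The response sum over states then
#' needs no additional spin factor.
#'
#' @return An object of class `ks_model`.
#' @export
ks_model <- function(type, alat, kmesh, gvectors,
                     band_energies, occupations,
                     fermi_energy, band_gap = 0,
                     band_g = NULL, wf_g = NULL, pw_coeffs = NULL,
                     orbitals = NULL, orbital_coeffs = NULL,
                     provenance = list()) {
  type <- match.arg(type, c("jellium", "lcao"))
  kmesh <- as.integer(kmesh)
  stopifnot(length(kmesh) == 3, all(kmesh >= 1), alat > 0)
  kpoints <- kpoint_grid(kmesh)
  n_k <- nrow(kpoints)
  gvectors <- as.matrix(gvectors)
  storage.mode(gvectors) <- "integer"
  if (any(gvectors[1, ] != 0L))
    stop("first row of `gvectors` must be G = 0")
  band_energies <- as.matrix(band_energies)
  occupations <- as.matrix(occupations)
  if (!all(dim(band_energies) == dim(occupations)))
    stop("`band_energies` and `occupations` must have identical dimensions")
  if (ncol(band_energies) != n_k)
    stop("need one column of `band_energies` per k-point (", n_k, ")")
  if (any(occupations < -1e-12 | occupations > 2 + 1e-12))
    stop("occupations must lie in [0, 2]")

  m <- structure(list(
    type = type,
    alat = alat,
    cell_volume = alat^3,
    kmesh = kmesh,
    kpoints = kpoints,
    kweights = rep(1 / n_k, n_k),
    gvectors = gvectors,
    n_bands = nrow(band_energies),
    band_energies = band_energies,
    occupations = occupations,
    fermi_energy = fermi_energy,
    band_gap = band_gap,
    band_g = band_g,
    wf_g = wf_g,
    pw_coeffs = pw_coeffs,
    orbitals = orbitals,
    orbital_coeffs = orbital_coeffs,
    provenance = provenance
  ), class = "ks_model")

  if (type == "jellium") {
    if (is.null(band_g) || nrow(band_g) != m$n_bands)
      stop("jellium models need one `band_g` row per band")
  } else {
    if (is.null(wf_g) || is.null(pw_coeffs))
      stop("lcao models need `wf_g` and `pw_coeffs`")
    if (!all(dim(pw_coeffs) == c(nrow(wf_g), m$n_bands, n_k)))
      stop("`pw_coeffs` must have dimension (n_wf_g, n_bands, N_k)")
  }
  if (!is.null(orbital_coeffs)) {
    if (is.null(orbitals) ||
        !all(c("atom", "species", "l") %in% names(orbitals)))
      stop("`orbitals` must label every orbital with atom, species and l")
    if (!all(dim(orbital_coeffs) == c(nrow(orbitals), m$n_bands, n_k)))
      stop("`orbital_coeffs` must have dimension (n_orbitals, n_bands, N_k)")
    nrm <- apply(abs(orbital_coeffs)^2, c(2, 3), sum)
    if (any(abs(nrm - 1) > 1e-8))
      stop("orbital coefficients must be normalised per state")
  }
  m
}

#' @export
print.ks_model <- function(x, ...) {
  cat(sprintf("<ks_model: %s>\n", x$type))
  cat(sprintf("  cell: cubic a = %.3f bohr (V = %.2f bohr^3)\n",
              x$alat, x$cell_volume))
  cat(sprintf("  k-mesh %dx%dx%d (%d points), %d bands, %d G-vectors\n",
              x$kmesh[1], x$kmesh[2], x$kmesh[3], nrow(x$kpoints),
              x$n_bands, nrow(x$gvectors)))
  cat(sprintf("  E_F = %.4f Ha (%.2f eV), gap = %.4f Ha, electrons/cell = %.3f\n",
              x$fermi_energy, ha_to_ev(x$fermi_energy), x$band_gap,
              electron_count(x)))
  invisible(x)
}

#' Electrons per unit cell of a model
#'
#' Sum of occupation numbers weighted over the k-mesh.
#' @param model a [ks_model()].
#' @return numeric scalar.
#' @export
electron_count <- function(model) {
  sum(model$occupations %*% model$kweights)
}

## Gamma-centred fractional k grid, one row per point, components i/n.
kpoint_grid <- function(kmesh) {
  g <- expand.grid(k1 = seq_len(kmesh[1]) - 1L,
                   k2 = seq_len(kmesh[2]) - 1L,
                   k3 = seq_len(kmesh[3]) - 1L)
  as.matrix(g) %*% diag(1 / kmesh)
}

## All integer reciprocal vectors with kinetic cutoff |G|^2/2 <= gcut (Ha),
## |G| measured in Cartesian a.u. for a cubic cell.  Ordered by norm so that
## G = 0 comes first; ties broken lexicographically for determinism.
gvector_list <- function(gcut, alat) {
  b <- 2 * pi / alat
  nmax <- max(0L, floor(sqrt(2 * gcut) / b))
  r <- -nmax:nmax
  g <- as.matrix(expand.grid(g1 = r, g2 = r, g3 = r))
  keep <- rowSums(g^2) * b^2 / 2 <= gcut + 1e-12
  g <- g[keep, , drop = FALSE]
  o <- order(rowSums(g^2), g[, 1], g[, 2], g[, 3])
  g <- g[o, , drop = FALSE]
  storage.mode(g) <- "integer"
  rownames(g) <- NULL
  g
}

## integer index key for G rows so membership tests are O(1) via match()
.gkey <- function(g, base = 101L) {
  (g[, 1] + 50L) + base * (g[, 2] + 50L) + base^2 * (g[, 3] + 50L)
}

#' Homogeneous electron gas (jellium) model
#'
#' Plane-wave eigenstates on a cubic cell: band `b` at k-point `k` is the
#' plane wave with momentum `k + G_b`, energy `|k + G_b|^2 / 2` hartree.
#' States with energy at or below the Fermi level of the requested density
#' are occupied with f = 2.  The plane-wave matrix elements are exact
#' Kronecker overlaps, so the model reproduces the analytic Lindhard
#' response as the k-mesh is refined and is used as the oracle system for
#' the RPA machinery.
#'
#' @param density electron density (electrons per cubic bohr); see
#'   [jellium_density()] to convert from a Wigner-Seitz radius.
#' @param kmesh integer vector of length 3.
#' @param alat cubic lattice constant in bohr.  The cell only discretises
#'   the spectrum; the physics is set by `density`.
#' @param n_bands number of plane-wave bands to retain.  The default keeps
#'   every band whose label satisfies `|G| <= k_F + band_headroom`, which
#'   guarantees that any occupied state displaced by a momentum transfer up
#'   to `band_headroom` still lands on a retained band.
#' @param gcutoff kinetic-energy cutoff (hartree) for the response-matrix
#'   G-vector basis.  The default retains the first two reciprocal shells
#'   (19 vectors).
#' @param band_headroom largest momentum transfer (a.u.) the band set must
#'   support without losing occupied-to-retained transitions.
#' @return A [ks_model()] of type `"jellium"`.
#' @export
#' @examples
#' m <- make_jellium(jellium_density(2), kmesh = c(4, 4, 4))
#' ha_to_ev(m$fermi_energy)
make_jellium <- function(density, kmesh = c(8, 8, 8), alat = 4,
                         n_bands = NULL, gcutoff = NULL,
                         band_headroom = 1.5) {
  stopifnot(density > 0, all(kmesh >= 1))
  kf <- (3 * pi^2 * density)^(1 / 3)
  ef <- kf^2 / 2
  b <- 2 * pi / alat

  if (is.null(gcutoff)) gcutoff <- 1.01 * (sqrt(2) * b)^2 / 2
  gv <- gvector_list(gcutoff, alat)

  ## band labels: plane-wave G such that some k in the BZ can reach the
  ## Fermi sphere inflated by band_headroom: |G| - sqrt(3)/2 * b <= kf + hr
  pw_cut_k <- kf + band_headroom + sqrt(3) * b / 2
  band_g <- gvector_list(pw_cut_k^2 / 2, alat)
  if (!is.null(n_bands)) {
    if (n_bands > nrow(band_g))
      band_g <- gvector_list(10 * pw_cut_k^2, alat)
    band_g <- band_g[seq_len(n_bands), , drop = FALSE]
  }
  nb <- nrow(band_g)

  kp <- kpoint_grid(kmesh)
  ## fold fractional k into the first BZ image closest to zero for energies:
  ## plane-wave momentum is k + G_b with k in [0,1)^3; energies use the
  ## literal k + G_b (band labels span both signs, so the spectrum is
  ## complete).
  nk <- nrow(kp)
  en <- matrix(0, nb, nk)
  for (ik in seq_len(nk)) {
    pk <- sweep(band_g, 2, kp[ik, ], "+") * b
    en[, ik] <- rowSums(pk^2) / 2
  }
  occ <- matrix(0, nb, nk)
  occ[en <= ef + 1e-9] <- 2
  if (all(occ == 2))
    stop("no empty bands: increase `n_bands`/`band_headroom`; ",
         "no excitations are possible")
  if (sum(occ) == 0)
    stop("no occupied states on this mesh; refine `kmesh` or raise density")

  ks_model("jellium", alat = alat, kmesh = kmesh, gvectors = gv,
           band_energies = en, occupations = occ,
           fermi_energy = ef, band_gap = 0, band_g = band_g,
           provenance = list(generator = "make_jellium",
                             density = density, r_s = (3 / (4 * pi * density))^(1 / 3)))
}

#' Electron density of jellium with Wigner-Seitz radius r_s
#'
#' @param rs Wigner-Seitz radius in bohr.
#' @return density in electrons per cubic bohr, `3 / (4 pi rs^3)`.
#' @export
jellium_density <- function(rs) 3 / (4 * pi * rs^3)

#' Plasma frequency of an electron gas
#'
#' @param density electrons per cubic bohr.
#' @return `sqrt(4 pi n)` in hartree.
#' @export
plasma_frequency <- function(density) sqrt(4 * pi * density)

## default orbital basis and per-band composition of the water-like toy.
## Weights are |C|^2 fractions over (O s, O p, H s, H p); rows are the four
## occupied molecular-orbital channels plus the unoccupied band.
.toy_water_default_weights <- function() {
  w <- rbind(
    `2a1` = c(O_s = 0.60, O_p = 0.10, H_s = 0.30, H_p = 0.00),
    `1b2` = c(O_s = 0.00, O_p = 0.45, H_s = 0.55, H_p = 0.00),
    `3a1` = c(O_s = 0.05, O_p = 0.55, H_s = 0.35, H_p = 0.05),
    `1b1` = c(O_s = 0.00, O_p = 0.90, H_s = 0.05, H_p = 0.05),
    `4a1` = c(O_s = 0.30, O_p = 0.00, H_s = 0.70, H_p = 0.00)
  )
  w
}

#' Water-like gapped toy model
#'
#' A four-occupied-band insulator whose band centres sit at the measured
#' liquid-water molecular-orbital binding energies (2a1, 1b2, 3a1, 1b1 at
#' 30.90, 17.34, 13.50 and 11.16 eV below the vacuum reference), with a
#' small cosine dispersion so the occupied bands are distinguishable but
#' non-overlapping, and one unoccupied band a band gap above the highest
#' occupied band.  States are expanded in plane waves with deterministic,
#' band-dependent coefficients (orthonormal per k), which makes the system
#' inhomogeneous: off-diagonal plane-wave matrix elements are non-zero and
#' local-field effects are non-trivial.  Each band also carries an atomic
#' orbital composition over H/O and s/p labels for the partition analyses.
#'
#' @param mo_energies binding energies (eV, positive) of the four occupied
#'   bands, deepest first.
#' @param mo_widths half-widths (eV) of the occupied-band cosine dispersion.
#' @param gap band gap (eV) between the top of the highest occupied band
#'   and the bottom of the unoccupied band.
#' @param kmesh integer vector of length 3.
#' @param species_weights matrix of |C|^2 fractions with one row per band
#'   (occupied bands first, then the unoccupied band) and columns
#'   `O_s`, `O_p`, `H_s`, `H_p`; rows must each sum to 1.
#' @param alat cubic lattice constant (bohr).
#' @param lumo_width half-width (eV) of the unoccupied band.
#' @param inhomogeneity mixing strength (0..1) of higher plane-wave
#'   components into the band states; 0 gives a homogeneous model for
#'   which local-field effects vanish identically.
#' @param band_strength per-band coupling amplitudes of the occupied bands
#'   to the unoccupied band (positions 1-4) and the unoccupied band's own
#'   higher-G weight (position 5).  The default concentrates oscillator
#'   strength on the 1b2-like transition so the ELF shows a single
#'   dominant feature between 15 and 30 eV at optical q, as liquid water
#'   does.
#' @return A [ks_model()] of type `"lcao"`.
#' @export
#' @examples
#' m <- make_toy_water(kmesh = c(2, 2, 2))
#' ha_to_ev(m$band_energies[, 1])
make_toy_water <- function(mo_energies = c(30.90, 17.34, 13.50, 11.16),
                           mo_widths = rep(0.5, 4),
                           gap = 8.7,
                           kmesh = c(2, 2, 2),
                           species_weights = NULL,
                           alat = 6,
                           lumo_width = 1.0,
                           inhomogeneity = 0.35,
                           band_strength = c(1.0, 1.4, 0.45, 0.35, 1.0)) {
  stopifnot(length(mo_energies) == 4, all(mo_energies > 0),
            all(mo_widths > 0), gap > 0)
  o <- order(-mo_energies)   # deepest (largest binding) first
  mo_energies <- mo_energies[o]
  mo_widths <- mo_widths[o]
  centres <- -mo_energies    # energies below the vacuum reference (eV)

  ## occupied windows must be separable for channel analyses
  lo <- centres - mo_widths
  hi <- centres + mo_widths
  if (any(hi[-4] > lo[-1]))
    stop("occupied bands overlap; molecular-orbital energy windows would ",
         "be ill-defined. Reduce `mo_widths` or spread `mo_energies`.")

  lumo_centre <- hi[4] + gap + lumo_width
  centres_all <- c(centres, lumo_centre)
  widths_all <- c(mo_widths, lumo_width)
  nb <- 5L

  if (is.null(species_weights)) species_weights <- .toy_water_default_weights()
  species_weights <- as.matrix(species_weights)
  if (nrow(species_weights) != nb ||
      !all(colnames(species_weights) == c("O_s", "O_p", "H_s", "H_p")))
    stop("`species_weights` needs ", nb,
         " rows and columns O_s, O_p, H_s, H_p")
  if (any(abs(rowSums(species_weights) - 1) > 1e-8))
    stop("each `species_weights` row must sum to 1")

  kp <- kpoint_grid(kmesh)
  nk <- nrow(kp)
  disp <- (cos(2 * pi * kp[, 1]) + cos(2 * pi * kp[, 2]) +
             cos(2 * pi * kp[, 3])) / 3     # in [-1, 1]
  en <- ev_to_ha(outer(centres_all, rep(1, nk)) +
                   outer(widths_all, disp))
  occ <- rbind(matrix(2, 4, nk), matrix(0, nb - 4, nk))

  ## plane-wave expansion: each band is a small deterministic rotation of
  ## a distinct plane wave, raw = I + inh * A(k) with A(k) anti-Hermitian,
  ## then re-orthonormalized.  Because A is k-dependent, interband optical
  ## matrix elements between k and k + q are O(inh) and controlled
  ## per transition: U(b -> unoccupied) ~ inh * band_strength[b] *
  ## (g_b(k + q) - g_b(k)).  Strictly k-independent coefficients would
  ## make all interband optical elements vanish by orthogonality wherever
  ## the k + q fold needs no zone wrap.
  b <- 2 * pi / alat
  gv <- gvector_list(1.01 * (sqrt(2) * b)^2 / 2, alat)   # 19 vectors
  nwg <- nrow(gv)
  h <- gv[, 1] + 2 * gv[, 2] + 4 * gv[, 3] + 0.5 * gv[, 1] * gv[, 2]
  env <- exp(-0.35 * rowSums(gv^2))
  ## distinct k-dependent mixing functions per occupied band
  gfun <- function(bnd, kf) {
    u <- switch(bnd, c(1, 0, 1), c(1, 1, 0), c(1, 0, 0), c(1, 1, 1))
    sin(2 * pi * sum(u * kf) + 0.4 + 0.5 * bnd)
  }
  pw <- array(0+0i, dim = c(nwg, nb, nk))
  for (ik in seq_len(nk)) {
    A <- matrix(0+0i, nwg, nb)
    kf <- kp[ik, ]
    for (bnd in seq_len(4)) {
      mix <- band_strength[bnd] * gfun(bnd, kf)
      A[nb, bnd] <- A[nb, bnd] - mix          # couple band to the LUMO row
      A[bnd, nb] <- A[bnd, nb] + mix
    }
    ## weak occupied-occupied mixing for richness
    for (bnd in seq_len(3)) {
      mx <- 0.15 * sin(2 * pi * kf[1] + 2 * pi * kf[2] + 0.7 * bnd)
      A[bnd + 1, bnd] <- A[bnd + 1, bnd] - mx
      A[bnd, bnd + 1] <- A[bnd, bnd + 1] + mx
    }
    ## genuine higher-G content (rows beyond the band block) drives the
    ## off-diagonal response and hence non-trivial local-field effects
    hig <- (nb + 1):nwg
    for (bnd in seq_len(nb)) {
      A[hig, bnd] <- band_strength[bnd] * env[hig] *
        (cos(0.9 * bnd * h[hig] + 0.4 * bnd^2) +
           0.5 * sin(2 * pi * kf[1] + 0.8 * h[hig] + bnd))
    }
    raw <- rbind(diag(nb), matrix(0, nwg - nb, nb)) + inhomogeneity * A
    pw[, , ik] <- .orthonormalize(raw)
  }

  ## atomic-orbital composition (k-independent); H weight split over the
  ## two protons with a sign alternating by band parity.
  orbitals <- data.frame(
    atom = c("O1", "O1", "H1", "H2", "H1", "H2"),
    species = c("O", "O", "H", "H", "H", "H"),
    l = c("s", "p", "s", "s", "p", "p"),
    stringsAsFactors = FALSE
  )
  cmat <- matrix(0, nrow(orbitals), nb)
  for (bnd in seq_len(nb)) {
    w <- species_weights[bnd, ]
    sgn <- if (bnd %% 2 == 0) -1 else 1
    cmat[1, bnd] <- sqrt(w["O_s"])
    cmat[2, bnd] <- sqrt(w["O_p"])
    cmat[3, bnd] <- sqrt(w["H_s"] / 2)
    cmat[4, bnd] <- sgn * sqrt(w["H_s"] / 2)
    cmat[5, bnd] <- sqrt(w["H_p"] / 2)
    cmat[6, bnd] <- sgn * sqrt(w["H_p"] / 2)
  }
  oc <- array(0+0i, dim = c(nrow(orbitals), nb, nk))
  for (ik in seq_len(nk)) oc[, , ik] <- cmat

  homo_top <- hi[4]
  ks_model("lcao", alat = alat, kmesh = kmesh, gvectors = gv,
           band_energies = en, occupations = occ,
           fermi_energy = ev_to_ha(homo_top + gap / 2),
           band_gap = ev_to_ha(gap),
           wf_g = gv, pw_coeffs = pw,
           orbitals = orbitals, orbital_coeffs = oc,
           provenance = list(generator = "make_toy_water",
                             mo_energies = mo_energies,
                             mo_widths = mo_widths, gap = gap,
                             band_labels = c("2a1", "1b2", "3a1", "1b1", "4a1")))
}

## modified Gram-Schmidt for complex columns
.orthonormalize <- function(m) {
  n <- ncol(m)
  for (j in seq_len(n)) {
    v <- m[, j]
    if (j > 1) for (i in seq_len(j - 1)) {
      v <- v - sum(Conj(m[, i]) * v) * m[, i]
    }
    nv <- sqrt(sum(Mod(v)^2))
    if (nv < 1e-12) stop("plane-wave coefficient columns are degenerate")
    m[, j] <- v / nv
  }
  m
}

#' Default molecular-orbital energy windows of a toy-water model
#'
#' Window boundaries are placed at the midpoints between the edges of
#' adjacent occupied bands (and half a gap beyond the outermost edges), so
#' each window contains exactly one occupied band.
#'
#' @param model a toy-water [ks_model()].
#' @return data frame with columns `label`, `lo`, `hi` (eV, band-energy
#'   scale, i.e. negative values below vacuum).
#' @export
mo_energy_windows <- function(model) {
  if (is.null(model$orbitals))
    stop("model carries no orbital labels; not a toy-water model?")
  occ_bands <- which(rowSums(model$occupations) > 0)
  en <- ha_to_ev(model$band_energies[occ_bands, , drop = FALSE])
  lo <- apply(en, 1, min); hi <- apply(en, 1, max)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  n <- length(lo)
  cuts <- (hi[-n] + lo[-1]) / 2
  labels <- model$provenance$band_labels[occ_bands][o]
  if (is.null(labels)) labels <- paste0("band", occ_bands[o])
  data.frame(label = labels,
             lo = c(lo[1] - 1, cuts),
             hi = c(cuts, hi[n] + 1),
             stringsAsFactors = FALSE)
}
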