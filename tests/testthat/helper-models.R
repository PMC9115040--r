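# Shared fixtures and independent oracles, all built in code.

rs2_density <- jellium_density(2)
rs2_kf <- (3 * pi^2 * rs2_density)^(1 / 3)

# small cached models (built once per test run)
tiny_jellium <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- make_jellium(rs2_density, kmesh = c(4, 4, 4))
    m
  }
})

toy_water <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- make_toy_water()
    m
  }
})

# smallest commensurate q of a model along x
optical_q_of <- function(model) 2 * pi / (model$kmesh[1] * model$alat)

# Independent naive triple-loop chi0: one term at a time through the
# public plane-wave matrix elements, nothing shared with .chi0_terms.
brute_chi0 <- function(model, q, E, eta, gv = model$gvectors) {
  qs <- elfxs:::.q_setup(model, q, c(1, 0, 0))
  nb <- model$n_bands
  nk <- nrow(model$kpoints)
  z <- complex(real = ev_to_ha(E), imaginary = ev_to_ha(eta))
  acc <- matrix(0 + 0i, nrow(gv), nrow(gv))
  for (ik in seq_len(nk)) for (n in seq_len(nb)) for (m in seq_len(nb)) {
    df <- model$occupations[n, ik] - model$occupations[m, qs$kto[ik]]
    if (abs(df) < 1e-14) next
    U <- plane_wave_matrix_elements(model, ik, q, n, m, gvectors = gv)
    om <- model$band_energies[m, qs$kto[ik]] - model$band_energies[n, ik]
    acc <- acc + df * (U %o% Conj(U)) / (z - om)
  }
  acc / (nk * model$cell_volume)
}

# single electron-hole pair system: one occupied + one empty band, 1 k-point
single_pair_model <- function(gap_ev = 12) {
  alat <- 5
  gv <- matrix(0L, 1, 3)                      # head-only response basis
  wf_g <- elfxs:::gvector_list(1.01 * (sqrt(2) * 2 * pi / alat)^2 / 2, alat)
  nwg <- nrow(wf_g)
  c1 <- rep(0 + 0i, nwg); c1[1] <- sqrt(0.9); c1[2] <- sqrt(0.1)
  c2 <- rep(0 + 0i, nwg); c2[1] <- -sqrt(0.1); c2[2] <- sqrt(0.9)
  pw <- array(0 + 0i, dim = c(nwg, 2, 1))
  pw[, 1, 1] <- c1; pw[, 2, 1] <- c2
  orbitals <- data.frame(atom = "H1", species = "H", l = "s")
  oc <- array(1 + 0i, dim = c(1, 2, 1))
  ks_model("lcao", alat = alat, kmesh = c(1, 1, 1), gvectors = gv,
           band_energies = matrix(ev_to_ha(c(-gap_ev, 0)), 2, 1),
           occupations = matrix(c(2, 0), 2, 1),
           fermi_energy = ev_to_ha(-gap_ev / 2),
           band_gap = ev_to_ha(gap_ev),
           wf_g = wf_g, pw_coeffs = pw,
           orbitals = orbitals, orbital_coeffs = oc)
}

# q-independent ELF surface (identical columns)
flat_q_surface <- function(energy_grid = seq(1, 80, by = 1),
                           q_grid = seq(0.2, 3, length.out = 12)) {
  col <- 400 * 10 * energy_grid / ((energy_grid^2 - 21^2)^2 + 100 * energy_grid^2)
  elf_surface(energy_grid, q_grid,
              matrix(col, length(energy_grid), length(q_grid)))
}
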