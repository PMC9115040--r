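test_that("kinematic limits obey their closed-form identities", {
  set.seed(7)
  for (i in 1:25) {
    T <- runif(1, 15, 5e4)
    E <- runif(40, 0, T)
    kl <- kinematic_limits(T, E)
    expect_lt(max(abs(kl$q_min * kl$q_max - 2 * ev_to_ha(kl$E)) /
                    pmax(2 * ev_to_ha(kl$E), 1)), 1e-13)
    expect_true(all(kl$q_min >= 0 & kl$q_min <= kl$q_max))
  }
  kl0 <- kinematic_limits(200, 0)
  expect_equal(kl0$q_min, 0)
  expect_equal(kl0$q_max, 2 * sqrt(2 * ev_to_ha(200)))
  klT <- kinematic_limits(200, 200)
  expect_equal(klT$q_min, klT$q_max)
  expect_equal(klT$q_min, sqrt(2 * ev_to_ha(200)))
  expect_error(kinematic_limits(100, 150), "0 <= E <= T")
})

test_that("the DDCS is the scaled surface value", {
  s <- flat_q_surface()
  expect_equal(ddcs(s, 100, 1e4, 0.5), 0)       # ELF zero out of range
  v1 <- ddcs(s, 100, 21, 0.5)
  v2 <- ddcs(s, 200, 21, 0.5)
  expect_equal(v2, v1 / 2, tolerance = 1e-12)   # explicit 1/T factor
  # direct substitution at a stored node
  qn <- s$q_grid[3]
  expect_equal(ddcs(s, 100, 21, qn),
               s$values[21, 3] / (pi * ev_to_ha(100) * qn) /
                 (elfxs_units$bohr_nm * elfxs_units$hartree_ev),
               tolerance = 1e-12)
})

test_that("a q-independent ELF integrates to the logarithmic closed form", {
  s <- flat_q_surface()
  T <- 150
  sd <- sdcs(s, T, energy_grid = c(5, 21, 40, 70))
  for (i in seq_len(nrow(sd))) {
    E <- sd$energy[i]
    kl <- kinematic_limits(T, E)
    ref <- s$values[E, 1] * log(kl$q_max / kl$q_min) /
      (pi * ev_to_ha(T)) / (elfxs_units$bohr_nm * elfxs_units$hartree_ev)
    expect_equal(sd$value[i], ref, tolerance = 1e-6)
  }
  # zero surface stays zero
  s0 <- elf_surface(s$energy_grid, s$q_grid, 0 * s$values)
  expect_true(all(sdcs(s0, T)$value == 0))
})

test_that("SDCS matches a brute-force fine linear-grid quadrature", {
  pk <- drude_peaks(21.4, 10, 462, dispersion = "quadratic")
  s <- make_drude_elf(pk, energy_grid = seq(0.5, 120, by = 0.5),
                      q_grid = exp(seq(log(0.05), log(8), length.out = 60)))
  T <- 100
  for (E in c(12, 24, 45)) {
    kl <- kinematic_limits(T, E)
    qf <- seq(kl$q_min, kl$q_max, length.out = 20000)
    y <- elf_lookup(s, rep(E, length(qf)), qf) / qf
    ref <- sum((y[-1] + y[-length(y)]) / 2 * diff(qf)) /
      (pi * ev_to_ha(T)) / (elfxs_units$bohr_nm * elfxs_units$hartree_ev)
    got <- sdcs(s, T, energy_grid = E)$value
    expect_equal(got, ref, tolerance = 5e-3)
  }
})

test_that("energies above T are excluded with a warning", {
  s <- flat_q_surface()
  expect_warning(out <- sdcs(s, 50), "excluded")
  expect_true(all(out$energy <= 50))
})

test_that("cross sections are linear in the ELF surface", {
  eg <- seq(0.5, 150, by = 0.5)
  qg <- exp(seq(log(0.05), log(6), length.out = 50))   # covers kinematics
  s1 <- make_drude_elf(drude_peaks(15, 6, 200, dispersion = "quadratic"), eg, qg)
  s2 <- make_drude_elf(drude_peaks(28, 9, 250, dispersion = "quadratic"), eg, qg)
  s12 <- elf_surface_sum(list(s1, s2))
  T <- 80   # q_max = 4.85 a.u. < max(qg): every lookup is interpolation
  a <- suppressWarnings(sdcs(s1, T)$value + sdcs(s2, T)$value)
  b <- suppressWarnings(sdcs(s12, T)$value)
  expect_equal(b, a, tolerance = 1e-12)
})

test_that("integration limits and bounds behave as required", {
  s <- flat_q_surface()
  # E_min = E_max: E_gap = T makes E_min = E_max = T, an empty range
  z2 <- total_cross_section(s, T_grid = 30, emin_mode = "gap",
                            E_gap = 30, E_F = 0)
  expect_equal(z2$sigma_total, 0)
  expect_true(is.infinite(z2$imfp))
  # adding a second positive peak strictly increases Sigma at every T
  eg <- seq(0.5, 200, by = 0.5); qg <- exp(seq(log(0.05), log(8), length.out = 50))
  sA <- make_drude_elf(drude_peaks(21.4, 10, 400, dispersion = "quadratic"), eg, qg)
  sB <- make_drude_elf(drude_peaks(c(21.4, 13), c(10, 5), c(400, 80),
                                   dispersion = "quadratic"), eg, qg)
  Tg <- c(25, 60, 150, 400)
  xa <- total_cross_section(sA, Tg)
  xb <- total_cross_section(sB, Tg)
  expect_true(all(xb$sigma_total > xa$sigma_total))
  # S_e bounded by E_min Sigma and E_max Sigma
  xs <- stopping_power(sA, Tg)
  emax <- pmin((Tg + 0) / 2, Tg - 0)
  expect_true(all(xs$stopping >= 0))
  expect_true(all(xs$stopping <= emax * xs$sigma_total))
  # imfp * sigma = 1 identically where sigma > 0
  expect_lt(max(abs(xa$imfp * xa$sigma_total - 1)), 1e-12)
})

test_that("quadrature refinement is converged below 0.2 percent", {
  eg <- seq(0.25, 300, by = 0.25)
  qg <- exp(seq(log(0.05), log(10), length.out = 80))
  s <- make_drude_elf(drude_peaks(21.4, 10, 462, dispersion = "quadratic"),
                      eg, qg)
  Tg <- c(60, 200)
  coarse <- total_cross_section(s, Tg, n_q = 200)
  fine <- total_cross_section(s, Tg, n_q = 400)
  expect_lt(max(abs(fine$sigma_total / coarse$sigma_total - 1)), 2e-3)
  expect_lt(max(abs(fine$stopping / coarse$stopping - 1)), 2e-3)
  # halving the energy step (denser nodes) is equally stable
  dense <- total_cross_section(s, Tg, n_q = 200,
                               energy_nodes = seq(0.125, 300, by = 0.125))
  expect_lt(max(abs(dense$sigma_total / coarse$sigma_total - 1)), 2e-3)
})

test_that("channel SDCS curves are exactly additive", {
  tw <- toy_water()
  q0 <- optical_q_of(tw)
  qg <- q0 * c(1, 3)   # odd multiples avoid the reciprocal lattice; the
                       # toy's momentum support ends near 2 a.u.
  eg <- seq(1, 40, by = 1)
  ch <- mo_channel_elf(tw, q_grid = qg, energy_grid = eg, eta = 2)
  cs <- channel_cross_sections(ch, T = 100)
  chan_sum <- rowSums(as.matrix(cs[, names(ch$channels)]))
  expect_lt(max(abs(chan_sum - cs$total)), 1e-8 * max(cs$total))
  # grid mismatch is an error
  bad <- ch$channels
  bad[[1]] <- elf_surface(eg + 1, qg, bad[[1]]$values, nonneg = FALSE)
  expect_error(channel_cross_sections(bad, T = 100), "grid")
})

test_that("a zero-weight channel yields an identically zero curve", {
  tw <- toy_water()
  q0 <- optical_q_of(tw)
  eg <- seq(1, 40, by = 1)
  ch <- mo_channel_elf(tw, q_grid = q0, energy_grid = eg, eta = 2)
  zero <- elf_surface(eg, q0, matrix(0, length(eg), 1))
  chans <- c(ch$channels, list(ghost = zero))
  cs <- channel_cross_sections(chans, T = 100)
  expect_true(all(cs$ghost == 0))
})
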