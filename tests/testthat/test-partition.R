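test_that("the effective potential solves its defining system", {
  tw <- toy_water()
  q0 <- optical_q_of(tw)
  x0 <- chi0(tw, q0, 18, eta = 1.0)[[1]]
  kern <- coulomb_kernel(tw, q0)
  ve <- effective_potential(x0, kern)
  expect_lt(ve$residual, 1e-10)
  # K = 0: Veff = Vext
  k0 <- structure(list(q = q0, matrix = diag(0, nrow(x0$matrix)),
                       gvectors = tw$gvectors), class = "kernel_matrix")
  v0 <- effective_potential(x0, k0)
  expect_equal(v0$vector, c(1 + 0i, rep(0 + 0i, nrow(x0$matrix) - 1)))
  # 1x1: Veff = 1 / (1 - v chi0)
  h <- x0$matrix[1, 1]
  v <- 4 * pi / q0^2
  v1 <- effective_potential(matrix(h, 1, 1), matrix(v, 1, 1))
  expect_equal(v1$vector, 1 / (1 - v * h), tolerance = 1e-13)
})

test_that("the effective-potential route reproduces the Dyson ELF", {
  tw <- toy_water()
  for (q in c(optical_q_of(tw), 3 * optical_q_of(tw))) {
    kern <- coulomb_kernel(tw, q)
    for (E in c(11, 18, 29)) {
      x0 <- chi0(tw, q, E, eta = 1.0)[[1]]
      elf_dyson <- -(4 * pi / q^2) * Im(dyson_solve(x0, kern)$matrix[1, 1])
      pr <- pair_contributions(tw, q, E, eta = 1.0)
      expect_equal(sum(pr$components), elf_dyson, tolerance = 1e-10)
      expect_equal(pr$total, sum(pr$components), tolerance = 1e-12)
    }
  }
})

test_that("pair terms vanish for a fully occupied model", {
  m <- tiny_jellium()
  m$occupations[] <- 2
  pr <- pair_contributions(m, optical_q_of(m), 10, eta = 1.0)
  expect_equal(length(pr$components), 0)
  expect_equal(pr$total, 0)
})

test_that("a single electron-hole pair carries the whole ELF", {
  m <- single_pair_model()
  q <- 2 * pi / m$alat
  pr <- pair_contributions(m, q, 12, eta = 1.0)
  expect_equal(length(pr$components), 2)   # excitation + de-excitation term
  expect_equal(sum(pr$components), pr$total, tolerance = 1e-14)
  # the resonant excitation term dominates
  expect_gt(abs(pr$components[which.max(abs(pr$components))]) / abs(pr$total),
            0.99)
})

test_that("DELF bins close, vanish off-band and resolve the four bands", {
  tw <- toy_water()
  q0 <- optical_q_of(tw)
  pr <- pair_contributions(tw, q0, 18, eta = 1.0)
  # one bin spanning everything: DELF equals the total
  d1 <- delf_occupied(pr, c(-35, -5))
  expect_equal(sum(d1$components), d1$total, tolerance = 1e-12)
  expect_equal(d1$components[1], d1$total, tolerance = 1e-12)
  # bins aligned with band windows and the gaps between them
  edges <- c(-33, -29.5, -19.5, -15.5, -14.8, -12.2, -11.9, -9.5)
  d2 <- delf_occupied(pr, edges)
  expect_equal(sum(d2$components), d2$total, tolerance = 1e-12)
  band_bins <- c(1, 3, 5, 7)                    # intervals containing bands
  gap_bins <- setdiff(seq_along(d2$components), band_bins)
  expect_true(all(d2$components[gap_bins] == 0)) # no occupied states there
  expect_true(all(abs(d2$components[band_bins]) > 0))
  # bins not covering every occupied energy are an error listing orphans
  expect_error(delf_occupied(pr, c(-20, -5)), "orphan|cover")
})

test_that("label projections close under every grouping", {
  tw <- toy_water()
  q0 <- optical_q_of(tw)
  pr <- pair_contributions(tw, q0, 18, eta = 1.0)
  for (g in c("species", "angular_momentum", "species_by_l", "species_pairs")) {
    pj <- project_labels(tw, pr, g)
    expect_equal(sum(pj$components), pj$total, tolerance = 1e-8 * abs(pj$total))
  }
  # species_pairs weights are symmetrised: H-O appears once
  pj <- project_labels(tw, pr, "species_pairs")
  expect_setequal(pj$labels, c("H-H", "H-O", "O-O"))
})

test_that("single-species composition routes all weight to that species", {
  w <- rbind(
    `2a1` = c(O_s = 0, O_p = 0, H_s = 1, H_p = 0),
    `1b2` = c(O_s = 0, O_p = 0, H_s = 0.6, H_p = 0.4),
    `3a1` = c(O_s = 0, O_p = 0, H_s = 1, H_p = 0),
    `1b1` = c(O_s = 0, O_p = 0, H_s = 0.2, H_p = 0.8),
    `4a1` = c(O_s = 0, O_p = 0, H_s = 1, H_p = 0))
  m <- make_toy_water(species_weights = w)
  pr <- pair_contributions(m, optical_q_of(m), 18, eta = 1.0)
  pj <- project_labels(m, pr, "species")
  expect_equal(unname(pj$components["H"]), pj$total, tolerance = 1e-12)
  if ("O" %in% pj$labels) expect_equal(unname(pj$components["O"]), 0)
  # an all-s model is pure s under the angular-momentum grouping
  w2 <- w; w2[, "H_s"] <- 1; w2[, "H_p"] <- 0
  m2 <- make_toy_water(species_weights = w2)
  pr2 <- pair_contributions(m2, optical_q_of(m2), 18, eta = 1.0)
  pj2 <- project_labels(m2, pr2, "angular_momentum")
  expect_equal(unname(pj2$components["s"]), pj2$total, tolerance = 1e-12)
})

test_that("models without labels refuse label projections", {
  m <- tiny_jellium()
  pr <- pair_contributions(m, optical_q_of(m) * 2, 10, eta = 1.5)
  expect_error(project_labels(m, pr, "species"), "no orbital labels")
})

test_that("molecular-orbital channels partition the ELF surface", {
  tw <- toy_water()
  q0 <- optical_q_of(tw)
  qg <- c(q0, 3 * q0)
  eg <- seq(2, 40, by = 1)
  ch <- mo_channel_elf(tw, q_grid = qg, energy_grid = eg, eta = 2)
  expect_setequal(names(ch$channels), c("2a1", "1b2", "3a1", "1b1"))
  sumc <- Reduce(`+`, lapply(ch$channels, function(s) s$values))
  expect_lt(max(abs(sumc - ch$total$values)),
            1e-8 * max(abs(ch$total$values)))
  # one window covering everything: the single channel is the total
  all_w <- data.frame(label = "all", lo = -35, hi = -5)
  ch1 <- mo_channel_elf(tw, all_w, q_grid = qg, energy_grid = eg, eta = 2)
  expect_equal(ch1$channels$all$values, ch1$total$values, tolerance = 1e-12)
  expect_equal(ch1$total$values, ch$total$values, tolerance = 1e-10)
  # moving a boundary through the empty region between bands changes nothing
  w1 <- mo_energy_windows(tw)
  w2 <- w1
  shift <- 0.8   # stays inside the 1b2 / 3a1 gap
  w2$hi[2] <- w2$hi[2] + shift; w2$lo[3] <- w2$lo[3] + shift
  chA <- mo_channel_elf(tw, w1, q_grid = q0, energy_grid = eg, eta = 2)
  chB <- mo_channel_elf(tw, w2, q_grid = q0, energy_grid = eg, eta = 2)
  for (lab in names(chA$channels))
    expect_equal(chA$channels[[lab]]$values, chB$channels[[lab]]$values,
                 tolerance = 1e-12)
  # overlapping windows are rejected
  w3 <- w1; w3$hi[1] <- w3$lo[2] + 1
  expect_error(mo_channel_elf(tw, w3, q_grid = q0, energy_grid = eg, eta = 2),
               "overlap")
  # a window with no occupied band is rejected
  w4 <- rbind(w1, data.frame(label = "ghost", lo = -8, hi = -6.5))
  expect_error(mo_channel_elf(tw, w4, q_grid = q0, energy_grid = eg, eta = 2),
               "no occupied band")
})
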