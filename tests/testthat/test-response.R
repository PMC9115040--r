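test_that("plane-wave matrix elements are Kronecker overlaps for jellium", {
  m <- tiny_jellium()
  q <- optical_q_of(m)
  qs <- elfxs:::.q_setup(m, q, c(1, 0, 0))
  ik <- 3
  gs <- qs$gshift[ik, ]
  for (n in c(1, 2)) for (mm in c(1, 4, 7)) {
    U <- plane_wave_matrix_elements(m, ik, q, n, mm)
    hit <- m$band_g[mm, ] - m$band_g[n, ] - gs
    key <- elfxs:::.gkey(m$gvectors)
    expected <- as.numeric(key == elfxs:::.gkey(matrix(hit, 1)))
    expect_equal(as.numeric(U), expected)
  }
  # identity overlap: n = m and G + q folding back onto the same state
  U <- plane_wave_matrix_elements(m, 1, q, 1, 1)
  d <- which(apply(m$gvectors, 1, function(g) all(g == -gs)))
  if (length(d) == 1) expect_equal(Mod(U[d]), 1)
  expect_equal(sum(Mod(U)^2), 1)   # a single unit entry, all others zero
})

test_that("LCAO matrix elements match real-space quadrature", {
  m <- single_pair_model()
  q <- 2 * pi / m$alat * 1        # kmesh 1^3: q spans a full lattice unit
  gv <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L))
  U <- plane_wave_matrix_elements(m, 1, q, 1, 2, gvectors = gv)
  # quadrature of int psi1* exp(-i(G+q)r) psi2 d3r (cell-normalised
  # states, dimensionless overlap) on a real-space grid
  ng <- 24
  xs <- (seq_len(ng) - 1) / ng * m$alat
  b <- 2 * pi / m$alat
  grid <- as.matrix(expand.grid(x = xs, y = xs, z = xs))
  k1 <- c(0, 0, 0); k2 <- c(0, 0, 0)   # single k-point at Gamma
  psi <- function(coefs, kfrac) {
    ph <- grid %*% t(sweep(m$wf_g, 2, kfrac, "+") * b)
    (exp(1i * ph) %*% coefs) / sqrt(m$cell_volume)
  }
  p1 <- psi(m$pw_coeffs[, 1, 1], k1)
  p2 <- psi(m$pw_coeffs[, 2, 1], k2)
  dv <- m$cell_volume / ng^3
  for (r in seq_len(nrow(gv))) {
    phase <- exp(-1i * grid %*% (gv[r, ] * b + c(q, 0, 0)))
    quad <- sum(Conj(p1) * phase * p2) * dv
    expect_equal(U[r], as.complex(quad), tolerance = 1e-10)
  }
})

test_that("chi0 equals an independent brute-force triple loop", {
  tw <- toy_water()
  q0 <- optical_q_of(tw)
  for (E in c(12, 22)) {
    fast <- chi0(tw, q0, E, eta = 1.0)[[1]]$matrix
    slow <- brute_chi0(tw, q0, E, 1.0)
    expect_lt(max(Mod(fast - slow)), 1e-12)
  }
  jl <- tiny_jellium()
  qj <- optical_q_of(jl) * 2
  fast <- chi0(jl, qj, 8, eta = 1.5)[[1]]$matrix
  slow <- brute_chi0(jl, qj, 8, 1.5)
  expect_lt(max(Mod(fast - slow)), 1e-12)
})

test_that("fully occupied models have exactly zero response", {
  m <- tiny_jellium()
  m$occupations[] <- 2
  x <- chi0(m, optical_q_of(m), 10, eta = 1.0)[[1]]$matrix
  expect_equal(max(Mod(x)), 0)
})

test_that("the static head approaches minus the Fermi-level density of states", {
  m <- make_jellium(rs2_density, kmesh = c(12, 12, 12))
  q <- optical_q_of(m)
  head <- chi0(m, q, 0.05, eta = 0.2,
               gvectors = matrix(0L, 1, 3))[[1]]$matrix[1, 1]
  # against the closed-form Lindhard value at the same (q, E, eta) ...
  ana <- lindhard_chi0(q, 0.05, 0.2, kf = rs2_kf)
  expect_equal(Re(head), Re(ana), tolerance = 0.1)
  # ... and against the ideal static limit -N(0) = -k_F / pi^2
  expect_equal(Re(head), -rs2_kf / pi^2, tolerance = 0.2)
})

test_that("chi0 causality: Im of the head is negative for E > 0", {
  tw <- toy_water()
  x <- suppressWarnings(chi0(tw, optical_q_of(tw), c(5, 15, 30), eta = 0.5))
  for (rm in x) expect_lt(Im(rm$matrix[1, 1]), 0)
})

test_that("incommensurate q is rejected with the nearest alternative", {
  tw <- toy_water()
  expect_error(chi0(tw, 0.3, 10, eta = 1), "nearest commensurate")
})

test_that("eta = 0 is rejected and small eta warns", {
  tw <- toy_water()
  expect_error(chi0(tw, optical_q_of(tw), 10, eta = 0), "eta")
  expect_warning(chi0(tw, optical_q_of(tw), c(10, 15), eta = 1),
                 "below twice the energy resolution")
})

test_that("the Dyson solve has the correct limits", {
  tw <- toy_water()
  q0 <- optical_q_of(tw)
  x0 <- chi0(tw, q0, 20, eta = 1.0)[[1]]
  # K = 0: chi = chi0 exactly
  k0 <- structure(list(q = q0, matrix = diag(0, nrow(x0$matrix)),
                       gvectors = tw$gvectors), class = "kernel_matrix")
  expect_equal(dyson_solve(x0, k0)$matrix, x0$matrix, tolerance = 1e-14)
  # 1x1 case: chi = chi0 / (1 - v chi0)
  h <- x0$matrix[1, 1]
  v <- 4 * pi / q0^2
  x1 <- structure(list(q = q0, energy = 20, matrix = matrix(h, 1, 1),
                       kind = "noninteracting",
                       gvectors = matrix(0L, 1, 3)), class = "response_matrix")
  k1 <- structure(list(q = q0, matrix = matrix(v, 1, 1),
                       gvectors = matrix(0L, 1, 3)), class = "kernel_matrix")
  expect_equal(dyson_solve(x1, k1)$matrix[1, 1], h / (1 - v * h),
               tolerance = 1e-13)
  # singular system reports its condition number
  xs <- structure(list(q = q0, energy = 0, matrix = matrix(1 / v + 0i, 1, 1),
                       kind = "noninteracting",
                       gvectors = matrix(0L, 1, 3)), class = "response_matrix")
  expect_error(dyson_solve(xs, k1), "singular")
})

test_that("local fields are a no-op for homogeneous systems", {
  # jellium is diagonal in G: LFE and NLFE identical to round-off
  m <- tiny_jellium()
  q <- optical_q_of(m) * 2
  eg <- seq(2, 30, by = 2)
  suppressWarnings({
    expect_lt(max(abs(elf_with_lfe(m, q, eg, eta = 2) -
                        elf_without_lfe(m, q, eg, eta = 2))), 1e-12)
    # a homogeneous LCAO toy behaves the same way
    hw <- make_toy_water(inhomogeneity = 0)
    q0 <- optical_q_of(hw)
    expect_lt(max(abs(elf_with_lfe(hw, q0, eg, eta = 2) -
                        elf_without_lfe(hw, q0, eg, eta = 2))), 1e-12)
    # restricting the basis to one G vector degenerates LFE to NLFE
    tw <- toy_water()
    expect_lt(max(abs(elf_with_lfe(tw, q0, eg, eta = 2,
                                   gvectors = matrix(0L, 1, 3)) -
                        elf_without_lfe(tw, q0, eg, eta = 2))), 1e-14)
  })
})

test_that("local fields are non-trivial for the inhomogeneous toy", {
  tw <- toy_water()
  q0 <- optical_q_of(tw)
  eg <- seq(10, 30, by = 1)
  lfe <- suppressWarnings(elf_with_lfe(tw, q0, eg, eta = 1.5))
  nlfe <- suppressWarnings(elf_without_lfe(tw, q0, eg, eta = 1.5))
  expect_gt(max(abs(lfe - nlfe)), 1e-3)
})

test_that("the toy-water ELF has a single dominant water-like peak", {
  tw <- toy_water()
  q0 <- optical_q_of(tw)
  eg <- seq(1, 45, by = 0.25)
  el <- elf_with_lfe(tw, q0, eg, eta = 1.0)
  pk <- eg[which.max(el)]
  expect_gt(pk, 15); expect_lt(pk, 30)
  # dominant: no feature outside the window reaches the main peak
  expect_gt(max(el[eg >= 15 & eg <= 30]), max(el[eg < 15 | eg > 30]))
  # causality proxy
  expect_gt(min(el), -1e-10)
})

test_that("jellium ELF matches the analytic Lindhard ELF on a refined mesh", {
  m <- make_jellium(rs2_density, kmesh = c(12, 12, 12))
  q <- 2 * optical_q_of(m)
  for (E in c(8, 14, 20)) {
    num <- elf_without_lfe(m, q, E, eta = 1.5)
    ana <- lindhard_elf(q, E, 1.5, kf = rs2_kf)
    expect_equal(num, ana, tolerance = 0.05)
  }
})

test_that("direction averaging reduces to a single direction for isotropic jellium", {
  m <- tiny_jellium()
  q <- optical_q_of(m)
  eg <- c(8, 16)
  one <- suppressWarnings(elf_without_lfe(m, q, eg, eta = 2))
  avg <- suppressWarnings(elf_without_lfe(m, q, eg, eta = 2,
                                          direction_average = TRUE))
  expect_equal(avg, one, tolerance = 1e-12)   # cubic symmetry: exact
})
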