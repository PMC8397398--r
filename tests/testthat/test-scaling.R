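# A small parameter grid with well-separated scales (u ~ 1, f small, N large)
scale_grid <- expand.grid(u = c(0.5, 1, 2), f = c(1 / 16, 1 / 64), N = c(1e4, 1e6))

test_that("regime boundaries are ordered and tied to the blob charges", {
  for (r in seq_len(nrow(scale_grid))) {
    p <- scaling_params(scale_grid$u[r], scale_grid$f[r], scale_grid$N[r],
                        Lambda = 1)
    b <- regime_boundaries(p)
    expect_true(b$L_ar < b$L_rhb && b$L_rhb < b$L_bs && b$L_bs < b$L_pe)
    expect_equal(b$L_rhb, blob_set(p)$q_e)  # crossover at electrostatic-blob charge
    expect_equal(b$L_pe, p$f * p$N)
  }
})

test_that("at L_bs bead charge, block charge, and string ionic count coincide", {
  for (r in seq_len(nrow(scale_grid))) {
    u <- scale_grid$u[r]; f <- scale_grid$f[r]; N <- scale_grid$N[r]
    b <- regime_boundaries(scaling_params(u, f, N, Lambda = 1))
    # evaluate regime-III observables exactly at the boundary
    pr <- suppressWarnings(
      predict_conformation(scaling_params(u, f, N, Lambda = b$L_bs * 0.999999)))
    expect_equal(pr$regime, "III")
    expect_equal(pr$Q / pr$N_bead, b$L_bs, tolerance = 1e-4)
    expect_equal(f * pr$m_str, b$L_bs, tolerance = 1e-4)
  }
})

test_that("globule density takes the correct branch and is continuous", {
  u <- 1; f <- 1 / 16; N <- 1e4
  b <- regime_boundaries(scaling_params(u, f, N, Lambda = 1))
  # alternating branch at Lambda = 0
  expect_equal(globule_density(scaling_params(u, f, N, Lambda = 0)),
               u^2 * f^(3 / 2))
  # continuity at both crossovers
  for (L in c(b$L_ar, b$L_rhb)) {
    lo <- globule_density(scaling_params(u, f, N, Lambda = L * (1 - 1e-9)))
    hi <- globule_density(scaling_params(u, f, N, Lambda = L * (1 + 1e-9)))
    expect_equal(lo, hi, tolerance = 1e-6)
  }
  # branch intersections occur exactly at the crossover formulas
  expect_equal(u^2 * f^(3 / 2), u * f * b$L_ar)
  expect_equal(u * f * b$L_rhb, (u * f^2)^(1 / 3))
  # Lambda-independence above L_rhb
  expect_equal(globule_density(scaling_params(u, f, N, Lambda = 2 * b$L_rhb)),
               globule_density(scaling_params(u, f, N, Lambda = 20 * b$L_rhb)))
  # dense-limit cap
  expect_warning(phi <- globule_density(scaling_params(5, 1, 100, Lambda = 1)),
                 "capping")
  expect_equal(phi, 1)
})

test_that("Rayleigh ratio vanishes for alternating chains and plateaus at 1", {
  u <- 1; f <- 1 / 16; N <- 1e4
  b <- regime_boundaries(scaling_params(u, f, N, Lambda = 1))
  expect_equal(rayleigh_ratio(scaling_params(u, f, N, Lambda = 0)), 0)
  expect_equal(rayleigh_ratio(scaling_params(u, f, N, Lambda = b$L_ar)), 1)
  # independent of Lambda throughout the random regime
  mid1 <- rayleigh_ratio(scaling_params(u, f, N, Lambda = b$L_ar * 1.5))
  mid2 <- rayleigh_ratio(scaling_params(u, f, N, Lambda = b$L_rhb * 0.7))
  expect_equal(mid1, 1)
  expect_equal(mid2, 1)
  expect_gt(rayleigh_ratio(scaling_params(u, f, N, Lambda = 50 * b$L_rhb)), 10)
})

test_that("regimes are assigned on half-open intervals", {
  u <- 1; f <- 1 / 16; N <- 1e4
  expect_equal(classify_regime(scaling_params(u, f, N, Lambda = 0)), "I")
  expect_equal(classify_regime(scaling_params(u, f, N, Lambda = 1)), "II")
  b <- regime_boundaries(scaling_params(u, f, N, Lambda = 1))
  expect_equal(classify_regime(scaling_params(u, f, N, Lambda = b$L_ar)), "II")
  expect_equal(classify_regime(scaling_params(u, f, N, Lambda = b$L_rhb)), "III")
  expect_equal(classify_regime(scaling_params(u, f, N, Lambda = b$L_bs)), "IV")
  expect_equal(
    classify_regime(suppressWarnings(scaling_params(u, f, N, Lambda = 10 * f * N))),
    "V")
  expect_warning(classify_regime(scaling_params(100, 1, 10, Lambda = 1)),
                 "separation")
})

test_that("chain size is continuous at the II/III, III/IV and IV/V boundaries", {
  for (r in seq_len(nrow(scale_grid))) {
    u <- scale_grid$u[r]; f <- scale_grid$f[r]; N <- scale_grid$N[r]
    b <- regime_boundaries(scaling_params(u, f, N, Lambda = 1))
    for (L in c(b$L_rhb, b$L_bs, b$L_pe)) {
      lo <- suppressWarnings(
        predict_conformation(scaling_params(u, f, N, Lambda = L * (1 - 1e-9))))
      hi <- suppressWarnings(
        predict_conformation(scaling_params(u, f, N, Lambda = L * (1 + 1e-9))))
      expect_equal(lo$R, hi$R, tolerance = 1e-6)
      expect_equal(lo$L_nec, hi$L_nec, tolerance = 1e-6)
    }
  }
})

test_that("bead count equals one at the II/III and IV/V crossovers", {
  for (r in seq_len(nrow(scale_grid))) {
    u <- scale_grid$u[r]; f <- scale_grid$f[r]; N <- scale_grid$N[r]
    b <- regime_boundaries(scaling_params(u, f, N, Lambda = 1))
    p3 <- predict_conformation(scaling_params(u, f, N, Lambda = b$L_rhb))
    expect_equal(p3$regime, "III")
    expect_equal(p3$N_bead, 1)
    p4 <- suppressWarnings(
      predict_conformation(scaling_params(u, f, N, Lambda = b$L_pe * (1 - 1e-12))))
    expect_equal(p4$regime, "IV")
    expect_equal(p4$N_bead, 1, tolerance = 1e-6)
  }
})

test_that("bead charge drops by (N/g_e)^(1/9) at the III/IV boundary", {
  for (r in seq_len(nrow(scale_grid))) {
    u <- scale_grid$u[r]; f <- scale_grid$f[r]; N <- scale_grid$N[r]
    p <- scaling_params(u, f, N, Lambda = 1)
    b <- regime_boundaries(p)
    q3 <- predict_conformation(scaling_params(u, f, N,
                                              Lambda = b$L_bs * (1 - 1e-9)))$Q_bead
    q4 <- predict_conformation(scaling_params(u, f, N,
                                              Lambda = b$L_bs * (1 + 1e-9)))$Q_bead
    expect_equal(q3 / q4, (N / blob_set(p)$g_e)^(1 / 9), tolerance = 1e-6)
  }
})

test_that("necklace mass bookkeeping closes within a factor 2 in II-IV", {
  for (r in seq_len(nrow(scale_grid))) {
    u <- scale_grid$u[r]; f <- scale_grid$f[r]; N <- scale_grid$N[r]
    b <- regime_boundaries(scaling_params(u, f, N, Lambda = 1))
    probes <- c(sqrt(b$L_ar * b$L_rhb), sqrt(b$L_rhb * b$L_bs),
                sqrt(b$L_bs * b$L_pe))
    for (L in probes) {
      pr <- predict_conformation(scaling_params(u, f, N, Lambda = L))
      total <- pr$N_bead * pr$m_bead + pr$N_bead * pr$m_str
      expect_gte(total / N, 0.5)
      expect_lte(total / N, 2)
      expect_lte(pr$m_str, pr$m_bead)  # strings are light in II-III
    }
  }
})

test_that("stretched-polyelectrolyte size law and tabulated row V hold", {
  u <- 2; f <- 1 / 4; N <- 1e4
  pr <- suppressWarnings(
    predict_conformation(scaling_params(u, f, N, Lambda = 20 * f * N)))
  expect_equal(pr$regime, "V")
  expect_equal(pr$R, u^(1 / 3) * f^(2 / 3) * N)
  expect_equal(pr$N_bead, 0)
  # regime I chain size from the phase diagram
  tab <- phase_diagram(u, f, N, c(0, 1e-6))
  expect_equal(tab$R[1], N^(1 / 3) / (u^(2 / 3) * sqrt(f)))
})

test_that("bead count peaks at L_bs and R is non-decreasing beyond L_ar", {
  u <- 1; f <- 1 / 16; N <- 1e4
  b <- regime_boundaries(scaling_params(u, f, N, Lambda = 1))
  grid <- exp(seq(log(b$L_ar), log(b$L_pe * 0.999), length.out = 400))
  tab <- phase_diagram(u, f, N, grid)
  expect_equal(grid[which.max(tab$N_bead)], b$L_bs, tolerance = 0.02)
  expect_true(all(diff(tab$R) > -1e-9))
  # linear rise in III, Lambda^(-1/2) fall in IV
  iii <- tab[tab$regime == "III", ]
  fit3 <- coef(lm(log(N_bead) ~ log(Lambda), data = iii))[2]
  expect_equal(unname(fit3), 1, tolerance = 1e-6)
  iv <- tab[tab$regime == "IV", ]
  fit4 <- coef(lm(log(N_bead) ~ log(Lambda), data = iv))[2]
  expect_equal(unname(fit4), -0.5, tolerance = 1e-6)
})

test_that("lengths scale linearly with the monomer size", {
  pr <- predict_conformation(scaling_params(1, 1 / 16, 1e4, Lambda = 5))
  phys <- to_physical(pr, a = 0.38)  # nm, a typical residue size
  for (fld in c("R", "D_bead", "l_str", "L_nec"))
    expect_equal(phys[[fld]], 0.38 * pr[[fld]])
  expect_equal(phys$N_bead, pr$N_bead)
  expect_equal(phys$Q_bead, pr$Q_bead)
})
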