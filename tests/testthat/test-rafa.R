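test_that("the 1:1 binding quadratic matches its textbook oracle", {
  # strong binding, equimolar: 99.8% of the ligand is complexed
  bf <- bound_fraction_1to1(20e-6, 20e-6, 10.2)
  expect_equal(bf$complex, oracle_quadratic_1to1(20e-6, 20e-6, 10.2),
               tolerance = 1e-10)
  expect_equal(bf$complex, 1.9964e-5, tolerance = 1e-4)
  expect_gt(bf$complex / 20e-6, 0.998)

  for (logK in c(2, 4.7, 8, 12)) {
    for (M in c(0, 1e-6, 2e-5, 1e-4)) {
      expect_equal(bound_fraction_1to1(M, 2e-5, logK)$complex,
                   oracle_quadratic_1to1(M, 2e-5, logK), tolerance = 1e-10)
    }
  }
  # no metal, and the weak-binding limit
  expect_identical(bound_fraction_1to1(0, 2e-5, 10)$complex, 0)
  expect_equal(bound_fraction_1to1(0, 2e-5, 10)$free_ligand, 2e-5)
  expect_lt(bound_fraction_1to1(2e-5, 2e-5, -8)$complex, 1e-15)
  # conservation: complex never exceeds either total
  expect_lte(bound_fraction_1to1(5e-6, 2e-5, 14)$complex, 5e-6)
})

test_that("RSD statistic agrees with an SVD oracle and detects rank", {
  set.seed(11)
  u <- runif(40); v <- runif(6)
  rank1 <- outer(u, v)
  expect_lt(rsd_statistic(rank1, 1), 1e-7)

  noise <- matrix(rnorm(40 * 6, sd = 0.01), 40)
  expect_gt(rsd_statistic(noise, 1), 0)

  rank2 <- rank1 + outer(runif(40), runif(6))
  expect_gt(rsd_statistic(rank2, 1) / max(rsd_statistic(rank2, 2), 1e-300), 10)

  # cross-check against singular values on a noisy matrix
  X <- rank2 + noise
  for (n in 1:3) {
    expect_equal(rsd_statistic(X, n),
                 sqrt(oracle_trailing_ssq(X, n) / (nrow(X) * (ncol(X) - n))),
                 tolerance = 1e-10)
    expect_equal(rsd_statistic(X, n, normalize = TRUE),
                 sqrt(oracle_trailing_ssq(X, n) / sum(svd(X)$d^2)),
                 tolerance = 1e-10)
  }
  expect_error(rsd_statistic(X, 6), "smaller than the sample count")
  expect_error(rsd_statistic(X[1, , drop = FALSE], 1), "degenerate")
})

test_that("annihilation at the generating constant collapses the rank to 1", {
  sp <- default_cip_spectra()
  sm <- gen_uvvis_titration(sp$ligand, sp$complex, logK_cond = 10.2)
  lam_true <- svd(annihilate(sm, 10.2))$d^2
  expect_lt(lam_true[2] / lam_true[1], 1e-16)
  # a grossly wrong constant leaves rank 2
  lam_off <- svd(annihilate(sm, 7))$d^2
  expect_gt(lam_off[2] / lam_off[1], 1e-8)
  # pure-ligand matrix annihilates itself at any constant
  sm0 <- gen_uvvis_titration(sp$ligand, sp$complex,
                             metal_totals = c(0, 0, 0), logK_cond = 10.2)
  expect_lt(max(abs(annihilate(sm0, 9))), 1e-12)
  expect_error(annihilate(sm, 10, ligand_spectrum = sp$ligand[-1]),
               "wavelength grid")
})

test_that("the RSD scan recovers the generating constant exactly without noise", {
  sp <- default_cip_spectra()
  b <- default_bands()
  nadp_l <- gen_species_spectrum(b$NADP, sp$wl)
  nadp_c <- gen_species_spectrum(b$AlNADP, sp$wl)
  for (cfg in list(list(l = sp$ligand, c = sp$complex, k = 10.2),
                   list(l = nadp_l, c = nadp_c, k = 10.7))) {
    sm <- gen_uvvis_titration(cfg$l, cfg$c, logK_cond = cfg$k)
    sc <- scan_logK(sm)
    expect_identical(sc$best_logK, cfg$k)
    expect_equal(sc$rsd[match(cfg$k, sc$logK_grid)], min(sc$rsd))
  }
  # single-point grid returns that value
  sm <- gen_uvvis_titration(sp$ligand, sp$complex, logK_cond = 10.2)
  expect_equal(scan_logK(sm, grid = 8.4)$best_logK, 8.4)
  expect_error(scan_logK(sm, grid = numeric(0)), "nonempty")
  expect_error(scan_logK(sm, grid = c(8, 7)), "strictly increasing")
})

test_that("a flat RSD valley ties break to the smallest constant with a warning", {
  sp <- default_cip_spectra()
  # ligand-only columns: every trial constant annihilates perfectly
  sm0 <- gen_uvvis_titration(sp$ligand, sp$complex,
                             metal_totals = c(0, 0, 0), logK_cond = 10.2)
  expect_warning(sc <- scan_logK(sm0, grid = c(8, 9, 10)), "flat RSD valley")
  expect_equal(sc$best_logK, 8)
})

test_that("scan recovery is consistent where the design is informative", {
  # at sigma = 1e-4 AU the equimolar sample still pins the constant
  sp <- default_cip_spectra()
  best <- vapply(1:10, function(s) {
    sm <- gen_uvvis_titration(sp$ligand, sp$complex, logK_cond = 10.2,
                              noise = noise_spec(sigma_intensity = 1e-4,
                                                 seed = 1000 + s))
    suppressWarnings(scan_logK(sm)$best_logK)
  }, numeric(1))
  expect_lt(abs(mean(best) - 10.2), 0.1)
  expect_true(all(abs(best - 10.2) <= 0.3))
})

test_that("rank estimation counts the responding species", {
  sp <- default_cip_spectra()
  sm <- gen_uvvis_titration(sp$ligand, sp$complex, logK_cond = 10.2)
  expect_equal(estimate_rank(sm, 1e-8), 2L)
  # replicate ligand-only columns: one species
  sm1 <- gen_uvvis_titration(sp$ligand, sp$complex,
                             metal_totals = c(0, 0, 0, 0), logK_cond = 10.2)
  expect_equal(estimate_rank(sm1, 1e-8), 1L)
  # constructed three-species bilinear mixture
  set.seed(21)
  S3 <- cbind(sp$ligand, sp$complex, rev(sp$ligand))
  C3 <- matrix(runif(15, 1e-6, 2e-5), nrow = 3)
  expect_equal(estimate_rank(S3 %*% C3, 1e-8), 3L)
  expect_error(estimate_rank(S3 %*% C3, 0), "positive")
})

test_that("residual spectra isolate what the two-binary model cannot explain", {
  wl <- default_wavelengths()
  b <- default_bands()
  ligs <- list(CIP = gen_species_spectrum(b$CIP, wl),
               NADP = gen_species_spectrum(b$NADP, wl))
  cpxs <- list(CIP = gen_species_spectrum(b$AlCIP, wl),
               NADP = gen_species_spectrum(b$AlNADP, wl))
  ks <- c(CIP = 10.2, NADP = 10.7)

  # self-consistency: data generated under the two-binary assumption
  sm <- gen_ternary_titration(ligs, cpxs, logK_cond = ks, wavelengths = wl)
  res <- residual_spectra(sm, ligs, cpxs, ks)
  expect_lt(max(abs(res)), 1e-10)

  # an interaction band near 290 nm shows up at 290 nm, same in all columns
  smi <- gen_ternary_titration(ligs, cpxs, logK_cond = ks, wavelengths = wl,
                               interaction_band = band_spec(290, 6, 2e3))
  resi <- residual_spectra(smi, ligs, cpxs, ks)
  peaks <- wl[apply(abs(resi), 2, which.max)]
  expect_true(all(abs(peaks - 290) <= 1))
  expect_lt(max(abs(resi - resi[, 1])), 1e-10)

  # metal-free column: observed minus the pure-ligand sum
  pure <- ligs$CIP * 2e-5 + ligs$NADP * 2e-5
  expect_equal(resi[, 1], smi$intensity[, 1] - pure, tolerance = 1e-10)
})
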