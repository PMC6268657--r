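test_that("strong-acid point and ligand pKa structure come out of the simulator", {
  m <- build_model(list(eq_component("H", 1L, "proton")), list(water_species()))
  d <- titration_dataset(0.05, c(H = 1e-3), 0.1026, 1e-9)
  s <- simulate_titration(m, d)
  expect_equal(s$points$pH, 3.00, tolerance = 1e-3)

  # CIP ligand-only: half-neutralization pH values sit at the stepwise pKas
  # (pKa1 = 14.76 - 8.60 = 6.16 for H2L/HL, pKa2 = 8.60 for HL/L)
  mc <- cip_nadp_model("CIP", metal = FALSE)
  acid <- 4e-3; cL <- 1e-3; V0 <- 0.05; Cb <- 0.1026
  # volume delivering the acid excess plus half (resp. 1.5x) the first proton
  v_half1 <- (acid + 0.5 * cL) * V0 / Cb
  v_half2 <- (acid + 1.5 * cL) * V0 / Cb
  d2 <- titration_dataset(V0, c(CIP = cL, H = acid + 2 * cL), Cb,
                          c(v_half1, v_half2))
  s2 <- simulate_titration(mc, d2)
  expect_equal(s2$points$pH[1], 14.76 - 8.60, tolerance = 0.02)
  expect_equal(s2$points$pH[2], 8.60, tolerance = 0.02)

  # doubling the titrant concentration halves the volume to a given pH
  d3 <- titration_dataset(V0, c(CIP = cL, H = acid + 2 * cL), 2 * Cb,
                          c(v_half1 / 2, v_half2 / 2))
  s3 <- simulate_titration(mc, d3)
  expect_equal(s3$points$pH, s2$points$pH, tolerance = 0.01)
})

test_that("sigma_fit is zero on self-simulated data and tracks perturbation and noise", {
  mc <- cip_nadp_model("CIP", metal = FALSE)
  dd <- standard_titration_design(c_cip = 1e-3, n_points = 40)
  obs <- simulate_titration(mc, dd)
  expect_lt(sigma_fit(mc, obs), 1e-6)

  m_off <- set_log_beta(mc, c("H(CIP)" = 9.1))
  expect_gt(sigma_fit(m_off, obs), 0.05)

  # gaussian read noise passes straight through to sigma_fit
  sds <- vapply(1:5, function(s) {
    noisy <- gen_potentiometric_titration(mc, dd,
                                          noise_spec(sigma_pH = 0.005, seed = s))
    sigma_fit(mc, noisy)
  }, numeric(1))
  expect_true(all(sds > 0.003 & sds < 0.007))
})

test_that("refinement recovers perturbed protonation constants and reports errors", {
  mc <- cip_nadp_model("CIP", metal = FALSE)
  dd <- standard_titration_design(c_cip = 1e-3, n_points = 40)
  obs <- simulate_titration(mc, dd)
  fit <- refine_constants(mc, obs, adjustable = c("H(CIP)", "H2(CIP)"),
                          start = c("H(CIP)" = 7.6, "H2(CIP)" = 15.76))
  expect_true(fit$converged)
  expect_equal(fit$refined$log_beta, c(8.60, 14.76), tolerance = 1e-6)
  expect_lt(fit$sigma_fit, 1e-6)
  expect_error(refine_constants(mc, obs, adjustable = "nope"), "not in model")
  expect_error(refine_constants(mc, obs, adjustable = character(0)),
               "no adjustable")
})

test_that("a species with zero concentration everywhere is reported unidentifiable", {
  # CIP-only titration, but refine a ternary species: NADP total is zero, so
  # the species never forms and carries no information
  mt <- cip_nadp_model()
  dd <- standard_titration_design(c_cip = 1e-3, n_points = 30)
  dd$totals <- c(dd$totals, Al = 0, NADP = 0)
  obs <- simulate_titration(mt, dd)
  expect_error(
    refine_constants(mt, obs, adjustable = "Al(CIP)(HNADP)"),
    "unidentifiable")
})

test_that("refined standard deviations shrink with replicate datasets", {
  mc <- cip_nadp_model("CIP", metal = FALSE)
  dd <- standard_titration_design(c_cip = 1e-3, n_points = 30)
  gen <- function(s) gen_potentiometric_titration(
    mc, dd, noise_spec(sigma_pH = 0.005, seed = s))
  f1 <- refine_constants(mc, gen(1), adjustable = "H(CIP)",
                         start = c("H(CIP)" = 8.2))
  f4 <- refine_constants(mc, lapply(1:4, gen), adjustable = "H(CIP)",
                         start = c("H(CIP)" = 8.2))
  expect_equal(f4$n_points_used, 4 * f1$n_points_used)
  # ~ 1/sqrt(4) = 0.5, allow a wide stochastic band
  expect_lt(f4$refined$sd, f1$refined$sd)
  expect_gt(f1$refined$sd / f4$refined$sd, 1.2)
})

test_that("stepwise building selects the ternary species only when the data demand it", {
  full <- cip_nadp_model()
  base_species <- full$species[!(rownames(full$stoich) %in%
                                   c("Al(CIP)(HNADP)", "Al(HCIP)(HNADP)"))]
  comps <- lapply(seq_len(nrow(full$components)), function(i)
    eq_component(full$components$name[i], full$components$charge[i],
                 full$components$role[i]))
  base <- build_model(comps, base_species)
  cands <- list(eq_species("Al(CIP)(HNADP)", c(Al = 1, CIP = 1, NADP = 1, H = 1),
                           26.0),
                eq_species("Al(HCIP)(HNADP)", c(Al = 1, CIP = 1, NADP = 1, H = 2),
                           32.0))
  dd <- standard_titration_design(c_al = 1e-3, c_cip = 1e-3, c_nadp = 1e-3,
                                  n_points = 40)

  # positive control: data generated WITH the ternary species
  obs_t <- simulate_titration(full, dd)
  built <- stepwise_model_build(base, cands, obs_t)
  expect_setequal(built$selected, c("Al(CIP)(HNADP)", "Al(HCIP)(HNADP)"))
  expect_lt(built$fit$sigma_fit, 0.01)

  # negative control: data generated WITHOUT them (plus realistic read noise)
  obs_b <- gen_potentiometric_titration(base, dd,
                                        noise_spec(sigma_pH = 0.005, seed = 7))
  built0 <- stepwise_model_build(base, cands, obs_b)
  expect_length(built0$selected, 0)

  # empty candidate list returns the base model unchanged
  built_e <- stepwise_model_build(base, list(), obs_t)
  expect_identical(built_e$model$log_beta, base$log_beta)
  expect_error(stepwise_model_build(full, cands, obs_t), "disjoint")
})
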