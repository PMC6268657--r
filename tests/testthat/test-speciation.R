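test_that("closed-form anchors: autoprotolysis, hydrolysis ratio, acidic limit", {
  # pure water with pKw 13.78: pH = pKw/2
  m <- build_model(list(eq_component("H", 1L, "proton")), list(water_species()))
  r <- solve_speciation(m, c(H = 0))
  expect_equal(r$pH, 13.78 / 2, tolerance = 1e-8)

  al <- build_model(list(eq_component("Al", 3L, "metal"),
                         eq_component("H", 1L, "proton")),
                    c(al_hydrolysis_species(), list(water_species())))
  # [Al(OH)]/[Al] = 10^(pH - 5.5), so exactly 1 at pH 5.5
  r2 <- solve_speciation(al, c(Al = 1e-3), fixed_pH = 5.5)
  expect_equal(r2$species_conc[["Al(OH)"]] / r2$free[["Al"]], 1, tolerance = 1e-9)
  # hydrolysis negligible at pH 2
  r3 <- solve_speciation(al, c(Al = 1e-3), fixed_pH = 2)
  expect_equal(r3$free[["Al"]], 1e-3, tolerance = 1e-3)
})

test_that("mass balances close to 1e-10 relative across representative systems", {
  m <- cip_nadp_model()
  cases <- list(
    list(tot = c(Al = 1e-3, CIP = 1e-3, NADP = 1e-3, H = 8e-3), pH = NULL),
    list(tot = c(Al = 1e-3, CIP = 1e-3, NADP = 1e-3, H = -2e-3), pH = NULL),
    list(tot = c(Al = 2e-5, CIP = 2e-5, NADP = 2e-5), pH = 7.0),
    list(tot = c(Al = 1e-2, CIP = 1e-2, NADP = 1e-2), pH = 5.0))
  for (cs in cases) {
    r <- solve_speciation(m, cs$tot, fixed_pH = cs$pH)
    expect_lt(max(r$residuals), 1e-10)
    expect_true(all(r$free > 0))
  }
})

test_that("Newton solution matches the bisection oracle to 6 significant figures", {
  # metal + ligand with ML and ML2, no proton
  comps <- list(eq_component("M", 2L, "metal"), eq_component("L", -1L, "ligand"))
  sp <- list(eq_species("ML", c(M = 1, L = 1), 5.2),
             eq_species("ML2", c(M = 1, L = 2), 9.1))
  m <- build_model(comps, sp)
  for (tots in list(c(M = 1e-3, L = 2e-3), c(M = 1e-4, L = 1e-4),
                    c(M = 5e-3, L = 1e-4))) {
    r <- solve_speciation(m, tots)
    o <- oracle_bisect_2comp(m$stoich, m$log_beta, tots[c("M", "L")])
    expect_equal(unname(r$free[c("M", "L")]), unname(o$free), tolerance = 1e-6)
    expect_equal(unname(r$species_conc), unname(o$species), tolerance = 1e-6)
  }
})

test_that("1:1 concentrations rescale as the quadratic oracle predicts", {
  m <- build_model(list(eq_component("M", 0L, "metal"),
                        eq_component("L", 0L, "ligand")),
                   list(eq_species("ML", c(M = 1, L = 1), 6.0)))
  for (f in c(1, 10)) {
    tots <- c(M = 1e-5 * f, L = 2e-5 * f)
    r <- solve_speciation(m, tots)
    expect_equal(r$species_conc[["ML"]],
                 oracle_quadratic_1to1(tots["M"], tots["L"], 6.0),
                 tolerance = 1e-9)
  }
})

test_that("zero totals eliminate the component and its species exactly", {
  m <- cip_nadp_model()
  r <- solve_speciation(m, c(Al = 1e-3, CIP = 0, NADP = 0), fixed_pH = 2.0)
  expect_identical(r$free[["CIP"]], 0)
  expect_identical(r$species_conc[["Al(CIP)"]], 0)
  expect_equal(r$free[["Al"]], 1e-3, tolerance = 1e-3)
})

test_that("input validation: negative and missing totals", {
  m <- cip_nadp_model("CIP")
  expect_error(solve_speciation(m, c(Al = -1e-3, CIP = 1e-3)), "negative total")
  expect_error(solve_speciation(m, c(Al = 1e-3)), "missing totals")
  expect_error(solve_speciation(m, c(Al = 1e-3, CIP = 1e-3, Zn = 1)),
               "undeclared")
})

test_that("pH distribution fractions sum to one and track the reference", {
  m <- cip_nadp_model()
  tab <- distribution_vs_pH(m, c(Al = 1e-2, CIP = 1e-2, NADP = 1e-2),
                            pH_grid = seq(3, 8, by = 0.5))
  sums <- tapply(tab$fraction, tab$pH, sum)
  expect_true(all(abs(sums - 1) < 1e-8))

  # single-component degenerate model: fraction 1 everywhere
  m1 <- build_model(list(eq_component("Al", 3L, "metal"),
                         eq_component("H", 1L, "proton")), list())
  t1 <- distribution_vs_pH(m1, c(Al = 1e-3), pH_grid = c(3, 5, 7),
                           reference = "Al")
  expect_equal(t1$fraction, rep(1, 3), tolerance = 1e-12)

  expect_error(distribution_vs_pH(m, c(Al = 1e-3), pH_grid = c(5, 4)),
               "strictly increasing")
  expect_error(distribution_vs_pH(m1, c(Al = 1e-3), pH_grid = c(3, 7),
                                  reference = "Cu"), "not a component")
})

test_that("metal-scan distribution conserves each ligand and is monotone", {
  grid <- seq(0, 4e-5, by = 5e-6)
  tab <- distribution_vs_metal(
    build_model(list(eq_component("M", 0L, "metal"),
                     eq_component("CIP", 0L, "ligand"),
                     eq_component("NADP", 0L, "ligand")),
                list(eq_species("MCIP", c(M = 1, CIP = 1), 10.2),
                     eq_species("MNADP", c(M = 1, NADP = 1), 10.7))),
    ligand_totals = c(CIP = 2e-5, NADP = 2e-5), metal_grid = grid)
  sums <- tapply(tab$fraction, list(tab$metal_total, tab$fraction_of), sum)
  expect_true(all(abs(sums - 1) < 1e-8))
  # no metal: all free
  at0 <- tab[tab$metal_total == 0, ]
  expect_equal(at0$fraction[at0$species %in% c("CIP", "NADP")], c(1, 1),
               tolerance = 1e-12)
  expect_true(all(at0$concentration[!(at0$species %in% c("CIP", "NADP"))] == 0))
  # complexes grow monotonically with metal
  for (sp in c("MCIP", "MNADP")) {
    cc <- tab$concentration[tab$species == sp]
    expect_true(all(diff(cc) > -1e-15))
  }
  # symmetry: equal constants and totals give identical complex curves
  tb <- distribution_vs_metal(
    build_model(list(eq_component("M", 0L, "metal"),
                     eq_component("A", 0L, "ligand"),
                     eq_component("B", 0L, "ligand")),
                list(eq_species("MA", c(M = 1, A = 1), 10.5),
                     eq_species("MB", c(M = 1, B = 1), 10.5))),
    ligand_totals = c(A = 2e-5, B = 2e-5), metal_grid = grid)
  ca <- tb$concentration[tb$species == "MA" & tb$fraction_of == "A"]
  cb <- tb$concentration[tb$species == "MB" & tb$fraction_of == "B"]
  expect_equal(ca, cb, tolerance = 1e-9)
})

test_that("side-reaction coefficient and conditional constants behave", {
  # direct summation: 1 + 10^1.5 + 10^2.9 + 10^4.4 + 10^4.8 at pH 7
  expect_equal(side_reaction_coefficient(pH = 7),
               log10(1 + 10^1.5 + 10^2.9 + 10^4.4 + 10^4.8))
  expect_equal(conditional_constant(10.2 + 4.95, pH = 7), 10.2,
               tolerance = 1e-3)
  # strongly acidic limit: conditional equals absolute
  expect_equal(conditional_constant(9.36, pH = 1), 9.36, tolerance = 1e-4)
  # monotone nondecreasing in pH
  a <- vapply(seq(2, 11, by = 0.5), side_reaction_coefficient,
              hydrolysis = al_hydrolysis_log_beta(), FUN.VALUE = numeric(1))
  expect_true(all(diff(a) >= 0))
})

test_that("Gibbs energy conversion is the ln(10) R T logK line", {
  expect_equal(gibbs_from_logK(0), 0)
  expect_equal(gibbs_from_logK(10.7, 298.15), 14.6, tolerance = 1e-2)
  # doubling logK doubles the energy
  expect_equal(gibbs_from_logK(20.4), 2 * gibbs_from_logK(10.2))
  expect_error(gibbs_from_logK(5, temperature = -1), "positive")
})
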