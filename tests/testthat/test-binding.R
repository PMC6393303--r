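# Anisotropy, two-site equilibrium, and segmented stoichiometry analysis

test_that("anisotropy formula handles the limiting channel ratios", {
  expect_identical(anisotropy_from_channels(1, 1, 1)$r, 0)   # isotropic
  expect_identical(anisotropy_from_channels(2, 0, 1)$r, 1)   # fully polarized
  out <- anisotropy_from_channels(2, 1, 1)
  expect_identical(out$r, 0.25)
  expect_identical(out$I_tot, 4)
  # G-factor scales the horizontal channel
  expect_equal(anisotropy_from_channels(2, 2, 0.5)$r, 0.25, tolerance = 1e-15)
})

brute_force_free_enzyme <- function(K1, K2, dna, enz, iters = 200) {
  f <- function(E) {
    E + dna * (E / K1 + 2 * E^2 / (K1 * K2)) /
      (1 + E / K1 + E^2 / (K1 * K2)) - enz
  }
  lo <- 0; hi <- enz
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

test_that("equilibrium solve matches a brute-force bisection oracle", {
  cases <- expand.grid(K1 = c(0.01, 1, 20), K2 = c(0.1, 5, 100),
                       dna = c(10, 50), enz = c(5, 50, 120, 400))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    m <- sequential_binding_model(cs$K1, cs$K2)
    sp <- solve_two_site_equilibrium(m, cs$dna, cs$enz)
    E_ref <- brute_force_free_enzyme(cs$K1, cs$K2, cs$dna, cs$enz)
    expect_lt(abs(sp$E_free - E_ref) / max(E_ref, 1e-12), 1e-8)
    # mass balances
    expect_lt(abs(sp$D + sp$DE + sp$DE2 - cs$dna) / cs$dna, 1e-10)
    expect_lt(abs(sp$E_free + sp$DE + 2 * sp$DE2 - cs$enz) / cs$enz, 1e-10)
    fr <- c(sp$D, sp$DE, sp$DE2) / cs$dna
    expect_true(all(fr >= 0 & fr <= 1 + 1e-12))
  }
})

test_that("sequential tight binding fills the sites in order", {
  # with K1 << K2 << concentrations, enzyme fills the first site, then the
  # second; note that merely equal tight constants would leave a
  # disproportionated D/DE/DE2 mixture at 1:1, so DE purity needs the
  # sequential separation K2/K1 >> 1 as well
  m <- sequential_binding_model(K1 = 1e-6, K2 = 1e-2)
  sp1 <- solve_two_site_equilibrium(m, 50, 50)
  expect_gt(sp1$DE / 50, 0.97)
  expect_lt(sp1$E_free, 0.1)
  sp2 <- solve_two_site_equilibrium(m, 50, 150)  # excess over 2:1
  expect_gt(sp2$DE2 / 50, 0.99)
  # equal tight constants: the 1:1 point disproportionates into thirds
  meq <- sequential_binding_model(1e-3, 1e-3)
  speq <- solve_two_site_equilibrium(meq, 50, 50)
  expect_equal(c(speq$D, speq$DE, speq$DE2) / 50, rep(1 / 3, 3),
               tolerance = 1e-3)
})

test_that("predicted titrations hit the free and saturated signal limits", {
  m <- sequential_binding_model(1e-3, 1e-2, r_free = 0.05, r_1 = 0.125,
                                r_2 = 0.2, q_1 = 0.8, q_2 = 0.6)
  curve <- predict_titration(m, 50, c(0, 50, 1000))
  expect_identical(curve$anisotropy[1], 0.05)
  expect_identical(curve$rel_intensity[1], 1)
  expect_equal(curve$anisotropy[3], 0.2, tolerance = 1e-4)
  expect_equal(curve$rel_intensity[3], 0.6, tolerance = 1e-4)
  expect_true(all(diff(curve$anisotropy) > 0))
})

test_that("with equal yields anisotropy reduces to mole-fraction weighting", {
  m1 <- sequential_binding_model(5, 50, q_1 = 1, q_2 = 1)
  g <- seq(0, 300, by = 20)
  a <- predict_titration(m1, 50, g, weighting = "intensity")
  b <- predict_titration(m1, 50, g, weighting = "mole")
  expect_equal(a$anisotropy, b$anisotropy, tolerance = 1e-12)
})

test_that("segmented fit reads stoichiometry 2 off tight-binding curves", {
  cond <- study_conditions("titration")
  curve <- predict_titration(cond$truth$model, 50, cond$grid)
  sf <- segmented_fit(curve, 2, signal = "intensity")
  expect_false(sf$unresolved)
  expect_lt(abs(max(sf$breakpoints) - 100), 2)
  expect_lt(abs(sf$stoichiometry - 2), 0.05)
  # breakpoint scales with DNA concentration
  curve2 <- predict_titration(cond$truth$model, 100, cond$grid)
  sf2 <- segmented_fit(curve2, 2, signal = "intensity")
  expect_lt(abs(max(sf2$breakpoints) - 200), 4)
  expect_lt(abs(sf2$stoichiometry - 2), 0.05)
})

test_that("mole-weighted anisotropy gives the same stoichiometry readout", {
  m <- sequential_binding_model(1e-2, 1e-1)  # q = 1: no quenching
  curve <- predict_titration(m, 50, seq(0, 400, length.out = 16))
  sf <- segmented_fit(curve, 2)
  expect_lt(abs(sf$stoichiometry - 2), 0.05)
})

test_that("stoichiometry is invariant to rescaling both axes", {
  cond <- study_conditions("titration")
  curve <- predict_titration(cond$truth$model, 50, cond$grid)
  scaled <- titration_curve(curve$enzyme_nM * 1000,
                            curve$anisotropy,
                            curve$rel_intensity * 50,
                            dna_total = 50 * 1000)
  sf <- segmented_fit(curve, 2, signal = "intensity")
  sf_scaled <- segmented_fit(scaled, 2, signal = "intensity")
  expect_equal(sf_scaled$stoichiometry, sf$stoichiometry, tolerance = 1e-6)
})

test_that("exactly linear data leave the breakpoint unresolved", {
  g <- seq(0, 400, length.out = 16)
  lin <- titration_curve(g, 0.05 + 2e-4 * g, dna_total = 50)
  expect_true(segmented_fit(lin, 2)$unresolved)
})

test_that("breakpoint sharpness degrades as binding loosens", {
  # weaker binding softens the titration corner; the residual of a
  # two-segment fit grows monotonically with K
  g <- seq(0, 400, length.out = 33)
  softness <- vapply(c(0.01, 0.1, 1, 5, 10), function(K) {
    m <- sequential_binding_model(K, 4 * K)
    curve <- predict_titration(m, 50, g)
    tss <- sum((curve$anisotropy - mean(curve$anisotropy))^2)
    segmented_fit(curve, 2)$rss / tss
  }, numeric(1))
  expect_true(all(diff(softness) > 0))
})

test_that("segmented fit needs enough points per segment", {
  g <- seq(0, 400, length.out = 5)
  curve <- titration_curve(g, c(0.05, 0.1, 0.15, 0.2, 0.2), dna_total = 50)
  expect_error(segmented_fit(curve, 2), ">= 3 points")
})
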