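# Burst-phase exponential fitting

test_that("noiseless single-exponential data are recovered exactly", {
  g <- log_grid(1e-3, 2, 25)
  tc <- time_course(g, burst_model(g, 1, 40))
  fit <- fit_exponential(tc, 1)
  expect_lt(abs(fit$k_fast - 40) / 40, 1e-6)
  expect_identical(fit$A, 1)
  expect_true(fit$A_fixed)
})

test_that("noiseless two-phase data are recovered to 1e-4 relative", {
  g <- log_grid(1e-3, 2, 25)
  tc <- time_course(g, burst_model(g, 0.5, 40, 2))
  fit <- fit_exponential(tc, 2)
  expect_lt(abs(fit$A - 0.5), 1e-4)
  expect_lt(abs(fit$k_fast - 40) / 40, 1e-4)
  expect_lt(abs(fit$k_slow - 2) / 2, 1e-4)
  expect_gte(fit$k_fast, fit$k_slow)
})

test_that("the two-phase model reduces to one phase at A = 1", {
  t <- log_grid(1e-3, 2, 50)
  expect_equal(burst_model(t, 1, 40, 2), burst_model(t, 1, 40, 0),
               tolerance = 1e-15)
})

test_that("phases are labelled by magnitude after every successful fit", {
  g <- log_grid(1e-3, 2, 25)
  for (seed in 1:10) {
    cfg <- generator_config("burst", list(A = 0.6, k_fast = 80, k_slow = 3),
                            g, sigma = 0.02, replicates = 1, seed = seed)
    fit <- fit_exponential(make_burst_timecourse(cfg)[[1]], 2)
    expect_gte(fit$k_fast, fit$k_slow)
  }
})

test_that("converging phases fall back to a flagged one-phase fit", {
  g <- log_grid(1e-3, 2, 25)
  tc <- time_course(g, burst_model(g, 1, 40))  # truly single-phase data
  fit <- fit_exponential(tc, 2)
  expect_true(fit$multiphase_unresolved)
  expect_equal(fit$n_phases, 1)
  expect_lt(abs(fit$k_fast - 40) / 40, 1e-4)
})

test_that("median recovery error stays below 5% across the rate range", {
  # the quench-flow rates span 3 decades; 100 noisy curves per rate
  g <- log_grid(1e-3, 2, 25)
  for (k in c(6, 40, 183, 350)) {
    cfg <- generator_config("burst", list(A = 1, k_fast = k), g,
                            sigma = 0.02, replicates = 100, seed = 1000 + k)
    rep <- recover_parameters(cfg, n_phases = 1)
    expect_lt(attr(rep, "summary")$median_abs_rel_error, 0.05)
  }
})

test_that("fixing k_fast from the saturating condition recovers amplitudes", {
  g <- log_grid(1e-3, 2, 25)
  for (A in c(0.3, 0.5, 0.8)) {
    cfg <- generator_config("burst", list(A = A, k_fast = 40, k_slow = 2),
                            g, sigma = 0.02, replicates = 1,
                            seed = round(100 * A))
    fit <- fit_exponential(make_burst_timecourse(cfg)[[1]], 2,
                           fixed_k_fast = 40)
    expect_true(fit$k_fast_fixed)
    expect_lt(abs(amplitude_to_bound_fraction(fit) - A), 0.05)
  }
})

test_that("bound fraction demands a resolved two-phase fit", {
  g <- log_grid(1e-3, 2, 25)
  one <- fit_exponential(time_course(g, burst_model(g, 1, 40)), 1)
  expect_error(amplitude_to_bound_fraction(one), "two-phase")
  two <- fit_exponential(time_course(g, burst_model(g, 0.5, 40, 2)), 2)
  expect_equal(amplitude_to_bound_fraction(two), 0.5, tolerance = 1e-4)
})

test_that("amplitude titration round-trips through the binding model", {
  # amplitudes generated from the two-site equilibrium (fraction of DNA
  # carrying at least one polymerase) come back from fixed-k_fast refits
  g <- log_grid(1e-3, 2, 25)
  model <- sequential_binding_model(K1 = 20, K2 = 60)
  for (E in c(35, 75, 150, 500)) {
    sp <- solve_two_site_equilibrium(model, 50, E)
    A_true <- (sp$DE + sp$DE2) / 50
    cfg <- generator_config("burst",
                            list(A = A_true, k_fast = 40, k_slow = 2), g,
                            sigma = 0.02, replicates = 1, seed = E)
    fit <- fit_exponential(make_burst_timecourse(cfg)[[1]], 2,
                           fixed_k_fast = 40)
    expect_lt(abs(fit$A - A_true), 0.06)
  }
})

test_that("fit contracts reject bad inputs", {
  g <- log_grid(1e-3, 2, 25)
  expect_error(time_course(c(1, 1, 2, 3, 4), rep(0.5, 5)), "increasing")
  expect_error(time_course(1:5, c(0.5, 0.5, 0.5, 0.5, 1.2)), "1.05")
  expect_error(fit_exponential(time_course(g[1:4], rep(c(0.1, 0.2), 2)), 1),
               ">= 5")
  expect_error(fit_exponential(time_course(g[1:6], rep(c(0.1, 0.2), 3)), 2),
               ">= 7")
  expect_error(fit_exponential(time_course(g, burst_model(g, 1, 40)), 1,
                               fixed_k_fast = 40), "n_phases = 2")
  expect_error(fit_exponential(time_course(g, rep(0.4, 25)), 1),
               "degenerate")
})

test_that("primer-band decay recovers the per-step rate", {
  ch <- extension_chain(20, 350)
  cfg <- generator_config("chain", ch, log_grid(1e-3, 0.1, 12), sigma = 0,
                          replicates = 1, seed = 1)
  fit <- fit_primer_disappearance(make_gel_lanes(cfg))
  expect_lt(abs(fit$k_fast - 350) / 350, 0.02)
})

test_that("with dissociation the primer-band rate is the total hazard", {
  ch <- extension_chain(20, 350, k_off = 100)
  cfg <- generator_config("chain", ch, log_grid(1e-3, 0.1, 12), sigma = 0,
                          replicates = 1, seed = 1)
  fit <- fit_primer_disappearance(make_gel_lanes(cfg))
  expect_lt(abs(fit$k_fast - 450) / 450, 0.02)   # k_step + k_off
  expect_lt(abs(fit$A - 350 / 450), 0.01)        # extendable amplitude
})

test_that("degenerate all-primer lane series is rejected", {
  lanes <- lapply(rep(0, 5), function(t)
    lane_profile(c(100, 0, 0), time = t))
  expect_error(fit_primer_disappearance(lanes, times = rep(0, 5)),
               "degenerate")
})
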