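# Four-step incorporation scheme and processive-extension chain

test_that("scheme ODE reproduces the two-step Erlang closed form", {
  k <- 100
  sch <- kinetic_scheme(k3 = k, k4 = k)
  init <- species_state(dna_pol_dntp = 50, dntp = 250e3)
  tg <- seq(0, 0.1, length.out = 101)
  traj <- simulate_scheme(sch, init, tg)
  closed <- 1 - (1 + k * tg) * exp(-k * tg)
  expect_lt(max(abs(traj$product_fraction - closed)), 1e-6)
  expect_identical(traj$product_fraction[1], 0)
})

test_that("trajectories conserve total DNA and polymerase", {
  sch <- kinetic_scheme(k1 = 0.1, k_minus1 = 10, k2 = 0.01, k_minus2 = 500,
                        k3 = 40, k_minus3 = 5, k4 = 300, k_minus4 = 1)
  init <- species_state(dna = 50, pol = 500, dntp = 250e3)
  traj <- simulate_scheme(sch, init, c(0, log_grid(1e-4, 2, 40)))
  ct <- conservation_totals(traj)
  expect_lt(max(abs(ct$total_dna / 50 - 1)), 1e-9)
  expect_lt(max(abs(ct$total_pol / 500 - 1)), 1e-9)
  expect_true(all(diff(traj$product_fraction) >= -1e-9))
})

test_that("observed rate approaches the slow step when rates separate", {
  # conformational change at 5/s, chemistry at 500/s: the preformed ternary
  # complex turns over at the rate of the slower step
  sch <- kinetic_scheme(k3 = 5, k4 = 500)
  init <- species_state(dna_pol_dntp = 50, dntp = 250e3)
  tg <- c(0, log_grid(1e-3, 2, 30))
  traj <- simulate_scheme(sch, init, tg)
  fit <- fit_exponential(time_course(tg[-1], traj$product_fraction[-1]), 1)
  expect_lt(abs(fit$k_fast - 5) / 5, 0.05)
})

test_that("scheme rejects invalid rates, concentrations and grids", {
  expect_error(kinetic_scheme(k3 = -1), "rate")
  expect_error(kinetic_scheme(), "forward rate")
  expect_error(species_state(dna = -5), "concentrations")
  sch <- kinetic_scheme(k3 = 10, k4 = 10)
  init <- species_state(dna_pol_dntp = 50)
  expect_error(simulate_scheme(sch, init, c(0.1, 0.2)), "start at 0")
  expect_error(simulate_scheme(sch, init, c(0, 0.2, 0.1)), "increasing")
})

chain_cases <- list(
  extension_chain(20, 350, k_off = 0),
  extension_chain(20, 350, k_off = 50),
  extension_chain(20, 500, k_off = 0),
  extension_chain(5, 150, k_off = 100),
  extension_chain(1, 40, k_off = 10),
  extension_chain(12, 30, k_off = 3)
)

test_that("chain closed form matches the master-equation ODE", {
  for (ch in chain_cases) {
    for (t in c(0, 0.002, 0.01, 0.05, 0.3)) {
      a <- chain_occupancy(ch, t, method = "analytic")
      o <- chain_occupancy_ode(ch, t)
      expect_lt(max(abs(a$probability - o$probability)), 1e-8)
      expect_lt(abs(sum(a$probability) - 1), 1e-9)
      expect_true(all(a$probability >= 0))
    }
  }
})

test_that("k_off = 0 occupancy is the censored Poisson distribution", {
  ch <- extension_chain(20, 400)
  d <- chain_occupancy(ch, 0.010)
  lambda <- 4
  expect_equal(d$probability[1:20], dpois(0:19, lambda), tolerance = 1e-12)
  expect_equal(d$probability[21], 1 - ppois(19, lambda), tolerance = 1e-6)
  expect_equal(mean_extension(d), lambda, tolerance = 1e-9)
  d0 <- chain_occupancy(ch, 0)
  expect_identical(d0$probability[1], 1)
})

test_that("mean extension is non-decreasing in time", {
  ch <- extension_chain(20, 350, k_off = 50)
  m <- vapply(seq(0, 0.05, by = 0.005),
              function(t) mean_extension(chain_occupancy(ch, t)), numeric(1))
  expect_true(all(diff(m) >= -1e-12))
})

test_that("Gillespie sampler agrees with the analytic chain", {
  ch <- extension_chain(20, 500)
  emp <- gillespie_chain(ch, 50000, 0.010, seed = 7)[[1]]
  # mean extension within 3 standard errors of k*t = 5
  exact <- chain_occupancy(ch, 0.010)
  v <- sum(exact$length^2 * exact$probability) - mean_extension(exact)^2
  se3 <- 3 * sqrt(v / 50000)
  expect_lt(abs(mean_extension(emp) - 5), se3)
  # and with dissociation, stalled mass matches the closed form
  ch2 <- extension_chain(20, 350, k_off = 100)
  emp2 <- gillespie_chain(ch2, 50000, 0.02, seed = 8)[[1]]
  exact2 <- chain_occupancy(ch2, 0.02)
  expect_lt(max(abs(emp2$probability - exact2$probability)), 0.01)
})

test_that("Gillespie runs are reproducible and single molecules monotone", {
  ch <- extension_chain(10, 200, k_off = 20)
  a <- gillespie_chain(ch, 100, c(0.005, 0.02), seed = 3)
  b <- gillespie_chain(ch, 100, c(0.005, 0.02), seed = 3)
  expect_identical(a, b)
  one <- gillespie_chain(ch, 1, seq(0, 0.1, by = 0.005), seed = 9)
  lens <- vapply(one, function(d) d$length[d$probability > 0], numeric(1))
  expect_true(all(diff(lens) >= 0))
})

test_that("rebinding chain relaxes toward full extension without a trap", {
  ch <- extension_chain(5, 100, k_off = 50, trap_active = FALSE,
                        rebind_rate = 1, enzyme_nM = 100)
  d1 <- chain_occupancy(ch, 0.05)
  d2 <- chain_occupancy(ch, 0.5)
  expect_lt(abs(sum(d1$probability) - 1), 1e-8)
  expect_gt(d2$probability[6], d1$probability[6])
  expect_gt(d2$probability[6], 0.99)  # every molecule eventually finishes
  # and the Gillespie route agrees
  emp <- gillespie_chain(ch, 4000, 0.05, seed = 11)[[1]]
  expect_lt(max(abs(emp$probability - d1$probability)), 0.03)
})

test_that("primer survival and band fraction follow competing-risks forms", {
  ch <- extension_chain(20, 350)
  expect_equal(primer_survival(ch, 0.01), exp(-3.5), tolerance = 1e-12)
  expect_identical(primer_survival(ch, 0), 1)
  ch2 <- extension_chain(20, 350, k_off = 50)
  expect_equal(primer_band_fraction(ch2, 10), 50 / 400, tolerance = 1e-10)
  # band fraction equals the length-0 mass of the occupancy solution
  expect_equal(primer_band_fraction(ch2, 0.004),
               chain_occupancy(ch2, 0.004)$probability[1], tolerance = 1e-10)
  expect_error(primer_survival(ch, -1), ">= 0")
})

test_that("run-length arithmetic gives nucleotides per second", {
  expect_identical(replication_rate(20, 0.040), 500)
  expect_error(replication_rate(20, 0), "> 0")
})
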