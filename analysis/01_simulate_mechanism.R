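#!/usr/bin/env Rscript
# Simulate the minimal four-step incorporation scheme under burst conditions
# (enzyme pre-bound, saturating dNTP) and show that the observed
# single-exponential rate reports on the slower of the conformational and
# chemical steps.

library(clampkin)

dir.create("results", showWarnings = FALSE)

# Preformed complex at 50 nM DNA, 250 uM dNTP; conformational change 40/s
# assumed rate-limiting against fast chemistry
sch <- kinetic_scheme(k3 = 40, k4 = 400)
init <- species_state(dna_pol_dntp = 50, dntp = 250e3)
grid <- c(0, log_grid(1e-3, 2, 40))
traj <- simulate_scheme(sch, init, grid)
utils::write.csv(traj, "results/01_scheme_trajectory.csv", row.names = FALSE)

fit <- fit_exponential(time_course(grid[-1], traj$product_fraction[-1]), 1)
cat(sprintf("observed burst rate with k3=40/s, k4=400/s: %.2f /s\n",
            fit$k_fast))

# rate-limiting sweep: hold the faster step at 500/s, vary the slower one
sweep <- do.call(rbind, lapply(c(5, 20, 40, 100), function(k3) {
  tr <- simulate_scheme(kinetic_scheme(k3 = k3, k4 = 500), init, grid)
  f <- fit_exponential(time_course(grid[-1], tr$product_fraction[-1]), 1)
  data.frame(k3 = k3, k4 = 500, observed_rate = f$k_fast)
}))
utils::write.csv(sweep, "results/01_rate_limiting_sweep.csv",
                 row.names = FALSE)
cat("observed rate tracks the slow step:\n")
print(sweep, row.names = FALSE)

write_config(list(scheme = unclass(sch),
                  initial_nM = unclass(init),
                  grid = list(from_s = 1e-3, to_s = 2, n = 40)),
             "results/01_config.yaml")
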