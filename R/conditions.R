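#' Canonical study conditions for the recovery experiments
#'
#' The ground-truth parameter sets and sampling grids that define the
#' package's standard simulated experiments, mirroring the conditions of
#' the quench-flow and titration assays they emulate:
#'
#' * `burst_30C`: single-exponential burst at saturating enzyme
#'   (500 nM Pol delta, 50 nM 23/15 template/primer, 250 uM dTTP),
#'   k = 40 s^-1, 25 log-spaced quench times 1 ms - 2 s, noise sd 0.02.
#' * `panel_12C`: the 12 C single-nucleotide panel, biphasic truths --
#'   wild-type clamp k_fast = 183 s^-1 and the clamp mutant
#'   k_fast = 55 s^-1 (amplitude 0.9, slow phase 5 s^-1: the slow phase of
#'   those curves is not constrained by the assays, so a plausible
#'   binding-limited value is fixed once), and no clamp k_fast = 6 s^-1
#'   with amplitude 0.5 and slow phase 1.5 s^-1; 25 log-spaced points
#'   2 ms - 1 s.
#' * `chain_trap`: 20-step processive extension under the heparin trap with
#'   per-step rate 350 s^-1 and k_off = 0, quenched at 12 log-spaced times
#'   1 - 100 ms, log-normal band noise of log-sd 0.05.
#' * `titration`: tight sequential binding (K1 = 0.01 nM, K2 = 0.1 nM, both
#'   far below the 50 nM DNA), anisotropies 0.05/0.125/0.20 and relative
#'   yields 1/0.8/0.6, 16-point enzyme grid 0 - 400 nM, anisotropy noise
#'   sd 0.002.
#'
#' @param condition which condition set to return.
#' @return A named list with elements `truth`, `grid` and `sigma`, ready to
#'   drop into [generator_config()]; `panel_12C` returns one such list per
#'   sub-condition (`wt_clamp`, `mutant_clamp`, `no_clamp`).
#' @export
study_conditions <- function(condition = c("burst_30C", "panel_12C",
                                           "chain_trap", "titration")) {
  condition <- match.arg(condition)
  switch(condition,
    burst_30C = list(
      truth = list(A = 1, k_fast = 40),
      grid = default_quench_grid("30C"),
      sigma = 0.02),
    panel_12C = {
      grid <- default_quench_grid("12C")
      list(
        wt_clamp = list(truth = list(A = 0.9, k_fast = 183, k_slow = 5),
                        grid = grid, sigma = 0.02),
        mutant_clamp = list(truth = list(A = 0.9, k_fast = 55, k_slow = 5),
                            grid = grid, sigma = 0.02),
        no_clamp = list(truth = list(A = 0.5, k_fast = 6, k_slow = 1.5),
                        grid = grid, sigma = 0.02))
    },
    chain_trap = list(
      truth = extension_chain(n_steps = 20, k_step = 350, k_off = 0),
      grid = log_grid(1e-3, 0.1, 12),
      sigma = 0.05),
    titration = list(
      truth = list(
        model = sequential_binding_model(K1 = 0.01, K2 = 0.1,
                                         r_free = 0.05, r_1 = 0.125,
                                         r_2 = 0.20, q_1 = 0.8, q_2 = 0.6),
        dna_total = 50),
      grid = seq(0, 400, length.out = 16),
      sigma = 0.002))
}
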