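#' Configuration for a synthetic-data generator
#'
#' Bundles the ground truth, sampling grid, noise level, replicate count and
#' RNG seed for one simulated experiment. Generators are pure functions of
#' this configuration: the same config always yields the same data, and the
#' truth travels with the output so recovery experiments can be scored.
#'
#' Noise conventions: additive Gaussian noise of standard deviation `sigma`
#' on fraction-extended and anisotropy/intensity observables (fluorimeter /
#' quantified-gel error character), multiplicative log-normal noise of
#' log-sd `sigma` on individual band intensities (phosphorimager error
#' character).
#'
#' @param kind `"burst"`, `"chain"` or `"titration"`.
#' @param truth ground-truth parameters: for `"burst"`, a list with `A`,
#'   `k_fast` and optionally `k_slow` (or a [kinetic_scheme()] plus initial
#'   state); for `"chain"`, an [extension_chain()]; for `"titration"`, a
#'   [sequential_binding_model()] plus `dna_total`.
#' @param grid sampling grid: quench times (s) or total enzyme (nM).
#' @param sigma noise standard deviation (>= 0) on the observable.
#' @param replicates number of replicate datasets.
#' @param seed integer RNG seed (mandatory).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(kind = c("burst", "chain", "titration"),
                             truth, grid, sigma = 0.02, replicates = 1,
                             seed) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (length(grid) < 1) stop("grid must be non-empty", call. = FALSE)
  if (replicates < 0) stop("replicates must be >= 0", call. = FALSE)
  structure(list(kind = kind, truth = truth, grid = grid, sigma = sigma,
                 replicates = replicates, seed = as.integer(seed)),
            class = "generator_config")
}

#' Default quench-time grids
#'
#' 25 log-spaced quench times spanning 1 ms - 2 s for 30 C single-nucleotide
#' assays or 2 ms - 1 s for the 12 C panel, mimicking rapid-quench sampling.
#'
#' @param panel `"30C"` or `"12C"`.
#' @param n number of points.
#' @return Times in seconds.
#' @export
default_quench_grid <- function(panel = c("30C", "12C"), n = 25) {
  panel <- match.arg(panel)
  if (panel == "30C") log_grid(1e-3, 2, n) else log_grid(2e-3, 1, n)
}

#' Simulate noisy quench-flow burst time courses
#'
#' Generates fraction-extended curves from the one- or two-exponential burst
#' model (truth given as `A`, `k_fast`, `k_slow`) or from a full scheme ODE
#' (truth given as a [kinetic_scheme()] with `initial` state), adds Gaussian
#' noise of sd `sigma`, and clips to the physical window `[-0.05, 1.05]`.
#'
#' @param cfg a [generator_config()] with `kind = "burst"`.
#' @return A list of `replicates` [time_course()] objects; the noiseless
#'   backbone is attached to each as attribute `backbone`.
#' @export
make_burst_timecourse <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"), cfg$kind == "burst")
  t <- cfg$grid
  tr <- cfg$truth
  backbone <- if (inherits(tr$scheme, "kinetic_scheme")) {
    grid0 <- if (t[1] == 0) t else c(0, t)
    traj <- simulate_scheme(tr$scheme, tr$initial, grid0)
    traj$product_fraction[match(t, traj$time_s)]
  } else {
    A <- if (is.null(tr$A)) 1 else tr$A
    ks <- if (is.null(tr$k_slow)) 0 else tr$k_slow
    burst_model(t, A, tr$k_fast, ks)
  }
  with_seed(cfg$seed, {
    lapply(seq_len(cfg$replicates), function(i) {
      y <- backbone + stats::rnorm(length(t), sd = cfg$sigma)
      tc <- time_course(t, pmin(pmax(y, -0.05), 1.05))
      attr(tc, "backbone") <- backbone
      tc
    })
  })
}

#' Simulate a noisy anisotropy / intensity titration
#'
#' Computes the exact titration curve with [predict_titration()] and adds
#' Gaussian noise of sd `sigma` to the anisotropy channel and
#' `sigma * intensity_noise_scale` to the relative-intensity channel
#' (intensity spans roughly ten times the dynamic range of anisotropy
#' in these experiments).
#'
#' @param cfg a [generator_config()] with `kind = "titration"`; `cfg$truth`
#'   must carry `model` (a [sequential_binding_model()]) and `dna_total`.
#' @param intensity_noise_scale multiplier on `sigma` for the intensity
#'   channel.
#' @return A `titration_curve` with the noiseless curve attached as
#'   attribute `backbone`.
#' @export
make_titration <- function(cfg, intensity_noise_scale = 10) {
  stopifnot(inherits(cfg, "generator_config"), cfg$kind == "titration")
  tr <- cfg$truth
  clean <- predict_titration(tr$model, tr$dna_total, cfg$grid)
  with_seed(cfg$seed, {
    noisy <- clean
    noisy$anisotropy <- clean$anisotropy +
      stats::rnorm(nrow(clean), sd = cfg$sigma)
    noisy$rel_intensity <- clean$rel_intensity +
      stats::rnorm(nrow(clean), sd = cfg$sigma * intensity_noise_scale)
    attr(noisy, "backbone") <- clean
    noisy
  })
}

#' Simulate quantified gel-lane series from the extension chain
#'
#' Produces one lane per quench time from the chain occupancy (analytic/ODE
#' solution by default, or an empirical Gillespie sample at finite molecule
#' count), scaled to an arbitrary intensity unit and corrupted with
#' multiplicative log-normal band noise of log-sd `sigma`.
#'
#' @param cfg a [generator_config()] with `kind = "chain"` and an
#'   [extension_chain()] as truth; `cfg$grid` holds the quench times.
#' @param n_molecules if finite, sample lanes with [gillespie_chain()] at
#'   this molecule count instead of the exact occupancy.
#' @param intensity_scale total lane intensity in arbitrary units.
#' @return A list of [lane_profile()] objects, one per quench time.
#' @export
make_gel_lanes <- function(cfg, n_molecules = Inf, intensity_scale = 1000) {
  stopifnot(inherits(cfg, "generator_config"), cfg$kind == "chain",
            inherits(cfg$truth, "extension_chain"))
  chain <- cfg$truth
  probs <- if (is.finite(n_molecules)) {
    lapply(gillespie_chain(chain, n_molecules, cfg$grid,
                           seed = cfg$seed + 1L),
           function(d) d$probability)
  } else {
    lapply(cfg$grid, function(t) chain_occupancy(chain, t)$probability)
  }
  with_seed(cfg$seed, {
    lapply(seq_along(cfg$grid), function(i) {
      noise <- stats::rlnorm(length(probs[[i]]), meanlog = 0,
                             sdlog = cfg$sigma)
      lane_profile(probs[[i]] * intensity_scale * noise,
                   time = cfg$grid[i])
    })
  })
}
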