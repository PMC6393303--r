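#' Quench-flow time course of fractional primer extension
#'
#' @param times sampling times in seconds, strictly increasing.
#' @param fraction fraction of primer extended at each time; values must lie
#'   in `[-0.05, 1.05]` (a small allowance for measurement noise).
#' @param condition optional condition label (e.g. "500 nM, 30C").
#' @param enzyme_nM optional enzyme concentration.
#' @param sigma optional per-point standard deviation used as fit weights.
#' @return An object of class `time_course` (a data.frame with columns
#'   `time_s`, `fraction_extended`, and optionally `sigma`).
#' @export
time_course <- function(times, fraction, condition = NA_character_,
                        enzyme_nM = NA_real_, sigma = NULL) {
  if (length(times) != length(fraction))
    stop("times and fraction must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(fraction < -0.05 | fraction > 1.05))
    stop("extension fractions outside [-0.05, 1.05]", call. = FALSE)
  tc <- data.frame(time_s = times, fraction_extended = fraction)
  if (!is.null(sigma)) tc$sigma <- sigma
  structure(tc, condition = condition, enzyme_nM = enzyme_nM,
            class = c("time_course", "data.frame"))
}

#' Burst-model prediction
#'
#' The two-phase burst equation
#' \deqn{[Product](t) = A (1 - e^{-k_{fast} t}) + (1 - A)(1 - e^{-k_{slow} t})}
#' where the fast phase (amplitude `A`) reports catalysis by the preformed
#' polymerase-DNA complex and the slow phase carries contributions of
#' polymerase binding followed by catalysis. With `A = 1` (the one-phase
#' model) this reduces to `1 - exp(-k_fast t)`.
#'
#' @param t times in seconds.
#' @param A fast-phase amplitude in `[0, 1]`.
#' @param k_fast,k_slow phase rates (s^-1).
#' @return Predicted extension fractions.
#' @export
burst_model <- function(t, A, k_fast, k_slow = 0) {
  A * (1 - exp(-k_fast * t)) + (1 - A) * (1 - exp(-k_slow * t))
}

new_burst_fit <- function(A, k_fast, k_slow, n_phases, rss, se,
                          k_fast_fixed = FALSE, A_fixed = FALSE,
                          multiphase_unresolved = FALSE,
                          k_slow_at_bound = FALSE) {
  structure(list(A = A, k_fast = k_fast, k_slow = k_slow,
                 n_phases = n_phases, rss = rss, se = se,
                 k_fast_fixed = k_fast_fixed, A_fixed = A_fixed,
                 multiphase_unresolved = multiphase_unresolved,
                 k_slow_at_bound = k_slow_at_bound),
            class = "burst_fit")
}

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf("burst fit (%d phase%s)\n", x$n_phases,
              if (x$n_phases > 1) "s" else ""))
  cat(sprintf("  A      = %.4f%s\n", x$A, if (x$A_fixed) " (fixed)" else ""))
  cat(sprintf("  k_fast = %.4g s^-1%s\n", x$k_fast,
              if (x$k_fast_fixed) " (fixed)" else ""))
  if (x$n_phases == 2)
    cat(sprintf("  k_slow = %.4g s^-1%s\n", x$k_slow,
                if (x$k_slow_at_bound) " (at zero bound)" else ""))
  cat(sprintf("  RSS    = %.4g\n", x$rss))
  if (x$multiphase_unresolved)
    cat("  note: phases unresolved (k_fast/k_slow < 3); one-phase fit reported\n")
  invisible(x)
}

burst_start_values <- function(t, y, n_phases) {
  # reciprocal of the time to half-maximal signal is a robust rate guess
  # across the 3-decade range these assays span
  ymax <- max(y)
  t_half <- t[which(y >= ymax / 2)[1]]
  if (!is.finite(t_half) || t_half <= 0) t_half <- stats::median(t)
  k0 <- 1 / t_half
  if (n_phases == 1) return(list(k = k0))
  A0 <- y[which(t >= 3 * t_half)[1]]
  if (!is.finite(A0)) A0 <- ymax
  A0 <- min(max(A0, 0.05), 1)
  list(A = A0, k_fast = k0, k_slow = k0 / 20)
}

#' Fit one- or two-exponential burst kinetics to a time course
#'
#' Bounded nonlinear least squares (`minpack.lm::nlsLM`; `A` in `[0, 1]`,
#' rates >= 0) for the burst-phase product equation. With `n_phases = 1`
#' the model is `1 - exp(-k t)` (amplitude fixed at 1, the saturating-enzyme
#' regime). With `fixed_k_fast` supplied, the fast rate is held at the value
#' determined under saturating enzyme and only `A` and `k_slow` are free,
#' the protocol used to read bound-DNA fractions out of subsaturating
#' curves. Phases are labelled by magnitude (`k_fast >= k_slow`); if the two
#' free phases converge to within a factor of 3 the one-phase fit is
#' reported instead with `multiphase_unresolved = TRUE`.
#'
#' @param tc a [time_course()] (>= 5 points for one phase, >= 7 for two).
#' @param n_phases 1 or 2.
#' @param fixed_k_fast optional fast-phase rate (s^-1) to hold fixed
#'   (requires `n_phases = 2`).
#' @param weights optional per-point weights; defaults to `1/sigma^2` when
#'   the time course carries a `sigma` column, else unweighted.
#' @return A `burst_fit` with fields `A`, `k_fast`, `k_slow`, `rss`,
#'   per-parameter standard errors `se`, and flags recording which
#'   parameters were held and whether phases resolved.
#' @export
fit_exponential <- function(tc, n_phases = 1, fixed_k_fast = NULL,
                            weights = NULL) {
  stopifnot(inherits(tc, "time_course"), n_phases %in% c(1, 2))
  if (!is.null(fixed_k_fast) && n_phases != 2)
    stop("fixed_k_fast requires n_phases = 2", call. = FALSE)
  t <- tc$time_s
  y <- tc$fraction_extended
  if (n_phases == 1 && length(t) < 5)
    stop("need >= 5 points for a one-phase fit", call. = FALSE)
  if (n_phases == 2 && length(t) < 7)
    stop("need >= 7 points for a two-phase fit", call. = FALSE)
  if (stats::sd(y) < 1e-12)
    stop("degenerate data: no signal change to fit", call. = FALSE)
  if (is.null(weights) && !is.null(tc$sigma)) weights <- 1 / tc$sigma^2
  if (is.null(weights)) weights <- rep(1, length(t))
  st <- burst_start_values(t, y, n_phases)
  dat <- data.frame(t = t, y = y)

  run_fit <- function(formula, start, lower, upper) {
    fit <- try(minpack.lm::nlsLM(formula, data = dat, start = start,
                                 lower = lower, upper = upper,
                                 weights = weights,
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 200, ftol = 1e-12,
                                   ptol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error"))
      stop("burst fit failed to converge; initial guesses: ",
           paste(names(start), signif(unlist(start), 3), sep = "=",
                 collapse = ", "),
           "; data: n=", length(t), ", range=[", signif(min(y), 3), ", ",
           signif(max(y), 3), "]", call. = FALSE)
    fit
  }

  if (n_phases == 1) {
    fit <- run_fit(y ~ 1 - exp(-k * t), st, lower = c(k = 0),
                   upper = c(k = Inf))
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    return(new_burst_fit(A = 1, k_fast = co[["k"]], k_slow = 0,
                         n_phases = 1, rss = sum(stats::resid(fit)^2),
                         se = c(k_fast = se[["k"]]), A_fixed = TRUE))
  }

  if (!is.null(fixed_k_fast)) {
    kf <- fixed_k_fast
    fit <- run_fit(y ~ A * (1 - exp(-kf * t)) + (1 - A) * (1 - exp(-ks * t)),
                   list(A = st$A, ks = st$k_slow),
                   lower = c(A = 0, ks = 0), upper = c(A = 1, ks = Inf))
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    return(new_burst_fit(A = co[["A"]], k_fast = kf, k_slow = co[["ks"]],
                         n_phases = 2, rss = sum(stats::resid(fit)^2),
                         se = c(A = se[["A"]], k_slow = se[["ks"]]),
                         k_fast_fixed = TRUE,
                         k_slow_at_bound = co[["ks"]] < 1e-9))
  }

  fit <- tryCatch(
    run_fit(y ~ A * (1 - exp(-kf * t)) + (1 - A) * (1 - exp(-ks * t)),
            list(A = st$A, kf = st$k_fast, ks = st$k_slow),
            lower = c(A = 0, kf = 0, ks = 0),
            upper = c(A = 1, kf = Inf, ks = Inf)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # a singular two-phase fit usually means the data carry no resolvable
    # second phase; report the one-phase fit, flagged
    one <- tryCatch(fit_exponential(tc, n_phases = 1, weights = weights),
                    error = function(e) NULL)
    if (is.null(one)) stop(fit)
    one$multiphase_unresolved <- TRUE
    return(one)
  }
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  A <- co[["A"]]; kf <- co[["kf"]]; ks <- co[["ks"]]
  se_out <- c(A = se[["A"]], k_fast = se[["kf"]], k_slow = se[["ks"]])
  if (kf < ks) {  # relabel phases by magnitude
    tmp <- kf; kf <- ks; ks <- tmp
    A <- 1 - A
    se_out <- c(A = se[["A"]], k_fast = se[["ks"]], k_slow = se[["kf"]])
  }
  if (ks > 0 && kf / ks < 3) {
    one <- fit_exponential(tc, n_phases = 1, weights = weights)
    one$multiphase_unresolved <- TRUE
    return(one)
  }
  new_burst_fit(A = A, k_fast = kf, k_slow = ks, n_phases = 2,
                rss = sum(stats::resid(fit)^2), se = se_out,
                k_slow_at_bound = ks < 1e-9)
}

#' Bound-DNA fraction from a two-phase burst amplitude
#'
#' In the burst regime the fast-phase amplitude equals the fraction of DNA
#' pre-bound in a productive polymerase complex at mixing time, so a
#' two-phase fit partitions the substrate into fast (pre-bound) and slow
#' (binding-limited) pools.
#'
#' @param result a `burst_fit` from a two-phase fit.
#' @return The pre-bound DNA fraction (the amplitude `A`).
#' @export
amplitude_to_bound_fraction <- function(result) {
  stopifnot(inherits(result, "burst_fit"))
  if (result$n_phases != 2 || result$multiphase_unresolved)
    stop("bound fraction requires a resolved two-phase fit", call. = FALSE)
  result$A
}

#' Catalytic rate from the disappearance of the unextended primer
#'
#' The primer band decays with the total hazard of leaving length 0,
#' independent of processivity, so a single-exponential fit to
#' 1 - (primer-band fraction) versus time yields a minimal per-step
#' catalytic rate. The amplitude is left free: with dissociation under a
#' trap the extended fraction saturates at `k_step / (k_step + k_off)` and
#' the fitted rate is the total hazard `k_step + k_off` (an upward bias on
#' `k_step` documented in the methods vignette); with `k_off = 0` the model
#' reduces to `1 - exp(-k t)` and the rate is `k_step` itself.
#'
#' @param lanes a list of [lane_profile()] objects, each carrying an
#'   unextended-primer (length-0) band; >= 5 distinct quench times.
#' @param times optional quench times (seconds); defaults to the lanes'
#'   time labels.
#' @return A `burst_fit` whose `k_fast` is the primer-disappearance rate
#'   and whose `A` is the fitted extendable amplitude.
#' @export
fit_primer_disappearance <- function(lanes, times = NULL) {
  stopifnot(is.list(lanes), length(lanes) >= 5)
  if (is.null(times)) times <- vapply(lanes, function(l) attr(l, "time"),
                                      numeric(1))
  if (anyNA(times)) stop("quench times missing", call. = FALSE)
  primer_frac <- vapply(lanes, function(l) {
    if (l$length[1] != 0)
      stop("unextended-primer band (length 0) absent from lane",
           call. = FALSE)
    l$intensity[1] / sum(l$intensity)
  }, numeric(1))
  ord <- order(times)
  t <- times[ord]
  y <- 1 - primer_frac[ord]
  if (stats::sd(y) < 1e-12)
    stop("degenerate lane series: primer band does not decay", call. = FALSE)
  dat <- data.frame(t = t, y = y)
  t_half <- t[which(y >= max(y) / 2)[1]]
  if (!is.finite(t_half) || t_half <= 0) t_half <- stats::median(t)
  fit <- try(minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)), data = dat,
                               start = list(A = min(max(y), 1), k = 1 / t_half),
                               lower = c(A = 0, k = 0),
                               upper = c(A = 1.05, k = Inf),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("primer-disappearance fit failed to converge", call. = FALSE)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  new_burst_fit(A = co[["A"]], k_fast = co[["k"]], k_slow = 0, n_phases = 1,
                rss = sum(stats::resid(fit)^2),
                se = c(A = se[["A"]], k_fast = se[["k"]]))
}
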