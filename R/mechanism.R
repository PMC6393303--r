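#' Minimal four-step single-nucleotide incorporation scheme
#'
#' Container for the eight rate constants of the reversible mechanism
#'
#' \deqn{DNA_n + Pol \rightleftharpoons DNA_n \cdot Pol
#'   \rightleftharpoons DNA_n \cdot Pol \cdot dNTP
#'   \rightleftharpoons DNA_n \cdot Pol^* \cdot dNTP
#'   \rightleftharpoons DNA_{n+1} \cdot Pol^* \cdot PPi}
#'
#' i.e. polymerase-DNA association (`k1`), dNTP binding (`k2`), the
#' open-to-closed conformational change (`k3`) and the chemical step (`k4`),
#' each with its reverse rate.
#'
#' Units are fixed throughout the package: time in seconds, concentrations in
#' nM, first-order rates in s^-1 and second-order rates (`k1`, `k2`) in
#' nM^-1 s^-1.
#'
#' @param k1 DNA-polymerase association rate (nM^-1 s^-1).
#' @param k_minus1 polymerase dissociation rate (s^-1).
#' @param k2 dNTP association rate (nM^-1 s^-1).
#' @param k_minus2 dNTP dissociation rate (s^-1).
#' @param k3 forward conformational-change rate (s^-1).
#' @param k_minus3 reverse conformational-change rate (s^-1).
#' @param k4 chemical (phosphoryl-transfer) rate (s^-1).
#' @param k_minus4 reverse chemistry rate (s^-1).
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(k1 = 0, k_minus1 = 0, k2 = 0, k_minus2 = 0,
                           k3 = 0, k_minus3 = 0, k4 = 0, k_minus4 = 0) {
  rates <- c(k1 = k1, k_minus1 = k_minus1, k2 = k2, k_minus2 = k_minus2,
             k3 = k3, k_minus3 = k_minus3, k4 = k4, k_minus4 = k_minus4)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  if (all(rates[c("k1", "k2", "k3", "k4")] == 0))
    stop("at least one forward rate must be > 0 for a productive scheme",
         call. = FALSE)
  structure(as.list(rates), class = "kinetic_scheme")
}

#' Initial species concentrations for the incorporation scheme
#'
#' Species are the free DNA substrate, free polymerase, binary complex,
#' free dNTP, open ternary complex, closed (activated) ternary complex, and
#' the extended product complex `DNA_{n+1}.Pol*.PPi`. All in nM.
#'
#' @param dna free `DNA_n` (nM).
#' @param pol free polymerase (nM).
#' @param dna_pol binary `DNA_n.Pol` complex (nM).
#' @param dntp dNTP (nM); held constant during integration unless dNTP
#'   depletion is enabled in [simulate_scheme()].
#' @param dna_pol_dntp open ternary complex (nM).
#' @param dna_pol_closed closed ternary complex after the conformational
#'   change (nM).
#' @param product extended `DNA_{n+1}.Pol*.PPi` complex (nM).
#' @return An object of class `species_state`.
#' @export
species_state <- function(dna = 0, pol = 0, dna_pol = 0, dntp = 0,
                          dna_pol_dntp = 0, dna_pol_closed = 0, product = 0) {
  conc <- c(dna = dna, pol = pol, dna_pol = dna_pol, dntp = dntp,
            dna_pol_dntp = dna_pol_dntp, dna_pol_closed = dna_pol_closed,
            product = product)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("species concentrations must be finite and >= 0", call. = FALSE)
  structure(as.list(conc), class = "species_state")
}

dna_species <- c("dna", "dna_pol", "dna_pol_dntp", "dna_pol_closed", "product")
pol_species <- c("pol", "dna_pol", "dna_pol_dntp", "dna_pol_closed", "product")

#' Simulate the incorporation scheme as a mass-action ODE system
#'
#' Integrates the mass-action rate equations of the four-step scheme with a
#' stiff-capable adaptive integrator (`deSolve::lsoda`, relative tolerance
#' 1e-8 by default; rate constants in these assays span second-order binding
#' through 500 s^-1 chemistry). By default the dNTP pool is treated as
#' constant (pseudo-first-order), reflecting assays run at saturating dNTP
#' (250 uM against <= 500 nM enzyme); set `deplete_dntp = TRUE` to integrate
#' dNTP consumption explicitly.
#'
#' @param scheme a [kinetic_scheme()].
#' @param initial a [species_state()].
#' @param times strictly increasing time grid in seconds, starting at 0.
#' @param deplete_dntp integrate explicit dNTP depletion?
#' @param rtol,atol integration tolerances passed to [deSolve::lsoda()].
#' @return A data.frame with columns `time_s`, one column per species, and
#'   `product_fraction` (product-containing DNA over total DNA).
#' @export
simulate_scheme <- function(scheme, initial, times, deplete_dntp = FALSE,
                            rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(initial, "species_state"))
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  y0 <- unlist(initial)
  p <- c(unlist(scheme), deplete = as.numeric(deplete_dntp))

  deriv <- function(t, y, p) {
    v1 <- p["k1"] * y["dna"] * y["pol"] - p["k_minus1"] * y["dna_pol"]
    v2 <- p["k2"] * y["dna_pol"] * y["dntp"] -
      p["k_minus2"] * y["dna_pol_dntp"]
    v3 <- p["k3"] * y["dna_pol_dntp"] - p["k_minus3"] * y["dna_pol_closed"]
    v4 <- p["k4"] * y["dna_pol_closed"] - p["k_minus4"] * y["product"]
    list(c(dna = -v1, pol = -v1, dna_pol = v1 - v2,
           dntp = if (p["deplete"] > 0) -v2 else 0,
           dna_pol_dntp = v2 - v3, dna_pol_closed = v3 - v4, product = v4))
  }

  out <- try(deSolve::lsoda(y0, times, deriv, p, rtol = rtol, atol = atol),
             silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times))
    stop("stiff integration failed for rates: ",
         paste(names(unlist(scheme)), unlist(scheme), sep = "=",
               collapse = ", "), call. = FALSE)
  out <- as.data.frame(out)
  names(out)[1] <- "time_s"
  total_dna <- sum(y0[dna_species])
  out$product_fraction <- if (total_dna > 0) out$product / total_dna else 0
  out
}

#' Conservation totals of a simulated trajectory
#'
#' Total DNA and total polymerase across all complexes at every time point;
#' both are conserved quantities of the mechanism.
#'
#' @param traj a trajectory from [simulate_scheme()].
#' @return A data.frame with columns `time_s`, `total_dna`, `total_pol`.
#' @export
conservation_totals <- function(traj) {
  data.frame(time_s = traj$time_s,
             total_dna = rowSums(traj[dna_species]),
             total_pol = rowSums(traj[pol_species]))
}

#' Processive-extension chain parameters
#'
#' The n-step sequential incorporation model used for multi-nucleotide
#' run-off templates (e.g. the 20-adenine run of the 49-mer assay):
#' a polymerase at primer+j incorporates the next nucleotide at `k_step`
#' (translocation folded in) or dissociates at `k_off`. Under a heparin trap
#' a dissociated polymerase can never rebind, so each molecule stalls at the
#' length it had reached; without the trap, rebinding is pseudo-first-order
#' at `rebind_rate * enzyme_nM`.
#'
#' @param n_steps template run length in nucleotides (>= 1).
#' @param k_step per-nucleotide incorporation rate (s^-1), > 0.
#' @param k_off polymerase dissociation rate (s^-1), >= 0.
#' @param trap_active if `TRUE` (default) dissociated polymerase is absorbed
#'   (heparin-trap condition).
#' @param rebind_rate re-association rate (nM^-1 s^-1); used only when the
#'   trap is inactive.
#' @param enzyme_nM free-polymerase concentration (nM) setting the
#'   pseudo-first-order rebinding rate when the trap is inactive.
#' @return An object of class `extension_chain`.
#' @export
extension_chain <- function(n_steps, k_step, k_off = 0, trap_active = TRUE,
                            rebind_rate = 0, enzyme_nM = 0) {
  if (n_steps < 1 || n_steps != round(n_steps))
    stop("n_steps must be a positive integer", call. = FALSE)
  if (!is.finite(k_step) || k_step <= 0)
    stop("k_step must be > 0", call. = FALSE)
  if (!is.finite(k_off) || k_off < 0)
    stop("k_off must be >= 0", call. = FALSE)
  structure(list(n_steps = as.integer(n_steps), k_step = k_step,
                 k_off = k_off, trap_active = isTRUE(trap_active),
                 rebind_rate = rebind_rate, enzyme_nM = enzyme_nM),
            class = "extension_chain")
}

new_length_distribution <- function(length, probability, stalled, time) {
  structure(data.frame(length = length, probability = probability,
                       stalled = stalled),
            time = time, class = c("length_distribution", "data.frame"))
}

#' Product-length occupancy of the extension chain at time t
#'
#' For `k_off = 0` this is the censored Poisson distribution of the
#' irreversible identical-rate chain: `P(j) = (k t)^j e^{-k t} / j!` for
#' `j < n_steps`, with the upper Poisson tail accumulated at the full-length
#' product (run-off mass is censored at `n_steps`). With dissociation under
#' the trap, the bound population advances at total hazard
#' `r = k_step + k_off` and the closed form is
#' `bound_j = e^{-r t} (k_step t)^j / j!`, a stalled mass
#' `(k_off/r)(k_step/r)^j P(Erlang_{j+1} <= r t)` per length, and full-length
#' arrival probability `(k_step/r)^n P(Erlang_n <= r t)`. Without the trap
#' (rebinding active) no closed form exists and the chain ODE is integrated.
#'
#' @param chain an [extension_chain()].
#' @param t time in seconds, >= 0.
#' @param method `"auto"` picks the closed form when it exists; `"analytic"`
#'   forces it (error if unavailable); `"ode"` integrates the chain master
#'   equation, which serves as an independent numerical route.
#' @return A `length_distribution`: data.frame with columns `length`
#'   (0..n_steps), `probability` (total mass per length) and `stalled`
#'   (the dissociated-without-rebinding component of that mass).
#'   Probabilities sum to 1.
#' @export
chain_occupancy <- function(chain, t, method = c("auto", "analytic", "ode")) {
  stopifnot(inherits(chain, "extension_chain"))
  method <- match.arg(method)
  if (!is.finite(t) || t < 0) stop("t must be >= 0", call. = FALSE)
  analytic_ok <- chain$trap_active || chain$k_off == 0 ||
    chain$rebind_rate * chain$enzyme_nM == 0
  if (method == "analytic" && !analytic_ok)
    stop("no closed form with active rebinding; use method = \"ode\"",
         call. = FALSE)
  if (method == "ode" || !analytic_ok)
    return(chain_occupancy_ode(chain, t))
  n <- chain$n_steps
  ks <- chain$k_step
  ko <- chain$k_off
  r <- ks + ko
  j <- 0:(n - 1)
  bound <- exp(-r * t + j * log(ks * t + (t == 0)) - lgamma(j + 1))
  if (t == 0) bound <- c(1, rep(0, n - 1))
  stalled <- if (ko > 0) {
    (ko / r) * (ks / r)^j * stats::pgamma(r * t, shape = j + 1)
  } else rep(0, n)
  full <- (ks / r)^n * stats::pgamma(r * t, shape = n)
  new_length_distribution(0:n, c(bound + stalled, full), c(stalled, 0), t)
}

#' Chain master-equation solution by ODE integration
#'
#' Numerical route for [chain_occupancy()]: integrates the linear master
#' equation over bound states 0..n-1, per-length stalled (dissociated)
#' states, and the absorbing full-length state; supports pseudo-first-order
#' rebinding when the trap is inactive.
#'
#' @inheritParams chain_occupancy
#' @return A `length_distribution` (see [chain_occupancy()]).
#' @export
chain_occupancy_ode <- function(chain, t) {
  stopifnot(inherits(chain, "extension_chain"))
  if (!is.finite(t) || t < 0) stop("t must be >= 0", call. = FALSE)
  n <- chain$n_steps
  ks <- chain$k_step
  ko <- chain$k_off
  kr <- if (chain$trap_active) 0 else chain$rebind_rate * chain$enzyme_nM
  # state vector: bound_0..bound_{n-1}, off_0..off_{n-1}, full
  y0 <- c(1, rep(0, 2 * n))
  deriv <- function(tt, y, p) {
    b <- y[1:n]
    f <- y[(n + 1):(2 * n)]
    db <- -(ks + ko) * b + kr * f + c(0, ks * b[-n])
    df <- ko * b - kr * f
    dfull <- ks * b[n]
    list(c(db, df, dfull))
  }
  if (t == 0) {
    sol <- y0
  } else {
    out <- deSolve::lsoda(y0, c(0, t), deriv, NULL, rtol = 1e-10, atol = 1e-12)
    sol <- out[2, -1]
  }
  bound <- sol[1:n]
  off <- sol[(n + 1):(2 * n)]
  new_length_distribution(0:n, c(bound + off, sol[2 * n + 1]), c(off, 0), t)
}

#' Stochastic (Gillespie) simulation of the extension chain
#'
#' Simulates `n_molecules` independent polymerase-DNA complexes through the
#' sequential incorporation/dissociation chain and returns the empirical
#' product-length distribution at each requested time. This is the
#' Monte-Carlo oracle against which the analytic and ODE occupancies are
#' checked. Reproducible for a fixed seed.
#'
#' @param chain an [extension_chain()].
#' @param n_molecules number of molecules to simulate (>= 1).
#' @param t_grid non-negative times (seconds) at which to record occupancy.
#' @param seed integer RNG seed (mandatory).
#' @return A list of `length_distribution` objects, one per element of
#'   `t_grid`.
#' @export
gillespie_chain <- function(chain, n_molecules, t_grid, seed) {
  stopifnot(inherits(chain, "extension_chain"))
  if (n_molecules < 1) stop("n_molecules must be >= 1", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (any(t_grid < 0)) stop("t_grid must be >= 0", call. = FALSE)
  n <- chain$n_steps
  ks <- chain$k_step
  ko <- chain$k_off
  r <- ks + ko
  kr <- if (chain$trap_active) 0 else chain$rebind_rate * chain$enzyme_nM
  with_seed(seed, {
    if (kr == 0) {
      # vectorized: residence times are Exp(r); each completed residence
      # advances with prob ks/r, else the molecule stalls for good
      waits <- matrix(stats::rexp(n_molecules * n, rate = r), n_molecules, n)
      arrive <- t(apply(waits, 1, cumsum))
      if (n == 1) arrive <- matrix(arrive, ncol = 1)
      stepped <- matrix(stats::runif(n_molecules * n) < ks / r,
                        n_molecules, n)
      first_fail <- apply(stepped, 1, function(s) {
        w <- which(!s); if (length(w)) w[1] else Inf
      })
      lapply(t_grid, function(t) {
        completed <- rowSums(arrive <= t)
        len <- pmin(completed, n)
        stall <- is.finite(first_fail) & completed >= first_fail
        len[stall] <- first_fail[stall] - 1
        tab <- tabulate(len + 1L, nbins = n + 1L)
        stab <- tabulate(len[stall] + 1L, nbins = n + 1L)
        new_length_distribution(0:n, tab / n_molecules,
                                stab / n_molecules, t)
      })
    } else {
      t_max <- max(t_grid)
      lengths_at <- matrix(0L, n_molecules, length(t_grid))
      for (m in seq_len(n_molecules)) {
        tt <- 0; len <- 0L; bound <- TRUE
        path_t <- 0; path_len <- 0L
        while (tt < t_max && len < n) {
          if (bound) {
            tt <- tt + stats::rexp(1, r)
            if (stats::runif(1) < ks / r) len <- len + 1L else bound <- FALSE
          } else {
            tt <- tt + stats::rexp(1, kr)
            bound <- TRUE
          }
          path_t <- c(path_t, tt); path_len <- c(path_len, len)
        }
        idx <- findInterval(t_grid, path_t)
        lengths_at[m, ] <- path_len[idx]
      }
      lapply(seq_along(t_grid), function(i) {
        tab <- tabulate(lengths_at[, i] + 1L, nbins = n + 1L)
        new_length_distribution(0:n, tab / n_molecules, rep(0, n + 1),
                                t_grid[i])
      })
    }
  })
}

#' Survival of the unextended primer
#'
#' Probability that a molecule that started as a bound complex is still at
#' length 0 *and bound* at time t: `exp(-(k_step + k_off) t)` (the primer
#' leaves state 0 either by the first incorporation or by dissociation).
#' The unextended-primer gel *band* additionally contains molecules that
#' dissociated before incorporating; see [primer_band_fraction()].
#'
#' @param chain an [extension_chain()].
#' @param t time in seconds, >= 0 (vectorized).
#' @return Survival fraction(s) in `[0, 1]`.
#' @export
primer_survival <- function(chain, t) {
  stopifnot(inherits(chain, "extension_chain"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  exp(-(chain$k_step + chain$k_off) * t)
}

#' Unextended-primer band fraction under the trap
#'
#' Total mass in the length-0 gel band at time t: bound survivors plus
#' molecules that dissociated before the first incorporation,
#' `exp(-r t) + (k_off/r)(1 - exp(-r t))` with `r = k_step + k_off`.
#' As t grows this tends to the competing-risks limit `k_off / r`.
#'
#' @inheritParams primer_survival
#' @return Band fraction(s) in `[0, 1]`.
#' @export
primer_band_fraction <- function(chain, t) {
  stopifnot(inherits(chain, "extension_chain"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  r <- chain$k_step + chain$k_off
  exp(-r * t) + (chain$k_off / r) * (1 - exp(-r * t))
}

#' Mean primer extension (nucleotides) of a length distribution
#'
#' @param dist a `length_distribution`.
#' @return Expected number of incorporated nucleotides.
#' @export
mean_extension <- function(dist) {
  sum(dist$length * dist$probability)
}

#' Overall replication rate from run length and completion time
#'
#' The elementary rate estimate used for run-off templates: a template run
#' of `n_nt` nucleotides completed in `t` seconds corresponds to
#' `n_nt / t` nucleotides per second (20 nt in 40 ms gives 500 nt/s).
#'
#' @param n_nt nucleotides replicated.
#' @param t time in seconds, > 0.
#' @return Rate in nucleotides per second.
#' @export
replication_rate <- function(n_nt, t) {
  if (any(t <= 0)) stop("t must be > 0", call. = FALSE)
  n_nt / t
}
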