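#' Strategy rate constants
#'
#' Bundle the exponential growth constant \eqn{\mu} (applied during
#' nutrient-replete intervals) and the exponential death constant \eqn{\delta}
#' (applied during starvation intervals) that define one heritable growth
#' strategy, e.g. the live-slow-die-old (naive) or live-fast-die-young
#' (prion-bearing) state.
#'
#' @param mu Exponential growth constant, per unit time (>= 0, finite).
#' @param delta Exponential death constant, per unit time (>= 0, finite).
#' @param label Optional strategy name (e.g. `"LS-DO"`, `"LF-DY"`).
#' @return An object of class `strategy_rates`.
#' @examples
#' naive <- strategy_rates(mu = 1, delta = 1, label = "LS-DO")
#' prion <- strategy_rates(mu = 1.01, delta = 1.01, label = "LF-DY")
#' @export
strategy_rates <- function(mu, delta, label = NULL) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.numeric(delta), length(delta) == 1L)
  if (!is.finite(mu) || mu < 0) stop("'mu' must be finite and >= 0")
  if (!is.finite(delta) || delta < 0) stop("'delta' must be finite and >= 0")
  structure(list(mu = as.numeric(mu), delta = as.numeric(delta), label = label),
            class = "strategy_rates")
}

#' @export
print.strategy_rates <- function(x, ...) {
  cat(sprintf("<strategy_rates%s> mu = %g, delta = %g\n",
              if (is.null(x$label)) "" else paste0(" ", x$label), x$mu, x$delta))
  invisible(x)
}

#' Feast/famine environment cycle
#'
#' One environmental regime: a nutrient-replete interval of duration
#' `tau_grow`, followed by a starvation interval of duration `tau_starve`,
#' repeated `n_cycles` times.
#'
#' @param tau_grow Duration of the nutrient-replete phase (>= 0), in the same
#'   time unit as the rate constants.
#' @param tau_starve Duration of the starvation phase (>= 0).
#' @param n_cycles Non-negative integer number of repletion/starvation cycles.
#' @return An object of class `environment_cycle`.
#' @export
environment_cycle <- function(tau_grow, tau_starve, n_cycles) {
  stopifnot(is.numeric(tau_grow), is.numeric(tau_starve), is.numeric(n_cycles))
  if (!is.finite(tau_grow) || tau_grow < 0) stop("'tau_grow' must be finite and >= 0")
  if (!is.finite(tau_starve) || tau_starve < 0) stop("'tau_starve' must be finite and >= 0")
  if (!is.finite(n_cycles) || n_cycles < 0 || n_cycles != round(n_cycles))
    stop("'n_cycles' must be a non-negative integer")
  structure(list(tau_grow = as.numeric(tau_grow), tau_starve = as.numeric(tau_starve),
                 n_cycles = as.integer(n_cycles)),
            class = "environment_cycle")
}

#' Paired sub-population state in log space
#'
#' Natural-log abundances of the two competing sub-populations. Log-space
#' bookkeeping keeps many-cycle trajectories finite even when absolute
#' abundances would overflow.
#'
#' @param log_x0 Natural-log abundance of the strategy-0 (reference)
#'   sub-population.
#' @param log_x1 Natural-log abundance of the strategy-1 sub-population.
#' @return An object of class `population_pair`.
#' @export
population_pair <- function(log_x0 = 0, log_x1 = 0) {
  stopifnot(is.numeric(log_x0), length(log_x0) == 1L,
            is.numeric(log_x1), length(log_x1) == 1L)
  if (!is.finite(log_x0) || !is.finite(log_x1))
    stop("log abundances must be finite")
  structure(list(log_x0 = as.numeric(log_x0), log_x1 = as.numeric(log_x1)),
            class = "population_pair")
}

#' Log population ratio log(x1/x0)
#' @param pop A [population_pair()].
#' @return Numeric scalar `log_x1 - log_x0`.
#' @export
log_ratio <- function(pop) pop$log_x1 - pop$log_x0

#' Apply one nutrient-replete phase
#'
#' Both sub-populations grow exponentially at their own rates:
#' `log_x0 + mu0 * tau` and `log_x1 + mu1 * tau`. Lag and stationary phases
#' are neglected because they do not change the population ratio.
#'
#' @param pop A [population_pair()].
#' @param rates0,rates1 [strategy_rates()] for the two strategies.
#' @param tau Phase duration (>= 0).
#' @return The updated `population_pair`.
#' @export
grow_phase <- function(pop, rates0, rates1, tau) {
  check_phase_args(pop, rates0, rates1, tau)
  population_pair(pop$log_x0 + rates0$mu * tau,
                  pop$log_x1 + rates1$mu * tau)
}

#' Apply one starvation phase
#'
#' Both sub-populations decay exponentially: `log_x0 - delta0 * tau`,
#' `log_x1 - delta1 * tau`.
#'
#' @inheritParams grow_phase
#' @return The updated `population_pair`.
#' @export
starve_phase <- function(pop, rates0, rates1, tau) {
  check_phase_args(pop, rates0, rates1, tau)
  population_pair(pop$log_x0 - rates0$delta * tau,
                  pop$log_x1 - rates1$delta * tau)
}

check_phase_args <- function(pop, rates0, rates1, tau) {
  if (!inherits(pop, "population_pair")) stop("'pop' must be a population_pair")
  if (!inherits(rates0, "strategy_rates") || !inherits(rates1, "strategy_rates"))
    stop("'rates0' and 'rates1' must be strategy_rates")
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop("'tau' must be a finite non-negative duration")
  invisible(TRUE)
}

#' Run the grow/starve recursion over repeated cycles
#'
#' Applies the recursion
#' \deqn{x_{0,i+1} = x_{0,i} e^{\mu_0 \tau_1},\quad
#'       x_{0,i+2} = x_{0,i+1} e^{-\delta_0 \tau_2}}
#' (and likewise for \eqn{x_1}) for `n_cycles` feast/famine cycles, recording a
#' snapshot at the start and at the end of every phase.
#'
#' @param start Initial [population_pair()].
#' @param rates0,rates1 [strategy_rates()] for the two strategies.
#' @param cycle An [environment_cycle()].
#' @return An object of class `cycle_trajectory`: a list with `snapshots`
#'   (data frame with columns `step`, `cycle`, `phase`, `log_x0`, `log_x1`,
#'   `log_ratio`; `2 * n_cycles + 1` rows) and `final` (the final
#'   `population_pair`).
#' @seealso [analytic_log_ratio()] for the closed-form endpoint.
#' @export
run_cycles <- function(start, rates0, rates1, cycle) {
  if (!inherits(cycle, "environment_cycle")) stop("'cycle' must be an environment_cycle")
  check_phase_args(start, rates0, rates1, 0)
  n <- cycle$n_cycles
  steps <- 2L * n + 1L
  log_x0 <- log_x1 <- numeric(steps)
  phase <- character(steps)
  cyc <- integer(steps)
  pop <- start
  log_x0[1L] <- pop$log_x0; log_x1[1L] <- pop$log_x1
  phase[1L] <- "start"; cyc[1L] <- 0L
  k <- 1L
  for (i in seq_len(n)) {
    pop <- grow_phase(pop, rates0, rates1, cycle$tau_grow)
    k <- k + 1L
    log_x0[k] <- pop$log_x0; log_x1[k] <- pop$log_x1
    phase[k] <- "grow"; cyc[k] <- i
    pop <- starve_phase(pop, rates0, rates1, cycle$tau_starve)
    k <- k + 1L
    log_x0[k] <- pop$log_x0; log_x1[k] <- pop$log_x1
    phase[k] <- "starve"; cyc[k] <- i
  }
  snapshots <- data.frame(step = seq_len(steps) - 1L, cycle = cyc, phase = phase,
                          log_x0 = log_x0, log_x1 = log_x1,
                          log_ratio = log_x1 - log_x0)
  structure(list(snapshots = snapshots, final = pop,
                 rates0 = rates0, rates1 = rates1, cycle = cycle),
            class = "cycle_trajectory")
}

#' @export
print.cycle_trajectory <- function(x, ...) {
  n <- x$cycle$n_cycles
  cat(sprintf("<cycle_trajectory> %d cycle(s), final log(x1/x0) = %.6g\n",
              n, log_ratio(x$final)))
  invisible(x)
}

#' Closed-form final log population ratio
#'
#' The per-cycle change in the log ratio is
#' \eqn{(\mu_1 - \mu_0)\tau_1 - (\delta_1 - \delta_0)\tau_2}; after `n_cycles`
#' cycles the log ratio is the starting value plus `n_cycles` times that
#' increment. Agrees with [run_cycles()] to machine precision.
#'
#' @inheritParams run_cycles
#' @param start_log_ratio Initial `log(x1/x0)` (default 0, equal populations).
#' @return Final natural-log population ratio.
#' @export
analytic_log_ratio <- function(rates0, rates1, cycle, start_log_ratio = 0) {
  if (!inherits(cycle, "environment_cycle")) stop("'cycle' must be an environment_cycle")
  if (!inherits(rates0, "strategy_rates") || !inherits(rates1, "strategy_rates"))
    stop("'rates0' and 'rates1' must be strategy_rates")
  stopifnot(is.numeric(start_log_ratio), is.finite(start_log_ratio))
  per_cycle <- (rates1$mu - rates0$mu) * cycle$tau_grow -
    (rates1$delta - rates0$delta) * cycle$tau_starve
  start_log_ratio + cycle$n_cycles * per_cycle
}

#' Phase-space scan of final population fraction
#'
#' Evaluates the closed-form final log10 ratio x1/x0 on a grid, either over
#' cycle durations (`mode = "durations"`: axis1 = tau_grow, axis2 = tau_starve
#' at fixed strategy advantages) or over strategy offsets
#' (`mode = "advantages"`: axis1 = growth advantage delta_mu, axis2 = death
#' cost delta_delta at fixed durations). Populations start equal.
#'
#' The default advantages follow the normalization in which the baseline
#' strategy has unit rates (`mu0 = delta0 = 1`) and the fast strategy carries
#' additive offsets of 0.01 on both, i.e. a 1% growth advantage and 1% higher
#' death rate; explicit baselines may be supplied via `rates0`.
#'
#' @param axis1,axis2 Non-negative numeric axis values (non-empty).
#' @param mode `"durations"` or `"advantages"`.
#' @param rates0 Baseline [strategy_rates()] (default unit rates).
#' @param delta_mu,delta_delta Additive growth advantage and death-rate cost of
#'   strategy 1 over the baseline (used directly in `"durations"` mode).
#' @param tau_grow,tau_starve Fixed phase durations (used in `"advantages"`
#'   mode).
#' @param n_cycles Number of feast/famine cycles (default 30).
#' @return An object of class `phase_space_grid`: list with `axis1`, `axis2`,
#'   `log10_ratio` (matrix `length(axis1) x length(axis2)`), `mode`.
#'   Use [as.data.frame()] for a tidy long table.
#' @export
phase_space_scan <- function(axis1, axis2, mode = c("durations", "advantages"),
                             rates0 = strategy_rates(1, 1, "LS-DO"),
                             delta_mu = 0.01, delta_delta = 0.01,
                             tau_grow = 1, tau_starve = 1, n_cycles = 30) {
  mode <- match.arg(mode)
  if (length(axis1) < 1L || length(axis2) < 1L) stop("axes must be non-empty")
  if (any(!is.finite(axis1)) || any(axis1 < 0) || any(!is.finite(axis2)) || any(axis2 < 0))
    stop("axis values must be finite and non-negative")
  m <- matrix(NA_real_, length(axis1), length(axis2))
  for (i in seq_along(axis1)) {
    for (j in seq_along(axis2)) {
      if (mode == "durations") {
        cyc <- environment_cycle(axis1[i], axis2[j], n_cycles)
        r1 <- strategy_rates(rates0$mu + delta_mu, rates0$delta + delta_delta, "LF-DY")
      } else {
        cyc <- environment_cycle(tau_grow, tau_starve, n_cycles)
        r1 <- strategy_rates(rates0$mu + axis1[i], rates0$delta + axis2[j], "LF-DY")
      }
      m[i, j] <- analytic_log_ratio(rates0, r1, cyc) / log(10)
    }
  }
  structure(list(axis1 = axis1, axis2 = axis2, log10_ratio = m, mode = mode,
                 n_cycles = n_cycles),
            class = "phase_space_grid")
}

#' @export
as.data.frame.phase_space_grid <- function(x, ...) {
  data.frame(axis1 = rep(x$axis1, times = length(x$axis2)),
             axis2 = rep(x$axis2, each = length(x$axis1)),
             log10_ratio = as.vector(x$log10_ratio))
}

#' @export
print.phase_space_grid <- function(x, ...) {
  cat(sprintf("<phase_space_grid> %d x %d (%s mode), %d cycles, log10 ratio range [%.3g, %.3g]\n",
              length(x$axis1), length(x$axis2), x$mode, x$n_cycles,
              min(x$log10_ratio), max(x$log10_ratio)))
  invisible(x)
}

#' Equal-fitness boundary in duration space
#'
#' The starvation/growth duration ratio tau_starve/tau_grow at which a growth
#' advantage `delta_mu` exactly cancels a death-rate cost `delta_delta`
#' (per-cycle log-ratio change zero): `delta_mu / delta_delta`.
#'
#' @param delta_mu Additive growth advantage (>= 0).
#' @param delta_delta Additive death-rate cost (> 0).
#' @return The neutral duration ratio tau_starve / tau_grow.
#' @export
equal_fitness_boundary <- function(delta_mu, delta_delta) {
  stopifnot(is.numeric(delta_mu), is.numeric(delta_delta))
  if (!is.finite(delta_delta) || delta_delta <= 0)
    stop("'delta_delta' must be > 0 (boundary undefined at zero cost)")
  if (!is.finite(delta_mu) || delta_mu < 0) stop("'delta_mu' must be >= 0")
  delta_mu / delta_delta
}
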