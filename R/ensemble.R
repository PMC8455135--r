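#' Draw rate constants from an empirical distribution
#'
#' Nonparametric sampling with replacement from the stored per-replicate
#' estimates (the rates' "experimentally determined distribution"); a
#' Gaussian mode resampling from N(mean, sd) truncated at zero is available
#' as an option.
#'
#' @param dist A [rate_distribution()].
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed; when given, draws are reproducible and
#'   the caller's RNG state is untouched.
#' @param method `"empirical"` (default) or `"gaussian"`.
#' @return Numeric vector of `n` rate draws.
#' @export
sample_rates <- function(dist, n, seed = NULL, method = c("empirical", "gaussian")) {
  method <- match.arg(method)
  if (!inherits(dist, "rate_distribution")) stop("'dist' must be a rate_distribution")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer")
  draw <- function() {
    if (method == "empirical") {
      sample(dist$values, n, replace = TRUE)
    } else {
      pmax(stats::rnorm(n, dist$mean, dist$sd), 0)
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Serial-passage competition protocol
#'
#' Mirrors the serial-dilution competition design: each passage allows a
#' fixed number of bulk generations of regrowth (a 1:1000 dilution is about
#' 10 doublings), optionally followed by a starvation interval before the
#' next dilution. The reference (strategy-0) strain sets the clock: a
#' passage of g generations corresponds to growth time
#' `tau1 = g * ln(2) / mu0`, so a growth advantage `mu1 - mu0` becomes a
#' per-generation log-fitness gap of `(mu1 - mu0) * ln(2) / mu0`.
#'
#' @param generations_per_passage Bulk generations of regrowth per passage
#'   (default 10).
#' @param n_passages Number of passages (default 10, i.e. ~100 generations).
#' @param starvation_hours Starvation interval per passage at the drawn
#'   death rates (default 0: growth-only protocol).
#' @return An object of class `competition_protocol`.
#' @export
competition_protocol <- function(generations_per_passage = 10, n_passages = 10,
                                 starvation_hours = 0) {
  stopifnot(generations_per_passage > 0, n_passages >= 0,
            n_passages == round(n_passages), starvation_hours >= 0)
  structure(list(generations_per_passage = generations_per_passage,
                 n_passages = as.integer(n_passages),
                 starvation_hours = starvation_hours),
            class = "competition_protocol")
}

#' Simulate competition trajectories for an ensemble of rate draws
#'
#' For each draw, applies the feast/famine recursion passage by passage
#' (growth for the passage's generations at the drawn growth constants, then
#' starvation for the protocol's starvation interval at the drawn death
#' constants) and records the strategy-1 population fraction
#' x1/(x0 + x1) at every passage boundary.
#'
#' @param mu0,mu1,delta0,delta1 Numeric vectors of rate draws (recycled to a
#'   common length; at least one draw). `mu0` must be positive (it sets the
#'   generation clock).
#' @param protocol A [competition_protocol()].
#' @param start_fraction Initial strategy-1 fraction, in (0,1).
#' @return Matrix of fractions, one row per draw, one column per recorded
#'   generation (0, g, 2g, ...); column names are the generations.
#' @export
simulate_competition <- function(mu0, mu1, delta0 = 0, delta1 = 0,
                                 protocol = competition_protocol(),
                                 start_fraction = 0.5) {
  if (!inherits(protocol, "competition_protocol"))
    stop("'protocol' must be a competition_protocol")
  n <- max(length(mu0), length(mu1), length(delta0), length(delta1))
  if (n < 1L) stop("at least one rate draw is required")
  if (start_fraction <= 0 || start_fraction >= 1)
    stop("'start_fraction' must lie strictly inside (0,1)")
  mu0 <- rep_len(mu0, n); mu1 <- rep_len(mu1, n)
  delta0 <- rep_len(delta0, n); delta1 <- rep_len(delta1, n)
  if (any(mu0 <= 0)) stop("'mu0' draws must be positive (reference strain sets the clock)")
  g <- protocol$generations_per_passage
  np <- protocol$n_passages
  gens <- seq(0, np * g, by = g)
  out <- matrix(NA_real_, n, np + 1L, dimnames = list(NULL, gens))
  lr0 <- log(start_fraction / (1 - start_fraction))
  for (d in seq_len(n)) {
    tau1 <- g * log(2) / mu0[d]
    step <- (mu1[d] - mu0[d]) * tau1 -
      (delta1[d] - delta0[d]) * protocol$starvation_hours
    lr <- lr0 + step * (0:np)
    out[d, ] <- stats::plogis(lr)
  }
  out
}

#' Summarize an ensemble of competition trajectories
#'
#' Per-timepoint median and empirical 2.5/97.5 percentiles (linear
#' interpolation) across draws.
#'
#' @param trajectories Matrix from [simulate_competition()] (rows = draws) or
#'   a list of equal-length numeric trajectories.
#' @param generations Optional numeric timepoints; defaults to the matrix
#'   column names or the index.
#' @return An object of class `ensemble_summary`: a data frame with columns
#'   `generation`, `median`, `lo95`, `hi95`.
#' @export
summarize_ensemble <- function(trajectories, generations = NULL) {
  if (is.list(trajectories) && !is.data.frame(trajectories)) {
    len <- unique(vapply(trajectories, length, integer(1)))
    if (length(len) != 1L) stop("ragged trajectories: all must have equal length")
    trajectories <- do.call(rbind, trajectories)
  }
  if (!is.matrix(trajectories) || nrow(trajectories) < 1L)
    stop("at least one trajectory is required")
  if (is.null(generations)) {
    cn <- colnames(trajectories)
    generations <- if (!is.null(cn)) as.numeric(cn) else seq_len(ncol(trajectories)) - 1
  }
  q <- apply(trajectories, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
             names = FALSE, type = 7)
  out <- data.frame(generation = generations, median = q[2, ],
                    lo95 = q[1, ], hi95 = q[3, ])
  rownames(out) <- NULL
  class(out) <- c("ensemble_summary", "data.frame")
  out
}

#' Compare an ensemble prediction with an observed competition
#'
#' Interpolates the ensemble median and 95% band at the observed generations
#' (linear interpolation within the predicted range) and reports, per point,
#' the residual from the median and whether the observation falls inside the
#' band, plus overall coverage.
#'
#' @param summary An [summarize_ensemble()] result.
#' @param generation,fraction Observed competition trajectory.
#' @return List with `points` (data frame: `generation`, `observed`,
#'   `median`, `lo95`, `hi95`, `residual`, `inside`) and `coverage`
#'   (fraction of observed points inside the band).
#' @export
compare_to_observed <- function(summary, generation, fraction) {
  if (!inherits(summary, "ensemble_summary")) stop("'summary' must be an ensemble_summary")
  stopifnot(is.numeric(generation), is.numeric(fraction),
            length(generation) == length(fraction))
  rng <- range(summary$generation)
  keep <- generation >= rng[1] & generation <= rng[2]
  if (!any(keep)) stop("observed generations do not overlap the predicted range")
  generation <- generation[keep]; fraction <- fraction[keep]
  med <- stats::approx(summary$generation, summary$median, xout = generation)$y
  lo <- stats::approx(summary$generation, summary$lo95, xout = generation)$y
  hi <- stats::approx(summary$generation, summary$hi95, xout = generation)$y
  inside <- fraction >= lo & fraction <= hi
  list(points = data.frame(generation = generation, observed = fraction,
                           median = med, lo95 = lo, hi95 = hi,
                           residual = fraction - med, inside = inside),
       coverage = mean(inside))
}

#' Monte Carlo prediction of competitive fitness
#'
#' Samples growth and death rates for both strategies from their empirical
#' distributions (independently per strategy, paired per draw), simulates
#' the competition for each draw, and summarizes the ensemble by its median
#' and 95% interval. The default of 1000 draws matches the usual ensemble
#' size for this design.
#'
#' @param growth0,growth1 [rate_distribution()] of growth constants for the
#'   reference and fast strategies.
#' @param death0,death1 [rate_distribution()] of death constants (defaults:
#'   degenerate at 0, growth-only protocol).
#' @param protocol A [competition_protocol()].
#' @param n_draws Number of Monte Carlo draws (default 1000).
#' @param seed Optional integer seed for bit-reproducible ensembles.
#' @param start_fraction Initial strategy-1 fraction.
#' @param method Passed to [sample_rates()].
#' @param keep_draws Keep the draw-level trajectory matrix (default FALSE).
#' @return List with `summary` (an `ensemble_summary`), `n_draws`, and
#'   optionally `trajectories`.
#' @export
predict_competition <- function(growth0, growth1,
                                death0 = rate_distribution(0), death1 = rate_distribution(0),
                                protocol = competition_protocol(),
                                n_draws = 1000, seed = NULL, start_fraction = 0.5,
                                method = c("empirical", "gaussian"),
                                keep_draws = FALSE) {
  method <- match.arg(method)
  run <- function() {
    m0 <- sample_rates(growth0, n_draws, method = method)
    m1 <- sample_rates(growth1, n_draws, method = method)
    d0 <- sample_rates(death0, n_draws, method = method)
    d1 <- sample_rates(death1, n_draws, method = method)
    simulate_competition(m0, m1, d0, d1, protocol, start_fraction)
  }
  traj <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- list(summary = summarize_ensemble(traj), n_draws = n_draws)
  if (keep_draws) out$trajectories <- traj
  out
}
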