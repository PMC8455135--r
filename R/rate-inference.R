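#' Maximal proliferation rate from a growth curve
#'
#' Estimates the maximal growth rate as the peak of the derivative of the
#' growth data. The curve is first smoothed with a centered moving average;
#' the derivative is then taken by central differences on the smoothed
#' series. Two conventions are supported:
#' \describe{
#'   \item{`"specific"`}{peak of d(ln OD)/dt — the exponential growth
#'     constant (1/h) consumed by the feast/famine model.}
#'   \item{`"absolute"`}{peak of d(OD)/dt — the raw derivative peak as
#'     plotted for plate-reader bar summaries.}
#' }
#' Because a centered moving average multiplies a pure exponential by a
#' constant factor, the specific rate is estimated without smoothing bias
#' during exponential phase.
#'
#' @param time Time points (hours), strictly increasing, length >= 5.
#' @param od Optical-density readings (>= 0), same length as `time`.
#' @param method `"specific"` (default) or `"absolute"`.
#' @param window Odd integer moving-average window in points (default 5).
#' @param min_od Ignore smoothed readings below this OD when locating the
#'   peak (default 0). Raising it above the instrument noise floor avoids
#'   spurious log-derivative peaks at near-blank densities.
#' @return List with `rate` (peak derivative), `time` (location of the
#'   peak), `method`, `window`.
#' @examples
#' t <- seq(0, 10, 0.1)
#' od <- 0.01 * exp(0.4 * t)
#' estimate_growth_constant(t, od)$rate  # 0.4
#' @export
estimate_growth_constant <- function(time, od, method = c("specific", "absolute"),
                                     window = 5, min_od = 0) {
  method <- match.arg(method)
  stopifnot(is.numeric(time), is.numeric(od))
  if (length(time) != length(od)) stop("'time' and 'od' must have equal length")
  if (length(time) < 5L) stop("at least 5 points are required")
  if (any(diff(time) <= 0)) stop("'time' must be strictly increasing")
  if (all(od <= 0)) stop("all OD values are zero or negative")
  if (!is.numeric(window) || length(window) != 1L || window < 1 || window %% 2 != 1)
    stop("'window' must be an odd integer >= 1")
  sm <- if (window > 1) {
    as.numeric(stats::filter(od, rep(1 / window, window), sides = 2))
  } else od
  n <- length(sm)
  deriv <- rep(NA_real_, n)
  idx <- 2:(n - 1L)
  dt2 <- time[idx + 1L] - time[idx - 1L]
  if (method == "specific") {
    ok <- !is.na(sm) & sm > 0
    lsm <- ifelse(ok, log(sm), NA_real_)
    deriv[idx] <- (lsm[idx + 1L] - lsm[idx - 1L]) / dt2
  } else {
    deriv[idx] <- (sm[idx + 1L] - sm[idx - 1L]) / dt2
  }
  use <- !is.na(deriv) & !is.na(sm) & sm >= min_od
  if (!any(use)) stop("no usable points after smoothing and 'min_od' filtering")
  i <- which(use)[which.max(deriv[use])]
  list(rate = deriv[i], time = time[i], method = method, window = window)
}

#' Exponential decay constant from a viability series
#'
#' Chronological-lifespan decay: fits ln(CFU) against day by least squares
#' and returns the negated slope. Zero (or negative) CFU values cannot enter
#' the log-linear fit and are dropped with a warning.
#'
#' @param day Sampling days, non-negative and increasing.
#' @param cfu Colony-forming units (dilution-corrected), >= 0.
#' @return List with `delta` (decay constant, 1/day; positive for dying
#'   cultures), `se` (slope standard error), `intercept` (fitted log CFU at
#'   day 0), `n` (points used).
#' @export
estimate_decay_constant <- function(day, cfu) {
  stopifnot(is.numeric(day), is.numeric(cfu))
  if (length(day) != length(cfu)) stop("'day' and 'cfu' must have equal length")
  keep <- is.finite(cfu) & cfu > 0
  if (!any(keep)) stop("no positive CFU values; cannot fit a log-linear decay")
  if (any(!keep)) warning(sprintf("dropping %d non-positive CFU value(s) before log-linear fit",
                                  sum(!keep)))
  day <- day[keep]; cfu <- cfu[keep]
  if (length(day) < 3L) stop("at least 3 positive CFU values are required")
  fit <- stats::lm(log(cfu) ~ day)
  # noiseless series fit exactly; silence summary.lm's perfect-fit warning
  co <- suppressWarnings(summary(fit))$coefficients
  list(delta = -unname(co["day", "Estimate"]),
       se = unname(co["day", "Std. Error"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       n = length(day))
}

#' Selection coefficient from a marker competition
#'
#' Under constant selection the log odds of the marked sub-population is
#' linear in generations: ln(f/(1-f)) = logit(f0) + s g. The per-generation
#' selection coefficient s is the least-squares slope.
#'
#' Supply either `fraction` (strictly inside (0,1)) or raw colony counts
#' (`resistant`, `total`), in which case the Haldane-Anscombe continuity
#' correction (r + 0.5)/(n + 1) is applied before the logit transform.
#'
#' @param generation Generations, non-negative increasing, length >= 3.
#' @param fraction Marker fractions in (0,1), or `NULL` when counts given.
#' @param resistant,total Raw colony counts (optional alternative input).
#' @return An object of class `fitness_estimate`: list with `s`
#'   (per-generation selection coefficient), `se`, `intercept`, `n`.
#' @export
estimate_selection_coefficient <- function(generation, fraction = NULL,
                                           resistant = NULL, total = NULL) {
  stopifnot(is.numeric(generation))
  if (is.null(fraction)) {
    if (is.null(resistant) || is.null(total))
      stop("supply either 'fraction' or both 'resistant' and 'total'")
    stopifnot(is.numeric(resistant), is.numeric(total))
    if (any(resistant < 0) || any(total < 1) || any(resistant > total))
      stop("counts must satisfy 0 <= resistant <= total, total >= 1")
    fraction <- (resistant + 0.5) / (total + 1)
  }
  if (length(generation) != length(fraction))
    stop("'generation' and 'fraction' must have equal length")
  if (length(generation) < 3L) stop("at least 3 timepoints are required")
  if (any(fraction <= 0 | fraction >= 1))
    stop("fractions must lie strictly inside (0,1); use raw counts for the continuity correction")
  fit <- stats::lm(stats::qlogis(fraction) ~ generation)
  co <- suppressWarnings(summary(fit))$coefficients
  structure(list(s = unname(co["generation", "Estimate"]),
                 se = unname(co["generation", "Std. Error"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 n = length(generation)),
            class = "fitness_estimate")
}

#' @export
print.fitness_estimate <- function(x, ...) {
  cat(sprintf("<fitness_estimate> s = %.4g per generation (SE %.2g, n = %d)\n",
              x$s, x$se, x$n))
  invisible(x)
}

#' Median replicative lifespan and survival curve
#'
#' Division counts are complete observations (each mother is followed to
#' death), so no censoring machinery is needed. The median uses the midpoint
#' convention for even sample sizes; the survival curve is the empirical
#' fraction of mothers still alive at (i.e. achieving at least) each integer
#' division count.
#'
#' @param divisions Non-negative integer division counts, one per mother
#'   cell; non-empty.
#' @return List with `median` and `survival`, a data frame with columns
#'   `divisions` (0..max) and `fraction_alive`.
#' @export
median_survival <- function(divisions) {
  stopifnot(is.numeric(divisions))
  if (length(divisions) == 0L) stop("empty lifespan sample")
  if (any(divisions < 0) || any(divisions != round(divisions)))
    stop("division counts must be non-negative integers")
  grid <- 0:max(divisions)
  surv <- vapply(grid, function(d) mean(divisions >= d), numeric(1))
  list(median = stats::median(divisions),
       survival = data.frame(divisions = grid, fraction_alive = surv))
}

#' Empirical distribution of rate constants
#'
#' Stores per-replicate estimates of a growth or death rate for one strain
#' and condition; used as the sampling pool for the Monte Carlo ensemble.
#'
#' @param values Finite, non-negative rate estimates (length >= 1).
#' @param label Optional strain label.
#' @param condition Optional condition label (e.g. `"growth"`, `"death"`).
#' @return An object of class `rate_distribution` with fields `values`,
#'   `mean`, `sd` (0 for a single value), `label`, `condition`.
#' @export
rate_distribution <- function(values, label = NULL, condition = NULL) {
  stopifnot(is.numeric(values))
  if (length(values) < 1L) stop("at least one rate estimate is required")
  if (any(!is.finite(values))) stop("rate estimates must be finite")
  if (any(values < 0)) stop("rate constants must be non-negative")
  s <- if (length(values) > 1L) stats::sd(values) else 0
  structure(list(values = as.numeric(values), mean = mean(values), sd = s,
                 label = label, condition = condition),
            class = "rate_distribution")
}

#' @export
print.rate_distribution <- function(x, ...) {
  cat(sprintf("<rate_distribution%s> n = %d, mean = %.4g, sd = %.4g\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              length(x$values), x$mean, x$sd))
  invisible(x)
}
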