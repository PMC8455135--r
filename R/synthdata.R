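# Seeded generators emulating the study-style raw inputs. Every generator is
# a pure function of its arguments: the same spec (including seed) yields the
# same table. Randomness is scoped with withr::with_seed so callers' RNG
# state is never disturbed.

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Generate replicate plate-reader growth curves
#'
#' Logistic OD trajectories
#' `x(t) = K / (1 + ((K - x0)/x0) exp(-mu t))` sampled on a regular grid
#' with additive Gaussian OD noise. The default rates encode the ~60% faster
#' maximal proliferation of the fast strain (0.56 vs 0.35 per hour).
#'
#' @param mu Named vector of true maximal specific growth rates (1/h).
#' @param K Carrying capacity (OD units, > inoculum).
#' @param od0 Inoculum density (OD, > 0).
#' @param t_max Duration (h). @param dt Sampling interval (h; default 10 min).
#' @param noise_sd Additive OD noise SD (>= 0).
#' @param n_reps Replicates per strain.
#' @param seed Optional integer seed.
#' @return Data frame with columns `time_h`, `od`, `strain`, `replicate`.
#' @export
gen_growth_curves <- function(mu = c(naive = 0.35, prion = 0.56), K = 1.5,
                              od0 = 0.01, t_max = 48, dt = 1 / 6,
                              noise_sd = 0.003, n_reps = 4, seed = NULL) {
  stopifnot(all(mu > 0), K > od0, od0 > 0, t_max > 0, dt > 0,
            noise_sd >= 0, n_reps >= 1)
  if (is.null(names(mu))) names(mu) <- paste0("strain", seq_along(mu))
  tt <- seq(0, t_max, by = dt)
  with_opt_seed(seed, {
    out <- do.call(rbind, lapply(names(mu), function(s) {
      do.call(rbind, lapply(seq_len(n_reps), function(r) {
        x <- K / (1 + ((K - od0) / od0) * exp(-mu[[s]] * tt))
        data.frame(time_h = tt, od = x + stats::rnorm(length(tt), 0, noise_sd),
                   strain = s, replicate = r)
      }))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate chronological-lifespan viability series
#'
#' Expected CFU decays exponentially, `N0 * exp(-delta * day)`; observed
#' counts are Poisson around the expectation divided by the plating dilution
#' and rescaled back to CFU.
#'
#' @param delta Named vector of true decay constants (1/day, >= 0).
#' @param n0 Initial viable density (CFU, > 0).
#' @param days Sampling days (default 0 to 80 every 10).
#' @param dilution Plating dilution factor.
#' @param n_reps Replicates per strain (default 8).
#' @param noise `"poisson"` or `"none"` (exact expectations).
#' @param seed Optional integer seed.
#' @return Data frame with columns `day`, `cfu`, `dilution`, `strain`,
#'   `replicate`.
#' @export
gen_viability_series <- function(delta = c(naive = 0.04, prion = 0.08), n0 = 1e6,
                                 days = seq(0, 80, by = 10), dilution = 100,
                                 n_reps = 8, noise = c("poisson", "none"),
                                 seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(all(delta >= 0), n0 > 0, all(days >= 0), dilution >= 1, n_reps >= 1)
  if (is.null(names(delta))) names(delta) <- paste0("strain", seq_along(delta))
  with_opt_seed(seed, {
    out <- do.call(rbind, lapply(names(delta), function(s) {
      do.call(rbind, lapply(seq_len(n_reps), function(r) {
        lambda <- n0 * exp(-delta[[s]] * days) / dilution
        counts <- if (noise == "poisson") stats::rpois(length(days), lambda) else lambda
        data.frame(day = days, cfu = counts * dilution, dilution = dilution,
                   strain = s, replicate = r)
      }))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate replicative-lifespan division counts
#'
#' Integer division counts from a discretized Gompertz distribution
#' calibrated so the continuous median equals the target: with shape g and
#' target median m, the rate is `g * log(2) / (exp(g * m) - 1)`.
#'
#' @param median Named vector of target median lifespans (divisions, > 0).
#' @param shape Gompertz shape (aging acceleration, 1/division).
#' @param n Mothers per strain (default 280).
#' @param seed Optional integer seed.
#' @return Data frame with columns `strain`, `divisions`.
#' @export
gen_lifespans <- function(median = c(naive = 30, prion = 23), shape = 0.15,
                          n = 280, seed = NULL) {
  stopifnot(all(median > 0), shape > 0, n >= 1)
  if (is.null(names(median))) names(median) <- paste0("strain", seq_along(median))
  rate <- shape * log(2) / (exp(shape * median) - 1)
  if (any(!is.finite(rate) | rate <= 0)) stop("calibration unreachable for target median")
  with_opt_seed(seed, {
    out <- do.call(rbind, lapply(names(median), function(s) {
      d <- round(flexsurv::rgompertz(n, shape = shape, rate = rate[[s]]))
      data.frame(strain = s, divisions = as.integer(d))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate a marker-competition trajectory
#'
#' The true marked fraction follows the logit-linear model
#' `logit(f) = logit(f0) + s * g`; observed resistant colony counts are
#' Binomial(`n_colonies`, f) at each timepoint.
#'
#' @param s True per-generation selection coefficient.
#' @param f0 Initial marked fraction, strictly in (0,1).
#' @param generations Sampling generations (default every 10 to 100).
#' @param n_colonies Colonies scored per timepoint (>= 1).
#' @param n_mixes Independent competition mixes.
#' @param exact If TRUE, return the noiseless true fractions (no counts).
#' @param seed Optional integer seed.
#' @return Data frame with columns `generation`, `resistant`, `total`,
#'   `fraction`, `mix_id`.
#' @export
gen_competition <- function(s = 0.01, f0 = 0.5, generations = seq(0, 100, by = 10),
                            n_colonies = 1000, n_mixes = 1, exact = FALSE,
                            seed = NULL) {
  stopifnot(is.finite(s), n_colonies >= 1, n_mixes >= 1)
  if (f0 <= 0 || f0 >= 1) stop("'f0' must lie strictly inside (0,1)")
  f_true <- stats::plogis(stats::qlogis(f0) + s * generations)
  with_opt_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_mixes), function(m) {
      if (exact) {
        data.frame(generation = generations, resistant = NA_integer_,
                   total = NA_integer_, fraction = f_true, mix_id = m)
      } else {
        r <- stats::rbinom(length(generations), n_colonies, f_true)
        data.frame(generation = generations, resistant = r,
                   total = n_colonies, fraction = r / n_colonies, mix_id = m)
      }
    }))
    rownames(out) <- NULL
    out
  })
}

#' Construct a synthetic polysome gradient trace
#'
#' A sum of Gaussian peaks (40S, 60S, monosome, disome, and heavier polysome
#' peaks) with specified areas on a linear baseline, plus matching boundary
#' annotations for the area-ratio rule. Defaults give a polysome:monosome
#' area ratio of 3.2 (disome 0.9 + heavier peaks 0.8, 0.7, 0.5, 0.3).
#'
#' @param mono_area Monosome peak area.
#' @param poly_areas Areas of the disome and heavier polysome peaks, in
#'   order of position (>= 0).
#' @param small_areas Areas of the 40S and 60S peaks.
#' @param centers Named list/vector of peak centers: `s40`, `s60`, `mono`,
#'   then polysome centers spaced by `poly_spacing`.
#' @param peak_sd Gaussian SD of every peak (same position units).
#' @param poly_spacing Spacing between successive polysome peak centers.
#' @param baseline_intercept,baseline_slope Linear baseline parameters.
#' @param grid Positions at which the trace is evaluated.
#' @param noise_sd Additive absorbance noise SD (default 0).
#' @param seed Optional integer seed (only used when `noise_sd > 0`).
#' @return List with `trace` (data frame `position`, `a260`) and
#'   `boundaries` (list with `monosome`, `disome`, `polysome` ranges).
#' @export
gen_polysome_trace <- function(mono_area = 1,
                               poly_areas = c(0.9, 0.8, 0.7, 0.5, 0.3),
                               small_areas = c(s40 = 0.3, s60 = 0.5),
                               centers = c(s40 = 10, s60 = 16, mono = 24),
                               peak_sd = 0.8, poly_spacing = 6,
                               baseline_intercept = 0.05, baseline_slope = 2e-5,
                               grid = seq(0, 65, by = 0.05),
                               noise_sd = 0, seed = NULL) {
  stopifnot(mono_area >= 0, all(poly_areas >= 0), peak_sd > 0, poly_spacing > 0)
  poly_centers <- centers[["mono"]] + poly_spacing * seq_along(poly_areas)
  all_centers <- c(centers[["s40"]], centers[["s60"]], centers[["mono"]], poly_centers)
  all_areas <- c(small_areas[[1]], small_areas[[2]], mono_area, poly_areas)
  if (any(diff(all_centers) < 2 * peak_sd))
    stop("degenerate peak spec: centers closer than 2 peak SDs")
  y <- baseline_intercept + baseline_slope * grid
  for (k in seq_along(all_centers)) {
    y <- y + all_areas[k] * stats::dnorm(grid, all_centers[k], peak_sd)
  }
  if (noise_sd > 0) y <- with_opt_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  half <- poly_spacing / 2
  boundaries <- list(
    monosome = c(centers[["mono"]] - half, centers[["mono"]] + half),
    disome = c(poly_centers[1] - half, poly_centers[1] + half),
    polysome = c(poly_centers[1] - half, max(grid)))
  list(trace = data.frame(position = grid, a260 = y), boundaries = boundaries)
}

#' Generate a dual-luciferase reporter plate
#'
#' Per-well firefly and Renilla luminescence with multiplicative lognormal
#' noise; the prion genotype's expected firefly/Renilla ratio is `fold`
#' times the naive genotype's within each reporter variant.
#'
#' @param fold Named vector of true prion:naive ratios per reporter variant
#'   (default a single rare-codon variant at 1.5).
#' @param n_wells Wells (replicates) per genotype and variant (default 8).
#' @param noise_cv Coefficient of variation of the multiplicative noise on
#'   each luminescence channel (default 0.05).
#' @param firefly_base,renilla_base Baseline luminescence counts.
#' @param genotypes Genotype labels (reference first).
#' @param seed Optional integer seed.
#' @return Data frame with columns `well`, `genotype`, `variant`, `firefly`,
#'   `renilla`, `od600`.
#' @export
gen_luciferase_plate <- function(fold = c(rare = 1.5), n_wells = 8,
                                 noise_cv = 0.05, firefly_base = 5e4,
                                 renilla_base = 1e5,
                                 genotypes = c("naive", "prion"), seed = NULL) {
  stopifnot(all(fold > 0), n_wells >= 1, noise_cv >= 0)
  if (is.null(names(fold))) names(fold) <- paste0("variant", seq_along(fold))
  sdlog <- sqrt(log(1 + noise_cv^2))
  rl <- function(n) if (sdlog > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
  with_opt_seed(seed, {
    out <- do.call(rbind, lapply(names(fold), function(v) {
      do.call(rbind, lapply(genotypes, function(g) {
        f_mean <- firefly_base * if (g == genotypes[1]) 1 else fold[[v]]
        data.frame(well = paste0(v, "_", g, "_", seq_len(n_wells)),
                   genotype = g, variant = v,
                   firefly = f_mean * rl(n_wells),
                   renilla = renilla_base * rl(n_wells),
                   od600 = 0.6)
      }))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate a two-background GFP/OD screen matrix
#'
#' Per-protein lognormal baseline expression shared across both backgrounds
#' (inducing the between-background correlation seen in real screens), with
#' per-replicate multiplicative gain noise and per-well lognormal
#' measurement noise. Effect proteins are shifted in the test (prion)
#' background by the stated number of cross-protein SDs of the measured
#' value, so a noiseless +2 effect yields a delta-Z of ~2.
#'
#' @param n_proteins Number of fusion proteins (>= 10).
#' @param n_reps Replicates per background (default 4).
#' @param effects Named numeric vector of Z-offsets keyed by protein name
#'   (names must exist among the generated proteins).
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline parameters.
#' @param noise_sdlog Per-well lognormal measurement noise (log-SD).
#' @param gain_sdlog Per-replicate multiplicative gain spread (log-SD).
#' @param backgrounds Background labels (reference first).
#' @param seed Optional integer seed.
#' @return Data frame with columns `protein`, `background`, `replicate`,
#'   `gfp`, `od600`.
#' @export
gen_screen <- function(n_proteins = 1000, n_reps = 4, effects = NULL,
                       baseline_meanlog = log(1000), baseline_sdlog = 0.5,
                       noise_sdlog = 0.05, gain_sdlog = 0.1,
                       backgrounds = c("naive", "prion"), seed = NULL) {
  stopifnot(n_proteins >= 10, n_reps >= 2, noise_sdlog >= 0, gain_sdlog >= 0)
  proteins <- sprintf("P%04d", seq_len(n_proteins))
  if (!is.null(effects)) {
    if (is.null(names(effects)) || !all(names(effects) %in% proteins))
      stop("'effects' must be named by generated proteins")
  }
  with_opt_seed(seed, {
    base <- exp(stats::rnorm(n_proteins, baseline_meanlog, baseline_sdlog))
    rows <- list()
    for (bg in backgrounds) {
      for (r in seq_len(n_reps)) {
        gain <- if (gain_sdlog > 0) stats::rlnorm(1, 0, gain_sdlog) else 1
        noise <- if (noise_sdlog > 0) stats::rlnorm(n_proteins, 0, noise_sdlog) else rep(1, n_proteins)
        v <- base * gain * noise
        if (bg != backgrounds[1] && !is.null(effects)) {
          i <- match(names(effects), proteins)
          v[i] <- pmax(v[i] + effects * stats::sd(v), min(v) * 0.01)
        }
        rows[[length(rows) + 1L]] <- data.frame(protein = proteins, background = bg,
                                                replicate = r, gfp = v, od600 = 1)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate per-cell projected-area samples
#'
#' Areas drawn from a lognormal (default) or Gaussian with the specified
#' mean and SD per strain; defaults are calibrated to the reference mean
#' areas of 22.01 (naive) and 25.36 (prion) um^2.
#'
#' @param mean_area Named vector of mean areas (um^2, > 0).
#' @param sd_area SDs (default 35% of the mean).
#' @param n Cells per strain (defaults mirror the reference sample sizes).
#' @param family `"lognormal"` or `"gaussian"`.
#' @param seed Optional integer seed.
#' @return Data frame with columns `cell_id`, `area_um2`, `strain`,
#'   `replicate`.
#' @export
gen_cell_areas <- function(mean_area = c(naive = 22.01, prion = 25.36),
                           sd_area = 0.35 * mean_area,
                           n = c(naive = 4678, prion = 5501),
                           family = c("lognormal", "gaussian"), seed = NULL) {
  family <- match.arg(family)
  stopifnot(all(mean_area > 0), all(sd_area >= 0))
  if (is.null(names(mean_area))) names(mean_area) <- paste0("strain", seq_along(mean_area))
  n <- rep_len(n, length(mean_area))
  sd_area <- rep_len(sd_area, length(mean_area))
  with_opt_seed(seed, {
    out <- do.call(rbind, lapply(seq_along(mean_area), function(i) {
      m <- mean_area[[i]]; s <- sd_area[[i]]
      a <- if (family == "gaussian") {
        x <- stats::rnorm(n[i], m, s)
        while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), m, s)
        x
      } else {
        sdl <- sqrt(log(1 + (s / m)^2))
        stats::rlnorm(n[i], log(m) - sdl^2 / 2, sdl)
      }
      data.frame(cell_id = seq_len(n[i]), area_um2 = a,
                 strain = names(mean_area)[i], replicate = 1L)
    }))
    rownames(out) <- NULL
    out
  })
}
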