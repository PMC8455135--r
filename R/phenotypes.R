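#' Large-cell threshold and fractions
#'
#' The large-cell threshold is set at one standard deviation above the mean
#' cell area of the naive (reference) sample; each sample's large-cell
#' fraction is the proportion of cells at or above that threshold. The
#' sample standard deviation (n - 1 denominator) is used.
#'
#' @param naive Numeric vector of naive-cell areas (um^2), non-empty.
#' @param test Numeric vector of test-cell areas (um^2), non-empty.
#' @return List with `threshold` and `fraction` (named vector: `naive`,
#'   `test`).
#' @export
large_cell_stats <- function(naive, test) {
  stopifnot(is.numeric(naive), is.numeric(test))
  if (length(naive) == 0L || length(test) == 0L) stop("samples must be non-empty")
  if (any(naive <= 0) || any(test <= 0)) stop("cell areas must be positive")
  s <- stats::sd(naive)
  if (length(naive) < 2L || !is.finite(s) || s == 0)
    stop("naive sample has zero spread; threshold undefined")
  thr <- mean(naive) + s
  list(threshold = thr,
       fraction = c(naive = mean(naive >= thr), test = mean(test >= thr)))
}

#' Sphere-equivalent radii and volume difference from projected areas
#'
#' Approximates cells as spheres whose cross-section equals the measured
#' projected area: radius = sqrt(area / pi). The volume difference of b over
#' a depends only on the area ratio: `100 * ((area_b/area_a)^(3/2) - 1)`.
#'
#' @param mean_area_a,mean_area_b Mean projected areas (um^2), > 0.
#' @return List with `radius_a`, `radius_b` (um) and `pct_volume_diff`
#'   (percent volume of b over a).
#' @examples
#' sphere_volume_stats(22.01, 25.36)  # ~23% larger volume
#' @export
sphere_volume_stats <- function(mean_area_a, mean_area_b) {
  stopifnot(is.numeric(mean_area_a), is.numeric(mean_area_b))
  if (mean_area_a <= 0 || mean_area_b <= 0) stop("areas must be positive")
  list(radius_a = sqrt(mean_area_a / pi),
       radius_b = sqrt(mean_area_b / pi),
       pct_volume_diff = 100 * ((mean_area_b / mean_area_a)^1.5 - 1))
}

#' Relative reduction in the unbudded (G1) fraction
#'
#' @param fraction_naive,fraction_test Percent of cells in G1 (unbudded),
#'   in (0, 100].
#' @return Percent reduction of test relative to naive:
#'   `100 * (naive - test) / naive`.
#' @examples
#' budding_reduction(36.2, 27.2)  # ~25% reduction
#' @export
budding_reduction <- function(fraction_naive, fraction_test) {
  stopifnot(is.numeric(fraction_naive), is.numeric(fraction_test))
  if (fraction_naive <= 0 || fraction_naive > 100 ||
      fraction_test <= 0 || fraction_test > 100)
    stop("fractions must lie in (0, 100]")
  100 * (fraction_naive - fraction_test) / fraction_naive
}

#' Polysome-to-monosome area ratio of a gradient trace
#'
#' Applies the trace-zeroing rule: the lowest absorbance between the
#' monosome and disome peaks defines zero; after subtracting it (negative
#' values clipped to zero) the ratio is the trapezoidal area over the
#' polysome region divided by that over the monosome region.
#'
#' @param position Gradient positions, strictly increasing.
#' @param a260 Absorbance values, finite, same length.
#' @param boundaries Named list of `c(lo, hi)` position ranges with at least
#'   `monosome` and `disome`; `polysome` (one range or a list of ranges)
#'   defaults to the disome start through the end of the trace.
#' @return List with `ratio`, `baseline` (the subtracted zero value),
#'   `monosome_area`, `polysome_area`.
#' @export
polysome_monosome_ratio <- function(position, a260, boundaries) {
  stopifnot(is.numeric(position), is.numeric(a260),
            length(position) == length(a260))
  if (any(diff(position) <= 0)) stop("'position' must be strictly increasing")
  if (any(!is.finite(a260))) stop("'a260' must be finite")
  if (!is.list(boundaries) || is.null(boundaries$monosome) || is.null(boundaries$disome))
    stop("'boundaries' must annotate at least 'monosome' and 'disome' ranges")
  in_range <- function(r) which(position >= r[1] & position <= r[2])
  mono_idx <- in_range(boundaries$monosome)
  di_idx <- in_range(boundaries$disome)
  if (length(mono_idx) < 2L || length(di_idx) < 1L)
    stop("annotated regions must contain trace points")
  # trough between the two peak maxima defines zero
  pk_mono <- mono_idx[which.max(a260[mono_idx])]
  pk_di <- di_idx[which.max(a260[di_idx])]
  between <- seq(min(pk_mono, pk_di), max(pk_mono, pk_di))
  baseline <- min(a260[between])
  y <- pmax(a260 - baseline, 0)
  area <- function(idx) {
    if (length(idx) < 2L) return(0)
    pracma::trapz(position[idx], y[idx])
  }
  poly <- boundaries$polysome
  if (is.null(poly)) poly <- c(boundaries$disome[1], max(position))
  if (!is.list(poly)) poly <- list(poly)
  poly_area <- sum(vapply(poly, function(r) area(in_range(r)), numeric(1)))
  mono_area <- area(mono_idx)
  if (mono_area <= .Machine$double.eps^0.5)
    stop("monosome area is zero after baseline subtraction")
  list(ratio = poly_area / mono_area, baseline = baseline,
       monosome_area = mono_area, polysome_area = poly_area)
}

#' Dual-luciferase normalization with the naive mean set to 1.0
#'
#' Each well's test-reporter (firefly) luminescence is divided by the
#' co-expressed control reporter (Renilla) from the same plasmid; per
#' genotype (within each reporter variant) the well values are averaged and
#' scaled so that the reference genotype's mean equals 1.0.
#'
#' @param plate Data frame with columns `genotype`, `firefly`, `renilla`,
#'   and optionally `variant` (a single variant is assumed when absent).
#' @param reference Reference genotype label (default `"naive"`).
#' @return Data frame with columns `variant`, `genotype`, `n_wells`,
#'   `mean_ratio`, `normalized`.
#' @export
normalize_luciferase <- function(plate, reference = "naive") {
  req <- c("genotype", "firefly", "renilla")
  if (!all(req %in% names(plate)))
    stop("'plate' must have columns genotype, firefly, renilla")
  if (any(plate$renilla <= 0)) stop("control (Renilla) luminescence must be > 0 in every well")
  if (!"variant" %in% names(plate)) plate$variant <- "reporter"
  plate$ratio <- plate$firefly / plate$renilla
  agg <- stats::aggregate(ratio ~ variant + genotype, data = plate, FUN = mean)
  nwell <- stats::aggregate(ratio ~ variant + genotype, data = plate, FUN = length)
  agg$n_wells <- nwell$ratio
  out <- do.call(rbind, lapply(split(agg, agg$variant), function(v) {
    ref <- v$ratio[v$genotype == reference]
    if (length(ref) != 1L)
      stop(sprintf("reference genotype '%s' missing for variant '%s'", reference, v$variant[1]))
    v$normalized <- v$ratio / ref
    v
  }))
  rownames(out) <- NULL
  names(out)[names(out) == "ratio"] <- "mean_ratio"
  out[c("variant", "genotype", "n_wells", "mean_ratio", "normalized")]
}

#' Z-score differential calls from a two-background reporter screen
#'
#' Within each genetic background, each replicate's OD-normalized GFP values
#' are standardized across proteins (Z-score); a protein's background score
#' is the mean of its replicate Z-scores. A protein is robustly quantified
#' when the replicate-to-replicate SD of its Z-score is below
#' `robustness_threshold` in both backgrounds, and is called `"up"`/`"down"`
#' when additionally |Z_test - Z_ref| >= `call_threshold`.
#'
#' @param screen Data frame with columns `protein`, `background`,
#'   `replicate`, and either `value` or both `gfp` and `od600`
#'   (`value = gfp / od600`).
#' @param reference Reference background label (default `"naive"`).
#' @param call_threshold Minimum |delta Z| for an up/down call (default 1).
#' @param robustness_threshold Maximum replicate SD of Z in each background
#'   (default 1).
#' @return Data frame with one row per protein: `protein`, `z_ref`,
#'   `z_test`, `z_sd_ref`, `z_sd_test`, `delta_z`, `robust`, `call`.
#' @export
screen_zscore_differential <- function(screen, reference = "naive",
                                       call_threshold = 1, robustness_threshold = 1) {
  if (!all(c("protein", "background", "replicate") %in% names(screen)))
    stop("'screen' must have columns protein, background, replicate")
  if (!"value" %in% names(screen)) {
    if (!all(c("gfp", "od600") %in% names(screen)))
      stop("'screen' must have a 'value' column or both 'gfp' and 'od600'")
    if (any(screen$od600 <= 0)) stop("'od600' must be positive")
    screen$value <- screen$gfp / screen$od600
  }
  bgs <- unique(as.character(screen$background))
  if (length(bgs) != 2L) stop("exactly two backgrounds are required")
  if (!reference %in% bgs)
    stop(sprintf("reference background '%s' not present", reference))
  test_bg <- setdiff(bgs, reference)
  zstats <- function(bg) {
    d <- screen[screen$background == bg, ]
    m <- tapply(d$value, list(d$protein, d$replicate), mean)
    if (ncol(m) < 2L) stop(sprintf("background '%s' needs >= 2 replicates", bg))
    if (anyNA(m)) stop("incomplete protein x replicate design")
    z <- apply(m, 2, function(col) {
      s <- stats::sd(col)
      if (!is.finite(s) || s == 0)
        stop("a replicate has zero variance across proteins; Z-score undefined")
      (col - mean(col)) / s
    })
    list(mean = rowMeans(z), sd = apply(z, 1, stats::sd), proteins = rownames(m))
  }
  ref <- zstats(reference)
  tst <- zstats(test_bg)
  if (!identical(sort(ref$proteins), sort(tst$proteins)))
    stop("backgrounds measure different protein sets")
  ord <- ref$proteins
  z_ref <- ref$mean[ord]; z_test <- tst$mean[ord]
  sd_ref <- ref$sd[ord]; sd_test <- tst$sd[ord]
  dz <- z_test - z_ref
  robust <- sd_ref < robustness_threshold & sd_test < robustness_threshold
  call <- ifelse(robust & dz >= call_threshold, "up",
                 ifelse(robust & dz <= -call_threshold, "down", "unchanged"))
  out <- data.frame(protein = ord, z_ref = unname(z_ref), z_test = unname(z_test),
                    z_sd_ref = unname(sd_ref), z_sd_test = unname(sd_test),
                    delta_z = unname(dz), robust = unname(robust), call = unname(call))
  rownames(out) <- NULL
  out
}
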