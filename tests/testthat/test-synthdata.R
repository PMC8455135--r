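test_that("every generator is a pure function of its spec and seed", {
  expect_identical(gen_growth_curves(seed = 3), gen_growth_curves(seed = 3))
  expect_identical(gen_viability_series(seed = 3), gen_viability_series(seed = 3))
  expect_identical(gen_lifespans(seed = 3), gen_lifespans(seed = 3))
  expect_identical(gen_competition(seed = 3), gen_competition(seed = 3))
  expect_identical(gen_luciferase_plate(seed = 3), gen_luciferase_plate(seed = 3))
  expect_identical(gen_screen(n_proteins = 20, seed = 3),
                   gen_screen(n_proteins = 20, seed = 3))
  expect_identical(gen_cell_areas(n = c(50, 50), seed = 3),
                   gen_cell_areas(n = c(50, 50), seed = 3))
  # generators leave the caller's RNG stream untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(gen_growth_curves(seed = 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("noiseless growth curves close the loop with the specific-rate estimator", {
  g <- gen_growth_curves(noise_sd = 0, n_reps = 1)
  r <- strain_peak_rates(g)
  expect_equal(unname(r["naive"]), 0.35 * (1 - 0.01 / 1.5), tolerance = 0.003)
  expect_equal(unname(r["prion"]), 0.56 * (1 - 0.01 / 1.5), tolerance = 0.003)
})

test_that("noisy replicate curves recover the strain rate ratio within 10%", {
  ratios <- vapply(1:30, function(s) {
    r <- strain_peak_rates(gen_growth_curves(seed = s), window = 15, min_od = 0.2)
    unname(r["prion"] / r["naive"])
  }, numeric(1))
  expect_true(all(abs(ratios - 1.6) / 1.6 < 0.10))
})

test_that("viability series recover the decay constant", {
  v <- gen_viability_series(noise = "none", n_reps = 1)
  for (s in unique(v$strain)) {
    d <- v[v$strain == s, ]
    expect_equal(estimate_decay_constant(d$day, d$cfu)$delta,
                 c(naive = 0.04, prion = 0.08)[[s]], tolerance = 1e-10)
  }
  # eight Poisson replicates give a tight rate distribution around truth
  vp <- gen_viability_series(seed = 11)
  d_naive <- vapply(split(vp[vp$strain == "naive", ],
                          vp$replicate[vp$strain == "naive"]),
                    function(d) estimate_decay_constant(d$day, d$cfu)$delta,
                    numeric(1))
  pool <- rate_distribution(d_naive, "naive", "death")
  expect_equal(pool$mean, 0.04, tolerance = 0.02)
  expect_equal(length(pool$values), 8)
  # zero decay stays flat in expectation
  flat <- gen_viability_series(delta = c(x = 0), noise = "none", n_reps = 1)
  expect_equal(var(flat$cfu), 0)
})

test_that("lifespan draws hit their calibrated medians", {
  big <- gen_lifespans(median = c(x = 30), n = 1e5, seed = 4)
  expect_equal(median(big$divisions), 30, tolerance = 0.51)
  ls <- gen_lifespans(seed = 12)
  expect_lte(abs(median(ls$divisions[ls$strain == "naive"]) - 30), 2)
  expect_lte(abs(median(ls$divisions[ls$strain == "prion"]) - 23), 2)
  expect_true(all(ls$divisions >= 0))
  expect_error(gen_lifespans(median = c(x = -3)), "median")
})

test_that("competition trajectories close the loop with the logit-slope estimator", {
  ex <- gen_competition(exact = TRUE)
  expect_equal(estimate_selection_coefficient(ex$generation, ex$fraction)$s,
               0.01, tolerance = 1e-12)
  flat <- gen_competition(s = 0, exact = TRUE)
  expect_equal(var(flat$fraction), 0)
  # seeded study: binomial colony noise leaves the estimator unbiased
  est <- vapply(1:100, function(sd) {
    d <- gen_competition(seed = sd)
    estimate_selection_coefficient(d$generation, resistant = d$resistant,
                                   total = d$total)$s
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.01), 0.001)
  expect_error(gen_competition(f0 = 1), "strictly inside")
})

test_that("constructed polysome traces reproduce their specified area ratio", {
  tr <- gen_polysome_trace()
  expect_equal(polysome_monosome_ratio(tr$trace$position, tr$trace$a260,
                                       tr$boundaries)$ratio,
               3.2, tolerance = 0.05)
  # a different baseline slope barely moves the measured ratio
  tr2 <- gen_polysome_trace(baseline_slope = 2e-4)
  expect_equal(polysome_monosome_ratio(tr2$trace$position, tr2$trace$a260,
                                       tr2$boundaries)$ratio,
               3.2, tolerance = 0.1)
  expect_error(gen_polysome_trace(poly_spacing = 0.5), "degenerate")
})

test_that("luciferase plates recover the true fold change", {
  clean <- gen_luciferase_plate(noise_cv = 0)
  out <- normalize_luciferase(clean)
  expect_equal(out$normalized[out$genotype == "prion"], 1.5, tolerance = 1e-12)
  # seeded study at 5% noise, 8 wells
  folds <- vapply(1:100, function(s) {
    nl <- normalize_luciferase(gen_luciferase_plate(seed = s))
    nl$normalized[nl$genotype == "prion"]
  }, numeric(1))
  expect_lt(abs(mean(folds) - 1.5), 0.03)
})

test_that("screen generator produces calls only where effects were planted", {
  none <- gen_screen(n_proteins = 100, noise_sdlog = 0, gain_sdlog = 0, seed = 5)
  expect_true(all(screen_zscore_differential(none)$call == "unchanged"))

  eff <- setNames(rep(2, 20), sprintf("P%04d", 1:20))
  scr <- gen_screen(n_proteins = 1000, effects = eff, noise_sdlog = 0,
                    gain_sdlog = 0, seed = 6)
  res <- screen_zscore_differential(scr)
  expect_setequal(res$protein[res$call == "up"], names(eff))

  # shared baselines induce strong between-background correlation
  noisy <- gen_screen(n_proteins = 500, seed = 7)
  resn <- screen_zscore_differential(noisy)
  expect_gt(cor(resn$z_ref, resn$z_test), 0.7)
  expect_error(gen_screen(effects = c(NOPE = 2), seed = 1), "named by generated")
})

test_that("cell-area samples recover the calibrated strain means", {
  ca <- gen_cell_areas(n = c(20000, 20000), seed = 8)
  m <- tapply(ca$area_um2, ca$strain, mean)
  expect_equal(unname(m["prion"] / m["naive"]), 25.36 / 22.01, tolerance = 0.01)
  expect_true(all(ca$area_um2 > 0))

  # equal strain specs: no systematic large-cell enrichment
  eq <- gen_cell_areas(mean_area = c(a = 22, b = 22), n = c(5000, 5000), seed = 9)
  st <- large_cell_stats(eq$area_um2[eq$strain == "a"], eq$area_um2[eq$strain == "b"])
  expect_lt(abs(st$fraction[["naive"]] - st$fraction[["test"]]), 0.02)

  # gaussian mode: naive large-cell fraction is 1 - Phi(1)
  g <- gen_cell_areas(mean_area = c(naive = 22, prion = 25.4),
                      sd_area = c(4, 5), n = c(50000, 1000),
                      family = "gaussian", seed = 10)
  stg <- large_cell_stats(g$area_um2[g$strain == "naive"],
                          g$area_um2[g$strain == "prion"])
  expect_equal(stg$fraction[["naive"]], 1 - pnorm(1), tolerance = 0.01)
})
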