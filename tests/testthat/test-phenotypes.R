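test_that("large-cell threshold sits one naive SD above the naive mean", {
  set.seed(314)
  naive <- rnorm(2e5, 50, 5)
  st <- large_cell_stats(naive, naive + sd(naive))
  expect_equal(st$threshold, mean(naive) + sd(naive))
  expect_equal(unname(st$fraction["naive"]), 1 - pnorm(1), tolerance = 0.01)
  expect_equal(unname(st$fraction["test"]), 0.5, tolerance = 0.01)

  # the fractions only depend on the shape, not the area unit
  st2 <- large_cell_stats(naive * 3.7, (naive + sd(naive)) * 3.7)
  expect_equal(st2$fraction, st$fraction)

  expect_error(large_cell_stats(c(5, 5), c(6, 7)), "zero spread")
  expect_error(large_cell_stats(numeric(0), c(6)), "non-empty")
})

test_that("sphere-volume conversion reproduces the area-to-volume arithmetic", {
  s <- sphere_volume_stats(22.01, 25.36)
  expect_equal(s$radius_a, 2.65, tolerance = 0.005)
  expect_equal(s$radius_b, 2.84, tolerance = 0.005)
  expect_equal(s$pct_volume_diff, 23, tolerance = 1)

  expect_equal(sphere_volume_stats(10, 10)$pct_volume_diff, 0)
  s2 <- sphere_volume_stats(pi, 4 * pi)
  expect_equal(s2$radius_a, 1)
  expect_equal(s2$radius_b, 2)
  expect_equal(s2$pct_volume_diff, 700)

  # inverse symmetry: (1 + p_ab/100)(1 + p_ba/100) = 1
  p_ab <- sphere_volume_stats(22.01, 25.36)$pct_volume_diff
  p_ba <- sphere_volume_stats(25.36, 22.01)$pct_volume_diff
  expect_equal((1 + p_ab / 100) * (1 + p_ba / 100), 1)

  expect_error(sphere_volume_stats(0, 5), "positive")
})

test_that("G1 reduction is the relative drop in the unbudded fraction", {
  expect_equal(budding_reduction(36.2, 27.2), 24.86, tolerance = 0.01)
  expect_equal(budding_reduction(40, 40), 0)
  expect_equal(budding_reduction(50, 25), 50)
  expect_error(budding_reduction(0, 10), "\\(0, 100\\]")
})

test_that("polysome/monosome ratio applies the trough-zeroing rule", {
  tr <- gen_polysome_trace()
  res <- polysome_monosome_ratio(tr$trace$position, tr$trace$a260, tr$boundaries)
  expect_equal(res$ratio, 3.2, tolerance = 0.05)

  # constant offsets are removed exactly by the zeroing rule
  up <- polysome_monosome_ratio(tr$trace$position, tr$trace$a260 + 0.35, tr$boundaries)
  expect_equal(up$ratio, res$ratio)

  # the ratio is scale-free in the absorbance unit
  sc <- polysome_monosome_ratio(tr$trace$position, tr$trace$a260 * 2.5, tr$boundaries)
  expect_equal(sc$ratio, res$ratio, tolerance = 1e-12)

  # no polysome signal -> ratio 0
  tr0 <- gen_polysome_trace(poly_areas = c(1e-9, 0, 0, 0, 0))
  res0 <- polysome_monosome_ratio(tr0$trace$position, tr0$trace$a260, tr0$boundaries)
  expect_lt(res0$ratio, 0.01)

  # flat trace: no monosome area to normalize by
  flat <- data.frame(position = tr0$trace$position, a260 = 0.05)
  expect_error(polysome_monosome_ratio(flat$position, flat$a260, tr0$boundaries),
               "monosome area")
  expect_error(polysome_monosome_ratio(tr$trace$position, tr$trace$a260,
                                       list(monosome = c(20, 28))),
               "disome")
})

test_that("luciferase normalization scales the naive mean to 1.0", {
  plate <- data.frame(genotype = rep(c("naive", "prion"), each = 4),
                      firefly = c(2, 4, 6, 8, 3, 6, 9, 12),
                      renilla = c(1, 2, 3, 4, 1, 2, 3, 4))
  out <- normalize_luciferase(plate)
  expect_equal(out$normalized[out$genotype == "naive"], 1)
  expect_equal(out$normalized[out$genotype == "prion"], 1.5)

  same <- normalize_luciferase(data.frame(genotype = c("naive", "prion"),
                                          firefly = c(5, 5), renilla = c(2, 2)))
  expect_equal(same$normalized, c(1, 1))

  bad <- plate; bad$renilla[3] <- 0
  expect_error(normalize_luciferase(bad), "Renilla")
})

test_that("screen Z-scoring standardizes each replicate and calls constructed shifts", {
  eff <- setNames(c(2, 2, -2), c("P0003", "P0010", "P0017"))
  scr <- gen_screen(n_proteins = 50, n_reps = 3, effects = eff,
                    noise_sdlog = 0, gain_sdlog = 0, seed = 21)
  res <- screen_zscore_differential(scr)

  # per-background scores average to ~0 across proteins by construction
  expect_lt(abs(mean(res$z_ref)), 1e-10)
  expect_lt(abs(sd(res$z_ref) - 1), 0.05)

  expect_setequal(res$protein[res$call == "up"], c("P0003", "P0010"))
  expect_setequal(res$protein[res$call == "down"], "P0017")

  # per-replicate multiplicative gain cancels in the Z-scores
  scr2 <- scr
  idx <- scr2$background == "prion" & scr2$replicate == 2
  scr2$gfp[idx] <- scr2$gfp[idx] * 5
  res2 <- screen_zscore_differential(scr2)
  expect_equal(res2$delta_z, res$delta_z, tolerance = 1e-12)

  const <- scr
  const$gfp[const$background == "naive" & const$replicate == 1] <- 100
  expect_error(screen_zscore_differential(const), "zero variance")
  expect_error(screen_zscore_differential(scr[scr$replicate == 1, ]), "2 replicates")
})

test_that("positional CAI is the windowed geometric mean of codon weights", {
  w <- c(AAA = 1, GAA = 0.5, CCA = 0.25, TTT = 1)
  expect_equal(cai_profile("AAAAAAAAA", w, window = 1)$mean_cai, rep(1, 3))
  expect_equal(cai_profile("GAAGAAGAA", w, window = 5)$mean_cai, rep(0.5, 3))
  # two-codon window over weights {0.25, 1}
  expect_equal(cai_profile("CCAAAA", w, window = 2)$mean_cai[1], sqrt(0.25))
  # terminal stop codon is dropped, internal unknown codons are rejected
  expect_equal(nrow(cai_profile("AAATTTTAA", w, window = 1)), 2)
  expect_error(cai_profile("AAACGGAAA", w, window = 1), "no weight")
  expect_error(cai_profile("AAAA", w), "divisible")
  # profiles live in (0, 1] and averaging respects sequence coverage
  prof <- cai_profile(c("AAAGAA", "AAAGAACCA"), w, window = 1)
  expect_true(all(prof$mean_cai > 0 & prof$mean_cai <= 1))
  expect_equal(prof$n_seqs, c(2L, 2L, 1L))
})

test_that("relative adaptiveness weights normalize each synonymous family to max 1", {
  u <- uniform_usage()
  w <- cai_weights(u)
  expect_length(w, 61)
  expect_true(all(w == 1))

  u2 <- u
  u2$count[u2$codon == "TTT"] <- 3  # Phe family: TTT 3, TTC 1
  w2 <- cai_weights(u2)
  expect_equal(unname(w2["TTT"]), 1)
  expect_equal(unname(w2["TTC"]), 1 / 3)
  expect_true(all(w2 > 0 & w2 <= 1))
  expect_error(cai_weights(u[-1, ]), "missing codon")
})

test_that("coding sequences round-trip through FASTA", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">gene1", "ATGGCTAAA", ">gene2", "atgttcgaa"), fa)
  seqs <- read_coding_sequences(fa)
  expect_equal(unname(seqs), c("ATGGCTAAA", "ATGTTCGAA"))
  expect_equal(names(seqs), c("gene1", "gene2"))
})
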