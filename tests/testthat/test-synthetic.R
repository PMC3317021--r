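test_that("platform generation is deterministic with sorted unique positions", {
  p1 <- make_platform(n_clones = 100, n_chrom = 1, seed = 4)
  p2 <- make_platform(n_clones = 100, n_chrom = 1, seed = 4)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$map), 100)
  expect_equal(unique(p1$map$chromosome), "1")
  expect_false(is.unsorted(p1$map$position, strictly = TRUE))
  p3 <- make_platform(n_clones = 100, n_chrom = 1, seed = 5)
  expect_false(identical(p1$map$position, p3$map$position))
  expect_error(make_platform(n_clones = 100, n_blocks = 2, block_rows = 2,
                             block_cols = 2), class = "wga_validation_error")
})

test_that("the default spacing model reproduces the target median clone gap", {
  pl <- make_platform(n_clones = 6000, seed = 2)
  gaps <- unlist(tapply(pl$map$position, pl$map$chromosome,
                        function(p) diff(sort(p))))
  expect_gte(median(gaps), 66000)   # 73.4 kb +/- 10%
  expect_lte(median(gaps), 81000)
  expect_gt(mean(gaps < 1e6), 0.88) # most clones spaced < 1 Mb
})

test_that("random truths hit the genome-wide segment count target", {
  pl <- make_platform(n_clones = 1100, n_chrom = 22, seed = 9)
  counts <- vapply(1:50, function(s)
    nrow(make_truth(pl$map, n_segments = 40, seed = s)), 0L)
  expect_true(all(counts >= 32 & counts <= 48))
  # flat truth: every effect zero, one segment per chromosome
  flat <- make_truth(pl$map, n_segments = 40, prop_neutral = 1, seed = 1)
  expect_true(all(flat$effect == 0))
  expect_equal(nrow(flat), 22)
})

test_that("scripted arm truths alter exactly the requested arms", {
  pl <- make_platform(n_clones = 900, n_chrom = 18, seed = 6)
  tr <- arm_truth(pl$map, gains = c("1q", "8q", "17q"), losses = c("1p", "17p"))
  alt <- tr[tr$effect != 0, ]
  expect_setequal(unique(alt$chromosome), c("1", "8", "17"))
  expect_equal(sum(alt$effect > 0), 3)
  expect_equal(sum(alt$effect < 0), 2)
  # chromosome 8: only the q arm altered
  c8 <- tr[tr$chromosome == "8", ]
  expect_equal(c8$effect[order(c8$start_idx)][1], 0)
})

test_that("noise-free hybridizations carry the truth exactly in the channel ratio", {
  pl <- make_platform(n_clones = 200, n_chrom = 2, seed = 3)
  flat <- flat_truth(pl$map)
  tab <- simulate_hybridization(flat, pl, preset_params("none"), seed = 1,
                                subgrid_imbalance_sd = 0)
  expect_equal(tab$intensity_ch1 / tab$intensity_ch2, rep(1, 200))

  tr <- truth_profile(data.frame(
    chromosome = c("1", "1", "2"),
    start_idx = c(1L, 51L, 1L),
    end_idx = c(50L, sum(pl$map$chromosome == "1"),
                sum(pl$map$chromosome == "2")),
    effect = c(1, 0, 0), stringsAsFactors = FALSE), pl$map)
  tab2 <- simulate_hybridization(tr, pl, preset_params("none"), seed = 1,
                                 subgrid_imbalance_sd = 0)
  ord <- match(pl$map$clone_id, tab2$clone_id)
  ratio <- (tab2$intensity_ch1 / tab2$intensity_ch2)[ord]
  inside <- pl$map$chromosome == "1" & seq_len(200) %in% which(pl$map$chromosome == "1")[1:50]
  expect_equal(ratio[inside], rep(2, sum(inside)))
  expect_equal(ratio[!inside], rep(1, sum(!inside)))
})

test_that("simulated spot tables are byte-identical under a fixed seed", {
  pl <- make_platform(n_clones = 300, n_chrom = 4, seed = 5)
  tr <- make_truth(pl$map, n_segments = 10, seed = 5)
  t1 <- simulate_hybridization(tr, pl, preset_params("dop_like"), seed = 77)
  t2 <- simulate_hybridization(tr, pl, preset_params("dop_like"), seed = 77)
  expect_identical(t1, t2)
  t3 <- simulate_hybridization(tr, pl, preset_params("dop_like"), seed = 78)
  expect_false(identical(t1, t3))
})

test_that("recurrent artifact clones are shared within a method and differ between methods", {
  pl <- make_platform(n_clones = 1000, n_chrom = 10, seed = 12)
  scomp <- preset_params("scomp_like")
  dop <- preset_params("dop_like")
  rec_of <- function(model) which(wgafidelity:::method_structures(pl$map, model)$recurrent != 0)
  expect_identical(rec_of(scomp), rec_of(scomp))
  expect_false(identical(rec_of(scomp), rec_of(dop)))
  expect_gt(length(rec_of(scomp)), 0)
  # replicate hybridizations of one method share the same biased clones:
  # with zero noise, the recurrent offsets appear identically in both runs
  tr <- flat_truth(pl$map)
  quiet <- artifact_model(recurrent_clone_fraction = 0.02, method_seed = 31)
  r1 <- simulate_hybridization(tr, pl, quiet, seed = 1, subgrid_imbalance_sd = 0)
  r2 <- simulate_hybridization(tr, pl, quiet, seed = 2, subgrid_imbalance_sd = 0)
  lr1 <- log2(r1$intensity_ch1 / r1$intensity_ch2)
  lr2 <- log2(r2$intensity_ch1 / r2$intensity_ch2)
  expect_equal(lr1, lr2, tolerance = 1e-12)
  expect_gt(sum(abs(lr1) > 1e-9), 0)
})

test_that("preset models honor their contracts", {
  none <- preset_params("none")
  expect_equal(none$random_flip_rate, 0)
  expect_equal(none$measurement_sd, 0)
  expect_equal(none$recurrent_clone_fraction, 0)
  expect_equal(none$regional_bias_amplitude, 0)
  expect_gt(preset_params("scomp_like")$recurrent_clone_fraction, 0)
  expect_gt(preset_params("dop_like")$regional_bias_amplitude,
            preset_params("scomp_like")$regional_bias_amplitude)
  expect_error(preset_params("unknown"))
  expect_error(artifact_model(random_flip_rate = 1.5),
               class = "wga_validation_error")
})

test_that("sign-flip artifacts translate into matching spot discordance", {
  d <- vapply(1:5, function(s) {
    pl <- make_platform(n_clones = 1100, n_chrom = 22, seed = s)
    tr <- make_truth(pl$map, n_segments = 40, prop_neutral = 0, seed = s)
    ctl <- to_log2_profile(simulate_hybridization(
      tr, pl, preset_params("none"), seed = s + 900, subgrid_imbalance_sd = 0),
      pl$map, sample_id = "c")
    tst <- to_log2_profile(simulate_hybridization(
      tr, pl, artifact_model(random_flip_rate = 0.1), seed = s,
      subgrid_imbalance_sd = 0), pl$map, sample_id = "t")
    100 - spot_concordance(spot_calls(tst), spot_calls(ctl))
  }, 0)
  expect_lt(abs(mean(d) - 10), 3 * stats::sd(d) / sqrt(5) + 1)
})
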