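seg_df <- function(chrom, start, end, mean) {
  segment_set(data.frame(chromosome = chrom, start_bp = start, end_bp = end,
                         n_clones = 2, mean_log2 = mean, call = "neutral",
                         stringsAsFactors = FALSE)) |> call_segments(0)
}
pk_df <- function(chrom, start, end, sign) {
  peak_set(data.frame(chromosome = chrom, start_bp = start, end_bp = end,
                      sign = sign, max_abs_smoothed = 1,
                      stringsAsFactors = FALSE))
}

test_that("spot calls follow the sign rule and exclude the neutral band", {
  map <- mini_map(3)
  p <- profile_on(map, c(0.3, -0.2, 0.0))
  calls <- spot_calls(p)
  expect_equal(calls$call, c("gain", "loss"))
  expect_false(map$clone_id[3] %in% calls$clone_id)
  expect_equal(spot_calls(profile_on(map, c(1, 2, 3)))$call, rep("gain", 3))
  expect_equal(spot_calls(p, threshold = 0.25)$call, "gain")
})

test_that("spot concordance counts shared equal calls as a percentage", {
  map <- mini_map(4)
  a <- spot_calls(profile_on(map, c(1, 1, -1, -1)))
  b <- spot_calls(profile_on(map, c(1, 1, -1, 1)))
  expect_equal(spot_concordance(a, a), 100)
  expect_equal(spot_concordance(a, spot_calls(profile_on(map, -c(1, 1, -1, -1)))), 0)
  expect_equal(spot_concordance(a, b), 75)
  other <- spot_calls(cgh_profile(c("zz1", "zz2"), c(1, 1)))
  expect_error(spot_concordance(a, other), class = "wga_undefined_statistic")
})

test_that("recurrent discordance requires opposition in every group sample", {
  map <- mini_map(100)
  ctrl_vals <- rep(1, 100)
  ctrl <- spot_calls(profile_on(map, ctrl_vals, "ctrl"))
  flip_at <- function(idx) {
    v <- ctrl_vals; v[idx] <- -1
    spot_calls(profile_on(map, v))
  }
  # clones 1 and 2 flipped in all three samples; clone 3 in only two
  grp <- list(flip_at(c(1, 2, 3)), flip_at(c(1, 2, 3)), flip_at(c(1, 2)))
  res <- recurrent_discordant(grp, ctrl)
  expect_equal(res$pct_recurrent, 2.0)
  expect_equal(res$n_shared, 100)
  expect_false(res$degenerate)

  none <- recurrent_discordant(list(flip_at(1), flip_at(2)), ctrl)
  expect_equal(none$pct_recurrent, 0)
  expect_true(is.na(none$mean_abs_log2_diff))

  single <- recurrent_discordant(list(flip_at(5)), ctrl)
  expect_true(single$degenerate)
  expect_equal(single$pct_recurrent, 1)
})

test_that("recurrent clones report the mean absolute log2 difference vs control", {
  map <- mini_map(10)
  ctrl_p <- profile_on(map, rep(0.5, 10), "ctrl")
  t1 <- profile_on(map, c(-0.5, rep(0.5, 9)))
  t2 <- profile_on(map, c(-1.5, rep(0.5, 9)))
  res <- recurrent_discordant(list(spot_calls(t1), spot_calls(t2)),
                              spot_calls(ctrl_p),
                              group_profiles = list(t1, t2),
                              control_profiles = ctrl_p)
  expect_equal(res$n_recurrent, 1)
  expect_equal(res$mean_abs_log2_diff, mean(c(1, 2)))
})

test_that("genome-length concordance intersects same-sign segment regions", {
  ctrl <- seg_df("1", c(1, 1000001), c(1000000, 2000000), c(0.8, 0))
  same <- segment_length_concordance(ctrl, ctrl)
  expect_equal(same, 100)
  # test gain shifted by half: 50% of the control's altered length
  tst <- seg_df("1", c(1, 500001, 1500001), c(500000, 1500000, 2000000),
                c(0, 0.8, 0))
  expect_equal(segment_length_concordance(tst, ctrl), 50)
  # all-neutral test scores 0
  flat <- seg_df("1", 1, 2000000, 0)
  expect_equal(segment_length_concordance(flat, ctrl), 0)
  # control with no altered length is undefined
  expect_error(segment_length_concordance(ctrl, flat),
               class = "wga_undefined_statistic")
  # sign-flipped partner scores 0
  expect_equal(segment_length_concordance(flip_segments(ctrl), ctrl), 0)
})

test_that("union denominator counts either sample's altered length", {
  ctrl <- seg_df("1", c(1, 1000001), c(1000000, 2000000), c(0.8, 0))
  tst <- seg_df("1", c(1, 500001, 1500001), c(500000, 1500000, 2000000),
                c(0, 0.8, 0))
  # intersection 500kb; union of gains 1.5Mb
  expect_equal(segment_length_concordance(tst, ctrl, denominator = "union"),
               100 * 500000 / 1500000)
})

test_that("the concordance numerator never exceeds the denominator", {
  set.seed(41)
  map <- mini_map(80)
  for (k in 1:10) {
    a <- cbs_segment(profile_on(map, rnorm(80) + rep(c(0.5, -0.5), each = 40)),
                     map, cbs_params(n_perm = 100, seed = k))
    b <- cbs_segment(profile_on(map, rnorm(80) + rep(c(0.5, -0.5), each = 40)),
                     map, cbs_params(n_perm = 100, seed = k + 100))
    pct <- segment_length_concordance(a, b)
    expect_gte(pct, 0); expect_lte(pct, 100)
  }
})

test_that("peak concordance matches test peaks by sign and any overlap", {
  ctrl <- pk_df("1", c(100, 5000, 9000), c(1000, 6000, 9500),
                c("positive", "negative", "positive"))
  expect_equal(peak_concordance(ctrl, ctrl), 100)
  expect_equal(peak_concordance(flip_peaks(ctrl), ctrl), 0)
  # 3 test peaks, 2 overlapping same-sign controls
  tst <- pk_df("1", c(900, 5500, 20000), c(1100, 5800, 21000),
               c("positive", "negative", "positive"))
  expect_equal(peak_concordance(tst, ctrl), 100 * 2 / 3, tolerance = 1e-9)
  empty <- peak_set(data.frame(chromosome = character(), start_bp = numeric(),
                               end_bp = numeric(), sign = character(),
                               max_abs_smoothed = numeric()))
  expect_error(peak_concordance(empty, ctrl), class = "wga_undefined_statistic")
})

test_that("a zero-artifact group scores 100 everywhere with Mann-Whitney p = 1", {
  pl <- make_platform(n_clones = 300, n_chrom = 3, seed = 8)
  tr <- make_truth(pl$map, n_segments = 9, prop_neutral = 0, seed = 8)
  prof <- function(s, id) to_log2_profile(
    simulate_hybridization(tr, pl, preset_params("none"), seed = s,
                           subgrid_imbalance_sd = 0), pl$map, sample_id = id)
  tests <- list(prof(1, "t1"), prof(2, "t2"), prof(3, "t3"))
  ctrls <- list(prof(4, "c1"), prof(5, "c2"), prof(6, "c3"))
  dups <- list(list(prof(7, "d1a"), prof(8, "d1b")),
               list(prof(9, "d2a"), prof(10, "d2b")),
               list(prof(11, "d3a"), prof(12, "d3b")))
  suppressWarnings(
    rep <- assess_group(tests, ctrls, dups, pl$map,
                        cbs = cbs_params(n_perm = 100, seed = 3),
                        min_overlap = 50))
  for (nm in c("spot_concordance_pct", "segment_length_concordance_pct",
               "peak_concordance_pct")) {
    expect_equal(rep$summary[[nm]]$group_mean, 100)
    expect_equal(rep$summary[[nm]]$reference_mean, 100)
    expect_equal(rep$summary[[nm]]$mann_whitney_p, 1)
  }
  expect_equal(rep$summary$pearson_r$group_mean, 1)
  expect_equal(rep$recurrent_discordance$pct_recurrent, 0)
})
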