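# independent oracle for the exact Mann-Whitney: enumerate group assignments
# with combn and compute U by pair counting (not ranks)
mw_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(xx, yy)
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  U_obs <- u_of(x, y)
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  U_all <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  list(U = U_obs, p = mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9))
}

test_that("Pearson correlation of profiles handles identity, negation and exact linearity", {
  map <- mini_map(10)
  a <- profile_on(map, c(1, 2, 3, 4, 2, 1, 5, 3, 2, 4))
  b <- profile_on(map, -a$log2)
  expect_equal(pearson_profiles(a, a, min_overlap = 5), 1)
  expect_equal(pearson_profiles(a, b, min_overlap = 5), -1)
  x <- profile_on(mini_map(4), c(1, 2, 3, 4))
  y <- profile_on(mini_map(4), c(2, 4, 6, 8))
  expect_equal(pearson_profiles(x, y, min_overlap = 4), 1)
  expect_error(pearson_profiles(a, b, min_overlap = 50),
               class = "wga_undefined_statistic")
  flat <- profile_on(map, rep(1, 10))
  expect_error(pearson_profiles(a, flat, min_overlap = 5),
               class = "wga_undefined_statistic")
})

test_that("the correlation matrix is symmetric, unit-diagonal and permutation-equivariant", {
  map <- mini_map(12)
  set.seed(3)
  ps <- lapply(1:3, function(k) profile_on(map, rnorm(12), sprintf("s%d", k)))
  m <- correlation_matrix(c(ps, list(profile_on(map, -ps[[1]]$log2, "neg"))),
                          min_overlap = 5)
  expect_equal(diag(m$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(m$r, t(m$r))
  expect_equal(m$r["s1", "neg"], -1)
  perm <- c(3, 1, 4, 2)
  m2 <- correlation_matrix(c(ps, list(profile_on(map, -ps[[1]]$log2, "neg")))[perm],
                           min_overlap = 5)
  expect_equal(m2$r, m$r[perm, perm])
})

test_that("identical profiles give an all-ones matrix and undefined pairs stay NA", {
  map <- mini_map(8)
  p <- profile_on(map, c(1, -1, 2, 0, 1, 3, -2, 1))
  m <- correlation_matrix(list(p, p, p), min_overlap = 4)
  expect_equal(max(abs(m$r - 1)), 0, tolerance = 1e-12)
  flat <- profile_on(map, rep(0, 8), "flat")
  m2 <- correlation_matrix(list(p, flat), min_overlap = 4)
  expect_true(is.na(m2$r[1, 2]))
})

test_that("self-self normals are uncorrelated with tumor profiles", {
  pl <- make_platform(n_clones = 600, n_chrom = 6, seed = 15)
  rs <- vapply(1:5, function(s) {
    tr <- make_truth(pl$map, n_segments = 12, seed = s)
    tum <- normalize_hybridization(
      simulate_hybridization(tr, pl, preset_params("control_like"), seed = s),
      pl$map, sample_id = "tumor")
    ss <- normalize_hybridization(
      simulate_self_self(pl, seed = s + 500), pl$map, sample_id = "self")
    pearson_profiles(tum, ss, min_overlap = 100)
  }, 0)
  expect_true(all(abs(rs) < 0.2))
})

test_that("exact Mann-Whitney reproduces enumeration results for separation cases", {
  r <- mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)   # 2 of the 20 assignments are as extreme
  expect_equal(r$U, 0)
  r2 <- mann_whitney_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(r2$p, 2 / 70)
  # same multiset on both sides: maximally unsurprising
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_warning(r3 <- mann_whitney_exact(c(2, 2), c(2, 2, 2)), "tied")
  expect_equal(r3$p, 1)
})

test_that("the exact test is exchangeable and matches a pair-counting oracle", {
  set.seed(19)
  for (k in 1:40) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- if (k %% 3 == 0) sample(1:4, n1, replace = TRUE) else rnorm(n1)
    y <- if (k %% 3 == 0) sample(1:4, n2, replace = TRUE) else rnorm(n2)
    got <- mann_whitney_exact(x, y)
    ora <- mw_oracle(x, y)
    expect_equal(got$U, ora$U)
    expect_equal(got$p, ora$p, tolerance = 1e-12)
    expect_equal(got$p, mann_whitney_exact(y, x)$p, tolerance = 1e-12)
  }
})

test_that("delta-delta-Ct quantities double per cycle and ignore global Ct shifts", {
  rec <- qpcr_record("G", c(25, 25.1, 24.9), c(25, 25, 25),
                     c(27, 27, 27), c(27, 27, 27))
  expect_equal(ddct_quantity(rec), 1.0)
  rec2 <- qpcr_record("G", c(24, 24, 24), c(25, 25, 25),
                      c(25, 25, 25), c(25, 25, 25))
  expect_equal(ddct_quantity(rec2), 2.0)  # delta-delta Ct of -1
  rec3 <- qpcr_record("G", c(27, 27, 27), c(25, 25, 25),
                      c(25, 25, 25), c(25, 25, 25))
  expect_equal(ddct_quantity(rec3), 0.25) # delta-delta Ct of +2
  shifted <- qpcr_record("G", rec$ct_target_sample + 3,
                         rec$ct_ref_gene_sample + 3,
                         rec$ct_target_calibrator + 3,
                         rec$ct_ref_gene_calibrator + 3)
  expect_equal(ddct_quantity(shifted), ddct_quantity(rec))
  expect_error(qpcr_record("G", c(25, NA, 25), 25, 25, 25),
               class = "wga_validation_error")
})

test_that("Q-PCR quantities bin at the 0.7 and 1.3 cutpoints with boundaries neutral", {
  expect_equal(qpcr_bin(5.86), "gain")
  expect_equal(qpcr_bin(0.98), "N")
  expect_equal(qpcr_bin(0.76), "N")
  expect_equal(qpcr_bin(0.7), "N")
  expect_equal(qpcr_bin(1.3), "N")
  expect_equal(qpcr_bin(0.69), "loss")
  expect_equal(qpcr_bin(1.31), "gain")
  expect_error(qpcr_bin(0), class = "wga_validation_error")
})

test_that("aCGH agreement confirms direction matches and never a blank category", {
  qp <- data.frame(gene = c("a", "b", "c"), quantity = c(2.0, 1.0, 0.5))
  ac <- data.frame(gene = c("a", "b", "c"), category = c("N", "N", "N"))
  r <- qpcr_acgh_agreement(qp, ac)
  expect_equal(r$n_confirmed, 1)  # only b sits in the neutral band
  all_n <- qpcr_acgh_agreement(data.frame(gene = "g", quantity = 1.0),
                               data.frame(gene = "g", category = "N"))
  expect_equal(all_n$n_confirmed, 1)
  opp <- qpcr_acgh_agreement(data.frame(gene = "g", quantity = 2.0),
                             data.frame(gene = "g", category = "-"))
  expect_equal(opp$n_confirmed, 0)
  blank <- qpcr_acgh_agreement(data.frame(gene = "g", quantity = 1.0),
                               data.frame(gene = "g", category = ""))
  expect_equal(blank$n_confirmed, 0)
  expect_warning(
    qpcr_acgh_agreement(data.frame(gene = c("g", "h"), quantity = c(1, 1)),
                        data.frame(gene = "g", category = "N")),
    "excluded")
})

test_that("the strict symmetric-bin rule counts 16 of 22 on the published panel", {
  tab <- uacc812_qpcr()
  r <- qpcr_acgh_agreement(data.frame(gene = tab$clone, quantity = tab$quantity),
                           data.frame(gene = tab$clone, category = tab$control),
                           rule = "strict_bin")
  expect_equal(r$n_total, 22)
  expect_equal(r$n_confirmed, 16)
  fails <- r$detail$gene[!r$detail$confirmed]
  # the two near-neutral gains (1.22, 1.18) fail under the symmetric rule
  expect_setequal(fails, c("H64260", "H85791", "H01255", "H62028",
                           "R24935", "H46055"))
})
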