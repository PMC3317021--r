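# The three concordance statistics between an amplified sample and its
# non-amplified control: per-spot gain/loss agreement, genome-length
# agreement of same-sign segments, and matched signed peaks; plus
# recurrent-discordance analysis and group assessment against duplicate
# control runs.

#' Binary gain/loss calls per clone
#'
#' `gain` if the log2 value exceeds `threshold`, `loss` if below
#' `-threshold`; values in `[-threshold, threshold]` are excluded from the
#' vector (with the default threshold 0, only exact zeros are excluded).
#'
#' @param profile a normalized `cgh_profile`.
#' @param threshold non-negative call threshold.
#' @return A `spot_call_vector` data.frame (clone_id, call).
#' @export
spot_calls <- function(profile, threshold = 0) {
  call <- ifelse(profile$log2 > threshold, "gain",
                 ifelse(profile$log2 < -threshold, "loss", NA))
  df <- data.frame(clone_id = profile$clone_id, call = call,
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$call), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "sample_id") <- attr(profile, "sample_id")
  class(df) <- c("spot_call_vector", "data.frame")
  df
}

#' Per-spot concordance between two call vectors
#'
#' 100 x (shared clones with equal gain/loss call) / (shared clones).
#'
#' @param a,b `spot_call_vector`s.
#' @return Percentage in [0, 100].
#' @export
spot_concordance <- function(a, b) {
  shared <- intersect(a$clone_id, b$clone_id)
  if (!length(shared))
    undefined_stat("no shared clones between call vectors")
  ca <- stats::setNames(a$call, a$clone_id)[shared]
  cb <- stats::setNames(b$call, b$clone_id)[shared]
  100 * mean(ca == cb)
}

#' Recurrently discordant clones within a group
#'
#' Identifies clones called opposite to the control in every sample of the
#' group, among clones shared by the control and all samples. Returns their
#' percentage of shared clones and, when profiles are supplied, the mean
#' absolute log2 difference versus the control over those clones (averaged
#' over clones and samples).
#'
#' @param group_calls list of `spot_call_vector`s (>= 2 samples expected; a
#'   single-sample group is degenerate and flagged in the output).
#' @param control_calls one control `spot_call_vector` shared by the group,
#'   or a list of per-sample controls parallel to `group_calls`.
#' @param group_profiles,control_profiles optional matching profiles used
#'   for the log2-difference summary (`control_profiles` follows the same
#'   single-or-list convention).
#' @return List: pct_recurrent, mean_abs_log2_diff (NA when the recurrent
#'   set is empty or profiles are not supplied), n_recurrent, n_shared,
#'   degenerate.
#' @export
recurrent_discordant <- function(group_calls, control_calls,
                                 group_profiles = NULL, control_profiles = NULL) {
  as_parallel_list <- function(x, n)
    if (!is.null(x) && !is.data.frame(x) && is.list(x) && length(x) == n) x
    else rep(list(x), n)
  ctrls <- as_parallel_list(control_calls, length(group_calls))
  shared <- Reduce(intersect, c(lapply(ctrls, `[[`, "clone_id"),
                                lapply(group_calls, `[[`, "clone_id")))
  opposite <- rep(TRUE, length(shared))
  for (k in seq_along(group_calls)) {
    cg <- stats::setNames(group_calls[[k]]$call, group_calls[[k]]$clone_id)[shared]
    cc <- stats::setNames(ctrls[[k]]$call, ctrls[[k]]$clone_id)[shared]
    opposite <- opposite & (cg != cc)
  }
  recurrent <- shared[opposite]
  pct <- if (length(shared)) 100 * length(recurrent) / length(shared) else 0
  diff <- NA_real_
  if (length(recurrent) && !is.null(group_profiles) && !is.null(control_profiles)) {
    ctrl_profs <- as_parallel_list(control_profiles, length(group_profiles))
    diffs <- unlist(lapply(seq_along(group_profiles), function(k) {
      vp <- stats::setNames(group_profiles[[k]]$log2, group_profiles[[k]]$clone_id)
      vc <- stats::setNames(ctrl_profs[[k]]$log2, ctrl_profs[[k]]$clone_id)
      abs(vp[recurrent] - vc[recurrent])
    }))
    diff <- mean(diffs, na.rm = TRUE)
  }
  list(pct_recurrent = pct, mean_abs_log2_diff = diff,
       n_recurrent = length(recurrent), n_shared = length(shared),
       clones = recurrent, degenerate = length(group_calls) < 2)
}

# IRanges per chromosome and call, from a segment or peak set
ranges_by <- function(df, chrom, want_call) {
  sel <- df$chromosome == chrom & df$call == want_call
  IRanges::IRanges(start = df$start_bp[sel], end = df$end_bp[sel])
}

#' Genome-length concordance of segment calls
#'
#' Intersects the two segment partitions; a base pair is concordant where
#' both samples call the covering segment gain, or both call it loss. The
#' numerator is the summed length of concordant regions; the denominator is
#' the summed length called gain or loss in the control
#' (`denominator = "control"`, treating the non-amplified sample as truth)
#' or in either sample (`denominator = "union"`).
#'
#' @param test,control `segment_set`s built on the same clone map.
#' @param denominator "control" (default) or "union".
#' @return Percentage in [0, 100].
#' @export
segment_length_concordance <- function(test, control,
                                       denominator = c("control", "union")) {
  denominator <- match.arg(denominator)
  chroms <- unique(c(test$chromosome, control$chromosome))
  num <- 0; den <- 0
  for (chrom in chroms) {
    for (want in c("gain", "loss")) {
      rt <- ranges_by(test, chrom, want)
      rc <- ranges_by(control, chrom, want)
      num <- num + sum(IRanges::width(IRanges::intersect(rt, rc)))
      if (denominator == "control") {
        den <- den + sum(IRanges::width(rc))
      } else {
        den <- den + sum(IRanges::width(IRanges::union(rt, rc)))
      }
    }
  }
  if (den == 0)
    undefined_stat("control has zero altered genome length")
  100 * num / den
}

#' Peak concordance
#'
#' A test peak is concordant when at least one control peak of the same
#' sign overlaps it by at least one base pair; amplitude is ignored.
#' Returns 100 x concordant test peaks / total test peaks.
#'
#' @param test,control `peak_set`s from the same clone map.
#' @return Percentage in [0, 100].
#' @export
peak_concordance <- function(test, control) {
  if (!nrow(test))
    undefined_stat("test peak set is empty; peak concordance not assessable")
  hit <- logical(nrow(test))
  for (r in seq_len(nrow(test))) {
    sel <- control$chromosome == test$chromosome[r] & control$sign == test$sign[r]
    if (!any(sel)) next
    ov <- IRanges::countOverlaps(
      IRanges::IRanges(test$start_bp[r], test$end_bp[r]),
      IRanges::IRanges(control$start_bp[sel], control$end_bp[sel]))
    hit[r] <- ov > 0
  }
  100 * mean(hit)
}

# All per-pair statistics for one (test, control) pair of profiles.
assess_pair <- function(test, control, map, cbs = cbs_params(),
                        peaks = peak_params(), spot_threshold = 0,
                        min_overlap = 100, denominator = "control") {
  seg_t <- cbs_segment(test, map, cbs)
  seg_c <- cbs_segment(control, map, cbs)
  pk_t <- find_peaks(moving_average(test, map, peaks$window), map, peaks)
  pk_c <- find_peaks(moving_average(control, map, peaks$window), map, peaks)
  maybe <- function(expr) tryCatch(expr, wga_undefined_statistic = function(e) NA_real_)
  list(
    pearson_r = maybe(pearson_profiles(test, control, min_overlap = min_overlap)),
    spot_concordance_pct = maybe(spot_concordance(
      spot_calls(test, spot_threshold), spot_calls(control, spot_threshold))),
    segment_length_concordance_pct = maybe(segment_length_concordance(
      seg_t, seg_c, denominator = denominator)),
    peak_concordance_pct = maybe(peak_concordance(pk_t, pk_c)),
    n_segments_test = nrow(seg_t), n_segments_control = nrow(seg_c),
    segment_counts_test = as.list(segment_counts(seg_t)),
    n_peaks_test = nrow(pk_t), n_peaks_control = nrow(pk_c)
  )
}

stat_names <- c("pearson_r", "spot_concordance_pct",
                "segment_length_concordance_pct", "peak_concordance_pct")

#' Assess a group of amplified samples against duplicate-control references
#'
#' Runs the full analysis (segmentation, smoothing, peak calling, the three
#' concordance statistics and the Pearson correlation of nonsegmented
#' profiles) for every test/control pair and for every duplicate control
#' pair, then compares each statistic's per-sample values against the
#' duplicate-control reference values with the exact two-tailed
#' Mann-Whitney U test.
#'
#' @param tests list of test (amplified) `cgh_profile`s.
#' @param controls list of paired control profiles, same length and order
#'   as `tests`.
#' @param control_duplicates list of length-2 lists of profiles: duplicate
#'   hybridizations of non-amplified controls, defining the reference.
#' @param map the shared `clone_map`.
#' @param cbs,peaks parameter objects for segmentation and peak calling.
#' @param spot_threshold call threshold for per-spot gain/loss.
#' @param min_overlap minimum shared clones for a Pearson correlation.
#' @param denominator denominator convention for segment-length concordance.
#' @return A `concordance_report` list with per-pair statistics, group
#'   means, reference values, Mann-Whitney p-values, and recurrent
#'   discordance summaries.
#' @export
assess_group <- function(tests, controls, control_duplicates, map,
                         cbs = cbs_params(), peaks = peak_params(),
                         spot_threshold = 0, min_overlap = 100,
                         denominator = "control") {
  if (length(tests) != length(controls))
    validation_error("every test sample needs exactly one paired control")
  pair_stats <- lapply(seq_along(tests), function(k)
    assess_pair(tests[[k]], controls[[k]], map, cbs, peaks, spot_threshold,
                min_overlap, denominator))
  names(pair_stats) <- vapply(tests, function(p)
    as.character(attr(p, "sample_id") %||% "sample"), "")
  ref_stats <- lapply(control_duplicates, function(pair)
    assess_pair(pair[[1]], pair[[2]], map, cbs, peaks, spot_threshold,
                min_overlap, denominator))

  pull <- function(stats, name) vapply(stats, function(s) as.numeric(s[[name]]), 0)
  group_summary <- lapply(stat_names, function(nm) {
    g <- pull(pair_stats, nm); r <- pull(ref_stats, nm)
    mw <- if (all(is.finite(g)) && all(is.finite(r)))
      mann_whitney_exact(g, r) else list(U = NA_real_, p = NA_real_)
    list(group_mean = mean(g, na.rm = TRUE),
         group_median = stats::median(g, na.rm = TRUE),
         reference_mean = mean(r, na.rm = TRUE),
         reference_median = stats::median(r, na.rm = TRUE),
         mann_whitney_U = mw$U, mann_whitney_p = mw$p)
  })
  names(group_summary) <- stat_names

  recur <- recurrent_discordant(
    lapply(tests, spot_calls, threshold = spot_threshold),
    lapply(controls, spot_calls, threshold = spot_threshold),
    group_profiles = tests, control_profiles = controls)
  recur$clones <- NULL

  report <- list(per_pair = pair_stats, reference_pairs = ref_stats,
                 summary = group_summary, recurrent_discordance = recur)
  class(report) <- "concordance_report"
  report
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance report\n")
  for (nm in names(x$summary)) {
    s <- x$summary[[nm]]
    cat(sprintf("  %-32s group mean %8.3f | reference %8.3f | MW p %s\n",
                nm, s$group_mean, s$reference_mean,
                format(s$mann_whitney_p, digits = 3)))
  }
  invisible(x)
}
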