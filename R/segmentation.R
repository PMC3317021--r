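# Circular binary segmentation of log2-ratio profiles into contiguous
# segments of statistically uniform signal, with permutation-based split
# testing and sign-based gain/loss calling.

#' CBS parameters
#'
#' @param alpha significance level for accepting a split (permutation p).
#'   `alpha >= 1` forces a split wherever one is feasible (useful for
#'   studying the arc statistic itself).
#' @param n_perm number of permutations per candidate split.
#' @param min_width minimum number of clones on each side of a split.
#' @param call_threshold `|mean log2|` above which a segment is called
#'   gain/loss; the default 0 is a pure sign rule.
#' @param seed integer seed; each recursion node derives its own substream
#'   deterministically so results do not depend on evaluation order.
#' @export
cbs_params <- function(alpha = 0.01, n_perm = 1000, min_width = 2,
                       call_threshold = 0, seed = 1) {
  if (alpha <= 0) validation_error("alpha must be > 0")
  if (n_perm < 100) validation_error("n_perm must be >= 100")
  if (min_width < 1) validation_error("min_width must be >= 1")
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 min_width = as.integer(min_width),
                 call_threshold = call_threshold, seed = as.integer(seed)),
            class = "cbs_params")
}

#' Construct a segment set
#'
#' @param df data.frame with columns chromosome, start_bp, end_bp, n_clones,
#'   mean_log2, call.
#' @param sample_id sample identifier.
#' @export
segment_set <- function(df, sample_id = NA_character_) {
  need <- c("chromosome", "start_bp", "end_bp", "n_clones", "mean_log2", "call")
  missing <- setdiff(need, names(df))
  if (length(missing))
    validation_error("segment set missing column(s): %s", paste(missing, collapse = ", "))
  if (nrow(df) && any(df$start_bp >= df$end_bp))
    validation_error("segment start_bp must be < end_bp")
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  class(df) <- c("segment_set", "data.frame")
  df
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("Segment set '%s': %d segments (%d gain, %d loss, %d neutral)\n",
              attr(x, "sample_id"), nrow(x), sum(x$call == "gain"),
              sum(x$call == "loss"), sum(x$call == "neutral")))
  invisible(x)
}

#' Summarize segment counts
#' @param segments a `segment_set`.
#' @return Named vector: total, gain, loss, neutral.
#' @export
segment_counts <- function(segments) {
  c(total = nrow(segments), gain = sum(segments$call == "gain"),
    loss = sum(segments$call == "loss"), neutral = sum(segments$call == "neutral"))
}

# Recursive splitter for one chromosome; returns a list of (lo, hi) index
# ranges in genomic order. Per-node seeds are derived from (seed, chromosome,
# lo, hi) so p-values are a function of the node alone.
split_chromosome <- function(x, params, chrom_idx) {
  out <- list()
  recurse <- function(lo, hi) {
    n <- hi - lo + 1
    if (n >= 2 * params$min_width) {
      if (params$alpha >= 1) {
        res <- cbs_max_arc(x[lo:hi], params$min_width)
        res$split <- !is.na(res$i)
      } else {
        set.seed(derive_seed(params$seed, chrom_idx, lo, hi))
        res <- cbs_split_test(x[lo:hi], params$min_width, params$n_perm,
                              params$alpha)
      }
      if (isTRUE(res$split)) {
        i <- res$i; j <- res$j
        if (i > 0) recurse(lo, lo + i - 1)
        recurse(lo + i, lo + j - 1)
        if (j < n) recurse(lo + j, hi)
        return(invisible(NULL))
      }
    }
    out[[length(out) + 1L]] <<- c(lo, hi)
    invisible(NULL)
  }
  recurse(1L, length(x))
  out
}

#' Segment a profile by circular binary segmentation
#'
#' Per chromosome, recursively finds the boundary pair maximizing the
#' circular-arc two-sample statistic and accepts the split when its
#' permutation p-value falls below `alpha`. A wrapping (circular) maximal
#' arc is emitted as the two linear breakpoints it induces. Segment
#' boundaries in base pairs are midpoints between flanking clones;
#' chromosome ends extend to the first/last clone position. Adjacent
#' segments whose means coincide to within 1e-9 (a degenerate outcome that
#' only arises on noiseless data) are merged back.
#'
#' @param profile a `cgh_profile`.
#' @param map a `clone_map`; only clones present in both are used.
#' @param params a [cbs_params()].
#' @return A `segment_set` partitioning every profiled clone.
#' @export
cbs_segment <- function(profile, map, params = cbs_params()) {
  m <- map[map$clone_id %in% profile$clone_id, , drop = FALSE]
  if (!nrow(m)) validation_error("no profile clones found in clone map")
  v <- stats::setNames(profile$log2, profile$clone_id)[m$clone_id]

  # leave the caller's RNG stream untouched
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  }

  chroms <- unique(m$chromosome)
  rows <- list()
  for (ci in seq_along(chroms)) {
    idx <- which(m$chromosome == chroms[ci])
    x <- as.numeric(v[idx])
    pos <- m$position[idx]
    n <- length(x)
    if (n < 2) {
      warning(sprintf("chromosome %s has < 2 clones; emitting a trivial segment",
                      chroms[ci]))
      pieces <- list(c(1L, n))
    } else {
      pieces <- split_chromosome(x, params, ci)
    }
    # merge adjacent equal-mean segments (possible only without noise)
    means <- vapply(pieces, function(p) mean(x[p[1]:p[2]]), 0)
    keep <- list(); km <- numeric()
    for (s in seq_along(pieces)) {
      if (length(keep) && abs(means[s] - km[length(km)]) < 1e-9) {
        keep[[length(keep)]][2] <- pieces[[s]][2]
        km[length(km)] <- mean(x[keep[[length(keep)]][1]:keep[[length(keep)]][2]])
      } else {
        keep[[length(keep) + 1L]] <- pieces[[s]]
        km <- c(km, means[s])
      }
    }
    # boundary base pairs: midpoint between flanking clones
    n_seg <- length(keep)
    for (s in seq_len(n_seg)) {
      lo <- keep[[s]][1]; hi <- keep[[s]][2]
      start_bp <- if (s == 1) pos[1] else rows[[length(rows)]]$end_bp + 1
      end_bp <- if (s == n_seg) pos[n] else (pos[hi] + pos[hi + 1]) %/% 2
      end_bp <- max(end_bp, start_bp + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chroms[ci], start_bp = start_bp, end_bp = end_bp,
        n_clones = hi - lo + 1, mean_log2 = km[s], call = "neutral",
        stringsAsFactors = FALSE)
    }
  }
  segs <- do.call(rbind, rows)
  segs <- segment_set(segs, sample_id = attr(profile, "sample_id"))
  call_segments(segs, params$call_threshold)
}

#' Call segments gain/loss/neutral
#'
#' `call = gain` if mean log2 exceeds `threshold`, `loss` if below
#' `-threshold`, otherwise `neutral` (strict inequalities: a mean exactly at
#' the threshold is neutral).
#'
#' @param segments a `segment_set`.
#' @param threshold non-negative call threshold (0 = pure sign rule).
#' @return The recalled `segment_set`.
#' @export
call_segments <- function(segments, threshold = 0) {
  segments$call <- ifelse(segments$mean_log2 > threshold, "gain",
                          ifelse(segments$mean_log2 < -threshold, "loss", "neutral"))
  segments
}

#' Robust per-chromosome noise estimate
#'
#' Median-absolute-deviation of first differences divided by sqrt(2): a
#' point-wise noise scale that is robust to the copy-number changes being
#' detected.
#'
#' @param x numeric vector of log2 ratios, in genomic order.
#' @return Noise standard deviation estimate (0 for constant input).
#' @export
mad_sigma <- function(x) {
  if (length(x) < 2) return(0)
  s <- stats::mad(diff(x)) / sqrt(2)
  if (s == 0) s <- stats::sd(x)
  if (is.na(s)) s <- 0
  s
}
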