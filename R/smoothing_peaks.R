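# Moving-average smoothing of profiles along the genome and detection of
# signed peaks of genomic alteration.

#' Peak-calling parameters
#'
#' @param window sliding window size in data points (clones), not base pairs.
#' @param threshold_k multiplier of the robust spread of smoothed values
#'   that sets the detection threshold.
#' @param min_run minimum number of consecutive super-threshold smoothed
#'   points forming a peak.
#' @export
peak_params <- function(window = 20, threshold_k = 2.0, min_run = 5) {
  if (window < 2) validation_error("window must be >= 2")
  if (threshold_k <= 0) validation_error("threshold_k must be > 0")
  if (min_run < 1) validation_error("min_run must be >= 1")
  structure(list(window = as.integer(window), threshold_k = threshold_k,
                 min_run = as.integer(min_run)), class = "peak_params")
}

#' Moving average of a profile along the genome
#'
#' The value at each clone is the mean of a window of up to `window`
#' consecutive clones centered on it. Interior windows hold exactly
#' `window` points (for even `window`, one extra point on the left); near
#' chromosome ends the window shrinks symmetrically so it stays centered.
#' Windows never cross chromosome boundaries. Chromosomes with fewer than
#' two clones are passed through with a warning.
#'
#' @param profile a `cgh_profile`.
#' @param map a `clone_map`.
#' @param window window size in data points.
#' @return A `cgh_profile` of smoothed values, indexed by the same clones.
#' @export
moving_average <- function(profile, map, window = 20) {
  m <- map[map$clone_id %in% profile$clone_id, , drop = FALSE]
  v <- stats::setNames(profile$log2, profile$clone_id)[m$clone_id]
  a <- floor(window / 2)            # points to the left of center
  b <- window - 1 - a               # points to the right
  out <- numeric(length(v))
  for (chrom in unique(m$chromosome)) {
    idx <- which(m$chromosome == chrom)
    x <- as.numeric(v[idx])
    n <- length(x)
    if (n < 2) {
      warning(sprintf("chromosome %s has < 2 clones; smoothing is a passthrough", chrom))
      out[idx] <- x
      next
    }
    cs <- c(0, cumsum(x))
    sm <- numeric(n)
    for (t in seq_len(n)) {
      if (t - a >= 1 && t + b <= n) {
        lo <- t - a; hi <- t + b
      } else {
        r <- min(t - 1, n - t, a)
        lo <- t - r; hi <- t + r
      }
      sm[t] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    }
    out[idx] <- sm
  }
  cgh_profile(m$clone_id, out, sample_id = attr(profile, "sample_id"),
              group = attr(profile, "group"))
}

#' Construct a peak set
#'
#' @param df data.frame with columns chromosome, start_bp, end_bp, sign
#'   ("positive"/"negative"), max_abs_smoothed.
#' @param sample_id sample identifier.
#' @export
peak_set <- function(df, sample_id = NA_character_) {
  need <- c("chromosome", "start_bp", "end_bp", "sign", "max_abs_smoothed")
  missing <- setdiff(need, names(df))
  if (length(missing))
    validation_error("peak set missing column(s): %s", paste(missing, collapse = ", "))
  if (nrow(df) && any(df$start_bp >= df$end_bp))
    validation_error("peak start_bp must be < end_bp")
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  class(df) <- c("peak_set", "data.frame")
  df
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set '%s': %d peaks (%d positive, %d negative)\n",
              attr(x, "sample_id"), nrow(x), sum(x$sign == "positive"),
              sum(x$sign == "negative")))
  invisible(x)
}

#' Find signed peaks in a smoothed profile
#'
#' The detection threshold is robust and genome-wide:
#' `tau = threshold_k * median(|smoothed - median(smoothed)|)`. A peak is a
#' maximal run of at least `min_run` consecutive clones with smoothed value
#' strictly above `tau` (positive peak) or below `-tau` (negative peak); the
#' peak interval spans the first to the last clone of the run.
#'
#' @param smoothed a `cgh_profile` produced by [moving_average()].
#' @param map a `clone_map`.
#' @param params a [peak_params()].
#' @return A `peak_set` (empty when nothing exceeds the threshold).
#' @export
find_peaks <- function(smoothed, map, params = peak_params()) {
  m <- map[map$clone_id %in% smoothed$clone_id, , drop = FALSE]
  v <- stats::setNames(smoothed$log2, smoothed$clone_id)[m$clone_id]
  tau <- params$threshold_k * stats::median(abs(v - stats::median(v)))
  rows <- list()
  for (chrom in unique(m$chromosome)) {
    idx <- which(m$chromosome == chrom)
    x <- as.numeric(v[idx])
    pos <- m$position[idx]
    for (sgn in c(1, -1)) {
      above <- if (sgn > 0) x > tau else x < -tau
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      hit <- which(r$values & r$lengths >= params$min_run)
      for (h in hit) {
        lo <- starts[h]; hi <- ends[h]
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = chrom,
          start_bp = pos[lo],
          end_bp = max(pos[hi], pos[lo] + 1),
          sign = if (sgn > 0) "positive" else "negative",
          max_abs_smoothed = max(abs(x[lo:hi])),
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chromosome = character(), start_bp = numeric(),
               end_bp = numeric(), sign = character(),
               max_abs_smoothed = numeric(), stringsAsFactors = FALSE)
  df <- df[order_genome(df$chromosome, df$start_bp), , drop = FALSE]
  peak_set(df, sample_id = attr(smoothed, "sample_id"))
}
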