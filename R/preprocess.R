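# Turning one spot table into one normalized log2-ratio profile:
# per-subgrid channel equalization, log2 ratios, median centering and
# median-absolute-value scaling.

#' Construct a CGH profile
#'
#' A profile is the normalized log2 ratio (test over reference channel) per
#' mapped clone for one hybridization.
#'
#' @param clone_id character vector of clone identifiers.
#' @param log2 numeric vector of log2 ratios (finite).
#' @param sample_id sample identifier.
#' @param group group label, e.g. control/scomp/dop/self_self.
#' @return A `cgh_profile` data.frame with attributes sample_id and group.
#' @export
cgh_profile <- function(clone_id, log2, sample_id = NA_character_,
                        group = NA_character_) {
  if (anyDuplicated(clone_id))
    validation_error("duplicate clone_id in profile")
  if (any(!is.finite(log2)))
    validation_error("profile values must be finite")
  df <- data.frame(clone_id = as.character(clone_id), log2 = as.numeric(log2),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  attr(df, "group") <- group
  class(df) <- c("cgh_profile", "data.frame")
  df
}

#' @export
print.cgh_profile <- function(x, ...) {
  cat(sprintf("CGH profile '%s' (group %s): %d clones, median %.3f, MAV %.3f\n",
              attr(x, "sample_id"), attr(x, "group"), nrow(x),
              stats::median(x$log2), stats::median(abs(x$log2 - stats::median(x$log2)))))
  invisible(x)
}

#' Normalization parameters
#'
#' @param subgrid_key grid field treated as the subgrid (default "block").
#' @param exclude_flags flag values excluded from normalization statistics.
#' @param scale_target positive value the median absolute (centered) log2
#'   value is scaled to; 1.0 makes profiles comparable across samples.
#' @export
normalization_params <- function(subgrid_key = "block",
                                 exclude_flags = c("anomalous", "absent"),
                                 scale_target = 1.0) {
  if (!is.numeric(scale_target) || scale_target <= 0)
    validation_error("scale_target must be > 0")
  structure(list(subgrid_key = subgrid_key, exclude_flags = exclude_flags,
                 scale_target = scale_target), class = "normalization_params")
}

#' Equalize channel intensities within each subgrid
#'
#' Within each subgrid, channel-1 intensities are multiplied by a single
#' factor chosen so that the subgrid total of channel 1 over usable spots
#' equals the subgrid total of channel 2. Spots that are flagged, or have a
#' zero intensity, never contribute to the factor but are rescaled by it.
#' Channel 2 is untouched.
#'
#' @param table a `spot_table`.
#' @param params a [normalization_params()].
#' @return The rescaled `spot_table`.
#' @export
subgrid_normalize <- function(table, params = normalization_params()) {
  key <- table[[params$subgrid_key]]
  for (g in unique(key)) {
    idx <- which(key == g)
    usable <- idx[!(table$flag[idx] %in% params$exclude_flags) &
                    table$intensity_ch1[idx] > 0 & table$intensity_ch2[idx] > 0]
    if (!length(usable))
      stop_wga("wga_normalization_error",
               "subgrid %s has no usable spots for normalization", g)
    factor <- sum(table$intensity_ch2[usable]) / sum(table$intensity_ch1[usable])
    table$intensity_ch1[idx] <- table$intensity_ch1[idx] * factor
  }
  table
}

#' Build a log2-ratio profile from a normalized spot table
#'
#' Per clone, log2(ch1/ch2). Spots flagged anomalous/absent or with a zero
#' intensity are omitted; clones absent from the map are omitted; replicate
#' spots for one clone are collapsed by the arithmetic mean of their
#' per-spot log2 ratios.
#'
#' @param table a subgrid-normalized `spot_table`.
#' @param map a `clone_map`.
#' @param sample_id,group metadata attached to the profile.
#' @return A `cgh_profile` ordered along the map.
#' @export
to_log2_profile <- function(table, map, sample_id = NA_character_,
                            group = NA_character_) {
  keep <- table$flag == "ok" & table$intensity_ch1 > 0 & table$intensity_ch2 > 0 &
    table$clone_id %in% map$clone_id
  if (!any(keep))
    validation_error("no usable spots overlap the clone map")
  sub <- table[keep, , drop = FALSE]
  lr <- log2(sub$intensity_ch1 / sub$intensity_ch2)
  agg <- tapply(lr, sub$clone_id, mean)
  ord <- map$clone_id[map$clone_id %in% names(agg)]
  cgh_profile(ord, as.numeric(agg[ord]), sample_id = sample_id, group = group)
}

#' Median-center and scale a profile
#'
#' Subtracts the median of the values, then divides by the median of
#' absolute deviations from that median and multiplies by `scale_target`,
#' so that the output has median 0 and median absolute value equal to
#' `scale_target`. Applying the operation twice is a no-op.
#'
#' @param profile a `cgh_profile`.
#' @param params a [normalization_params()]; only `scale_target` is used.
#' @return The centered and scaled `cgh_profile`.
#' @export
center_and_scale <- function(profile, params = normalization_params()) {
  v <- profile$log2
  if (!length(v)) validation_error("empty profile")
  med <- stats::median(v)
  centered <- v - med
  mav <- stats::median(abs(centered))
  if (mav == 0)
    degenerate_error("constant profile: median absolute deviation is zero")
  profile$log2 <- centered / mav * params$scale_target
  profile
}

#' Full preprocessing of one hybridization
#'
#' Convenience wrapper: subgrid normalization, log2 profile construction,
#' then median centering and scaling.
#'
#' @inheritParams to_log2_profile
#' @inheritParams subgrid_normalize
#' @return A normalized `cgh_profile`.
#' @export
normalize_hybridization <- function(table, map, params = normalization_params(),
                                    sample_id = NA_character_,
                                    group = NA_character_) {
  table <- subgrid_normalize(table, params)
  profile <- to_log2_profile(table, map, sample_id = sample_id, group = group)
  center_and_scale(profile, params)
}
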