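# Readers and writers for the file shapes the pipeline touches: spot
# quantification tables (GenePix-style), clone maps, profiles, segment sets
# and concordance reports.

#' Construct a clone map
#'
#' A clone map assigns each array clone a chromosome and a 1-based base-pair
#' position; it is the coordinate backbone for profiles, segments and peaks.
#'
#' @param clone_id character vector of unique clone identifiers.
#' @param chromosome character vector of chromosome names.
#' @param position integer vector of 1-based base-pair positions.
#' @return A `clone_map` data.frame sorted by (chromosome, position).
#' @export
clone_map <- function(clone_id, chromosome, position) {
  if (anyDuplicated(clone_id))
    validation_error("duplicate clone_id in clone map: %s",
                     paste(unique(clone_id[duplicated(clone_id)]), collapse = ", "))
  position <- as.numeric(position)
  if (any(!is.finite(position)) || any(position < 1) || any(position != round(position)))
    format_error("clone map positions must be integers >= 1")
  df <- data.frame(clone_id = as.character(clone_id),
                   chromosome = as.character(chromosome),
                   position = position,
                   stringsAsFactors = FALSE)
  df <- df[order_genome(df$chromosome, df$position), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("clone_map", "data.frame")
  df
}

#' Read a clone map from a TSV file
#'
#' Expects three tab-separated columns: clone_id, chromosome, position.
#' A header line is detected (and skipped) when the third field of the first
#' line is not numeric. Clones on unmapped chromosomes (empty, `NA`, `"0"`,
#' or `"unmapped"`) are dropped with a message.
#'
#' @param path path to the TSV file.
#' @return A `clone_map`.
#' @export
read_clone_map <- function(path) {
  first <- readLines(path, n = 1)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- length(fields) >= 3 &&
    is.na(suppressWarnings(as.numeric(fields[3])))
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          colClasses = "character", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    format_error("clone map must have 3 columns (clone_id, chromosome, position)")
  if (!nrow(df))
    format_error("clone map has no data rows")
  names(df)[1:3] <- c("clone_id", "chromosome", "position")
  unmapped <- is.na(df$chromosome) | df$chromosome %in% c("", "0", "NA", "unmapped")
  if (any(unmapped)) {
    message(sum(unmapped), " clone(s) on unmapped chromosomes dropped")
    df <- df[!unmapped, , drop = FALSE]
  }
  pos <- suppressWarnings(as.numeric(df$position))
  if (any(is.na(pos)))
    format_error("non-integer position in clone map (rows %s)",
                 paste(utils::head(which(is.na(pos)), 5), collapse = ", "))
  clone_map(df$clone_id, df$chromosome, pos)
}

#' Default column-name mapping for GenePix-style spot tables
#' @export
default_spot_columns <- function() {
  list(block = "Block", row = "Row", column = "Column", id = "ID",
       ch1 = "F635 Median", ch2 = "F532 Median", flag = "Flags")
}

#' Default GenePix flag-code mapping
#'
#' GenePix marks spots with non-negative codes when usable and negative codes
#' otherwise; by convention `-75` (empty) maps to "absent" and other negative
#' codes to "anomalous".
#' @export
default_flag_map <- function() {
  function(code) {
    code <- suppressWarnings(as.numeric(code))
    out <- rep("ok", length(code))
    out[!is.na(code) & code < 0] <- "anomalous"
    out[!is.na(code) & code == -75] <- "absent"
    out[is.na(code)] <- "anomalous"
    out
  }
}

#' Construct a spot table
#'
#' @param df data.frame with columns block, row, column, clone_id,
#'   intensity_ch1, intensity_ch2, flag (one of ok/anomalous/absent).
#' @return A `spot_table` data.frame.
#' @export
spot_table <- function(df) {
  need <- c("block", "row", "column", "clone_id",
            "intensity_ch1", "intensity_ch2", "flag")
  missing <- setdiff(need, names(df))
  if (length(missing))
    format_error("spot table missing column(s): %s", paste(missing, collapse = ", "))
  df <- df[, need, drop = FALSE]
  bad <- which(!is.finite(df$intensity_ch1) | !is.finite(df$intensity_ch2) |
                 df$intensity_ch1 < 0 | df$intensity_ch2 < 0)
  if (length(bad))
    validation_error("malformed spot rows (non-finite or negative intensity): rows %s",
                     paste(utils::head(bad, 10), collapse = ", "))
  if (!all(df$flag %in% c("ok", "anomalous", "absent")))
    validation_error("flag values must be ok/anomalous/absent")
  key <- paste(df$block, df$row, df$column)
  if (anyDuplicated(key))
    validation_error("duplicate grid coordinate(s): %s",
                     paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  df <- df[order(df$block, df$row, df$column), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Read a GenePix-style spot quantification table
#'
#' Tab-delimited with a header naming at least the seven mapped fields.
#' Column names and the numeric-flag vocabulary are configurable; rows with
#' non-finite or negative intensities are rejected with their row numbers.
#' Flagged rows are retained but marked.
#'
#' @param path path to the tab-delimited file.
#' @param columns name mapping as from [default_spot_columns()].
#' @param flag_map function mapping raw flag codes to ok/anomalous/absent.
#' @param skip number of lines to skip before the header.
#' @return A `spot_table`.
#' @export
read_spot_table <- function(path, columns = default_spot_columns(),
                            flag_map = default_flag_map(), skip = 0) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                           check.names = FALSE, quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  missing <- setdiff(unlist(columns), names(raw))
  if (length(missing))
    format_error("spot table header missing column(s): %s",
                 paste(missing, collapse = ", "))
  df <- data.frame(
    block = as.integer(raw[[columns$block]]),
    row = as.integer(raw[[columns$row]]),
    column = as.integer(raw[[columns$column]]),
    clone_id = as.character(raw[[columns$id]]),
    intensity_ch1 = suppressWarnings(as.numeric(raw[[columns$ch1]])),
    intensity_ch2 = suppressWarnings(as.numeric(raw[[columns$ch2]])),
    flag = flag_map(raw[[columns$flag]]),
    stringsAsFactors = FALSE
  )
  spot_table(df)
}

#' Write / read a segment set as a BED-like TSV
#'
#' Segments are held internally with 1-based inclusive coordinates and
#' emitted with the standard BED convention (0-based half-open); the
#' conversion is centralized here.
#'
#' @param segments a `segment_set`.
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#sample_id=%s", attr(segments, "sample_id") %||% "NA"), con)
  writeLines(paste("chromosome", "start", "end", "n_clones", "mean_log2", "call",
                   sep = "\t"), con)
  if (nrow(segments)) {
    lines <- sprintf("%s\t%d\t%d\t%d\t%.17g\t%s",
                     segments$chromosome,
                     as.integer(segments$start_bp - 1),  # to 0-based half-open
                     as.integer(segments$end_bp),
                     segments$n_clones, segments$mean_log2, segments$call)
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  header <- readLines(path, n = 1)
  sample_id <- if (startsWith(header, "#sample_id=")) sub("^#sample_id=", "", header) else NA
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "numeric",
                                         "integer", "numeric", "character"))
  names(df) <- c("chromosome", "start", "end", "n_clones", "mean_log2", "call")
  out <- data.frame(chromosome = df$chromosome,
                    start_bp = df$start + 1,  # back to 1-based inclusive
                    end_bp = df$end,
                    n_clones = df$n_clones,
                    mean_log2 = df$mean_log2,
                    call = df$call,
                    stringsAsFactors = FALSE)
  segment_set(out, sample_id = sample_id)
}

#' Serialize / deserialize a concordance report as JSON
#' @param report a `concordance_report` (nested list).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(rep) <- "concordance_report"
  rep
}

#' Write / read a normalized profile as TSV
#' @param profile a `cgh_profile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#sample_id=%s", attr(profile, "sample_id") %||% "NA"),
               sprintf("#group=%s", attr(profile, "group") %||% "NA"),
               "clone_id\tlog2"), con)
  writeLines(sprintf("%s\t%.17g", profile$clone_id, profile$log2), con)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  hdr <- readLines(path, n = 2)
  sample_id <- sub("^#sample_id=", "", hdr[1])
  group <- sub("^#group=", "", hdr[2])
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = c("character", "numeric"),
                          stringsAsFactors = FALSE)
  cgh_profile(df$clone_id, df$log2, sample_id = sample_id, group = group)
}

#' Write a clone map as TSV
#' @param map a `clone_map`.
#' @param path output path.
#' @export
write_clone_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("clone_id\tchromosome\tposition", con)
  writeLines(sprintf("%s\t%s\t%d", map$clone_id, map$chromosome,
                     as.integer(map$position)), con)
  invisible(path)
}
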