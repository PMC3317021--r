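# Internal helpers shared across modules.

#' @useDynLib wgafidelity, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Typed conditions so callers can distinguish config/format errors from
# statistics that are genuinely undefined on the given input.
stop_wga <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "wga_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

format_error      <- function(msg, ...) stop_wga("wga_format_error", msg, ...)
validation_error  <- function(msg, ...) stop_wga("wga_validation_error", msg, ...)
undefined_stat    <- function(msg, ...) stop_wga("wga_undefined_statistic", msg, ...)
degenerate_error  <- function(msg, ...) stop_wga("wga_degenerate_profile", msg, ...)

# Canonical chromosome ordering: numeric chromosomes first in numeric order,
# then X, Y, then anything else alphabetically.
chrom_rank <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(chrom))
  rank <- ifelse(!is.na(num), num,
                 ifelse(chrom == "X", 100,
                        ifelse(chrom == "Y", 101, 200 + match(chrom, sort(unique(chrom))))))
  rank
}

order_genome <- function(chrom, pos) order(chrom_rank(chrom), pos)

# Deterministic 31-bit seed derivation so every stage/node can reseed
# independently of evaluation order. Plain integer hashing, kept below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(paste(p, collapse = ""))) else as.numeric(p)
  })))
  h <- 0
  for (p in parts) h <- (h * 69069 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(h %% 2147483562) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
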