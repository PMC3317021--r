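# Small fixtures built in code: clone maps, profiles and GenePix-style
# spot files used across the suite.

mini_map <- function(n = 50, chrom = "1", spacing = 1e5, prefix = "c") {
  clone_map(sprintf("%s%03d", prefix, seq_len(n)), rep(chrom, n),
            seq(spacing, by = spacing, length.out = n))
}

# map spanning several chromosomes with n clones each
multi_map <- function(n_per = 50, chroms = c("1", "2"), spacing = 1e5) {
  ids <- unlist(lapply(seq_along(chroms), function(ci)
    sprintf("c%s_%03d", chroms[ci], seq_len(n_per))))
  clone_map(ids, rep(chroms, each = n_per),
            rep(seq(spacing, by = spacing, length.out = n_per), length(chroms)))
}

profile_on <- function(map, values, sample_id = "s1", group = NA_character_) {
  cgh_profile(map$clone_id, values, sample_id = sample_id, group = group)
}

# write a GenePix-style tab-delimited spot file
write_spot_file <- function(df, path,
                            header = c("Block", "Row", "Column", "ID",
                                       "F635 Median", "F532 Median", "Flags")) {
  lines <- c(paste(header, collapse = "\t"),
             apply(df, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  path
}

# mirrored segment/peak sets (same intervals, opposite calls/signs)
flip_segments <- function(segs) {
  segs$mean_log2 <- -segs$mean_log2
  call_segments(segs, 0)
}
flip_peaks <- function(pks) {
  pks$sign <- ifelse(pks$sign == "positive", "negative", "positive")
  pks
}
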