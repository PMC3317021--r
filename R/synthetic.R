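# Synthetic two-channel array generator: clone maps emulating a ~11,000
# clone cDNA platform, ground-truth copy-number profiles, and spot tables
# for control duplicates, self-self normals, and WGA-amplified replicates
# carrying method-specific artifact models.

# Approximate human autosome + X lengths (Mb), used as relative weights
# when distributing clones over chromosomes.
human_chrom_weights <- function(n_chrom = 23) {
  w <- c(247, 243, 199, 191, 181, 171, 159, 146, 140, 135, 134, 132,
         114, 106, 100, 89, 79, 76, 63, 62, 47, 50, 155)
  names(w) <- c(as.character(1:22), "X")
  w[seq_len(min(n_chrom, length(w)))]
}

#' Generate a synthetic array platform (clone map + grid layout)
#'
#' Inter-clone gaps are drawn log-normally with median 73.4 kb and a log-sd
#' chosen so ~93% of gaps fall below 1 Mb, emulating the clone spacing of a
#' mapped ~11,000-clone cDNA array. Clones are assigned to print subgrids
#' round-robin.
#'
#' @param n_clones total clones on the map.
#' @param n_chrom number of chromosomes (up to 22 autosomes + X).
#' @param gap_meanlog,gap_sdlog log-normal gap parameters.
#' @param n_blocks,block_rows,block_cols print grid geometry.
#' @param seed integer seed; the same seed reproduces the map exactly.
#' @return List with `map` (a `clone_map`) and `grid` (data.frame
#'   clone_id/block/row/column).
#' @export
make_platform <- function(n_clones = 11000, n_chrom = 23,
                          gap_meanlog = log(73400), gap_sdlog = 1.77,
                          n_blocks = 48, block_rows = 16, block_cols = 16,
                          seed = 1) {
  if (n_blocks * block_rows * block_cols < n_clones)
    validation_error("grid capacity %d below n_clones %d",
                     n_blocks * block_rows * block_cols, n_clones)
  with_seed(derive_seed(seed, "platform"), {
    w <- human_chrom_weights(n_chrom)
    alloc <- stats::setNames(pmax(2L, as.integer(round(n_clones * w / sum(w)))),
                             names(w))
    while (sum(alloc) != n_clones) {  # fix rounding drift, keep >= 2 each
      k <- if (sum(alloc) > n_clones) which.max(alloc) else which.min(alloc)
      alloc[k] <- max(2L, alloc[k] + sign(n_clones - sum(alloc)))
    }
    rows <- lapply(seq_along(alloc), function(ci) {
      gaps <- stats::rlnorm(alloc[ci], gap_meanlog, gap_sdlog)
      pos <- cumsum(pmax(1, round(gaps)))
      data.frame(chromosome = names(alloc)[ci], position = pos,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$clone_id <- sprintf("CL%05d", seq_len(nrow(df)))
    map <- clone_map(df$clone_id, df$chromosome, df$position)
    k <- seq_len(nrow(map)) - 1L
    s <- k %/% n_blocks
    grid <- data.frame(clone_id = map$clone_id,
                       block = k %% n_blocks + 1L,
                       row = s %/% block_cols + 1L,
                       column = s %% block_cols + 1L,
                       stringsAsFactors = FALSE)
    list(map = map, grid = grid)
  })
}

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Construct a truth profile from explicit segments
#'
#' @param df data.frame with columns chromosome, start_idx, end_idx
#'   (1-based clone indices within the chromosome) and effect (copy-number
#'   log2 effect; 0 for neutral segments). Segments must partition each
#'   chromosome's clones.
#' @param map the `clone_map` the indices refer to.
#' @export
truth_profile <- function(df, map) {
  for (chrom in unique(df$chromosome)) {
    sel <- df[df$chromosome == chrom, , drop = FALSE]
    sel <- sel[order(sel$start_idx), , drop = FALSE]
    n <- sum(map$chromosome == chrom)
    if (sel$start_idx[1] != 1 || sel$end_idx[nrow(sel)] != n ||
        (nrow(sel) > 1 && any(sel$start_idx[-1] != sel$end_idx[-nrow(sel)] + 1)))
      validation_error("truth segments must partition chromosome %s", chrom)
  }
  rownames(df) <- NULL
  class(df) <- c("truth_profile", "data.frame")
  df
}

#' Generate a random ground-truth copy-number profile
#'
#' Partitions each chromosome into segments (about `n_segments` genome-wide,
#' distributed proportionally to clone counts) with effects drawn from a
#' mixture: neutral (effect 0) with probability `prop_neutral`, otherwise a
#' gain or loss of magnitude uniform in `effect_range`. Adjacent segments
#' always differ in effect, so every recorded breakpoint is real.
#'
#' @param map a `clone_map`.
#' @param n_segments genome-wide segment count target.
#' @param prop_neutral probability a segment is copy-neutral.
#' @param effect_range magnitude range of non-neutral log2 effects.
#' @param min_seg_clones minimum clones per truth segment.
#' @param seed integer seed.
#' @return A `truth_profile`.
#' @export
make_truth <- function(map, n_segments = 40, prop_neutral = 0.4,
                       effect_range = c(0.4, 1.2), min_seg_clones = 5,
                       seed = 1) {
  with_seed(derive_seed(seed, "truth"), {
    chroms <- unique(map$chromosome)
    n_c <- vapply(chroms, function(ch) sum(map$chromosome == ch), 0L)
    cap <- pmax(1L, n_c %/% min_seg_clones)
    alloc <- pmin(cap, pmax(1L, as.integer(round(n_segments * n_c / sum(n_c)))))
    while (sum(alloc) < n_segments && any(alloc < cap)) {
      k <- which(alloc < cap)[which.max(n_c[alloc < cap] / alloc[alloc < cap])]
      alloc[k] <- alloc[k] + 1L
    }
    while (sum(alloc) > n_segments && any(alloc > 1L)) {
      k <- which(alloc > 1L)[which.min(n_c[alloc > 1L] / alloc[alloc > 1L])]
      alloc[k] <- alloc[k] - 1L
    }
    rows <- list()
    for (ci in seq_along(chroms)) {
      s <- alloc[ci]; n <- n_c[ci]
      if (n < s * min_seg_clones || prop_neutral >= 1) s <- 1L
      len <- if (s == 1L) n else
        min_seg_clones + as.vector(stats::rmultinom(1, n - s * min_seg_clones,
                                                    rep(1, s)))
      ends <- cumsum(len)
      starts <- ends - len + 1
      eff <- numeric(s)
      if (prop_neutral < 1) {
        for (k in seq_len(s)) {
          repeat {
            e <- if (stats::runif(1) < prop_neutral) 0 else
              sample(c(-1, 1), 1) * stats::runif(1, effect_range[1], effect_range[2])
            if (k == 1 || e != eff[k - 1]) break
          }
          eff[k] <- e
        }
      }
      rows[[ci]] <- data.frame(chromosome = chroms[ci], start_idx = starts,
                               end_idx = ends, effect = eff,
                               stringsAsFactors = FALSE)
    }
    truth_profile(do.call(rbind, rows), map)
  })
}

#' Scripted truth with alterations on chosen chromosome arms
#'
#' Builds a truth profile that is flat except for whole-arm gains and
#' losses, e.g. `gains = c("1q", "8q", "17q")`, `losses = c("1p", "17p")`
#' to emulate a breast-cancer cell-line pattern.
#'
#' @param map a `clone_map`.
#' @param gains,losses character vectors of arms like "8q".
#' @param effect magnitude of the log2 effect.
#' @param centromere_frac fraction of a chromosome's clones on the p arm.
#' @export
arm_truth <- function(map, gains = character(), losses = character(),
                      effect = 0.8, centromere_frac = 0.4) {
  arm_of <- function(arms) list(chrom = sub("[pq]$", "", arms),
                                arm = sub("^.*([pq])$", "\\1", arms))
  g <- arm_of(gains); l <- arm_of(losses)
  rows <- list()
  for (chrom in unique(map$chromosome)) {
    n <- sum(map$chromosome == chrom)
    cen <- max(1L, min(n - 1L, as.integer(round(n * centromere_frac))))
    eff_p <- if (chrom %in% g$chrom[g$arm == "p"]) effect else
      if (chrom %in% l$chrom[l$arm == "p"]) -effect else 0
    eff_q <- if (chrom %in% g$chrom[g$arm == "q"]) effect else
      if (chrom %in% l$chrom[l$arm == "q"]) -effect else 0
    if (eff_p == eff_q) {
      rows[[length(rows) + 1L]] <- data.frame(chromosome = chrom, start_idx = 1L,
                                              end_idx = n, effect = eff_p,
                                              stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chrom, start_idx = c(1L, cen + 1L), end_idx = c(cen, n),
        effect = c(eff_p, eff_q), stringsAsFactors = FALSE)
    }
  }
  truth_profile(do.call(rbind, rows), map)
}

#' Per-clone effect vector of a truth profile
#' @param truth a `truth_profile`.
#' @param map the `clone_map`.
#' @return Numeric vector of log2 effects aligned to map order.
#' @export
truth_effects <- function(truth, map) {
  eff <- numeric(nrow(map))
  for (chrom in unique(truth$chromosome)) {
    idx <- which(map$chromosome == chrom)
    sel <- truth[truth$chromosome == chrom, , drop = FALSE]
    for (r in seq_len(nrow(sel)))
      eff[idx[sel$start_idx[r]:sel$end_idx[r]]] <- sel$effect[r]
  }
  eff
}

#' WGA artifact model
#'
#' @param random_flip_rate probability a spot's signal is replaced by a
#'   wide-magnitude draw whose sign opposes the clone's true signal
#'   (uniform sign on copy-neutral clones), inverting the downstream
#'   gain/loss call. This makes the rate identifiable: the expected
#'   discordance against a clean duplicate equals the rate.
#' @param flip_mag_sd standard deviation of the replacement magnitude.
#' @param recurrent_clone_fraction fraction of clones carrying a fixed
#'   per-clone bias shared by every replicate of the same method.
#' @param recurrent_bias_sd standard deviation of the recurrent offsets.
#' @param regional_bias_amplitude amplitude (log2) of a smooth bias field
#'   along the genome; 0 disables it.
#' @param regional_corr_length correlation length of the field, in clones.
#' @param measurement_sd per-spot log2-scale noise.
#' @param flag_rate fraction of spots flagged anomalous/absent.
#' @param method_seed integer distinguishing the method: recurrent clones
#'   and the regional field are derived from it so replicates of one method
#'   share them and different methods do not.
#' @export
artifact_model <- function(random_flip_rate = 0, flip_mag_sd = 1.2,
                           recurrent_clone_fraction = 0, recurrent_bias_sd = 0.6,
                           regional_bias_amplitude = 0, regional_corr_length = 40,
                           measurement_sd = 0, flag_rate = 0, method_seed = 0) {
  rates <- c(random_flip_rate, recurrent_clone_fraction, flag_rate)
  if (any(rates < 0 | rates > 1)) validation_error("rates must be in [0, 1]")
  if (regional_bias_amplitude < 0 || measurement_sd < 0)
    validation_error("amplitudes must be >= 0")
  structure(list(random_flip_rate = random_flip_rate, flip_mag_sd = flip_mag_sd,
                 recurrent_clone_fraction = recurrent_clone_fraction,
                 recurrent_bias_sd = recurrent_bias_sd,
                 regional_bias_amplitude = regional_bias_amplitude,
                 regional_corr_length = regional_corr_length,
                 measurement_sd = measurement_sd, flag_rate = flag_rate,
                 method_seed = as.integer(method_seed)),
            class = "artifact_model")
}

#' Preset artifact models
#'
#' `none` is the all-zero model. `control_like` carries only the baseline
#' hybridization noise of a non-amplified sample. `scomp_like` adds a small
#' random flip rate and a recurrent clone set but no regional bias;
#' `dop_like` has a larger flip rate, a recurrent clone set, a strong
#' smooth regional bias and more measurement noise. The numeric constants
#' are calibration choices (the methods vignette discusses them); they are
#' set once to preserve the qualitative ordering
#' dop < scomp < duplicate-control on every concordance statistic.
#'
#' @param name one of "none", "control_like", "scomp_like", "dop_like".
#' @return An [artifact_model()].
#' @export
preset_params <- function(name = c("none", "control_like", "scomp_like", "dop_like")) {
  name <- match.arg(name)
  switch(name,
    none = artifact_model(),
    control_like = artifact_model(measurement_sd = 0.40, flag_rate = 0.02,
                                  method_seed = 11),
    scomp_like = artifact_model(random_flip_rate = 0.08,
                                recurrent_clone_fraction = 0.04,
                                recurrent_bias_sd = 0.9,
                                measurement_sd = 0.70, flag_rate = 0.03,
                                method_seed = 101),
    dop_like = artifact_model(random_flip_rate = 0.15,
                              recurrent_clone_fraction = 0.015,
                              regional_bias_amplitude = 0.65,
                              regional_corr_length = 30,
                              measurement_sd = 0.85, flag_rate = 0.04,
                              method_seed = 202))
}

# method-specific structures shared by replicates: recurrent clone offsets
# and the smooth regional bias field, derived from the model's method_seed
# only, so every replicate of one method sees the same structures and
# different methods see different ones.
method_structures <- function(map, artifacts) {
  n <- nrow(map)
  rec <- numeric(n); regional <- numeric(n)
  if (artifacts$recurrent_clone_fraction > 0) {
    rec <- with_seed(derive_seed(artifacts$method_seed, "recurrent"), {
      k <- max(1L, round(artifacts$recurrent_clone_fraction * n))
      idx <- sample.int(n, k)
      out <- numeric(n)
      out[idx] <- sample(c(-1, 1), k, replace = TRUE) *
        (artifacts$recurrent_bias_sd * (0.5 + abs(stats::rnorm(k))))
      out
    })
  }
  if (artifacts$regional_bias_amplitude > 0) {
    regional <- with_seed(derive_seed(artifacts$method_seed, "regional"), {
      out <- numeric(n)
      for (chrom in unique(map$chromosome)) {
        idx <- which(map$chromosome == chrom)
        wn <- stats::rnorm(length(idx))
        L <- max(2L, min(artifacts$regional_corr_length, length(idx) %/% 2))
        sm <- as.numeric(stats::filter(wn, rep(1 / L, L), sides = 2,
                                       circular = TRUE))
        s <- stats::sd(sm)
        sm <- if (s > 1e-8) sm / s else numeric(length(idx))
        out[idx] <- artifacts$regional_bias_amplitude * sm
      }
      out
    })
  }
  list(recurrent = rec, regional = regional)
}

#' Simulate one two-channel hybridization
#'
#' The reference channel intensity per spot is log-normal; the test channel
#' is the reference scaled by 2 to the power of (truth effect + regional
#' bias + recurrent bias + spot noise), except flipped spots whose
#' log-ratio is replaced by a wide-magnitude draw opposing the clone's true
#' signal. A per-subgrid multiplicative channel imbalance is injected so
#' subgrid normalization has real work to do, and spots are flagged
#' anomalous/absent at `flag_rate` (flagged spots get corrupted
#' intensities).
#'
#' @param truth a `truth_profile`.
#' @param platform the list from [make_platform()] (map + grid).
#' @param artifacts an [artifact_model()].
#' @param seed integer seed; identical inputs and seed give a
#'   byte-identical table.
#' @param base_meanlog,base_sdlog log-normal reference-channel intensity.
#' @param subgrid_imbalance_sd log-sd of the per-subgrid channel-1 factor
#'   (0 disables the imbalance).
#' @return A `spot_table`.
#' @export
simulate_hybridization <- function(truth, platform, artifacts = preset_params("none"),
                                   seed = 1, base_meanlog = log(1000),
                                   base_sdlog = 0.25,
                                   subgrid_imbalance_sd = 0.15) {
  map <- platform$map; grid <- platform$grid
  n <- nrow(map)
  eff <- truth_effects(truth, map)
  ms <- method_structures(map, artifacts)
  with_seed(derive_seed(seed, "hyb"), {
    noise <- if (artifacts$measurement_sd > 0)
      stats::rnorm(n, 0, artifacts$measurement_sd) else numeric(n)
    logratio <- eff + ms$recurrent + ms$regional + noise
    if (artifacts$random_flip_rate > 0) {
      flip <- stats::runif(n) < artifacts$random_flip_rate
      nf <- sum(flip)
      if (nf) {
        s <- sign(eff[flip])
        s[s == 0] <- sample(c(-1, 1), sum(s == 0), replace = TRUE)
        logratio[flip] <- -s * abs(stats::rnorm(nf, 0, artifacts$flip_mag_sd))
      }
    }
    ch2 <- stats::rlnorm(n, base_meanlog, base_sdlog)
    blockfac <- if (subgrid_imbalance_sd > 0)
      stats::rlnorm(max(grid$block), 0, subgrid_imbalance_sd)
    else rep(1, max(grid$block))
    ch1 <- ch2 * 2^logratio * blockfac[grid$block]
    flag <- rep("ok", n)
    if (artifacts$flag_rate > 0) {
      flagged <- which(stats::runif(n) < artifacts$flag_rate)
      flag[flagged] <- sample(c("anomalous", "absent"), length(flagged),
                              replace = TRUE)
      ch1[flagged] <- ch1[flagged] * stats::runif(length(flagged), 0.05, 20)
    }
    spot_table(data.frame(block = grid$block, row = grid$row,
                          column = grid$column, clone_id = map$clone_id,
                          intensity_ch1 = ch1, intensity_ch2 = ch2,
                          flag = flag, stringsAsFactors = FALSE))
  })
}

#' Simulate a self-self hybridization (same DNA in both channels)
#'
#' A flat-truth hybridization with only baseline noise: the negative
#' control of the platform.
#'
#' @inheritParams simulate_hybridization
#' @param measurement_sd baseline per-spot noise.
#' @export
simulate_self_self <- function(platform, seed = 1, measurement_sd = 0.40,
                               flag_rate = 0.02) {
  flat <- flat_truth(platform$map)
  simulate_hybridization(flat, platform,
                         artifact_model(measurement_sd = measurement_sd,
                                        flag_rate = flag_rate, method_seed = 7),
                         seed = seed)
}

#' Flat (all-neutral) truth profile
#' @param map a `clone_map`.
#' @export
flat_truth <- function(map) {
  rows <- lapply(unique(map$chromosome), function(chrom)
    data.frame(chromosome = chrom, start_idx = 1L,
               end_idx = sum(map$chromosome == chrom), effect = 0,
               stringsAsFactors = FALSE))
  truth_profile(do.call(rbind, rows), map)
}
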