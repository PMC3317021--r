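# Generic statistics used by the assessment: Pearson correlation of
# nonsegmented profiles, the exact two-tailed Mann-Whitney U test, and
# delta-delta-Ct quantification of Q-PCR validation assays with categorical
# binning and aCGH agreement counting.

#' Pearson correlation of two nonsegmented profiles
#'
#' @param a,b `cgh_profile`s.
#' @param min_overlap minimum number of shared clones required.
#' @return Pearson r over the shared clones' log2 values.
#' @export
pearson_profiles <- function(a, b, min_overlap = 100) {
  shared <- intersect(a$clone_id, b$clone_id)
  if (length(shared) < min_overlap)
    undefined_stat("only %d shared clones (min_overlap = %d)",
                   length(shared), min_overlap)
  va <- stats::setNames(a$log2, a$clone_id)[shared]
  vb <- stats::setNames(b$log2, b$clone_id)[shared]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    undefined_stat("zero variance in one of the profiles")
  stats::cor(va, vb)
}

#' Pairwise correlation matrix of profiles
#'
#' Undefined pairs (insufficient overlap or zero variance) are returned as
#' `NA` entries; the matrix is still produced.
#'
#' @param profiles list of `cgh_profile`s (>= 2).
#' @param min_overlap minimum shared clones per pair.
#' @return List with `sample_ids`, the symmetric matrix `r` (unit
#'   diagonal), and the matrix `n_overlap` of shared-clone counts.
#' @export
correlation_matrix <- function(profiles, min_overlap = 100) {
  if (length(profiles) < 2) validation_error("need at least 2 profiles")
  ids <- vapply(seq_along(profiles), function(k)
    as.character(attr(profiles[[k]], "sample_id") %||% paste0("S", k)), "")
  n <- length(profiles)
  r <- diag(1, n); nov <- matrix(0L, n, n)
  dimnames(r) <- dimnames(nov) <- list(ids, ids)
  for (i in seq_len(n)) nov[i, i] <- nrow(profiles[[i]])
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- intersect(profiles[[i]]$clone_id, profiles[[j]]$clone_id)
    nov[i, j] <- nov[j, i] <- length(shared)
    rij <- tryCatch(pearson_profiles(profiles[[i]], profiles[[j]], min_overlap),
                    wga_undefined_statistic = function(e) NA_real_)
    r[i, j] <- r[j, i] <- rij
  }
  list(sample_ids = ids, r = r, n_overlap = nov)
}

# Mann-Whitney U for group x against group y, with midrank tie handling.
u_statistic <- function(x, y) {
  n1 <- length(x)
  ranks <- rank(c(x, y))
  sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Exact two-tailed Mann-Whitney U test
#'
#' The U statistic uses midranks under ties. The exact p-value enumerates
#' all `choose(n1+n2, n1)` assignments of the pooled values to the two
#' groups; the two-tailed p is the probability mass of assignments whose U
#' is at least as far from the null mean `n1*n2/2` as the observed U
#' (distance-from-mean rule, well defined under ties and unequal group
#' sizes). With all pooled values tied, p = 1 with a warning.
#'
#' @param x,y numeric vectors (both nonempty).
#' @param exact enumerate all assignments (default). Set `FALSE` to use the
#'   normal approximation with tie correction instead, for group sizes
#'   where enumeration is impractical.
#' @return List with elements `U` (for group `x`) and `p` (two-tailed).
#' @export
mann_whitney_exact <- function(x, y, exact = TRUE) {
  if (!length(x) || !length(y)) validation_error("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  U_obs <- u_statistic(x, y)
  mu <- n1 * n2 / 2
  if (length(unique(pooled)) == 1) {
    warning("all pooled values tied; p = 1")
    return(list(U = U_obs, p = 1))
  }
  if (!exact || choose(n, n1) > 5e6) {
    if (exact)
      warning("enumeration over ", choose(n, n1),
              " assignments is impractical; using the normal approximation")
    ties <- table(pooled)
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1))))
    z <- (abs(U_obs - mu) - 0.5) / sigma
    return(list(U = U_obs, p = min(1, 2 * stats::pnorm(-max(z, 0)))))
  }
  ranks <- rank(pooled)
  offset <- n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  U_all <- colSums(matrix(ranks[combs], nrow = n1)) - offset
  d_obs <- abs(U_obs - mu)
  p <- mean(abs(U_all - mu) >= d_obs - 1e-9)
  list(U = U_obs, p = min(p, 1))
}

#' A Q-PCR record for delta-delta-Ct quantification
#'
#' @param gene gene name.
#' @param ct_target_sample,ct_ref_gene_sample triplicate Ct values of the
#'   target and reference gene in the sample.
#' @param ct_target_calibrator,ct_ref_gene_calibrator triplicate Ct values
#'   in the calibrator (e.g. normal placenta DNA).
#' @export
qpcr_record <- function(gene, ct_target_sample, ct_ref_gene_sample,
                        ct_target_calibrator, ct_ref_gene_calibrator) {
  cts <- list(ct_target_sample = ct_target_sample,
              ct_ref_gene_sample = ct_ref_gene_sample,
              ct_target_calibrator = ct_target_calibrator,
              ct_ref_gene_calibrator = ct_ref_gene_calibrator)
  for (nm in names(cts)) {
    v <- cts[[nm]]
    if (!length(v) || any(!is.finite(v)) || any(v <= 0))
      validation_error("%s must be nonempty, finite and > 0", nm)
  }
  structure(c(list(gene = gene), cts), class = "qpcr_record")
}

#' Relative quantity by the delta-delta-Ct method
#'
#' `quantity = 2^-((Ct_target - Ct_ref)_sample - (Ct_target - Ct_ref)_calibrator)`
#' with each Ct the mean of its triplicate. Invariant to adding a constant
#' to every Ct in the record.
#'
#' @param rec a [qpcr_record()].
#' @return Relative quantity (1 = equal to calibrator).
#' @export
ddct_quantity <- function(rec) {
  d_sample <- mean(rec$ct_target_sample) - mean(rec$ct_ref_gene_sample)
  d_cal <- mean(rec$ct_target_calibrator) - mean(rec$ct_ref_gene_calibrator)
  2^-(d_sample - d_cal)
}

#' Categorical bin of a Q-PCR relative quantity
#'
#' "loss" when the quantity is below 0.7, "gain" when above 1.3, and "N"
#' in between (boundary values map to "N").
#'
#' @param quantity relative quantity (> 0).
#' @return One of "loss", "N", "gain".
#' @export
qpcr_bin <- function(quantity) {
  if (!is.finite(quantity) || quantity <= 0)
    validation_error("quantity must be > 0")
  if (quantity < 0.7) "loss" else if (quantity > 1.3) "gain" else "N"
}

# aCGH category to direction: "-" loss, "N" neutral, any "+" level gain,
# blank no-call.
acgh_direction <- function(category) {
  category <- gsub(" ", "", as.character(category))
  ifelse(category == "-" | category == "−", "loss",
         ifelse(category == "N", "neutral",
                ifelse(grepl("^\\++$", category), "gain", "nocall")))
}

#' Agreement between Q-PCR quantities and aCGH copy-number categories
#'
#' Counts genes whose Q-PCR relative quantity confirms the aCGH category.
#' Under the default `"elevated_gain"` rule a gain call (any "+" level) is
#' confirmed by any quantity above the calibrator (q > 1), a loss call by a
#' quantity below the loss cutpoint (q < 0.7), and an "N" call by a
#' quantity inside the neutral band (0.7 <= q <= 1.3). The asymmetry
#' reflects the strong compression of amplified copy numbers in relative
#' quantification: high-level gains routinely yield ratios well below the
#' nominal gain cutpoint, whereas losses are already expressed within
#' [0, 1). `rule = "strict_bin"` instead requires the [qpcr_bin()] category
#' to equal the aCGH direction symmetrically. A blank aCGH category is
#' never confirmed; genes present in only one input are excluded with a
#' warning.
#'
#' @param qpcr data.frame with columns `gene` and `quantity`.
#' @param acgh data.frame with columns `gene` and `category` (one of
#'   `-`, `N`, `+`, `++`, `+++`, `++++`, or blank).
#' @param rule `"elevated_gain"` (default) or `"strict_bin"`.
#' @return List: `n_confirmed`, `n_total`, and the per-gene data.frame
#'   `detail`.
#' @export
qpcr_acgh_agreement <- function(qpcr, acgh,
                                rule = c("elevated_gain", "strict_bin")) {
  rule <- match.arg(rule)
  shared <- intersect(qpcr$gene, acgh$gene)
  only <- c(setdiff(qpcr$gene, acgh$gene), setdiff(acgh$gene, qpcr$gene))
  if (length(only))
    warning("gene(s) present in one input only, excluded: ",
            paste(only, collapse = ", "))
  q <- stats::setNames(qpcr$quantity, qpcr$gene)[shared]
  dir <- acgh_direction(stats::setNames(acgh$category, acgh$gene)[shared])
  confirmed <- vapply(seq_along(shared), function(k) {
    if (dir[k] == "nocall") return(FALSE)
    if (rule == "strict_bin") {
      bin <- qpcr_bin(q[k])
      return((dir[k] == "gain" && bin == "gain") ||
             (dir[k] == "loss" && bin == "loss") ||
             (dir[k] == "neutral" && bin == "N"))
    }
    switch(dir[k],
           gain = q[k] > 1,
           loss = q[k] < 0.7,
           neutral = q[k] >= 0.7 && q[k] <= 1.3)
  }, logical(1))
  list(n_confirmed = sum(confirmed), n_total = length(shared),
       detail = data.frame(gene = shared, quantity = as.numeric(q),
                           acgh_direction = dir, confirmed = confirmed,
                           stringsAsFactors = FALSE))
}

#' Published Q-PCR validation table for the UACC-812 cell line
#'
#' The 22-gene validation panel for the UACC-812 breast cancer cell line:
#' relative gene quantity by Q-PCR (versus normal placenta DNA, the
#' calibrator) and the copy-number category assigned by aCGH to the
#' corresponding cDNA clone in non-amplified (control), SCOMP-amplified and
#' DOP-amplified material.
#'
#' @return data.frame with columns clone, gene, quantity, control, scomp,
#'   dop.
#' @export
uacc812_qpcr <- function() {
  path <- system.file("extdata", "uacc812_qpcr.tsv", package = "wgafidelity")
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = character(),
                    colClasses = c("character", "character", "numeric",
                                   "character", "character", "character"),
                    stringsAsFactors = FALSE)
}
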