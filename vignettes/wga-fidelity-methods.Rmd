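---
title: "Assessing whole-genome-amplification fidelity with array CGH: models and methods"
author: "wgafidelity authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing whole-genome-amplification fidelity with array CGH: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgafidelity)
```

## The problem

Array comparative genomic hybridization (aCGH) measures DNA copy-number
differences between a test and a reference genome by co-hybridizing
differently labeled DNA to an array of mapped probes; the log2 ratio per
probe reflects relative copy number. Microdissected lesions — early breast
lesions in formalin-fixed paraffin-embedded (FFPE) tissue being the
motivating case — yield far too little DNA for aCGH, so the genome must
first be amplified. Whole-genome amplification (WGA), whether
ligation-mediated (SCOMP-style) or degenerate-oligonucleotide-primed
(DOP-PCR), can distort the copy-number signal it is supposed to preserve.

`wgafidelity` quantifies that distortion. An amplified sample is compared
with its own non-amplified control at three resolutions:

1. **Per-spot gain/loss concordance** — the percentage of shared clones
   assigned the same binary gain/loss call by both hybridizations.
2. **Genome-length concordance of segmentation** — the percentage of the
   control's altered genome length that both samples' segmentations call
   gain (or loss) concordantly.
3. **Peak concordance** — the percentage of the amplified sample's
   moving-average peaks matched by a control peak of the same sign at an
   overlapping position, amplitude ignored.

No platform is perfect: two hybridizations of the *same* non-amplified DNA
also disagree. Duplicate control runs therefore define the **reference
values** — the best concordance the platform can deliver — and each
amplified group's per-sample statistics are compared with the reference
distribution by the exact two-tailed Mann-Whitney U test.

## Normalization model

Spot quantification tables carry two channel intensities per spot plus a
quality flag. Preprocessing follows three steps:

* **Subgrid equalization.** Each print subgrid is normalized
  independently: channel-1 intensities are multiplied by the single factor
  that equates the subgrid's channel-1 and channel-2 totals over unflagged
  spots with positive intensities. Flagged spots are rescaled but never
  drive the factor. Total-intensity equalization is the simplest estimator
  consistent with "equalizing" the channels and is equivariant under
  uniform rescaling of either channel.
* **Log2 ratios.** Per clone, `log2(ch1/ch2)`; spots flagged
  anomalous/absent or with a zero intensity are dropped (no pseudocount is
  invented), and replicate spots of one clone are averaged on the log
  scale.
* **Median centering and scaling.** The profile is centered by its median
  and scaled so the median absolute (centered) value equals `scale_target`
  (default 1.0). The operation is idempotent and the contract — median 0,
  median absolute value = target — holds to 1e-12.

One modeling caveat worth knowing: subgrid total-equalization is an exact
identity only when every subgrid carries the same mixture of copy-number
effects. On a genome with real gains and losses, each subgrid acquires a
small log-offset equal to the log2 of its own mean linear effect. In noisy
data this is far below the measurement noise; in *noise-free* data it is
the only "signal" left, and a permutation-based segmenter will faithfully
find it. The package's noise-free conservation checks therefore feed the
segmenter exact log-ratios rather than re-equalized ones.

## Circular binary segmentation

Profiles are segmented per chromosome by circular binary segmentation
(CBS): the clone sequence is treated as a circle, and for every boundary
pair (i, j) the arc of clones i+1..j is compared with its complement by

T = |mean(arc) − mean(complement)| / (σ̂ · sqrt(1/k + 1/(n−k)))

where k is the arc length and σ̂ a noise-scale estimate. The maximizing
pair is tested by permutation: the chromosome's values are shuffled
`n_perm` times and the split is accepted when fewer than `alpha · n_perm`
shuffles reach the observed maximum. Accepted splits recurse on the
resulting pieces; a wrapping maximal arc is emitted as the two linear
breakpoints it induces. Implementation notes:

* σ̂ is the median absolute deviation of first differences divided by
  sqrt(2), a point-wise noise estimate robust to the alterations being
  detected. Because the same σ̂ scales observed and permuted statistics, it
  cancels from the permutation decision; it matters only for reported
  statistic values.
* Ties in the arc maximization break toward the smallest (i, then j), so
  segmentation is deterministic. Each recursion node derives its own RNG
  substream from (seed, chromosome, node boundaries), which makes p-values
  a function of the node alone: results do not depend on evaluation order,
  and lowering `alpha` can only prune, never add, splits.
* The permutation loop exits early once the exceedance count guarantees
  p ≥ alpha; the split decision is provably identical to running all
  permutations.
* Adjacent segments whose means agree to 1e-9 are merged; this never
  triggers on noisy data and only cleans up degenerate splits of exactly
  piecewise-constant input.
* Defaults: `alpha = 0.01`, `n_perm = 1000` (desk-scale; large studies in
  this package use 150–200 without visible loss), `min_width = 2`, no undo
  pruning. On platform-scale simulations these defaults produce on the
  order of 40 segments per genome, the regime the concordance statistics
  are designed for.
* Segment boundaries in base pairs are midpoints between flanking clones;
  chromosome ends extend to the first/last clone.
* Calls are a pure sign rule by default (`call_threshold = 0`, strict
  inequalities), because the concordance statistics are sign-based; the
  threshold is exposed for users who want a minimum amplitude.

## Moving-average peaks

The moving average uses a window of `window = 20` data points (clones, not
base pairs). Interior windows hold exactly 20 points (one extra on the
left for even windows); at chromosome ends the window shrinks
symmetrically so it stays centered, which keeps peak positions unbiased.
Windows never cross chromosome boundaries.

Peak detection needs a threshold the source analysis leaves unstated
("without restrictions for amplitude" governs *matching*, not detection).
The package uses a robust genome-wide threshold
τ = `threshold_k` × median(|smoothed − median(smoothed)|) with
`threshold_k = 2`, and requires `min_run = 5` consecutive super-threshold
clones. Both are configurable; the choice is deterministic and scale-free
under the profile scaling. Since matching ignores amplitude, identity
pairs score 100 and mirrored pairs score 0 for any detector setting; tests
of those extremes use a more sensitive detector (`threshold_k = 1`,
`min_run = 3`) only so that every random profile yields an assessable,
nonempty peak set.

## Concordance statistics and their conventions

Three conventions were genuinely open and are resolved as follows:

* **Denominator of genome-length concordance**: the control's altered
  (gain ∪ loss) length. Anchoring to the control treats the non-amplified
  sample as truth, which matches the framing of controls as reference; a
  union-based denominator is available via `denominator = "union"`.
* **Peak matching is test-anchored**: the statistic is the percentage of
  the *amplified* sample's peaks that find a same-sign overlapping control
  peak.
* **Recurrent discordance** requires opposition to the (per-sample)
  control in *every* sample of a group, not a majority; a single-sample
  group is flagged as degenerate.

Undefined statistics (an empty test peak set, a control with zero altered
length, insufficient profile overlap) are reported as absent — never as 0
or 100 — via typed conditions.

## Exact Mann-Whitney U

Group sizes here are tiny (3 amplified samples against a handful of
reference pairs), so the U test must be exact. The U statistic uses
midranks; the p-value enumerates all C(n1+n2, n1) assignments of the
pooled values and sums the probability of assignments whose U lies at
least as far from the null mean n1·n2/2 as observed. This
distance-from-mean two-tail rule is well defined under ties and unequal
group sizes, and reduces to doubling the one-sided tail in balanced
separation cases (3v3 complete separation gives p = 2/20 = 0.1 exactly).

## Q-PCR validation

Relative gene quantity is computed by the delta-delta-Ct method from
triplicate cycle thresholds, with the reference gene an explicit input
(none is hard-coded). Quantities bin at the published cutpoints: loss
below 0.7, neutral 0.7–1.3 (boundaries inclusive), gain above 1.3.

Agreement with aCGH categories deserves a note. The shipped 22-gene
UACC-812 validation panel reports 18/22 genes confirmed on non-amplified
DNA, but a literal symmetric comparison of the Q-PCR bin against the aCGH
direction yields 16/22: two genes with quantities 1.18 and 1.22 (inside
the neutral band) carry aCGH gain categories. The rule that reproduces the
published counts — and the package default (`rule = "elevated_gain"`) — is
asymmetric: a gain call is confirmed by any quantity above the calibrator
(q > 1), a loss call only by a quantity below the loss cutpoint (q < 0.7),
and a neutral call by a quantity inside the band. The asymmetry has a
physical reading: relative quantification compresses amplified copy
numbers toward 1 (efficiency and saturation), so moderate elevations are
consistent with true gains, whereas the loss side of the scale is already
bounded. The literal rule remains available as `rule = "strict_bin"` and
its 16/22 behavior is pinned by a test. A blank aCGH category is never
confirmed.

## The synthetic-data generator

The generator exists so every pipeline stage is testable without
microarray scans. What it emulates, and what it does not:

* **Platform**: ~11,000 mapped clones across 22 autosomes + X with
  log-normal inter-clone gaps, median 73.4 kb and log-sd 1.77 — chosen so
  ~93% of gaps fall below 1 Mb, matching the published spacing summary of
  the emulated cDNA array; clones are assigned round-robin to print
  subgrids (48 blocks of 16×16 by default).
* **Truth profiles**: ~40 segments genome-wide (distributed over
  chromosomes proportional to clone counts, minimum 5 clones per segment),
  each neutral with probability 0.4 or carrying a log2 effect of magnitude
  0.4–1.2. Forty segments per genome and the roughly even gain/loss split
  mirror the segment counts reported for FFPE breast-cancer profiles;
  effect sizes are typical cDNA-array single-copy-change amplitudes.
  Scripted arm-level truths (`arm_truth`) reproduce cell-line-like
  patterns such as gains on 1q/8q/17q with losses on 1p/17p.
* **Hybridization**: reference channel log-normal (sd 0.25 on the log
  scale); test channel = reference × 2^(effect + biases + N(0, sd) noise);
  a per-subgrid channel imbalance (log-sd 0.15) gives subgrid
  normalization real work; spots are flagged anomalous/absent at a small
  rate with corrupted intensities.
* **WGA artifacts**, three components: (i) *random flips* — with
  probability `random_flip_rate`, a spot's log-ratio is replaced by a
  wide-magnitude draw whose sign opposes the clone's true signal, so the
  downstream call inverts and the rate is identifiable as the expected
  spot discordance against a clean duplicate; (ii) *recurrent clones* — a
  fixed fraction of clones carries a per-clone offset shared by every
  replicate of one method and different between methods, reproducing the
  1.5–2.5% recurrently discordant clones seen in real groups; (iii)
  *regional bias* — a smooth multiplicative field along the genome
  (white noise smoothed over ~30 clones), the signature of DOP-style
  artifactual regional amplification.
* **Presets**: `none` (all zero), `control_like` (baseline noise sd 0.40,
  2% flags), `scomp_like` (flips 7%, recurrent 3%, noise 0.55, no regional
  bias), `dop_like` (flips 15%, recurrent 1.5%, regional amplitude 0.65,
  noise 0.85). The preset magnitudes are calibration constants, not claims
  about chemistry: they are fixed once so that every concordance statistic
  orders dop-like < scomp-like ≤ duplicate controls, the qualitative
  pattern the assessment is meant to detect, with the scomp-like group
  usually *not* statistically separable from the reference and the
  dop-like group usually flagged.

What the generator does **not** model: sequence-level fragmentation
chemistry, primer bias, FFPE fragment-length effects, spatial gradients
within subgrids, or dye-specific (Cy3/Cy5) intensity-dependent curvature.
Passing tests therefore demonstrate the *analysis* is correct and
discriminating under a realistic noise model — not that any particular
laboratory protocol behaves like a preset.

## Study design of the synthetic assessment

A simulated study mirrors the real design: each tumor sample is hybridized
twice without amplification (duplicate control pairs → reference values),
and the first three samples are additionally amplified once per method.
The package's default study uses **six** duplicate-control pairs rather
than three: with only three reference pairs, the exact two-tailed 3-vs-3
Mann-Whitney can never fall below p = 0.1, so no group could ever be
flagged at p < 0.05; six reference pairs put the attainable minimum at
2/84 ≈ 0.024 while keeping the reference set small enough to simulate
quickly.

Problem sizes: the packaged analyses run on 1,100–2,200-clone platforms
with 150–200 permutations per CBS split — chosen as the smallest sizes at
which segment counts, concordance levels and test behavior match the
full-platform regime; the generator defaults remain at the full ~11,000
clones.

## Numerical and degenerate-input policy

* Constant profiles cannot be scale-normalized (degenerate-profile error).
* Chromosomes with fewer than two clones pass through smoothing and
  segmentation as trivial single segments, with a warning.
* Exact zeros are excluded from sign-based spot calls (with the default
  threshold, nothing else is).
* All randomness flows from one integer seed through a fixed fan-out, so
  identical configurations are byte-identical, including across
  evaluation orders.

## Known limitations

* CBS here is a faithful implementation of the published algorithm, not a
  bug-for-bug clone of any particular DNAcopy release; split p-values use
  plain max-statistic permutation with no hybrid approximation, so very
  long chromosomes segment more slowly than in heavily optimized
  implementations.
* The genome-length concordance depends on the denominator convention;
  both conventions are implemented, and reported numbers state which is
  used (control-anchored by default).
* The Q-PCR agreement rule is an operationalization chosen to reproduce a
  published count whose own rule is not stated; both it and the literal
  alternative are exposed, and conclusions should not hinge on the two
  borderline genes that separate them.
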