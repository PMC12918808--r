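---
title: "Methods: scoring pooled fractionation reporter screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring pooled fractionation reporter screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frepscreen)
```

# The measurement and its model

A fractionation reporter screen reads out, for every CRISPRi knockdown in a
pooled library, how a barcoded reporter mRNA partitions between a total
lysate fraction and a 20,000 g condensate-enriched pellet fraction. The
unit of measurement is the barcode: each guide RNA is linked to one or more
unique 3′-UTR barcodes, and each sequencing sample is a vector of barcode
counts. Because every barcode reports on the *same* reporter transcript,
intrinsic mRNA features (length, cis-elements) are controlled by design,
and differences between barcodes reflect the genetic perturbations.

The scoring chain is:

1. **Size factors.** Median-of-ratios to a geometric-mean pseudo-reference
   over features detected in all samples (total-count scaling when fewer
   than 50 such features exist). See *Depth anchoring* below for the
   absolute-scale convention the pipeline uses.
2. **Log ratio.** Per barcode and replicate,
   `lr = log2((pellet/s_p + c)/(total/s_t + c))` with pseudocount
   `c = 0.5`. The pseudocount is symmetric; a barcode sequenced in the
   total but absent from the pellet stays finite and strongly negative.
3. **Neighborhood normalization.** Count ratios are strongly
   heteroskedastic: low-abundance barcodes have noisy ratios, and
   composition effects can bend the ratio-versus-abundance trend. Barcodes
   are therefore sorted by normalized total-fraction abundance and each is
   standardized against the window of `K = 201` barcodes centered on it
   (truncated symmetrically at the edges):
   `NNS = (lr − median(window)) / (1.4826 · MAD(window))`. Median/MAD was
   chosen over mean/sd because pooled screens have heavy-tailed ratio
   distributions — the few true modulators would otherwise inflate their
   own neighborhood's scale. The MAD is multiplied by 1.4826 so the score
   is in standard-deviation units for Gaussian data, and floored at 1e-8 so
   constant windows yield a score of 0 rather than NaN.
4. **Gene aggregation.** Barcode scores are averaged within guides, then
   guides within genes (unweighted means; medians are available via
   `aggregate = "median"`). Genes none of whose guides retain a scored
   barcode are marked missing rather than imputed.
5. **Replicate combination.** The gene's FRep score is the arithmetic mean
   of its per-replicate scores; reproducibility is a two-sided one-sample
   t-test against zero across replicates. The score could alternatively be
   defined as one NNS of replicate-pooled counts; the mean-of-replicates
   reading was chosen because it is the one compatible with reporting a
   per-gene t-test over biological replicates.

Sign convention throughout: **positive = more condensate-associated**
(pellet-enriched), in units of neighborhood standard deviations.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pseudocount` | 0.5 | normalized counts | symmetric zero-guard; keeps dropout barcodes finite |
| `min_count` | 20 | normalized counts | below this, ratios are Poisson-noise dominated |
| `window_size` (K) | 201 | barcodes | wide enough for stable median/MAD, narrow enough to track abundance trends |
| `aggregate` | mean | — | unweighted; median available for outlier-heavy libraries |
| `p_floor` | 1e-12 | probability | zero replicate variance reports this floor plus a flag, never p = 0 |
| `hit` / `hit_threshold` | 2 | NNS sd units | hit convention for trajectories and screen comparisons |
| `basal_cap` | 3 | NNS sd units | verbatim upper cap of the basal rule (see below) |
| `delta_threshold` | 1 | NNS sd units | minimum between-screen difference for an interaction call |
| `bin_size` | 100 | transcripts | length bins for transcriptome z-scores |
| `nominal_depth` | 2e5 (screen), 2e6 (RNA-seq) | reads | absolute scale of normalized counts (see below) |

# Depth anchoring

`size_factors()` offers two conventions. The standard `"geomean"`
convention rescales factors to geometric mean 1 and is what the function
reports by default. The scoring pipelines instead use `"depth"`: factors
are anchored so normalized counts are expressed as *counts per
`nominal_depth` sequenced reads* (an absolute scale). The reason is
exactness of depth invariance: with geometric-mean-1 factors, multiplying
one of *m* samples by a constant λ shifts **every** normalized count by
λ^(1/m), and because the pseudocount and the abundance filter are additive
thresholds on that scale, scores would move by ~1e-2. With depth-anchored
factors, rescaling any sample changes only that sample's factor, so every
normalized count — and hence every NNS and condensation z-score — is
bit-for-bit unchanged. `nominal_depth` only sets the units of
`min_count` and `pseudocount`; it defaults to the depth regime the
defaults were calibrated for (2×10⁵ reads/sample for screens).

# Trajectory classification

The responder rules are strict inequalities on the score at 0/10/30/60
minutes of heat shock: *sustained* (> 2 everywhere), *basal* (> 2 at 0 min,
< 3 at the heat time points), *early* (< 2 at 0 min, > 2 afterwards),
*time-dependent* (all three consecutive differences > 0 and > 2 at 60 min),
else *other*. Two choices were open:

* **Precedence.** The printed rules overlap (a flat trajectory at 2.5 is
  both sustained and basal; a monotone rise from below 2 is both early and
  time-dependent). Rules are evaluated sustained → basal → early →
  time-dependent, resolving overlaps toward the stronger/more specific
  phenotype; the order is an argument.
* **The basal cap.** The basal rule's asymmetric thresholds (> 2 at time 0
  but < 3 afterwards) are implemented verbatim; `basal_cap = 2` gives the
  symmetric variant.
* Scores exactly at a threshold fail the strict comparison: (2,2,2,2) is
  *other*. Non-finite scores are an error in the scalar API and are
  labelled *other* with a flag in the table API.

# Fractionated RNA-seq

Condensation is `log2(pellet/total)` per condition; ribosome association
is `log2(ribosome/total)`. Longer transcripts sediment more regardless of
stress, so transcripts are sorted by length (ties broken by transcript id,
for determinism), cut into consecutive bins of 100, and z-scored within
bins ((n−1)-denominator sd). A final bin smaller than 10 is merged into
its predecessor to avoid unstable variances; zero-variance bins yield
z = 0 with a flag. Group contrasts of Δcondensation (heat minus basal) use
Wilcoxon rank-sum tests against the background group — exact when both
groups have ≤ 12 members and no ties, otherwise the tie-corrected normal
approximation — with Bonferroni correction across tested groups.

The qPCR calculator takes the median Ct of technical replicates per well,
forms ΔCt against the reference gene (ACT1 by default) within each
fraction, and reports condensation as −(ΔCt_pellet − ΔCt_total): +1 equals
2-fold pellet enrichment. Strain-normalized values are reported both as
log2 differences and linear folds.

# What the synthetic generator emulates — and what it does not

The screen generator draws log-normal baseline barcode abundances
(heavy-tailed, `abundance_logsd = 1`), negative-binomial counts
(variance = μ + φμ², `φ = 0.05`), ~12 guides/gene with 2 barcodes each,
4 biological replicates at 2×10⁵ reads/sample, and planted condensation
effects that multiply **pellet means only** by `2^(effect + jitter)` —
mirroring the interpretation that FRep scores capture fraction
partitioning, not expression. Per-gene, per-replicate jitter
(`replicate_sd = 0.1` log2 units) models biological partitioning noise.
The read generator emits anchored `flank5 + barcode + flank3` reads with
i.i.d. substitution errors. The transcriptome generator plants a
length-condensation slope (1 log2 unit per sd of log-length, giving a raw
score–length correlation around 0.8) and group-by-condition shifts at
42 °C (RPG-like +1, Hsf1-like −1, Msn2/4-like −0.5 log2 condensation;
opposite-signed ribosome-association shifts), with 100 transcripts per
group among 5000.

Not modelled, by design: PCR amplification bias and UMIs, indel sequencing
errors, guide-efficacy heterogeneity, expression-level effects of
knockdowns, batch structure between replicates, and condensate
substructure (the pellet is one compartment). Passing recovery tests on
this generator therefore demonstrates the statistical machinery —
normalization, neighborhood standardization, aggregation, calibration —
not robustness to these real-data complications.

Barcodes are rejection-sampled to pairwise Hamming distance ≥ 3 (two
barcodes are within distance 2 exactly when their one-substitution balls
intersect, so a hash of accepted balls gives an exact linear-time check);
this makes one-mismatch read assignment provably unambiguous. Reads are
assigned via a precomputed hash of all one-substitution neighborhoods;
ambiguous reads are dropped, never fractionally assigned, and N bases
count as mismatches.

All randomness derives from a single top-level seed through labelled
substreams (`substream_seed`), so regenerating any artifact is
byte-identical and adding a stage never perturbs the draws of another.

# Calibration behaviour and known limitations

* Under the null generator at the default depth, the mean barcode NNS sits
  slightly below zero (about −0.04, within the score's calibration band):
  the abundance filter truncates only the denominator's low tail, leaving
  the pseudocounted log-ratio mildly left-skewed, and the median centers
  the distribution while the mean stays below it. Consequently the
  gene-level t-test inherits a small shared negative noncentrality, and
  its p-value uniformity — while comfortably accepted at the package's
  default seed — is not guaranteed for every random seed at
  Kolmogorov–Smirnov α = 0.01 with 300 genes. Filtering on a symmetric
  abundance measure would remove the skew but would change the reference
  abundance definition; the current definition (normalized total counts)
  was kept.
* The assignment-rate bound for error-containing reads,
  P(≤1 flank error)·P(≤1 barcode error), is a probability statement; the
  empirical assigned fraction at 10⁵ reads fluctuates around it within
  binomial sampling error, and tests allow 4 standard errors of slack.
* Problem sizes used by the validation suite: 300-gene screens
  (7200 barcodes, 8 samples), 5000-transcript transcriptomes, 10⁵-read
  FASTQ round trips — sizes at which every stage completes in seconds on
  one CPU while keeping Monte-Carlo noise well inside the asserted bands.
* `compare_screens` labels use fixed thresholds, echoing the FRep > 2 hit
  convention; no attempt is made to model the joint null of two screens.
* The CLI is a thin wrapper; all behaviour is in exported functions, and
  the run log's timestamps are the only non-deterministic bytes a rerun
  produces.
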