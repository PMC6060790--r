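---
title: "Methods: copy-number calling and score interpretation for methylation arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number calling and score interpretation for methylation arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylDx)
```

# Scope and model

methylDx implements the computational interpretation layer of methylation
array based CNS tumor workup: copy-number variation (CNV) from probe
intensities, cohort-level CNV frequencies, calibrated classifier-score
semantics, batch quality control, and a three-state *MGMT* call. It does
*not* train or apply the random-forest classifier itself (scores enter as
data), does not decode binary IDAT files (an adapter boundary,
`read_idat_pair()`, accepts any external decoder), and does not model
wet-lab chemistry.

## Signal model

Each CpG probe reports a methylated (M) and unmethylated (U) intensity.
`beta = M/(M+U+offset)` is the methylation fraction; the default
`offset = 100` is the usual platform stabilizer for low-intensity probes
and can be set to 0 where exact ratios are wanted. The combined intensity
`M+U` is proportional to the local DNA amount, which is what CNV calling
uses: probe-level ratios are formed against a flat-genome reference panel
(aggregated per probe by median across at least three copy-number-neutral
samples; mean available). Probes whose reference signal falls below a floor
(default 50) are excluded — they cannot support a stable ratio.

The overall intensity scale of an array is arbitrary, so the sample is
scaled to the panel by genome-wide median matching of combined intensities
before the ratio (an optional decile-based quantile matching is available
behind the same interface). Median matching deliberately does *not* decide
the copy-number-neutral level; that is the baseline's job. Probe log2
ratios are clamped at ±4 by default, which bounds the unboundedly negative
ratios of homozygous deletions without touching any realistic amplification.

## Binning

Probes are aggregated into genomic bins (default target 8000, at least 15
probes per bin) by the median of member-probe log2 ratios. The bin budget
is allocated across chromosomes proportionally to probe counts with
largest-remainder rounding, capped so each chromosome can satisfy the probe
minimum; within a chromosome probes split into contiguous near-equal runs.
No bin crosses a chromosome boundary. The genome-wide count therefore
equals the target exactly whenever the probe supply allows, while the
boundaries adapt to probe density. Chromosome Y is excluded by default
(diagnostic CNV plots do not display it and the female reference carries no
Y signal); X is binned but marked as a sex chromosome.

## Baseline: the minimal-MAD neutral line

Methylation arrays carry no allele frequencies, so the copy-number-neutral
state cannot be anchored to heterozygous SNPs. Instead the baseline is the
shift `b` minimizing the median absolute deviation `median(|log2 - b|)`
over all bins — the line closest to the predominant copy-number state. This
is found by grid search over the value range at 0.001 log2 resolution.

Two numerical choices matter:

* **Median convention.** For even bin counts the *lower* middle order
  statistic is used rather than the average of the two middle values. The
  averaged form produces exactly flat plateaus of the objective wider than
  the grid step (any value inside the plateau is an equally valid
  minimizer), which makes the fitted baseline unstable under a constant
  shift of the data. The lower-order-statistic form is piecewise linear
  with a generically unique minimizer, so the fit is translation
  equivariant to the grid resolution.
* **Tie-break.** Remaining exact ties (possible with heavily quantized or
  strongly bimodal profiles — e.g. half the genome at one state) are broken
  toward the smallest `|b|`, the "most of the genome is neutral" reading.
  This is the honest failure mode of MAD-based baselines: when a tumor is
  predominantly aneuploid the neutral state is genuinely ambiguous, and the
  package prefers the reading closest to balance.

All event thresholds are applied relative to the fitted baseline, since the
baseline defines neutrality.

## Segmentation

Per chromosome, recursive binary splitting with a *circular* scan: the
candidate interior segment maximizing the two-sample t statistic (segment
vs rest of the chromosome) over all start/end pairs. The circular form is
essential — a short embedded change such as a focal amplification needs two
boundaries cut in a single test; a single-cut statistic dilutes it. A
candidate is accepted at `alpha` (default 0.01) through either of two
routes:

* **Robust z bound.** The mean shift standardized by a noise estimate that
  is insensitive to the shift itself — the median absolute consecutive bin
  difference scaled to a Gaussian sigma — is compared against the
  Bonferroni-corrected normal critical value over all candidate segments.
  This decides overwhelming changes immediately, and it is the only route
  able to isolate a 1–2-bin focal amplification on a short chromosome: a
  permutation of the sequence re-creates an adjacent extreme pair with
  probability about `2/n`, so for small `n` the permutation p-value can
  never reach `alpha` no matter how extreme the signal.
* **Permutation test.** Otherwise the maximum statistic is compared against
  its distribution over permuted sequences (default 200 permutations, with
  early stopping once significance is out of reach). This is the
  distribution-free route for moderate, broad changes.

Accepted splits recurse on the three resulting pieces. Minimum segment
width defaults to 1 bin so single-bin focal events are representable.
Segment means are unweighted means of member bins, baseline-relative.

## Event calling

Segments beyond ±0.15 log2 are reported: within a focal span (≤ 10 Mb) and
beyond ±0.4 they are amplifications / homozygous deletions, otherwise
gains / losses. The ±0.4 bound is the conventional log2 landmark for
high-level events on these arrays; ±0.15 captures arm-scale single-copy
changes diluted by typical tumor purity (a trisomy at 40% purity sits at
`log2(1.2) ≈ 0.26`). The 10 Mb focal cap separates focal from arm-level
biology; none of these numbers is sharp, and all are configurable. Events
overlapping any of the 29 bundled highlight genes carry the gene symbols.
The bundled gene list and its approximate hg19 coordinates are a
reconstruction of the conventionally highlighted CNS set, used for
annotation and synthetic construction only.

Tumor purity `p` dilutes an integer copy number `n` to an expected segment
mean of `log2((p·n + (1−p)·2)/2)`; the generator, the recovery tests and
the interpretation guidance all use this closed form.

## Cohort summaries

Across samples sharing bin boundaries, per-bin gain and loss frequencies
count baseline-relative bin values beyond ±0.15 (configurable) — by design
amplitude-blind, so amplification and single-copy gain contribute equally.
Bins missing in a sample drop out of that sample's denominator. The
summary-inclusion threshold for the original cohort plots is not published;
±0.15 was chosen once to match the arm-scale calling bound.

## Calibrated scores and the decision ladder

Calibrated scores are class-membership probabilities summing to 1 over all
schema classes (bundled v11b4 schema: 82 tumor + 9 control classes, 8
methylation class families of 2–6 members; the schema is an editable TSV so
future classifier versions load without code change). Because they are
probabilities, a family score is the exact sum of member scores (the
probability sum rule).

The ladder, applied to the best of top class score and top family score:
≥ 0.9 classifiable (family-level when only the sum clears it; the most
likely subclass is named when the best member ≥ 0.5); [0.84, 0.9)
borderline — 0.84 is the Youden-optimal cut-off on the reference cohort, so
such scores are valid classifications *if nothing else speaks against
them*, and the package surfaces that condition as its own category rather
than silently accepting; [0.5, 0.84) suggestive; < 0.5 no match. Scores
above 0.3 are listed in reports. Design choices taken where behaviour was
open:

* When class and family both clear 0.9, the class-level category is
  reported with the family attached as context (the more specific result
  wins; the family adds information rather than overriding).
* Score vectors violating normalization beyond 1e-6 are rejected, not
  renormalized — silent repair would change the meaning of calibration.
* Low tumor-cell content is an input flag, not an inference: borderline and
  suggestive reports then carry the annotation that a lower score may be
  accepted as an indication of a specific diagnosis. Control-tissue scores
  summing to ≥ 0.3 set a `control_elevated` flag, the typical signature of
  low tumor content.

## Batch quality control

* **Sex concordance.** Median combined intensity on X and Y relative to the
  autosomal median: two X copies and no Y reads female, one X plus Y reads
  male, anything else undetermined. Germline sex chromosomes are not
  diluted by purity, so the call is stable in low-purity samples. The
  numeric cutoffs (X ratio 0.75; Y ratio 0.2 present / 0.1 absent) are
  calibrated on the synthetic generator and exposed in configuration — no
  published numeric thresholds exist for this step.
* **Noise.** There is no community-standard numeric noise metric for these
  plots (they are conventionally judged by eye), so this package defines
  one: the median absolute difference of consecutive within-chromosome bin
  values. It ignores the profile level and true copy-number steps (steps
  occupy a sparse set of junctions), and for i.i.d. Gaussian bin noise
  equals `0.6745·sqrt(2)·sigma`. Grades: crisp < 0.1, unusable > 0.3
  (configurable); unusable forces a reanalysis recommendation.
* **Contamination.** For every sample with an amplification, all other
  samples in the run are scanned for amplifications or focal gains at the
  identical region (reciprocal overlap ≥ 0.5 — "identical" needs a
  tolerance once bins quantize boundaries). Only amplifications surface in
  the recipient: at 5% contamination a 50-fold amplification appears at
  `log2((0.95·2 + 0.05·100)/2) ≈ 1.8`, while a donor trisomy contributes
  `log2(2.05/2) ≈ 0.035`, far below any calling threshold. Flags are
  advisory; data usability remains a case-by-case decision.
* **Consistency.** Top classes are compared with per-sample expectations;
  a fully mismatched batch of ≥ 4 raises a plate-level warning (e.g. an
  array loaded in reverse order).

## MGMT

A two-probe logistic model on M-values (`log2(beta/(1−beta))`, beta clamped
to `[1e-6, 1−1e-6]`) with an indeterminate probability band: below
`cutoff_low` unmethylated, above `cutoff_high` methylated, in between not
determinable. The clinically validated coefficients belong to their
published source and are deliberately not bundled; the shipped model file
is synthetic (named so) and serves testing and format documentation.

# The synthetic generator: what it emulates and what it does not

Generators produce every input the pipelines need, deterministically under
a seed: manifests, flat-genome reference panels, tumors with known
copy-number truth / sex / purity, contamination mixtures, and score
vectors with controllable top class/family structure.

The intensity model is intentionally minimal: per-probe affinity (drawn
once with the manifest, log-normal, sd 0.3 on the log scale) times the
expected copy factor `(p·cn + (1−p)·germline)/2`, plus a 1% background
(keeping zero-copy loci finite), with multiplicative log-normal probe noise
(default sd 0.1 on the log2 scale). The channel split follows a fixed
per-probe methylation fraction drawn from a bimodal Beta mixture. This
captures exactly what ratio-based CNV calling consumes — relative combined
intensity and its noise — and none of what it does not: no probe type I/II
chemistry, no dye bias, no spatial artifacts, no FFPE degradation
structure, no subclonal heterogeneity. Passing recovery tests on these
synthetics therefore demonstrates the correctness of the computation
(binning, baseline, segmentation, thresholds, purity arithmetic), not
robustness to every real-world artifact; bisulfite-failure-like noise is
emulated only as globally inflated probe noise.

Problem sizes were chosen so full pipelines run in seconds: the test-scale
manifest holds ~30,000 probes over 24 chromosomes with hg19-proportional
spacing, profiled into 800 bins (the 8000-bin default scaled by the same
factor as the probe count); the full-scale manifest (~450,000 probes,
8000 bins) is used where the genome-scale configuration itself is under
test. Reference panels default to 5–8 members. The recovery harness uses
50 genomes with two spiked arm-scale events each across purities 0.7–1.0.

# Known limitations

* The minimal-MAD baseline is ambiguous for predominantly aneuploid
  genomes; the toward-zero tie-break is a convention, not an inference.
* Contamination detection is blind to donors without amplifications, and
  the contamination fraction is not estimated.
* Focal events shorter than a bin are attenuated by the bin median; at the
  default genome-scale bin size (~370 kb) this is rarely limiting, but at
  the test scale (~3.9 Mb bins) sub-bin events are deliberately not part of
  the test conditions.
* The segmentation p-values are per-chromosome; no genome-wide FDR control
  is applied across chromosomes (matching diagnostic practice, where the
  plot is read as a whole).
* Cohort frequencies use per-bin values, not segment calls; very noisy
  samples should be excluded upstream via the noise grade.
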