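# methylDx

Diagnostic computation layer for DNA methylation array workup of CNS tumors:
copy-number-variation (CNV) calling from array intensities, cohort CNV
frequency summaries, calibrated classifier-score interpretation, batch
quality control, and a three-state *MGMT* promoter methylation call. A
first-class synthetic-data generator makes every pipeline exercisable
without array data.

It is written for neuropathology/molecular-diagnostics analysts and for
developers of methylation-based classification workflows who need the
downstream interpretation machinery — not the classifier itself — as
testable, scriptable components.

## What it computes

**CNV from methylation arrays.** Every interrogated CpG carries a methylated
and an unmethylated signal. Their ratio gives the methylation beta value,
`beta = M / (M + U + offset)`; their **sum** `M + U` is proportional to local
DNA copy number. For one tumor sample against a flat-genome reference panel,
methylDx computes per-probe ratios

    log2( sample(M + U) / reference(M + U) )

after genome-wide median matching, aggregates them into (by default) 8000
genomic bins by median, fits the copy-number-neutral baseline as the shift
`b` minimizing the median absolute deviation `median(|log2 - b|)` over all
bins (methylation arrays carry no allele frequencies, so the neutral state
must be inferred this way), segments the profile by recursive binary
splitting with a circular max-t scan and a permutation test, and calls
events relative to baseline: segment mean ≥ +0.4 log2 over a focal span
(≤ 10 Mb) is an amplification, ≤ −0.4 a homozygous deletion, and ±0.15 at
arm/chromosome scale a gain/loss. Bundled annotations highlight 29
CNS-relevant genes (*EGFR*, *CDKN2A/B*, *MYC(N)*, …); profiles export as
IGV and SEG tracks plus a genome plot.

**Cohort summaries.** Across a cohort of profiles, the per-bin percentage of
samples gained or lost — amplitude-blind, so a single-copy gain and a
high-level amplification count identically — rendered as a mirrored
gains-up/losses-down plot.

**Calibrated score interpretation.** The classifier emits one calibrated
probability per methylation class (82 tumor + 9 control classes in the
bundled v11b4 schema; all 91 sum to 1). Closely related classes form eight
methylation class families; since calibrated scores are probabilities, a
family score is the plain sum of its members' scores. The decision ladder:
best class-or-family score ≥ 0.9 is classifiable (subclass named within a
family when the best member ≥ 0.5); [0.84, 0.9) is borderline (0.84 is the
Youden-optimal cut-off); [0.5, 0.84) is suggestive; below 0.5, no match.
Only scores above 0.3 are listed. Low-tumor-content samples carry an
annotation that lower scores may be acceptable, and elevated control-tissue
scores (≥ 0.3 summed) are flagged.

**Batch QC.** Sex prediction from X/Y vs autosomal intensity, checked
against the reported sex; a CNV noise score (median absolute consecutive
bin difference) graded crisp/elevated/unusable; a cross-contamination scan
that looks for a donor's amplifications resurfacing as focal gains at
identical loci in other samples of the run; and an expectation-consistency
check that spots case mix-ups and systematic plate errors.

**MGMT.** A pluggable two-probe logistic model on M-values with an
indeterminate probability band yields methylated / unmethylated /
not determinable. No clinical coefficients are bundled — the shipped model
file is synthetic; load validated parameters from their published source.

## Worked example

```r
library(methylDx)

## -- classifier scores: the worked glioblastoma case --------------------
schema <- read_class_schema()            # bundled v11b4 schema
v <- gbm_worked_example(schema)          # GBM, RTK I 0.6; MES 0.2; RTK II 0.07; ...
decide(v, schema)
#> sample: GBM_worked_example
#> category: classifiable_family
#> top class: GBM, RTK I (calibrated score 0.6000)
#> top family: Glioblastoma, IDH wt (family score 0.9300)
#> subclass: GBM, RTK I (class score 0.6000)
#> ...
```

No single member class reaches 0.9, but the family sum 0.93 does, so the
case is classifiable at family level; the best member (0.6 ≥ 0.5) names the
RTK I subclass.

```r
## -- CNV on synthetic data ----------------------------------------------
m     <- simulate_manifest("test", seed = 3)            # ~30k probes
panel <- build_reference(simulate_reference_panel(5, m, seed = 4), m)
bins  <- build_bins(m, target_bins = 800, min_probes = 15)

truth <- cn_truth(data.frame(chrom = c("7", "9"),
                             start = c(1, 19e6), end = c(159138663, 25e6),
                             cn = c(4, 0)),
                  sex = "female", purity = 0.8)
tumor <- simulate_tumor(m, truth, seed = 5, sample_id = "t1")
res <- cnv_pipeline(tumor, panel, m, bins = bins)
res$events[, c("chrom", "n_bins", "mean_log2", "kind", "gene")]
#>   chrom n_bins mean_log2                kind                   gene
#> 1     7     42  0.841                 gain EGFR,CDK6,MET,SMO,BRAF
#> 2     9      2 -2.228  homozygous_deletion               CDKN2A/B
```

The chromosome 7 segment mean matches the purity mixture
`log2((0.8*4 + 0.2*2)/2) = 0.848`, and the 6 Mb copy-0 region is called as
a focal homozygous deletion at the *CDKN2A/B*-like locus. `export_igv()`,
`export_seg()` and `plot_cnv_profile()` write the track files and the plot;
`cmd_cnv()`, `cmd_classify()`, `cmd_qc()`, `cmd_summarize()` and
`cmd_simulate()` (or `inst/cli/methyldx.R`) wire the same steps into batch
commands.

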