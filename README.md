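# xenomark

Discovery and validation of DNA-methylation biomarkers of chemotherapy
response from patient-derived xenograft (PDX) cohorts profiled with
MeDIP-seq.

## Who this is for

Cancer epigenomics groups that measure genome-wide methylation by
**enrichment sequencing** (MeDIP-seq) in matched tumor/PDX and normal
tissue, determine each model's drug response in vivo (relative tumor
volume of treated vs control animals, T/C), and want to triage
methylation marks whose level predicts response — then validate the
leading mark in an independent clinical cohort with locus-specific qMSP
and survival follow-up. All stages run equally on a bundled synthetic
data generator, so the whole pipeline is testable end to end without any
external data.

## The model in brief

Counts are summarized in fixed 250-bp genome windows. For sample *i* and
window *w* with CpG count *g(w)*, the expected MeDIP fragment count is

```
mu(i, w) = s_i * c_{i,w} * ( o_i + beta(i, w) * f_i(g(w)) )
```

* `s_i` — library size factor (counts-per-million convention),
* `c_{i,w}` — relative copy number, estimated from CpG-free fragment
  coverage in 1-Mb bins (CpG-free fragments cannot be enriched, so their
  coverage tracks copy number),
* `o_i` — background rate at zero methylation,
* `f_i(g)` — monotone CpG-density enrichment profile, calibrated per
  sample against a reference methylation compendium on windows with
  reference mean > 0.90 and variance < 0.05,
* `beta(i, w)` — absolute methylation in [0, 1], recovered by inverting
  the mean model and clamping.

Differential methylation is tested window-wise with **negative-binomial
GLM likelihood-ratio tests**: one shared beta (null) against one beta
per group (tumor vs normal DMRs), or against a clamped linear response
`beta = clamp(b0 + b1 * log T/C)` (response-associated rDMRs, slope
`b1` > 0 meaning methylation rises with resistance). P-values are
chi-square(1); multiplicity is controlled by Benjamini-Hochberg FDR.
Large hypomethylated blocks (LHBs) are maximal runs of 100-kb tiles with
mean methylation drop ≤ −0.20 spanning ≥ 1 Mb. Candidate biomarkers pass
a three-stage triage: promoter rDMR at p < 0.01 → promoter methylation
correlated with T/C (Spearman p < 0.05) → expression correlated with T/C
in the **opposite** direction. Validation statistics include
control-normalized qMSP levels, Mann-Whitney group comparison, a
maximum-accuracy threshold classifier, and Kaplan-Meier / log-rank
survival analysis.

## Worked example

```r
library(xenomark)
cfg <- read_pipeline_config(system.file("extdata", "demo_config.yaml",
                                        package = "xenomark"))
rep <- run_pipeline(cfg, "demo_out")
```

The demo world is a 4.2-Mb genome (16,800 windows), 22 PDX models with
paired normals, a planted 1.2-Mb LHB at −0.30 on chr1, focal promoter
hypermethylation, four response-coupled promoters with slope
0.05/log-unit, anti-correlated expression, and a 36-patient matched
validation cohort. Selected outputs (seed 17):

```
demo_out/dmr_filtered.tsv     779 DMRs at FDR < 1e-4 and |delta| > 0.20
                              (27 hyper, 752 hypo — hypomethylation-dominated)
demo_out/lhb.tsv              chr1:500000-1700000  mean_delta -0.229
                              (exactly the planted block, attenuated by clamping)
demo_out/enrichment.tsv       hyper DMRs: odds ratio 37.0 in promoters,
                              180.4 in CpG islands
demo_out/triage_stages.tsv    stage1 8 -> stage2 4 -> stage3 4
demo_out/candidates.tsv       G001-G004 (all four planted genes), e.g.
                              G002: rdmr_p 2.9e-4, meth_rho +0.77,
                              expr_rho -0.94, opposite_sign TRUE
demo_out/validation_summary.tsv
                              threshold 10.3% methylation,
                              sensitivity 0.72, specificity 0.72,
                              Mann-Whitney p 0.003,
                              log-rank OS chi-square 2.91 (p 0.088)
```

Reading the numbers: the caller recovers the planted hypomethylated
block at its exact boundaries; hypermethylated DMRs concentrate in
promoters/CGIs as planted; the triage cascade shrinks monotonically and
ends exactly on the planted biomarker genes, each with a positive
methylation-resistance correlation and a negative expression
correlation. In the validation cohort the maximum-accuracy threshold
separates relapse from relapse-free patients (group difference
Mann-Whitney p = 0.003); with only 36 patients the log-rank test is
directionally right but not significant at 0.05 — survival power at this
cohort size is established separately in the test suite (hazard ratio 3,
50 pairs: p < 0.05 in 100/100 replicates).

A command-line entry point wraps the same stages:

```sh
Rscript inst/cli/xenomark.R run-all --config demo_config.yaml --seed 17 --outdir out/
Rscript inst/cli/xenomark.R validate --outdir out/   # re-run one stage
```

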