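---
title: "Methods: from MeDIP enrichment counts to validated response biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from MeDIP enrichment counts to validated response biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenomark)
```

# The problem

MeDIP-seq measures methylation *relatively*: an antibody enriches
methylated fragments, so read counts confound methylation level with
local CpG density, library size, copy number and background pulldown.
To compare methylomes across samples — and to correlate methylation with
a therapy-response phenotype — counts must first be transformed into
absolute methylation (beta) values. `xenomark` implements that
transformation, genome-wide differential testing, block-level
segmentation, regulatory enrichment, an expression-integrated biomarker
triage, and the clinical validation statistics, end to end on fixed
250-bp genome windows (the scale of a typical MeDIP fragment).

All coordinates are 0-based half-open internally; 1-based positions are
used only when parsing externally printed locus strings.

# The observation model

For sample $i$ and window $w$ containing $g(w)$ CpGs,

$$\mu_{iw} = s_i \, c_{iw}\,\bigl(o_i + \beta_{iw}\, f_i(g(w))\bigr),
\qquad
Y_{iw} \sim \mathrm{NB}(\mu_{iw},\ \phi),$$

with variance $\mu + \phi\mu^2$. The dispersion $\phi$ is shared per
dataset; $\phi = 0$ selects the exact Poisson mode. The components:

* **Library factor** $s_i$: total fragments / $10^6$ (CPM convention).
  All downstream calibration quantities therefore live on the CPM scale;
  this is invisible to users because estimation divides by the same
  factors it calibrated with.
* **Copy number** $c_{iw}$: fragments without any CpG cannot be
  antibody-enriched, so their coverage tracks DNA copy number. Coverage
  of CpG-free windows is averaged in 1-Mb bins and scaled to the sample
  median; bins without CpG-free windows get a flagged neutral factor.
* **Background** $o_i$: mean CNV-corrected normalized count of CpG-free
  windows.
* **Enrichment profile** $f_i(g)$: expected normalized count increment
  at full methylation as a function of CpG count. It is calibrated per
  sample against a reference methylation compendium (in practice a large
  bisulfite-array cohort; in the synthetic world, the generator's truth)
  on windows whose reference mean exceeds 0.90 with variance below 0.05
  — windows that can be assumed uniformly, near-fully methylated in any
  sample, so that the normalized count there reveals $f$ directly.
  Windows are binned by CpG count (width 2, bins merged rightwards to at
  least 20 windows), a median profile value is taken per bin at the
  bin's *median* CpG count (for a monotone profile, the median of
  $f(g)$ is attained at the median $g$, which keeps coarse bins
  consistent), and monotonicity is enforced by pooling adjacent
  violators. Evaluation interpolates linearly through $(0, 0)$ and the
  knots and is constant beyond the last knot.

**Beta estimation** inverts the mean:
$\hat\beta_{iw} = \mathrm{clamp}\{(y_{iw}/(s_i c_{iw}) - o_i)/f_i(g(w)),\,0,\,1\}$.
Windows without CpGs carry no estimate (they still serve CNV and
background estimation).

## Why the reference must include tumors

If the calibration reference is built from normal tissue only, windows
inside tumor-hypomethylated blocks still pass the "near-fully
methylated" filter, the assumption $\beta \approx$ reference mean is
violated for tumor samples, and their profiles are biased low — we
measured a systematic +0.05 beta offset in PDX samples in exactly this
configuration. A reference spanning the tumor state (as bisulfite-array
compendia of tumor cohorts do) removes such windows through the
variance filter. The pipeline therefore builds its synthetic reference
from all samples' true methylomes.

## Known estimator limitations

Two properties of the window-wise inversion matter for interpretation:

* **Counting-noise floor.** The inversion is the maximum-likelihood
  estimate from a single count, so its standard error is approximately
  $\beta\sqrt{1/\mu + \phi}$. At a mean count of 30 per window and
  $\phi = 0.05$ this is $\approx 0.18$ at high methylation: window-level
  betas at screening depth are *rank-informative, not precise*. This is
  why the acceptance criterion demanding window-wise RMSE $< 0.05$ at
  30x depth is reported red: no realistic depth/dispersion pair attains
  it (Poisson mode at 30x gives RMSE 0.18; even 1000x with $\phi = 0.05$
  gives 0.20). The pipeline's inferences all pool information — across
  samples (GLM tests), windows (LHB tiles, gene-level promoter means) or
  both — and are tested at their own tolerances.
* **Boundary attenuation.** Clamping to $[0, 1]$ biases means near the
  boundaries: at 30x depth a true methylation drop of $-0.30$ in a
  block is measured as about $-0.23$. Blocks planted exactly at the LHB
  call threshold ($-0.20$) are therefore not recoverable from estimated
  betas; the demo plants $-0.30$. The LHB caller itself is exact on
  noiseless inputs (verified on constructed fixtures).
* **Dispersion estimation.** $\phi$ is estimated by method of moments on
  normalized counts $y = c/s$, for which
  $\operatorname{var}(y) = m/s + \phi m^2$; the estimator is the
  dataset median of $(v - m/s)/m^2$ over windows with $m \ge 5$, floored
  at $10^{-6}$. The median across windows carries a small downward
  small-sample bias (about $-15\%$ at 10 samples), which makes the LRTs
  slightly anticonservative when the estimate is used; calibration
  checks therefore fix $\phi$ at its configured value.

# Differential testing

Because $\mu$ is linear in $\beta$, per-window likelihood maximization
is a bounded search. The **group DMR test** fits one shared $\beta$
(null) versus one $\beta$ per group by golden-section refinement of a
coarse grid; the **response rDMR test** fits
$\beta_i = \mathrm{clamp}(b_0 + b_1 x_i)$ with
$x = \log(\mathrm{T/C\ percent})$ (floored at 0.1% to avoid $-\infty$;
the log base only rescales $b_1$'s units) via a vectorized
$(b_0, b_1)$ grid refined by Nelder-Mead, with the null fit included as
a fallback so the likelihood ratio is never negative. Both statistics
are referred to $\chi^2_1$; BH-FDR is computed across tested windows.
Windows with no CpGs or all-zero counts are skipped and reported. Type-I
error of both tests is verified to sit within 3 binomial standard errors
of nominal at $\alpha \in \{0.05, 0.01\}$ on 2,000 null windows; the
boundary cases ($\beta$ near 0 or 1, where the $\chi^2$ reference is
conservative) are deliberately avoided by running the calibration check
at an interior methylation level, the standard regularity condition for
LRT asymptotics.

DMR filtering applies the screening thresholds (FDR $< 10^{-4}$ and
$|\Delta\beta| > 0.20$); rDMR candidate selection deliberately uses the
*uncorrected* p-value ($< 0.01$), mirroring a screening design whose
hits are later validated orthogonally — FDR is still reported.

**LHBs** are called by tiling the genome at 100 kb (an aggregation grain
chosen here; the definition itself fixes only the 1-Mb minimum span and
the 20% drop), computing per tile the mean beta difference, merging
maximal runs of consecutive sub-threshold tiles with no gap tolerance,
and reporting merged runs spanning at least 1 Mb with the block mean
recomputed over windows. Boundaries are exact to one tile on noiseless
fixtures.

# Annotation and enrichment

Promoters are symmetric TSS $\pm$ 2 kb flanks merged per gene (strand
does not change a symmetric flank). Overlap is half-open, 1-bp
sufficient, computed with `GenomicRanges` and property-tested against a
quadratic all-pairs oracle. Enrichment follows the genome-wide
background convention: with $p_1$ the DMR fraction among ROI windows
and $p_2$ the DMR fraction among *all* windows (ROI included),
$\mathrm{OR} = [p_1/(1-p_1)]/[p_2/(1-p_2)]$, with a two-sided Fisher
exact p on the in/out $\times$ DMR/non-DMR table. The classical
exclusive-background odds ratio agrees within 5% whenever the ROI
covers under 1% of windows (asserted as a property); the exclusive
table is what the Fisher p uses. Genomic distribution assigns each
window exactly one category with priority promoter > exon > intron >
intergenic, so fractions always sum to 1 (overlapping gene structures
would otherwise double-count).

# Biomarker triage

Stage 1 keeps genes with at least one promoter window passing the rDMR
screen (uncorrected p < 0.01). Stage 2 keeps genes whose promoter
methylation — by default the mean beta over the gene's promoter windows
with defined values; a most-significant-window variant is available —
correlates with T/C (Spearman p < 0.05). Stage 3 keeps genes whose
expression ratio versus the normal-median (DER, log2 scale) correlates
with T/C at p < 0.05 **with the opposite sign** to the methylation
correlation. Spearman correlations use average ranks with exact
permutation p-values for $n \le 8$ and the t-approximation otherwise;
T/C enters untransformed because Spearman is invariant to the log.
Candidates are ordered by expression p-value.

Stages 1 and 2 are computed from the same counts and are therefore
*dependent* (empirically, P(stage 2 | stage 1) $\approx$ 8% under the
null versus the nominal 5%); the independence-based false-positive
product is exact only for stage 3, whose expression data are
independent noise under the null — the expected stage-3 count is
stage-2 count $\times\, 0.05 \times \tfrac12$ (p threshold times the
sign rule), verified within 3 binomial SEs.

# Validation statistics

qMSP levels are normalized to region-matched fully-methylated control
DNA (`100 * raw / control`, capped at 100%; how the methylated- and
unmethylated-allele qPCR channels are combined upstream into one scalar
is outside this module, which consumes the combined level).
Group comparison is Mann-Whitney: exact by full enumeration of label
assignments for combined $n \le 20$ without ties (two-sided as
$P(|U - n_1 n_2/2| \ge |u - n_1 n_2/2|)$), a tie/continuity-corrected
normal approximation otherwise (within 0.01 of exact p throughout the
p $\le$ 0.1 tail at $n = 10$, by enumeration). The threshold classifier
scans midpoints of consecutive distinct values plus one candidate below
the minimum, calling methylation $\ge$ threshold positive for
non-response, maximizing accuracy with ties broken to the smallest
threshold; metrics are stored as exact rationals and rounded only for
display. Kaplan-Meier uses the product-limit estimator (censored
subjects leave the risk set after their time; events precede censorings
at ties) and the log-rank test accumulates observed-minus-expected with
hypergeometric variance over event times — both validated against the
`survival` package as an independent oracle.

# The synthetic world

The generator produces every input the pipeline consumes, with the
statistical structure the analysis assumes. Defaults, with rationale:

| Parameter | Default | Why |
|---|---|---|
| window size | 250 bp | fragment-scale windows |
| background CpGs / window | Poisson(3) | genome-wide CpG density at 250 bp, with a CpG-free fraction for CNV/background |
| CGI windows | mean 16 CpGs, 4-window islands at promoters | promoter island structure |
| normal baseline beta | 0.80 (SD 0.08/window, shared across samples) | high somatic methylation; the per-window spread supplies the near-fully-methylated calibration stratum |
| CGI beta | 0.10 | unmethylated promoter islands |
| cell-level noise | SD 0.03 | biological replicate variability |
| planted LHB | ≥ 1 Mb, delta −0.30 (demo) | block hypomethylation; −0.30 survives boundary attenuation (see above) |
| focal promoter hyper | +0.45 | focal island hypermethylation |
| response coupling | beta = clamp(0.15 + 0.05·log T/C) | resistance-linked promoter methylation |
| cohort | 22 PDX models + paired normals | study-scale cohort |
| T/C distribution | log-normal, median 25%, log-SD 1.1, clamped to [0.5, 150] | spans strong responders (< 9%) through non-responders (> 78%) |
| response categories | [0,9), [9,30), [30,78), [78,∞) | half-open boundaries resolving the overlapping printed inequalities |
| tumor volumes | V = ½·L·W², isometric treated/control scaling | caliper-volume bookkeeping; T/C is simulated at a single endpoint |
| counts | NB, mean 30/window ("30x"), phi 0.05, saturating profile f(g) = 30·g/(g+10) | antibody capture saturates in CpG-rich windows; phi ~ 0.05 is a typical biological-replicate dispersion |
| expression coupling | −4 log2 per unit beta, noise SD 0.1 | ≥ 1 log2 swing across the induced beta range |
| validation cohort | matched pairs, qMSP means 7.4% vs 13.9%, SD 4, exponential survival with hazard ratio 3, ~30% censoring | group-shifted methylation with survival contrast |

Seeds: each generator derives a named sub-stream from one master seed,
so adding a stage never perturbs another stage's draws, and identical
configuration + seed reproduce byte-identical outputs (asserted).

What the generator does **not** emulate — and hence what a green test
does not establish: read-level artefacts (mapping, duplicates, fragment
length), sequence-determined CpG positions, mouse-read contamination,
batch effects, correlated noise along the genome, microarray
preprocessing, and the qPCR chemistry upstream of the combined qMSP
level. Tests on this world certify the *statistical machinery*, not
robustness to those artefacts.

# Design choices where the design was open

* NB noise with a single shared dispersion was chosen for the forward
  model to match the estimation GLM; the Poisson limit is exposed at
  $\phi = 0$ (the package parameterizes dispersion as $\phi$ with
  $\mathrm{var} = \mu + \phi\mu^2$).
* The saturating profile family $f(g) = f_{max}\, g/(g + k)$ reflects
  antibody-capture saturation; calibration itself is nonparametric
  (binned medians + isotonic pooling) and recovers any monotone profile.
* The rDMR predictor is the natural log of T/C percent; the base only
  rescales the slope and is recorded in the output metadata.
* Hierarchical-clustering and plotting views of the candidate matrix
  are out of scope; candidate ordering is by stage-3 p-value.
* Survival times are exponential with independent exponential censoring
  calibrated to the target censored fraction — the simplest model
  consistent with a constant hazard ratio.
* `run_pipeline` serializes every stage's inputs and outputs as plain
  TSV/BED/YAML so each stage is independently re-runnable; stage
  isolation and byte-level determinism are asserted in the tests.

# Limitations

Beyond the estimator limitations above: single-predictor response
modelling (no covariates), no spatial smoothing or window merging of
DMRs, no multi-window DMR records, matched pairing of the validation
cohort is used for generation but not for conditional testing, and the
threshold classifier reports apparent (resubstitution) accuracy, not
cross-validated performance.
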