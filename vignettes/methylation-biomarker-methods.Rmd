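---
title: "Methods: differential methylation and promoter mBV biomarkers along adenoma progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation and promoter mBV biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adenometh)
```

## Scope and model

`adenometh` analyses Illumina 450K-style DNA methylation cohorts spanning the
colorectal progression sequence normal mucosa → low-grade adenoma (LGA) →
high-grade adenoma (HGA) → carcinoma. The pipeline has five analytic layers:

1. **Beta values.** The methylation fraction at a CpG is computed from the
   methylated (M) and unmethylated (U) channel intensities as
   `β = max(M, 0) / (max(M, 0) + max(U, 0) + 100)`. Negative intensities
   (possible after background subtraction) are clamped; the +100 offset
   stabilises low-intensity probes and keeps β strictly below 1. β is
   monotone nondecreasing in M and nonincreasing in U.
2. **Probe QC.** Probes are removed when they lie on a sex chromosome, fail
   detection p-value testing (p > 0.01) in at least one sample, or overlap a
   SNP. Removal is attributed to the first rule that fires, in that order,
   so the filter report always reconciles with the input count. A second
   `fraction` mode removes a probe only when the failing fraction exceeds a
   configurable bound and leaves the rest to nearest-neighbour imputation —
   the two modes reflect the two processing conventions in common use
   (removal for in-house arrays, imputation for heterogeneous public sets);
   removal is the default. Failed entries are imputed per sample from the
   nearest non-failed probes flanking them on the same chromosome (mean of
   both flanks, single flank at chromosome ends). We interpret "nearest
   neighbour" genomically and within-sample because it preserves per-sample
   structure; an across-sample alternative would borrow strength from other
   arrays and blur sample-level signal.
3. **Differential methylation.** Sites: two-sided Wilcoxon rank-sum test per
   probe, Benjamini–Hochberg FDR across all tested probes, and the DMS rule
   `q < 0.05` and `|Δβ| > 0.20`, with Δβ the difference of group mean betas
   (contrast minus reference; means rather than medians, for comparability
   with the |Δβ| thresholds). Regions: probes are aggregated into
   (gene × region-category) or whole-promoter units — the promoter being
   TSS200, TSS1500, 5'UTR and first exon — by unweighted means, then tested
   with the same machinery under the region rule `|Δβ| > 0.15`. Region
   p-values are computed on the region means (pooling member sites instead
   is possible but conflates region size with evidence). Sites and regions
   are adjusted separately, within contrast. The rank-sum test uses the
   exact U null distribution when the pooled size is at most 12 with no
   ties, otherwise a midrank normal approximation with tie-corrected
   variance and continuity correction; when every value is tied p = 1.
4. **mBV biomarkers.** A site set (e.g. the hyper-DMS set, or a gene's
   promoter-island probes) is scored per sample by its mean beta value
   (mBV). Cutoff optimisation scans midpoints of adjacent sorted unique
   scores plus one candidate below the minimum and one above the maximum —
   a grid that provably attains the optimum over all real thresholds — and
   breaks ties toward the smallest threshold (favouring sensitivity for
   hyper markers; one rule, applied consistently). ROC curves are computed
   over all thresholds with diagonal movement through tied scores, so the
   trapezoidal AUC equals the pairwise concordance probability with ties
   counted one half; AUC is invariant under strictly monotone score
   transforms. Competing site-set models are compared by a stratified
   paired bootstrap: sample ids are resampled with replacement within each
   class, both AUCs are recomputed per replicate, and the two-sided p-value
   is `2 × min(frac ≤ 0, frac ≥ 0)` of the AUC differences with +1
   smoothing in numerator and denominator, capped at 1. The resampling is
   paired because both models score the same samples.
5. **Classifier harness.** Random forest (5000 trees) and a single-hidden-
   layer neural network (2 units, weight decay 1e-4, at most 400
   iterations) are consumed through a minimal fit/predict contract; the
   package contains no learning algorithm of its own. The default
   evaluation is stratified 5-fold cross-validation with out-of-fold
   predictions pooled into one confusion matrix (disease = positive class);
   out-of-bag and resubstitution schemes are selectable because the
   evaluation scheme behind published confusion tables of this kind is
   rarely stated — the ambiguity is surfaced as an explicit option rather
   than hidden. Sensitivity and specificity flow through one shared
   definition (`sens_spec_at()`), reported to 3 decimals; error rates to 2
   decimals in percent.

## The synthetic cohort generator

Every downstream stage is testable without array downloads because the
generator produces cohorts with known ground truth.

**Manifest.** Gene models are laid down in 8-probe blocks (TSS1500/shore,
TSS200, 5'UTR and 1stExon in the CpG island, three Body probes, one 3'UTR),
so every gene exercises all four promoter categories; requested fractions of
sex-chromosome and SNP-flagged probes are added (SNP flags avoid promoter
probes so the promoter machinery stays exercised after QC), and intergenic
probes fill the remainder. Positions are 1-based and strictly increasing
per chromosome.

**Baselines.** Each probe draws a baseline level from a two-component beta
mixture (defaults: modes 0.1 and 0.85, weight 0.5, concentration 30). The
mixing weight acts on the log-odds scale with an island-relation shift
(island +2, shore +0.5, shelf −0.5, open sea −1), reflecting that island
probes are predominantly unmethylated and open-sea probes methylated;
degenerate weights 0 and 1 remain degenerate. Concentration 30 keeps the
two humps sharp and well separated, as in whole-array beta densities.
Per-sample values are a mean-preserving beta perturbation of the baseline
(precision 100) plus a per-sample Gaussian offset (sd 0.05) emulating
array- and tissue-level variation. The offset matters: without correlated
per-sample variation, averaging over a site set annihilates independent
probe noise and every nonzero effect produces a perfect AUC, making model
comparisons degenerate and unlike real cohorts.

**Effects.** Disease stages shift affected probes additively on the beta
scale with clamping to [0, 1] — matching how |Δβ| thresholds are defined;
logit-scale (M-value) effects were rejected because they would decouple the
injected truth from the beta-scale gates. Monotone specs require the shift
magnitudes to be maintained or amplified along LGA → HGA → cancer, the
progression pattern of early methylation changes. Hyper effects are drawn
from low-baseline probes and hypo effects from high-baseline probes
(autosomal, non-SNP, so truth survives QC), mirroring island-promoter gain
and open-sea loss. Marker genes receive a coordinated hyper effect on all
their promoter-island probes. Each diseased sample attenuates all its
effects by a purity factor drawn uniformly from `purity_range` (default
0.7–1), emulating tumour-cell fraction; `c(1, 1)` disables attenuation and
makes shifts exact, which the unit tests exploit. Detection failures are a
two-point mechanism (pass: p ~ tiny; fail: p uniform on (0.01, 1]), since
detection p is used only as a filter.

**Default study design.** 20 normal, 18 LGA, 22 HGA, with an optional
carcinoma arm — the adenoma-progression design the default parameters are
scaled to. The demo pipeline adds a 20-sample cancer arm and uses strong
hyper effects (δ = 0.30/0.35/0.40 along LGA/HGA/cancer) against weak hypo
effects (δ = −0.08/−0.09/−0.10), a construction in which the hyper site-set
model must win the comparison if the machinery is sound. Because the weak
hypo effects sit below the 0.20 DMS gate by construction, the pipeline's
hyper-vs-hypo comparison falls back from DMS-derived sets to the simulation
truth sets whenever one direction is absent; on user data without truth the
DMS-derived sets are used.

**What the generator does not emulate.** Probe-type (Infinium I/II)
chemistry differences, batch structure beyond the per-sample offset,
spatial/block hypomethylation domains, and cell-type composition. Passing
tests therefore demonstrate correctness of the statistical machinery under
a clean additive-shift model, not robustness to the full technical
heterogeneity of public repositories; the published external-cohort
performance figures (e.g. AUC 0.97 on 833 samples) are not reproduction
targets at simulation scale.

## Numerical choices and degenerate inputs

- All generators and resampling procedures are pure functions of their
  arguments and a seed; the pipeline derives stage seeds from one master
  seed, and reruns are bit-identical.
- `compute_beta` rejects non-finite input; all-tied rank-sum data yield
  p = 1; a single unique score makes cutoff optimisation return a flagged
  degenerate result; samples with every member beta missing are dropped
  from mBV with a warning; a chromosome×sample slice that is entirely
  failed stays missing after imputation, with a warning.
- Unannotated probes are retained (filters act on positive evidence) and
  listed in the filter report.
- Test problem sizes: the null-calibration suite uses 20 seeds × 5000
  probes × 38 samples; recovery uses 100 injected sites in an 80-sample
  four-arm cohort; the demo pipeline uses 3000 probes. These sizes keep the
  whole suite under a minute while leaving the stochastic assertions
  comfortable margins.

## Known limitations

- The DMR unit is the gene-region mean; sliding-window or bump-hunting
  region detection is out of scope.
- No covariate adjustment, cell-type deconvolution, or probe-type bias
  correction (BMIQ/SWAN); the pipeline accepts normalised betas or raw
  M/U intensities and leaves vendor normalisation upstream.
- The bootstrap comparison is a resampling heuristic, not a DeLong-style
  analytic test; its p-value granularity is bounded below by
  `2 / (B + 1)`.

## A worked run

```{r demo, eval = FALSE}
cfg <- pipeline_config(
  cohort = list(n_probes = 3000, n_genes = 80,
                n_normal = 20, n_lga = 18, n_hga = 22, n_cancer = 20),
  effects = list(n_hyper_sites = 100, n_hypo_sites = 200),
  learner = list(params = list(ntree = 500)),
  bootstrap = list(n_replicates = 1000),
  seed = 1
)
report <- run_pipeline(cfg)
print(report)
```

The report carries the QC reconciliation, DMS/DMR tallies with direction
fractions, the marker promoter's cutoff/error-rate/AUC, the bootstrap
comparison, the classifier confusions, and the seed registry needed to
reproduce it.
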