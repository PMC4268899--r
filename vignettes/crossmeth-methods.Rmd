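---
title: "Methods: PCA-guided differential methylation in a crossover exposure study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PCA-guided differential methylation in a crossover exposure study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmeth)
```

## The analysis problem

crossmeth analyses genome-scale DNA methylation array data from a two-arm
crossover exposure study: each subject is exposed once to a control
condition (filtered air, FA) and once to the active exposure (diesel
exhaust, DE), with blood drawn immediately before exposure (0 h) and at
two post-exposure times (6 h and 30 h). With 16 subjects this yields 96
arrays. The scientific question is which CpG sites change methylation in
response to the exposure but not the control, after removing technical
artefacts and the dominant biological confounder in mixed blood cell
populations — cell composition.

The pipeline has a fixed stage order:

1. **Probe QC** — remove probes with detection p-value > 0.01 or missing
   values in any sample, then probes on the sex chromosomes, then
   cross-hybridizing or polymorphic probes. The order matters because the
   per-stage counts are conditional.
2. **Normalization** — quantile normalization across samples, then
   peak-based correction of the type II probe chemistry (below).
3. **PCA screen** — probe-wise mean-centred SVD of the M-value matrix;
   every component is tested against every declared covariate.
4. **Cell-composition filter** — probes loading strongly on
   count-associated components, confirmed per probe by regression on
   lymphocyte and monocyte counts, are flagged.
5. **Scenario association** — three dichotomous codings of when an
   exposure effect would be visible (6 h only; 30 h only; 6 h and 30 h,
   all against the pooled baseline of all FA samples plus DE 0 h) are
   tested against component scores; a significant, confound-free
   component defines the candidate CpG set via its loadings.
6. **Mixed-effects DMP calling** — per probe,
   `M ~ exposure * time + (1 | subject)` by REML; a probe is a
   differentially methylated position (DMP) when its exposure-arm time
   contrast is significant at FDR 0.10, its control-arm time effect is
   not, and it is not cell-associated.
7. **Region analyses** — the same model restricted to probes overlapping
   Alu or LINE1 repeat intervals by at least 15 bp (of a 50 bp probe
   footprint) or microRNA loci by at least 1 bp, each with its own
   q-value family.

## Scales and transforms

Betas (fraction methylated, `[0,1]`) are used for effect sizes and
display; M values (`log2(beta/(1-beta))`) for all modelling. Betas are
clipped to `[1e-6, 1 - 1e-6]` before the logit so M stays finite; on the
clipped domain the transform is an exact monotone bijection.

Peak-based correction addresses the two Infinium chemistries' different
dynamic ranges: type II probes show unmethylated/methylated density peaks
compressed towards M = 0. Both peaks are located per probe type by kernel
density (Silverman's bandwidth) as the density maxima below and above
zero; the type II values are rescaled by the linear map sending its peaks
onto the type I peaks. If either type does not show two peaks (at least
10% of the maximum density each) the matrix passes through with a
warning — the correction is only meaningful for the canonical bimodal
methylation profile.

## The mixed model and its contrasts

Time is dichotomized pre (the 0 h draw) versus post (6 h and 30 h
pooled). The single joint model per probe is

$$Y = \beta_0 + u_{\text{subject}} + \beta_1\,\text{Exposure}
      + \beta_2\,\text{Time} + \beta_3\,\text{Exposure}\times\text{Time}
      + \varepsilon,$$

fitted by REML (`nlme::lme`). The control-arm time effect is
$\beta_2$; the exposure-arm time effect is the contrast
$\beta_2+\beta_3$. Both are tested per probe with Wald z statistics.
Fitting one joint model (rather than two per-arm fits) uses all 96
observations for variance estimation; for this balanced design the fixed
effects equal their OLS values, which the tests exploit as an oracle.
Probes whose fit fails are flagged non-converged and excluded from the
q-value families rather than assigned p = 1.

The two p-value families (`p_DE` over tested probes, `p_FA` over tested
probes) are FDR-adjusted separately with Storey q-values. A DMP requires
`q_DE <= 0.10` and `q_FA > 0.10` — the change must be attributable to the
active exposure specifically. Effect sizes are reported as
$\Delta\beta$: the mean over subjects of (mean post beta − pre beta),
per arm, on the interpretable percent-methylation scale.

## Multiple testing: Storey q-values

`storey_qvalue` implements the smoothed-estimator recipe:
$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(n(1-\lambda))$ on the grid
$\lambda = 0.05, 0.10, \ldots, 0.90$, smoothed with a df = 3 natural
cubic spline and read off at the largest $\lambda$, clipped to
$(0, 1]$. With $\pi_0 = 1$ the q-values equal Benjamini–Hochberg
adjusted p-values exactly (a frozen test). Families smaller than 20
force $\pi_0 = 1$ with a warning because the spline is unstable there.

## The covariate association screen in a nested design

Every retained component's scores are tested against every declared
covariate: one-way ANOVA for nominal variables, Spearman correlation for
continuous variables, Wilcoxon rank-sum for dichotomous variables
(exact when the combined sample is at most 20 and tie-free, otherwise a
tie- and continuity-corrected normal approximation). Storey q-values are
computed over the whole (component × variable) table as one family, and
the scenario codings are screened in this same family.

Two statistical choices deserve emphasis because they differ from a
naive per-sample screen:

**Subject-level testing.** Each subject contributes six samples. A
covariate that is constant within subject — age, BMI, sex, ethnicity,
genotype, chip — carries only 16 independent observations, so testing it
against 96 per-sample scores would count each subject six times and
inflate significance roughly sixfold. Such covariates are tested against
subject-mean scores. The same applies to continuous covariates whose
variance is predominantly between subjects: blood counts vary a little
from visit to visit but mostly between people, so when the subject
explains more than half of a continuous covariate's variance it is
aggregated likewise. Without this, pure-noise components with incidental
subject structure acquire absurdly small count-association p-values,
which both pollutes the q-value family and triggers false confound
vetoes.

**Confound attribution by dominance.** A scenario-associated component
is rejected as confounded only when some confound variable is associated
with it at least as decisively (confound q ≤ scenario q). The stricter
rule — any significant confound association disqualifies — is available
(`confound_rule = "strict"`) but fragile: a component dominated by
within-subject exposure signal has vanishing subject-mean scores, so
even a 1% subject-level admixture yields a formally significant, yet
negligible, covariate correlation. Significance without magnitude is not
evidence that a component *is* a confound pattern; requiring dominance
asks which explanation carries the component.

## The synthetic-data generator

The generator (`generate_dataset`) emulates the statistical structure the
pipeline assumes, so the whole analysis is testable without array data:

- **Design**: 16 subjects × {FA, DE} × {0, 6, 30 h}; exposure order
  counterbalanced (8 subjects DE-first). Demographics are drawn to match
  the emulated cohort (age 28.7 ± 6.7 y, BMI 24.8 ± 3.9, 7 of 16 male,
  a 12/2/1/1 ethnicity split, 5 of 16 subjects carrying the minor
  genotype allele at the stratification locus).
- **Baseline betas**: a two-component Beta mixture with modes near 0.1
  and 0.85 — the canonical bimodal array profile — so peak-based
  correction operates on realistic densities.
- **Exposure effects**: `n_effect_probes` per scenario shift their mean
  beta by `effect_size_beta` (default 0.05 on 50 scenario-3 probes) in
  exactly the scenario-defining samples, directed away from the nearer
  beta boundary.
- **Cell composition**: subject-level lymphocyte and monocyte counts are
  moment-matched lognormals (1.9 ± 0.5 and 0.43 ± 0.13 K/µL) with
  correlation 0.5 (the two lineages share hematopoietic and inflammatory
  drivers) plus ~10% per-visit variation. 200 probes respond linearly
  with slopes 0.06 and 0.25 beta per K/µL — the magnitudes implied by a
  two-cell mixture at strongly cell-type-specific CpGs (a between-type
  methylation difference near 0.8 times the derivative of the cell
  fraction with respect to each count). Their baselines are intermediate
  (Beta(8, 8)) because a composition-sensitive probe is by construction a
  mixture of differing cell-type extremes, and the slope sign alternates
  per probe (lymphoid-high vs myeloid-high CpGs), which keeps the panel
  mean-balanced across probes.
- **Demographic covariates**: 100 probes linear in age (0.002 beta/year)
  or BMI (0.003 beta/unit), so the screen has true demographic
  components to find, as the emulated study reports.
- **Noise model**: probe-specific subject random intercepts
  (`subject_sd_m = 0.05`) and iid Gaussian noise (`noise_sd_m = 0.15`) on
  the M scale, added to the logit of the mean beta and mapped back, so
  betas stay inside (0, 1). Type II probes are then compressed towards
  M = 0 by `typeII_compression = 0.8`.
- **Artefacts**: 1% of probes receive a failing detection p-value, 0.5% a
  missing beta, 2% sit on chrX/chrY, 3% carry blacklist flags.
- **Regions**: Alu (40 × 300 bp) and LINE1 (30 × 1000 bp) interval tracks
  with 150 probes placed fully inside each class, probes planted at
  exactly 14/15/16 bp overlap for boundary testing, four microRNA loci
  with 7 overlapping probes, and a planted −0.039 beta exposure effect on
  the first microRNA probe.

The noise defaults were set by an operating-regime argument, not fitted
to data: loading-based selection can only work when the planted signal's
eigenvalue clears the random-matrix bulk of the noise
(\(\sigma^2(\sqrt{P}+\sqrt{S})^2\)) and the eigenvalue band of the iid
subject intercepts. At 5000 probes the defaults place the exposure
(~600) and cell (~1300) eigenvalues well above the bulk (~200), which is
the premise of the published analysis at 363k probes. Conversely the iid
subject intercept is kept small because, unlike in a generator, real
between-subject variance is largely *structured* (composition,
demographics) — and those structured parts are modelled explicitly.

What the generator does **not** emulate: spatial correlation along the
genome (neighbouring CpGs are independent here), probe-specific variance
heterogeneity beyond the beta-to-M geometry, batch/chip effects on the
measurements (chip and position labels exist but carry no signal),
per-probe cell-type reference profiles (composition acts through two
shared slope patterns), raw two-channel intensities (the colour-bias
correction is exercised on constructed intensities in tests), and
genotype effects on methylation (genotype is a label; the stratified
test is validated on constructed data). Passing tests therefore show the
machinery is correct and calibrated under the stated noise model, not
that the pipeline's biological conclusions transfer to any real dataset.

## Numerical and procedural choices

- Filtering order detection/missing → X/Y → blacklist is fixed; stage
  counts are conditional and sum to input − output.
- Quantile normalization averages tied ranks' target values; it is
  idempotent and exactly matches the sort-and-average definition.
- PCA: probe-wise centring (which removes the global-intensity offset
  dimension by construction), SVD, at most `samples − 1` components;
  each component is oriented so its largest-magnitude loading is
  positive, making reports reproducible despite SVD sign ambiguity.
- Loading selection uses mean ± k·SD of the component's loading
  distribution (k = 3 by default); it is invariant to component sign.
- The cell-count regression tests both count coefficients jointly with
  an F-test — one p-value per probe, matching a single significance
  count; zero-variance probes are excluded as NA.
- Welch's t-test (unequal variances) is the default two-sample test for
  score separation, carryover and genotype baselines; the carryover test
  compares per-subject mean FA methylation between exposure-order groups
  within each DMP direction class.
- Exact Wilcoxon p-values come from the exact Mann–Whitney null
  distribution for tie-free combined samples of at most 20; beyond that
  the tie-corrected, continuity-corrected normal approximation is used
  (accuracy ≈ the reference implementation: mean |error| < 0.005 at
  n = 10 per group).
- All randomness flows from the single generator seed; the analysis
  stages themselves are deterministic, so re-running a pipeline on the
  same dataset reproduces identical outputs.

## Problem sizes in the test suite

The package's own validation runs at the emulated study scale: 5000
probes × 96 samples for end-to-end properties (20 replicate seeds for
the recovery and null-calibration properties), 2000 probes for the
per-probe p-value uniformity checks, and toy matrices for exact oracle
comparisons. These sizes keep the full suite in the low minutes on a
single CPU while leaving the planted-signal eigenvalues in the regime
discussed above.

## Known limitations

- With 16 subjects, subject-level covariate tests have modest power;
  genuinely weak cell-count components can fall short of q ≤ 0.1 in the
  full screen family, in which case the cell-filter stage passes through
  an empty candidate set (the per-probe DMP criteria still apply).
- The dominance rule for confound attribution is a heuristic; a
  component that mixes exposure signal with a *strong* confound is
  excluded, but subtler admixtures survive and must be caught by the
  per-probe cell filter.
- Peak-based correction assumes bimodality per probe type; heavily
  skewed subsets (e.g. a region-restricted matrix) may pass through
  uncorrected.
- Per-probe REML fits are exact but not fast; epigenome-wide fitting at
  450k-probe scale (`epigenome_wide = TRUE`) is a sensitivity analysis,
  not the default path.
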