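---
title: "Identifying blood methylation marks that mediate genetic disease risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying blood methylation marks that mediate genetic disease risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A case–control EWAS of blood methylation finds CpGs whose methylation
differs by disease status, but cannot say whether a mark *causes* risk or
*reacts* to disease. Three directed relationships among a genotype `G`, a
methylation mark `M` and an outcome `Y` produce such an association:

* **mediated** — `G → M → Y`: the genetic effect on disease flows through
  methylation;
* **consequential** — `Y → M`: methylation changes as a consequence of
  disease (reverse causality), while any G–Y association is direct;
* **independent** — `M ← G → Y`: the genotype acts on methylation and on
  disease separately.

Because germline genotype is fixed at conception, it can serve as an
anchor: only in the mediated topology does conditioning on `M` remove the
G–Y association. `citewas` operationalises this with the Causal Inference
Test (CIT) and a three-step filtering cascade, plus the supporting
machinery (QC, M-values, batch/plate adjustment, leukocyte deconvolution,
FDR control) that a blood-methylation study needs before the causal
question is even well-posed.

## Models and assumptions

### Scales

Methylation arrives as beta values (fraction methylated, in `[0, 1]`).
All regression modelling happens on the M-value scale,
`M = log2(beta / (1 - beta))`, clipped at `beta ∈ [0.001, 0.999]` so
M-values stay within about ±10 (`logit_transform()`, exact inverse
`inverse_logit()`). Cell mixing, in contrast, is linear on the *beta*
scale — a blood sample's beta is the cell-fraction-weighted average of
its constituent cell types' betas — so deconvolution projects on betas.

### Quality control

Rules are applied in a fixed, documented order so every exclusion has one
deterministic reason: probes — rsid-named, Y-chromosome, SNP-overlapping,
negative-control beta above mean + 4·SD (mean and SD taken across all
probes' negative-control betas; the per-probe-across-replicates reading
is a plausible alternative the sources leave open), detected
(p ≤ 0.05) in < 70% of samples; samples — > 25% of probes (strict) with
detection p > 1e-5; SNPs — call rate < 95%, MAF < 0.05 (strict
boundaries), HWE chi-square p < 1e-4. HWE uses the 1-df goodness-of-fit
chi-square rather than an exact test: at the post-QC MAF ≥ 0.05 and
array-scale counts the two agree, and the chi-square is the array-QC
convention; `hwe_test()` is a single function should an exact swap ever
be wanted.

### Batch and plate adjustment

Batch effects are removed by parametric empirical-Bayes location–scale
adjustment (ComBat, through `sva::ComBat`) on M-values, with case status
protected in the standardisation model so disease signal is not absorbed.
Protection matters: without it, a case-imbalanced batch would have part
of the case effect subtracted as "batch". The empirical-Bayes shrinkage
has one visible consequence worth knowing: per-probe batch-mean removal
is exact only when the standardised batch effects are identical across
probes; in general a small shrinkage residue remains per probe, while the
*systematic* batch signal (the one PCA sees) is removed — which is the
property the pipeline needs and the one we assert. Plate effects are then
removed per probe by OLS on a plate indicator, adding the probe's grand
mean back onto the residuals; this equalises plate means exactly and
preserves each probe's grand mean to machine precision. A singleton plate
simply lands on the grand mean.

### Leukocyte deconvolution

Fractions of the six major leukocyte subtypes (CD8T, CD4T, NK, Bcell,
Mono, Gran) are estimated per sample by constrained projection onto a
purified-cell reference panel: minimise `||beta - R w||^2` subject to
`w ≥ 0`, `Σw ≤ 1`, solved exactly with quadratic programming
(`quadprog`). The inequality (rather than equality) sum constraint
follows the constrained-projection formulation — the residual mass
absorbs cell types absent from the panel; a `renormalize` flag rescales
to 1 for reporting. Projection uses the `k = 100` most discriminating
panel probes by default. Because the panel stores one mean per cell type
(no replicates), between-type discrimination is ranked by the variance of
the six means — the numerator of the usual between-group F statistic,
whose denominator does not exist here — balanced between hyper- and
hypomethylated markers. The pipeline adjusts on the M scale, then
back-transforms and projects on the beta scale; the sources do not pin
down this ordering, and it keeps each method on the scale where its model
is linear.

### Association cascade and FDR

The EWAS fits, per CpG, OLS of M on case status plus the six cell
fractions, age, smoking, alcohol, enrollment-year stratum, residence,
parity stratum and ancestry PC1. All six fractions are entered; if the
design degenerates because fractions sum to ~1, the smallest-variance
fraction is dropped automatically and reported. The matched design is
analysed unconditionally (matching variables are covariates; `match_id`
is carried but unused). The meQTL scan is the crude additive model
`M ~ dosage` per pair, with one FDR family over *all* tested pairs. The
SNP–disease model is crude logistic `Y ~ dosage` by default (covariate
adjustment available); under quasi-separation the Wald p falls back to a
likelihood-ratio test and the SNP is flagged. q-values use Storey's
smoother for π₀ over λ = 0.05…0.95 (step 0.05, spline df 3), falling
back to π₀ = 1 — exactly Benjamini–Hochberg — when the estimate leaves
(0, 1] or fewer than 100 p-values are available. Thresholds: EWAS
q < 0.05, meQTL q < 0.10, SNP p < 0.05, CIT p < 0.05, condition-4
p > 0.05 (strict, so p4 = 0.05 rejects), all configurable via
`cascade_config()` / YAML `load_config()`.

### The CIT

`cit_test()` fits, on the trio's complete cases: logistic `y ~ g` (p1),
linear `m ~ g + y` (p2), logistic `y ~ m + g` (p3 on m, p4 on g — one
fit serves both conditions), and reports
`p_CIT = max(p1, p2, p3)` with the mediated label iff `p_CIT < 0.05` and
`p4 > 0.05`. Condition 1 is recomputed on the trio's own sample set
rather than reusing the step-3 scan, keeping all four conditions on one
set of observations. The conditional models contain only `g`, `m`, `y`
by default; a covariate block can be switched on
(`cascade_config(cit_covariates = ...)`) since the sources leave
covariate use inside the CIT regressions unstated. Only
mediated/not-mediated labels are emitted: no decision rule distinguishes
consequential from independent topologies, so no such label is assigned.
The G–Y log-odds before and after conditioning on M are stored per trio
so attenuation can be inspected directly.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the pipeline targets: 214
cases + 214 controls (the default calibration target) on a ~27K-style
array in two batches (132/296 split) across four plates.

Generation order: (1) per-sample cell fractions from a Dirichlet centred
at (Gran .60, CD4T .15, CD8T .10, Bcell .06, NK .05, Mono .04),
concentration 150 — plausible adult blood; published sources give only
the *signs* of case–control differences, so the case shift defaults
(Gran +0.05; CD4T, CD8T −0.02; NK, Bcell −0.005) are chosen for
qualitative agreement only. (2) baseline beta as the mixture of panel
means; (3) M-values plus `a·G` for mediated and independent trios, plus
residual biological noise (`noise_sd`, default 0.5 M-units). The noise is
drawn *before* the outcome deliberately: it is variation in the mediator
itself, and the mediated topology is only genuinely mediated with
respect to observable methylation if the outcome depends on the
methylation value the analyst can (after batch correction) observe. Were
noise added after the outcome draw, the observed M would be an
error-prone proxy of the true mediator and condition 4 would fail by
residual confounding — the planted "mediated" trios would not be
mediated in any testable sense. (4) case status from a logistic model —
mediated trios contribute `b·(M − mean)`, independent trios a direct
`a·b·(G − mean)` per allele (matching the mediated path's marginal G–Y
slope, so topologies are power-comparable; the direct-effect size is not
separately parameterised by design) — with the intercept calibrated by
root-finding so the *expected* case count hits `n_cases`; realised
counts are Bernoulli draws. (5) the case cell-composition shift is then
applied to realised cases and the mixture baseline rebuilt — composition
change is a *consequence* of disease here, which is exactly why the EWAS
must adjust for estimated fractions; (6) `c·Y` is added to consequential
probes; (7) technical batch location–scale effects (location ±0.5
M-units, scale ×1.1/×0.9 by default) and plate shifts (±0.2, ±0.1) are
applied around each probe's grand mean, matching the location–scale
model the empirical-Bayes correction assumes; (8) back-transform to beta
clipped to [0.001, 0.999], detection p-values uniform(0, 1e-6) with a
0.2% failure rate drawn from (0.06, 1). Passing detection draws sit well
inside both detection rules; a wider "passing" range would conflict with
the 1e-5 sample rule.

What the generator does **not** emulate: linkage disequilibrium, probe
cross-reactivity, the two-channel Illumina error model, type-I/II probe
chemistry, and matched-pair sampling. Passing tests therefore demonstrate
the pipeline's statistical behaviour under its own model assumptions —
correct causal discrimination, calibration, and effect recovery — not
robustness to array artefacts beyond location–scale batch structure.

## Numerical choices

* Logit clip ε = 0.001; round-trip exact to < 1e-12 inside the clipped
  domain.
* The projection QP adds a 1e-10 ridge to `R'R` for numerical positive
  definiteness; recovered weights are clamped at 0.
* Monomorphic SNPs: skipped (meQTL), `r² = NA` (LD), HWE p = 1 by
  convention.
* Ties in minor-allele determination (frequency exactly 0.5) keep the
  counted/ALT allele — deterministic recoding.
* One global seed drives per-stage substreams (a stable hash of the stage
  name mixed with the seed, kept below 2³¹), so genotypes, fractions,
  outcome, noise and detection layers are independently reproducible.
* Every q-value/p-value computation is deterministic given the data; the
  cascade run twice on the same inputs is byte-identical.

## Problem sizes in the test suite

The suite exercises the pipeline at desk scale, chosen as the smallest
sizes at which each property is statistically crisp: null calibration on
50 replicate cohorts of 400 samples × 5,000 probes × 500 SNPs;
mediation recovery on 50 replicates of 400 samples × 260 probes
(5 mediated + 5 consequential trios, MAF 0.3, a = 0.8 M-units/allele,
b = 1.0 log-odds/M-unit); deconvolution accuracy at 200 samples;
single-trio CIT behaviour at n = 2,000. Large-sample identities (slope
recovery, conditional-independence collapse) use n up to 5,000.

## Known limitations

* With several strong trios feeding one outcome, the per-probe EWAS
  signal is diluted (logistic attenuation grows with the linear
  predictor's total variance); recovery rates are therefore sensitive to
  how many causal paths coexist in a cohort.
* The CIT inherits a structural blind spot at fixed thresholds: a trio
  whose G–M and G–Y legs are both chance associations (each passing its
  5–10% screen) but whose M–Y leg is real cannot be rejected by
  condition 4, so occasional false "mediated" calls on
  disease-consequential CpGs are expected at a rate governed by the
  screening thresholds, not by the implementation.
* Consequential vs independent topologies are not distinguished — only
  mediated vs not.
* Reference-based deconvolution is only as good as the panel; no
  reference-free mode is provided.
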