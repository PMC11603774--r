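---
title: "Non-targeted LC-HRMS post-processing: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-targeted LC-HRMS post-processing: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntaflow)
```

## The problem

Non-targeted analysis (NTA) by liquid chromatography coupled to
high-resolution mass spectrometry screens biological samples for every
detectable chemical feature — a unique (m/z, retention time) pair with
per-sample peak areas — rather than a predefined analyte list. Applied to
paired maternal serum and urine, it can characterize the chemical
exposome: endogenous metabolites alongside drugs, personal-care
ingredients, natural products and environmental contaminants. Raw
alignment tables are, however, dominated by redundancy (adduct
satellites, the same neutral molecule ionizing in both polarities),
laboratory background, below-detection-limit censoring, and batch-to-
batch instrumental drift. `ntaflow` implements the full post-processing
chain from aligned feature tables to annotated, batch-corrected,
statistically analyzed results, plus a ground-truthed simulator so each
stage is testable without instrument data.

## The emulated cohort

The synthetic cohort is fixed, not tunable toward any result: 95
participants, each contributing one serum and one urine sample collected
at the same visit; 35 preterm and 60 term birth outcomes; an instrumental
run split into 4 batches, with each participant's pair analyzed in the
same batch (round-robin assignment). Urinary creatinine is drawn
lognormal with median 100 mg/dL and geometric SD 1.5 — a typical adult
range — since the source cohort reports no values.

## Abundance model

Peak areas are simulated on the log10 scale and exponentiated (the
workflow log-transforms areas without a stated base; base 10 is used
consistently everywhere, including imputation and correction). Feature
`f` in sample `s` of batch `b` has

    log10 A_fs = mu_f + m_f * 1[urine] + gamma_b + delta_b * sigma_f * eps_fs

with `mu_f` anchored to the method detection limit (below), matrix offset
`m_f ~ N(0, 0.3)`, additive batch shifts `gamma_b = (0, 0.3, -0.2, 0.15)`
and variance scalings `delta_b = (1, 1.2, 0.9, 1.1)` — exactly the
location/scale model the parametric empirical-Bayes correction assumes,
so parameter recovery is well-posed. Residuals are standard normal except
within planted correlation clusters, where
`eps = sqrt(r) u_s + sqrt(1-r) z` shares a per-sample latent factor,
giving pairwise Pearson correlation `r` (default 0.7) exactly.

**Censoring.** Any simulated area below the method detection limit (MDL,
default 10,000 — also the Orbitrap noise floor used by the detection
rule) is set to missing; missing is encoded as `NA`/empty cell, never 0,
because 0 is a legal area. Each feature receives a target censoring
ceiling `p_f`: uniform on (0, 2·`missing_rate`) for background features
(default `missing_rate` 0.1) and on (0, min(`missing_rate`, 0.1)) for
planted differential and cluster features, reflecting that compounds
reported as surviving a 70% detection filter — and stable across 60/70/
80% cutoffs — are detected in most samples. `mu_f` is anchored so `p_f`
bounds the censoring fraction in *both* matrices (the urine offset would
otherwise silently inflate it). This is a stated-world choice, recorded
here once.

**Planted structure.** 40 differential features carry a preterm/term
log2 fold change of 2 in serum; 30 shared neutral molecules appear as
`[M+H]+` at `M + 1.00782` and `[M-H]-` at `M - 1.00782` with RT agreement
within 0.2 min; 10 decoy near-pairs violate exactly one merge tolerance
(mass error 10–20 ppm, or delta-RT 0.6–1.0 min); 20 positive-mode adduct
satellites carry a link to their parent; 5 blank-artifact features have
laboratory-blank areas rivaling their sample areas.

What the generator does **not** emulate: chromatograms, centroiding or
peak picking; isotope fine structure; ion suppression; pooling chemistry
(MS2 spectra attach directly to features rather than to physical pools).
A green test therefore establishes correctness of the *post-processing*
contracts on data obeying the stated statistical model — not robustness
to upstream acquisition artifacts.

## Filtering cascade

Stages run in a fixed order, each idempotent:

1. **Adduct removal** — features whose `adduct_link` points (transitively)
   to another ion are dropped; link roots are kept.
2. **Blank filtering** — a feature is background when its mean
   laboratory-blank area reaches 1/3 of its mean sample area. The 1/3
   ratio is a package default (the source protocol's exact rule is not
   public) and is exposed as a parameter.
3. **Detection frequency** — "detected" means non-missing *and* area
   above the 10,000 noise floor; features detected in >= 70% of samples
   are retained. The cutoff is inclusive (>= rather than >): the
   workflow says "cutoff" without strictness, and inclusivity is the
   documented choice.
4. **Cross-polarity merge** — neutral mass is `mz - 1.00782` (ESI+) or
   `mz + 1.00782` (ESI-); candidate pairs within 5 ppm and < 0.5 min are
   matched one-to-one greedily by ascending ppm error, ties broken by
   smaller delta-RT then smaller feature id (the conflict rule is
   unstated upstream; greedy-by-ppm is ours, and is verified against a
   brute-force enumeration oracle). For a merged pair, the mode with the
   higher median area feeds downstream statistics — which polarity's
   areas feed the published figures is unstated, so this is a documented
   package choice.

## Normalization, imputation, batch correction

**Creatinine.** Urine areas are multiplied by (cohort median creatinine /
sample creatinine); serum is untouched. Median-ratio scaling keeps urine
areas on the same numeric scale as serum; plain division is available as
a strategy flag since the source's exact formula is not public.

**Below-MDL imputation.** Per feature, missing cells are drawn from
`Normal(median, sd)` of the observed log10 areas, truncated above at
`min(observed minimum, log10 MDL)`. The truncation is our guarantee that
fills genuinely represent sub-MDL values (the cited method description
fits a normal but does not state a bound). Observed values are never
modified; the pre-imputation detection mask is preserved and reused for
detection-frequency and node-pie computations. Draws are reproducible
from a seed.

**Batch correction.** Parametric empirical-Bayes location/scale
adjustment: feature-wise standardization retaining sample matrix and
outcome as design terms; method-of-moments priors (normal for additive
effects, inverse-gamma for variance effects) estimated across features;
iterative shrinkage to the posterior until the maximum absolute change is
below 1e-4 (cap 100 iterations, warning and last iterate on
non-convergence); adjustment `(z - gamma*) / delta*` back-transformed.
Decisions taken here: the parametric branch only (the nonparametric
variant is out of scope); covariates (matrix, outcome) are retained
during standardization — whether the original analysis ran with
covariates is unknown, so this is flagged as a divergence risk; a single
batch is a no-op; a batch of one sample is an error. Note that EB
shrinkage preserves per-feature grand means only approximately (relative
residue ~1e-3 at cohort scale); `eb = FALSE` disables shrinkage and then
batch means are removed exactly and grand means are preserved to
numerical precision.

Imputation runs after merging and before correction; the upstream order
is ambiguous, so it is fixed here and recorded in the run manifest.

## Annotation

Pooled-sample MS2 spectra (>= 2 fragments required to be informative)
are scored against library entries of the same ion mode within a 10 ppm
precursor window. The score is 100 x the cosine similarity of
square-root-intensity-weighted fragment vectors aligned greedily within
10 ppm — the scoring function of the original vendor tools is not
published, so this standard weighted cosine is the package's documented,
configurable choice. Confidence levels:

| Level | Rule |
|---|---|
| 1 | best match is an authentic standard, delta-RT < 0.05 min, precursor and all matched product ions < 5 ppm |
| 2 | library match with score > 90 |
| 3 | candidate with 50 < score <= 90 (the 50 floor is our construction; only Levels 1, 2 and 4 are operationally defined upstream) |
| 4 | informative MS2 but no candidate above 50 |
| 5 | no usable MS2 |

Annotations transfer onto the MS1 alignment at |delta-RT| <= 0.1 min and
<= 2 ppm, lowest ppm error winning ties. Sources are copied from the
entry's category set — endogenous metabolite, natural product, drug,
personal-care product, exogenous contaminant — with multi-category
membership allowed and an empty set reported as "unknown"; online
database lookups are replaced by local library tags (no network calls).

## Statistics and network

Differential testing is a per-feature Welch t-test on log10 abundances
(Welch rather than pooled-variance: the upstream description says only
"t-test", and unequal variances are the safe default), with
Benjamini-Hochberg adjustment over all tested features. Fold changes are
computed from linear-scale group means and reported as log2, matching the
volcano cutoffs p < 0.05 and |log2 FC| > 1.2. PCA runs on
feature-standardized log10 abundances; PCs 1–3 are correlated against
matrix, batch and outcome (binary covariates coded 0/1; batch as integer
with a companion one-way ANOVA, since the upstream coding is unstated).
Heatmap structures use average linkage: correlation distance for
features, Euclidean on standardized values for samples.

The chemical network takes annotated Level 1–2 compounds as nodes;
candidate edges pair endogenous metabolites with every other annotated
compound, kept when |Pearson R| > 0.5 on log10 corrected abundances
(log scale is our choice; unstated upstream). Negative edges are
retained and sign-flagged — the published display is positive-only, but
the stated filter is on absolute R, so filtering by sign is left to the
exporter. No multiple-testing control is applied on edges (none was
applied upstream). Node pies report, among samples where the compound is
detected, the percentage of detections in each outcome group.

## Numerical and degenerate-input conventions

* All randomness flows from a single integer seed; identical config +
  seed gives byte-identical run directories.
* Truncated-normal draws use inverse-CDF sampling; a degenerate bound
  (zero upper-tail mass or zero sd) falls back to the bound itself.
* Constant features: excluded from PCA with a warning; an error for
  correlation-distance clustering and for batch standardization.
* Empty spectra cannot be scored (error); one-fragment spectra are
  Level 5 by definition.
* Ties in merging and annotation transfer are broken deterministically
  (ppm, then delta-RT, then id).

## Known limitations

Semiquantification, nonparametric batch correction, vendor-specific
matching, mzML/raw ingestion and interactive visualization are out of
scope. The simulator's independence assumptions (no ion suppression, no
correlated censoring between paired matrices) mean recovery rates
measured here are upper bounds on what heterogeneous real cohorts would
give. All empirical numbers quoted anywhere in this documentation are
computed by the test suite or by `scripts/acceptance.R`; none are
transcribed from external sources.
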