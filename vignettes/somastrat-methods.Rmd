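---
title: "Methods: proteomic risk stratification with competing risks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic risk stratification with competing risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somastrat)
```

# The problem

After a first myocardial infarction, a patient's long-term risk of
hospitalization for heart failure (HF) competes with death from any cause:
a patient who dies can never be hospitalized for HF, so naive survival
methods that censor deaths overstate HF risk. `somastrat` implements a
complete workflow for stratifying such patients from high-dimensional
aptamer-based (SOMAscan-style) plasma proteomics measured during the index
hospitalization:

1. **Selection** — normalize and calibrate the raw relative-fluorescence
   (RFU) data, collapse SOMAmer reagents to proteins, log2-transform,
   standardize on the *derivation* cohort, and screen every protein with a
   univariate Fine–Gray subdistribution-hazard model under Bonferroni
   familywise error control.
2. **Stratification** — cluster derivation patients on the selected panel
   with k-means, choosing the number of groups by the overall average
   silhouette width, and transfer the groups to a *validation* cohort by
   nearest-centroid assignment in the derivation cohort's standardized
   space.
3. **Prediction** — quantify the groups' effect on HF occurrence with
   cumulative incidence curves and group-level Fine–Gray models, unadjusted
   and adjusted for clinical covariates, plus a drop-protein sensitivity
   analysis.

Because raw cohort data of this kind are not publicly deposited, the
package ships a synthetic-cohort generator that emulates the statistical
structure of the inputs end to end; every stage is tested against it.

# The competing-risk machinery

## Cumulative incidence

The Aalen–Johansen estimator for cause $k$ is

$$\hat F_k(t) = \sum_{t_j \le t} \hat S(t_j-)\,\frac{d_{kj}}{n_j},$$

with $\hat S$ the all-cause Kaplan–Meier survivor, $d_{kj}$ the cause-$k$
events at $t_j$ and $n_j$ the number at risk. Without censoring,
$\hat F_1(\infty) + \hat F_2(\infty) + \hat S(\infty) = 1$ exactly; the
test suite asserts this to $10^{-12}$.

## Fine–Gray regression

The subdistribution hazard of cause 1 is modelled as
$\lambda_1(t \mid x) = \lambda_{10}(t)\exp(x^\top\beta)$. The fit maximizes
the IPCW-weighted partial likelihood: a subject failing from the competing
cause at $T_i$ *remains in the risk set* afterwards with weight

$$w_i(t) = \frac{\hat G(t-)}{\hat G(T_i-)},$$

where $\hat G$ is the Kaplan–Meier estimator of the censoring
distribution, evaluated left-continuously. Ties are handled with the
Breslow approximation. Newton–Raphson with step-halving guarantees a
monotone likelihood ascent; convergence is declared when the relative
log-likelihood change drops below $10^{-9}$ (at most 100 iterations, an
error otherwise), and $|\beta| > 20$ is treated as separation and refused.
Standard errors come from the observed information of the weighted partial
likelihood; confidence intervals are 95% Wald intervals and p-values are
two-sided normal, matching how subhazard ratios (SHR) are conventionally
reported. The implementation is validated two ways: against a brute-force
1-D maximization of the Cox partial likelihood on a fixture without
competing events (where Fine–Gray reduces to Cox), and against the
`cmprsk` reference estimator under competing risks and censoring.

For genome-scale screening the risk sets and IPCW weights depend only on
the outcomes, so they are computed once and all single-covariate Newton
iterations advance in lockstep as dense matrix products; 200 protein fits
on 150 patients take a few milliseconds. The screen fixes the number of
tests $m$ at the number of protein columns *before* fitting: a protein
whose fit fails is reported untestable and never selected, but still
counts in $m$, so the Bonferroni threshold $\alpha/m$ does not drift with
convergence failures.

# The synthetic-data generator

## Event times

Event times follow the *direct* subdistribution parameterization: given a
linear predictor $\eta$,

$$F_1(t \mid \eta) = 1 - \bigl\{1 - p\,(1 - e^{-\lambda_1 t})\bigr\}^{\exp(\eta)},$$

so the asymptotic HF probability at baseline is $p$ and — crucially — the
true subdistribution hazard ratio for a unit change in the covariate is
exactly $e^{\beta}$. Cause-1 times are drawn by inverse-CDF; patients who
escape cause 1 die at an exponential($\lambda_2$) time; administrative
censoring is uniform on a follow-up window. This construction makes exact
parameter-recovery tests possible: fitting the generating covariate
returns $\beta$ without attenuation bias.

The linear predictor is $\beta_1\,\mathbb 1(\text{group 2})$, i.e. risk is
driven by the *latent group*, with the informative proteins acting as
correlated markers of that group. A superficially attractive alternative —
driving risk by the standardized mean of the informative proteins — breaks
the identity between $\beta_1$ and the group-level log-SHR (at the default
separation it inflates the group contrast roughly twofold), which would
make honest recovery and coverage tests impossible; the group-indicator
construction keeps the true group SHR exactly $e^{\beta_1}$ while leaving
per-protein screening behaviour realistic (each protein is an imperfect,
attenuated proxy of the group).

## Assay layer

Raw RFU values are true abundances times three multiplicative
disturbances: a per-sample readout bias (uniform on $[0.7, 1.4]$ — the
range that keeps clean-data scale factors inside the printed acceptance
band), a per-plate bias (lognormal, 5% scale), and lognormal measurement
noise (5% CV). Each sample carries 12 hybridization-control sequences
spanning the signal range; each plate carries calibrator, QC and buffer
samples sharing a pooled population profile (buffer sits at background).
Proteins measured by two or three SOMAmers get per-reagent efficiency
offsets; a configurable number of SOMAmers is flagged for manufacturer
removal.

## Default study conditions

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `n_patients` | 254 | patients | derivation-cohort scale |
| `n_somamers` / `n_proteins` | 320 / 275 | reagents / proteins | desk-scale panel with the same bookkeeping shape as a full array (removals, 2–3-fold SOMAmer multiplicity) |
| `group2_fraction` | 0.37 | — | observed high-risk group prevalence in post-MI cohorts |
| `n_informative`, `delta` | 50, 1.5 | proteins, log2 units | a 50-protein panel separated by 1.5 log2 units |
| `protein_sd` | 0.5 | log2 units | between-patient biological SD; keeps single proteins informative but imperfect markers |
| `beta1` | log 7 | — | group-level subhazard ratios near 7 are the magnitude reported for proteomic risk groups after MI; with ~50 HF events a smaller effect would be undetectable by any univariate test at the Bonferroni threshold, making the default demonstration vacuous |
| `p_asym`, `lambda1` | 0.10, 0.12 | —, 1/years | yields ≈ 20–25% observed HF incidence under censoring |
| `lambda2` | 0.035 | 1/years | ≈ 25% all-cause death over follow-up |
| `censor_lo`–`censor_hi` | 6–16 | years | long follow-up with ~9-year mean |
| `clinical_missing_rate` | 53/6858 | — | sparse missingness, a handful of cells per cohort |

The clinical table has 27 variables: the eight used for model adjustment
(age, gender, ejection fraction, diabetes, Killip ≥ 2, creatinine, BNP,
NT-proBNP), simulated with group-correlated distributions, plus 19 pure
noise columns.

## What the generator does *not* emulate

Real per-protein marginal distributions and their heavy tails; effect-size
heterogeneity across the informative panel (all informative proteins share
one shift); assay drift over time and plate-layout artifacts beyond a
scalar plate bias; echocardiographic remodeling variables; informative
censoring. A green test suite therefore demonstrates that the *machinery*
is correct under a faithful but idealized data-generating process — it is
not evidence that any particular protein panel generalizes to real
patients.

One interaction worth knowing: per-sample median normalization to a
reference assumes most analytes are unregulated. If a large fraction of
the panel shifts with the group (easy to provoke in tiny configurations),
the per-dilution median ratio absorbs part of the shift and smears a
small opposite-signed artifact across the unshifted proteins. At realistic
informative fractions (≈ 1% of a full array; ≤ 20% in the shipped
defaults) the artifact is negligible, but miniature test configurations
keep the informative fraction below ~10% for this reason.

# Normalization and calibration

Five multiplicative corrections run in sequence; each is a
median-of-ratios step, and after each one the defining median ratio equals
1 to machine precision:

1. **Hybridization control normalization** (per sample): reference is the
   within-plate median of each control; the median control ratio scales
   everything in the sample.
2. **Intraplate median signal normalization** (calibrator samples only,
   per dilution set): reference is the within-plate calibrator median per
   SOMAmer.
3. **Plate scaling** (per plate): the median over SOMAmers of
   global-reference/local-calibrator-median ratios.
4. **Calibration** (per plate × SOMAmer): forces every plate's calibrator
   median onto the global reference exactly.
5. **Median normalization to a reference** (study/QC/buffer samples, per
   dilution): aligns each sample's median ratio to the reference.

The global calibrator reference is the pooled per-SOMAmer median over all
calibrator samples across plates; the same profile serves as the
normalization reference for step 5 (no external healthy-donor reference
exists in a synthetic study). Medians of even counts are midpoints of the
two central order statistics. Hybridization controls are excluded from all
analyte medians. QC acceptance applies the 0.4–2.5 band to hybridization,
intraplate and plate-scale factors, and requires ≥ 85% of per-SOMAmer
QC-sample ratios inside [0.84, 1.19]; per-sample median-normalization
factors are reported but not banded, since buffer samples sit far below
the reference by design.

Idempotence deserves a caveat: the reference-anchored steps (3–5, with the
reference held fixed) are *exactly* idempotent, and the tests assert unit
second-pass factors to $10^{-12}$. The locally-referenced steps (1–2)
re-estimate their reference from the already-scaled data, so their
second-pass factors are only approximately 1 (within a few percent on
clean data); exact idempotence is not a property these steps possess.

# Preprocessing decisions

* **Aggregation before log**: multi-SOMAmer proteins are averaged on the
  RFU scale, then log2-transformed — the arithmetic mean of raw
  fluorescence is the natural "give each protein one column" operation,
  and the downstream standardization is indifferent to monotone ordering.
* **Standardization**: per-protein $(x - m_p)/s_p$ with $m_p, s_p$
  estimated on the derivation cohort only, sample SD ($n-1$ denominator,
  the default convention of mainstream statistical environments).
  Parameters serialize to a three-column TSV so an external cohort — or a
  single patient — can be projected into derivation space; constant
  columns are refused rather than silently zeroed.
* **Clinical imputation**: deterministic single imputation by iterative
  low-rank (principal-axes) completion — initialize missing cells at
  column means, standardize columns, alternate truncated rank-$r$ SVD
  reconstruction of the centered matrix with re-imputation of the missing
  cells until the largest imputed-cell change is below $10^{-6}$ (cap 200
  iterations, with a warning). Default rank 2. Columns are scaled during
  the iterations so large-scale variables (natriuretic peptides) cannot
  monopolize the principal axes, and observed cells are restored exactly
  afterwards. One structural caveat, asserted in the tests: completing a
  rank-1 matrix with one masked cell requires a rank-1 model — a rank-2
  truncation can represent the one-cell perturbation exactly and stalls at
  the initialization.

# Stratification decisions

* k-means is Lloyd's algorithm (`stats::kmeans`), best of 25 random
  restarts under a fixed seed; on desk-scale data this reliably attains
  the WCSS optimum (verified against exhaustive 2-partition search on a
  6-point fixture), so no bespoke seeding scheme is used.
* The average silhouette width $\bar s = \mathrm{mean}_i\,(b_i -
  a_i)/\max(a_i, b_i)$ uses Euclidean distance; members of singleton
  clusters get $s_i = 0$ (the usual convention). $k$ ranges over 2–6 and
  ties go to the smaller $k$.
* Nearest-centroid assignment breaks exact ties toward the lowest group
  index — a probability-zero event that still needs a deterministic rule.
* After fitting, the cluster with the higher crude HF incidence is
  relabelled group 2, so "group 2" always denotes the high-risk stratum.
* Group comparisons use Welch's $t$ (Satterthwaite df) for quantitative
  variables and the chi-square test *without* continuity correction for
  categorical ones (variables with ≤ 4 distinct values are treated as
  categorical); raw p-values at the 0.05 level, no multiplicity
  adjustment, mirroring standard cohort-description practice.
* The sensitivity analysis re-selects $k$ and re-clusters on the reduced
  panel, maps new groups to baseline groups by the overlap-maximizing
  bijection (exhaustive over $k!$ permutations), and counts label changes
  in both cohorts.

# Enrichment

Term-set overrepresentation is the one-sided hypergeometric upper tail
$P(X \ge \text{overlap})$ with $X \sim \mathrm{Hypergeom}(|U|,
|\text{term}|, |\text{selected}|)$, computed with `stats::phyper` and
verified against complete enumeration on a 6-element universe. Terms are
flat symbol sets intersected with the tested universe (no ontology graph);
raw p-values by default, optional Bonferroni adjustment. This reflects the
package's scope: the machinery is generic, the annotation content is the
user's.

# Problem sizes and determinism

The shipped analyses and tests run at desk scale by design: cohorts of
120–254 patients (2000 for recovery/coverage loops), panels of 31–275
proteins, 500-replicate null simulations for the familywise-error check,
and the 5284-column bookkeeping fixture exercised once with constant
values. One master seed drives each simulated cohort; sub-streams are
derived deterministically per component (structure, abundances, outcomes,
clinical, missingness), so any component can be regenerated independently
and every pipeline run is a pure function of its configuration and seeds.

# Known limitations

* The Fine–Gray variance is the model-based observed-information estimate;
  no robust sandwich or censoring-estimation correction, so standard
  errors are mildly optimistic in small samples (the reference `cmprsk`
  variance differs for the same coefficients).
* No time-varying covariates, stratified baselines, or Gray's k-sample
  test.
* Multiple imputation is out of scope; the single deterministic completion
  understates imputation uncertainty (harmless at ~0.8% missingness).
* The silhouette criterion is the only cluster-number rule implemented;
  alternatives (gap statistic, model-based BIC) can disagree at weak
  separation.
* Synthetic validation only: see the generator's non-goals above.
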