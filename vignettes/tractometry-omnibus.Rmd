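---
title: "Tractometry group statistics with a permutation omnibus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tractometry group statistics with a permutation omnibus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractomnibus)
```

## The analysis problem

Tractometry reduces a diffusion-MRI metric map to one scalar per
white-matter bundle per subject: here 72 bundles times 11 metrics (FA, MD,
AD, RD from the diffusion tensor model; FA, MD, AD, RD, MK, AK, RK from the
kurtosis model; diffusivities in um^2/ms, the rest dimensionless).
Comparing two small groups — concussed athletes against matched controls —
then means 792 rank-sum tests, far too many to interpret at a fixed alpha
without some account of multiplicity, yet with samples of about twenty per
group there is little appetite for the power cost of family-wise
correction.

The package implements the middle road this literature uses: report every
per-tract Mann–Whitney test uncorrected, but judge each *metric* by an
omnibus statistic — the **count of significant tracts** — whose null
distribution is obtained by permuting group labels. Because the labels are
shuffled jointly across tracts, the permutation null inherits the real
(unknown, typically strong) inter-tract dependence, which an independence
argument such as a binomial calculation would badly understate.

## Per-tract and global tests

Each per-tract comparison is a two-sided Mann–Whitney U test computed from
midranks, with the tie-corrected variance and a 0.5 continuity correction
in the normal-approximation mode, or the exact U distribution (tie-free) /
full enumeration of label assignments (with ties) in exact mode. `auto`
mode switches from exact to asymptotic above a combined sample size of 12:
the permutation engine recomputes 72 tests per permutation, and at the
study's sizes (about 40 subjects) the exact and asymptotic p-values agree
to well under 0.02, which we verify by property test. Significance is
strict, `p < alpha`: the boundary rule is unstated in this literature, and
strict inequality is both conventional and conservative.

Each metric also gets a **single WM ROI** summary: the subject's mean over
all 72 tract values (the sum divided by 72), compared between groups with
the same U test. Medians and interquartile ranges are computed with linear
interpolation between order statistics (quantile type 7), the common
statistical-software default.

## The permutation omnibus

For metric $k$ and per-tract level $\alpha$, the observed statistic is
$T_\mathrm{obs}$, the number of tracts with $p < \alpha$. For each of $B =
10^4$ permutations, group labels are reassigned uniformly at random among
the subjects (preserving group sizes), all 72 tests are recomputed, and the
count recorded. Two p-value rules are provided:

* `strict_greater` — the fraction of permutations whose count strictly
  exceeds $T_\mathrm{obs}$; this follows the verbal definition used in the
  field but can return exactly zero;
* `ge_plus_one` — $(1 + \#\{T_b \ge T_\mathrm{obs}\})/(B+1)$, the add-one
  estimator, never zero and never anti-conservative. This is the default;
  the strict rule is available for comparability.

The **null 95th percentile** `q95_null` uses the inverse-empirical-CDF
convention (the smallest integer covering 95% of the null counts), because
it is interpreted as a count: the largest number of false-positive tracts
expected under the null. A metric is *flagged* when
$T_\mathrm{obs} > q_{95}$ and the permutation p is below 0.05.

Implementation note: midranks and the tie-corrected variance per tract
depend on the data only, not the labels, so one permutation's 72 U
statistics are a single matrix product of the rank matrix with a label
indicator; $B = 10^4$ permutations for one metric are a 72-by-$B$ matrix
operation. The observed count uses the identical per-tract test, so the
observed and null statistics are exchangeable under the null — the property
the Monte-Carlo p rests on. For a given seed the same permutation matrix is
reused for all metrics sharing a subject set (e.g. all DKI metrics); this
makes per-metric omnibus p-values dependent, which is documented behaviour
and irrelevant to their marginal validity.

## Effect sizes and the null bound

Effect sizes are Cohen's d with pooled SD (athlete minus control). The
significance bound is the half-width of the central 95% interval of the
estimated d under no true effect: the normal approximation
$z_{0.975}\sqrt{(n_1+n_2)/(n_1 n_2)}$ gives 0.64 for two groups of 19 —
the threshold used at these group sizes. The exact null law of the
*estimated* d is t-scaled ($d\sqrt{n_1 n_2/(n_1+n_2)} \sim t_{n_1+n_2-2}$),
so the `t` method gives a slightly wider 0.658, and the `montecarlo`
method — the empirical 95% quantile of $|d|$ over $10^5$ null normal
simulations — reproduces the t bound, not the normal one. The normal
method is the default because it reproduces the conventional two-decimal
threshold; the other two quantify how liberal that convention is
(about 0.02 at n = 19 per group).

The per-tract map is summarised by mean $|d|$ per metric plus "average"
rows for DTI and DKI computed over FA, MD, AD and RD only — the four
metrics the two models share, so the model comparison is like-for-like.

## Correlations and deficit classification

Global (single-ROI) metric values are correlated with outcomes — CSF
neurofilament light (NfL) and GFAP, and neuropsychological raw scores —
with Spearman's rank correlation, within the athlete group only (controls
contribute no injury variance and, in the emulated design, no CSF).
Missing values are deleted pairwise, so each cell of the grid carries its
own n; p-values use the t-transform on $r_s$ with $n-2$ degrees of freedom,
or exact enumeration of rank permutations for $n \le 8$.

Neuropsychological raw scores are converted to Z-scores against a normative
table, sign-flipped where a lower raw score means better performance, and a
deficit is declared at $Z \le -1.5$ — boundary inclusive — which
corresponds to the lower 6.7% of a normative population
(`normal_lower_tail(-1.5)` = 0.0668). The normative table shipped with the
package (`default_norms()`) is synthetic: plausible manual-style means and
SDs shaped like an RBANS-type battery plus self-report scales, not
published norms.

## The synthetic cohort generator

No subject-level data accompany this design, so the generator is
first-class, tested code that emulates the statistical structure the
analysis assumes:

* **Latent injury factor.** Each athlete carries
  $L_i = |N(1, 0.5^2)|$ (the absolute value keeps the factor positive;
  variance 0.25); controls have $L_i = 0$. One factor drives tract
  effects, NfL, symptom scores and neuropsychological depression, which is
  the simplest structure reproducing the sign pattern of the reported
  metric–biomarker correlations.
* **Tract noise.** Within a metric, tract values share an equicorrelated
  Gaussian noise field: correlation `inter_tract_rho` (default 0.5), unit
  variance on the metric's scale. Equicorrelation is the one-parameter
  stand-in for the strong spatial dependence of real tractometry; at
  $\rho = 0.5$ the null 95th-percentile counts come out at 12–20 of 72
  tracts, the order observed in real data, versus 7 under independence.
* **Calibration.** Baseline centers and scales are healthy-adult global WM
  medians and IQR-derived SDs ($\sigma = \mathrm{IQR}/1.349$, the normal
  conversion, applied as the per-tract noise scale). In the study preset
  (`study_config()`), per-tract effect magnitudes are derived from
  published global-median group differences: with $m$ affected tracts,
  $\delta = |\Delta| / (\sigma \cdot m/72)$, so the cohort's global medians
  reproduce the published ones by construction and the affected-tract
  counts for the DKI metrics land close to the reported ones. Signs follow
  the published directions (athletes: DKI FA and AK up; DKI MD, RD, MK, RK
  down; DTI essentially unchanged — the derived DTI deltas are near noise
  level, so DTI is never omnibus-flagged, as in the study).
* **Biomarkers.** $\mathrm{NfL} = 150 + 70 L_i + N(0, 28^2)$ ng/L, floored
  at zero. The noise SD is calibrated so the implied NfL–DKI-FA Spearman
  correlation among athletes (~0.6) matches the reported magnitude, and the
  athlete median lands near 220 ng/L. GFAP is drawn around 248 ng/L
  uncoupled from $L$, mirroring its reported null associations.
* **Missingness.** Whole subjects are dropped per modality (DTI, DKI, CSF,
  neuropsychology) at preset rates that approximate the study's attrition
  (DTI 20/20 of 22+22, DKI 19/19, CSF in 16 of 22 athletes).

What the generator does *not* emulate: spatially structured (non-exchangeable)
tract dependence, tract-specific effect heterogeneity beyond the
affected/unaffected dichotomy, non-Gaussian tails, age/sex structure, and
any imaging-level artefact. Passing tests therefore demonstrate the
statistical machinery's correctness and calibration under a faithful but
idealised dependence structure, not robustness to everything real data do.

## Numerical and design choices

* Exact U p-values use the exact rank-sum distribution when the pooled
  sample is tie-free and full enumeration of label assignments otherwise;
  two-sidedness is defined by $|U - n_1 n_2/2|$, which matches the doubled
  tail for the symmetric null.
* Degenerate inputs: a tract constant across both groups returns p = 1
  with a flag (never spuriously significant); zero pooled SD yields an
  undefined effect excluded from maps; zero rank variance yields an
  undefined correlation, flagged.
* Tracts present in only one group are excluded with a warning; subjects
  with partial tract coverage are dropped per metric for the global
  summary and the omnibus (listwise per modality, as in the emulated
  design — no imputation).
* Report percentages round half away from zero; raw fractions are always
  retained alongside.
* Reproducibility: every stochastic routine takes an explicit integer
  seed, and identical inputs plus seed give byte-identical outputs.

## Problem sizes used in the checks

The test suite and acceptance script size their simulations for a desktop
run: type-I calibration of the omnibus uses 300–500 null cohorts at
$B = 1000$; the enumeration cross-check uses $n = 4+4$ subjects and 5
tracts against all 70 label splits with $B = 10^4$; the signal-recovery
check uses 40 preset cohorts at $B = 1000$; the Monte-Carlo effect bound
uses $10^5$ draws. The full pipeline on one preset cohort with $B = 10^4$
runs in a few seconds.

## Known limitations

* The joint replication probability of every directional claim at the
  study's group sizes is about 0.93 per simulated cohort, dominated by the
  two global effects that are borderline at n of about 19 per group (the
  radial-diffusivity and radial-kurtosis medians). That is a faithful
  property of the emulated design, not an implementation defect: effects
  are calibrated to the published shifts, and several of those are
  themselves only marginally significant.
* The omnibus tells you *that* a metric has more significant tracts than
  chance allows, and how many of its significant tracts chance could
  explain — not *which* tracts are real. Tract-level inference remains
  uncorrected by design.
* Equicorrelation is exchangeable across tracts; real dependence is
  spatially structured. The omnibus itself does not rely on the
  equicorrelation assumption (it permutes labels on whatever data it is
  given); only the generator does.
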