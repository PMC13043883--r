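---
title: "Methods: z-score subtype-and-stage inference and stage-association scans"
author: "sustainz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: z-score subtype-and-stage inference and stage-association scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the model and its assumptions, the parameters that matter, the design
decisions taken where the design was genuinely open, and what the
synthetic validation does and does not demonstrate.

## 1. Control-referenced atrophy z-scores

Regional volumes (mm³) are adjusted per region by ordinary least squares on
age, sex and total intracranial volume, **fitted on controls only**
(`fit_control_model()`). All subjects — controls and patients — are then
scored against this control-anchored reference (`compute_zscores()`):

$$ z = \frac{\hat y_{\text{control model}} - y}{\hat\sigma_{\text{resid}}} $$

Design choices, with rationale:

* **Atrophy-positive sign.** The event model assumes monotone *increase*
  along the stage axis, so the z-score is flipped: volume deficit is
  positive. Feeding raw (deficit-negative) residual z-scores into an
  increasing-event model would be incoherent.
* **Residual SD with the unbiased $n-p$ denominator** ($p = 4$
  coefficients): an unbiased scale matters for modest control pools.
  In-sample control z-scores consequently have SD
  $\sqrt{(n-p)/(n-1)}$ ≈ 0.99 at $n = 224$, and per-column mean 0.
* **Per-region residual SD**, not pooled: region volumes span two orders
  of magnitude (amygdala ≈ 1.7 ml per side, frontal lobe ≈ 160 ml), so a
  pooled scale would be meaningless. This also makes z-scores invariant to
  positive rescaling of any single region.
* **Patients are scored with the control-fitted coefficients, including
  TIV.** The control group defines the reference distribution; refitting on
  patients would absorb disease effect into the covariate model.
* **No winsorizing of extreme z.** The Gaussian stage likelihood handles
  tails gracefully; a symmetric cap is available via `compute_zscores(cap=)`
  but off by default.
* **Bilateral averaging** (`average_bilateral()`) collapses left/right
  subcortical columns to their arithmetic mean before z-scoring, reducing
  dimensionality; cortical lobes stay hemisphere-specific. Sex enters the
  design as a single female indicator — with a two-level factor any coding
  yields identical predictions.
* Degenerate inputs: a rank-deficient control design (for example constant
  TIV) fails with the offending column named; zero residual variance marks
  the region's scale `NA` with a warning, and scoring such a region is an
  error rather than an infinity.

## 2. The z-score event model

Events are (biomarker, threshold) pairs; default thresholds are z = 1, 2, 3
(mild, moderate, severe), so 13 biomarkers give $N = 39$ events and a stage
axis $0..39$. Within a sequence each biomarker's thresholds must appear in
increasing order — a biomarker cannot reach z = 2 before z = 1. This
constraint is enforced everywhere (validity of random restarts, hill-climb
moves, user-supplied sequences); without it the trajectory interpolation
would be non-monotone and meaningless.

The expected z of biomarker $i$ at stage $k$ is the piecewise-linear
interpolant through $(0, 0)$, each event position at its threshold, and
$(N, z_{\max})$ (`expected_z_at_stage()`). The subject likelihood
marginalises the latent stage over a **uniform prior on $0..N$ including
the no-event stage** — the convention of the cited model class; nothing in
the data argues for a non-uniform prior at fitting time. Everything is
computed in log space; z-scores up to |z| = 20 and 60-event grids stay
finite.

Tunable parameters, defaults and units:

| parameter | default | unit | why |
|---|---|---|---|
| `z_thresholds` | 1, 2, 3 | z | mild/moderate/severe atrophy events |
| `sigma` | 1 | z | data are control-referenced z-scores, whose control scatter is 1 by construction |
| `z_max` | 5 | z | plateau above the last threshold; must exceed max(thresholds) |
| `n_restarts` | 25 | — | random valid restarts of the hill climb |
| `em_iters` | 100 | — | EM cap; convergence tolerance 1e-6 on total log-likelihood |

`sigma` and `z_max` are per-biomarker recyclable. The biomarker count is
deliberately configuration, not a constant: the maximum stage always equals
(number of biomarkers) × (number of thresholds), and the 13-biomarker
default (8 cortical hemisphere-specific + 5 bilateral subcortical) is one
realistic panel, not a requirement.

## 3. Sequence search, subtype growth, model selection

The per-subtype sequence maximising the weighted stage-marginalised
log-likelihood is found by **greedy single-event relocation hill-climbing**:
each pass visits every event in random order and relocates it to its best
valid position; passes repeat until no move improves the objective; the best
of `n_restarts` random valid starts is kept. On all small instances
enumerable by brute force (≤ 6 valid sequences) the climb provably attains
the exhaustive optimum (tested). This maximum-likelihood search replaces
the MCMC posterior machinery of the original model class: the package
reports ML sequences and ML assignments, not positional credible intervals
— a deliberate scope decision; `optimize_sequence()` flags exact ties
between distinct restart optima as `degenerate`.

Subtypes are grown hierarchically. The C-subtype model seeds the (C+1)
model by splitting the subtype with the largest membership. The **primary
split is 2-means on row-normalised z profiles** — normalising each
patient's z-vector to unit length removes overall severity (stage) and
leaves atrophy *shape*, which is what distinguishes subtypes; random
bipartitions are used as additional split starts. A purely random split of
a balanced mixture is almost exactly symmetric, leaving EM a very weak
gradient, and in development runs it reliably converged to blended
sequences; the shape-based split fixes the basin of attraction and the EM
then only polishes. Each split start is refined by full EM — responsibilities
and mixture fractions in the E/M steps, sequences re-optimised by
warm-started climbs under the responsibility weights — and the best start
wins. The EM trace is monotone non-decreasing (asserted to 1e-9 in tests).

The number of subtypes minimises
$\mathrm{BIC}_C = -2\log L_C + P_C \log n$ with
$P_C = C \cdot N + (C-1)$: one positional degree of freedom per event per
subtype plus the free mixture fractions. The parameter-count convention is
explicit and overridable (`select_model(n_params=)`) because any such count
for a discrete permutation space is a convention, not a theorem. Ties go to
the smaller C.

Assignment (`assign_subjects()`) is maximum likelihood: subtype
$\arg\max_c f_c P(x \mid S_c)$, then the MAP stage of that subtype's stage
posterior. Ties break deterministically toward the lower subtype index and
lower stage and are flagged — an all-zero z-row, for instance, fits every
subtype equally at stage 0 and is flagged rather than silently resolved.
Controls never enter the fit; they define the z reference only.

## 4. Permutation-based stage-association scans

`permutation_scan()` relates assigned stage to any unit matrix (region
volumes; all $R(R-1)/2$ connectome edges — 4560 for 96 regions). Both stage
and units are residualised on covariates, then Spearman-correlated with
average ranks for ties (integer ML stages tie often, so the tie convention
matters and is used throughout). Default covariate sets follow the
measurement model: volumes scans use age, sex, handedness, TIV;
connectivity scans use age, sex, handedness, scanner.

Decisions taken where the procedure was open:

* **Permuted quantity**: the residualised stage vector is shuffled against
  the fixed unit residuals. The Freedman–Lane scheme (permuting residuals
  under the reduced model and refitting) is a known alternative and is
  *not* implemented; for a pure residual-rank correlation the two coincide
  in the statistic being permuted.
* **Two-sided on |ρ|**: "exceeding" is read as ≥ on the absolute
  correlation, since signed effects in both directions are of interest.
* **Add-one smoothing**: $p = (1 + \#\{|\rho_b| \ge |\rho_{obs}|\})/(B+1)$,
  so p-values are valid and never exactly zero; an exact-proportion mode
  exists (`p_mode = "proportion"`), and the exhaustive mode ($n \le 8$,
  all $n!$ permutations) reports exact proportions in which the identity
  permutation guarantees $p \ge 1/n!$.
* **One shared permutation stream across units** per scan. This is not an
  optimisation: the max-statistic FWER correction compares each observed
  |ρ| against the permutation distribution of $\max_u |\rho_b^{(u)}|$, and
  that distribution is only meaningful if all units see the same
  permutations. A corollary, tested: per-unit p-values are unchanged
  whether a unit is scanned alone or within a family.
* BH-FDR q-values are computed over the full scan family via
  `stats::p.adjust`; $p_{FWER} \ge p$ per unit by construction.

## 5. Clinical statistics

`compare_groups()` uses the Mann-Whitney U (normal approximation with
continuity and tie correction; exact distribution when both groups have
≤ 12 untied observations) for continuous variables and the Pearson
chi-square without Yates correction for categorical ones — both
conventions configurable, both silent points in the underlying protocol.
Missing rows are dropped per variable and the analysed n always reported.
`ancova_stage_adjusted()` fits `outcome ~ subtype * stage` and reports
**type-II** F tests (via `car::Anova`): robust to unbalanced subtype sizes,
and the interaction term directly answers whether a subtype difference is
stage-dependent. `stage_clinical_regression()` is OLS of an outcome on
stage with age and sex covariates, returning the stage slope in outcome
units per stage.

## 6. The synthetic cohort generator

The generator (`simulate_cohort()` and its parts) emulates the statistical
structure the pipeline assumes, with every stochastic stage drawing a named
sub-stream of one root seed (bitwise reproducibility is tested):

* **Demographics**: control age 34.5 ± 12.8 y, patient age 39.8 ± 10.4 y,
  ~61%/52% male, ~95% right-handed, two scanners with different group
  mixes, TIV ≈ 1.50/1.35 l (male/female) ± 0.11 l.
* **Ground truth**: per-subtype event sequences; patient subtype from the
  mixture fractions; **stage uniform on $0..N$**, matching the model's
  stage prior so that recovery tests probe the estimator, not a
  prior-mismatch artefact. The default two subtypes are contrasting
  progression *waves* — the same staggered threshold pattern with reversed
  biomarker onset order (cortical-first versus subcortical-first). The
  wave stagger matters: if thresholds were laid out in whole-panel blocks,
  the two subtypes' expected profiles would coincide whenever a block
  completes, creating periodically unidentifiable stages; the wave design
  keeps the profiles distinct at every interior stage.
* **Volumes**: controls are the linear covariate predictor plus Gaussian
  residuals (SD 4% of structure volume), which defines the z unit; the
  left/right residuals of a bilateral structure share a symmetric component
  plus an antisymmetric part that cancels in the bilateral average.
  Patients sit at the predictor displaced by
  $-(\text{expected } z + \eta)\,\hat\sigma$, $\eta \sim N(0,
  \texttt{noise\_sd})$ with `noise_sd` = 0.25 z by default — so a patient's
  observed z-score is the trajectory value plus displacement noise.
* **Connectivity**: per-edge fixed population means (Fisher-z ≈ 0.25 ±
  0.15) plus subject noise (SD 0.2). A planted edge adds, for the selected
  patients, a mean shift linear in the *normal scores* of the stage rank,
  scaled through the bivariate-normal identity $r = 2\sin(\pi\rho_s/6)$ so
  the realised Spearman correlation approximates the requested ρ at the
  given noise — verified by Monte-Carlo (mean within ±0.15 at n = 60 over
  20 seeds).
* **Clinical scores**: patient score = baseline + slope[subtype] × stage +
  noise; controls receive norm-referenced values only where a control
  baseline exists (symptom scales stay `NA`); missingness is a per-score
  Bernoulli mask, so downstream statistics must be missing-aware.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: no scanner site effects on volumes, no
spatially correlated residuals between neighbouring regions, no BOLD time
series or motion artefacts behind the connectivity matrices, no
heavy-tailed clinical score distributions, and patients' deviation from
the covariate predictor is purely the planted trajectory. Recovery results
are claims about the estimator under its own generative assumptions, not
about any clinical cohort.

## 7. Problem sizes and numerical choices

Validation runs use deliberately chosen scales: planted-recovery at 13
biomarkers × thresholds 1/2/3 (39 events), n = 300 patients, displacement
noise 0.25 z, 5 hill-climb restarts and 20 EM iterations; scan calibration
at n = 40, 100 units, B = 2000 permutations over 200 replicate cohorts;
power at one planted ρ = 0.7 edge among 99 nulls over 50 seeds. The
pipeline's `default_config()` is demonstration-scale (48 patients, 12
regions, B = 500); B = 20 000 remains the production default of
`permutation_scan()` itself. EM convergence is 1e-6 absolute
log-likelihood; hill-climb move acceptance 1e-9; stage posteriors are
normalised and asserted to sum to 1 within 1e-9; permutation exceedance
comparisons carry a 1e-12 guard so exact ties count as exceeding.

## 8. Known limitations

* Maximum-likelihood sequences only: no positional-variance diagrams or
  credible intervals; the `degenerate` flag is the only uncertainty signal
  for the ordering.
* Greedy search offers no global-optimum guarantee beyond the enumerable
  instances it is tested on; pathological likelihood landscapes could
  require more restarts than the defaults.
* The BIC parameter count for a permutation space is a convention; model
  selection near the decision boundary should be read with that in mind.
* Integer ML stages discard stage-posterior width; downstream rank
  correlations inherit heavy ties at small n.
* Scanner harmonisation of volumes is out of scope; scanner enters only as
  a covariate in connectivity scans.
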