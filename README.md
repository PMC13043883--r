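# sustainz

Subtype-and-stage inference for control-referenced brain atrophy z-scores,
with permutation-based stage-association scans over regional volumes and
functional-connectivity edges.

## The problem

Cross-sectional psychiatric and neurodegenerative cohorts mix patients who
differ both in *which* disease variant they have (subtype) and in *how far*
it has progressed (stage). Analysing such cohorts as a homogeneous group
dilutes any pathological signal. `sustainz` implements the z-score
event-based subtype-and-stage mixture model for cross-sectional data, plus
the downstream statistics needed to relate the inferred stage to other
measurements, and a seeded synthetic-cohort generator for end-to-end
validation.

## The model

Regional volumes are first adjusted for age, sex and total intracranial
volume (TIV = grey + white + CSF) by linear regression **in the control
group only**, and converted to atrophy-positive z-scores

    z = (predicted − observed) / residual SD,

so that volume deficit relative to the control expectation is positive.

Each biomarker *i* contributes one *event* per z-threshold (default z = 1,
2, 3: mild, moderate, severe atrophy). A subtype *c* is an ordering
*S<sub>c</sub>* of all N events; a patient at integer stage *k* has passed
the first *k* events. The expected z of biomarker *i* at stage *k* is
piecewise-linear through (0, 0), each of the biomarker's event positions at
its threshold, and (N, z<sub>max</sub>). With Gaussian observation noise
σ<sub>i</sub> and a uniform stage prior, the likelihood of patient **x** under
subtype *c* is

    P(x | S_c) = 1/(N+1) · Σ_k Π_i Normal(x_i ; E[z_i | S_c, k], σ_i)

and the cohort is modelled as a mixture Σ<sub>c</sub> f<sub>c</sub>
P(x | S<sub>c</sub>). Sequences are estimated by greedy single-event
relocation hill-climbing from random valid restarts; subtypes are grown
hierarchically (splitting the largest subtype, primary split by 2-means on
row-normalised z profiles) and refined by EM; the number of subtypes is
chosen by BIC with P<sub>C</sub> = C·N + (C−1) parameters; patients receive
maximum-likelihood subtype and stage assignments.

Inferred stage is then related to regional volumes, connectome edges
(Fisher-z correlations over all region pairs) and clinical scores by
**partial Spearman correlation**: both variables are residualised on
covariates, then rank-correlated. Significance uses permutation of the
stage residuals (default B = 20 000) with one shared permutation stream
across all test units, giving per-unit p-values, Benjamini–Hochberg FDR
q-values over the scan family, and max-statistic FWER-adjusted p-values
that respect the dependence between units.

## Worked example

```r
library(sustainz)

coh <- simulate_cohort(n_controls = 120, n_patients = 150, n_subtypes = 2,
                       z_thresholds = c(1, 2), noise_sd = 0.25, seed = 42)
fit <- sustain(coh$zscores_patients, max_subtypes = 2, z_thresholds = c(1, 2),
               n_restarts = 4, em_iters = 15, seed = 42)
fit
#> Subtype-and-stage inference fit
#>   patients: 150   biomarkers: 13   events: 26
#>   selected subtypes (BIC): 2
#>  n_subtypes   logLik n_params     BIC
#>           1 -2735.70       26 5601.68
#>           2 -2278.93       53 4823.43
#>   stage range of assignments: 0-26

summary(fit)
#> Selected 2 subtype(s); mixture fractions: 0.510, 0.490
#> ...
#> Earliest events per subtype:
#>   subtype 1: temporal_L(z=1), frontal_L(z=1), frontal_R(z=1), parietal_L(z=1), occipital_L(z=1)
#>   subtype 2: thalamus(z=1), basal_ganglia(z=1), occipital_L(z=1), amygdala(z=1), insula(z=1)

table(estimated = fit$assignments$subtype, planted = coh$truth$subtype)
#>          planted
#> estimated  1  2
#>         1 77  0
#>         2  1 72
```

The generator planted two contrasting progression waves — one starting
cortically, one subcortically. The fit selects two subtypes by BIC (ΔBIC ≈
778), recovers their earliest events (cortical-onset vs
thalamus/basal-ganglia-onset), and assigns 149/150 patients to the planted
subtype. `plot(fit)` draws the per-subtype expected-z heat maps over the
stage axis; `predict(fit, Z)` stages new patients; `permutation_scan()`
relates the assigned stages to any unit matrix.

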