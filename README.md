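# intgrad

Intrinsic neural timescales and hierarchical gradients: estimation,
inference, and a biophysical interpretation layer.

## What this package is for

Resting-state fMRI activity decorrelates at different speeds across the
cortex: sensory regions forget quickly, association regions integrate over
longer windows. The *intrinsic neural timescale* (INT) summarizes this per
voxel or parcel as the repetition-time-scaled area under the initial
positive segment of the autocorrelation function,

```
ACF_k = sum_{t=k+1..T} (y_t - ybar)(y_{t-k} - ybar) / sum_t (y_t - ybar)^2
INT   = TR * sum_{k=1..N} ACF_k,    N = lag before the first ACF_k <= 0.
```

INT rises along sensory-to-prefrontal hierarchies, which makes it a handle
on a clinically important question: do hallucinations and delusions — which
co-occur but can manifest alone — alter neural integration at *different
levels* of those hierarchies? `intgrad` implements the full analysis chain
for that question:

1. **INT estimation** (`clean_bold`, `estimate_int`, `parcellate_map`,
   `icc_reliability`) from cleaned BOLD series, with motion censoring,
   band-pass filtering, hemisphere-averaged parcellation and ICC(2,1)
   reliability.
2. **Hierarchy selection** (`candidate_orderings`, `score_ordering`,
   `select_hierarchy`, `ordering_permutation_null`, `spearman_validate`):
   anatomically constrained orderings of the auditory, visual and
   somatosensory systems scored by mixed-model fits of hierarchical level
   on T1w/T2w and cortical thickness, with permutation nulls.
3. **Symptom-gradient inference** (`fit_parcelwise_glm`, `fit_gradient_glm`,
   `permutation_null_gradient`, `set_level_test`, `bca_ci`,
   `exemplary_profiles`, `rank_binned_profile`): mass-univariate symptom
   regressions, a 54-point symptom-by-level-by-system interaction model
   (42 residual df), joint-symptom-block permutation tests, set-level
   pattern tests, and BCa bootstrap intervals.
4. **Biophysical modeling** (`rate_model`, `calibrate_background`,
   `simulate_network`, `bold_forward`, `estimate_insilico_int`,
   `apply_ei_perturbation`, `fit_ei_parameters`): a hierarchical
   excitatory-inhibitory rate network with rectified f-I curves and
   FLN-routed long-range coupling, a Balloon-Windkessel hemodynamic
   forward model, and grid-search fitting of triangle-shaped
   excitation-inhibition (E/I) perturbations to observed delta-INT
   profiles.
5. **Synthetic data** (`sim_bold_ou`, `sim_cohort`,
   `sim_structural_cohort`, `sim_connectivity`): seeded generators for
   every input — OU time series with known timescales, patient cohorts
   with correlated ordinal symptoms and planted hierarchical-gradient
   effects, structural maps, and tract-tracing-style FLN/SLN matrices —
   so the whole chain runs and is tested end to end with no external data.

## Worked example

Generate a synthetic cohort at the study scale (127 patients, 188 parcels,
hallucination-compressed and delusion-expanded gradients), fit the
parcel-wise symptom model and the gradient model, and test the auditory
effects by permutation:

```r
library(intgrad)
sim <- sim_cohort(seed = 42)
m1 <- fit_parcelwise_glm(sim$int, sim$cohort, design = "M1_primary")
g  <- fit_gradient_glm(m1, sim$hierarchies)
g
#> <gradient_fit> 54 points, 12 coefficients, residual df = 42
#> omnibus F(11,42) = 16.65, p = 5.93e-12
#> Derived hierarchical-gradient effects:
#>                                   estimate     t    f2        p
#> grad_hallucinations_auditory        -0.684 -6.56 1.025 6.21e-08
#> grad_delusions_auditory              0.706  6.77 1.092 3.09e-08
#> interact_auditory                    1.391  9.43 2.116 6.35e-12
#> ...

permutation_null_gradient(sim$int, sim$cohort, sim$hierarchies,
                          terms = c("grad_hallucinations_auditory",
                                    "grad_delusions_auditory",
                                    "interact_auditory"),
                          n_perm = 999, seed = 7)
#> <gradient_perm> 999 surrogates
#>                                   t p_permutation
#> grad_hallucinations_auditory -6.560         0.001
#> grad_delusions_auditory       6.771         0.001
#> interact_auditory             9.426         0.001
```

The hallucination gradient is negative (compression of the INT hierarchy),
the delusion gradient positive (expansion), and their interaction positive,
each beyond all 999 symptom-shuffled surrogates — the planted effect
structure recovered with its direction and significance.

INT estimation itself, on surrogates with known timescales:

```r
y <- sim_bold_ou(timescale = c(0.5, 2), tr = 0.72, n_timepoints = 2500,
                 seed = 3)
estimate_int(y)
#> <int_map> 2 units; median 1.114 s [IQR 0.912], 0 undefined
```

On the biophysical side, `sim_connectivity()` builds a
hierarchy-consistent FLN/SLN set, `calibrate_background()` pins the
network at the 10 Hz (excitatory) / 35 Hz (inhibitory) operating point,
and `estimate_insilico_int()` reads out per-node INT from simulated BOLD
at TR = 2 s, with matched-seed deltas against the unaltered model.

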