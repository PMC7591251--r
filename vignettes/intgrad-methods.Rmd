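---
title: "Methods: intrinsic neural timescales, hierarchical gradients, and the E/I network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intrinsic neural timescales, hierarchical gradients, and the E/I network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices behind
`intgrad`, in the order a resting-state dataset would flow through them. The
package covers four linked analyses: (i) estimation of intrinsic neural
timescales (INT) from fMRI autocorrelation, (ii) data-driven selection of
hierarchical orderings of sensory cortical systems from structural MRI,
(iii) inference on symptom-specific hierarchical INT gradients with
permutation and bootstrap statistics, and (iv) a hierarchical
excitatory-inhibitory (E/I) rate-network simulator with a hemodynamic
forward model used to interpret observed INT changes as local E/I changes.
A fifth component, the synthetic-data generators, produces inputs with the
statistical structure each stage assumes, so the entire chain is testable
without any imaging data.

## 1. The INT estimator

For a demeaned signal $y_t$ with $T$ timepoints, the lag-$k$ autocorrelation
is estimated with the full-series variance in the denominator,

$$\mathrm{ACF}_k = \frac{\sum_{t=k+1}^{T}(y_t-\bar y)(y_{t-k}-\bar y)}
                        {\sum_{t=1}^{T}(y_t-\bar y)^2},$$

and INT is the repetition-time-scaled area under the initial positive
segment,

$$\mathrm{INT} = \mathrm{TR}\cdot\sum_{k=1}^{N}\mathrm{ACF}_k,$$

where $N$ is the lag directly preceding the first non-positive coefficient.
This biased estimator (no lag-dependent re-normalization) is deliberate: it
is the definition used throughout, and the brute-force double-loop oracle in
the test suite pins the vectorized implementation to it at $10^{-10}$.

Three boundary conventions matter in practice:

* **$\mathrm{ACF}_1 \le 0$ gives $\mathrm{INT}=0$** (an empty sum). This is
  distinct from a constant, zero-variance series, whose ACF is undefined;
  such units are flagged and reported as missing, never as 0.
* **Censored frames** enter pairwise-complete: a lag-$k$ product contributes
  only when both frames are retained, and the mean and denominator run over
  retained frames. This avoids manufacturing spurious fast decorrelation at
  censored joins. `censor_mode = "concatenate"` reproduces the naive
  re-indexed alternative for comparison.
* **Maximum lag** is `min(T_retained - 1, ceiling(100 s / TR))`; the sum
  stops at the first non-positive coefficient well before that in any
  realistic signal.

An exponential comparator (`exp_fit = TRUE`) fits $A e^{-k\,\mathrm{TR}/\tau}$
to the initial positive segment by nonlinear least squares; $\tau$ is
initialized from a log-linear fit restricted to coefficients above 0.05,
because the noisy near-zero tail otherwise dominates the starting slope.

### Cleaning

`clean_bold()` applies, in order: nuisance regression (supplied confounds
plus their first backward differences), zero-phase band-pass filtering
(second-order Butterworth run forward and backward, default 0.01-0.1 Hz),
and motion censoring of every volume with framewise displacement above the
threshold (default 0.3 mm) together with both immediate neighbors.
Filtering precedes censoring because the filter needs contiguous samples;
the censor mask then excludes the flagged volumes from all autocorrelation
sums. Fewer retained volumes than confound regressors plus eight aborts
with an "insufficient degrees of freedom" error.

### Parcellation and reliability

Parcel values are unweighted means of member units (no volume weighting);
empty or all-missing parcels yield `NA` with a warning. Left/right pairs can
be averaged into single parcels, matching the 188-parcel scheme
(180 cortical + 8 subcortical) used for cohort analyses. Test-retest
reliability uses the two-way random-effects, single-measure intraclass
correlation ICC(2,1), computed per unit across the subject dimension of two
stacked maps and summarized as median and interquartile range.

## 2. Hierarchy selection from structural maps

Candidate hierarchical orderings of each sensory system are enumerated
under anatomical constraints: two swap pairs per system (e.g. the auditory
belt regions at levels 2/3 and parabelt/retroinsular regions at levels 4/5
around fixed anchors), giving exactly four sensory-cortex candidates, then
two prefrontal extensions placing the downstream areas at levels 8/9.

Each ordering is scored by a linear mixed model predicting hierarchical
level from the T1w/T2w myelin proxy and cortical thickness with a
per-subject random intercept and random slopes for both predictors. The
random-effects covariance is diagonal (independent terms), which stabilizes
fitting at small parcel counts. The score is the squared correlation
between observed levels and conditional (random-effects-included)
predictions; a `r2 = "marginal"` switch scores fixed effects only. Since
all candidates share the same dimensionality, this "variance explained"
comparison cannot systematically favor a candidate by complexity. Exact
ties are broken deterministically (first candidate in canonical enumeration
order) with a warning. Levels are treated as numeric integers, as the
regression formulation implies. If the random-slopes fit fails to converge
it is refit with a random intercept only and flagged.

The permutation null re-scores the cohort under random full permutations of
the levels over all regions of the scored hierarchy, with the one-sided
add-one p-value $(1+\#\{R^2_{null} \ge R^2_{obs}\})/(n_{perm}+1)$.
Numerically tied null values count as exceeding: the level-reversed
assignment produces an exactly tied $R^2$ through a different arithmetic
path, so a small tolerance ($10^{-12}$) keeps the count well defined.
Validation against any parcel metric (group INT, layer-IV gene expression)
uses Spearman correlation with the analogous two-sided permutation p.

A practical note on engines: the permutation machinery is engine-agnostic,
and the calibration-style properties in the test suite (type-I uniformity
over 200 replicate cohorts; 100-seed ordering recovery) run with the
marginal OLS engine, which is hundreds of times faster per refit; the
conditional mixed-model engine is exercised on a smaller number of
replicates. This is purely a problem-size choice for the bundled tests.

## 3. Symptom-specific hierarchical gradients

**M1 (mass-univariate).** Per parcel, ordinary least squares predicts INT
either from the seven symptom scores (patients only, `M1_primary`) or from
the diagnosis flag (`M1_exploratory`), always controlling for age, gender
(binary dummy), mean framewise displacement, and acquisition site
(treatment-coded, largest site as reference). Rank-deficient designs abort
with the collinear columns named. The diagnosis-level "overall effect" is a
count-of-significant-parcels statistic against a diagnosis-shuffled null.

**M2 (gradient model).** The M1 t-statistics of the two focal symptoms,
one per (symptom, level, system) cell, are regressed on symptom, numeric
level and system with full interactions. Prefrontal parcels shared across
systems contribute one point per system, so the standard design has
$2 \times 9 \times 3 = 54$ points, 12 coefficients and 42 residual degrees
of freedom. (The analytically correct df is reported throughout.)
Single-symptom (27 points, 21 df) and two-system (36 points, 28 df)
variants use the same machinery. Rather than requiring reference-level
gymnastics, the fit also reports the substantive quantities directly as
linear contrasts: the per-system hierarchical-gradient slope of each
symptom and the per-system symptom-by-level interaction (second minus first
symptom). Cohen's $f^2$ is computed by explicit full-versus-reduced refit,
$(R^2_{full}-R^2_{reduced})/(1-R^2_{full})$, which for a single contrast
equals $t^2/\mathrm{df}$.

**Permutation inference.** Surrogates jointly permute the rows of the
seven-symptom block across patients, leaving INT and covariates in place,
so every surrogate preserves the inter-symptom correlation matrix exactly.
M1 and M2 are refit per surrogate and two-sided add-one p-values are
reported; all null draws are retained. Identical seeds give bit-identical
results. A caution worth knowing: because t-statistics are scale-free,
permutation nulls of the gradient model inherit partial linear structure
from the finite-sample correlation between shuffled and true scores, so
planted effects of unrealistically large size do *not* drive p to its
minimum; the machinery is calibrated (type-I error at nominal level), which
is the property that matters.

**Set-level tests.** The family-wise probability of a result *pattern* is
estimated by declaring, within each surrogate, an effect significant when
it exceeds the two-sided 95% plug-in thresholds of its own null
distribution with the expected sign, and counting surrogates that satisfy a
conjunction of "at least k of m effects" clauses. The plug-in threshold is
a maxT-style approximation that avoids nested permutation; it is an
approximation and is labeled as such.

**BCa intervals.** Patients are resampled with replacement; M1 and M2 are
refit per draw; the accelerated bias-corrected interval uses
$z_0 = \Phi^{-1}(F_{boot}(\hat\theta))$ (ties split) and the jackknife
skewness $a = \sum d_i^3 / (6 (\sum d_i^2)^{3/2})$. Draws in which a site
level vanishes drop that dummy and are flagged; degenerate bootstrap
distributions collapse the interval to a flagged point. The generic core
is exposed as `bca_interval()` and validated against an exhaustive
enumeration of a four-point bootstrap in the tests.

**Exemplary cases.** Fitted INT per hierarchy level for the four
(hallucination, delusion) score settings $(0,0), (5,0), (0,5), (5,5)$ with
every other predictor at the patient-sample mean (site dummies at their
sample proportions). By linearity the deltas are five times the fitted
symptom coefficients and the combined case is exactly the sum of the
single-symptom deltas.

**Rank-binned control.** Voxels ranked by a reference INT map are split
into equally sized bins (`floor(V / n_bins)` each, remainder to the last
bin with a warning), voxel t-statistics are averaged per bin, and the
gradient model runs with bin index as level.

## 4. The hierarchical E/I rate network

Each node has an excitatory and an inhibitory population with first-order
rate dynamics driven by rectified input currents; local excitatory and
long-range inputs are scaled by $(1+\eta h_i)$, where $h_i \in [0,1]$ is
the node's hierarchy value. Long-range input is excitatory, routed by the
row-normalized FLN matrix, and targets both populations. The parameter set
is the printed one: $\tau_E = 20$ ms, $\tau_I = 10$ ms,
$\beta_E = 0.066$, $\beta_I = 0.351$ Hz/pA, $w_{EE} = 24.3$,
$w_{IE} = 12.2$, $w_{EI} = 19.7$, $w_{II} = 12.5$, $\mu_{EE} = 33.7$,
$\mu_{IE} = 25.3$ pA/Hz, $\eta = 0.68$.

**Hierarchy from tracing data.** Hierarchy values are fit by logistic
regression of the supragranular labeled-neuron fraction (SLN) on a signed
node-indicator design (+1 target, -1 source, one node's value fixed as the
gauge), each projection weighted by the logarithm of its FLN. Raw
log-FLN weights are negative, so they are shifted to be positive as
$\log \mathrm{FLN} - \log(\min \mathrm{FLN}) + 1$, which preserves the
ordering the weighting is meant to express; the recovered values are
min-max normalized to $[0,1]$. Recovery from noiseless logistic SLN is
exact up to this affine gauge.

**Calibration.** Background currents are solved in closed form so that
every excitatory population fires at 10 Hz and every inhibitory population
at 35 Hz, with rectifications active and long-range input included. The
linearized system at the resulting fixed point must have all eigenvalues in
the left half-plane, otherwise calibration aborts ("unstable operating
point"). Perturbed models keep the unaltered background, so their operating
point shifts; their fixed point is found by an active-set iteration over
the rectification branches (populations whose branch solution turns
negative are clamped to zero and the reduced system re-solved), with a
noiseless-relaxation fallback if the active set cycles.

**Integration.** Euler-Maruyama with default `dt` = 0.2 ms for the rate
equations; white noise enters the external current of both populations
with the rate-equivalent amplitude `noise_sd` (default $10^{-5}$ Hz, the
printed resting-state value) converted through the f-I slope and scaled by
$1/\sqrt{dt}$ so the integrated variance is step-size invariant. The
printed noise units are ambiguous between current and rate; the
rate-equivalent reading is used and documented here. Simulations start at
the model's fixed point, and the simulated autocovariance is pinned to the
analytic Lyapunov solution of the linearized system in the tests.

**Hemodynamics.** The vasodilatory-signal / inflow / volume /
deoxyhemoglobin ODE system is integrated per node on the recorded rate
grid (default 1 ms), driven by the deviation of the excitatory rate from
its steady-state baseline — the baseline subtraction is required for the
resting fixed point of the hemodynamic system to correspond to zero BOLD.
Constants are the standard 3 T set: $\kappa = 0.65$, $\gamma = 0.41$
s$^{-1}$, $\tau_{MTT} = 0.98$ s, $\alpha = 0.32$, $\rho = 0.34$,
$V_0 = 0.02$, $\vartheta_0 = 40.3$ Hz, $r_0 = 25$ Hz, $\varepsilon = 1.43$,
and an echo time of 0.04 s (a typical 3 T value; the k-coefficients are
always derived from the printed formulas, never set directly). BOLD is
point-sampled at the output repetition time (2 s), matching the in vivo
processing; integration failure (volume or deoxyhemoglobin reaching zero)
aborts with a diagnostic suggesting a smaller step.

**In-silico INT and perturbations.** The INT estimator from Section 1 is
applied to the simulated BOLD at TR = 2 s, with the ACF averaged across
repetitions before the sum. The unaltered reference uses the same noise
seeds, so a zero-magnitude perturbation gives a delta of exactly zero — a
regression guard for the seed plumbing. E/I perturbations follow a
triangle profile over hierarchy levels 1-9 (peak level 1-8, peak magnitude
0-40%, minimum magnitude -30-40%), applied by scaling $w_{IE}$ down or
$w_{EE}$ up per node; the top node (46d) is always fixed because its strong
coupling destabilizes the model under even ~1% changes. Near the top of
the hierarchy the critical cut is intrinsically small (about 7.5% at level
8 here), so large high-level perturbations are rejected by the stability
check rather than simulated; this mirrors the small fitted magnitude at
level 8.

**Fitting E/I parameters.** The two perturbations (one per symptom) are fit
to a 6-level x 3-case delta-INT target by an outer grid over the two peak
levels and an inner optimization of the four magnitudes, minimizing the sum
of squared errors over the 18 points with common random numbers (the same
noise seeds for every objective evaluation), which makes the whole fit
deterministic given one seed and gives the generating parameters an exact
zero objective in self-consistency experiments. The inner optimizer is a
two-stage scheme: a deterministic coarse lattice over peak-magnitude pairs
locates the basin (unstable combinations score infinity and are skipped),
then bounded Nelder-Mead — the bounds imposed through a logistic
reparametrization — refines the magnitudes. A plain multi-start
Nelder-Mead was found to stall in the nearly flat low-level directions of
the objective; the lattice stage removes that failure mode at a fraction of
the evaluation budget.

## 5. Synthetic data: what it emulates, and what it does not

**Time series.** Ornstein-Uhlenbeck surrogates use the exact
discretization $x_{t+1} = \phi x_t + \sqrt{1-\phi^2}\,\varepsilon_t$ with
$\phi = e^{-\mathrm{TR}/\tau}$, so the ground-truth lag-$k$ autocorrelation
is exactly $\phi^k$ and the implied discrete-sum INT is
$\mathrm{TR}\,\phi/(1-\phi)$.

**Cohorts.** Seven ordinal symptom scores come from a thresholded Gaussian
copula. The marginal cutpoints are fixed to match the coarse shape of the
observed ratings (means near 2.2-2.4, SD near 1.7-1.9); the latent
hallucination-delusion correlation is calibrated by quadrature — bivariate
normal cell probabilities and the grade transform give the population
Spearman correlation of the discretized pair in closed form, inverted by
root finding — so the generated scores hit the target rank correlation
(default 0.62) without simulation tuning. INT matrices carry a base
hierarchical gradient (0.55 s + 0.03 s/level), a hallucination effect with
a negative level slope in the auditory system (-0.005 s per score-point per
centered level) and a delusion effect with a positive slope in the auditory
and somatosensory systems (+0.004), a global diagnosis effect (-5%),
covariate and site effects, and between-subject (0.10 s) and within-parcel
(0.06 s) Gaussian noise. The effect slopes were chosen a priori so that the
parcel-level t-statistics at n = 127 have the magnitude reported in vivo
(|t| around 3-5 at the extreme levels); with those conditions the full
pipeline recovers the planted gradient directions at permutation p < 0.05
in essentially every replicate.

**Structural maps.** T1w/T2w decreases and thickness increases linearly
with level, plus per-subject random intercepts and slopes and measurement
noise — exactly the structure the mixed-model scoring assumes.

**Connectivity.** SLN follows the logistic of the hierarchy difference with
link noise, clipped to (0.01, 0.99); FLN weights are log-normal with a
distance-decaying mean, a feedback penalty growing with hierarchical
distance, and row normalization. The default layout deserves explanation,
because it is the one place where a naive generator fails to reproduce the
model class's behavior. With the printed parameters, a plain 6-node
distance-decay network is either unstable under the study-scale
perturbations or too fast for BOLD INT at TR = 2 s to resolve the
hierarchy: neural timescales below roughly 0.4 s are washed out by the
hemodynamic kernel (we measured the INT-versus-timescale response curve of
the forward model directly). The tract-traced network solves this with a
strongly recurrent association cluster that carries a slow, near-critical
mode, of which only six nodes are perturbed. The generator therefore adds a
three-node self-contained "core" cluster high in the hierarchy: its
internal row-normalized connectivity has Perron eigenvalue exactly one, so
its stability margin — and hence its timescale — is set by its hierarchy
value alone (`core_h = 0.77`), independent of the weight noise. Matched
nodes receive a hierarchy-graded share of their long-range input from the
core (`core_mix`, 2% at V1 up to 18% at 46d) and project nothing back, so
the slow mode expresses increasingly strongly up the hierarchy while E/I
perturbations of the matched nodes cannot destabilize it. The matched
hierarchy values are (0, 0.125, 0.375, 0.5, 0.8, 1); level 8 sits at 0.8
rather than 0.875 because its critical E/I cut at 0.875 (≈5.5%) would
leave no margin for the ~4% perturbation the high-level fit requires.

What the generators do **not** emulate: spatial smoothness or artifact
structure of real volumes (parcels are independent given the planted
structure), scanner-specific confounds beyond additive site offsets,
non-Gaussian INT noise, or the full 29-node anatomy. Passing tests
therefore demonstrate that the estimators and inference machinery do what
they claim under the stated generative assumptions — not that real data
meet those assumptions.

## 6. Problem sizes used by the bundled tests

The test suite and acceptance checks run everything at desk scale, as a
deliberate design choice: rate-network simulations of 1.5-8 simulated
minutes per repetition with 1-2 repetitions and steps of 0.5-1 ms
(averaging ACFs across up to 10 noise seeds where a population-level
property is asserted); permutation counts of 199-1000 with 100-200
replicate cohorts for calibration properties; bootstrap counts of 200-399;
and the E/I grid search on the {1,8} x {1,8} peak grid with a 3 x 3
magnitude lattice and 60 Nelder-Mead iterations. Defaults in the functions
themselves are the study-scale values (30 simulated minutes, 5 repetitions,
0.2 ms steps, 10,000 permutations or bootstraps).

## 7. Known limitations

* The set-level "significant within surrogate" rule uses plug-in
  percentile thresholds from the same null draws, not nested permutations.
* The BOLD readout at TR = 2 s cannot resolve neural timescales below
  ~0.4 s, so low-level perturbation signatures are weak; the E/I fit
  works through the common-random-numbers objective, but magnitudes at low
  levels are the least constrained part of the fit — visibly so in the
  width of its recovery tolerance.
* The permutation null of the gradient model conditions on the observed
  symptom correlation structure (rows permuted jointly); surrogates do not
  reshuffle covariates, matching the described procedure.
* Mixed-model scoring treats levels as numeric and assumes independent
  random effects; orderings whose structural gradients are strongly
  nonlinear in level would be scored suboptimally by both engines alike.
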