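---
title: "Box-Behnken response-surface modelling and desirability optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Box-Behnken response-surface modelling and desirability optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbdopt)
```

## The problem

Nanoparticle formulations are tuned over a handful of composition
factors, and the responses that matter -- particle size (PS), zeta
potential (ZP), entrapment efficiency (EE) -- pull in different
directions: smaller particles, higher surface charge and higher drug
entrapment are all wanted at once. Response-surface methodology (RSM)
handles this with a small designed experiment, a low-order polynomial
model per response, and a multi-response desirability criterion that
turns "minimize PS, maximize ZP and EE" into a single objective over the
factor space.

`bbdopt` implements that computational arm end to end for the
three-factor case, and ships a worked study -- a 17-run Box-Behnken
formulation study of berberine-loaded lecithin-chitosan nanoparticles
(factors: lecithin 100-200 mg, chitosan 10-40 mg, isopropyl myristate
1-3 % w/v) -- as its running example and test bed.

## The design

A three-factor Box-Behnken design (BBD) consists of the 12 edge
midpoints of the factor cube (each factor pair at its four +/-1 sign
combinations with the third factor at 0) plus replicated center runs,
17 runs with the usual 5 center replicates:

```{r}
des <- bbd_design(ber_factors(), n_center = 5)
des
```

Factor levels are *coded*: `coded = (actual - center) / half-range`, so
the design columns take values in {-1, 0, +1}, sum to zero, and are
mutually orthogonal together with the pairwise products. Orthogonality
is what makes the fitted coefficients directly comparable across terms
and stable under model reduction. `bbd_design()` emits runs in a fixed
canonical order (pair blocks (1,2), (1,3), (2,3), each in (-,-), (+,-),
(-,+), (+,+) order, then the centers); published tables are usually run
in randomized order, so the shipped study carries a permutation fixture
mapping one order to the other. Center replication is what funds the
pure-error estimate below; `n_center = 5` gives 4 pure-error degrees of
freedom.

Asymmetric level spacing (center not midway between low and high) is
accepted with a warning: the coding formula still applies, but the coded
center then corresponds to a different physical point than the midpoint
of the range.

## The models

Each response is modelled by a *reduced* polynomial in the coded
factors, fitted by ordinary least squares: a subset of the full
quadratic vocabulary {x1, x2, x3, x1:x2, x1:x3, x2:x3, x1^2, x2^2,
x3^2} plus an always-present intercept. Responses that live on a
positive, right-skewed scale (here ZP) can be fitted on the natural-log
scale (`transform = "ln"`); predictions are back-transformed with a
plain `exp()`, with no lognormal bias correction, so a point prediction
is the median rather than the mean of the implied lognormal -- the
convention of the common DoE packages and the scale on which the worked
study's expected values are reported.

```{r}
study <- ber_study()
ps <- fit_rsm(study$data, "PS", c("x1", "x2", "x3"))
summary(ps)
```

Standard errors come from the unbiased residual variance and the
diagonal of the inverse Gram matrix; t-statistics (coefficient / SE) are
the *standardized effects* that `standardized_effects()` ranks into a
Pareto ordering, flagged against the two-tailed 95 % critical t with the
fit's residual degrees of freedom. On the worked study, chitosan amount
dominates PS and ZP while the oil (IPM) level dominates EE.

**Lack of fit.** Replicated runs let the residual sum of squares be
split into *pure error* (within-replicate-group scatter, identified by
exact coded-row equality) and *lack of fit* (everything the model fails
to capture beyond that scatter). `lack_of_fit()` reports the F-test of
the two mean squares; a p-value of 0.1 or more is the usual reading of
"the model's misfit is indistinguishable from replicate noise". All
three reduced models of the worked study clear that bar. Without
replicated runs the test is undefined and the function says so rather
than returning a silent zero.

**Term selection.** The worked study's term sets (PS linear; ln ZP
linear + chitosan quadratic; EE linear + chitosan:IPM interaction + IPM
quadratic) are available as fixed specs via `ber_model_specs()` and are
what every validation against the printed study uses. When the term set
is open, `select_terms()` backward-eliminates from the full quadratic at
alpha = 0.05 with hierarchy enforced (a main effect stays while any of
its children remain), ties broken alphabetically so the procedure is
deterministic. Backward elimination from the full quadratic is our
choice among the several defensible reduction schemes; on an orthogonal
BBD the retained estimates are identical whichever nested route is
taken, which is why the fixed and selected specs agree on the worked
study.

Two printed-value caveats found while validating, both traceable to
rounding in the published inputs rather than to the fitting: refitting
the EE term set to the published runs reproduces every orthogonal
coefficient to the printed precision but gives an intercept of 72.566
(printed: 72.5489) and an IPM quadratic of -7.489 (printed: -7.47264)
-- these two columns of the EE model matrix are the non-orthogonal ones
(intercept and a pure quadratic), so they absorb any rounding of the
response column. The study's tabulated "expected" checkpoint values
likewise differ by up to ~1 nm from evaluating the printed equations at
the printed optimum. The package treats the published
estimated/expected pairs as data (shipped in the checkpoint fixture)
and recomputes prediction errors from them exactly.

## The optimizer

Each goal maps a predicted response to a desirability in [0, 1] by a
one-sided Derringer-Suich ramp: 0 at or beyond the unfavourable anchor,
1 at or beyond the favourable one, `((v - low)/(high - low))^weight`
between (mirrored for minimization). The overall desirability D is the
weighted geometric mean, so any response at desirability 0 vetoes a
candidate point. Anchors default to each response's observed min/max
over the run table -- the convention of common DoE software, and the
natural choice when, as here, the study states goals but no explicit
limits -- and weights default to 1 (equal importance).

The search is an exhaustive regular grid over the coded cube (default
spacing 0.01, evaluated in slices to keep memory flat) followed by a
Nelder-Mead polish started from the best grid point, with evaluations
clamped to the cube; everything is deterministic, and exact grid ties
resolve by lower predicted value of the first minimized response, then
lexicographically smallest coordinates. A grid-plus-polish search is
deliberate: D is cheap to evaluate, non-smooth at the ramp anchors
(where gradient methods stall), and the grid guarantees the global cell
before the polish sharpens it.

```{r}
zp <- fit_rsm(study$data, "ZP", c("x1", "x2", "x3", "x2^2"), "ln")
ee <- fit_rsm(study$data, "EE", c("x1", "x2", "x3", "x2:x3", "x3^2"))
opt <- optimize_desirability(
  list(PS = ps, ZP = zp, EE = ee),
  list(desirability_goal("PS", "minimize"),
       desirability_goal("ZP", "maximize"),
       desirability_goal("EE", "maximize")))
opt
```

Lecithin lands on its lower bound (100 mg) -- its PS and EE effects are
small while its ZP effect is negative, so nothing pulls it off the
boundary -- matching the worked study's optimum coordinate. The interior
coordinates (chitosan, IPM) depend on the anchors and weights, which the
study does not state; with the defaults the IPM optimum (~2.59 % w/v)
agrees with the study's 2.6 % and chitosan lands near center.

**Checkpoint validation.** `validate_checkpoint()` compares measured
responses of a confirmation formulation with model predictions via the
absolute prediction error `|estimated - expected| / estimated * 100`,
flagging responses above 10 % -- a conventional acceptability gate for
RSM confirmation runs.

## Formulation metrics

Three closed-form metrics round out the pipeline.
`entrapment_efficiency()` and `wound_closure_rate()` are the standard
relative differences (both scale-invariant). `cumulative_release()`
converts sampled receptor concentrations from a diffusion-cell
experiment to released percentages of the dose; the literal reading
(`Q_i = C_i x V_receptor`) is the default, and an opt-in
`correct_sampling` flag additionally credits the drug mass withdrawn in
earlier samples -- with replacement sampling the literal formula
understates release at later time points by exactly that sum. The
corrected series is non-decreasing for any physically consistent
profile. The flag is off by default to keep the default faithful to the
conventional direct reading; whether a given published curve was
corrected is usually unstated.

## Synthetic data and what the tests show

`simulate_bbd_responses()` generates run tables from a known truth: a
coefficient vector on the coded vocabulary plus homoscedastic Gaussian
noise on the transform scale (ln-scale truths exponentiate after the
noise, giving log-normal responses). `ber_truth_models()` wraps the
worked study's fitted equations as default truths, with noise SDs of 6
nm (PS), 0.04 ln-units (ZP) and 4 percentage points (EE) -- typical
replicate SDs from the study's run table, chosen once as the simulation
operating point. Homoscedasticity is the simplest structure consistent
with that table, which reports per-run SDs but no replicate-level
model; real tables show run-to-run SD variation that the generator does
not emulate, so passing recovery tests demonstrate correctness of the
estimator under the stated noise model, not robustness to
heteroscedasticity.

`recovery_study()` repeats simulate-then-fit (replicate r reseeds with
`seed + r`, so replicates are order-independent), reporting per
coefficient the empirical bias, RMSE and 95 % CI coverage. At the
default operating point with 500 replicates, coverage sits within the
binomial band around 0.95 and biases within two Monte-Carlo SEs of zero;
because OLS is linear in the noise, doubling the noise SD doubles every
RMSE exactly under shared seeds -- both are exercised in the test suite.
Problem sizes throughout the tests (17-run designs, 100 random
design/spec draws for the oracle comparison, 500 Monte-Carlo replicates)
are chosen to estimate these properties tightly while keeping the whole
suite fast.

## Numerical choices

* Fitting uses QR (as `lm` does); the test suite checks it against an
  explicit normal-equations solve to 1e-9 relative tolerance on random
  problems. Coefficients are kept at full double precision; printing
  rounds to 6 significant figures.
* Coded levels are exact rationals of the coding formula; no rounding on
  construction, so center rows compare exactly equal when replicate
  groups are identified.
* The residual decomposition `residual = lack-of-fit + pure error` holds
  to 1e-9 relative tolerance by construction and is asserted.
* Degenerate inputs fail loudly: singular model matrices, non-positive
  responses under `ln`, designs without replicates for lack of fit,
  release profiles exceeding the dose.

## Limitations

Three factors only (the design family the package targets); no
central-composite or D-optimal alternatives; one-sided desirability
ramps only (no two-sided target goals); no Box-Cox search beyond the
identity/ln pair; no release-kinetics model fitting. The optimizer
searches the coded cube -- constraints outside it are out of scope.
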