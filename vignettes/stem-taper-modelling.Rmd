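---
title: "Stem taper modelling: taper equations, pooled machine learning, and the evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stem taper modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Stem taper is the decrease of outside-bark diameter $d$ with height $h$
along a tree bole. A taper model predicts $d(h)$ from two cheap tree-level
measurements — diameter at breast height ($dbh$, measured at 1.3 m, in cm)
and total height ($ht$, in m) — and thereby also predicts merchantable and
total stem volume, because volume is the integral of cross-sectional area:

$$ Vac(h) = \int_{0.1}^{h} K\, d(x)^2\, dx, \qquad K = \pi/40000, $$

with $d$ in cm, heights in m and $Vac$ in m³. The lower bound is the stump
height (0.1 m): all volumes in this package are referenced to it, and the
stump itself is excluded.

In structurally complex tropical vegetation — a savanna (cerrado) with
short, often multi-stemmed shrubs and trees, a seasonal semi-deciduous
forest, and a dense rainforest with buttressed stems — no single parametric
taper law fits all sites well. The package therefore implements and compares
three approaches on equal terms:

1. **TM** — six literature taper equations, fitted *per forest type* (a
   site-specific model) by Gauss-Newton nonlinear least squares and ranked
   by AICc;
2. **NN** — one pooled multilayer perceptron per target across all forest
   types, with forest-type dummies as inputs;
3. **RF** — one pooled random forest per target, same inputs.

Targets are $d$ (cm) and $Vac$ (m³) at each measurement height.

## Stem geometry and multi-stemmed trees

Field volumes are constructed from measured profiles with Smalian's
formula: a section of length $L$ with end diameters $d_1, d_2$ has volume
$L \cdot (K d_1^2 + K d_2^2)/2$. Above the last measurement point the stem
is treated as a cone. Smalian's rule over-estimates a true conic frustum
(arithmetic mean of end areas rather than the area at the mean diameter),
which is why the field protocol uses short (1 m) sections; the test suite
checks the convergence of the Smalian total to the exact area integral as
spacing shrinks.

Multi-stemmed trees (common in cerrado) are combined by the **equivalent
diameter** $D_e = \sqrt{\sum_i d_i^2}$, which preserves basal area exactly;
the tree's total volume is the sum of its stems' volumes, and the two
operations commute (an identity the tests assert). The breast-height
predictor of a multi-stem tree is the equivalent diameter of its stems at
1.3 m — the source protocol does not pin the height at which stems are
combined, and 1.3 m is the only choice consistent with using the result in
place of $dbh$.

## The six taper equations

The printed source of the six forms is typographically damaged (exponent
groupings lost), so each form is reconstructed to its canonical published
shape and isolated in a single function (`taper_form_*` in
`R/taper_models.R`) so that any correction is a one-line change:

| name | parameters | form |
|---|---|---|
| demaerschalk | 4 | $10^{\beta_0} dbh^{\beta_1} ht^{-\beta_2} (ht-h)^{\beta_3}$ |
| biging | 2 | $dbh\{\beta_0+\beta_1\ln[1-q^{1/3}(1-e^{-\beta_0/\beta_1})]\}$ |
| bi | 7 | trigonometric variable-exponent form on $\ln\sin(\pi q/2)/\ln\sin(\pi p/2)$ |
| lee | 5 | $\beta_1 dbh^{\beta_2}(1-q)^{\beta_3 q^2+\beta_4 q+\beta_5}$ |
| kozak | 9 | variable-exponent form on $X=(1-q^{1/3})/(1-p^{1/3})$ |
| metcalf | 1 | $dbh\, e^{-\beta_1(h-1.3)}$ |

with $q=h/ht$ and $p=1.3/ht$. The biging printed string is ambiguous about
the self-referencing exponential; $e^{-\beta_0/\beta_1}$ is used, which
gives the form its characteristic property $d \to 0$ as $q \to 1$.
Metcalf's $D$ is read as $dbh$, so that form passes through $dbh$ at
breast height exactly.

### Fitting and selection

Fitting minimises $\sum (d_{obs}-d_{pred})^2$ by Gauss-Newton iteration:
central finite-difference Jacobian (relative step $10^{-6}$), normal
equations solved through an SVD with a condition-number guard ($>10^{12}$
declares non-convergence), step-halving line search (up to 20 halvings),
convergence at relative SSE decrease $<10^{-8}$, at most 50 iterations.
Non-convergence is an expected *outcome* for the complex variable-exponent
forms on irregular stems, so it is reported, tallied and rendered as a
"no convergence" marker, never raised as an error. During fitting,
negative or non-finite predictions contribute their raw residual so the
optimizer feels the penalty; clipping at zero applies only at prediction
time.

Model ranking uses the least-squares AICc,
$n\ln(SSE/n) + 2k + 2k(k+1)/(n-k-1)$ with $k$ = parameter count + 1 (the
error variance counts). The additive constant $n\ln(2\pi)+n$ is dropped:
it is common to every candidate on the same data, so ranking — and the
per-forest "wins" tally that picks the overall best model — is unaffected,
but absolute AICc values are shifted relative to implementations that keep
it. Ties within $10^{-6}$ credit all tied models and are flagged.

$Vac$ under a fitted law is obtained by adaptive composite Simpson
quadrature of $K d(h)^2$ to $10^{-9}$ m³; the cross-validation harness
uses a cumulative fixed-grid Simpson variant (1-cm grid) that computes all
heights of a tree in one pass and is tested against the adaptive scalar
integrator.

## The pooled machine-learning regressors

Inputs are always the 6-vector $(dbh/100,\ ht/10,\ h/10,\ d_1,\ d_2,\ d_3)$
with one-hot forest dummies (cerrado, semi-deciduous, rainforest). The
scalings put typical values near $[0,1]$ but are *not* a normalisation:
the largest trees exceed 1 (e.g. $dbh = 157$ gives 1.57).

**NN.** Two logistic hidden layers of 25 and 10 neurons. The output unit is
linear: the hidden layers are specified as logistic but a logistic output
could never emit a 157-cm diameter, so the only consistent reading is an
unbounded output. Targets are used unscaled. Training is full-batch
resilient backpropagation with weight backtracking (Rprop+), with the
standard constants of that algorithm family: initial step 0.1,
$\eta^+{=}1.2$, $\eta^-{=}0.5$, steps bounded to $[10^{-6}, 50]$. Training
stops when $\max_w |\partial SSE/\partial w| < 0.01$, with a 10,000-epoch
safety cap (the gradient criterion alone need not terminate). Each training
event runs 50 independent Gaussian weight initialisations
($\mathcal N(0, 0.5^2)$) and keeps the restart with the lowest *training*
SSE (whether the selection should use validation SSE is unspecified in the
source protocol; training SSE keeps the validation set untouched).

**RF.** 300 trees, bootstrap resampling, 2 candidate predictors per split
among the 6 inputs, SSE split criterion, and nodes with fewer than 5
observations never split. Prediction is the mean of leaf means — which
entails the *bounded-range property*: the forest can never predict outside
the training target range. That property is asserted as an invariant, and
it is the structural mechanism behind the RF's characteristic residual
trend (over-prediction of the smallest diameters, under-prediction of the
largest), which the acceptance suite reproduces on synthetic data.

Both engines are implemented in C++ (Rcpp/RcppArmadillo) and draw all
randomness from R's RNG, so `set.seed()` makes training bit-reproducible.

## Evaluation protocol

Metrics, pooled over all measurement points $j$ of all trees $i$ in the
evaluated partition ($N$ points):

$$ RMSE = \sqrt{\tfrac1N \sum\sum (\hat Y_{ij}-Y_{ij})^2}, \quad
   Bias = \tfrac1N \sum\sum (\hat Y_{ij}-Y_{ij}), \quad
   EF = 1-\frac{\sum\sum (Y_{ij}-\hat Y_{ij})^2}{\sum\sum (Y_{ij}-\bar Y)^2}. $$

The divisor is $N$ (not $N$ minus a parameter count — the protocol does not
say otherwise), and bias is signed so that positive means over-prediction.

`cross_validate()` repeats, 500 times by default: set aside 25% of the
*trees* (not rows) for validation, fit everything on the remaining 75%,
compute the metrics on both partitions, for both targets and all three
methods. Splitting is stratified by forest type — the protocol does not
state stratification, but without it a small site can lose so many trees
that its site-specific taper fit degenerates, so stratification is the
design choice here and is what the split-integrity tests assert. The taper
model *form* per site is selected once, on the full data by AICc, before
any splitting (mirroring the study design in which model selection precedes
the method comparison); only its parameters are refitted per iteration.
Iterations in which the per-site taper refit fails to converge are flagged
and excluded from summaries, with the count reported. Summary statistics
are arithmetic means over iterations; the raw per-iteration stream is kept
so distributional claims (skew, bimodality) remain inspectable.

## The synthetic world

`generate_inventory()` emulates the three-site field study so the whole
pipeline runs and is testable without the deposited field data: 52/53/55
taper trees with dbh ranges 5.0–52.0, 5.0–135.0 and 5.1–157.0 cm, height
ranges 1.7–17.0, 2.0–24.0 and 1.4–26.0 m, plus walk-through censuses of
531/446/540 stems. Profiles are drawn from a known lee-family taper law
(the pattern a flexible variable-exponent family fits well), with
forest-specific coefficients giving neiloid-like bases; heights follow
$ht = a\,dbh^{0.45}$ allometries with lognormal scatter chosen to span the
stated ranges. Measurement heights follow the field protocol: 0.1, 0.3,
0.7, 1.3 m, then 1-m steps until the true diameter falls below the 5-cm
top limit. Cerrado trees are multi-stemmed with probability 0.25, splitting
basal area across stems so the equivalent diameter reproduces the drawn dbh
exactly; rainforest stems get a 15% butt-swell multiplier below breast
height emulating buttressing. Measurement noise is multiplicative Gaussian
with sd 2% of the true diameter — a stand-in for optical-dendrometer error,
since no instrument error magnitude is stated for the original data.

What the generator does **not** emulate: species-level taxonomy (labels
are placeholders), spatial plot structure, crooked or forked boles beyond
the butt-swell device, height-measurement error, and the heavy-tailed
irregularity of real buttressed stems. A green test on this world
establishes that the machinery is correct and that the qualitative
mechanisms (RF edge bias, TM site-specificity, generalization gaps)
reproduce — not that the published headline metrics are recovered; those
depend on the deposited field data, which the package can ingest through
`read_inventory()` but does not ship.

## Numerical and design choices

- **Initial values.** Each equation ships literature-informed defaults
  (e.g. the lee family starts near published tropical fits); they are
  overridable per call. The ill-conditioned bi and kozak forms are only
  guaranteed to recover generating parameters from inits near the truth,
  and may legitimately fail to converge from the defaults — which is the
  behaviour the selection tally is designed to absorb.
- **Degenerate inputs.** Empty diameter sets, non-positive lengths,
  heights at or above $ht$, and unknown forest types raise descriptive
  errors at the boundary; fitting never raises for non-convergence.
- **Integration tolerances.** Adaptive Simpson to $10^{-9}$ m³ (scalar);
  the 1-cm cumulative grid used in the CV harness agrees with it to well
  below measurement noise (tested at $10^{-7}$).
- **Budget scaling in tests.** The protocol values — 500 iterations, 50 NN
  restarts, 10,000-epoch cap — are the package defaults. The shipped test
  suite runs the protocol-scale integration test at 100 iterations with 2
  NN restarts and a 200-epoch cap so the whole suite fits a CI budget;
  these reductions change nothing about the split protocol, the RF
  configuration or the metric definitions, and every scaled-down setting
  is passed explicitly through `nn_control`/`n_iter` arguments.
- **Reproducibility.** Every stochastic stage (generator, splits, NN
  initialisation, RF bootstrap) consumes R's seeded RNG stream; the CLI
  writes a manifest (config, seed, package and R versions, input
  checksums) sufficient to reproduce a run bit-for-bit.

## Known limitations

- The reconstructed bi and kozak exponent groupings follow the cited
  original publications' shapes as far as the damaged source allows; a
  correction is a one-line change in the isolated form functions.
- Inside-bark volumes, bark thickness, merchantable assortments,
  autocorrelation within stems and mixed-effects extensions are out of
  scope by design.
- $Vac$ ground truth is defined only at measurement heights (plus the
  cone tip at $ht$); no within-section interpolation is offered.
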