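---
title: "Group-specific discriminant analysis for brain-network lateralization: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-specific discriminant analysis for brain-network lateralization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsda)
```

## The problem

A left-vs-right hemisphere classifier trained on intrahemispheric
functional connectivity is a quantitative probe of lateralization: its
held-out accuracy measures how well the learned asymmetry pattern
generalizes, and its weights rank connections by lateralization
strength.  Trained naively — even on data from a single group — such a
classifier learns *common* lateralization: it transfers almost
perfectly to the other group, so within-group training alone does not
produce group-specific findings.  `gsda` implements an estimator that
makes group specificity an explicit part of the objective, plus the
validation machinery (specificity index, subject-aware cross-validation,
second-order classification) to demonstrate it.

## The estimator

Each observation is one hemisphere: a feature vector $x_i \in
\mathbb{R}^p$ of Fisher-z connectivity values, a hemisphere label $y_i
\in \{0,1\}$ (left/right), and a group code $g_i \in \{0,1\}$.  With an
implicit constant feature and $w \in \mathbb{R}^{p+1}$ (bias included),
GSDA-Logit minimizes

$$J(w) = -\!\!\sum_{i\,\in\,\text{target}}\!\! \big[y_i \log S(w^\top x_i)
  + (1-y_i)\log(1 - S(w^\top x_i))\big]
  + \tfrac{\alpha}{2}\, w^\top w
  - \lambda \log S\!\big(\rho_{sh}(w^\top X, g)\big),$$

where only target-group samples enter the likelihood (the nontarget
group's labels are masked) but *all* training samples enter the
dependence reward.  $\rho_{sh}$ is the simplified HSIC between the
1-D projection $w^\top X$ and the grouping vector: with $L = g g^\top$
and centering matrix $H$ the trace estimator collapses to a quadratic
form, computed here as $(\,w^\top X\,(g - \bar g)\,)^2$ in $O(mp)$ —
the $m \times m$ matrices are never materialized.

Assumptions worth stating: the dependence measure is first-moment only
(a squared covariance between projection and group), so group
specificity is driven by *mean* differences in the projected features
between groups; features are treated as commensurate (Fisher-z values),
so standardization is off by default; and the bias participates in both
the ridge term and $\rho_{sh}$ — faithful to the $w \in \mathbb{R}^{p+1}$
formulation, though unusual relative to common practice where the
intercept is unpenalized (the second-order classifier, a plain logistic
ridge, uses the conventional unpenalized intercept).

### Why the dependence term is HSIC-normalized by default

The printed simplified form drops the $1/(m-1)^2$ factor that the
general HSIC trace estimator carries.  Implemented that way, the raw
quadratic form scales like $m^2$: the moment the projection has *any*
sample correlation with $g$, $\rho_{sh}$ is in the hundreds, $S(\rho_{sh})$
is numerically 1, and both $-\lambda \log S(\rho_{sh})$ and its gradient
vanish along the whole optimization path.  Empirically, fits at
$\lambda = 5$ with the raw form are behaviorally identical to
$\lambda = 0$ — no accuracy divergence, GSI pinned at 0 — which
contradicts every reported property of the method.  With the
$1/(m-1)^2$ factor retained, the dependence term is active exactly in
the regime where projected group means differ by a few score units, and
$\lambda = 5$ reproduces the published divergence behavior.  We
therefore treat the factor's absence in the printed simplified form as
typographical: `simplified_hsic()` exposes both conventions
(`normalize`), and `gsda_hyperparams(normalize_hsic = TRUE)` is the
estimator default.  The practical consequence of normalization is also
that a given $\lambda$ has comparable strength across sample sizes.

### The gradient's factor of two

Differentiating $-\lambda \log S(w^\top A w)$ for symmetric
$A = XHLHX^\top$ yields $2\lambda\,(S(\rho_{sh})-1)\,A w$; the printed
gradient omits the 2.  Since the factor is absorbable into $\lambda$,
the default (`grad_variant = "verbatim"`) implements the printed form
and pairs it, inside the optimizer, with its matched objective (the
dependence log-sigmoid at $\lambda/2$), so that objective and gradient
are mutually consistent and quasi-Newton line searches behave.
`grad_variant = "exact"` gives the analytically exact pairing.  The
finite-difference tests check both pairings.

### Optimization

* Initialization $w^0 = 0$ — deterministic, and it makes the dependence
  term initially inactive ($\rho_{sh}(0) = 0$), so the early trajectory
  is driven by the likelihood.
* Default optimizer: L-BFGS-B on the matched objective/gradient pair;
  plain gradient descent ($w^{k+1} = w^k - \eta \nabla J$,
  $\eta = 10^{-3}$) is available and is used by the
  objective-monotonicity tests.
* Stopping: gradient norm below `tol` ($10^{-5}$) or `max_iter` (500);
  no stopping rule is prescribed by the source formulation, so these are
  implementation choices, and `converged` is recorded on the model.
* A non-finite objective aborts with the iteration index.
* Fits are deterministic given identical inputs and settings; the seed
  argument is recorded for provenance.

### Defaults that matter

| parameter | default | units / meaning |
|---|---|---|
| `alpha` | 0.1 | $\ell_2$ strength $1/\sigma^2$; the reference experimental setting |
| `lam` grid | 0, 1, 2, 5, 8, 10 | dependence strength; 5 is the elbow in accuracy/GSI trade-off |
| `tol` | 1e-5 | gradient-norm stop |
| `max_iter` | 500 | iterations |
| `top_fraction` | 0.05 | mask threshold; $k = \lfloor 0.05\,p \rfloor$, ties broken by lower index |
| holdout fraction | 0.2 | subject-holdout partition |
| second-order penalty | 1 | plain logistic ridge, intercept unpenalized |

## Metrics

Balanced accuracy $(\mathrm{TPR} + \mathrm{TNR})/2$ guards against
imbalance; in the hemisphere design the test sets are balanced by
construction, so it coincides with plain accuracy.  If a test subset
happens to contain one class only, the defined rate is returned with a
warning rather than `NA` — a deliberate convention for degenerate
inputs that balanced designs never hit.

The group specificity index
$\mathrm{GSI} = 2\,\mathrm{BAT}(\mathrm{BAT} - 0.5 - |\mathrm{BANT} - 0.5|)$
is 0 for equally generalizing models and 1 at maximal specificity.  Two
conventions we fixed where the design was open: GSI is *not* clipped to
$[0,1]$ — it evaluates negative when the nontarget accuracy is farther
from chance than the target margin, and clipping would discard that
information — and models with $\mathrm{BAT} < 0.5$ return their raw
value flagged via an attribute instead of being silently dropped.

Model-weight correlations (for comparing lateralization patterns across
models) exclude the bias and flag zero-variance vectors as missing.

## Cross-validation

Both partition schemes are subject-aware.  The hemisphere split halves
the subjects (group-stratified, odd subject to the training half) and
trains on half A's left plus half B's right hemispheres — no subject
contributes both hemispheres to training, and the training set is
exactly label-balanced.  The subject holdout additionally reserves a
fraction of subjects entirely.  Group stratification is on by default
so that both groups appear in every training set, which the dependence
term requires; the source protocol is silent on this point.
Repetition $r$ of an ensemble uses seed $\texttt{base\_seed} + r$, so
entire ensembles are reproducible from one integer.

## Second-order stage and the mask

First-order connection weights (bias excluded) become features; the
label is the model's target group.  Each of the repeated splits draws a
stratified 80/20 partition, fits the plain logistic ridge, and records
test accuracy and weights.  Averaged second-order weights from two
datasets are thresholded at the top 5% by magnitude
($k = \lfloor 0.05\,p\rfloor$; ties at the $k$-th magnitude break
toward the lower index, a convention the source never states) and
intersected.  The "top 5%" rule is a top-$k$ magnitude rule, not a
two-sided z-cut — the wording of the derivation admits both readings;
we implement what the results text describes.  Shared/exclusive
partitions, per-lobe average chord degree, and inter/intra-lobe sign
counts are provided for interpretation; connection tallies across
datasets are reported both with and without repetition, since both
conventions are defensible.

## The synthetic world

The generator emulates, directly in Fisher-z feature space, the
structure the analysis assumes real data to have:

* a population baseline connectivity (sd 0.3 z) plus per-subject random
  effects (sd 0.15), shared between a subject's two hemispheres;
* **common lateralized** connections (8 by default, offset 1.2 z split
  as $\mp$offset/2 between left and right) — these make left/right
  classification nearly perfect for *both* groups, as observed in real
  cohorts;
* **shared, group-scaled** connections (3, offset 1.2, scaled 0.4× in
  group 0 vs 1.6× in group 1) — lateralized in both groups but with
  different strength;
* **group-exclusive** connections (3 per group, offset 1.2) —
  lateralized in one group only;
* **group-mean** connections (4, +0.8 z in group 1, both hemispheres) —
  hemisphere-symmetric mean differences, emulating well-documented
  group differences in mean connectivity;
* independent white noise, sd 0.25 per hemisphere and connection.

The group-mean component deserves emphasis: because the dependence
measure is first-moment only and lateralization offsets cancel across a
subject's two hemispheres, a world with *only* lateralization effects
gives the HSIC term nothing to correlate with — scores cannot depend on
group in expectation, and no target/nontarget divergence can arise.
Real resting-state cohorts do show group differences in mean
connectivity; planting them provides the group-discriminative direction
the estimator demonstrably exploits (the fitted models shift nontarget
scores through exactly these connections, degrading nontarget accuracy
while the anchored target likelihood keeps target accuracy high).

Composition was chosen once against two structural constraints and then
frozen.  First, the mask has exactly $\lfloor 0.05 \cdot 190\rfloor = 9$
slots, so the planted sex-different set (shared-unequal + exclusives)
has size 9 — with fewer plants the remaining slots fill with the
estimator's systematic footprint (even group-common connections acquire
slightly group-different weights under the dependence term, identically
in both datasets, so cross-dataset intersection does not remove them)
and precision is structurally capped.  Second, redundant same-kind
plants dilute each other's second-order contrast: under near-separable
logistic fitting, weight mass spreads across interchangeable
informative connections, so effects are few, strong and distinct rather
than many and weak.

What the generator does **not** emulate: BOLD time series and their
autocorrelation (the feature-extraction path is tested separately on
analytic series), spatial autocorrelation between connections,
site/scanner effects, heavy-tailed motion artifacts, or realistic
effect-size spectra.  A green acceptance suite therefore establishes
that the estimator and workflow behave as designed *in a world whose
assumptions they match* — it does not certify effect sizes or error
rates on real neuroimaging data.

## Numerical choices

* Sigmoid and log-sigmoid use overflow-free branches; scores of $\pm10^3$
  are safe.
* Correlations are clamped to $\pm(1 - 10^{-12})$ before `atanh`, so
  numerically perfect correlations give large finite z.
* Connectivity diagonals are defined as 0 and never extracted.
* Connection indices and ROI ids are 0-based throughout, matching the
  atlas labeling convention; the row-major strict-upper-triangle order
  is the single vectorization convention, with closed-form maps in both
  directions (exhaustively tested).
* Run averaging happens after the Fisher transform, per the stated
  processing order; averaging is per (subject, session) and never
  across sessions, which serve as held-out test sets.

## Open design points, resolved

* The population-level objective that motivates the method mixes a
  likelihood with an absolute-dependence term under $1/m_t$ and
  $\lambda/m$ scalings that do not reappear in the estimable
  maximum-likelihood form; the implementation follows the estimable
  form and notes the discrepancy rather than attempting to reconcile
  the two.
* Multivariate grouping factors ($G$ with $q > 1$, e.g. sex × age band)
  are supported by the same trace formula in `hsic()`, but no reference
  value exercises them; they are exposed untested.
* `fit` reports the objective it actually minimized (the matched
  pairing), alongside the gradient norm and convergence flag.

## Limitations

The estimator's group specificity is driven by group-mean structure in
the features; groups that differ only in covariance cannot be separated
by the simplified (linear-kernel, first-moment) dependence term.  The
$\lambda$ elbow is data-dependent and should be re-examined per
dataset.  No harmonization across datasets is attempted — masks are
intersections of per-dataset results, which is conservative.  Runtime
is $O(\text{reps} \times |\lambda\text{ grid}| \times \text{groups})$
L-BFGS fits of dimension $p + 1$; the desk-scale world (190 features,
400 training hemispheres) fits in tens of milliseconds each, and the
full-scale problem (7,503 features) remains a plain dense-vector
workload.
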