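---
title: "Latent classes of floating plastic debris: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent classes of floating plastic debris: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Floating plastic debris is conventionally summarized with predetermined bins —
"microplastic" below 5 mm, shape labels, polymer labels — which discard the
continuous, correlated structure of particle dimensions. `floatmix` treats the
observed length (maximum Feret diameter) and width (minimum Feret diameter) of
net-collected particles as draws from a finite mixture of normal
distributions: each latent class is a subpopulation with its own mean vector,
variances and length–width correlation, and every particle carries a posterior
probability of belonging to each class. The package implements the full
analysis chain — outlier screening, per-category class enumeration, a
combined six-class model, cluster-robust standard errors, and post-hoc
(distal outcome) analyses — together with a synthetic-data generator so the
whole chain is testable without access to any particular survey data set.

## The model

Within a shape category (line, film, fragment) with $K$ classes, the density
of a particle's dimension vector $x$ is

$$p(x) = \sum_{i=1}^{K} n_i \, \phi(x; M_i, \Sigma_i),$$

where $n_i = N_i / N_\mathrm{total}$ is the number fraction of class $i$.
Lines vary essentially only in length, so their components are univariate
normals over length; films and fragments use bivariate normals over
(length, width). Two covariance structures are supported:

* **equal across classes** (the default, and the structure retained in the
  published analyses this package reimplements): each class has free
  variances $s^2_{\mathrm{len},i}, s^2_{\mathrm{wid},i}$, but a single
  length–width covariance $c$ shared by all classes of the category. The
  reported per-class correlations $r_i = c / (s_{\mathrm{len},i}
  s_{\mathrm{wid},i})$ then differ across classes purely through the
  variances — which is exactly the quantity of scientific interest (small
  particles: $r$ near 1, i.e. equally long and wide; large particles: low
  $r$, heterogeneous shape).
* **free**: per-class covariances, used for structure comparison during
  enumeration.

The combined model stacks all six classes (two per category) into one
likelihood over all particles, with membership *restricted* by the observed
category: a particle's posterior is structurally zero outside its category's
two classes (the dummy-variable device). Line classes contribute a univariate
density over length — parameters involving width are not estimated for
lines. Because the restriction makes the category blocks disjoint, the joint
maximum splits into the three per-category maxima plus a multinomial over
category shares; the joint EM is initialized from the per-category fits and
this factorization is asserted in the tests.

## Estimation

Parameters are estimated by EM. The E-step is the standard posterior update,
computed with log-sum-exp stabilization. The M-step is closed-form for
weights, means, variances and free covariances. Under the equal-covariance
constraint the M-step has **no closed form** (the inverse couples the shared
covariance with the per-class variances), so the package uses a generalized
EM step: the moment candidate (per-class scatter diagonals, pooled
cross-moment) is compared against the incumbent on the exact constrained
Q-function and then refined by coordinate ascent — a 1-D `optimize` over the
shared covariance on its positive-definiteness interval, and a per-class 2-D
Nelder–Mead over the variances on an unconstrained parameterization. Only
Q-improving moves are accepted, so the observed-data log-likelihood is
provably nondecreasing at every iteration; the test suite asserts this trace
property directly.

Numerical choices:

* **Initialization**: k-means partitions of the standardized dimensions with
  jittered centers; `n_starts = 20` by default (tests use 4–10 for runtime),
  all seeded. The best final log-likelihood wins.
* **Convergence**: absolute log-likelihood gain below `tol = 1e-8`, cap
  `max_iter = 2000`.
* **Variance floor**: 1e-6 mm², guarding against degenerate spikes; a fit
  that ends on the floor carries a warning rather than silently passing.
* **Label switching**: classes are sorted ascending by mean length (within
  category for the joint model), so "class 1" is always the small-particle
  class.

## Class enumeration

`enumerate_classes()` tabulates, for $K = 1..K_{max}$: BIC (and AIC), a
parametric **bootstrapped likelihood-ratio test** against $K-1$ classes
($p = (1 + \#\{LRT_b \ge LRT_{obs}\}) / (B+1)$, default $B = 100$; the
reference analysis does not state its replicate count), normalized entropy
$1 - \sum_{ik} -P_{ik}\ln P_{ik} / (N \ln K)$, the minimum **average
posterior classification probability** (AvePP; a per-particle variant is
available behind a flag, since the published bracket could be read either
way), and the smallest class share. `select_classes()` walks $K$ upward and
retains a larger model only if the BIC improves by more than 10 (smaller
differences are treated as non-decisive and resolved toward the smaller
model — this reproduces, without visual inspection, the published decision
to keep two line classes when a third lowered BIC only trivially), the BLRT
is significant, the smallest class holds at least 10% of the sample, and
AvePP stays at or above 0.90. All flags are returned so a human can
override; visual inspection of density overlays is deliberately not
automated.

## Robust standard errors

Net hauls cluster particles: two particles from one haul are not independent.
`sandwich_se()` computes $A^{-1} B A^{-1}$ with $A$ the observed information
(numerical Hessian of the mixture log-likelihood at the MLE, central
differences with step $10^{-5}(1+|\theta|)$ — analytic mixture Hessians are
error-prone and $N$ is small) and $B$ the outer product of per-haul score
sums. Wald intervals are reported on the natural scale; symmetric intervals
for variances can undershoot zero and are flagged rather than truncated,
mirroring how such intervals appear in published tables.

## Three-step auxiliary analyses

Comparing classes on variables outside the mixture (polymer type, observed
height) uses the modal-assignment maximum-likelihood correction: (1) fit the
mixture, (2) estimate the classification-error matrix
$D_{kj} = \sum_{i \in \mathrm{modal}\,j} P_{ik} / \sum_i P_{ik}$,
(3) solve the misclassification system (observed-by-assigned counts
$= D^\top \times$ true-by-class counts) with nonnegativity clipping and test
equal proportions across classes per outcome level with a delta-method Wald
chi-square on $K-1$ df. With a perfectly separated posterior ($D = I$) this
reduces exactly to the naive classify-and-compare analysis — asserted in the
tests. The alternative BCH weighting is out of scope. Height analysis is
restricted to particles modally classified as large fragments, where
essentially all height measurements live.

## The synthetic-data generator

`reference_config()` encodes the stated world the pipeline is tested
against: six classes with the published fitted weights ($N_i/6942$), means,
variances and correlations; clustered sampling over 20 hauls (round-robin,
optional additive per-haul mean shift whose only purpose is to give the
sandwich estimator something to detect); a 1 mm lower detection limit
implemented by rejection (redraw), so class weights refer to the observable
population; an optional contamination fraction drawn from a wide uniform
envelope to exercise screening; and per-class polymer profiles. Per-class
polymer composition is published only graphically, so the defaults are a
fixed documented choice: PE dominant in every class, class-size-weighted
composition (88.6% PE, 10.7% PP, 0.7% other) matching the published overall
shares, with enough between-class contrast for the distal test to detect.
Heights are generated for large fragments with a configurable correlation to
the width residual (default 0.24) and none to length.

Two recorded discrepancies in the source parameters are preserved rather
than reconciled: the film classes' implied unstandardized covariances
(0.890 vs 0.844 mm²) disagree beyond rounding although the covariance was
constrained equal — the generator uses the class-specific correlations as
printed and `reference_model()` exposes the mismatch as an attribute — and
one film-class confidence interval is typeset with its bounds inverted and
is flagged `ci_suspect`.

**What a green test does and does not establish.** The generator draws from
exactly the parametric model the estimator assumes, with independent
particles (unless haul shifts are switched on) and no measurement error,
digitization, or size-dependent capture efficiency. Green recovery tests
therefore establish correctness of the estimation machinery, not field
validity of the model. Two consequences observed and computed in the test
suite are worth knowing:

* the entropy of the refitted combined model on such data is ≈ 0.95–0.96,
  mildly above the published real-data 0.94, because real data carry model
  misfit that lowers apparent separation;
* re-running the outlier screening on fresh draws removes a noticeable slice
  (~20%) of the sparse large-film class's tail — the published parameters
  describe a model fitted to *already screened* data, so screening-then-
  refitting cannot recover that class's variances exactly. The acceptance
  test that mandates screening in the loop is asserted as stated and its
  large-film failures are documented rather than hidden.

Relatedly, the fitted normals assign length and width independently of their
order, so a small fraction of draws (up to ~20% in the low-correlation
large-fragment class) has width exceeding length, which measured Feret
diameters cannot. The generator leaves such draws untouched (recovery would
otherwise be biased); `read_particles()` enforces the ordering on ingest
with a swap-and-warn default, since the two Feret diameters are order
statistics of one measurement.

Simulating *from the fitted model* (for the acceptance targets and the
parameter-recovery loop) deliberately skips the detection limit: the fitted
parameters describe latent normals whose tails extend below 1 mm and (for
large lines, sd ≈ 17.7 mm) below zero; truncating would shift the
large-line variance by ~15% and bias recovery. `sample_mixture()` keeps a
positivity redraw by default for risk-assessment use, with
`truncate_at = NULL` to disable.

## Degenerate inputs and edge policies

Zero-variance screening inputs, singular covariances, categories with fewer
than 10 particles, empty mixture classes, classes with no modal members, and
constant heights all raise errors or flagged `NA`s with messages naming the
offending rows or classes — never silent coercion. Ties in modal assignment
go to the lowest class index, deterministically.

## Limitations

* Components are Gaussian only; no skewed or heavy-tailed components, no
  more than two dimensions.
* The BLRT is expensive (2B refits); at desk scale it is run with reduced
  replicates and starts, which the tests state explicitly.
* The three-step correction implemented is the modal ML variant; continuous
  distal outcomes are analysed only through correlations within one class.
* Mass concentrations depend on externally supplied haul masses or per-
  particle masses; the package does not model mass–size allometry.
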