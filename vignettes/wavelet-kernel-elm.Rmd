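---
title: "Wavelet-kernel ELM classification of dysphonia measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-kernel ELM classification of dysphonia measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wkelm)
```

## The model

An Extreme Learning Machine (ELM) is a single-hidden-layer feedforward
network whose hidden parameters are fixed — randomly or through a
kernel — so that the output weights can be computed in closed form by
regularised least squares instead of gradient descent.  `wkelm`
implements the two-class kernel form.  With training rows
$x_1,\dots,x_N$, labels encoded $C_i \in \{+1,-1\}$ and a kernel
$b(\cdot,\cdot)$, the *full-kernel* model solves

$$\left(\tfrac{1}{E} I + D\right) S = C, \qquad D_{ij} = b(x_i, x_j),$$

and scores a new sample $r$ as
$u(r) = \sum_i S_i\, b(r, x_i)$, classifying by $\operatorname{sign} u$
(ties to the positive class).  $E > 0$ is the *regulation coefficient*:
small $E$ means heavy ridge shrinkage, large $E$ approaches exact
interpolation.  Training accuracy is therefore non-decreasing in $E$, a
property the test suite checks empirically.

The working kernel is the three-parameter wavelet family

$$b(r,g) = \cos\!\left(\frac{w\,\lVert r-g\rVert}{x}\right)
  \exp\!\left(-\frac{\lVert r-g\rVert^{2}}{y}\right),$$

an oscillatory modulation ($w$, $x$) of a Gaussian envelope ($y$).  The
printed form of this kernel in the literature is typographically
ambiguous about where $x$ and $y$ divide and whether the form is
norm-based or a per-dimension product; we adopt the norm-based reading
above — the standard three-parameter translation-invariant wavelet
kernel, using each parameter exactly once — and offer the per-dimension
product form behind `kernel_spec(..., form = "product")`.  Distance is
always the Euclidean norm.  Note the norm-based form is *not*
guaranteed positive semidefinite; the solver never assumes definiteness
and falls back to a pseudoinverse least-squares solution (with a
warning) if the regularised system is singular at tolerance $10^{-10}$.
Classical kernels (linear, polynomial, Gaussian, exponential) are
available for comparison studies.

Two further variants cover the "how many hidden neurons?" question,
which the kernel form renders moot but a hyperparameter search needs to
be meaningful:

* `center_subset`: an explicit hidden layer of $K$ kernel neurons
  centred on a seeded random subset of training rows;
  $A_{ik} = b(x_i, c_k)$ and $S = A^\top(\tfrac1E I + AA^\top)^{-1}C$.
  This is the regularised least-squares solution in the sample space
  (the push-through identity $A^\top(\tfrac1E I + AA^\top)^{-1} =
  (\tfrac1E I + A^\top A)^{-1}A^\top$ is used as an independent oracle
  in the tests).  Note this is a *different* estimator from the
  full-kernel model even at $K = N$: the kernel there acts as the
  feature map itself, not as an inner product, so the two solutions
  coincide only in the limit of no regularisation on easy problems.
* `random_feature`: the classic ELM baseline with uniform$(-1,1)$
  input weights and biases and a choice of five activations; output
  weights via the Moore–Penrose pseudoinverse.

Features are z-scored with statistics fitted on the training split
only.  This matters twice over: the voice features span five orders of
magnitude (Hz versus dimensionless ratios), and fitting the scaler on
all data would leak test information into the model.  Constant features
get $\mathrm{sd} = 1$ so they map to zero harmlessly.

## The genetic algorithm

`ga_optimize()` tunes $(w, x, y, K)$ with a binary GA.  One candidate
is a 20-bit chromosome: bits 1–4, 5–8 and 9–12 are offset-binary codes
of $w, x, y \in \{1,\dots,16\}$ (`0000` $\to$ 1, `1111` $\to$ 16) and
bits 13–20 code $K \in \{5,\dots,260\}$ (`00000000` $\to$ 5,
`11111111` $\to$ 260).  Fitness is the training accuracy of the decoded
center-subset WK-ELM — the center-subset variant is used precisely so
that the neuron-count bits influence fitness.  Accuracy is measured on
the same training split the model was fitted on; this mirrors the
method's published formulation, and generalisation is measured
separately by the evaluation protocols (or by the GA-in-the-loop mode
of the CLI, which reruns the search inside every training split).

Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| population size | 40 | the size used in the experiment this package operationalises (an alternative description says 20; both are one flag away) |
| generations | 50 | comfortable for 432-point grid-equivalent searches; early stop via `stall_generations` |
| crossover | single-point, $p_c = 0.8$ | standard choice; the operator itself is only constrained to "copy parents when no crossover" |
| mutation | per-bit flips, $p_m = 0.02$ | "one or more bits" mutate; 0.02 gives 0.4 expected flips per child |
| selection | roulette (fitness-proportionate) | matches "higher fitness, more likely reproduced"; uniform fallback when all fitness is zero |
| elitism | 1 | the loop "returns the best solution"; elitism makes the best-fitness history provably non-decreasing, which the tests assert |

Fitness ties are broken toward fewer hidden neurons, then the
lexicographically smaller bit string: the cheapest equally-accurate
model wins.  The entire search is driven by one seed and is
bit-reproducible; the fitness function holds its center-selection seed
fixed so fitness is a pure function of the chromosome.

## Evaluation

`run_protocol()` implements repeated stratified holdout and stratified
k-fold splitting.  The published account of the experiment this package
generalises is self-contradictory about its split (3-fold
cross-validation, two-fifths training, 128-of-192 and 100-of-192
training cases are all stated); rather than hard-code one reading,
`split_plan()` expresses all of them, and the package demos default to
stratified 2:1 holdout with 3 repeats.  Stratification is on by default
because the motivating data are ~75% PD and small unstratified test
sets can lose the healthy class entirely.  An optional `group` column
keeps all recordings of one subject on the same side of every split,
for corpora with repeated measurements per person.

Per split we report the confusion counts against a declared positive
(diseased) class, sensitivity, specificity, overall accuracy, the ROC
curve (threshold swept over the distinct score values, predicting
positive at `score >= t`, tied scores collapsed) and the trapezoidal
AUC, which equals the Mann–Whitney rank statistic
$P(u_{pos} > u_{neg}) + \tfrac12 P(u_{pos} = u_{neg})$ — an identity the
tests verify to $10^{-12}$ against an exhaustive pair count and against
an independent ROC implementation.  Aggregates are arithmetic means at
full precision; rounding to two decimals is display-only.

## The synthetic generator

`simulate_parkinsons()` emulates the canonical 22-feature dysphonia
schema so that every pipeline stage can be exercised, sized and tested
without an external download: a log-normal fundamental-frequency trio
with $F_{lo} \le F_o \le F_{hi}$ enforced by construction,
positive-valued jitter and shimmer families with a shared within-block
correlation (default 0.6) on the latent Gaussian scale, NHR/HNR coupled
so HNR falls as NHR rises, and the six nonlinear measures on their
natural scales.  The PD class is shifted by `effect_size` latent
standard deviations on the jitter, shimmer and PPE features — the
measurements most consistently elevated in parkinsonian dysphonia.
Defaults are 192 recordings at prevalence 0.75, matching the class
balance of the motivating corpus; `effect_size = 1.5` yields held-out
accuracies in the low-to-mid 90s, the regime reported for real voice
data.

What the generator does *not* emulate: repeated recordings per subject
(rows are independent unless you add a group column), heavy-tailed
measurement error, cross-family correlations beyond the NHR–HNR link,
and the exact marginal distributions of any real corpus.  Passing tests
on this generator therefore demonstrate the correctness and the
statistical behaviour of the pipeline, not clinical performance on real
recordings.

## Numerical choices and problem sizes

* Linear systems: `solve()` on the symmetric regularised matrix,
  tolerance $10^{-10}$; pseudoinverse fallback with a warning, never an
  explicit inverse.
* Default kernel parameters (`w = 1, x = 8, y = 16`): the cosine factor
  must vary slowly relative to typical distances between z-scored
  feature vectors ($\approx \sqrt{2p}$ for $p$ weakly correlated
  features, about 6 for the 22-feature schema), i.e. $w/x \ll
  \pi/(2\,d_{typ})$; otherwise neighbouring training samples contribute
  with alternating signs and held-out accuracy collapses toward chance.
  The GA discovers this region on its own; the fixed default simply
  starts inside it.  $E$ defaults to 1 and is exposed everywhere.
* Label ties: $u = 0$ predicts the positive class.
* Prevalence rounding: the simulated PD count is
  `round(prevalence * n)`, exactly.
* Test-suite problem sizes (chosen to keep the full suite under a
  minute): toys of 4–40 rows for the algebraic oracles, 120 rows for
  the two-ring GA benchmark against a 432-point exhaustive grid, and
  300–400 rows with 20 holdout repeats for the end-to-end learnability
  and null-signal checks.

## Known limitations

Binary classification only; no probability calibration, confidence
intervals on AUC, or multiclass extension.  The wavelet kernel's
possible indefiniteness means the full-kernel solution is a regularised
linear-system solution rather than a proper RKHS estimator; in practice
the regularisation term keeps the system well-posed.  The GA is a
single-population, single-objective search — adequate for a 20-bit
space, not a general-purpose optimiser.
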