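---
title: "Methods: image-based shrinkage and polynomial moisture-ratio estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based shrinkage and polynomial moisture-ratio estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dryshrink)
```

## The measurement problem

During convective or microwave drying, high-moisture slices lose most of
their mass as water, and their projected area shrinks with it. Weighing the
product mid-run is intrusive; an overhead camera is not. `dryshrink` turns a
time-ordered stack of top-view frames into a shrinkage series
$S(t) = A(t)/A(0)$ and models the dimensionless moisture ratio
$\mathrm{MR}(t) = \mathrm{MC}(t)/\mathrm{MC}(0)$ (dry-basis moisture content
$\mathrm{MC} = (m - m_d)/m_d$) as a polynomial in $S$:

$$\mathrm{MR}(k) = \varphi^\top(k)\,\alpha + v(k), \qquad
  \varphi(k) = (1, S(k), \dots, S^n(k))^\top,$$

with $v(k)$ independent zero-mean Gaussian noise of variance $\sigma^2$.
The polynomial form is justified by uniform approximation of any continuous
MR–S law; orders 1–3 suffice in practice for drying curves.

## Imaging pipeline and its conventions

Each frame passes through six steps: grayscale conversion, automatic
thresholding, binarization, hole filling, particle filtering, and area
summation. Several conventions are deliberately pinned down because they
change pixel counts at the margins:

* **Grayscale** is the plain average of the three channels, rounded
  half-to-even. (An exact .5 never arises from a sum of three integers
  divided by 3, so the rule only matters for documentation completeness.)
* **Threshold**: the default is iterative intermeans (Ridler–Calvard): start
  from the global mean, replace the threshold by the rounded mean of the two
  class means (classes $\le T$ and $> T$), iterate to a fixed point. Otsu
  (exhaustive between-class-variance maximization, smallest maximizer on
  ties) is selectable; on clean bimodal histograms the two differ by at most
  a few levels. A constant image returns its constant with a warning.
* **Binarization** keeps pixels *strictly above* the threshold (bright
  slices on a dark cavity floor; polarity is configurable). Strictness
  matters because thresholds are integers.
* **Hole filling** fills background regions not 4-connected to the border;
  **particle labeling** uses 8-connectivity — the standard complementary
  pair, so a diagonal chain of foreground pixels is one particle and does
  not leak the background through itself. Labels are ordered by first
  appearance in R's column-major scan; a tie at rank $k$ keeps the
  earlier-labelled particle and warns.
* **Top-6 filtering** assumes six slices per tray; `k` is configurable. The
  filter removes small bright debris; hole filling removes dark specks
  inside slices.

Connected components are computed by `EBImage::bwlabel` (4-connectivity)
followed by a union-find merge across diagonal adjacencies; hole filling
labels the mask complement the same way. The test suite checks both against
a pure-R border flood-fill oracle.

## The fitness and the evolution

For Gaussian noise the log-likelihood, after profiling out $\sigma^2$
(whose MLE is the mean squared residual), is
$\ell = \mathrm{const} - \tfrac{D}{2}\ln J(\alpha)$ with

$$J(\alpha) = \frac{1}{D}\sum_{k=1}^{D}\left[\mathrm{MR}(k) -
  \varphi^\top(k)\alpha\right]^2 .$$

Maximizing the likelihood is therefore exactly minimizing $J$, which for a
linear-in-parameters model is also the ordinary-least-squares objective.
This gives the package a sharp internal oracle: the normal equations. Every
stochastic fit can be compared against the closed-form optimum, and the
acceptance checks do precisely that.

$J$ is minimized by differential evolution (`rand/1/bin`):

* uniform initialization of $P$ individuals;
* mutation $\beta = \alpha_{r1} + F(\alpha_{r2} - \alpha_{r3})$ with
  distinct donors $r1, r2, r3 \ne p$ drawn by rejection;
* binomial crossover at rate $CR$ with one guaranteed mutant coordinate
  $q_{\mathrm{rand}} \in \{1..Q\}$ (drawn per individual);
* greedy selection: the trial replaces the target only on a strictly
  smaller $J$; ties keep the incumbent;
* synchronous generations: donors and targets always come from the previous
  generation, and the final estimate is the arg-min over the last
  population rather than an elitist archive.

A single seeded RNG stream drives initialization, index draws and crossover
uniforms in a documented order (per individual: donors, then
$q_{\mathrm{rand}}$, then $Q$ uniforms), so fits are bit-reproducible.

### Parameter defaults and the initialization range

| parameter | default | units / range | rationale |
|---|---|---|---|
| `population_size` | 30 | individuals | reported drying-study setting |
| `max_generations` | 20 | generations | reported setting; see below |
| `scale_factor` F | 0.5 | – | standard DE practice |
| `crossover_rate` CR | 0.9 | – | standard DE practice |
| `init_low`, `init_high` | −15, 15 | coefficient units | must cover the coefficient scale |
| observation noise σ | 0.02 | MR units | generator default |

Two defaults deserve explanation.

**Generations.** Twenty generations reproduce the historical setting but do
not reach the least-squares optimum tightly; the package's own validation
and examples use `max_generations = 500`, at which the fit matches the
normal-equations solution to within 1% of $J$ in every seeded run the
acceptance script reports.

**Initialization range.** Unit-uniform initialization ($[0,1)^Q$) is common
in this literature, but fitted drying cubics have coefficients of magnitude
up to ~12, far outside that box. Differential mutation can in principle
migrate the population there, but with $F = 0.5$ the migration frequently
ends in premature collapse: best-$J$ stalls a few percent above the optimum
and never recovers, because all individuals become identical and the
difference vectors vanish. Initializing over $[-15, 15)$ — a range that
covers the plausible coefficient magnitudes of MR–S polynomials with
margin — removes the failure mode (the acceptance script reports the
fraction of seeded runs reaching the least-squares optimum) without touching
$F$, $CR$, $P$ or the number of generations. Both bounds remain
configurable, and the unit-range behaviour is exercised in the unit tests.

No bound clamping is applied to mutants: the search space is all of
$\mathbb{R}^Q$; the initialization range only positions the first
generation.

### Degenerate inputs

* $D < n + 1$: the fit proceeds with a warning (under-determined; $J$ can
  reach 0 without identifying $\alpha$).
* $J = 0$ (perfect fit): the profiled log-likelihood reports `Inf` with a
  `perfect_fit` flag.
* Non-finite data are rejected outright.
* A degenerate initialization range (`init_low == init_high`) warns: the
  population is constant and mutation can never leave it.

## Order selection

Candidates $n = 1, 2, 3$ (configurable) are fitted independently and
compared by adjusted
$R^2 = 1 - (1 - R^2)(D - 1)/(D - (n+1))$, which penalizes the extra
coefficients; the largest adjusted $R^2$ wins, ties broken toward the
smaller order, then the smaller RMSE. Information criteria (AIC/BIC) and
cross-validation are deliberately out of scope: with $D = 83$ and orders
$\le 3$ the adjusted-$R^2$ rule is the field's convention, and the
acceptance script reports its recovery rate of the true order over seeded
end-to-end runs. Each candidate order is fitted
with seed `cfg$seed + n` so the candidates are independent but the whole
comparison is reproducible.

## The synthetic generator

The generator emulates the drying experiment the method was designed for,
not drying physics:

* **Kinetics**: $\mathrm{MR}(t) = e^{-kt}$ with $k$ set so a 41-minute run
  ends at $\mathrm{MR} = 0.176/9.87 \approx 0.0178$ (the stopping moisture
  content over the initial one, both dry basis); sampling every 0.5 min
  gives $D = 83$.
* **MR–S link**: a known monotone cubic $p$ with $p(1) = 1$. The default was
  constructed from a strictly positive derivative,
  $p'(S) = 10\,(S - 0.35)^2 + 0.103$, anchored at $p(1) = 1$ and
  $p(0.35) = \mathrm{MR}_{\mathrm{final}}$, giving
  $\alpha_{\mathrm{true}} = (-0.1610,\ 1.3277,\ -3.5000,\ 3.3333)$. Shrinkage
  then spans $[0.35, 1]$, the curve is steep near $S = 1$ and flat near the
  floor (the shape drying studies report), and the order-3 design matrix
  stays well-conditioned ($\kappa(\Phi^\top\Phi) \approx 5 \times 10^5$).
  The generator validates monotonicity on a 2048-point grid, the $p(1) = 1$
  boundary, and the inversion bracket, and rejects violations.
* **Shrinkage** is recovered from true MR by bisection on $p$ to $10^{-10}$.
* **Noise**: additive zero-mean Gaussian on MR ($\sigma = 0.02$ by
  default), seeded.
* **Images**: six rasterized disks (initial radius 40 px on a 280×400
  canvas, foreground 200 on background 40) whose radii scale with
  $\sqrt{S}$; rasterization keeps the summed pixel ratio within ~0.8% of
  the true area ratio at this radius. Optional Gaussian luminance noise
  (σ = 10 in the validation runs) perturbs intensities after rasterization;
  frame rendering draws from seed + 1 so series and images are separately
  reproducible. Disks never touch; layouts that would overlap or leave the
  canvas are rejected.

What the generator does **not** emulate — and hence what passing tests do
not establish about laboratory data: non-circular and fragmenting slices,
uneven illumination and specular highlights, browning (intensity drift),
correlated or heteroscedastic mass-measurement error, slice-to-slice
kinetic heterogeneity (a per-disk radius multiplier exists but is off by
default), and any deviation of real kinetics from the exponential-plus-
polynomial structure. The end-to-end checks validate the estimator and the
pipeline's numerics, not the biology.

## Validation problem sizes

The shipped checks use: 20 seeded datasets of $D = 83$ for the
estimator-vs-OLS and parameter-recovery studies (order 3, $P = 30$,
500 generations); 83-frame stacks at 280×400 px for the imaging round trip
(noiseless: exact area equality; σ = 10: shrinkage within 2% at every
frame); and 20 end-to-end simulate→extract→fit→select runs plus a two-batch
fit/predict split. These sizes were chosen to match the emulated experiment
while keeping the whole suite comfortably fast on a laptop.

## Known limitations

* The estimator is stochastic; with pathological settings (tiny
  populations, $F$ far below 0.5, initialization far from the coefficient
  scale) it can converge prematurely. The closed-form OLS solution exists
  for this model class and is the better choice when the model is truly
  linear in parameters; the evolution earns its keep as a general fitness
  minimizer and for its faithfulness to the published procedure.
* Thresholding is global per frame; vignetting or uneven lighting would
  require local thresholds, which are out of scope.
* The "top 6" particle rule assumes slices neither fragment nor merge; a
  fragmented slice redistributes area among extra particles and biases $S$
  downward, which no test here detects.
* Time is carried in minutes throughout; the sampling period enters only
  through the manifest (or the `sample_period` fallback when a directory has
  no manifest).
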