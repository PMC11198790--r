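---
title: "Boosted atomic orbital search for CNN hyperparameter neuroevolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boosted atomic orbital search for CNN hyperparameter neuroevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baoscnn)
```

## The problem

Convolutional networks for patch-based benthic habitat classification
(seagrass morphotypes against background texture) are sensitive to
architectural and training hyperparameters: depth, filter count, kernel
and pooling sizes, epochs, batch size, dropout, learning rate and
momentum. `baoscnn` treats the choice of these nine values as a
black-box minimization problem and solves it with an atomic orbital
search metaheuristic boosted by Lévy flights, using stratified
cross-validated accuracy of the trained network as the fitness signal.
The package also ships analytic benchmark objectives, a synthetic image
generator for desk-scale experiments, grid slicing and overlay
utilities, and standard classification metrics.

## The search space and discretization

`default_seagrass_space()` declares the nine dimensions. All nine are
enumerated grids: integer ranges for the architectural parameters
(layers 1–20, kernel 1–30, filters 1–500, epochs 1–400, pooling 1–20),
batch sizes 10–200 in steps of 10, and fixed-step grids for dropout
(0.20–0.65 by 0.05) and momentum (0.05–0.95 by 0.05). The printed
learning-rate grid steps by 0.005 from 0.001; since that step does not
land on the endpoint, the grid runs 0.001, 0.006, …, 0.096 with 0.1
appended as the final category. This choice is a package decision where
the enumeration is not printed in full.

Optimizers never move in the native units of a discrete dimension.
Each discrete coordinate lives on $[0, 1]$ and is decoded lazily by the
discretization map: for $n$ ordered categories and a coordinate $R$,

$$\alpha = 1 + nR, \qquad \beta = \min(\lfloor\alpha\rfloor, n),$$

and the decoded value is the $\beta$-th category. Flooring $\alpha$ and
clamping at $n$ makes the map total on $[0, 1]$ (both endpoints decode
to real categories) and uniform: uniform $R$ induces uniform category
frequencies, which the test suite checks by a chi-square test at
$10^5$ draws. Boundary repair clamps coordinates to their admissible
interval and is idempotent, so decoding after repair is total on
arbitrary real vectors.

## The optimizer

The population ("electron cloud") holds $m$ candidate positions with
objective values read as energies (lower is better). Each iteration:

1. A layer count is drawn uniformly from $1..L_{\max}$ (default 5) and
   the electrons, sorted by energy, are partitioned into contiguous
   layers with sizes proportional to a discretized standard normal
   density over the layer index, at least one electron per layer. The
   best electrons land in layer 1.
2. Binding records are computed: per-layer and global centroids
   (binding states) and mean energies (binding energies), the per-layer
   best, and the best-so-far candidate (lowest energy, LE).
3. Each electron draws fresh uniform vectors $\alpha, \beta, \gamma \in
   [0,1]^d$ and a scalar $\phi \in (0,1)$. With probability
   $1 - PR$ (photon interaction, $\phi \ge PR$): electrons at or above
   their layer's binding energy take the global pull
   $X \mathrel{+}= \alpha \odot (\beta\,LE - \gamma\,BS)/k$, damped by
   layer depth $k$; better electrons take the layer-local pull toward
   their layer's best and centroid. Otherwise the electron takes a
   small uniform random walk, $\pm 5\%$ of each dimension span.
4. Candidates are repaired into the box and accepted greedily. Equal
   energies are accepted too — on the plateaus of a discretized
   landscape an electron must be free to drift — but only strict
   improvement resets the per-electron stagnation counter; any
   non-improving move increments it.

The boosted variant (BAOS) adds two Lévy-flight mechanisms:

* **Photon-rate modulation.** Each electron's photon rate is re-drawn
  every iteration as $PR_i = \mathrm{clamp}_{[0,1]}(c\,|\ell|)$ with
  $\ell$ a Lévy step of stability index $\beta = 1.5$. The constant $c$
  is calibrated — deterministically, by quadrature on the Mantegna
  sampling distribution — so the median $PR$ equals the conventional
  0.1. Most iterations therefore behave like plain AOS, with rare
  heavy-tailed excursions into random-walk-dominated behaviour.
* **Stagnation restarts.** An electron whose counter exceeds the
  threshold is relocated by a Lévy flight centred on the best-so-far
  position and its counter resets. The restart uses the module's
  default step scale of 1% of each dimension span, so most restarts are
  local refinements around the incumbent with occasional long jumps.

Steps are sampled with Mantegna's algorithm
($u/|v|^{1/\beta}$ with the standard $\sigma_u$), whose magnitude
survival function has power-law exponent $\approx \beta$; the test
suite recovers the exponent within $\pm 0.15$ at $10^6$ draws for
$\beta \in \{1.1, 1.5, 1.9\}$. The closed-form density exposed by
`levy_density()` is the one-sided stable (Lévy) law the boost is named
for; the sampler, not that density, carries general $\beta$. Extreme
tail draws are clipped at 100 dimension spans before repair purely for
numerical robustness.

Each of `n_runs` independent runs derives its seed from the master seed
by a fixed increment, so the whole protocol is bitwise reproducible.
Per run, the evaluation budget is exactly $m(1 + T)$ objective calls
for $T$ iterations; the budget-matched `random_search()` baseline
spends the same number of uniform draws.

### What the optimizer cannot do at tiny budgets

Greedy acceptance with population-scaled steps contracts the cloud
geometrically but slowly: on the 5-dimensional sphere with a 1000-call
budget the median best energy lands around $10^{-1}$–$10^{-2}$, far
better than a matched random search (about 10) but far from machine
precision. The operators scale their steps with the magnitudes of the
incumbent positions, so precision beyond roughly the restart step scale
is reached only slowly. The test suite asserts the achievable property
(order-of-magnitude dominance over random search), not an arbitrary
precision.

On purely discrete spaces the landscape is piecewise constant and the
search benefits much more from independent restarts than from long
single runs; the exhaustive-enumeration check therefore spends its
budget as several short runs.

## The fitness function

`build_blueprint()` decodes an assignment into an architecture: `Nc`
blocks of valid (unpadded, stride-1) convolution with shared filter
count and kernel size, ReLU, and non-overlapping max-pooling where
spatially feasible; then flatten, dropout, and a dense softmax head
trained by SGD with momentum under cross-entropy. Oversized kernels are
clipped to the current spatial extent and pooling is skipped once it
would reduce a spatial dimension below one pixel, so every point of the
space decodes to a trainable network — the optimizer never sees a
crash-valued candidate. ReLU is used inside blocks (the conventional
choice where none is dictated) and plain SGD with momentum is implied
by the momentum hyperparameter.

`evaluate_fitness()` partitions the training set into $k = 5$
stratified folds (per fold and class the count deviates from the equal
share by at most one), trains on $k-1$ folds with early stopping on
validation loss (patience 20), caps epochs at
$\min(N_e, \text{epoch\_cap})$, and returns the mean fold validation
accuracy. The mean is used as the scalar fed back to the optimizer —
the lowest-variance choice — while the best fold is recorded
separately. Training divergence (non-finite loss) yields fitness 0 with
a `diverged` flag rather than an error. Identical assignment/seed pairs
are served from a memo cache without retraining, and the evaluator
saves and restores the global RNG state so that fitness evaluation
never perturbs the optimizer's random stream.

The tensor computation itself is a compact in-package backend:
im2col gathers feeding BLAS matrix multiplies, exact backpropagation
(verified against finite differences in the tests), inverted dropout,
and mini-batch SGD with momentum.

### The compute guard

Table-range extremes (20 layers of 500 filters with no pooling) are
GPU-scale. For desk-scale runs the fitness configuration carries a
budget on estimated training cost, `forward flops/image + 40 ×
parameter count` (the second term proxies weight-update and
initialization cost); blueprints over budget score fitness 0 with an
`over_budget` flag, exactly like divergence. The desk profile sets this
budget to $10^7$, under which well-performing small networks remain
plentiful; the paper-scale profile disables the guard.

## The synthetic data generator

`generate_dataset()` draws each class from a distinct parametric
texture family chosen as a minimal generative stand-in for the four
habitat morphotypes: oriented sinusoidal gratings (strap-like leaves),
near-round bright ellipses on a mid ground with one blob per image
quadrant (oval leaves), recursive branching line segments rooted in
each horizontal half (stems), and bilinearly-smoothed low-frequency
noise with bright speckle (background). Additive Gaussian pixel noise
(sd 0.03–0.05) is applied and pixels are clamped to $[0, 1]$.
Generation, slicing and overlay rendering are deterministic under the
generator seed.

The families are constructed so that *every* grid patch of an image
contains class-typical material, because patch labels are inherited
from the whole image; without that property patch labels would be
irreducibly noisy. What passing tests on this generator show is that
the pipeline can discover architectures separating visually distinct
texture classes under a tiny budget — they say nothing about underwater
imaging conditions, class imbalance, illumination or scale variation in
real habitat photographs.

Grid slicing is row-major with the top-left patch first; reassembling
patches in provenance order reconstructs the image exactly. The overlay
palette defaults to blue / yellow / purple / maroon, one colour per
morphotype class.

## The pipeline and its profiles

`run_search()` splits the dataset at the *image* level (stratified
80/20) before any slicing, so no parent image contributes patches to
both sides; cross-validation folds are drawn from the training side
only. The optimizer minimizes $1 -$ accuracy, preserving the
energy-minimization convention. After the search, the winning
blueprint's five cross-validation fold models are rebuilt (same fold
split, same initialization seeds as the fitness evaluation — these
*are* the models trained during the search's evaluation of that
candidate) and the untouched test split is classified once by their
averaged softmax. This saved-models protocol was chosen over a
fresh full-training-set retrain after measuring both: at desk scale a
single retrained network's test accuracy varies with initialization by
several percentage points (sd ≈ 0.06 on a fixed blueprint), which
swamps the optimizer comparison, while the fold-model average is both
closer to the protocol of saving the best cross-validation model and
far more stable (sd ≈ 0.015).

Two profiles bundle the protocol constants. The paper-scale profile is
population 30, 20 iterations, 10 runs, patience 20, $k = 5$, no
compute guard. The desk profile, used by the tests and the acceptance
script, scales the search to population 8, 5 iterations, 1 run, epoch
cap 15 (30 for the final retrain), the compute guard above, a
stagnation threshold of 2 (a threshold of 5 can never fire within 5
iterations), and a dataset of 120 patch-sized (12 × 12 px) images, 30
per class. These sizes were chosen once as the smallest configuration
on which the four texture classes remain reliably learnable.

## Numerical choices and degenerate inputs

* Ties in max-pooling take the first maximum, making pooling gradients
  deterministic.
* Softmax is computed with the row-max subtracted; validation
  cross-entropy floors probabilities at $10^{-12}$.
* Sample standard deviation ($n-1$) throughout; a single-run summary
  reports sd 0.
* Precision, recall and F1 are defined as 0 when their denominator is
  0, so metrics are total on degenerate folds.
* Layer counts drawn above the population size are clamped to it;
  every layer keeps at least one electron.
* `repair()` is idempotent clamping; `discretize()` rejects
  coordinates outside $[0, 1]$ rather than silently wrapping.

## Known limitations

* The backend is CPU-only and deliberately minimal (no padding, no
  stride choices, no batch normalization, no augmentation); it exists
  to make architecture search testable end-to-end, not to reach
  state-of-the-art accuracy on real imagery.
* One filter count, kernel size and pooling size are shared across all
  blocks, mirroring the one-value-per-hyperparameter search space;
  per-layer spaces are out of scope.
* The update rule of the undefined auxiliary parameter mentioned in
  some algorithm listings of this family ("C2") has no published
  definition and is not implemented.
* Fitness is noisy at desk scale (validation folds of ~20 samples);
  run-to-run variance of the searched-and-retrained test accuracy is a
  few percentage points.

## A worked desk-scale example

```{r example, eval = FALSE}
library(baoscnn)

cfg <- run_config("desk", optimizer = list(algorithm = "baos"),
                  output = "run-artifacts")
res <- run_search(cfg, seed = 1)

res$search_summary        # best/worst/mean/sd of per-run search accuracy
res$test_metrics          # per-class precision/recall/F1 and accuracy
res$best_assignment       # the selected hyperparameters
```

Benchmark comparisons run in seconds:

```{r bench, eval = FALSE}
run_benchmarks(c("sphere", "rastrigin"), c("aos", "baos", "random"),
               d = 5, m = 20, max_iterations = 25, n_runs = 3, seed = 1)
```
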