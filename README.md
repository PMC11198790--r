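# baoscnn

Hyperparameter neuroevolution for patch-based habitat image
classification, built around the **Boosted Atomic Orbital Search
(BAOS)** metaheuristic — atomic orbital search augmented with
Lévy-flight photon-rate updates and stagnation restarts.

The package is for researchers who want to tune small convolutional
classifiers for benthic imagery (seagrass morphotypes: strap-like
leaves, oval leaves, branched stems, background texture) without manual
architecture engineering, and for anyone studying population
metaheuristics on mixed discrete/continuous spaces.

## The method

Candidate solutions ("electrons") are positions in a nine-dimensional
hyperparameter space (conv layers `Nc`, kernel `Ks`, filters `Nf`,
epochs `Ne`, batch size `Bs`, pooling `MPs`, dropout `Dr`, learning
rate `Lr`, momentum `Mr`). Discrete dimensions live on [0, 1] and are
decoded through the discretization map

    alpha = 1 + n R,   beta = min(floor(alpha), n),   value = K_beta

for a category grid `K_1..K_n`. Each iteration the population is sorted
into imaginary orbital layers; an electron either undergoes a *photon
interaction* — a pull combining the best-so-far candidate `LE` and a
binding state `BS` (centroid), `X += a ⊙ (b·LE − c·BS)/k` — or a small
random walk, followed by greedy acceptance. BAOS boosts plain AOS by
re-drawing each electron's photon rate from a Lévy(β = 1.5) step
(Mantegna sampler, median calibrated to 0.1) and by relocating
stagnating electrons with a Lévy flight from `LE`.

The fitness of a candidate is the mean validation accuracy of the
decoded CNN over stratified 5-fold cross-validation with early stopping
(patience 20), i.e. the optimizer minimizes `1 − accuracy`. An
in-package backend (im2col convolution over BLAS, exact
backpropagation, SGD with momentum) trains the networks.

## A worked example

A desk-scale search (population 8, 5 iterations, epoch cap 15, four
synthetic texture classes, 120 images of 12×12 px):

```r
library(baoscnn)

cfg <- run_config("desk", optimizer = list(algorithm = "baos"),
                  output = "run-artifacts")
res <- run_search(cfg, seed = 3)

res$search_summary
#> best 0.8900  worst 0.8900  mean 0.8900  sd 0.0000
res$test_accuracy
#> [1] 1
str(res$best_assignment)
#> List of 9
#>  $ n_conv_layers: int 4
#>  $ kernel_size  : int 2
#>  $ n_filters    : int 63
#>  $ n_epochs     : int 57
#>  $ batch_size   : int 10
#>  $ pool_size    : int 6
#>  $ dropout      : num 0.3
#>  $ learning_rate: num 0.031
#>  $ momentum     : num 0.95
```

`search_summary` reports best/worst/mean/sd of the cross-validated
search accuracy over the independent runs (one run in the desk
profile); `test_accuracy` scores the winning blueprint's five
cross-validation fold models (averaged softmax) once on the held-out
image-level test split. The run directory receives `config.yaml`,
`log.txt`, `best_assignment.json`, `convergence.csv` and
`metrics.json`.

Optimizer behaviour on analytic benchmarks:

```r
run_benchmarks("rastrigin", c("aos", "baos", "random"),
               d = 10, m = 30, max_iterations = 100, n_runs = 3, seed = 1)
```

A thin command-line front end with the same capabilities is installed
at `inst/cli/baoscnn` (subcommands `search`, `benchmark`,
`generate-data`, `evaluate`, `overlay`).

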