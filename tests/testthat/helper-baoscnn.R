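# Shared helpers for the test suite.

# Power-law tail index of |x| by least squares on the empirical survival
# function, using order statistics of rank kmin..kmax (descending), i.e.
# regressing log(rank/n) on log magnitude; returns the negated slope.
tail_index <- function(x, kmin = 20L, kmax = 2000L) {
  a <- sort(abs(x), decreasing = TRUE)
  k <- seq.int(kmin, min(kmax, length(a)))
  fit <- stats::lm(log(k / length(a)) ~ log(a[k]))
  -unname(stats::coef(fit)[2L])
}

# Tiny discrete space whose 4 x 4 x 4 = 64 assignments can be enumerated.
tiny_discrete_space <- function() {
  search_space(
    hp_discrete("a", 1:4),
    hp_discrete("b", 1:4),
    hp_discrete("c", 1:4)
  )
}

# Deterministic pseudo-random objective over the tiny space with a unique
# global minimum; the table is frozen so tests and exhaustive enumeration
# see the same landscape.
tiny_objective_table <- local({
  set.seed(20240607)
  vals <- sample(seq_len(64))
  array(vals, dim = c(4, 4, 4))
})

tiny_objective <- function(assignment) {
  tiny_objective_table[assignment$a, assignment$b, assignment$c]
}

# Build a population at fixed positions (through the public API).
initialize_population_at <- function(space, positions) {
  pop <- initialize_population(space, nrow(positions))
  pop$positions <- positions
  pop
}

# A small, reliably trainable blueprint assignment.
modest_assignment <- function() {
  list(n_conv_layers = 2L, kernel_size = 3L, n_filters = 16L,
       n_epochs = 15L, batch_size = 20L, pool_size = 2L, dropout = 0.2,
       learning_rate = 0.051, momentum = 0.9)
}

# Small separable synthetic dataset of patch-sized images.
small_dataset <- function(per_class = 10L, size = 12L, seed = 7L,
                          noise_sd = 0.03) {
  generate_dataset(synthetic_spec(per_class = per_class,
                                  image_size = c(size, size),
                                  rows = 1L, cols = 1L,
                                  noise_sd = noise_sd, seed = seed))
}
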