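test_that("blueprints are built with feasible conv/pool stacks", {
  a <- modest_assignment()
  bp <- build_blueprint(a, c(32L, 32L), 4L)
  types <- vapply(bp$plan$ops, `[[`, character(1L), "type")
  expect_equal(types, c("conv", "pool", "conv", "pool"))
  expect_true(all(bp$plan$out_shape >= 1L))

  # a deep stack on a small input pools only while spatially feasible
  deep <- a
  deep$n_conv_layers <- 20L
  deep$pool_size <- 2L
  bp20 <- build_blueprint(deep, c(32L, 32L), 4L)
  types20 <- vapply(bp20$plan$ops, `[[`, character(1L), "type")
  expect_equal(sum(types20 == "conv"), 20L)
  expect_lt(sum(types20 == "pool"), 20L)
  expect_true(all(bp20$plan$out_shape >= 1L))

  # oversized kernels are clipped, never rejected
  wide <- a
  wide$kernel_size <- 30L
  bp30 <- build_blueprint(wide, c(12L, 12L), 4L)
  expect_equal(bp30$plan$ops[[1L]]$k, 12L)

  expect_error(build_blueprint(list(n_conv_layers = 1L), c(12L, 12L), 4L),
               "lacks")
})

test_that("the network head is a softmax over n_classes", {
  bp <- build_blueprint(modest_assignment(), c(12L, 12L), 4L)
  set.seed(61)
  model <- baoscnn:::cnn_init(bp$plan, 4L, bp$dropout)
  expect_equal(ncol(model$dense$W), 4L)
  X <- matrix(stats::runif(3L * 144L), 3L)
  fw <- baoscnn:::cnn_forward(model, X)
  expect_equal(dim(fw$probs), c(3L, 4L))
  expect_equal(rowSums(fw$probs), rep(1, 3L), tolerance = 1e-12)
  expect_true(all(fw$probs > 0))
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(62)
  plan <- baoscnn:::cnn_plan(2L, 3L, 4L, 2L, c(8L, 8L))
  model <- baoscnn:::cnn_init(plan, 3L, dropout = 0)
  X <- matrix(stats::runif(5L * 64L), 5L)
  y <- c(1L, 2L, 3L, 1L, 2L)
  loss <- function(m) {
    fw <- baoscnn:::cnn_forward(m, X)
    -mean(log(fw$probs[cbind(1:5, y)]))
  }
  fw <- baoscnn:::cnn_forward(model, X, train = TRUE)
  gr <- baoscnn:::cnn_backward(model, X, y, fw)
  eps <- 1e-6
  for (li in 1:2) {
    for (ij in list(c(1L, 1L), c(5L, 2L), c(9L, 4L))) {
      m2 <- model
      m2$conv[[li]]$W[ij[1L], ij[2L]] <- m2$conv[[li]]$W[ij[1L], ij[2L]] + eps
      num <- (loss(m2) - loss(model)) / eps
      expect_equal(gr$conv[[li]]$W[ij[1L], ij[2L]], num, tolerance = 1e-4)
    }
  }
  m2 <- model
  m2$dense$b[2L] <- m2$dense$b[2L] + eps
  expect_equal(gr$dense$b[2L], (loss(m2) - loss(model)) / eps,
               tolerance = 1e-4)
})

test_that("stratified folds balance every class to within one sample", {
  labels <- rep(1:4, each = 25L)
  f <- stratified_folds(labels, 5L, seed = 63L)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(as.vector(table(f)), rep(20L, 5L))
  for (k in 1:5) {
    expect_equal(as.vector(table(labels[f == k])), rep(5L, 4L))
  }
  # unbalanced classes stay within one of the equal share
  lab2 <- c(rep(1L, 23L), rep(2L, 11L))
  f2 <- stratified_folds(lab2, 4L, seed = 64L)
  for (k in 1:4) {
    for (cl in 1:2) {
      n_cl <- sum(lab2 == cl)
      expect_lte(abs(sum(lab2[f2 == k] == cl) - n_cl / 4), 1)
    }
  }
  expect_identical(stratified_folds(labels, 5L, seed = 1L),
                   stratified_folds(labels, 5L, seed = 1L))
  expect_error(stratified_folds(c(1L, 1L, 2L), 3L), "fewer than")
})

test_that("cross-validated fitness is the mean of its fold accuracies", {
  ds <- small_dataset(per_class = 10L)
  rec <- evaluate_fitness(modest_assignment(), ds,
                          fitness_config(epoch_cap = 4L, seed = 2L))
  expect_length(rec$fold_accuracies, 5L)
  expect_equal(rec$fitness, mean(rec$fold_accuracies))
  expect_gte(rec$fitness, min(rec$fold_accuracies))
  expect_lte(rec$fitness, max(rec$fold_accuracies))
  expect_equal(rec$best_fold, which.max(rec$fold_accuracies))
  expect_length(rec$history, 5L)
  # epoch cap respected in every fold
  expect_true(all(vapply(rec$history, nrow, integer(1L)) <= 4L))
})

test_that("a modest network separates the synthetic classes", {
  ds <- small_dataset(per_class = 50L)
  rec <- evaluate_fitness(modest_assignment(), ds, fitness_config(seed = 1L))
  expect_gt(rec$fitness, 0.9)
})

test_that("label-shuffled data scores near the chance level", {
  ds <- small_dataset(per_class = 25L)
  set.seed(65)
  ds$labels <- sample(ds$labels)
  rec <- evaluate_fitness(modest_assignment(), ds,
                          fitness_config(epoch_cap = 8L, seed = 3L))
  expect_lt(abs(rec$fitness - 0.25), 0.1)
})

test_that("identical assignment and seed hit the cache without retraining", {
  ds <- small_dataset(per_class = 10L)
  cfg <- fitness_config(epoch_cap = 3L, seed = 4L)
  obj <- make_fitness_objective(ds, cfg)
  a <- modest_assignment()
  e1 <- obj(a)
  expect_equal(attr(obj, "trainings")(), 1L)
  e2 <- obj(a)
  expect_equal(attr(obj, "trainings")(), 1L)  # cached: no second training
  expect_identical(e1, e2)
  b <- a; b$n_filters <- 8L
  obj(b)
  expect_equal(attr(obj, "trainings")(), 2L)
})

test_that("divergence and over-budget blueprints score zero with a flag", {
  ds <- small_dataset(per_class = 10L)
  diverging <- modest_assignment()
  diverging$learning_rate <- 1e150
  rec <- evaluate_fitness(diverging, ds, fitness_config(epoch_cap = 3L,
                                                        seed = 5L))
  expect_equal(rec$fitness, 0)
  expect_true("diverged" %in% rec$flags)

  heavy <- modest_assignment()
  heavy$n_filters <- 500L
  heavy$n_conv_layers <- 10L
  rec2 <- evaluate_fitness(heavy, ds,
                           fitness_config(flop_budget = 1e6, seed = 6L))
  expect_equal(rec2$fitness, 0)
  expect_true("over_budget" %in% rec2$flags)
})

test_that("fitness evaluation does not perturb the caller's random stream", {
  ds <- small_dataset(per_class = 10L)
  set.seed(66)
  r1 <- stats::runif(1)
  set.seed(66)
  invisible(evaluate_fitness(modest_assignment(), ds,
                             fitness_config(epoch_cap = 2L, seed = 7L)))
  r2 <- stats::runif(1)
  expect_identical(r1, r2)
})
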