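#' Build a CNN blueprint from a hyperparameter assignment
#'
#' Decodes a named assignment from the default nine-dimensional space into
#' a backend-agnostic architecture description: `n_conv` convolutional
#' blocks (valid convolution, ReLU, max-pool while spatially feasible)
#' sharing one filter count / kernel size / pool size, a flatten stage,
#' dropout, and a dense softmax output trained by SGD with momentum.
#' Infeasible kernel or pool sizes are clipped, never rejected: kernels
#' are clipped to the current spatial extent and pooling is skipped once
#' it would reduce a spatial dimension below one pixel, so every
#' assignment decodes to a trainable network.
#'
#' @param assignment Named list with `n_conv_layers`, `kernel_size`,
#'   `n_filters`, `n_epochs`, `batch_size`, `pool_size`, `dropout`,
#'   `learning_rate`, `momentum` (as produced by [decode()] on
#'   [default_seagrass_space()]).
#' @param input_shape `(height, width)` or `(height, width, channels)`.
#' @param n_classes Number of output classes.
#' @return A `cnn_blueprint` with the resolved layer plan and a
#'   forward-flops-per-image estimate.
#' @export
build_blueprint <- function(assignment, input_shape, n_classes) {
  need <- c("n_conv_layers", "kernel_size", "n_filters", "n_epochs",
            "batch_size", "pool_size", "dropout", "learning_rate",
            "momentum")
  missing <- setdiff(need, names(assignment))
  if (length(missing) > 0L) {
    stop(sprintf("assignment lacks hyperparameters: %s",
                 paste(missing, collapse = ", ")))
  }
  input_shape <- as.integer(input_shape)
  plan <- cnn_plan(n_conv = as.integer(assignment$n_conv_layers),
                   kernel = as.integer(assignment$kernel_size),
                   filters = as.integer(assignment$n_filters),
                   pool = as.integer(assignment$pool_size),
                   input_shape = input_shape)
  structure(list(
    n_conv = as.integer(assignment$n_conv_layers),
    kernel = as.integer(assignment$kernel_size),
    filters = as.integer(assignment$n_filters),
    pool = as.integer(assignment$pool_size),
    dropout = as.numeric(assignment$dropout),
    learning_rate = as.numeric(assignment$learning_rate),
    momentum = as.numeric(assignment$momentum),
    epochs = as.integer(assignment$n_epochs),
    batch_size = as.integer(assignment$batch_size),
    input_shape = input_shape, n_classes = as.integer(n_classes),
    plan = plan, flops = plan_flops(plan, n_classes),
    params = plan_params(plan, n_classes)),
    class = "cnn_blueprint")
}

#' @export
print.cnn_blueprint <- function(x, ...) {
  cat(sprintf(paste0("cnn_blueprint: %d conv block(s), %d filters, kernel %d, ",
                     "pool %d -> %s features\n"),
              x$n_conv, x$filters, x$kernel, x$pool, x$plan$out_dim))
  cat(sprintf("  dropout %.2f, lr %g, momentum %.2f, epochs %d, batch %d\n",
              x$dropout, x$learning_rate, x$momentum, x$epochs, x$batch_size))
  cat(sprintf("  ~%.2g forward flops/image\n", x$flops))
  invisible(x)
}

#' Stratified k-fold partition
#'
#' Assigns every sample a fold index in `1..k` such that each class is
#' split as evenly as possible across folds (per fold and class the count
#' deviates from the equal share by at most one).
#'
#' @param labels Integer class labels.
#' @param k Number of folds (`>= 2`).
#' @param seed Optional seed for the shuffle.
#' @return Integer vector of fold indices, one per sample.
#' @export
stratified_folds <- function(labels, k, seed = NULL) {
  stopifnot(k >= 2L)
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop(sprintf("class %s has %d samples, fewer than k = %d folds",
                   cl, length(idx), k))
    }
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Fitness evaluation configuration
#'
#' @param k_folds Cross-validation folds (default 5).
#' @param patience Early-stopping patience in epochs (default 20).
#' @param epoch_cap Per-fold epoch ceiling; the effective epoch count is
#'   `min(n_epochs, epoch_cap)`.
#' @param flop_budget Desk-scale compute guard: blueprints whose estimated
#'   training cost, `forward flops/image + 40 * parameter count` (the
#'   second term proxies weight-update and initialization cost), exceeds
#'   this ceiling score fitness 0 with an `over_budget` flag (use `Inf`
#'   to disable).
#' @param seed Seed governing fold assignment, weight initialization,
#'   dropout and batch shuffling.
#' @return A `fitness_config` object.
#' @export
fitness_config <- function(k_folds = 5L, patience = 20L, epoch_cap = 15L,
                           flop_budget = Inf, seed = 1L) {
  stopifnot(k_folds >= 2L, patience >= 1L, epoch_cap >= 1L, flop_budget > 0)
  structure(list(k_folds = as.integer(k_folds), patience = as.integer(patience),
                 epoch_cap = as.integer(epoch_cap), flop_budget = flop_budget,
                 seed = as.integer(seed)),
            class = "fitness_config")
}

# Memo key over the *resolved* training computation: the realized layer
# stack (clipped kernels, applied pooling), the effective epoch count
# and batch size, the training-rate hyperparameters and the seed.
# Assignments that differ only in ways the clipping/capping erases
# (e.g. epochs beyond the cap) share one cache entry.
blueprint_key <- function(bp, config, n_samples) {
  ops <- vapply(bp$plan$ops, function(o) {
    if (o$type == "conv") sprintf("c%d.%d", o$k, o$f) else sprintf("p%d", o$p)
  }, character(1L))
  paste(c(ops,
          sprintf("e%d", min(bp$epochs, config$epoch_cap)),
          sprintf("b%d", min(bp$batch_size, n_samples)),
          format(c(bp$dropout, bp$learning_rate, bp$momentum), digits = 15),
          config$seed, config$k_folds), collapse = "|")
}

dataset_matrix <- function(dataset) {
  t(vapply(dataset$images, as.vector,
           numeric(length(dataset$images[[1L]]))))
}

#' Cross-validated fitness of a hyperparameter assignment
#'
#' Trains the blueprint on each of `k` stratified folds (holding one fold
#' out for validation) with early stopping on validation loss, and
#' returns the mean fold validation accuracy as the fitness, together
#' with the per-fold accuracies, the best fold and the training
#' histories. Training divergence (non-finite loss) and blueprints over
#' the flop budget yield fitness 0 with a diagnostic flag rather than an
#' error. When `cache` (an environment) is supplied, identical
#' assignment + seed pairs return the stored record without retraining.
#' The global RNG state is saved and restored, so calling this inside an
#' optimizer does not perturb the optimizer's random stream.
#'
#' @param assignment Named hyperparameter list (see [build_blueprint()]).
#' @param dataset A `morphotype_dataset` (or any list with `images`,
#'   `labels`, `class_names`).
#' @param config A [fitness_config()].
#' @param cache Optional environment used as a memo table.
#' @return A `fitness_record`: `fold_accuracies`, `fitness`, `best_fold`,
#'   `history`, `flags`, `blueprint`.
#' @export
evaluate_fitness <- function(assignment, dataset, config = fitness_config(),
                             cache = NULL) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  n_classes <- length(dataset$class_names)
  shape <- dim(dataset$images[[1L]])
  bp <- build_blueprint(assignment, shape, n_classes)
  key <- blueprint_key(bp, config, length(dataset$labels))
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  k <- config$k_folds
  if (bp$flops + 40 * bp$params > config$flop_budget) {
    rec <- structure(list(fold_accuracies = rep(0, k), fitness = 0,
                          best_fold = 1L, history = list(),
                          flags = "over_budget", blueprint = bp),
                     class = "fitness_record")
  } else {
    X <- dataset_matrix(dataset)
    y <- dataset$labels
    folds <- stratified_folds(y, k, seed = config$seed)
    accs <- numeric(k)
    hist <- vector("list", k)
    flags <- character(0)
    for (j in seq_len(k)) {
      tr <- folds != j
      set.seed(config$seed * 131L + j)
      model <- cnn_init(bp$plan, n_classes, bp$dropout)
      fit <- cnn_fit(model, X[tr, , drop = FALSE], y[tr],
                     X[!tr, , drop = FALSE], y[!tr],
                     epochs = min(bp$epochs, config$epoch_cap),
                     batch_size = bp$batch_size, lr = bp$learning_rate,
                     momentum = bp$momentum, patience = config$patience)
      hist[[j]] <- fit$history
      if (fit$diverged) {
        accs <- rep(0, k)
        flags <- "diverged"
        break
      }
      accs[j] <- mean(cnn_predict(fit$model, X[!tr, , drop = FALSE]) == y[!tr])
    }
    rec <- structure(list(fold_accuracies = accs,
                          fitness = if (length(flags)) 0 else mean(accs),
                          best_fold = which.max(accs), history = hist,
                          flags = flags, blueprint = bp),
                     class = "fitness_record")
  }
  if (!is.null(cache)) cache[[key]] <- rec
  rec
}

#' @export
print.fitness_record <- function(x, ...) {
  cat(sprintf("fitness %.4f (fold accuracies: %s; best fold %d)%s\n",
              x$fitness, paste(sprintf("%.3f", x$fold_accuracies),
                               collapse = ", "),
              x$best_fold,
              if (length(x$flags)) paste0(" [", x$flags, "]") else ""))
  invisible(x)
}

#' Wrap cross-validated fitness as a minimization objective
#'
#' Returns a closure mapping an assignment to `1 - fitness` (so that the
#' optimizer's energy-minimization convention maximizes accuracy), with a
#' shared memo cache and a true-training counter.
#'
#' @param dataset A `morphotype_dataset`.
#' @param config A [fitness_config()].
#' @return A function with attributes `cache` (the memo environment) and
#'   `trainings()` (count of non-cached evaluations).
#' @export
make_fitness_objective <- function(dataset, config = fitness_config()) {
  cache <- new.env(parent = emptyenv())
  f <- function(assignment) {
    1 - evaluate_fitness(assignment, dataset, config, cache = cache)$fitness
  }
  attr(f, "cache") <- cache
  # each distinct cache entry corresponds to one real k-fold training
  attr(f, "trainings") <- function() length(ls(cache))
  f
}
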