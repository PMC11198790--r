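#' Run configuration for the neuroevolution pipeline
#'
#' Builds the nested configuration consumed by [run_search()]. Two
#' profiles are provided: `"desk"` (population 8, 5 iterations, 1 run,
#' epoch cap 15, a forward-flop compute guard, small synthetic images) for
#' CPU-scale experimentation, and `"paper"` (population 30, 20 iterations,
#' 10 runs, no compute guard) matching the full search protocol. Any
#' element can be overridden via the block arguments, which are merged
#' over the profile defaults.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param optimizer,fitness,data,space Named lists merged over the
#'   profile's defaults for that block.
#' @param split Training fraction of the image-level train/test split.
#' @param output Optional output directory for run artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(profile = c("desk", "paper"), optimizer = list(),
                       fitness = list(), data = list(), space = "default",
                       split = 0.8, output = NULL) {
  profile <- match.arg(profile)
  base <- if (profile == "desk") {
    list(optimizer = list(algorithm = "baos", m = 8L, max_iterations = 5L,
                          n_runs = 1L, layer_max = 5L, limit_threshold = 2,
                          seed = 1L, levy = list(beta = 1.5)),
         fitness = list(k_folds = 5L, patience = 20L, epoch_cap = 15L,
                        flop_budget = 1e7),
         data = list(type = "synthetic", n_classes = 4L, per_class = 30L,
                     image_size = c(12L, 12L), rows = 1L, cols = 1L,
                     noise_sd = 0.03, seed = 7L, patch_based = FALSE))
  } else {
    list(optimizer = list(algorithm = "baos", m = 30L, max_iterations = 20L,
                          n_runs = 10L, layer_max = 5L, limit_threshold = 5,
                          seed = 1L, levy = list(beta = 1.5)),
         fitness = list(k_folds = 5L, patience = 20L, epoch_cap = 400L,
                        flop_budget = Inf),
         data = list(type = "synthetic", n_classes = 4L, per_class = 40L,
                     image_size = c(2400L, 2400L), rows = 6L, cols = 6L,
                     noise_sd = 0.05, seed = 7L, patch_based = TRUE))
  }
  cfg <- list(profile = profile,
              space = space,
              optimizer = utils::modifyList(base$optimizer, optimizer),
              fitness = utils::modifyList(base$fitness, fitness),
              data = utils::modifyList(base$data, data),
              split = split, output = output)
  class(cfg) <- "run_config"
  cfg
}

#' Load / save a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `run_config`.
#' @return `read_run_config()`: a `run_config`; `write_run_config()`: the
#'   path, invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  profile <- raw$profile %||% "desk"
  run_config(profile = profile,
             optimizer = raw$optimizer %||% list(),
             fitness = raw$fitness %||% list(),
             data = raw$data %||% list(),
             space = raw$space %||% "default",
             split = raw$split %||% 0.8,
             output = raw$output)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_space <- function(space) {
  if (inherits(space, "search_space")) return(space)
  if (identical(space, "default")) return(default_seagrass_space())
  space_from_config(space)
}

# Stratified image-level split: per class, round(frac * n) samples go to
# the training side (at least 1 on each side when n >= 2).
stratified_split <- function(labels, frac, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, min(length(idx) - 1L, round(frac * length(idx))))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

subset_dataset <- function(dataset, keep) {
  structure(list(images = dataset$images[keep],
                 labels = dataset$labels[keep],
                 class_names = dataset$class_names),
            class = "morphotype_dataset")
}

build_run_dataset <- function(dcfg, split, seed) {
  if (identical(dcfg$type, "synthetic")) {
    spec <- synthetic_spec(n_classes = dcfg$n_classes,
                           per_class = dcfg$per_class,
                           image_size = dcfg$image_size,
                           rows = dcfg$rows, cols = dcfg$cols,
                           noise_sd = dcfg$noise_sd,
                           seed = dcfg$seed)
    imgs <- generate_dataset(spec)
  } else if (identical(dcfg$type, "directory")) {
    imgs <- read_dataset(dcfg$path)
  } else {
    stop("data$type must be 'synthetic' or 'directory'")
  }
  # split at image level (before any slicing) so no parent image
  # contributes patches to both sides
  tr <- stratified_split(imgs$labels, split, seed = seed + 17L)
  train <- subset_dataset(imgs, tr)
  test <- subset_dataset(imgs, !tr)
  if (isTRUE(dcfg$patch_based)) {
    train <- slice_dataset(train, dcfg$rows, dcfg$cols)
    test <- slice_dataset(test, dcfg$rows, dcfg$cols)
  }
  list(train = train, test = test)
}

#' Execute a hyperparameter search and evaluate the best network
#'
#' The full pipeline: build (or load) the dataset, split it into training
#' and test sets at the image level, slice images into the patch grid,
#' run the configured optimizer with the cross-validated accuracy fitness
#' (minimizing `1 - accuracy`), rebuild the winning blueprint's five
#' cross-validation fold models (the saved-models protocol) and classify
#' the held-out test split once with their averaged softmax. When `config$output` is
#' set, writes the resolved configuration, a log, the best assignment
#' (JSON), the convergence trace (CSV) and the test metrics (JSON).
#'
#' @param config A [run_config()].
#' @param seed Optional master-seed override applied to every random
#'   component of the run.
#' @return Invisibly, a list: `result` (the `optimization_result`),
#'   `best_assignment`, `search_summary` (accuracy [run_statistics()] over
#'   runs), `test_metrics`, `test_accuracy`, `artifacts`.
#' @export
run_search <- function(config, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$optimizer$seed <- as.integer(seed)
  master <- config$optimizer$seed
  space <- resolve_space(config$space)
  ds <- build_run_dataset(config$data, config$split, master)

  fcfg <- fitness_config(k_folds = config$fitness$k_folds,
                         patience = config$fitness$patience,
                         epoch_cap = config$fitness$epoch_cap,
                         flop_budget = config$fitness$flop_budget %||% Inf,
                         seed = master)
  objective <- make_fitness_objective(ds$train, fcfg)
  lcfg <- do.call(levy_config, config$optimizer$levy %||% list())
  params <- optimizer_params(algorithm = config$optimizer$algorithm,
                             m = config$optimizer$m,
                             max_iterations = config$optimizer$max_iterations,
                             n_runs = config$optimizer$n_runs,
                             layer_max = config$optimizer$layer_max,
                             limit_threshold = config$optimizer$limit_threshold,
                             levy = lcfg, seed = master)
  result <- optimize_space(objective, space, params)

  # final classifier: re-run the k-fold training of the best blueprint,
  # saving all fold models, and classify the untouched test split with
  # their averaged softmax (the saved-models protocol; far lower variance
  # than a single retrained network at desk scale)
  best <- result$best_assignment
  n_classes <- length(ds$train$class_names)
  bp <- build_blueprint(best, dim(ds$train$images[[1L]]), n_classes)
  X <- dataset_matrix(ds$train)
  y <- ds$train$labels
  # identical fold split and init seeds as the fitness evaluation, so
  # these are exactly the cross-validation models of the winning candidate
  folds <- stratified_folds(y, fcfg$k_folds, seed = fcfg$seed)
  models <- vector("list", fcfg$k_folds)
  for (j in seq_len(fcfg$k_folds)) {
    tr_j <- folds != j
    set.seed(master * 131L + j)
    model <- cnn_init(bp$plan, n_classes, bp$dropout)
    fit <- cnn_fit(model, X[tr_j, , drop = FALSE], y[tr_j],
                   X[!tr_j, , drop = FALSE], y[!tr_j],
                   epochs = min(bp$epochs, fcfg$epoch_cap),
                   batch_size = bp$batch_size, lr = bp$learning_rate,
                   momentum = bp$momentum, patience = fcfg$patience)
    models[[j]] <- fit$model
  }
  Xte <- dataset_matrix(ds$test)
  probs <- Reduce(`+`, lapply(models, function(m) cnn_forward(m, Xte)$probs))
  pred <- max.col(probs, ties.method = "first")
  cm <- confusion_matrix(ds$test$labels, pred, n_classes,
                         class_names = ds$test$class_names)
  metrics <- classification_metrics(cm)

  run_best_acc <- 1 - vapply(result$per_run, `[[`, numeric(1L), "best_energy")
  out <- list(result = result, best_assignment = best,
              search_summary = run_statistics(run_best_acc),
              confusion = cm, test_metrics = metrics,
              test_accuracy = metrics$accuracy,
              trainings = attr(objective, "trainings")(),
              artifacts = NULL)

  if (!is.null(config$output)) {
    dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      config = file.path(config$output, "config.yaml"),
      log = file.path(config$output, "log.txt"),
      best = file.path(config$output, "best_assignment.json"),
      convergence = file.path(config$output, "convergence.csv"),
      metrics = file.path(config$output, "metrics.json"))
    write_run_config(config, paths$config)
    export_convergence(stats::setNames(list(result),
                                       config$optimizer$algorithm),
                       paths$convergence, as_accuracy = TRUE)
    jsonlite::write_json(best, paths$best, auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(
      test_accuracy = metrics$accuracy,
      per_class = metrics$per_class,
      search = unclass(out$search_summary),
      confusion = unclass(cm)), paths$metrics, auto_unbox = TRUE, digits = NA)
    writeLines(c(
      sprintf("algorithm: %s", config$optimizer$algorithm),
      sprintf("master seed: %d", master),
      sprintf("run seeds: %s",
              paste(vapply(result$per_run, `[[`, numeric(1L), "seed"),
                    collapse = ", ")),
      sprintf("objective evaluations: %d", result$evaluations),
      sprintf("distinct trainings: %d", out$trainings),
      sprintf("best search fitness: %.4f", 1 - result$best_energy),
      sprintf("test accuracy: %.4f", metrics$accuracy)), paths$log)
    out$artifacts <- paths
  }
  invisible(out)
}

#' Compare optimizers on analytic benchmarks
#'
#' Runs the selected algorithms on the selected benchmark functions under
#' a shared configuration and summarizes per-run best values.
#'
#' @param benchmarks Character vector of benchmark names.
#' @param algorithms Character vector among `"aos"`, `"baos"`, `"random"`.
#' @param d Dimension.
#' @param m,max_iterations,n_runs,seed Optimizer protocol.
#' @param out Optional CSV path for the summary table.
#' @return A data frame with one row per (benchmark, algorithm):
#'   best/worst/mean/sd of the per-run best energies, plus the
#'   `optimization_result`s as the `"results"` attribute.
#' @export
run_benchmarks <- function(benchmarks = "sphere",
                           algorithms = c("aos", "baos", "random"),
                           d = 2L, m = 20L, max_iterations = 25L,
                           n_runs = 3L, seed = 1L, out = NULL) {
  rows <- list()
  results <- list()
  for (bn in benchmarks) {
    space <- benchmark_space(bn, d)
    obj <- benchmark_objective(bn)
    for (alg in algorithms) {
      params <- optimizer_params(algorithm = alg, m = m,
                                 max_iterations = max_iterations,
                                 n_runs = n_runs, seed = seed)
      res <- optimize_space(obj, space, params)
      results[[paste(bn, alg, sep = "_")]] <- res
      e <- vapply(res$per_run, `[[`, numeric(1L), "best_energy")
      rows[[length(rows) + 1L]] <- data.frame(
        benchmark = bn, algorithm = alg, d = d,
        best = min(e), worst = max(e), mean = mean(e),
        sd = if (length(e) > 1L) stats::sd(e) else 0,
        evaluations = res$evaluations)
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(df, out, row.names = FALSE)
  attr(df, "results") <- results
  df
}
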