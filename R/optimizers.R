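#' Optimizer parameters
#'
#' Configuration shared by the atomic orbital search (AOS), its
#' Levy-boosted variant (BAOS) and the budget-matched random-search
#' baseline. The defaults mirror the neuroevolution protocol: population
#' of 30 electrons, 20 iterations, 10 independent runs.
#'
#' @param algorithm One of `"baos"`, `"aos"`, `"random"`.
#' @param m Population size (number of electrons).
#' @param max_iterations Iterations per run.
#' @param n_runs Independent restarts; per-run seeds are derived from
#'   `seed` by fixed increments.
#' @param layer_max Maximum number of imaginary orbital layers; the layer
#'   count each iteration is drawn uniformly from `1..layer_max`.
#' @param limit_threshold Consecutive non-improving iterations after which
#'   a BAOS electron is relocated by a Levy flight from the best-so-far
#'   position (`Inf` disables restarts).
#' @param pr Baseline photon rate in `[0, 1]`; AOS keeps it fixed.
#' @param pr_update Whether the photon rate is re-drawn each iteration
#'   from a Levy-modulated rule (default: `TRUE` for BAOS only). The rule
#'   is `PR_i = clamp01(c * |l|)` with `l` a Levy step and `c` calibrated
#'   (by quadrature, deterministically) so the median PR equals `pr`.
#' @param levy A [levy_config()] for photon-rate updates and restarts.
#' @param seed Master seed.
#' @return An `optimizer_params` object.
#' @export
optimizer_params <- function(algorithm = c("baos", "aos", "random"),
                             m = 30L, max_iterations = 20L, n_runs = 10L,
                             layer_max = 5L, limit_threshold = 5,
                             pr = 0.1, pr_update = NULL,
                             levy = levy_config(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(m >= 1, max_iterations >= 1, n_runs >= 1, layer_max >= 1,
            pr >= 0, pr <= 1, inherits(levy, "levy_config"))
  if (is.null(pr_update)) pr_update <- algorithm == "baos"
  use_restarts <- algorithm == "baos" && is.finite(limit_threshold)
  pr_scale <- if (pr_update) pr / levy_abs_median(levy$beta) else NA_real_
  structure(list(algorithm = algorithm, m = as.integer(m),
                 max_iterations = as.integer(max_iterations),
                 n_runs = as.integer(n_runs), layer_max = as.integer(layer_max),
                 limit_threshold = limit_threshold, pr = pr,
                 pr_update = pr_update, use_restarts = use_restarts,
                 pr_scale = pr_scale, levy = levy, seed = as.integer(seed)),
            class = "optimizer_params")
}

#' Initialize an electron population
#'
#' Draws `m` uniform positions from the space; energies are unset until
#' [evaluate_population()] is called; limit counters start at 0 and the
#' photon rate at its baseline value.
#'
#' @param space A `search_space`.
#' @param m Population size.
#' @param pr Baseline photon rate.
#' @return An `aos_population` object.
#' @export
initialize_population <- function(space, m, pr = 0.1) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) stop("m must be >= 1")
  m <- as.integer(m)
  pos <- sample_uniform(space, m)
  colnames(pos) <- NULL
  structure(list(positions = pos,
                 energies = rep(NA_real_, m),
                 pr = rep(pr, m),
                 limit = integer(m),
                 best_position = NULL,
                 best_energy = Inf),
            class = "aos_population")
}

#' Evaluate every electron's energy
#'
#' Applies the objective to each decoded position, records the energies
#' and updates the best-so-far (lowest-energy) candidate. A non-finite
#' objective value is an error reporting the offending position.
#'
#' @param pop An `aos_population`.
#' @param objective Function mapping a decoded named assignment to a real.
#' @param space The `search_space` the positions live in.
#' @return The population with energies set.
#' @export
evaluate_population <- function(pop, objective, space) {
  for (i in seq_along(pop$energies)) {
    e <- objective(decode(space, pop$positions[i, ]))
    if (!is.finite(e)) {
      stop(sprintf("objective returned a non-finite value at position [%s]",
                   paste(signif(pop$positions[i, ], 6), collapse = ", ")))
    }
    pop$energies[i] <- e
    if (e < pop$best_energy) {
      pop$best_energy <- e
      pop$best_position <- pop$positions[i, ]
    }
  }
  pop
}

#' Assign electrons to imaginary orbital layers
#'
#' Draws the layer count uniformly from `1..layer_max`, sorts electrons by
#' energy and partitions them into contiguous groups whose sizes follow a
#' discretized standard normal density over the layer index (every layer
#' keeps at least one electron). The lowest-energy electrons always land
#' in layer 1.
#'
#' @param pop An evaluated `aos_population`.
#' @param layer_max Maximum layer count.
#' @return List with `n_layers` and the per-electron `layer_of` index.
#' @export
assign_layers <- function(pop, layer_max) {
  m <- length(pop$energies)
  L <- min(sample.int(layer_max, 1L), m)
  sizes <- layer_sizes(m, L)
  layer_of <- integer(m)
  layer_of[order(pop$energies)] <- rep.int(seq_len(L), sizes)
  list(n_layers = L, layer_of = layer_of)
}

# Partition m electrons into L contiguous groups with sizes proportional
# to a standard normal density evaluated at layer midpoints on (0, 3],
# by largest remainder, with a floor of one electron per layer.
layer_sizes <- function(m, L) {
  if (L == 1L) return(m)
  w <- stats::dnorm(3 * (seq_len(L) - 0.5) / L)
  target <- w / sum(w) * (m - L)  # reserve one per layer up front
  sizes <- floor(target)
  rem <- (m - L) - sum(sizes)
  if (rem > 0) {
    extra <- order(target - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  as.integer(sizes) + 1L
}

#' Binding state, binding energy and lowest-energy records
#'
#' Computes, for each layer and globally, the binding state (position
#' centroid) and binding energy (mean energy), the per-layer best
#' candidate, and the best-so-far (lowest energy, LE) candidate of the
#' run.
#'
#' @param pop An evaluated `aos_population`.
#' @param layers A layer assignment from [assign_layers()].
#' @return A `binding_record` list.
#' @export
binding <- function(pop, layers) {
  L <- layers$n_layers
  d <- ncol(pop$positions)
  bs_k <- matrix(NA_real_, L, d)
  be_k <- numeric(L)
  le_k <- matrix(NA_real_, L, d)
  le_k_energy <- numeric(L)
  for (k in seq_len(L)) {
    idx <- which(layers$layer_of == k)
    if (length(idx) == 0L) stop("internal error: empty orbital layer")
    bs_k[k, ] <- colMeans(pop$positions[idx, , drop = FALSE])
    be_k[k] <- mean(pop$energies[idx])
    b <- idx[which.min(pop$energies[idx])]
    le_k[k, ] <- pop$positions[b, ]
    le_k_energy[k] <- pop$energies[b]
  }
  structure(list(bs = colMeans(pop$positions), be = mean(pop$energies),
                 bs_k = bs_k, be_k = be_k, le_k = le_k,
                 le_k_energy = le_k_energy,
                 le = pop$best_position, le_energy = pop$best_energy),
            class = "binding_record")
}

# One population update shared by AOS and BAOS. Per electron: optionally
# re-draw the photon rate from the Levy-modulated rule; optionally
# relocate stagnating electrons by a Levy flight from LE; otherwise move
# by the photon/non-photon rules, repair, re-evaluate and accept greedily
# (limit counter resets on improvement, increments otherwise).
step_population <- function(pop, bind, layers, space, params, objective) {
  d <- ncol(pop$positions)
  b <- space_bounds(space)
  span <- b$upper - b$lower
  for (i in seq_along(pop$energies)) {
    if (params$pr_update) {
      pop$pr[i] <- min(1, max(0, params$pr_scale *
                                abs(levy_steps(1L, params$levy$beta))))
    }
    if (params$use_restarts && pop$limit[i] > params$limit_threshold) {
      cand <- levy_move(space, bind$le, params$levy)
      e <- objective(decode(space, cand))
      if (!is.finite(e)) stop("objective returned a non-finite value after restart")
      pop$positions[i, ] <- cand
      pop$energies[i] <- e
      pop$limit[i] <- 0L
    } else {
      k <- layers$layer_of[i]
      x <- pop$positions[i, ]
      av <- stats::runif(d); bv <- stats::runif(d); gv <- stats::runif(d)
      phi <- stats::runif(1L)
      if (phi >= pop$pr[i]) {
        if (pop$energies[i] >= bind$be_k[k]) {
          x <- x + av * (bv * bind$le - gv * bind$bs) / k
        } else {
          x <- x + av * (bv * bind$le_k[k, ] - gv * bind$bs_k[k, ])
        }
      } else {
        x <- x + stats::runif(d, -0.05, 0.05) * span
      }
      cand <- repair(space, x)
      e <- objective(decode(space, cand))
      if (!is.finite(e)) {
        stop(sprintf("objective returned a non-finite value at position [%s]",
                     paste(signif(cand, 6), collapse = ", ")))
      }
      if (e <= pop$energies[i]) {
        # ties are accepted (the electron drifts across plateaus of
        # discrete landscapes) but only strict improvement resets the
        # stagnation counter
        pop$positions[i, ] <- cand
        pop$limit[i] <- if (e < pop$energies[i]) 0L else pop$limit[i] + 1L
        pop$energies[i] <- e
      } else {
        pop$limit[i] <- pop$limit[i] + 1L
      }
    }
    if (pop$energies[i] < pop$best_energy) {
      pop$best_energy <- pop$energies[i]
      pop$best_position <- pop$positions[i, ]
    }
  }
  pop
}

#' One AOS / BAOS iteration
#'
#' `aos_step()` applies the plain atomic-orbital update rules with a fixed
#' photon rate and no restarts (limit counters are still tracked);
#' `baos_step()` additionally re-draws each electron's photon rate from
#' the Levy-modulated rule and relocates electrons whose limit counter
#' exceeds the threshold by a Levy flight from the best-so-far position.
#'
#' @param pop An evaluated `aos_population`.
#' @param bind A [binding()] record.
#' @param layers An [assign_layers()] assignment.
#' @param space The `search_space`.
#' @param params An [optimizer_params()].
#' @param objective Objective over decoded assignments.
#' @return The updated population.
#' @export
aos_step <- function(pop, bind, layers, space, params, objective) {
  p <- params
  p$pr_update <- FALSE
  p$use_restarts <- FALSE
  step_population(pop, bind, layers, space, p, objective)
}

#' @rdname aos_step
#' @export
baos_step <- function(pop, bind, layers, space, params, objective) {
  step_population(pop, bind, layers, space, params, objective)
}

#' Run an optimizer on a search space
#'
#' Executes `n_runs` independent restarts of: initialize, evaluate, then
#' `max_iterations` iterations of layer assignment, binding computation
#' and a population step (`algorithm = "random"` instead draws the same
#' evaluation budget uniformly). Positions of discrete dimensions move in
#' their `[0, 1]` embedding and are decoded only at evaluation. Named
#' `optimize_space` to avoid masking `stats::optimize`.
#'
#' @param objective Function mapping a decoded named assignment to a real
#'   energy (lower is better).
#' @param space A `search_space`.
#' @param params An [optimizer_params()].
#' @return An `optimization_result`: `best_assignment`, `best_position`,
#'   `best_energy`, `trace` (best-so-far per iteration, for the best run),
#'   `evaluations` (total objective calls), `per_run`, `algorithm`.
#' @export
optimize_space <- function(objective, space, params = optimizer_params()) {
  stopifnot(inherits(space, "search_space"), inherits(params, "optimizer_params"))
  per_run <- vector("list", params$n_runs)
  budget <- params$m * (1L + params$max_iterations)
  for (r in seq_len(params$n_runs)) {
    run_seed <- params$seed + (r - 1L) * 1009L
    if (params$algorithm == "random") {
      rs <- random_search(objective, space, budget, seed = run_seed)
      per_run[[r]] <- list(seed = run_seed, best_energy = rs$best_energy,
                           best_position = rs$best_position,
                           trace = rs$trace, evaluations = rs$evaluations)
      next
    }
    set.seed(run_seed)
    nevals <- 0L
    counted <- function(a) { nevals <<- nevals + 1L; objective(a) }
    pop <- initialize_population(space, params$m, pr = params$pr)
    pop <- evaluate_population(pop, counted, space)
    trace <- numeric(params$max_iterations)
    for (t in seq_len(params$max_iterations)) {
      layers <- assign_layers(pop, params$layer_max)
      bind <- binding(pop, layers)
      pop <- step_population(pop, bind, layers, space, params, counted)
      trace[t] <- pop$best_energy
    }
    per_run[[r]] <- list(seed = run_seed, best_energy = pop$best_energy,
                         best_position = pop$best_position,
                         trace = trace, evaluations = nevals)
  }
  finish_result(per_run, space, params$algorithm)
}

finish_result <- function(per_run, space, algorithm) {
  energies <- vapply(per_run, `[[`, numeric(1L), "best_energy")
  best <- which.min(energies)
  structure(list(
    best_assignment = decode(space, per_run[[best]]$best_position),
    best_position = per_run[[best]]$best_position,
    best_energy = energies[best],
    trace = per_run[[best]]$trace,
    evaluations = sum(vapply(per_run, `[[`, integer(1L), "evaluations")),
    per_run = per_run,
    algorithm = algorithm), class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("%s: best energy %.6g after %d evaluations (%d run%s)\n",
              x$algorithm, x$best_energy, x$evaluations, length(x$per_run),
              if (length(x$per_run) == 1L) "" else "s"))
  cat("best assignment:\n")
  for (nm in names(x$best_assignment)) {
    cat(sprintf("  %-32s %s\n", nm, format(x$best_assignment[[nm]])))
  }
  invisible(x)
}

#' Budget-matched random search baseline
#'
#' Draws `budget` uniform positions, evaluates each and keeps the best;
#' the trace records the best-so-far energy per evaluation.
#'
#' @param objective Objective over decoded assignments.
#' @param space A `search_space`.
#' @param budget Number of evaluations (`>= 1`).
#' @param seed Seed.
#' @return An `optimization_result` with one run record.
#' @export
random_search <- function(objective, space, budget, seed = 1L) {
  if (!is.numeric(budget) || length(budget) != 1L || budget < 1) {
    stop("budget must be >= 1")
  }
  budget <- as.integer(budget)
  set.seed(seed)
  pos <- sample_uniform(space, budget)
  energies <- numeric(budget)
  for (i in seq_len(budget)) {
    e <- objective(decode(space, pos[i, ]))
    if (!is.finite(e)) {
      stop(sprintf("objective returned a non-finite value at position [%s]",
                   paste(signif(pos[i, ], 6), collapse = ", ")))
    }
    energies[i] <- e
  }
  best <- which.min(energies)
  per_run <- list(list(seed = seed, best_energy = energies[best],
                       best_position = pos[best, ],
                       trace = cummin(energies), evaluations = budget))
  finish_result(per_run, space, "random")
}
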