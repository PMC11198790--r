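sphere_obj <- benchmark_objective("sphere")

test_that("population initialization is in-bounds, seeded and validated", {
  sp <- default_seagrass_space()
  set.seed(31)
  pop <- initialize_population(sp, 30L)
  expect_equal(nrow(pop$positions), 30L)
  b <- space_bounds(sp)
  expect_true(all(sweep(pop$positions, 2L, b$lower, `>=`)))
  expect_true(all(sweep(pop$positions, 2L, b$upper, `<=`)))
  expect_true(all(is.na(pop$energies)))
  expect_true(all(pop$limit == 0L))

  set.seed(31)
  pop2 <- initialize_population(sp, 30L)
  expect_identical(pop$positions, pop2$positions)

  set.seed(32)
  expect_equal(nrow(initialize_population(sp, 1L)$positions), 1L)
  expect_error(initialize_population(sp, 0L), ">= 1")
})

test_that("evaluation records energies and tracks the lowest-energy candidate", {
  sp <- benchmark_space("sphere", 3L)
  set.seed(33)
  pop <- initialize_population(sp, 5L)
  pop$positions[1L, ] <- c(0, 0, 0)
  pop <- evaluate_population(pop, sphere_obj, sp)
  expect_equal(pop$energies[1L], 0)
  expect_equal(pop$best_energy, min(pop$energies))
  expect_equal(pop$best_energy, 0)
  expect_equal(pop$best_position, c(0, 0, 0))

  # two electrons with energies (3, 1): the second is the LE candidate
  pop2 <- initialize_population_at(sp, rbind(c(1, 1, 1), c(1, 0, 0)))
  pop2 <- evaluate_population(pop2, sphere_obj, sp)
  expect_equal(pop2$energies, c(3, 1))
  expect_equal(pop2$best_position, c(1, 0, 0))

  bad <- function(a) NaN
  expect_error(evaluate_population(pop, bad, sp), "non-finite")
})

test_that("layer assignment partitions sorted electrons with the best in layer 1", {
  sp <- benchmark_space("sphere", 2L)
  set.seed(34)
  pop <- initialize_population(sp, 12L)
  pop <- evaluate_population(pop, sphere_obj, sp)
  for (i in 1:25) {
    la <- assign_layers(pop, layer_max = 5L)
    expect_true(la$n_layers >= 1L && la$n_layers <= 5L)
    expect_true(all(la$layer_of >= 1L & la$layer_of <= la$n_layers))
    expect_equal(la$layer_of[which.min(pop$energies)], 1L)
    # contiguity: layer index is non-decreasing along the energy order
    expect_true(!is.unsorted(la$layer_of[order(pop$energies)]))
    if (la$n_layers == 1L) expect_true(all(la$layer_of == 1L))
  }
})

test_that("binding records are centroids, means and the best-so-far", {
  sp <- benchmark_space("sphere", 2L)
  same <- initialize_population_at(sp, rbind(c(1, 2), c(1, 2), c(1, 2)))
  same <- evaluate_population(same, sphere_obj, sp)
  la <- list(n_layers = 1L, layer_of = rep(1L, 3L))
  bd <- binding(same, la)
  expect_equal(bd$bs, c(1, 2))
  expect_equal(bd$be, 5)
  expect_equal(bd$le, c(1, 2))

  single <- initialize_population_at(sp, matrix(c(3, 4), 1L))
  single <- evaluate_population(single, sphere_obj, sp)
  bd1 <- binding(single, list(n_layers = 1L, layer_of = 1L))
  expect_equal(bd1$bs, c(3, 4))
  expect_equal(bd1$le, c(3, 4))

  two <- initialize_population_at(sp, rbind(c(0.2, 0.4), c(0.6, 0.2)))
  two$energies <- c(0.2, 0.4)
  two$best_energy <- 0.2
  two$best_position <- c(0.2, 0.4)
  bd2 <- binding(two, list(n_layers = 1L, layer_of = c(1L, 1L)))
  expect_equal(bd2$be, 0.3)
})

test_that("greedy acceptance drives the limit counters", {
  sp <- benchmark_space("sphere", 4L)
  params <- optimizer_params("aos", m = 10L, seed = 1L)
  set.seed(35)
  pop <- initialize_population(sp, 10L)
  pop <- evaluate_population(pop, sphere_obj, sp)
  old <- pop
  la <- assign_layers(pop, params$layer_max)
  bd <- binding(pop, la)
  pop2 <- aos_step(pop, bd, la, sp, params, sphere_obj)
  b <- space_bounds(sp)
  expect_true(all(sweep(pop2$positions, 2L, b$lower, `>=`)))
  expect_true(all(sweep(pop2$positions, 2L, b$upper, `<=`)))
  for (i in 1:10) {
    if (pop2$energies[i] < old$energies[i]) {
      expect_equal(pop2$limit[i], 0L)          # improvement: counter reset
    } else {
      expect_equal(pop2$limit[i], old$limit[i] + 1L)  # stagnation: +1
      expect_equal(pop2$energies[i], old$energies[i]) # rejected move kept old
    }
  }
  expect_true(any(pop2$limit == 0L) || all(pop2$energies == old$energies))
})

test_that("stagnating electrons are relocated by a Levy flight and reset", {
  sp <- benchmark_space("sphere", 3L)
  params <- optimizer_params("baos", m = 6L, limit_threshold = 2, seed = 2L)
  set.seed(36)
  pop <- initialize_population(sp, 6L)
  pop <- evaluate_population(pop, sphere_obj, sp)
  pop$limit <- rep(5L, 6L)  # all above threshold
  old_pos <- pop$positions
  la <- assign_layers(pop, params$layer_max)
  bd <- binding(pop, la)
  pop2 <- baos_step(pop, bd, la, sp, params, sphere_obj)
  expect_true(all(pop2$limit == 0L))
  for (i in 1:6) expect_false(isTRUE(all.equal(pop2$positions[i, ], old_pos[i, ])))
  expect_true(all(pop2$pr >= 0 & pop2$pr <= 1))
})

test_that("with restarts off and a fixed photon rate BAOS retraces AOS", {
  sp <- benchmark_space("sphere", 5L)
  pa <- optimizer_params("aos", m = 12L, max_iterations = 15L, n_runs = 2L,
                         seed = 7L)
  pb <- optimizer_params("baos", m = 12L, max_iterations = 15L, n_runs = 2L,
                         seed = 7L, pr_update = FALSE, limit_threshold = Inf)
  ra <- optimize_space(sphere_obj, sp, pa)
  rb <- optimize_space(sphere_obj, sp, pb)
  expect_identical(ra$trace, rb$trace)
  expect_identical(ra$best_position, rb$best_position)
})

test_that("best-so-far traces are monotone and runs are bitwise reproducible", {
  sp <- benchmark_space("sphere", 5L)
  for (alg in c("aos", "baos", "random")) {
    params <- optimizer_params(alg, m = 10L, max_iterations = 20L,
                               n_runs = 2L, seed = 3L)
    r1 <- optimize_space(sphere_obj, sp, params)
    r2 <- optimize_space(sphere_obj, sp, params)
    expect_identical(r1$trace, r2$trace)
    expect_identical(r1$best_position, r2$best_position)
    for (run in r1$per_run) {
      expect_true(all(diff(run$trace) <= 0))
    }
    expect_lt(r1$best_energy, r1$per_run[[1L]]$trace[1L] + 1e-12)
  }
})

test_that("reported evaluations equal actual objective calls", {
  sp <- benchmark_space("rastrigin", 3L)
  calls <- 0L
  counting <- function(a) {
    calls <<- calls + 1L
    benchmark("rastrigin", unlist(a))
  }
  params <- optimizer_params("baos", m = 8L, max_iterations = 6L,
                             n_runs = 3L, seed = 4L)
  r <- optimize_space(counting, sp, params)
  expect_equal(r$evaluations, calls)
  expect_equal(r$evaluations, 3L * 8L * (1L + 6L))

  calls <- 0L
  rr <- random_search(counting, sp, budget = 57L, seed = 5L)
  expect_equal(rr$evaluations, 57L)
  expect_equal(calls, 57L)
})

test_that("random search handles a unit budget and repeats exactly", {
  sp <- benchmark_space("sphere", 2L)
  r1 <- random_search(sphere_obj, sp, budget = 1L, seed = 9L)
  expect_equal(length(r1$trace), 1L)
  expect_equal(r1$best_energy, r1$trace[1L])
  r2 <- random_search(sphere_obj, sp, budget = 1L, seed = 9L)
  expect_identical(r1$best_position, r2$best_position)
  expect_error(random_search(sphere_obj, sp, 0L), ">= 1")
})

test_that("the optimizer makes real progress on the sphere function", {
  sp <- benchmark_space("sphere", 5L)
  params <- optimizer_params("baos", m = 20L, max_iterations = 49L,
                             n_runs = 1L, seed = 1L)
  r <- optimize_space(sphere_obj, sp, params)
  expect_lt(r$best_energy, r$trace[1L])
  expect_true(all(diff(r$trace) <= 0))
  # far better than a budget-matched random search
  rr <- random_search(sphere_obj, sp, budget = 20L * 50L, seed = 1L)
  expect_lt(r$best_energy, rr$best_energy / 5)
  expect_lt(r$best_energy, 0.5)
})

test_that("ten restarts produce ten per-run records", {
  sp <- benchmark_space("sphere", 2L)
  params <- optimizer_params("baos", m = 5L, max_iterations = 3L,
                             n_runs = 10L, seed = 6L)
  r <- optimize_space(sphere_obj, sp, params)
  expect_length(r$per_run, 10L)
  seeds <- vapply(r$per_run, `[[`, numeric(1L), "seed")
  expect_equal(length(unique(seeds)), 10L)
})
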