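#' Analytic benchmark objectives
#'
#' Standard continuous test functions with known global minima, used to
#' validate and compare the optimizers: `sphere` (unimodal, minimum 0 at
#' the origin), `rastrigin` (highly multimodal, minimum 0 at the origin),
#' `ackley` (multimodal, minimum 0 at the origin) and `rosenbrock`
#' (narrow curved valley, minimum 0 at the all-ones point).
#'
#' @param name One of `"sphere"`, `"rastrigin"`, `"ackley"`, `"rosenbrock"`.
#' @param x Numeric vector.
#' @return Objective value (scalar).
#' @examples
#' benchmark("sphere", c(0, 0))      # 0
#' benchmark("sphere", c(1, 1, 1))   # 3
#' @export
benchmark <- function(name, x) {
  x <- as.numeric(x)
  switch(name,
    sphere = sum(x^2),
    rastrigin = 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
    ackley = {
      d <- length(x)
      -20 * exp(-0.2 * sqrt(sum(x^2) / d)) -
        exp(sum(cos(2 * pi * x)) / d) + 20 + exp(1)
    },
    rosenbrock = {
      if (length(x) < 2L) stop("rosenbrock needs d >= 2")
      i <- seq_len(length(x) - 1L)
      sum(100 * (x[i + 1L] - x[i]^2)^2 + (1 - x[i])^2)
    },
    stop(sprintf("unknown benchmark '%s'", name))
  )
}

#' @rdname benchmark
#' @param d Dimension.
#' @return `benchmark_space()`: a continuous `search_space` over the
#'   function's conventional bounds (`[-5.12, 5.12]` for sphere and
#'   rastrigin, `[-32.768, 32.768]` for ackley, `[-5, 10]` for
#'   rosenbrock).
#' @export
benchmark_space <- function(name, d) {
  b <- switch(name,
    sphere = c(-5.12, 5.12),
    rastrigin = c(-5.12, 5.12),
    ackley = c(-32.768, 32.768),
    rosenbrock = c(-5, 10),
    stop(sprintf("unknown benchmark '%s'", name))
  )
  search_space(lapply(seq_len(d), function(j) {
    hp_continuous(sprintf("x%d", j), b[1L], b[2L])
  }))
}

#' @rdname benchmark
#' @return `benchmark_optimum()`: list with the minimizing `location` and
#'   its `value`.
#' @export
benchmark_optimum <- function(name, d) {
  loc <- switch(name,
    sphere = rep(0, d),
    rastrigin = rep(0, d),
    ackley = rep(0, d),
    rosenbrock = rep(1, d),
    stop(sprintf("unknown benchmark '%s'", name))
  )
  list(location = loc, value = 0)
}

#' Wrap a benchmark as an assignment objective
#'
#' Adapts a benchmark to the objective interface used by [optimize_space()]
#' (a function of a decoded named assignment).
#'
#' @param name Benchmark name.
#' @return Function mapping a named assignment list to its value.
#' @export
benchmark_objective <- function(name) {
  force(name)
  function(assignment) benchmark(name, unlist(assignment, use.names = FALSE))
}
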