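#' Hyperparameter dimension constructors
#'
#' A search space is an ordered list of dimensions, each either continuous
#' (a real interval) or discrete (an ordered category list). Discrete
#' dimensions are represented internally on the unit interval and decoded
#' lazily through [discretize()], so optimizers always move in a box:
#' native units for continuous dimensions, `[0, 1]` for discrete ones.
#'
#' @param name Dimension name (unique within a space).
#' @param lower,upper Bounds of a continuous dimension (`lower < upper`).
#' @param categories Ordered vector of admissible values for a discrete
#'   dimension; no duplicates.
#' @return A `hp_spec` object.
#' @examples
#' hp_continuous("scale", 0, 1)
#' hp_discrete("batch_size", seq(10, 200, by = 10))
#' @export
hp_continuous <- function(name, lower, upper) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lower), is.numeric(upper), length(lower) == 1L,
            length(upper) == 1L)
  if (!(lower < upper)) stop("continuous dimension requires lower < upper")
  structure(list(name = name, kind = "continuous",
                 lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "hp_spec")
}

#' @rdname hp_continuous
#' @export
hp_discrete <- function(name, categories) {
  stopifnot(is.character(name), length(name) == 1L, length(categories) >= 1L)
  if (anyDuplicated(categories)) stop("discrete categories must not contain duplicates")
  structure(list(name = name, kind = "discrete", categories = categories),
            class = "hp_spec")
}

#' Assemble a search space from dimensions
#'
#' @param ... `hp_spec` objects (or a single list of them).
#' @return A `search_space` object with fields `specs` and `d`.
#' @export
search_space <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1L]], "hp_spec")) specs <- specs[[1L]]
  if (length(specs) < 1L) stop("a search space needs at least one dimension")
  ok <- vapply(specs, inherits, logical(1L), what = "hp_spec")
  if (!all(ok)) stop("all dimensions must be hp_spec objects")
  nm <- vapply(specs, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("dimension names must be unique")
  structure(list(specs = specs, d = length(specs)), class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("search_space with %d dimensions\n", x$d))
  for (s in x$specs) {
    if (s$kind == "continuous") {
      cat(sprintf("  %-32s continuous [%g, %g]\n", s$name, s$lower, s$upper))
    } else {
      n <- length(s$categories)
      cat(sprintf("  %-32s discrete   %d categories (%s .. %s)\n", s$name, n,
                  format(s$categories[[1L]]), format(s$categories[[n]])))
    }
  }
  invisible(x)
}

#' Default nine-dimensional CNN hyperparameter space
#'
#' The hyperparameter space searched by the seagrass-morphotype
#' neuroevolution pipeline: number of convolutional layers, filter size,
#' number of filters, number of epochs, batch size, max-pooling size,
#' dropout rate, learning rate and momentum rate. Integer hyperparameters
#' are enumerations of consecutive integers; rate hyperparameters are
#' fixed-step grids. The learning-rate grid steps by 0.005 from 0.001 and
#' appends the endpoint 0.1 as its final category.
#'
#' @return A `search_space` with `d = 9` dimensions, all discrete.
#' @export
default_seagrass_space <- function() {
  lr <- c(seq(0.001, 0.096, by = 0.005), 0.1)
  search_space(
    hp_discrete("n_conv_layers", 1:20),
    hp_discrete("kernel_size",   1:30),
    hp_discrete("n_filters",     1:500),
    hp_discrete("n_epochs",      1:400),
    hp_discrete("batch_size",    seq(10L, 200L, by = 10L)),
    hp_discrete("pool_size",     1:20),
    hp_discrete("dropout",       seq(0.20, 0.65, by = 0.05)),
    hp_discrete("learning_rate", lr),
    hp_discrete("momentum",      seq(0.05, 0.95, by = 0.05))
  )
}

#' Box bounds of a space's optimizer embedding
#'
#' Per-dimension lower/upper limits of the coordinates the optimizers
#' move in: native units for continuous dimensions, `[0, 1]` for discrete
#' ones.
#'
#' @param space A `search_space`.
#' @return List with numeric vectors `lower` and `upper`.
#' @export
space_bounds <- function(space) {
  lo <- vapply(space$specs, function(s) if (s$kind == "continuous") s$lower else 0, numeric(1L))
  hi <- vapply(space$specs, function(s) if (s$kind == "continuous") s$upper else 1, numeric(1L))
  list(lower = lo, upper = hi)
}

#' Sample uniform positions from a search space
#'
#' Each continuous coordinate is drawn as `lower + u * (upper - lower)`
#' with `u` uniform on `[0, 1]`; each discrete coordinate is drawn uniform
#' on `[0, 1]` (its decoding interval). Uses the current RNG state, so
#' results are reproducible under `set.seed()`.
#'
#' @param space A `search_space`.
#' @param count Number of positions (rows) to draw.
#' @return A `count x d` numeric matrix; one position per row.
#' @export
sample_uniform <- function(space, count) {
  stopifnot(inherits(space, "search_space"))
  if (!is.numeric(count) || length(count) != 1L || count < 1) {
    stop("count must be a positive integer")
  }
  count <- as.integer(count)
  b <- space_bounds(space)
  u <- matrix(stats::runif(count * space$d), nrow = count)
  pos <- sweep(sweep(u, 2L, b$upper - b$lower, `*`), 2L, b$lower, `+`)
  colnames(pos) <- vapply(space$specs, `[[`, character(1L), "name")
  pos
}

#' Map a unit-interval coordinate onto a category list
#'
#' The discretization map for discrete dimensions: given `R` in `[0, 1]`
#' and `n` ordered categories, computes `alpha = 1 + n * R`, takes the
#' index `beta = min(floor(alpha), n)` and returns the `beta`-th category.
#' Uniform `R` induces a uniform distribution over the categories; the
#' endpoints `R = 0` and `R = 1` map to the first and last category.
#'
#' @param R Real value(s) in `[0, 1]`.
#' @param categories Ordered category vector (length `n >= 1`).
#' @return The selected category value(s).
#' @examples
#' discretize(0, 1:5)    # 1
#' discretize(1, 1:5)    # 5
#' discretize(0.5, 1:4)  # 3
#' @export
discretize <- function(R, categories) {
  n <- length(categories)
  stopifnot(n >= 1L)
  if (any(!is.finite(R)) || any(R < 0) || any(R > 1)) {
    stop("R must lie in [0, 1]")
  }
  alpha <- 1 + n * R
  beta <- pmin(floor(alpha), n)
  categories[beta]
}

#' Decode a position into a native hyperparameter assignment
#'
#' Continuous coordinates pass through unchanged; discrete coordinates are
#' mapped onto their category lists via [discretize()]. Decoding is
#' deterministic and total on repaired positions.
#'
#' @param space A `search_space`.
#' @param position Numeric vector of length `d` (or a 1-row matrix).
#' @return Named list mapping each dimension name to its decoded value.
#' @export
decode <- function(space, position) {
  position <- as.numeric(position)
  if (length(position) != space$d) {
    stop(sprintf("position has length %d but the space has %d dimensions",
                 length(position), space$d))
  }
  vals <- vector("list", space$d)
  for (j in seq_len(space$d)) {
    s <- space$specs[[j]]
    vals[[j]] <- if (s$kind == "continuous") position[j] else
      discretize(position[j], s$categories)
  }
  names(vals) <- vapply(space$specs, `[[`, character(1L), "name")
  vals
}

#' Clamp a position into the admissible box
#'
#' Coordinates outside their dimension's interval (native bounds for
#' continuous dimensions, `[0, 1]` for discrete ones) are clamped to the
#' nearest endpoint; in-bounds coordinates are unchanged. Idempotent.
#'
#' @param space A `search_space`.
#' @param position Numeric vector of length `d`.
#' @return Repaired numeric vector of length `d`.
#' @export
repair <- function(space, position) {
  position <- as.numeric(position)
  if (length(position) != space$d) {
    stop(sprintf("position has length %d but the space has %d dimensions",
                 length(position), space$d))
  }
  b <- space_bounds(space)
  pmin(pmax(position, b$lower), b$upper)
}

#' Serialize / deserialize a search space
#'
#' `space_to_config()` turns a space into a plain list suitable for a
#' YAML/JSON configuration block; `space_from_config()` inverts it.
#'
#' @param space A `search_space`.
#' @param config A list as produced by `space_to_config()`.
#' @return A list, or a `search_space`.
#' @export
space_to_config <- function(space) {
  lapply(space$specs, function(s) {
    if (s$kind == "continuous") {
      list(name = s$name, kind = "continuous", lower = s$lower, upper = s$upper)
    } else {
      list(name = s$name, kind = "discrete", categories = s$categories)
    }
  })
}

#' @rdname space_to_config
#' @export
space_from_config <- function(config) {
  specs <- lapply(config, function(s) {
    if (identical(s$kind, "continuous")) {
      hp_continuous(s$name, s$lower, s$upper)
    } else if (identical(s$kind, "discrete")) {
      hp_discrete(s$name, unlist(s$categories))
    } else {
      stop("dimension kind must be 'continuous' or 'discrete'")
    }
  })
  search_space(specs)
}
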