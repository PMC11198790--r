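#' Levy flight configuration
#'
#' Parameters of the heavy-tailed step machinery used to boost the atomic
#' orbital search: the stability index `beta` of the step sampler, the
#' scale `gamma` and minimum step `mu` of the closed-form density, and the
#' step-size multiplier applied to position updates. When `step_scale` is
#' `NULL` it defaults, per dimension, to 1% of the dimension span at the
#' time of the move.
#'
#' @param beta Stability index in `(0, 2]`; default 1.5.
#' @param gamma Scale parameter of the density; `> 0`.
#' @param mu Minimum step of the density; `>= 0`.
#' @param step_scale Step multiplier (`> 0`), either a scalar or a vector
#'   recycled over dimensions, or `NULL` for the span-proportional default.
#' @return A `levy_config` object.
#' @export
levy_config <- function(beta = 1.5, gamma = 1, mu = 0, step_scale = NULL) {
  if (!is.numeric(beta) || beta <= 0 || beta > 2) stop("beta must lie in (0, 2]")
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (!is.numeric(mu) || mu < 0) stop("mu must be >= 0")
  if (!is.null(step_scale) && any(step_scale <= 0)) stop("step_scale must be > 0")
  structure(list(beta = beta, gamma = gamma, mu = mu, step_scale = step_scale),
            class = "levy_config")
}

#' Closed-form Levy density
#'
#' Density `sqrt(gamma / (2 pi)) * exp(-gamma / (2 (s - mu))) *
#' (s - mu)^(-3/2)` for `s > mu`, and 0 otherwise. This is the
#' one-sided stable density of index 1/2 (the Levy distribution proper);
#' for large `s` it behaves as `sqrt(gamma / (2 pi)) * s^(-3/2)`.
#'
#' @param s Evaluation point(s).
#' @param gamma Scale parameter, `> 0`.
#' @param mu Location (minimum step), `>= 0`.
#' @return Non-negative density value(s).
#' @examples
#' levy_density(1, gamma = 1)  # ~ 0.2420
#' @export
levy_density <- function(s, gamma = 1, mu = 0) {
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  out <- numeric(length(s))
  ok <- is.finite(s) & s > mu
  x <- s[ok] - mu
  out[ok] <- sqrt(gamma / (2 * pi)) * exp(-gamma / (2 * x)) * x^(-3 / 2)
  out
}

#' Sample heavy-tailed Levy steps (Mantegna's algorithm)
#'
#' Draws steps as `u / |v|^(1/beta)` with `u ~ N(0, sigma_u^2)`,
#' `v ~ N(0, 1)` and the standard Mantegna variance
#' `sigma_u = (Gamma(1+beta) sin(pi beta / 2) /
#' (Gamma((1+beta)/2) beta 2^((beta-1)/2)))^(1/beta)`, giving step
#' magnitudes whose survival function decays with power-law exponent
#' approximately `beta`.
#'
#' @param count Number of steps.
#' @param beta Stability index in `(0, 2]`.
#' @return Numeric vector of `count` signed steps.
#' @export
levy_steps <- function(count, beta = 1.5) {
  if (!is.numeric(count) || length(count) != 1L || count < 1) {
    stop("count must be a positive integer")
  }
  if (!is.numeric(beta) || beta <= 0 || beta > 2) stop("beta must lie in (0, 2]")
  count <- as.integer(count)
  su <- mantegna_sigma(beta)
  u <- stats::rnorm(count, 0, su)
  v <- stats::rnorm(count)
  u / abs(v)^(1 / beta)
}

mantegna_sigma <- function(beta) {
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

# Median of |step| under Mantegna sampling, computed by quadrature on
# P(|s| <= x) = E_v[2 Phi(x |v|^(1/beta) / sigma_u) - 1]; deterministic,
# used to calibrate the photon-rate scale without consuming RNG draws.
levy_abs_median <- function(beta) {
  su <- mantegna_sigma(beta)
  cdf <- function(x) {
    f <- function(v) {
      (2 * stats::pnorm(x * abs(v)^(1 / beta) / su) - 1) * stats::dnorm(v)
    }
    2 * stats::integrate(f, 0, Inf, rel.tol = 1e-8)$value
  }
  stats::uniroot(function(x) cdf(x) - 0.5, c(1e-6, 50), tol = 1e-8)$root
}

#' Levy-flight position update
#'
#' Moves a position by `u (entry-wise *) levy_steps(d, beta) * step_scale`,
#' with `u` a fresh uniform vector on `[0, 1]^d`, then clips extreme tail
#' draws at 100 dimension spans and repairs the result into the search
#' box. With `step_scale = 0` the position is returned unchanged.
#'
#' @param space A `search_space` (supplies spans and repair bounds).
#' @param position Numeric vector of length `d`.
#' @param config A [levy_config()].
#' @return Repaired numeric vector of length `d`.
#' @export
levy_move <- function(space, position, config = levy_config()) {
  stopifnot(inherits(space, "search_space"), inherits(config, "levy_config"))
  position <- as.numeric(position)
  b <- space_bounds(space)
  span <- b$upper - b$lower
  scale <- if (is.null(config$step_scale)) 0.01 * span else
    rep_len(config$step_scale, space$d)
  step <- stats::runif(space$d) * levy_steps(space$d, config$beta) * scale
  step <- pmin(pmax(step, -100 * span), 100 * span)
  repair(space, position + step)
}
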