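# Grid posteriors for the hatch location under arbitrary bounded priors.
# The likelihood is flat on the likelihood interval and zero outside, so the
# posterior is the prior restricted to that interval and renormalized —
# "excluding values we know to be impossible".

#' Prior specifications on a bounded support
#'
#' A prior is a nonnegative density on a bounded interval, evaluated on a
#' grid and normalized internally; only relative values matter.
#'
#' @param lower,upper Support endpoints, `lower < upper`, both finite.
#' @param density Function returning nonnegative density values on the
#'   support (need not be normalized).
#' @param label Text label.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(lower, upper, density, label = "prior") {
  stopifnot(is.numeric(lower), is.numeric(upper), is.finite(lower),
            is.finite(upper), lower < upper, is.function(density))
  structure(list(lower = lower, upper = upper, density = density,
                 label = label),
            class = "prior_spec")
}

#' @rdname prior_spec
#' @export
uniform_prior <- function(lower, upper) {
  prior_spec(lower, upper, function(theta) rep(1, length(theta)),
             label = sprintf("uniform on [%g, %g]", lower, upper))
}

#' @rdname prior_spec
#' @param mode Peak of the triangular density, in `[lower, upper]`.
#' @export
triangular_prior <- function(lower, mode, upper) {
  stopifnot(lower <= mode, mode <= upper)
  prior_spec(lower, upper, function(theta) {
    ifelse(theta < mode,
           (theta - lower) / max(mode - lower, .Machine$double.eps),
           (upper - theta) / max(upper - mode, .Machine$double.eps))
  }, label = sprintf("triangular on [%g, %g], mode %g", lower, upper, mode))
}

#' Grid posterior and central credible interval for the hatch location
#'
#' Multiplies the prior density by the likelihood (the indicator of the
#' likelihood interval), renormalizes on an equally spaced grid over the
#' prior's support, and reads off the central credible interval at level
#' `level` by linear interpolation of the grid CDF: the interval excluding
#' `(1 - level)/2` posterior mass in each tail.
#'
#' @param pair A single [bubble_pair()].
#' @param prior A [prior_spec()]; its support must overlap the likelihood
#'   interval, otherwise the data carry zero evidence under the prior and an
#'   error is raised.
#' @param grid_step Grid spacing in meters (default 0.001).
#' @param level Credibility level for the central interval (default 0.5).
#' @return List with `grid` (data frame of `theta` and posterior probability
#'   `mass` summing to 1), `interval` (an [interval()]), `level`, and the
#'   prior's label.
#' @examples
#' p <- posterior_grid(bubble_pair(1, 1.5), uniform_prior(-20, 20))
#' p$interval # matches bayes_central_interval() at the 50% level
#' @export
posterior_grid <- function(pair, prior, grid_step = 0.001, level = 0.5) {
  pair <- as_single_pair(pair)
  stopifnot(inherits(prior, "prior_spec"))
  if (!is.numeric(grid_step) || grid_step <= 0) {
    stop("'grid_step' must be positive", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)",
                                     call. = FALSE)
  lik <- likelihood_interval(pair)
  if (prior$upper < lik$lower || prior$lower > lik$upper) {
    stop("zero evidence: prior support is disjoint from the likelihood interval",
         call. = FALSE)
  }
  theta <- seq(prior$lower, prior$upper, by = grid_step)
  dens <- prior$density(theta)
  if (any(dens < 0) || any(!is.finite(dens))) {
    stop("prior density must be finite and nonnegative on its support",
         call. = FALSE)
  }
  dens[!interval_contains(lik, theta)] <- 0
  total <- sum(dens)
  if (total <= 0) {
    stop("zero evidence: prior mass on the likelihood interval is zero",
         call. = FALSE)
  }
  mass <- dens / total
  cdf <- cumsum(mass)
  lo <- grid_quantile(theta, cdf, (1 - level) / 2)
  hi <- grid_quantile(theta, cdf, (1 + level) / 2)
  list(grid = data.frame(theta = theta, mass = mass),
       interval = interval(lo, hi), level = level, prior = prior$label)
}

# Inverse of the grid CDF by linear interpolation between grid points.
grid_quantile <- function(theta, cdf, p) {
  i <- findInterval(p, cdf) + 1L
  i <- min(max(i, 1L), length(theta))
  if (i == 1L) return(theta[1L])
  c0 <- cdf[i - 1L]
  c1 <- cdf[i]
  if (c1 <= c0) return(theta[i])
  theta[i - 1L] + (theta[i] - theta[i - 1L]) * (p - c0) / (c1 - c0)
}
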