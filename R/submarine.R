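# The uniform-location ("lost submarine") model: two observations drawn
# i.i.d. uniform on [theta - 5, theta + 5], where theta is the unknown
# location (the rescue hatch) and 5 m is the fixed half-length of the craft.
# Writing xbar for the midpoint of the two observations and d for their
# spread, the likelihood of theta is the indicator of
# [xbar - (5 - d/2), xbar + (5 - d/2)], an interval of width 10 - d: the
# further apart the bubbles, the tighter the data pin down the hatch.

HALF_LENGTH <- 5

#' The uniform location model
#'
#' @param theta True location (meters). Observations are i.i.d. uniform on
#'   `[theta - 5, theta + 5]`; the half-length 5 m is fixed by the model.
#' @return An object of class `submarine_model`.
#' @export
submarine_model <- function(theta = 0) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  structure(list(theta = theta, half_length = HALF_LENGTH),
            class = "submarine_model")
}

#' @export
print.submarine_model <- function(x, ...) {
  cat(sprintf("<uniform location model: theta = %g, half-length %g m>\n",
              x$theta, x$half_length))
  invisible(x)
}

#' One or more observation pairs
#'
#' Bundles a pair of observations with its derived statistics: the sorted
#' values `x1 <= x2`, the spread `d = x2 - x1`, the signed difference
#' `b = y2 - y1` and the midpoint `mean`. The midpoint and spread carry all
#' of the information in the pair: the midpoint is the natural point estimate
#' and the spread indexes precision.
#'
#' @param y1,y2 Observations in draw order (numeric vectors of equal length).
#' @return Data frame of class `bubble_pair` with columns `y1`, `y2`, `x1`,
#'   `x2`, `d`, `b`, `mean`.
#' @examples
#' bubble_pair(4, 6)
#' @export
bubble_pair <- function(y1, y2) {
  stopifnot(is.numeric(y1), is.numeric(y2), length(y1) == length(y2),
            all(is.finite(y1)), all(is.finite(y2)))
  out <- data.frame(
    y1 = y1, y2 = y2,
    x1 = pmin(y1, y2), x2 = pmax(y1, y2),
    d = abs(y2 - y1), b = y2 - y1,
    mean = (y1 + y2) / 2
  )
  class(out) <- c("bubble_pair", "data.frame")
  out
}

#' Sample observation pairs from the model
#'
#' @param model A [submarine_model()].
#' @param n_pairs Number of pairs to draw.
#' @param seed Integer seed; a fixed seed reproduces the identical sequence.
#' @return A [bubble_pair()] data frame with `n_pairs` rows.
#' @export
sample_bubbles <- function(model, n_pairs, seed) {
  stopifnot(inherits(model, "submarine_model"))
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || n_pairs < 1) {
    stop("'n_pairs' must be a positive count", call. = FALSE)
  }
  lo <- model$theta - model$half_length
  hi <- model$theta + model$half_length
  with_seed(seed, {
    bubble_pair(stats::runif(n_pairs, lo, hi), stats::runif(n_pairs, lo, hi))
  })
}

#' Sampler for the Monte-Carlo harness
#'
#' Wraps [sample_bubbles()] as an [mc_sampler()], with the likelihood width
#' `10 - d` as the per-draw reference width.
#'
#' @param theta True location.
#' @return An [mc_sampler()].
#' @export
bubble_sampler <- function(theta = 0) {
  model <- submarine_model(theta)
  lo <- theta - HALF_LENGTH
  hi <- theta + HALF_LENGTH
  mc_sampler(
    draw = function(n) bubble_pair(stats::runif(n, lo, hi),
                                   stats::runif(n, lo, hi)),
    theta = theta,
    ref_width = function(draws) 2 * HALF_LENGTH - draws$d,
    label = sprintf("uniform location, theta = %g", theta)
  )
}

as_single_pair <- function(pair) {
  if (!inherits(pair, "bubble_pair")) {
    if (is.data.frame(pair) && all(c("y1", "y2") %in% names(pair))) {
      pair <- bubble_pair(pair$y1, pair$y2)
    } else {
      stop("'pair' must be a bubble_pair (see bubble_pair())", call. = FALSE)
    }
  }
  if (nrow(pair) != 1L) stop("expected a single observation pair",
                             call. = FALSE)
  pair
}

#' Likelihood interval for an observation pair
#'
#' The set of locations with positive likelihood: every `theta` within 5 m of
#' both observations, i.e. `[mean - (5 - d/2), mean + (5 - d/2)]`, of width
#' `10 - d`. Values outside are impossible given the data.
#'
#' @param pair A single [bubble_pair()].
#' @return An [interval()].
#' @examples
#' likelihood_interval(bubble_pair(4, 6)) # [1, 9]
#' @export
likelihood_interval <- function(pair) {
  pair <- as_single_pair(pair)
  if (pair$d > 2 * HALF_LENGTH) {
    stop(sprintf(
      "impossible data: spread %g exceeds the craft length %g",
      pair$d, 2 * HALF_LENGTH), call. = FALSE)
  }
  h <- HALF_LENGTH - pair$d / 2
  interval(pair$mean - h, pair$mean + h)
}

# Half-width of each nontrivial procedure's interval as a function of the
# spread d. Conditional on d, xbar - theta is uniform on +/-(5 - d/2), which
# is what makes the analytic coverage computations below exact.
procedure_half_width <- function(name, d, confidence = 0.5) {
  switch(name,
    sampling_distribution = rep(sd_half_width(confidence), length(d)),
    nonparametric = d / 2,
    ump = ifelse(d < HALF_LENGTH, d / 2, HALF_LENGTH - d / 2),
    bayes = confidence * (HALF_LENGTH - d / 2),
    likelihood = HALF_LENGTH - d / 2,
    stop(sprintf("unknown procedure '%s'", name), call. = FALSE)
  )
}

sd_half_width <- function(confidence) {
  # quantile of |xbar - theta|, symmetric triangular on +/-5:
  # P(|xbar - theta| <= h) = 1 - (1 - h/5)^2
  HALF_LENGTH * (1 - sqrt(1 - confidence))
}

#' The trivial order-based procedure
#'
#' A 50% procedure that ignores the bubble locations entirely: when the first
#' observation exceeds the second (probability 1/2) it returns the whole real
#' line, otherwise an empty interval (`variant = "order_empty"`) or a single
#' fixed point (`variant = "order_point"`, the spot "directly under the
#' rescue boat", which has probability zero of being the true location). It
#' attains its confidence coefficient while conveying nothing about the
#' parameter.
#'
#' @param pair A single [bubble_pair()].
#' @param variant `"order_empty"` or `"order_point"`.
#' @param point_location The fixed point for `"order_point"`.
#' @return An [interval()].
#' @export
trivial_interval <- function(pair, variant = c("order_empty", "order_point"),
                             point_location = 0) {
  pair <- as_single_pair(pair)
  variant <- match.arg(variant)
  if (pair$y1 > pair$y2) return(whole_line())
  if (variant == "order_empty") empty_interval()
  else point_interval(point_location)
}

#' The sampling-distribution procedure
#'
#' `mean +/- q(conf)` where `q` is the quantile of the triangular sampling
#' distribution of the midpoint: `q(conf) = 5 (1 - sqrt(1 - conf))`. At the
#' 50% level the half-width is `5 - 5/sqrt(2)`, about 1.46 m — the familiar
#' fixed-width `xbar +/- C * SE` form, with SE about 2.04 m.
#'
#' @param pair A single [bubble_pair()].
#' @param confidence Confidence coefficient in (0, 1); default 0.5.
#' @return An [interval()].
#' @export
sampling_distribution_interval <- function(pair, confidence = 0.5) {
  pair <- as_single_pair(pair)
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      is.na(confidence) || confidence <= 0 || confidence >= 1) {
    stop("'confidence' must be in (0, 1)", call. = FALSE)
  }
  h <- sd_half_width(confidence)
  interval(pair$mean - h, pair$mean + h)
}

#' The nonparametric procedure
#'
#' The interval between the two observations, `[x1, x2]` = `mean +/- d/2`: a
#' 50% procedure because the probability that both observations fall on the
#' same side of the true location is 1/2. Coincides with the 50% Student's t
#' interval for n = 2. Defined at the 50% level only.
#'
#' @param pair A single [bubble_pair()].
#' @return An [interval()]; degenerate when the observations coincide.
#' @export
nonparametric_interval <- function(pair) {
  pair <- as_single_pair(pair)
  interval(pair$x1, pair$x2)
}

#' The uniformly most powerful procedure
#'
#' The nonparametric interval truncated to the likelihood set whenever it is
#' wider than the likelihood: `mean +/- d/2` when `d < 5`, else
#' `mean +/- (5 - d/2)`. Truncation removes only impossible values, so
#' coverage is unchanged; the result inverts the uniformly most powerful
#' test and excludes every false value at least as often as any competitor.
#' Defined at the 50% level only.
#'
#' @param pair A single [bubble_pair()].
#' @return An [interval()]; never wider than the likelihood interval.
#' @export
ump_interval <- function(pair) {
  pair <- as_single_pair(pair)
  h <- if (pair$d < HALF_LENGTH) pair$d / 2 else HALF_LENGTH - pair$d / 2
  interval(pair$mean - h, pair$mean + h)
}

#' The objective Bayes central interval
#'
#' The central `conf` fraction of the likelihood: `mean +/- conf (5 - d/2)`.
#' Under a flat prior the posterior is uniform on the likelihood interval, so
#' this is the central posterior credible interval; its width is always
#' `conf` times the likelihood width, and its conditional coverage given any
#' spread `d` is exactly `conf`.
#'
#' @param pair A single [bubble_pair()].
#' @param confidence Credibility level in (0, 1); default 0.5.
#' @return An [interval()]; always a subset of the likelihood interval.
#' @export
bayes_central_interval <- function(pair, confidence = 0.5) {
  pair <- as_single_pair(pair)
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      is.na(confidence) || confidence <= 0 || confidence >= 1) {
    stop("'confidence' must be in (0, 1)", call. = FALSE)
  }
  h <- confidence * (HALF_LENGTH - pair$d / 2)
  interval(pair$mean - h, pair$mean + h)
}

#' The five procedures as harness-ready objects
#'
#' Packages each named interval rule as a [procedure()] (with a vectorized
#' rule for fast Monte-Carlo work). The nonparametric and UMP procedures are
#' defined at the 50% level only; the sampling-distribution and Bayes
#' procedures generalize through their closed forms, and `"likelihood"`
#' returns the full likelihood interval (a 100%-coverage reference).
#'
#' @param name One of `"trivial"`, `"sampling_distribution"`,
#'   `"nonparametric"`, `"ump"`, `"bayes"`, `"likelihood"`.
#' @param confidence Confidence coefficient (ignored, and fixed at 0.5, for
#'   the trivial, nonparametric and UMP procedures).
#' @param variant,point_location Passed to [trivial_interval()].
#' @return A [procedure()].
#' @examples
#' mc_coverage(submarine_procedure("ump"), bubble_sampler(0), 2000, seed = 8)
#' @export
submarine_procedure <- function(name = c("trivial", "sampling_distribution",
                                         "nonparametric", "ump", "bayes",
                                         "likelihood"),
                                confidence = 0.5,
                                variant = "order_empty", point_location = 0) {
  name <- match.arg(name)
  if (name %in% c("nonparametric", "ump", "trivial") && confidence != 0.5) {
    stop(sprintf("the %s procedure is defined at confidence 0.5 only", name),
         call. = FALSE)
  }
  if (name == "likelihood") {
    return(procedure("likelihood", 0.5,
      rule = function(draw) likelihood_interval(draw),
      vrule = function(draws) {
        h <- HALF_LENGTH - draws$d / 2
        data.frame(lower = draws$mean - h, upper = draws$mean + h,
                   empty = FALSE)
      }))
  }
  if (name == "trivial") {
    return(procedure("trivial", 0.5,
      rule = function(draw) trivial_interval(draw, variant, point_location),
      vrule = function(draws) {
        up <- draws$y1 > draws$y2
        if (variant == "order_empty") {
          data.frame(lower = ifelse(up, -Inf, NA_real_),
                     upper = ifelse(up, Inf, NA_real_),
                     empty = !up)
        } else {
          data.frame(lower = ifelse(up, -Inf, point_location),
                     upper = ifelse(up, Inf, point_location),
                     empty = FALSE)
        }
      }))
  }
  rule <- switch(name,
    sampling_distribution = function(draw)
      sampling_distribution_interval(draw, confidence),
    nonparametric = function(draw) nonparametric_interval(draw),
    ump = function(draw) ump_interval(draw),
    bayes = function(draw) bayes_central_interval(draw, confidence)
  )
  procedure(name, confidence, rule = rule, vrule = function(draws) {
    h <- procedure_half_width(name, draws$d, confidence)
    data.frame(lower = draws$mean - h, upper = draws$mean + h, empty = FALSE)
  })
}

#' Density of the spread between two observations
#'
#' The spread `d = |y1 - y2|` of two i.i.d. uniforms on a length-10 interval
#' has density `f(d) = (10 - d)/50` on `[0, 10]` (mean 10/3).
#'
#' @param d Numeric vector of spreads.
#' @return Density values (0 outside `[0, 10]`).
#' @export
spread_density <- function(d) {
  ifelse(d >= 0 & d <= 2 * HALF_LENGTH, (2 * HALF_LENGTH - d) / 50, 0)
}

#' Exact conditional coverage given the spread
#'
#' Conditional on the spread `d`, the midpoint error `mean - theta` is
#' uniform on `+/-(5 - d/2)`, so a procedure with half-width `h(d)` has
#' conditional coverage `min(1, 2 h(d) / (10 - d))`. The set of samples with
#' a given spread is a relevant subset whenever this differs from the nominal
#' level: at `d = 0.5` the sampling-distribution procedure covers about 31%
#' of the time and the nonparametric/UMP procedures about 5%, while the Bayes
#' procedure covers exactly its nominal level at every spread. The trivial
#' procedure covers 50% regardless of `d`.
#'
#' @param name Procedure name (as [submarine_procedure()]).
#' @param d Spread, in `[0, 10)`; vectorized.
#' @param confidence Confidence coefficient for the sampling-distribution and
#'   Bayes procedures.
#' @return Conditional coverage probabilities in `[0, 1]`.
#' @examples
#' conditional_coverage_analytic("sampling_distribution", 0.5) # about 0.31
#' conditional_coverage_analytic("nonparametric", 0.5)         # about 0.05
#' conditional_coverage_analytic("bayes", 0.5)                 # exactly 0.5
#' @export
conditional_coverage_analytic <- function(name, d, confidence = 0.5) {
  stopifnot(is.numeric(d), all(d >= 0), all(d < 2 * HALF_LENGTH))
  if (name == "trivial") return(rep(0.5, length(d)))
  h <- procedure_half_width(name, d, confidence)
  pmin(1, 2 * h / (2 * HALF_LENGTH - d))
}

#' Exact probability of including a false value
#'
#' The probability that a procedure's interval includes the value
#' `theta + offset`, marginally over the data. Conditional on the spread `d`
#' the midpoint error is uniform on `+/-(5 - d/2)`, so the conditional
#' inclusion probability is the length of the overlap of
#' `[offset - h(d), offset + h(d)]` with `+/-(5 - d/2)` divided by `10 - d`;
#' integrating against the spread density `(10 - d)/50` gives
#' `(1/50) * integral of the overlap length over d in [0, 10]`, evaluated by
#' adaptive quadrature (absolute tolerance 1e-6). At offset 0 this is the
#' coverage probability; the trivial procedure includes every value, true or
#' false, with probability 1/2.
#'
#' @inheritParams conditional_coverage_analytic
#' @param offset Displacement `theta' - theta`; vectorized.
#' @return Inclusion probabilities in `[0, 1]`.
#' @export
inclusion_probability_analytic <- function(name, offset, confidence = 0.5) {
  stopifnot(is.numeric(offset), all(is.finite(offset)))
  if (name == "trivial") return(rep(0.5, length(offset)))
  one <- function(off) {
    integrand <- function(d) {
      h <- procedure_half_width(name, d, confidence)
      s <- HALF_LENGTH - d / 2
      pmax(0, pmin(off + h, s) - pmax(off - h, -s))
    }
    stats::integrate(integrand, 0, 2 * HALF_LENGTH, abs.tol = 1e-9,
                     rel.tol = 1e-9, subdivisions = 500L)$value / 50
  }
  vapply(offset, one, numeric(1))
}
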