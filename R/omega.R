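# Effect-size interval machinery for the one-way ANOVA: omega squared (the
# population fraction of total variance due to group membership) maps to the
# noncentrality of the F distribution by lambda = N w / (1 - w); the
# test-inversion confidence interval collects all omega^2 values rejected by
# neither of two size-alpha/2 one-sided noncentral-F tests (Steiger's
# construction), with the bound-existence bookkeeping that construction
# requires.

#' One-way ANOVA design summary
#'
#' A balanced one-way design with `k` groups of `n_per_group` observations
#' and an observed F statistic on (`k - 1`, `N - k`) degrees of freedom.
#'
#' @param f_stat Observed F statistic (nonnegative).
#' @param k Number of groups (>= 2).
#' @param n_per_group Observations per group (>= 2).
#' @return Object of class `anova_summary` with fields `f_stat`, `df1`,
#'   `df2`, `k`, `n_per_group`, `N`.
#' @examples
#' anova_summary(5, k = 3, n_per_group = 10) # F(2, 27), N = 30
#' @export
anova_summary <- function(f_stat, k, n_per_group) {
  if (!is.numeric(f_stat) || length(f_stat) != 1L || is.na(f_stat) ||
      f_stat < 0) {
    stop("'f_stat' must be a single nonnegative number", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k)) {
    stop("'k' must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L ||
      n_per_group < 2 || n_per_group != round(n_per_group)) {
    stop("'n_per_group' must be an integer >= 2", call. = FALSE)
  }
  N <- as.integer(k * n_per_group)
  structure(list(f_stat = f_stat, df1 = as.integer(k - 1),
                 df2 = as.integer(N - k), k = as.integer(k),
                 n_per_group = as.integer(n_per_group), N = N),
            class = "anova_summary")
}

#' @export
print.anova_summary <- function(x, ...) {
  cat(sprintf("<one-way ANOVA: F(%d, %d) = %g, k = %d, n = %d per group>\n",
              x$df1, x$df2, x$f_stat, x$k, x$n_per_group))
  invisible(x)
}

check_omega2 <- function(omega2) {
  if (!is.numeric(omega2) || any(is.na(omega2)) || any(omega2 < 0) ||
      any(omega2 >= 1)) {
    stop("'omega2' must lie in [0, 1)", call. = FALSE)
  }
}

#' Convert between omega squared and the F noncentrality parameter
#'
#' `lambda = N omega2 / (1 - omega2)`, strictly increasing with exact inverse
#' `omega2 = lambda / (lambda + N)`. `omega2 = 0` gives the central F.
#'
#' @param omega2 Effect size in `[0, 1)`; vectorized.
#' @param N Total sample size (>= 2).
#' @param lambda Noncentrality (nonnegative); vectorized.
#' @return Numeric vector.
#' @export
lambda_from_omega <- function(omega2, N) {
  check_omega2(omega2)
  stopifnot(is.numeric(N), length(N) == 1L, N >= 2)
  N * omega2 / (1 - omega2)
}

#' @rdname lambda_from_omega
#' @export
omega_from_lambda <- function(lambda, N) {
  stopifnot(is.numeric(lambda), all(lambda >= 0), is.numeric(N),
            length(N) == 1L, N >= 2)
  lambda / (lambda + N)
}

#' One-sided noncentral-F p values for a hypothesized effect size
#'
#' `p_upper` is the upper-tail probability of the observed F under the
#' noncentral F implied by `omega2` — the p value of the one-sided test that
#' rejects for large F. It increases with `omega2` (larger effects make
#' large F more probable). `p_lower = 1 - p_upper` is the lower-tailed
#' counterpart and decreases with `omega2`.
#'
#' @param summary An [anova_summary()].
#' @param omega2 Hypothesized effect size in `[0, 1)`; vectorized.
#' @return Probabilities in `[0, 1]`.
#' @examples
#' s <- anova_summary(5, 3, 10)
#' p_upper(s, 0.1) # about .16: omega2 = .1 is on the rejection boundary
#' p_lower(s, 0.2) # about .58
#' @export
p_upper <- function(summary, omega2) {
  stopifnot(inherits(summary, "anova_summary"))
  check_omega2(omega2)
  lam <- lambda_from_omega(omega2, summary$N)
  stats::pf(summary$f_stat, summary$df1, summary$df2, ncp = lam,
            lower.tail = FALSE)
}

#' @rdname p_upper
#' @export
p_lower <- function(summary, omega2) {
  stopifnot(inherits(summary, "anova_summary"))
  check_omega2(omega2)
  lam <- lambda_from_omega(omega2, summary$N)
  stats::pf(summary$f_stat, summary$df1, summary$df2, ncp = lam)
}

# Solve p_fun(lambda) = target for lambda >= 0 by bracket doubling plus
# uniroot on the lambda scale (unbounded above, better conditioned than
# omega^2). p_fun must be monotone in lambda.
solve_lambda <- function(p_fun, target, tol = 1e-8) {
  f <- function(lam) p_fun(lam) - target
  f0 <- f(0)
  if (f0 == 0) return(0)
  hi <- 1
  fhi <- f(hi)
  it <- 0L
  while (sign(fhi) == sign(f0)) {
    hi <- hi * 2
    fhi <- f(hi)
    it <- it + 1L
    if (it > 60L) {
      stop(sprintf(
        "root bracketing failed: f(0) = %.3g, f(%.3g) = %.3g, target %.3g",
        f0, hi, fhi + 0, target), call. = FALSE)
    }
  }
  stats::uniroot(f, c(0, hi), tol = tol)$root
}

#' Test-inversion confidence interval for omega squared
#'
#' Inverts two one-sided noncentral-F tests of size `alpha/2`
#' (`alpha = 1 - confidence`): the interval collects every `omega2` rejected
#' by neither test. The lower bound solves `p_upper = alpha/2` and exists
#' only when the ordinary ANOVA p value (central F) is at most `alpha/2`;
#' otherwise it is set to 0 and flagged. The upper bound solves
#' `p_lower = alpha/2` and exists only when the central p value is at most
#' `1 - alpha/2`; otherwise the interval is empty and reported as `[0, 0]`
#' (the convention of the construction's source software) with the `empty`
#' flag preserved. Any interval with a bound forced to 0 is flagged
#' `suspect`: its width cannot be read as estimation precision.
#'
#' Roots are found on the noncentrality scale (tolerance 1e-8) and mapped
#' back to `omega2`.
#'
#' @param summary An [anova_summary()].
#' @param confidence Confidence coefficient in (0, 1).
#' @return Object of class `omega_ci`: fields `interval` (an [interval()] on
#'   the `omega2` scale), `lower`, `upper` (the reported bounds, 0 where
#'   nonexistent), `alpha`, `lower_set_to_zero`, `upper_set_to_zero`,
#'   `empty`, `suspect`, `lambda_bounds`, `p_central`, and the design.
#' @examples
#' steiger_ci(anova_summary(5, 3, 10), confidence = 0.68)    # [.10, .36]
#' steiger_ci(anova_summary(0.18, 3, 10), confidence = 0.68) # suspect
#' @export
steiger_ci <- function(summary, confidence = 0.68) {
  stopifnot(inherits(summary, "anova_summary"))
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence >= 1) {
    stop("'confidence' must be in (0, 1)", call. = FALSE)
  }
  alpha <- 1 - confidence
  p_central <- stats::pf(summary$f_stat, summary$df1, summary$df2,
                         lower.tail = FALSE)
  lam_lower <- lam_upper <- NA_real_

  if (1 - p_central < alpha / 2) {
    # even omega2 = 0 is rejected by the lower-tailed test: empty interval
    res <- list(interval = empty_interval(), lower = 0, upper = 0,
                alpha = alpha, lower_set_to_zero = TRUE,
                upper_set_to_zero = TRUE, empty = TRUE, suspect = TRUE,
                lambda_bounds = c(lower = NA_real_, upper = NA_real_),
                p_central = p_central, summary = summary,
                confidence = confidence)
    class(res) <- "omega_ci"
    return(res)
  }

  lower_exists <- p_central <= alpha / 2
  if (lower_exists) {
    lam_lower <- solve_lambda(
      function(lam) stats::pf(summary$f_stat, summary$df1, summary$df2,
                              ncp = lam, lower.tail = FALSE),
      alpha / 2)
  }
  lam_upper <- solve_lambda(
    function(lam) stats::pf(summary$f_stat, summary$df1, summary$df2,
                            ncp = lam),
    alpha / 2)

  lower <- if (lower_exists) omega_from_lambda(lam_lower, summary$N) else 0
  upper <- omega_from_lambda(lam_upper, summary$N)
  res <- list(interval = interval(lower, upper), lower = lower,
              upper = upper, alpha = alpha,
              lower_set_to_zero = !lower_exists, upper_set_to_zero = FALSE,
              empty = FALSE, suspect = !lower_exists,
              lambda_bounds = c(lower = lam_lower, upper = lam_upper),
              p_central = p_central, summary = summary,
              confidence = confidence)
  class(res) <- "omega_ci"
  res
}

#' @export
print.omega_ci <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%.0f%% test-inversion CI for omega^2, F(%d, %d) = %g:\n",
              100 * x$confidence, s$df1, s$df2, s$f_stat))
  if (x$empty) {
    cat(sprintf("  empty (reported [0, 0]); central p = %.3f > 1 - alpha/2\n",
                x$p_central))
  } else {
    cat(sprintf("  [%.4f, %.4f]%s\n", x$lower, x$upper,
                if (x$lower_set_to_zero) "  (lower bound nonexistent, set to 0)"
                else ""))
  }
  if (x$suspect) cat("  suspect: width is not interpretable as precision\n")
  invisible(x)
}

#' Likelihood curve for omega squared
#'
#' The probability density of the observed F statistic under the noncentral F
#' implied by each candidate `omega2` — the likelihood of the effect size
#' given the observed F.
#'
#' @param summary An [anova_summary()].
#' @param grid Numeric vector of `omega2` values in `[0, 1)`.
#' @return Data frame with columns `omega2` and `likelihood`.
#' @export
omega_likelihood <- function(summary, grid = seq(0, 0.995, length.out = 1000)) {
  stopifnot(inherits(summary, "anova_summary"))
  check_omega2(grid)
  lam <- lambda_from_omega(grid, summary$N)
  lik <- stats::df(summary$f_stat, summary$df1, summary$df2, ncp = lam)
  data.frame(omega2 = grid, likelihood = lik)
}

#' Grid posterior and HPD interval for omega squared
#'
#' Posterior proportional to the F-statistic likelihood times a prior on
#' `omega2`, normalized by the trapezoid rule on the grid. The highest
#' posterior density (HPD) interval at level `level` is the smallest-length
#' set `{omega2 : posterior >= c}` holding mass `level`; the threshold `c` is
#' found by bisection (mass tolerance 1e-6), with linear interpolation at the
#' threshold crossings. Contiguity of the set is checked and reported.
#'
#' @param summary An [anova_summary()].
#' @param prior Prior density on the grid: a function of `omega2`, a numeric
#'   vector matching `grid`, or `NULL` for flat.
#' @param level HPD mass in (0, 1).
#' @param grid Grid of `omega2` values (default 1000 points on [0, 0.995]).
#' @return List with `grid` (data frame `omega2`, `density` integrating to 1,
#'   `prior`), `hpd` (an [interval()]), `level`, `mass` (attained mass),
#'   `mode`, and `contiguous`.
#' @export
omega_posterior_hpd <- function(summary, prior = NULL, level = 0.68,
                                grid = seq(0, 0.995, length.out = 1000)) {
  stopifnot(inherits(summary, "anova_summary"))
  check_omega2(grid)
  stopifnot(length(grid) >= 10, !is.unsorted(grid))
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)",
                                     call. = FALSE)
  pr <- if (is.null(prior)) rep(1, length(grid))
        else if (is.function(prior)) prior(grid)
        else prior
  if (length(pr) != length(grid) || any(!is.finite(pr)) || any(pr < 0)) {
    stop("prior must be finite and nonnegative on the grid", call. = FALSE)
  }
  lik <- omega_likelihood(summary, grid)$likelihood
  dens <- lik * pr
  total <- trapz(grid, dens)
  if (total <= 0) stop("posterior has zero total mass", call. = FALSE)
  dens <- dens / total

  mass_above <- function(c) hpd_region(grid, dens, c)$mass
  lo_c <- 0
  hi_c <- max(dens)
  for (i in 1:60) {
    mid <- (lo_c + hi_c) / 2
    if (mass_above(mid) >= level) lo_c <- mid else hi_c <- mid
    if (hi_c - lo_c < 1e-12 * max(dens)) break
  }
  reg <- hpd_region(grid, dens, lo_c)
  if (abs(reg$mass - level) > 1e-3 && lo_c > 0) {
    # fall back to tightening within mass tolerance 1e-6 by more bisection
    for (i in 1:40) {
      mid <- (lo_c + hi_c) / 2
      if (mass_above(mid) >= level) lo_c <- mid else hi_c <- mid
    }
    reg <- hpd_region(grid, dens, lo_c)
  }
  list(grid = data.frame(omega2 = grid, density = dens, prior = pr),
       hpd = interval(reg$lower, reg$upper), level = level,
       mass = reg$mass, mode = grid[which.max(dens)],
       contiguous = reg$contiguous)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# Region {x : dens >= c}: mass (trapezoid, with interpolated crossings),
# outer endpoints, and whether the region is a single run.
hpd_region <- function(x, dens, c) {
  above <- dens >= c
  if (!any(above)) return(list(mass = 0, lower = NA_real_, upper = NA_real_,
                               contiguous = TRUE))
  n <- length(x)
  mass <- 0
  for (i in seq_len(n - 1L)) {
    a <- above[i]; b <- above[i + 1L]
    dx <- x[i + 1L] - x[i]
    if (a && b) {
      mass <- mass + dx * (dens[i] + dens[i + 1L]) / 2
    } else if (a || b) {
      # linear crossing of the threshold inside the cell
      t <- (c - dens[i]) / (dens[i + 1L] - dens[i])
      if (a) mass <- mass + t * dx * (dens[i] + c) / 2
      else mass <- mass + (1 - t) * dx * (c + dens[i + 1L]) / 2
    }
  }
  idx <- which(above)
  runs <- sum(diff(idx) > 1L) + 1L
  # outer endpoints, interpolated to the threshold crossing where interior
  lo <- x[idx[1L]]
  if (idx[1L] > 1L) {
    i <- idx[1L] - 1L
    t <- (c - dens[i]) / (dens[i + 1L] - dens[i])
    lo <- x[i] + t * (x[i + 1L] - x[i])
  }
  hi <- x[idx[length(idx)]]
  if (idx[length(idx)] < n) {
    i <- idx[length(idx)]
    t <- (c - dens[i]) / (dens[i + 1L] - dens[i])
    hi <- x[i] + t * (x[i + 1L] - x[i])
  }
  list(mass = mass, lower = lo, upper = hi, contiguous = runs == 1L)
}

#' Simulate a balanced one-way ANOVA with a target population effect size
#'
#' Generates `k` groups of `n_per_group` normal observations with unit error
#' variance and fixed, equally spaced, centered group means scaled so the
#' population between-group variance fraction equals `omega2_true`; the
#' implied F noncentrality is then exactly `N omega2 / (1 - omega2)`. The F
#' statistic is computed from the standard one-way between/within mean-square
#' decomposition.
#'
#' @param k Number of groups (>= 2).
#' @param n_per_group Observations per group (>= 2).
#' @param omega2_true Population effect size in `[0, 1)`.
#' @param seed Integer seed; a fixed seed reproduces the identical dataset.
#' @return List with `data` (long data frame `group`, `value`), `summary`
#'   (an [anova_summary()] carrying the simulated F), `group_means` (the
#'   population means) and `omega2_true`.
#' @export
simulate_anova <- function(k, n_per_group, omega2_true, seed) {
  if (!is.numeric(k) || k < 2 || k != round(k)) {
    stop("'k' must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(n_per_group) || n_per_group < 2 ||
      n_per_group != round(n_per_group)) {
    stop("'n_per_group' must be an integer >= 2", call. = FALSE)
  }
  check_omega2(omega2_true)
  k <- as.integer(k); n_per_group <- as.integer(n_per_group)
  base <- seq_len(k) - (k + 1) / 2          # centered, equally spaced
  var_between <- omega2_true / (1 - omega2_true)  # sigma_mu^2 with sigma^2 = 1
  mu <- if (var_between > 0) base * sqrt(var_between / mean(base^2))
        else rep(0, k)
  g <- factor(rep(seq_len(k), each = n_per_group))
  y <- with_seed(seed, rep(mu, each = n_per_group) +
                   stats::rnorm(k * n_per_group))
  gm <- tapply(y, g, mean)
  grand <- mean(y)
  ms_between <- n_per_group * sum((gm - grand)^2) / (k - 1)
  ms_within <- sum((y - gm[g])^2) / (k * n_per_group - k)
  f_stat <- ms_between / ms_within
  list(data = data.frame(group = g, value = y),
       summary = anova_summary(f_stat, k, n_per_group),
       group_means = mu, omega2_true = omega2_true)
}
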