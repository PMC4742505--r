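test_that("bubble pairs derive ordered values, spread and midpoint", {
  p <- bubble_pair(c(4, 6, 2), c(6, 4, 2))
  expect_equal(p$x1, c(4, 4, 2))
  expect_equal(p$x2, c(6, 6, 2))
  expect_equal(p$d, c(2, 2, 0))
  expect_equal(p$b, c(2, -2, 0))
  expect_equal(p$mean, c(5, 5, 2))
})

test_that("sampling respects the model support, spread moments, and the seed", {
  m <- submarine_model(theta = 3)
  draws <- sample_bubbles(m, 1e5, seed = 42)
  expect_true(all(draws$y1 >= -2 & draws$y1 <= 8))
  expect_true(all(draws$y2 >= -2 & draws$y2 <= 8))
  expect_true(all(draws$d >= 0 & draws$d <= 10))

  # E[d] for the range of two uniforms on a length-10 interval, by an
  # independent quadrature oracle on the spread density f(d) = (10 - d)/50
  e_d <- integrate(function(d) d * spread_density(d), 0, 10)$value
  expect_equal(e_d, 10 / 3, tolerance = 1e-8)
  expect_lt(abs(mean(draws$d) - e_d), 3 * sd(draws$d) / sqrt(nrow(draws)))

  # standard error of the midpoint: sqrt(100/24), about 2.04
  expect_equal(sqrt(100 / 24), 2.0412, tolerance = 1e-4)
  expect_lt(abs(sd(draws$mean - 3) - sqrt(100 / 24)), 0.02)

  expect_identical(draws, sample_bubbles(m, 1e5, seed = 42))
})

test_that("likelihood interval brackets exactly the possible locations", {
  expect_interval_equal(likelihood_interval(bubble_pair(4, 6)), 1, 9)
  expect_interval_equal(likelihood_interval(bubble_pair(2.5, 2.5)), -2.5, 7.5)
  expect_interval_equal(likelihood_interval(bubble_pair(0.5, 9.5)), 4.5, 5.5)
  expect_error(likelihood_interval(bubble_pair(0, 11)), "impossible")
})

test_that("the trivial procedure returns the whole line or nothing by draw order", {
  expect_equal(trivial_interval(bubble_pair(2, 1)), whole_line())
  expect_true(is_empty(trivial_interval(bubble_pair(1, 2), "order_empty")))
  pt <- trivial_interval(bubble_pair(1, 2), "order_point", point_location = 0)
  expect_true(is_degenerate(pt))
  expect_equal(pt$lower, 0)
})

test_that("sampling-distribution interval uses the triangular quantile", {
  int <- sampling_distribution_interval(bubble_pair(1, 1.5))
  h <- (int$upper - int$lower) / 2
  expect_equal(h, 5 - 5 / sqrt(2), tolerance = 1e-12)
  expect_equal(round(h, 2), 1.46)

  # the confidence -> half-width map approaches the full half-range
  wide <- sampling_distribution_interval(bubble_pair(0, 0), 1 - 1e-12)
  expect_equal((wide$upper - wide$lower) / 2, 5, tolerance = 1e-5)
  expect_error(sampling_distribution_interval(bubble_pair(0, 0), 1.5),
               "confidence")

  # at a non-half level the closed form is checked against brute-force MC
  # coverage under the triangular sampling distribution of the midpoint
  cov75 <- mc_coverage(submarine_procedure("sampling_distribution",
                                           confidence = 0.75),
                       bubble_sampler(0), 1e5, seed = 7)
  expect_lt(abs(cov75$estimate - 0.75), mc_tol(0.75, 1e5))
})

test_that("nonparametric interval spans the observations and matches Student's t at n = 2", {
  expect_interval_equal(nonparametric_interval(bubble_pair(1, 1.5)), 1, 1.5)
  expect_true(is_degenerate(nonparametric_interval(bubble_pair(2, 2))))

  # 50% t interval for n = 2: xbar +/- qt(.75, 1) * s / sqrt(2) = xbar +/- d/2
  set.seed(19)
  for (i in 1:25) {
    y <- runif(2, -10, 10)
    s <- sd(y)
    t_lo <- mean(y) - qt(0.75, df = 1) * s / sqrt(2)
    t_hi <- mean(y) + qt(0.75, df = 1) * s / sqrt(2)
    np <- nonparametric_interval(bubble_pair(y[1], y[2]))
    expect_equal(np$lower, t_lo, tolerance = 1e-10)
    expect_equal(np$upper, t_hi, tolerance = 1e-10)
  }
})

test_that("UMP interval truncates to the likelihood above spread 5", {
  expect_interval_equal(ump_interval(bubble_pair(1, 1.5)), 1, 1.5)
  expect_interval_equal(ump_interval(bubble_pair(-3.5, 6)), 1, 1.5)
  # branch continuity at d = 5
  at5 <- ump_interval(bubble_pair(0, 5))
  expect_equal((at5$upper - at5$lower) / 2, 2.5)
  # never wider than the likelihood
  draws <- sample_bubbles(submarine_model(0), 200, seed = 3)
  for (i in seq_len(200)) {
    u <- ump_interval(draws[i, ])
    l <- likelihood_interval(draws[i, ])
    expect_true(u$lower >= l$lower - 1e-12 && u$upper <= l$upper + 1e-12)
  }
})

test_that("Bayes central interval is the central fraction of the likelihood", {
  expect_interval_equal(bayes_central_interval(bubble_pair(1, 1.5)),
                        -1.125, 3.625)
  expect_true(is_degenerate(bayes_central_interval(bubble_pair(-5, 5))))

  draws <- sample_bubbles(submarine_model(0), 500, seed = 4)
  b <- apply_procedure(submarine_procedure("bayes"), draws)
  expect_equal(b$upper - b$lower, 0.5 * (10 - draws$d), tolerance = 1e-12)
})

test_that("for far-apart bubbles the nominal-50% intervals are certain to cover", {
  pair <- bubble_pair(0.5, 9.5)
  lik <- likelihood_interval(pair)
  for (f in list(sampling_distribution_interval, nonparametric_interval,
                 ump_interval)) {
    int <- f(pair)
    expect_true(int$lower <= lik$lower && int$upper >= lik$upper)
  }
  bay <- bayes_central_interval(pair)
  expect_true(bay$lower > lik$lower && bay$upper < lik$upper)
})

test_that("the four nontrivial procedures share a center and nest on every draw", {
  draws <- sample_bubbles(submarine_model(2), 500, seed = 12)
  tabs <- lapply(c("sampling_distribution", "nonparametric", "ump", "bayes"),
                 function(nm) apply_procedure(submarine_procedure(nm), draws))
  centers <- sapply(tabs, function(t) (t$lower + t$upper) / 2)
  expect_true(all(abs(centers - draws$mean) < 1e-12))
  # nesting: on every draw, each pair of intervals has one inside the other
  for (i in seq_len(50)) {
    for (a in 1:3) for (b in (a + 1):4) {
      ia <- tabs[[a]][i, ]; ib <- tabs[[b]][i, ]
      nested <- (ia$lower <= ib$lower && ia$upper >= ib$upper) ||
        (ib$lower <= ia$lower && ib$upper >= ia$upper)
      expect_true(nested)
    }
  }
})

test_that("analytic conditional coverage matches its derivation and MC at several spreads", {
  expect_equal(conditional_coverage_analytic("sampling_distribution", 0.5),
               2 * (5 - 5 / sqrt(2)) / 9.5, tolerance = 1e-12)
  expect_equal(round(100 * conditional_coverage_analytic(
    "sampling_distribution", 0.5)), 31)
  expect_equal(round(100 * conditional_coverage_analytic(
    "nonparametric", 0.5)), 5)
  expect_equal(conditional_coverage_analytic("ump", 0.5),
               conditional_coverage_analytic("nonparametric", 0.5))
  expect_equal(conditional_coverage_analytic("bayes", c(0.5, 2, 7.7)),
               rep(0.5, 3))
  expect_equal(conditional_coverage_analytic("trivial", c(0.5, 8)),
               rep(0.5, 2))
  expect_error(conditional_coverage_analytic("mystery", 1), "unknown")

  # gate on Monte-Carlo before trusting the formula as an oracle
  sampler <- bubble_sampler(0)
  for (d0 in c(0.5, 3, 8)) {
    for (nm in c("sampling_distribution", "nonparametric", "bayes")) {
      mc <- mc_conditional_coverage(submarine_procedure(nm), sampler,
                                    function(dr) dr$d, d0, 0.05,
                                    n_reps = 4e5, seed = 91)
      ana <- conditional_coverage_analytic(nm, d0)
      n_acc <- round(mc$acceptance_rate * 4e5)
      expect_lt(abs(mc$estimate - ana), mc_tol(max(ana, 0.05), n_acc) + 0.01)
    }
  }
})

test_that("conditional coverage integrates to the nominal level over the spread density", {
  for (nm in c("sampling_distribution", "nonparametric", "ump", "bayes",
               "trivial")) {
    total <- integrate(function(d)
      conditional_coverage_analytic(nm, d) * spread_density(d),
      0, 10 - 1e-12, rel.tol = 1e-10, subdivisions = 500L)$value
    expect_equal(total, 0.5, tolerance = 1e-6)
  }
})

test_that("analytic inclusion probabilities: coverage at offset 0 and dominance ordering", {
  for (nm in c("sampling_distribution", "nonparametric", "ump", "bayes")) {
    expect_equal(inclusion_probability_analytic(nm, 0), 0.5,
                 tolerance = 1e-6)
  }
  offsets <- seq(0.25, 9.75, by = 0.25)
  expect_equal(inclusion_probability_analytic("trivial", offsets),
               rep(0.5, length(offsets)))

  ump <- inclusion_probability_analytic("ump", offsets)
  sd_ <- inclusion_probability_analytic("sampling_distribution", offsets)
  np <- inclusion_probability_analytic("nonparametric", offsets)
  bay <- inclusion_probability_analytic("bayes", offsets)
  # the UMP procedure excludes every false value most often
  expect_true(all(ump <= sd_ + 1e-9))
  expect_true(all(ump <= np + 1e-9))
  expect_true(all(ump <= bay + 1e-9))
  # sampling-distribution always at or below Bayes; NP and Bayes cross
  expect_true(all(sd_ <= bay + 1e-9))
  expect_true(any(np < bay - 1e-6) && any(bay < np - 1e-6))
})

test_that("analytic inclusion agrees with the Monte-Carlo curve", {
  sampler <- bubble_sampler(0)
  offsets <- c(0, 1, 2.5, 6)
  for (nm in c("sampling_distribution", "ump", "bayes")) {
    curve <- inclusion_curve(submarine_procedure(nm), sampler, offsets,
                             n_reps = 1e5, seed = 23)
    ana <- inclusion_probability_analytic(nm, offsets)
    expect_true(all(abs(curve$estimate - ana) <
                      mc_tol(pmax(ana, 0.05), 1e5)))
  }
})

test_that("grid posterior: flat prior reproduces the central credible interval", {
  pair <- bubble_pair(1, 1.5)
  post <- posterior_grid(pair, uniform_prior(-20, 20))
  expect_equal(sum(post$grid$mass), 1, tolerance = 1e-9)
  ref <- bayes_central_interval(pair)
  expect_lt(abs(post$interval$lower - ref$lower), 0.001)
  expect_lt(abs(post$interval$upper - ref$upper), 0.001)
  # posterior is uniform on the likelihood interval
  lik <- likelihood_interval(pair)
  on <- interval_contains(lik, post$grid$theta)
  expect_true(all(post$grid$mass[!on] == 0))
  expect_lt(diff(range(post$grid$mass[on])), 1e-12)
})

test_that("grid posterior: informative prior matches a 10x finer refinement", {
  pair <- bubble_pair(1, 1.5)
  prior <- triangular_prior(-10, -2, 10)
  coarse <- posterior_grid(pair, prior, grid_step = 0.01)
  fine <- posterior_grid(pair, prior, grid_step = 0.001)
  expect_equal(sum(fine$grid$mass), 1, tolerance = 1e-9)
  # normalized density at shared grid points
  at <- seq(-9, 9, by = 0.5)
  dc <- approx(coarse$grid$theta, coarse$grid$mass / 0.01, xout = at)$y
  df_ <- approx(fine$grid$theta, fine$grid$mass / 0.001, xout = at)$y
  expect_true(all(abs(dc - df_) < 1e-3))
  expect_lt(abs(coarse$interval$lower - fine$interval$lower), 0.01)
  expect_lt(abs(coarse$interval$upper - fine$interval$upper), 0.01)

  expect_error(posterior_grid(pair, uniform_prior(15, 20)), "zero evidence")
})
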