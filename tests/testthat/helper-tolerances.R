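# 3 Monte-Carlo standard errors: the package-wide agreement criterion for
# stochastic checks.
mc_tol <- function(p, n, k = 3) k * sqrt(p * (1 - p) / n)

# independent trapezoid integrator used to check posterior normalization
trapz_mass <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

expect_interval_equal <- function(int, lower, upper, tol = 1e-12) {
  expect_false(is_empty(int))
  expect_equal(int$lower, lower, tolerance = tol)
  expect_equal(int$upper, upper, tolerance = tol)
}
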