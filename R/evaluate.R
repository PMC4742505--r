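# Monte-Carlo evaluation harness: coverage, conditional coverage on relevant
# subsets, false-value inclusion curves, width profiles. Everything is
# reproducible from an explicit seed; the harness never touches the caller's
# RNG state.

with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Data samplers for the Monte-Carlo harness
#'
#' A sampler bundles a draw function with the true parameter value it draws
#' under, so that coverage can be scored, plus (optionally) a per-draw
#' reference width used by [width_profile()].
#'
#' @param draw Function of a single count `n` returning a data frame of `n`
#'   i.i.d. draws, one per row.
#' @param theta True parameter value under which `draw` samples.
#' @param ref_width Optional function mapping the draw data frame to a numeric
#'   vector of reference (likelihood) widths, one per draw.
#' @param label Text label.
#' @return An object of class `mc_sampler`.
#' @seealso [bubble_sampler()]
#' @export
mc_sampler <- function(draw, theta, ref_width = NULL, label = "sampler") {
  stopifnot(is.function(draw), is.numeric(theta), length(theta) == 1L)
  if (!is.null(ref_width)) stopifnot(is.function(ref_width))
  structure(list(draw = draw, theta = theta, ref_width = ref_width,
                 label = label),
            class = "mc_sampler")
}

eval_result <- function(procedure, statistic, estimate, n_used, n_reps, seed,
                        condition = NA_character_) {
  data.frame(
    procedure = procedure,
    statistic = statistic,
    estimate  = estimate,
    mc_se     = sqrt(estimate * (1 - estimate) / n_used),
    n_reps    = n_reps,
    seed      = seed,
    condition = condition,
    stringsAsFactors = FALSE
  )
}

check_reps <- function(n_reps) {
  if (!is.numeric(n_reps) || length(n_reps) != 1L || is.na(n_reps) ||
      n_reps < 1) {
    stop("'n_reps' must be a positive count", call. = FALSE)
  }
}

#' Monte-Carlo coverage of an interval procedure
#'
#' Draws `n_reps` datasets from `sampler`, applies the procedure to each, and
#' estimates the coverage probability as the fraction of intervals containing
#' the sampler's true parameter value. Containment is closed at finite
#' endpoints; empty intervals never cover.
#'
#' @param proc A [procedure()].
#' @param sampler An [mc_sampler()].
#' @param n_reps Number of Monte-Carlo replicates.
#' @param seed Integer seed; identical seed and settings give an identical
#'   estimate.
#' @return One-row data frame with columns `procedure`, `statistic`,
#'   `estimate`, `mc_se`, `n_reps`, `seed`, `condition`, where
#'   `mc_se = sqrt(estimate (1 - estimate) / n)`.
#' @examples
#' sd50 <- submarine_procedure("sampling_distribution")
#' mc_coverage(sd50, bubble_sampler(theta = 0), n_reps = 2000, seed = 1)
#' @export
mc_coverage <- function(proc, sampler, n_reps, seed) {
  stopifnot(inherits(proc, "procedure"), inherits(sampler, "mc_sampler"))
  check_reps(n_reps)
  draws <- with_seed(seed, sampler$draw(n_reps))
  ints <- apply_procedure(proc, draws)
  hit <- !ints$empty & ints$lower <= sampler$theta & sampler$theta <= ints$upper
  eval_result(proc$name, "coverage", mean(hit), n_reps, n_reps, seed)
}

#' Conditional coverage on a relevant subset
#'
#' Estimates coverage among draws whose conditioning statistic falls in the
#' bin `bin_center` +/- `bin_halfwidth` (rejection conditioning). A procedure
#' admits a relevant subset when this conditional coverage differs from the
#' nominal confidence coefficient.
#'
#' @inheritParams mc_coverage
#' @param condition_stat Function mapping the draw data frame to a numeric
#'   vector (one statistic value per draw), e.g. `function(d) d$d` for the
#'   spread between two observations.
#' @param bin_center,bin_halfwidth Center and halfwidth of the accepted bin;
#'   `bin_halfwidth` must be positive.
#' @return As [mc_coverage()], with `condition` describing the bin and an
#'   `acceptance_rate` column. Errors if fewer than 1000 draws land in the
#'   bin, naming the acceptance rate.
#' @export
mc_conditional_coverage <- function(proc, sampler, condition_stat, bin_center,
                                    bin_halfwidth = 0.05, n_reps, seed) {
  stopifnot(inherits(proc, "procedure"), inherits(sampler, "mc_sampler"),
            is.function(condition_stat))
  check_reps(n_reps)
  if (!is.numeric(bin_halfwidth) || bin_halfwidth <= 0) {
    stop("'bin_halfwidth' must be positive", call. = FALSE)
  }
  draws <- with_seed(seed, sampler$draw(n_reps))
  stat <- condition_stat(draws)
  keep <- abs(stat - bin_center) <= bin_halfwidth
  n_acc <- sum(keep)
  rate <- n_acc / n_reps
  if (n_acc < 1000) {
    stop(sprintf(
      "insufficient conditioned data: %d of %d draws accepted (acceptance rate %.4f); increase n_reps",
      n_acc, n_reps, rate), call. = FALSE)
  }
  ints <- apply_procedure(proc, draws[keep, , drop = FALSE])
  hit <- !ints$empty & ints$lower <= sampler$theta & sampler$theta <= ints$upper
  out <- eval_result(proc$name, "conditional_coverage", mean(hit), n_acc,
                     n_reps, seed,
                     condition = sprintf("|stat - %g| <= %g", bin_center,
                                         bin_halfwidth))
  out$acceptance_rate <- rate
  out
}

#' False-value inclusion curve
#'
#' For each offset in `offsets`, estimates the probability that the
#' procedure's interval includes the false value `theta + offset`. At offset 0
#' this is the coverage probability; a procedure that excludes false values
#' more often is the more powerful one. A common set of draws is reused across
#' offsets, so curves at different offsets are positively correlated (which
#' sharpens curve comparisons).
#'
#' @inheritParams mc_coverage
#' @param offsets Numeric vector of finite displacements from the true value.
#' @return Data frame with one row per offset: `procedure`, `offset`,
#'   `estimate`, `mc_se`, `n_reps`, `seed`.
#' @export
inclusion_curve <- function(proc, sampler, offsets, n_reps, seed) {
  stopifnot(inherits(proc, "procedure"), inherits(sampler, "mc_sampler"),
            is.numeric(offsets), all(is.finite(offsets)))
  check_reps(n_reps)
  draws <- with_seed(seed, sampler$draw(n_reps))
  ints <- apply_procedure(proc, draws)
  rows <- lapply(offsets, function(off) {
    v <- sampler$theta + off
    hit <- !ints$empty & ints$lower <= v & v <= ints$upper
    data.frame(procedure = proc$name, offset = off, estimate = mean(hit),
               mc_se = sqrt(mean(hit) * (1 - mean(hit)) / n_reps),
               n_reps = n_reps, seed = seed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Interval width against estimation uncertainty
#'
#' Pairs each draw's interval width with the width of its likelihood set (the
#' sampler's `ref_width`), the model's index of how much the data actually
#' constrain the parameter. Procedures whose width tracks the likelihood
#' width convey precision; procedures with fixed or inversely related widths
#' do not.
#'
#' @inheritParams mc_coverage
#' @return Data frame with columns `likelihood_width`, `interval_width`
#'   (`Inf` for unbounded intervals, 0 for empty ones), one row per draw.
#' @export
width_profile <- function(proc, sampler, n_reps, seed) {
  stopifnot(inherits(proc, "procedure"), inherits(sampler, "mc_sampler"))
  if (is.null(sampler$ref_width)) {
    stop("sampler supplies no reference width function", call. = FALSE)
  }
  check_reps(n_reps)
  draws <- with_seed(seed, sampler$draw(n_reps))
  ints <- apply_procedure(proc, draws)
  w <- ifelse(ints$empty, 0, ints$upper - ints$lower)
  data.frame(likelihood_width = sampler$ref_width(draws),
             interval_width = w)
}

#' Serialize evaluation results
#'
#' Writes the evaluation-result data frame produced by the harness to CSV or
#' JSON with identical keys.
#'
#' @param results Data frame from [mc_coverage()] and friends (rows may be
#'   concatenated with `rbind`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eval_csv <- function(results, path) {
  stopifnot(is.data.frame(results))
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eval_csv
#' @export
write_eval_json <- function(results, path) {
  stopifnot(is.data.frame(results))
  jsonlite::write_json(results, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
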