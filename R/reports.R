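# Config-driven report generation: the machine-readable counterpart of the
# two worked examples. Reports validate their full config up front, compute
# everything, and only then write files, so a failed run leaves nothing
# behind. Every emitted file embeds the seed and a hash of the resolved
# config; identical configs produce identical files.

SCHEMA_VERSION <- 1L

submarine_keys <- c("pairs", "level", "d_grid", "offsets", "n_reps", "seed",
                    "bin_halfwidth", "out_dir")
omega_keys <- c("f_stat", "k", "n_per_group", "level", "grid_points",
                "prior", "simulate", "out_dir", "seed")

#' Run configurations for report generation
#'
#' A validated bundle of command name plus parameters. Unknown parameter
#' keys are rejected. Configs can be read from JSON or YAML files
#' (extension-dispatched); flags passed by the command-line wrapper override
#' file values.
#'
#' @param command `"submarine"` or `"omega"`.
#' @param params Named list of parameters (see [run_submarine_report()] and
#'   [run_omega_report()] for the accepted keys).
#' @return Object of class `run_config`.
#' @export
run_config <- function(command = c("submarine", "omega"), params = list()) {
  command <- match.arg(command)
  stopifnot(is.list(params))
  allowed <- if (command == "submarine") submarine_keys else omega_keys
  bad <- setdiff(names(params), allowed)
  if (length(bad)) {
    stop(sprintf("unknown config key(s) for '%s': %s", command,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(command = command, params = params,
                 schema_version = SCHEMA_VERSION),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON (`.json`) or YAML (`.yaml`/`.yml`) config file with
#'   top-level fields `command` and `params`.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop(sprintf("unsupported config format '.%s' (use JSON or YAML)", ext),
         call. = FALSE))
  if (is.null(raw$command)) stop("config lacks a 'command' field",
                                 call. = FALSE)
  run_config(raw$command, as.list(raw$params))
}

# FNV-1a over the canonical JSON serialization of the resolved config.
# The output directory is where results land, not part of what was computed,
# so it is excluded: the same analysis written to two places hashes equally.
config_hash <- function(config) {
  x <- unclass(config)
  x$params$out_dir <- NULL
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  # 32-bit FNV-1a carried in doubles: xor touches only the low byte, and the
  # multiply is split into 16-bit halves to stay within exact double range
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    lo <- h %% 65536
    hi <- h %/% 65536
    t <- lo * 16777619
    h <- ((hi * 16777619 + t %/% 65536) %% 65536) * 65536 + t %% 65536
  }
  sprintf("%08x", h)
}

param_or <- function(params, key, default) {
  if (is.null(params[[key]])) default else params[[key]]
}

stamp <- function(df, hash, seed) {
  df$config_hash <- hash
  df$seed <- seed
  df
}

write_outputs <- function(tables, jsons, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(jsons)) {
    p <- file.path(out_dir, paste0(nm, ".json"))
    jsonlite::write_json(jsons[[nm]], p, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  paths
}

#' Generate the uniform-location report
#'
#' Emits, for a configured set of observation pairs and settings: the five
#' procedure intervals plus the likelihood interval per pair
#' (`intervals.csv`/`.json`), the analytic conditional-coverage table over a
#' spread grid with Monte-Carlo confirmation at each spread
#' (`conditional_coverage.csv`), the analytic and Monte-Carlo inclusion
#' curves (`inclusion_curve.csv`), and a width-profile table
#' (`width_profile.csv`).
#'
#' Accepted `params`: `pairs` (list of two-element vectors or a data frame
#' with columns `y1`, `y2`; default the pair (1, 1.5)), `level` (default
#' 0.5), `d_grid` (default `c(0.5, 2, 5, 8)`), `offsets` (default
#' `seq(0, 9.75, 0.25)`), `n_reps` (default 1e5), `bin_halfwidth` (default
#' 0.05), `seed` (default 1), `out_dir` (required).
#'
#' @param config A [run_config()] with command `"submarine"`.
#' @return Character vector of written file paths, invisibly.
#' @export
run_submarine_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$command != "submarine") {
    stop("config command must be 'submarine'", call. = FALSE)
  }
  p <- config$params
  out_dir <- p$out_dir
  if (is.null(out_dir)) stop("config requires 'out_dir'", call. = FALSE)
  level <- param_or(p, "level", 0.5)
  seed <- param_or(p, "seed", 1L)
  n_reps <- param_or(p, "n_reps", 1e5)
  d_grid <- param_or(p, "d_grid", c(0.5, 2, 5, 8))
  offsets <- param_or(p, "offsets", seq(0, 9.75, by = 0.25))
  binhw <- param_or(p, "bin_halfwidth", 0.05)
  pairs <- param_or(p, "pairs", list(c(1, 1.5)))
  if (is.data.frame(pairs)) pairs <- Map(c, pairs$y1, pairs$y2)
  pairs <- lapply(pairs, function(v) {
    v <- as.numeric(v)
    if (length(v) != 2L || any(!is.finite(v))) {
      stop("each pair must be two finite numbers", call. = FALSE)
    }
    v
  })
  hash <- config_hash(config)
  procs <- c("trivial", "sampling_distribution", "nonparametric", "ump",
             "bayes")

  interval_rows <- do.call(rbind, lapply(pairs, function(v) {
    pair <- bubble_pair(v[1], v[2])
    ints <- list(
      likelihood = likelihood_interval(pair),
      trivial = trivial_interval(pair),
      sampling_distribution = sampling_distribution_interval(pair, level),
      nonparametric = nonparametric_interval(pair),
      ump = ump_interval(pair),
      bayes = bayes_central_interval(pair, level)
    )
    do.call(rbind, lapply(names(ints), function(nm) {
      int <- ints[[nm]]
      data.frame(y1 = v[1], y2 = v[2], procedure = nm,
                 lower = if (int$empty) NA_real_ else int$lower,
                 upper = if (int$empty) NA_real_ else int$upper,
                 empty = int$empty, stringsAsFactors = FALSE)
    }))
  }))

  sampler <- bubble_sampler(0)
  cond_rows <- do.call(rbind, lapply(d_grid, function(d) {
    do.call(rbind, lapply(procs, function(nm) {
      analytic <- conditional_coverage_analytic(nm, d, level)
      mc <- mc_conditional_coverage(submarine_procedure(nm, confidence = level),
                                    sampler, function(dr) dr$d, d, binhw,
                                    n_reps, seed)
      data.frame(procedure = nm, d = d, analytic = analytic,
                 mc_estimate = mc$estimate, mc_se = mc$mc_se,
                 n_accepted = round(mc$acceptance_rate * n_reps),
                 stringsAsFactors = FALSE)
    }))
  }))

  incl_rows <- do.call(rbind, lapply(procs, function(nm) {
    analytic <- inclusion_probability_analytic(nm, offsets, level)
    mc <- inclusion_curve(submarine_procedure(nm, confidence = level),
                          sampler, offsets, n_reps, seed)
    data.frame(procedure = nm, offset = offsets, analytic = analytic,
               mc_estimate = mc$estimate, mc_se = mc$mc_se,
               stringsAsFactors = FALSE)
  }))

  wp <- do.call(rbind, lapply(procs[-1], function(nm) {
    tab <- width_profile(submarine_procedure(nm, confidence = level),
                         sampler, min(n_reps, 2000), seed)
    tab$procedure <- nm
    tab
  }))

  tables <- list(
    intervals = stamp(interval_rows, hash, seed),
    conditional_coverage = stamp(cond_rows, hash, seed),
    inclusion_curve = stamp(incl_rows, hash, seed),
    width_profile = stamp(wp, hash, seed)
  )
  jsons <- list(intervals = list(config_hash = hash, seed = seed,
                                 level = level, intervals = interval_rows))
  invisible(write_outputs(tables, jsons, out_dir))
}

#' Generate the effect-size report
#'
#' Emits the test-inversion confidence interval with its existence flags and
#' noncentrality bounds (`omega_ci.json`), the likelihood grid
#' (`omega_likelihood.csv`), the grid posterior with its HPD interval
#' (`omega_posterior.csv`, `omega_hpd.json`) and, when `simulate` is
#' supplied, a simulated coverage table (`omega_coverage.csv`).
#'
#' Accepted `params`: `f_stat`, `k`, `n_per_group` (required), `level`
#' (default 0.68), `grid_points` (default 1000), `prior` (`"flat"` only),
#' `simulate` (optional list with `omega2`, `reps`), `seed` (default 1),
#' `out_dir` (required).
#'
#' @param config A [run_config()] with command `"omega"`.
#' @return Character vector of written file paths, invisibly.
#' @export
run_omega_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$command != "omega") {
    stop("config command must be 'omega'", call. = FALSE)
  }
  p <- config$params
  out_dir <- p$out_dir
  if (is.null(out_dir)) stop("config requires 'out_dir'", call. = FALSE)
  for (key in c("f_stat", "k", "n_per_group")) {
    if (is.null(p[[key]])) {
      stop(sprintf("config requires '%s'", key), call. = FALSE)
    }
  }
  summ <- anova_summary(p$f_stat, p$k, p$n_per_group)
  level <- param_or(p, "level", 0.68)
  gp <- param_or(p, "grid_points", 1000)
  seed <- param_or(p, "seed", 1L)
  hash <- config_hash(config)

  ci <- steiger_ci(summ, level)
  grid <- seq(0, 0.995, length.out = gp)
  lik <- omega_likelihood(summ, grid)
  post <- omega_posterior_hpd(summ, prior = NULL, level = level, grid = grid)

  tables <- list(
    omega_likelihood = stamp(lik, hash, seed),
    omega_posterior = stamp(post$grid, hash, seed)
  )
  jsons <- list(
    omega_ci = list(config_hash = hash, seed = seed,
                    f_stat = summ$f_stat, df1 = summ$df1, df2 = summ$df2,
                    confidence = level, lower = ci$lower, upper = ci$upper,
                    empty = ci$empty,
                    lower_set_to_zero = ci$lower_set_to_zero,
                    upper_set_to_zero = ci$upper_set_to_zero,
                    suspect = ci$suspect, p_central = ci$p_central,
                    lambda_bounds = as.list(ci$lambda_bounds)),
    omega_hpd = list(config_hash = hash, seed = seed, level = level,
                     lower = post$hpd$lower, upper = post$hpd$upper,
                     mass = post$mass, mode = post$mode,
                     contiguous = post$contiguous)
  )

  if (!is.null(p$simulate)) {
    sim <- p$simulate
    if (is.null(sim$omega2) || is.null(sim$reps)) {
      stop("'simulate' requires 'omega2' and 'reps'", call. = FALSE)
    }
    reps <- sim$reps
    cover <- logical(reps)
    for (i in seq_len(reps)) {
      run <- simulate_anova(p$k, p$n_per_group, sim$omega2,
                            seed = (seed + i) %% .Machine$integer.max)
      ci_i <- steiger_ci(run$summary, level)
      cover[i] <- !ci_i$empty && ci_i$lower <= sim$omega2 &&
        sim$omega2 <= ci_i$upper
    }
    tables$omega_coverage <- stamp(
      data.frame(omega2_true = sim$omega2, level = level, reps = reps,
                 coverage = mean(cover),
                 mc_se = sqrt(mean(cover) * (1 - mean(cover)) / reps)),
      hash, seed)
  }
  invisible(write_outputs(tables, jsons, out_dir))
}
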