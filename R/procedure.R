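#' Named interval procedures
#'
#' A procedure is a deterministic rule mapping one dataset draw to an
#' [interval()] at a stated confidence coefficient. All randomness lives in
#' data generation; given its input the rule always returns the same interval.
#'
#' The scalar `rule` defines the procedure. An optional vectorized form
#' `vrule` may be supplied for speed: it takes a data frame of draws (one row
#' per draw) and returns a data frame with columns `lower`, `upper`, `empty`.
#' When absent, the Monte-Carlo harness falls back to applying `rule` row by
#' row; the two forms must agree.
#'
#' @param name Identifier for the procedure.
#' @param confidence Confidence coefficient in (0, 1).
#' @param rule Function taking one draw (a one-row data frame or list) and
#'   returning an [interval()].
#' @param vrule Optional vectorized rule (see Details).
#' @return An object of class `procedure`.
#' @seealso [submarine_procedure()] for the five uniform-location procedures.
#' @export
procedure <- function(name, confidence, rule, vrule = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      is.na(confidence) || confidence <= 0 || confidence >= 1) {
    stop("'confidence' must be a single number in (0, 1)", call. = FALSE)
  }
  stopifnot(is.function(rule))
  if (!is.null(vrule)) stopifnot(is.function(vrule))
  structure(list(name = name, confidence = confidence,
                 rule = rule, vrule = vrule),
            class = "procedure")
}

#' @export
print.procedure <- function(x, ...) {
  cat(sprintf("<procedure '%s' at confidence %.3g>\n", x$name, x$confidence))
  invisible(x)
}

#' Apply a procedure to a batch of draws
#'
#' @param proc A [procedure()].
#' @param draws Data frame of draws, one row per draw.
#' @return Data frame with one row per draw and columns `lower`, `upper`,
#'   `empty` (endpoints are `NA` on empty rows).
#' @export
apply_procedure <- function(proc, draws) {
  stopifnot(inherits(proc, "procedure"), is.data.frame(draws))
  if (!is.null(proc$vrule)) {
    out <- proc$vrule(draws)
    stopifnot(is.data.frame(out),
              all(c("lower", "upper", "empty") %in% names(out)),
              nrow(out) == nrow(draws))
    return(out[c("lower", "upper", "empty")])
  }
  n <- nrow(draws)
  lower <- upper <- numeric(n)
  empty <- logical(n)
  for (i in seq_len(n)) {
    int <- proc$rule(draws[i, , drop = FALSE])
    stopifnot(inherits(int, "interval"))
    empty[i] <- int$empty
    lower[i] <- if (int$empty) NA_real_ else int$lower
    upper[i] <- if (int$empty) NA_real_ else int$upper
  }
  data.frame(lower = lower, upper = upper, empty = empty)
}
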