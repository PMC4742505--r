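#' Closed real intervals with explicit empty and degenerate states
#'
#' An `interval` is the universal return type of every interval procedure in
#' this package: a closed interval on the extended real line, possibly
#' unbounded on either side, possibly empty, possibly a single point.
#' Emptiness is a distinct state, never encoded as a zero-width interval.
#'
#' @param lower Lower endpoint; may be `-Inf`.
#' @param upper Upper endpoint; may be `Inf`. Must satisfy `lower <= upper`.
#' @return An object of class `interval` with fields `lower`, `upper`,
#'   `empty`, `degenerate`.
#' @examples
#' interval(1, 9)
#' whole_line()
#' point_interval(0)
#' empty_interval()
#' @export
interval <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper) ||
      length(lower) != 1L || length(upper) != 1L) {
    stop("'lower' and 'upper' must be single numeric values", call. = FALSE)
  }
  if (is.na(lower) || is.na(upper)) {
    stop("interval endpoints must not be NA", call. = FALSE)
  }
  if (lower > upper) {
    stop(sprintf("invalid interval: lower (%g) > upper (%g)", lower, upper),
         call. = FALSE)
  }
  structure(
    list(lower = lower, upper = upper, empty = FALSE,
         degenerate = (lower == upper)),
    class = "interval"
  )
}

#' @rdname interval
#' @export
empty_interval <- function() {
  structure(list(lower = NA_real_, upper = NA_real_, empty = TRUE,
                 degenerate = FALSE),
            class = "interval")
}

#' @rdname interval
#' @param x Location of the single point.
#' @export
point_interval <- function(x) interval(x, x)

#' @rdname interval
#' @export
whole_line <- function() interval(-Inf, Inf)

#' @export
print.interval <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.interval <- function(x, ...) {
  if (x$empty) return("<interval: empty>")
  if (x$degenerate) return(sprintf("<interval: {%g}>", x$lower))
  sprintf("<interval: [%g, %g]>", x$lower, x$upper)
}

#' Containment, width and state queries for intervals
#'
#' Containment is closed at finite endpoints: `interval(1, 9)` contains both
#' 1 and 9. An empty interval contains nothing; a degenerate interval contains
#' exactly its point.
#'
#' @param int An [interval()].
#' @param v Numeric vector of candidate values.
#' @return `interval_contains`: logical vector; `interval_width`: a single
#'   number (0 for empty intervals, `Inf` when unbounded); `is_empty`,
#'   `is_degenerate`: single logicals.
#' @export
interval_contains <- function(int, v) {
  stopifnot(inherits(int, "interval"))
  if (int$empty) return(rep(FALSE, length(v)))
  v >= int$lower & v <= int$upper
}

#' @rdname interval_contains
#' @export
interval_width <- function(int) {
  stopifnot(inherits(int, "interval"))
  if (int$empty) return(0)
  int$upper - int$lower
}

#' @rdname interval_contains
#' @export
is_empty <- function(int) {
  stopifnot(inherits(int, "interval"))
  int$empty
}

#' @rdname interval_contains
#' @export
is_degenerate <- function(int) {
  stopifnot(inherits(int, "interval"))
  !int$empty && int$degenerate
}
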