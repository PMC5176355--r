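# shared internal helpers

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves always rounded up in
#' magnitude (so 0.5 -> 1, 1.5 -> 2), the convention used for reported
#' integer percentages throughout the package. Base R's `round()` rounds
#' halves to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`
# (seed = NULL leaves the global RNG untouched).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

check_number <- function(x, name, lower = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop(sprintf("`%s` must be %s %s (got %g)", name,
                 if (strict) ">" else ">=", format(lower), x), call. = FALSE)
  }
  invisible(x)
}

check_numeric_vec <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("`%s` must be numeric with no missing values", name),
         call. = FALSE)
  }
  ok <- if (strict) all(x > lower) else all(x >= lower)
  if (!ok) {
    stop(sprintf("all elements of `%s` must be %s %s", name,
                 if (strict) ">" else ">=", format(lower)), call. = FALSE)
  }
  invisible(x)
}

# standard error of a ratio a/b by first-order error propagation
ratio_se <- function(a, sa, b, sb) {
  abs(a / b) * sqrt((sa / a)^2 + (sb / b)^2)
}
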