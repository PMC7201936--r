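# internal helpers

stopf <- function(fmt, ..., class = "lifecourseMR_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

config_error <- function(fmt, ...) stopf(fmt, ..., class = "lifecourseMR_config_error")
input_error  <- function(fmt, ...) stopf(fmt, ..., class = "lifecourseMR_input_error")
format_error <- function(fmt, ...) stopf(fmt, ..., class = "lifecourseMR_format_error")

#' @noRd
check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    config_error("field '%s' must be an integer >= %d (got %s)", name, min,
                 paste(format(x), collapse = ","))
  as.integer(x)
}

#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok)
    config_error("field '%s' must be a number in %s%s, %s%s (got %s)",
                 name, if (open_lower) "(" else "[", format(lower),
                 format(upper), if (open_upper) ")" else "]",
                 paste(format(x), collapse = ","))
  as.numeric(x)
}

# two-sided p from a z statistic (normal approximation), floored at the
# smallest positive double so p stays in (0, 1] under extreme signals
z_pvalue <- function(z) pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)

# run an expression with a private RNG state restored afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
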