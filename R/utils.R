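#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Abort with a class so callers can test error categories.
stop_calspike <- function(msg, class) {
  abort(msg, class = c(class, "calspike_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE, integerish = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper &&
    (!integerish || is.infinite(x) || x == trunc(x))
  if (!ok) {
    stop_calspike(
      sprintf("`%s` must be a single %snumber in [%s, %s], got %s",
              name, if (integerish) "integer " else "",
              format(lower), format(upper),
              paste(format(x), collapse = ", ")),
      "calspike_invalid_parameter"
    )
  }
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  check_number(seed, "seed", integerish = TRUE)
  withr::with_seed(as.integer(seed), expr)
}

# Derive independent child seeds from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Shared sampling-interval inference for trace tables.
infer_dt <- function(time_s) {
  dts <- unique(round(diff(time_s), 9))
  if (length(dts) != 1L || dts[1] <= 0) {
    stop_calspike("trace times must be evenly spaced and increasing",
                  "calspike_unsupported_sampling")
  }
  dts[1]
}
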