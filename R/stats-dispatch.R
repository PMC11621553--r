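#' Gate-driven test selection and execution
#'
#' Implements the full statistical decision procedure used throughout the
#' analysis:
#'
#' 1. **Normality gate** — Shapiro-Wilk per group at `alpha_gate`. If any
#'    group fails, a log10 transform is attempted, then a Box-Cox transform
#'    (shared \eqn{\lambda} fitted by maximum likelihood on the one-way
#'    model), re-testing normality after each. Transforms require strictly
#'    positive data and are skipped otherwise.
#' 2. **Variance gate** (only when normal on some scale) — F test of equal
#'    variances for 2 groups, Bartlett for more, at `alpha_gate`.
#' 3. **Dispatch** — two normal homoscedastic groups: Student t; two normal
#'    heteroscedastic groups: Welch t; >= 3 normal homoscedastic groups:
#'    one-way ANOVA + Tukey HSD; anything non-normal after transforms (or
#'    >= 3 heteroscedastic groups, for which the test menu has no
#'    parametric entry): Mann-Whitney (2 groups) or Kruskal-Wallis (>= 3).
#'
#' Groups with fewer than 3 observations cannot be normality-tested; the
#' procedure then falls back to the nonparametric branch with a warning.
#' Every gate decision (test, p-value, outcome) is recorded in the result's
#' `audit` table.
#'
#' @param data Long data frame with columns `group` and `value` (e.g. from
#'   [frequency_table()] / [amplitude_table()]), or a named list of numeric
#'   vectors.
#' @param tail `"two"` (default) or `"one"`; one-tailed is honoured by the
#'   two-group t tests and Mann-Whitney.
#' @param alpha_gate Significance level of the normality and variance
#'   gates (default 0.05).
#' @param transforms Candidate transforms, tried in order, when raw data
#'   fail normality. Default `c("log10", "boxcox")`.
#' @return A `ca_test`; its `transform` field names the scale the final
#'   test ran on, `audit` holds the gate trail.
#' @examples
#' set.seed(1)
#' d <- data.frame(group = rep(c("a", "b"), each = 30), value = rnorm(60))
#' choose_and_run(d)$test   # "student_t"
#' @export
choose_and_run <- function(data, tail = c("two", "one"), alpha_gate = 0.05,
                           transforms = c("log10", "boxcox")) {
  tail <- match.arg(tail)
  check_number(alpha_gate, "alpha_gate", lower = 0, upper = 1)
  groups <- as_group_list(data)
  k <- length(groups)
  if (k < 2L) {
    stop_calspike("need at least 2 groups", "calspike_invalid_input")
  }
  if (any(lengths(groups) < 2L)) {
    stop_calspike("every group needs n >= 2", "calspike_invalid_input")
  }

  audit <- list()
  note <- function(stage, detail, p, outcome) {
    audit[[length(audit) + 1L]] <<- tibble(
      stage = stage, detail = detail, p = p, outcome = outcome
    )
  }

  if (any(lengths(groups) < 3L)) {
    warn("a group has n < 3: normality untestable, using the nonparametric branch")
    note("normality", "n < 3 in some group", NA_real_, "nonparametric fallback")
    res <- run_nonparametric(groups, tail)
    res$audit <- dplyr::bind_rows(audit)
    return(res)
  }

  normal_on <- NULL
  used_groups <- groups
  lambda <- NULL
  for (scale in c("none", transforms)) {
    cand <- if (scale == "none") {
      groups
    } else if (all(unlist(groups) > 0)) {
      if (scale == "boxcox") {
        lambda <- boxcox_lambda(unlist(groups, use.names = FALSE),
                                rep(names(groups), lengths(groups)))
        purrr::map(groups, transform_values, kind = "boxcox", lambda = lambda)
      } else {
        purrr::map(groups, transform_values, kind = scale)
      }
    } else {
      note("transform", paste(scale, "skipped: non-positive values"),
           NA_real_, "skipped")
      next
    }
    sw <- vapply(cand, shapiro_wilk_safe, numeric(1))
    ok <- all(sw > alpha_gate, na.rm = FALSE) && !anyNA(sw)
    note("normality",
         sprintf("Shapiro-Wilk on %s scale%s (min p over groups)",
                 scale,
                 if (scale == "boxcox") sprintf(", lambda = %.6f", lambda) else ""),
         suppressWarnings(min(sw)),
         if (ok) "normal" else "non-normal")
    if (ok) {
      normal_on <- scale
      used_groups <- cand
      break
    }
  }

  res <- if (is.null(normal_on)) {
    note("dispatch", "non-normal after transforms", NA_real_,
         if (k == 2) "mann_whitney" else "kruskal_wallis")
    run_nonparametric(groups, tail)   # rank tests run on the raw scale
  } else if (k == 2L) {
    vg <- stats::var.test(used_groups[[1]], used_groups[[2]])
    homo <- vg$p.value > alpha_gate
    note("variance", "F test of equal variances", vg$p.value,
         if (homo) "homoscedastic" else "heteroscedastic")
    tt <- stats::t.test(used_groups[[1]], used_groups[[2]],
                        var.equal = homo,
                        alternative = if (tail == "two") "two.sided" else "greater")
    new_ca_test(if (homo) "student_t" else "welch_t", "t",
                unname(tt$statistic), unname(tt$parameter), tail,
                tt$p.value,
                transform = transform_label(normal_on, lambda),
                n = lengths(groups))
  } else {
    g <- factor(rep(names(used_groups), lengths(used_groups)),
                levels = names(used_groups))
    bt <- stats::bartlett.test(unlist(used_groups, use.names = FALSE), g)
    homo <- bt$p.value > alpha_gate
    note("variance", "Bartlett test", bt$p.value,
         if (homo) "homoscedastic" else "heteroscedastic")
    if (homo) {
      res3 <- anova_tukey(used_groups)
      res3$transform <- transform_label(normal_on, lambda)
      res3
    } else {
      note("dispatch", "normal but heteroscedastic, >= 3 groups",
           NA_real_, "kruskal_wallis")
      run_nonparametric(groups, tail)
    }
  }
  res$audit <- dplyr::bind_rows(audit)
  res
}

run_nonparametric <- function(groups, tail) {
  if (length(groups) == 2L) {
    mann_whitney(groups[[1]], groups[[2]], tail = tail)
  } else {
    kruskal_wallis(groups)
  }
}

shapiro_wilk_safe <- function(x) {
  tryCatch(shapiro_wilk(x), calspike_error = function(e) NA_real_)
}

transform_label <- function(scale, lambda) {
  if (scale == "none") "none"
  else if (scale == "log10") "log10"
  else sprintf("boxcox(%.6f)", lambda)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a test result
#'
#' One row per comparison: the overall test for `tidy()`, plus one row per
#' Tukey pair when a post-hoc table is present. `glance()` gives the
#' one-row overall summary.
#'
#' @param x A `ca_test`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ca_test <- function(x, ...) {
  overall <- glance(x)
  if (is.null(x$posthoc)) return(overall)
  ph <- dplyr::mutate(x$posthoc, test = "tukey_hsd", .before = 1)
  dplyr::bind_rows(
    overall,
    tibble(test = ph$test, contrast = ph$pair, estimate = ph$diff,
           p = ph$p_adj)
  )
}

#' @rdname tidy.ca_test
#' @export
glance.ca_test <- function(x, ...) {
  tibble(
    test = x$test,
    statistic_symbol = x$statistic_symbol,
    statistic = x$statistic,
    df1 = if (is.null(x$df)) NA_real_ else x$df[1],
    df2 = if (is.null(x$df) || length(x$df) < 2) NA_real_ else x$df[2],
    tail = x$tail,
    transform = x$transform,
    p = x$p
  )
}
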