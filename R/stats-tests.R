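#' Construct a test-result object
#'
#' Internal container shared by all tests: a `ca_test` carries the test
#' identity, its statistic and degrees of freedom, the tail, the transform
#' applied to the data (if any), the p-value, optional post-hoc table and
#' the gate audit trail. Use [generics::tidy()] / [generics::glance()] or
#' `print()` to inspect it.
#' @noRd
new_ca_test <- function(test, symbol, statistic, df, tail, p,
                        transform = "none", posthoc = NULL, audit = NULL,
                        n = NULL, letters = NULL) {
  structure(
    list(test = test, statistic_symbol = symbol, statistic = statistic,
         df = df, tail = tail, transform = transform, p = p,
         posthoc = posthoc, audit = audit, n = n, letters = letters),
    class = "ca_test"
  )
}

#' @export
print.ca_test <- function(x, ...) {
  dfs <- if (is.null(x$df)) "" else
    sprintf(", df = %s", paste(format(x$df, digits = 6), collapse = ", "))
  cat(sprintf("<ca_test> %s (%s-tailed%s)\n", x$test, x$tail,
              if (x$transform == "none") "" else
                paste0(", transform: ", x$transform)))
  cat(sprintf("  %s = %s%s, p = %s\n", x$statistic_symbol,
              format(x$statistic, digits = 6), dfs, format.pval(x$p, digits = 4)))
  if (!is.null(x$posthoc)) {
    cat("  post hoc (Tukey HSD):\n")
    print(x$posthoc, ...)
  }
  invisible(x)
}

#' Student / Welch t p-value from the statistic
#'
#' Maps a t statistic and its degrees of freedom to a p-value:
#' two-tailed \eqn{p = 2 S(|t|)}, one-tailed \eqn{p = S(t)}, with \eqn{S}
#' the upper-tail probability of the t distribution. Useful to verify
#' reported (t, df, p) triples without the raw data.
#'
#' @param t Observed t statistic.
#' @param df Degrees of freedom (> 0, fractional allowed for Welch).
#' @param tail `"two"` (default) or `"one"`.
#' @return The p-value.
#' @examples
#' t_pvalue(-3.0927, 39)        # ~0.0037
#' t_pvalue(2.1821, 9, "one")   # ~0.0285
#' @export
t_pvalue <- function(t, df, tail = c("two", "one")) {
  tail <- match.arg(tail)
  check_number(t, "t")
  if (!is.numeric(df) || length(df) != 1L || !is.finite(df) || df <= 0) {
    stop_calspike("`df` must be a single positive number",
                  "calspike_invalid_parameter")
  }
  if (tail == "two") 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  else stats::pt(t, df, lower.tail = FALSE)
}

#' Welch-Satterthwaite degrees of freedom
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param s1,s2 Group standard deviations (not both zero).
#' @return Fractional degrees of freedom.
#' @examples
#' welch_df(10, 1, 10, 1)   # 18, the pooled case
#' @export
welch_df <- function(n1, s1, n2, s2) {
  check_number(n1, "n1", lower = 2, integerish = TRUE)
  check_number(n2, "n2", lower = 2, integerish = TRUE)
  check_number(s1, "s1", lower = 0)
  check_number(s2, "s2", lower = 0)
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  if (v1 + v2 == 0) {
    stop_calspike("both groups have zero variance", "calspike_degenerate")
  }
  (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' The statistic `W` is the U statistic of the first group: its rank sum
#' minus \eqn{n_1(n_1+1)/2} (average ranks under ties). The exact p uses
#' the exact null distribution of U (valid without ties); the normal
#' approximation uses mean \eqn{n_1 n_2/2} and SD
#' \eqn{\sqrt{n_1 n_2 (n_1+n_2+1)/12}} with tie correction and, by
#' default, a continuity correction. `method = "auto"` picks exact when
#' \eqn{n_1 + n_2 \le 50} and there are no ties.
#'
#' @param x,y Numeric samples (first and second group).
#' @param method `"auto"`, `"exact"` or `"normal_approx"`. Exact with ties
#'   falls back to the approximation with a warning.
#' @param continuity Apply the continuity correction in the approximation.
#' @param tail `"two"` or `"one"` (one-tailed: upper tail of W, i.e. first
#'   group stochastically larger).
#' @return A `ca_test` with `statistic_symbol = "W"`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p   # exact two-tailed 1/3
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "normal_approx"),
                         continuity = TRUE, tail = c("two", "one")) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) {
    stop_calspike("both groups must be non-empty", "calspike_invalid_input")
  }
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (method == "auto") {
    method <- if (!has_ties && n1 + n2 <= 50) "exact" else "normal_approx"
  }
  if (method == "exact" && has_ties) {
    warn("ties present: exact Mann-Whitney unavailable, using the normal approximation")
    method <- "normal_approx"
  }
  p <- if (method == "exact") {
    wilcox_exact_p(w, n1, n2, tail)
  } else {
    wilcox_approx_p(w, n1, n2, tail, continuity, tie_counts = as.vector(ties))
  }
  new_ca_test("mann_whitney", "W", w, NULL, tail, p,
              n = c(n1 = n1, n2 = n2))
}

#' p-value from a Mann-Whitney W statistic alone
#'
#' Recomputes the p-value from a reported `W` and the group sizes, for
#' statistic-only verification when the raw data are unavailable. No tie
#' correction can be applied (tie structure is unknown from `W` alone).
#'
#' @param w Observed U statistic of the first group.
#' @param n1,n2 Group sizes.
#' @inheritParams mann_whitney
#' @return The p-value.
#' @examples
#' p_from_w(91032, 371, 440)   # ~0.0046
#' @export
p_from_w <- function(w, n1, n2, method = c("normal_approx", "exact"),
                     continuity = TRUE, tail = c("two", "one")) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  check_number(w, "w", lower = 0)
  check_number(n1, "n1", lower = 1, integerish = TRUE)
  check_number(n2, "n2", lower = 1, integerish = TRUE)
  if (w > n1 * n2) {
    stop_calspike("W cannot exceed n1 * n2", "calspike_invalid_parameter")
  }
  if (method == "exact") wilcox_exact_p(w, n1, n2, tail)
  else wilcox_approx_p(w, n1, n2, tail, continuity, tie_counts = NULL)
}

# Exact p from the null distribution of U (no ties). pwilcox is the exact
# recursion over rank configurations.
wilcox_exact_p <- function(w, n1, n2, tail) {
  upper <- stats::pwilcox(w - 1, n1, n2, lower.tail = FALSE)
  lower <- stats::pwilcox(w, n1, n2)
  if (tail == "one") return(upper)
  min(2 * min(upper, lower), 1)
}

wilcox_approx_p <- function(w, n1, n2, tail, continuity, tie_counts = NULL) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_term <- if (is.null(tie_counts)) 0 else
    sum(tie_counts^3 - tie_counts) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  if (sigma == 0) {
    warn("all observations identical: Mann-Whitney p set to 1")
    return(1)
  }
  z <- w - mu
  if (continuity) {
    cc <- if (tail == "two") sign(z) * 0.5 else 0.5
    z <- z - cc
  }
  z <- z / sigma
  if (tail == "one") stats::pnorm(z, lower.tail = FALSE)
  else min(2 * stats::pnorm(abs(z), lower.tail = FALSE), 1)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected K statistic over >= 2 groups, referred to the chi-square
#' distribution with `k - 1` df. `kw_pvalue()` maps a reported K directly
#' to its p-value.
#'
#' @param data Long data frame with columns `group` and `value`, or a list
#'   of numeric vectors.
#' @return A `ca_test` with `statistic_symbol = "K"`.
#' @examples
#' kw_pvalue(55.44, 3)   # ~9.1e-13
#' @export
kruskal_wallis <- function(data) {
  groups <- as_group_list(data)
  if (length(groups) < 2L) {
    stop_calspike("need at least 2 groups", "calspike_invalid_input")
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    warn("all observations identical: Kruskal-Wallis p set to 1")
    return(new_ca_test("kruskal_wallis", "K", 0, length(groups) - 1L,
                       "two", 1, n = lengths(groups)))
  }
  g <- factor(rep(names(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  new_ca_test("kruskal_wallis", "K", unname(kt$statistic),
              unname(kt$parameter), "two", kt$p.value,
              n = lengths(groups))
}

#' @rdname kruskal_wallis
#' @param k Reported K statistic.
#' @param k_groups Number of groups (>= 2).
#' @export
kw_pvalue <- function(k, k_groups) {
  check_number(k, "k", lower = 0)
  check_number(k_groups, "k_groups", lower = 2, integerish = TRUE)
  stats::pchisq(k, df = k_groups - 1, lower.tail = FALSE)
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Fits a one-way ANOVA (F with `(k - 1, N - k)` df), follows with Tukey
#' honest-significant-difference adjusted p-values for every pair
#' (studentized range distribution), and derives a compact letter display:
#' groups sharing a letter are not distinguished at `alpha`.
#'
#' @param data Long data frame (`group`, `value`) or list of vectors; >= 3
#'   groups of >= 2 observations each.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A `ca_test` with `statistic_symbol = "F"`, `df = c(k - 1, N - k)`,
#'   a `posthoc` tibble (`pair`, `diff`, `lwr`, `upr`, `p_adj`) and a
#'   `letters` named character vector.
#' @export
anova_tukey <- function(data, alpha = 0.05) {
  groups <- as_group_list(data)
  if (length(groups) < 3L) {
    stop_calspike("ANOVA + Tukey path expects >= 3 groups",
                  "calspike_invalid_input")
  }
  if (any(lengths(groups) < 2L)) {
    stop_calspike("every group needs >= 2 observations",
                  "calspike_invalid_input")
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    stop_calspike("all observations identical: F undefined",
                  "calspike_degenerate")
  }
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  fstat <- tab[["F value"]][1]
  df <- c(tab[["Df"]][1], tab[["Df"]][2])
  p <- tab[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$g
  posthoc <- tibble(
    pair = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  letters <- letter_display(names(groups), posthoc, alpha)
  new_ca_test("anova_tukey", "F", fstat, df, "two", p,
              posthoc = posthoc, n = lengths(groups), letters = letters)
}

# Insert-and-absorb compact letter display from pairwise adjusted p-values.
letter_display <- function(levels, posthoc, alpha) {
  distinct <- matrix(FALSE, length(levels), length(levels),
                     dimnames = list(levels, levels))
  pairs <- strsplit(posthoc$pair, "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    if (posthoc$p_adj[i] < alpha) {
      distinct[a, b] <- distinct[b, a] <- TRUE
    }
  }
  # each letter set is a maximal clique of mutually non-distinct groups,
  # built greedily in level order (adequate for one-way layouts)
  sets <- list()
  for (lv in levels) {
    placed <- FALSE
    for (j in seq_along(sets)) {
      if (all(!distinct[lv, sets[[j]]])) {
        sets[[j]] <- c(sets[[j]], lv)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- lv
  }
  out <- vapply(levels, function(lv) {
    paste(letters[which(vapply(sets, function(s) lv %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  out
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test; the two-tailed p sums all tables with null
#' probability at most that of the observed table (the minimum-likelihood
#' rule).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param tail `"two"` (default) or `"one"`.
#' @return A `ca_test` with `statistic_symbol = "OR"` (conditional
#'   maximum-likelihood odds ratio).
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2))$p   # ~0.486
#' @export
fisher_exact <- function(table, tail = c("two", "one")) {
  tail <- match.arg(tail)
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L))) {
    stop_calspike("`table` must be 2x2", "calspike_invalid_input")
  }
  if (any(table < 0) || any(table != round(table))) {
    stop_calspike("counts must be non-negative integers",
                  "calspike_invalid_input")
  }
  ft <- stats::fisher.test(table, alternative = if (tail == "two")
    "two.sided" else "greater")
  new_ca_test("fisher_exact", "OR", unname(ft$estimate), NULL, tail,
              ft$p.value, n = sum(table))
}

#' Normalising transforms
#'
#' `transform_values()` applies log10 or the Box-Cox power transform
#' \eqn{(x^\lambda - 1)/\lambda} (natural log at \eqn{\lambda = 0}).
#' `boxcox_lambda()` fits \eqn{\lambda} by profile maximum likelihood.
#' Both require strictly positive input.
#'
#' @param values Strictly positive numeric vector.
#' @param kind `"log10"` or `"boxcox"`.
#' @param lambda Box-Cox exponent; `NULL` fits it by maximum likelihood.
#' @return Transformed values, with attribute `lambda` for Box-Cox.
#' @examples
#' transform_values(c(1, 10, 100), "log10")
#' transform_values(1:5, "boxcox", lambda = 1)   # x - 1
#' @export
transform_values <- function(values, kind = c("log10", "boxcox"),
                             lambda = NULL) {
  kind <- match.arg(kind)
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    stop_calspike(
      sprintf("%s requires strictly positive values; offending index %d (value %s)",
              kind, bad[1], format(values[bad[1]])),
      "calspike_domain_error"
    )
  }
  if (kind == "log10") return(log10(values))
  if (is.null(lambda)) lambda <- boxcox_lambda(values)
  out <- if (lambda == 0) log(values) else (values^lambda - 1) / lambda
  structure(out, lambda = lambda)
}

#' @rdname transform_values
#' @param group Optional grouping factor: the likelihood is profiled on a
#'   one-way model so lambda is shared across groups.
#' @export
boxcox_lambda <- function(values, group = NULL) {
  if (any(values <= 0)) {
    stop_calspike("Box-Cox requires strictly positive values",
                  "calspike_domain_error")
  }
  d <- data.frame(
    v = values,
    g = if (is.null(group)) factor(rep(1L, length(values))) else factor(group)
  )
  fit <- if (nlevels(d$g) > 1) stats::lm(v ~ g, data = d, y = TRUE, qr = TRUE)
         else stats::lm(v ~ 1, data = d, y = TRUE, qr = TRUE)
  bc <- MASS::boxcox(fit, lambda = seq(-3, 3, 1 / 99), plotit = FALSE)
  bc$x[which.max(bc$y)]
}

#' Shapiro-Wilk normality p-value
#'
#' Thin wrapper over the Royston AS R94 implementation; valid for
#' 3 <= n <= 5000 and non-constant samples.
#'
#' @param values Numeric sample.
#' @return The p-value.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    stop_calspike(sprintf("Shapiro-Wilk needs 3 <= n <= 5000, got %d", n),
                  "calspike_unsupported_size")
  }
  if (stats::sd(values) == 0) {
    stop_calspike("constant sample: Shapiro-Wilk undefined",
                  "calspike_degenerate")
  }
  stats::shapiro.test(values)$p.value
}

# Accept a long (group, value) data frame or a named/unnamed list of vectors.
as_group_list <- function(data) {
  if (is.data.frame(data)) {
    if (!all(c("group", "value") %in% names(data))) {
      stop_calspike("data frame input needs columns `group` and `value`",
                    "calspike_invalid_input")
    }
    data <- data[is.finite(data$value), , drop = FALSE]
    lv <- unique(as.character(data$group))   # keep first-appearance order
    sp <- split(data$value, factor(as.character(data$group), levels = lv))
    return(sp)
  }
  if (is.list(data)) {
    if (is.null(names(data))) names(data) <- paste0("g", seq_along(data))
    return(purrr::map(data, as.numeric))
  }
  stop_calspike("`data` must be a data frame or a list of numeric vectors",
                "calspike_invalid_input")
}
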