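# Independent oracles used across the suite. These are deliberately naive
# (direct loops, full enumeration) and share no code with the package.

# Direct-loop evaluation of the baseline and SNR definitions.
naive_snr <- function(values, dt = 5, mode = "relative") {
  o1 <- as.integer(10 / dt)
  o2 <- as.integer(15 / dt)
  n <- length(values)
  out <- data.frame(sample = integer(), baseline = numeric(),
                    snr = numeric())
  for (t in seq_len(n)) {
    if (t - o2 < 1 || t + o2 > n) next
    b <- (values[t - o2] + values[t - o1] + values[t + o1] + values[t + o2]) / 4
    s <- if (mode == "relative") (values[t] - b) / b else values[t] - b
    out <- rbind(out, data.frame(sample = t, baseline = b, snr = s))
  }
  out
}

# Direct run extraction: maximal runs of snr >= theta, apex = earliest max.
naive_peaks <- function(snr_values, theta = 0.3) {
  runs <- list()
  inside <- FALSE
  for (i in seq_along(snr_values)) {
    if (snr_values[i] >= theta) {
      if (!inside) { runs[[length(runs) + 1]] <- c(i, i); inside <- TRUE }
      else runs[[length(runs)]][2] <- i
    } else inside <- FALSE
  }
  do.call(rbind, lapply(runs, function(r) {
    idx <- r[1]:r[2]
    apex <- idx[which(snr_values[idx] == max(snr_values[idx]))[1]]
    data.frame(run_start = r[1], run_end = r[2], apex_index = apex,
               apex_snr = snr_values[apex])
  }))
}

# Full-enumeration null distribution of the Mann-Whitney U statistic of the
# first group, for given group sizes (no ties assumed).
enumerate_u_distribution <- function(n1, n2) {
  n <- n1 + n2
  combos <- utils::combn(n, n1)
  u <- apply(combos, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  table(factor(u, levels = 0:(n1 * n2))) / ncol(combos)
}

# Two-tailed p by doubling the smaller enumerated tail (capped at 1);
# one-tailed p is the enumerated upper tail.
enumerate_mw_p <- function(w, n1, n2, tail = "two") {
  dist <- enumerate_u_distribution(n1, n2)
  u_vals <- as.numeric(names(dist))
  upper <- sum(dist[u_vals >= w])
  lower <- sum(dist[u_vals <= w])
  if (tail == "one") return(upper)
  min(2 * min(upper, lower), 1)
}

# Exact two-tailed Fisher p on a 2x2 table by hypergeometric enumeration
# (minimum-likelihood rule).
enumerate_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# One-ulp-of-the-printed-value comparison for reported p-values.
expect_printed <- function(computed, printed) {
  digits <- nchar(sub("^[^.]*\\.", "", format(printed, scientific = FALSE)))
  expect_lt(abs(computed - printed), 10^(-digits) + 1e-12)
}

random_trace <- function(n, dt = 5) {
  pmax(stats::runif(n, 50, 150) +
         stats::rnorm(n, 0, 10) * stats::rbinom(n, 1, 0.3), 0)
}
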