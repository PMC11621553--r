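worked_trace <- function() {
  f <- rep(100, 11)
  f[6] <- 140   # sample index 5 in 0-based terms
  f
}

test_that("the hand-worked 11-sample trace reproduces the SNR values", {
  s <- compute_snr(worked_trace(), dt = 5)
  expect_equal(s$sample, 4:8)
  expect_equal(s$snr, c(-1 / 11, 0, 0.4, 0, -1 / 11), tolerance = 1e-10)
  abs_s <- compute_snr(worked_trace(), mode = "absolute", dt = 5)
  expect_equal(abs_s$snr, c(-10, 0, 40, 0, -10))
})

test_that("constant and affine traces give exactly zero SNR in both modes", {
  for (mode in c("relative", "absolute")) {
    expect_true(all(compute_snr(rep(7, 15), mode = mode, dt = 5)$snr == 0))
    affine <- 3 + 2 * (0:19) * 5
    expect_true(all(compute_snr(affine, mode = mode, dt = 5)$snr == 0))
  }
})

test_that("SNR length and edge exclusion follow the baseline window", {
  n <- 25
  s <- compute_snr(runif(n, 50, 100), dt = 5)
  expect_equal(nrow(s), n - 6)
  expect_equal(range(s$sample), c(4, n - 3))
})

test_that("SNR input contract errors are classed and informative", {
  expect_error(compute_snr(rep(1, 6), dt = 5), class = "calspike_empty_series")
  expect_error(compute_snr(rep(1, 20), dt = 4),
               class = "calspike_unsupported_sampling")
  expect_error(compute_snr(rep(0, 11), dt = 5),
               class = "calspike_undefined_snr")
  expect_error(compute_snr(c(rep(1, 10), -1), dt = 5),
               class = "calspike_invalid_input")
  # dt = 2.5 is fine: offsets are 4 and 6 samples
  expect_silent(compute_snr(rep(1, 13), dt = 2.5))
})

test_that("peak calling splits supra-threshold runs and picks the apex", {
  s <- tibble::tibble(sample = 1:6, snr = c(0, 0.35, 0.5, 0.31, 0, 0.4))
  pk <- detect_peaks(s)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$apex_snr, c(0.5, 0.4))
  expect_equal(pk$run_start, c(2, 6))
  expect_equal(pk$run_end, c(4, 6))

  expect_equal(nrow(detect_peaks(tibble::tibble(sample = 1:5,
                                                snr = rep(0.29, 5)))), 0)

  # boundary: a single sample exactly at theta is a peak (>= rule)
  one <- detect_peaks(tibble::tibble(sample = 1:3, snr = c(0, 0.3, 0)))
  expect_equal(nrow(one), 1)
  expect_equal(one$apex_snr, 0.3)

  # apex ties resolve to the earliest sample
  tie <- detect_peaks(tibble::tibble(sample = 1:4, snr = c(0, 0.4, 0.4, 0)))
  expect_equal(tie$apex_index, 2)
})

test_that("nucleus summaries follow the frequency and spiking rules", {
  f <- worked_trace()
  pk <- detect_peaks(compute_snr(f, dt = 5))
  sm <- summarize_nucleus(f, pk, dt = 5)
  expect_equal(sm$duration_s, 50)
  expect_equal(sm$frequency, 12)
  expect_equal(sm$mean_peak_snr, 0.4)
  expect_true(sm$spiking)

  none <- summarize_nucleus(rep(1, 20), detect_peaks(
    compute_snr(rep(1, 20), dt = 5)), dt = 5)
  expect_equal(none$n_peaks, 0)
  expect_equal(none$frequency, 0)
  expect_true(is.na(none$mean_peak_snr))
  expect_false(none$spiking)
})

test_that("the spiking classification boundary is strict at 2 peaks / 10 min", {
  # n_peaks over a 600 s trace (121 samples): frequency equals the count
  fake_peaks <- function(k) tibble::tibble(apex_snr = rep(0.5, k))
  for (k in 0:4) {
    sm <- summarize_nucleus(rep(1, 121), fake_peaks(k), dt = 5)
    expect_identical(sm$spiking, k > 2)
  }
  # 2 peaks in exactly 600 s: frequency 2, not spiking
  sm2 <- summarize_nucleus(rep(1, 121), fake_peaks(2), dt = 5)
  expect_equal(sm2$frequency, 2)
  expect_false(sm2$spiking)
  # same count over a shorter acquisition crosses the boundary
  sm_short <- summarize_nucleus(rep(1, 61), fake_peaks(2), dt = 5)
  expect_equal(sm_short$frequency, 4)
  expect_true(sm_short$spiking)
})

test_that("shipped SNR and peak calling agree exactly with the naive oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(7:60, 1)
    v <- random_trace(n)
    s <- compute_snr(v, dt = 5)
    o <- naive_snr(v, dt = 5)
    expect_equal(s$sample, o$sample)
    expect_equal(s$baseline, o$baseline)
    expect_equal(s$snr, o$snr)
    pk <- detect_peaks(s)
    opk <- naive_peaks(o$snr)
    if (is.null(opk)) {
      expect_equal(nrow(pk), 0)
    } else {
      expect_equal(nrow(pk), nrow(opk))
      expect_equal(pk$apex_snr, opk$apex_snr)
      expect_equal(pk$apex_index, s$sample[opk$apex_index])
    }
  }
})

test_that("bleaching alone never calls peaks at the default threshold", {
  # exponential bleaching with tau >= 100 dt, no spikes, no noise
  for (tau in c(500, 1000, 5000)) {
    sim <- simulate_trace(bleach_tau = tau, spike_rate = 0, noise_sigma = 0,
                          seed = 1)
    s <- compute_snr(sim$trace)
    expect_lt(max(abs(s$snr)), 0.01)
    expect_equal(nrow(detect_peaks(s)), 0)
  }
})

test_that("well-separated simulated spikes map one-to-one onto detected peaks", {
  recovered <- 0L
  total <- 0L
  for (s in 1:100) {
    sim <- simulate_trace(spike_rate = 6, spike_amplitude = 0.6,
                          noise_sigma = 0.02, seed = 300 + s)
    ts <- sim$truth$spike_times
    pk <- detect_peaks(compute_snr(sim$trace))
    gaps_ok <- function(t) all(abs(setdiff(ts, t) - t) > 30) || length(ts) == 1
    for (t in ts) {
      if (!gaps_ok(t)) next
      total <- total + 1L
      hits <- sum(abs(pk$apex_time_s - t) <= 10)
      recovered <- recovered + as.integer(hits == 1)
    }
  }
  expect_gt(total, 100)
  expect_equal(recovered, total)
})

test_that("detected frequency is monotone in the simulated spike rate", {
  rates <- c(1, 2, 4, 6, 8, 10, 12)
  mean_freq <- vapply(rates, function(r) {
    mean(vapply(1:20, function(s) {
      sim <- simulate_trace(spike_rate = r, seed = 700 + s)
      summarize_nucleus(sim$trace,
                        detect_peaks(compute_snr(sim$trace)))$frequency
    }, numeric(1)))
  }, numeric(1))
  expect_gte(cor(rates, mean_freq, method = "spearman"), 0.95)
})

test_that("batch summaries keep non-spiking nuclei in the frequency table only", {
  spiky <- simulate_trace(spike_rate = 8, spike_amplitude = 0.8, seed = 1,
                          nucleus_id = "a")$trace
  spiky2 <- simulate_trace(spike_rate = 8, spike_amplitude = 0.8, seed = 2,
                           nucleus_id = "b")$trace
  flat <- simulate_trace(spike_rate = 0, seed = 3, nucleus_id = "c")$trace
  traces <- dplyr::bind_rows(spiky, spiky2, flat)
  summ <- batch_summaries(traces)
  expect_equal(nrow(summ), 3)
  expect_equal(nrow(frequency_table(summ)), 3)
  expect_equal(nrow(amplitude_table(summ)), 2)

  empty <- batch_summaries(tibble::tibble(nucleus_id = character(),
                                          time_s = numeric(),
                                          intensity = numeric()))
  expect_equal(nrow(empty), 0)
})

test_that("batches with mixed sampling intervals are rejected", {
  a <- simulate_trace(seed = 1, nucleus_id = "a")$trace
  b <- simulate_trace(seed = 2, dt = 2.5, duration = 300,
                      nucleus_id = "b")$trace
  expect_error(batch_summaries(dplyr::bind_rows(a, b)),
               class = "calspike_unsupported_batch")
})

test_that("spiking flags recover the simulated ground truth", {
  coh <- simulate_cohort("g", n_nuclei = 40, fraction_spiking = 0.5,
                         rate_mean = 8, amplitude_mean = 0.8, seed = 11)
  summ <- batch_summaries(coh)
  truth <- coh$truth[match(summ$nucleus_id, coh$truth$nucleus_id), ]
  agreement <- mean(summ$spiking == truth$spiker)
  expect_gte(agreement, 0.95)
})

test_that("trace CSV round-trips through write_traces / read_traces", {
  coh <- simulate_cohort("g", 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces(coh$traces, path)
  back <- read_traces(path)
  expect_equal(back$intensity, coh$traces$intensity)
  expect_equal(back$nucleus_id, coh$traces$nucleus_id)
  expect_no_error(read_traces(write_traces(tibble::tibble(
    nucleus_id = "x", time_s = 0, intensity = 1), path)))
})
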