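#' Signal-to-noise transform of a fluorescence trace
#'
#' For each time point \eqn{t}, the local baseline is the average of the four
#' fluorescence values taken 10 and 15 s before and after \eqn{t}:
#' \deqn{B_t = (F_{t-15\,s} + F_{t-10\,s} + F_{t+10\,s} + F_{t+15\,s})/4.}
#' The SNR is \eqn{(F_t - B_t)/B_t} in `"relative"` mode (the default; the
#' fixed unitless peak threshold only makes sense scale-free) or
#' \eqn{F_t - B_t} in `"absolute"` mode. The window is symmetric, so any
#' affine trend (including locally linear bleaching) cancels exactly.
#'
#' SNR is defined only where all four baseline samples exist: with `dt = 5`
#' the offsets are 2 and 3 samples, so the first and last three samples of
#' the trace carry no SNR value (no partial-window fallback is used).
#'
#' @param trace A data frame with columns `time_s` and `intensity` for a
#'   single nucleus (as produced by [simulate_trace()] or [read_traces()]),
#'   or a bare numeric vector of intensities (then `dt` must be given).
#' @param mode `"relative"` (default) or `"absolute"`.
#' @param dt Sampling interval in seconds; inferred from `time_s` when
#'   `trace` is a data frame. Must divide 10 s and 15 s exactly.
#' @return A tibble of class `ca_snr` with columns `sample` (1-based index
#'   into the trace), `time_s`, `intensity`, `baseline`, `snr`, and
#'   attributes `mode` and `dt`. Length is `N - 6` for `dt = 5`.
#' @examples
#' f <- rep(100, 11); f[6] <- 140
#' compute_snr(f, dt = 5)$snr    # -0.0909, 0, 0.4, 0, -0.0909
#' @export
compute_snr <- function(trace, mode = c("relative", "absolute"), dt = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(trace)) {
    if (!all(c("time_s", "intensity") %in% names(trace))) {
      stop_calspike("`trace` needs columns time_s and intensity",
                    "calspike_invalid_input")
    }
    if ("nucleus_id" %in% names(trace) &&
        length(unique(trace$nucleus_id)) > 1L) {
      stop_calspike("`trace` holds several nuclei; use batch_summaries()",
                    "calspike_invalid_input")
    }
    trace <- trace[order(trace$time_s), ]
    values <- trace$intensity
    dt <- dt %||% infer_dt(trace$time_s)
    time_s <- trace$time_s
  } else {
    values <- as.numeric(trace)
    if (is.null(dt)) {
      stop_calspike("`dt` is required for a bare numeric trace",
                    "calspike_invalid_input")
    }
    time_s <- (seq_along(values) - 1) * dt
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_calspike("intensities must be finite and non-negative",
                  "calspike_invalid_input")
  }
  o1 <- 10 / dt
  o2 <- 15 / dt
  if (o1 != round(o1) || o2 != round(o2)) {
    stop_calspike(
      sprintf("dt = %s does not divide the 10 s / 15 s baseline offsets", dt),
      "calspike_unsupported_sampling"
    )
  }
  o1 <- as.integer(round(o1)); o2 <- as.integer(round(o2))
  n <- length(values)
  if (n < 2L * o2 + 1L) {
    stop_calspike(
      sprintf("trace too short for SNR: need at least %d samples, got %d",
              2L * o2 + 1L, n),
      "calspike_empty_series"
    )
  }
  idx <- (o2 + 1L):(n - o2)
  baseline <- (values[idx - o2] + values[idx - o1] +
                 values[idx + o1] + values[idx + o2]) / 4
  if (mode == "relative" && any(baseline == 0)) {
    bad <- idx[baseline == 0][1]
    stop_calspike(
      sprintf("relative SNR undefined at sample %d: baseline is 0", bad),
      "calspike_undefined_snr"
    )
  }
  snr <- if (mode == "relative") (values[idx] - baseline) / baseline
         else values[idx] - baseline
  out <- tibble(sample = idx, time_s = time_s[idx],
                intensity = values[idx], baseline = baseline, snr = snr)
  structure(out, class = c("ca_snr", class(out)), mode = mode, dt = dt)
}

#' Call spike peaks on an SNR series
#'
#' A peak is a maximal run of consecutive samples with `snr >= theta`
#' (default 0.3); its apex is the run's maximum, with ties resolved to the
#' earliest sample. Distinct peaks are separated by at least one
#' sub-threshold sample. No prominence or refractory constraint is applied
#' beyond run separation.
#'
#' @param snr An SNR series from [compute_snr()] (or any data frame with
#'   columns `sample` and `snr`).
#' @param theta Peak threshold on the SNR (default 0.3).
#' @return A tibble with one row per peak: `peak`, `run_start`, `run_end`,
#'   `apex_index` (all 1-based trace sample indices), `apex_time_s` (when
#'   available) and `apex_snr`. Zero rows when nothing crosses `theta`.
#' @examples
#' s <- tibble::tibble(sample = 1:6, snr = c(0, 0.35, 0.5, 0.31, 0, 0.4))
#' detect_peaks(s)$apex_snr    # 0.5, 0.4
#' @export
detect_peaks <- function(snr, theta = 0.3) {
  if (!all(c("sample", "snr") %in% names(snr))) {
    stop_calspike("`snr` needs columns sample and snr", "calspike_invalid_input")
  }
  if (nrow(snr) == 0L) {
    stop_calspike("empty SNR series", "calspike_empty_series")
  }
  check_number(theta, "theta")
  above <- snr$snr >= theta
  if (!any(above)) return(empty_peaks())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  peaks <- purrr::map_dfr(keep, function(k) {
    i <- starts[k]:ends[k]
    apex <- i[which.max(snr$snr[i])]   # which.max takes the earliest tie
    tibble(
      run_start = snr$sample[starts[k]],
      run_end = snr$sample[ends[k]],
      apex_index = snr$sample[apex],
      apex_time_s = if ("time_s" %in% names(snr)) snr$time_s[apex] else NA_real_,
      apex_snr = snr$snr[apex]
    )
  })
  dplyr::mutate(peaks[order(peaks$apex_index), ], peak = dplyr::row_number(),
                .before = 1)
}

empty_peaks <- function() {
  tibble(peak = integer(), run_start = integer(), run_end = integer(),
         apex_index = integer(), apex_time_s = numeric(), apex_snr = numeric())
}

#' Per-nucleus spiking summary
#'
#' Reduces a trace and its called peaks to the standard per-nucleus readout:
#' peak count, spiking frequency rescaled to a 10-minute window
#' (`n_peaks * 600 / duration_s` with `duration_s = (N - 1) * dt`), the
#' amplitude as the mean of peak SNR values (absent when no peak was
#' called), and the spiking classification — a nucleus is spiking when it
#' shows more than 2 peaks per 10 min (strict inequality).
#'
#' @param trace The trace the peaks were called on (data frame or numeric
#'   vector, as in [compute_snr()]).
#' @param peaks Peak table from [detect_peaks()].
#' @param dt Sampling interval; inferred from the data frame when possible.
#' @return A one-row tibble: `nucleus_id`, `n_peaks`, `duration_s`,
#'   `frequency` (peaks per 600 s), `mean_peak_snr` (`NA` when `n_peaks` is
#'   0), `spiking`.
#' @export
summarize_nucleus <- function(trace, peaks, dt = NULL) {
  if (is.data.frame(trace)) {
    n <- nrow(trace)
    dt <- dt %||% infer_dt(trace$time_s)
    id <- if ("nucleus_id" %in% names(trace) && n > 0)
      as.character(trace$nucleus_id[1]) else NA_character_
    grp <- if ("group" %in% names(trace) && n > 0)
      as.character(trace$group[1]) else NA_character_
  } else {
    n <- length(trace)
    if (is.null(dt)) {
      stop_calspike("`dt` is required for a bare numeric trace",
                    "calspike_invalid_input")
    }
    id <- NA_character_
    grp <- NA_character_
  }
  duration_s <- (n - 1) * dt
  n_peaks <- nrow(peaks)
  frequency <- n_peaks * 600 / duration_s
  tibble(
    nucleus_id = id,
    group = grp,
    n_peaks = n_peaks,
    duration_s = duration_s,
    frequency = frequency,
    mean_peak_snr = if (n_peaks > 0) mean(peaks$apex_snr) else NA_real_,
    spiking = frequency > 2
  )
}

#' Summarise every nucleus in a long trace table
#'
#' Runs [compute_snr()], [detect_peaks()] and [summarize_nucleus()] per
#' nucleus and stacks the results, ordered by (`group`, `nucleus_id`).
#' Non-spiking nuclei are retained: they contribute to the frequency table
#' (so the frequency sample size exceeds the amplitude one) but drop out of
#' the amplitude table, which holds spiking nuclei only.
#'
#' @param traces Long data frame with columns `nucleus_id`, `time_s`,
#'   `intensity` and optionally `group`, or a `ca_cohort` from
#'   [simulate_cohort()].
#' @param mode,theta Passed to [compute_snr()] / [detect_peaks()].
#' @param dt Sampling interval; must be shared by all nuclei in the batch.
#' @return A tibble with one row per nucleus (columns as in
#'   [summarize_nucleus()]). Use [frequency_table()] and [amplitude_table()]
#'   for the two analysis views.
#' @examples
#' coh <- simulate_cohort("g", n_nuclei = 3, seed = 7)
#' batch_summaries(coh)
#' @export
batch_summaries <- function(traces, mode = c("relative", "absolute"),
                            theta = 0.3, dt = NULL) {
  mode <- match.arg(mode)
  if (inherits(traces, "ca_cohort")) traces <- traces$traces
  if (nrow(traces) == 0L) {
    return(summarize_nucleus(data.frame(nucleus_id = character(),
                                        time_s = numeric(),
                                        intensity = numeric()),
                             empty_peaks(), dt = dt %||% 5)[0, ])
  }
  if (!"group" %in% names(traces)) traces$group <- NA_character_
  split_tr <- split(traces, traces$nucleus_id)
  dts <- vapply(split_tr, function(tr) infer_dt(tr$time_s), numeric(1))
  if (length(unique(round(dts, 9))) > 1L) {
    stop_calspike("traces in one batch must share the sampling interval dt",
                  "calspike_unsupported_batch")
  }
  if (!is.null(dt) && !isTRUE(all.equal(dt, dts[[1]]))) {
    stop_calspike("supplied dt disagrees with the trace time stamps",
                  "calspike_unsupported_batch")
  }
  out <- purrr::map_dfr(split_tr, function(tr) {
    s <- compute_snr(tr, mode = mode)
    summarize_nucleus(tr, detect_peaks(s, theta = theta))
  })
  dplyr::arrange(out, .data$group, .data$nucleus_id)
}

#' Frequency and amplitude analysis tables
#'
#' `frequency_table()` keeps every nucleus (non-spiking nuclei enter with
#' frequency 0); `amplitude_table()` keeps only nuclei with at least one
#' called peak, so its `n` is smaller.
#'
#' @param summaries Output of [batch_summaries()].
#' @return A tibble with columns `group`, `nucleus_id`, `value` ready for
#'   the statistics layer.
#' @export
frequency_table <- function(summaries) {
  dplyr::transmute(summaries, group = .data$group,
                   nucleus_id = .data$nucleus_id, value = .data$frequency)
}

#' @rdname frequency_table
#' @export
amplitude_table <- function(summaries) {
  dplyr::transmute(
    dplyr::filter(summaries, .data$n_peaks > 0),
    group = .data$group, nucleus_id = .data$nucleus_id,
    value = .data$mean_peak_snr
  )
}
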