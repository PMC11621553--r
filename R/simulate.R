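#' Simulate a nuclear calcium-indicator fluorescence trace
#'
#' Generates one nucleus-like fluorescence time series following the signal
#' model
#' \deqn{F(t) = F_0 \, e^{-t/\tau_b}\,\bigl(1 + \sum_k A_k\, g(t - t_k)\bigr) + \varepsilon_t,}
#' where \eqn{g} rises linearly over `rise_samples` sampling intervals to its
#' apex and then decays as \eqn{e^{-u/\tau_d}}, and
#' \eqn{\varepsilon_t \sim N(0, (\sigma F_0)^2)} is additive detector-like
#' noise. Negative intensities are clipped at zero. Spike apex times are
#' drawn as a hard-core point process: the number of events is Poisson with
#' mean `spike_rate * duration / 600` and apexes are placed uniformly on the
#' sampling grid, at least `refractory` seconds apart, inside the interior
#' window where the downstream SNR baseline is defined (three samples in
#' from each end).
#'
#' @param baseline_f0 Resting fluorescence \eqn{F_0} (arbitrary units, > 0).
#' @param bleach_tau Photobleaching time constant in seconds; `Inf` disables
#'   bleaching.
#' @param spike_amplitude Relative spike amplitude \eqn{A}: peak fractional
#'   increase over the local (bleached) baseline. All spikes in a trace
#'   share this amplitude.
#' @param decay_tau Spike decay time constant in seconds.
#' @param rise_samples Number of sampling intervals over which a spike rises
#'   linearly to its apex (>= 0; 0 = instantaneous).
#' @param spike_rate Expected number of spikes per 600 s.
#' @param refractory Minimum gap between consecutive spike apexes, seconds.
#' @param noise_sigma Gaussian noise SD as a fraction of `baseline_f0`.
#' @param duration Acquisition length in seconds (>= 7 * `dt`).
#' @param dt Sampling interval in seconds (default 5, matching typical
#'   confocal time-series acquisition).
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output. `NULL` uses (and advances) the current RNG stream.
#' @param nucleus_id Identifier attached to the trace.
#'
#' @return A list of class `ca_sim` with elements
#'   * `trace`: tibble with columns `nucleus_id`, `time_s`, `intensity`;
#'   * `truth`: list with `spike_times` (apex seconds, strictly increasing),
#'     `per_spike_amplitude`, and `clean` (tibble `time_s`, `intensity` of
#'     the noise-free signal).
#' @examples
#' sim <- simulate_trace(spike_rate = 8, seed = 1)
#' nrow(sim$trace)             # floor(duration/dt) + 1 samples
#' sim$truth$spike_times
#' @export
simulate_trace <- function(baseline_f0 = 100, bleach_tau = Inf,
                           spike_amplitude = 0.6, decay_tau = 15,
                           rise_samples = 1, spike_rate = 0,
                           refractory = 20, noise_sigma = 0.02,
                           duration = 600, dt = 5, seed = NULL,
                           nucleus_id = "nucleus_1") {
  check_number(baseline_f0, "baseline_f0", lower = 1e-12)
  check_number(bleach_tau, "bleach_tau", lower = 1e-12, allow_inf = TRUE)
  check_number(spike_amplitude, "spike_amplitude", lower = 0)
  check_number(decay_tau, "decay_tau", lower = 1e-12)
  check_number(rise_samples, "rise_samples", lower = 0, integerish = TRUE)
  check_number(spike_rate, "spike_rate", lower = 0)
  check_number(refractory, "refractory", lower = 0)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(dt, "dt", lower = 1e-12)
  check_number(duration, "duration", lower = 7 * dt)

  n <- floor(duration / dt) + 1L
  time_s <- (seq_len(n) - 1L) * dt

  with_seed(seed, {
    spike_times <- draw_spike_times(spike_rate, duration, dt, refractory)
    clean <- clean_signal(time_s, baseline_f0, bleach_tau, spike_amplitude,
                          decay_tau, rise_samples, dt, spike_times)
    noisy <- clean + stats::rnorm(n, 0, noise_sigma * baseline_f0)
    noisy <- pmax(noisy, 0)
    list(
      trace = tibble(nucleus_id = nucleus_id, time_s = time_s,
                     intensity = noisy),
      truth = list(
        spike_times = spike_times,
        per_spike_amplitude = rep(spike_amplitude, length(spike_times)),
        clean = tibble(time_s = time_s, intensity = clean)
      )
    )
  }) -> out
  structure(out, class = "ca_sim")
}

# Hard-core (refractory-thinned) spike apex times on the sampling grid,
# restricted to the interior where the SNR baseline window exists.
draw_spike_times <- function(spike_rate, duration, dt, refractory) {
  if (spike_rate == 0) return(numeric(0))
  grid <- seq(3 * dt, duration - 3 * dt, by = dt)
  if (length(grid) == 0) return(numeric(0))
  n_target <- stats::rpois(1, spike_rate * duration / 600)
  times <- numeric(0)
  tries <- 0L
  while (length(times) < n_target && tries < 200L * max(n_target, 1L)) {
    cand <- grid[sample.int(length(grid), 1L)]
    # the grid makes sub-dt gaps impossible; also forbids duplicate apexes
    if (!length(times) || all(abs(cand - times) >= max(refractory, dt))) {
      times <- c(times, cand)
    }
    tries <- tries + 1L
  }
  sort(times)
}

clean_signal <- function(time_s, f0, bleach_tau, amplitude, decay_tau,
                         rise_samples, dt, spike_times) {
  spikes <- rep(0, length(time_s))
  rise_s <- rise_samples * dt
  for (tk in spike_times) {
    u <- time_s - tk
    g <- ifelse(u >= 0, exp(-u / decay_tau),
                ifelse(rise_s > 0 & u >= -rise_s, 1 + u / rise_s, 0))
    spikes <- spikes + amplitude * g
  }
  f0 * exp(-time_s / bleach_tau) * (1 + spikes)
}

#' Simulate a cohort of nuclei with a known spiking fraction
#'
#' Draws `n_nuclei` traces for one experimental group. A fixed fraction of
#' nuclei spike, with per-nucleus spike rate and amplitude drawn from
#' truncated normal distributions; the remaining nuclei are simulated with
#' `spike_rate = 0`. All other parameters are shared and passed on to
#' [simulate_trace()].
#'
#' @param group_label Group name attached to every trace.
#' @param n_nuclei Number of nuclei (>= 1).
#' @param fraction_spiking Fraction of nuclei that spike, in \[0, 1\].
#'   The number of spikers is `round(fraction_spiking * n_nuclei)`.
#' @param rate_mean,rate_sd Mean and SD of the per-nucleus spike rate
#'   (spikes per 600 s) among spiking nuclei; draws are truncated at 0.
#' @param amplitude_mean,amplitude_sd Mean and SD of the per-nucleus
#'   relative spike amplitude; draws are truncated at 0.
#' @param seed Integer master seed; per-nucleus seeds are derived from it.
#' @param ... Further parameters forwarded to [simulate_trace()]
#'   (e.g. `noise_sigma`, `duration`, `dt`, `bleach_tau`).
#'
#' @return A list of class `ca_cohort`:
#'   * `traces`: long tibble (`nucleus_id`, `group`, `time_s`, `intensity`);
#'   * `truth`: tibble with one row per nucleus (`nucleus_id`, `group`,
#'     `spiker` ground-truth flag, `spike_rate`, `spike_amplitude`,
#'     `n_spikes`, `spike_times` list-column).
#' @examples
#' coh <- simulate_cohort("RHE", n_nuclei = 5, fraction_spiking = 0.6, seed = 2)
#' coh$truth
#' @export
simulate_cohort <- function(group_label, n_nuclei, fraction_spiking = 1,
                            rate_mean = 8, rate_sd = 1,
                            amplitude_mean = 0.6, amplitude_sd = 0.05,
                            seed = NULL, ...) {
  check_number(n_nuclei, "n_nuclei", lower = 1, integerish = TRUE)
  check_number(fraction_spiking, "fraction_spiking", lower = 0, upper = 1)
  check_number(rate_sd, "rate_sd", lower = 0)
  check_number(amplitude_sd, "amplitude_sd", lower = 0)
  check_number(rate_mean, "rate_mean", lower = 0)
  check_number(amplitude_mean, "amplitude_mean", lower = 0)

  n_spiking <- round(fraction_spiking * n_nuclei)
  with_seed(seed, {
    rates <- pmax(stats::rnorm(n_nuclei, rate_mean, rate_sd), 0)
    amps <- pmax(stats::rnorm(n_nuclei, amplitude_mean, amplitude_sd), 0)
    rates[seq_len(n_nuclei) > n_spiking] <- 0
    seeds <- sample.int(.Machine$integer.max, n_nuclei)
    list(rates = rates, amps = amps, seeds = seeds)
  }) -> draw

  ids <- sprintf("%s_%03d", group_label, seq_len(n_nuclei))
  sims <- purrr::pmap(
    list(draw$rates, draw$amps, draw$seeds, ids),
    function(rate, amp, sd_i, id) {
      simulate_trace(spike_rate = rate, spike_amplitude = amp,
                     seed = sd_i, nucleus_id = id, ...)
    }
  )

  traces <- purrr::map_dfr(sims, function(s) {
    dplyr::mutate(s$trace, group = group_label, .after = "nucleus_id")
  })
  truth <- tibble(
    nucleus_id = ids,
    group = group_label,
    spiker = draw$rates > 0,
    spike_rate = draw$rates,
    spike_amplitude = draw$amps,
    n_spikes = purrr::map_int(sims, ~ length(.x$truth$spike_times)),
    spike_times = purrr::map(sims, ~ .x$truth$spike_times)
  )
  structure(list(traces = traces, truth = truth), class = "ca_cohort")
}

#' Write / read trace tables as delimited text
#'
#' Traces travel as plain CSV with columns `nucleus_id`, `time_s`,
#' `intensity` and optionally `group`; ground truth can be written as a JSON
#' sidecar.
#'
#' @param traces Data frame with at least `nucleus_id`, `time_s`, `intensity`.
#' @param path Output CSV path.
#' @return `write_traces()` returns `path` invisibly; `read_traces()` returns
#'   a tibble.
#' @export
write_traces <- function(traces, path) {
  stopifnot(all(c("nucleus_id", "time_s", "intensity") %in% names(traces)))
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("nucleus_id", "time_s", "intensity"), names(df))
  if (length(missing)) {
    stop_calspike(paste("trace table lacks columns:",
                        paste(missing, collapse = ", ")),
                  "calspike_invalid_input")
  }
  as_tibble(df)
}
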