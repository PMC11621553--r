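#' Build / validate a pipeline configuration
#'
#' A configuration drives one end-to-end run: simulate (or ingest) traces,
#' call spikes, summarise per nucleus, and compare groups statistically.
#' It can be given as a nested list or a YAML file. Unknown keys are
#' rejected so typos fail fast.
#'
#' Recognised structure (defaults in parentheses):
#' ```yaml
#' seed: 1                      # global seed, required for simulation
#' input:
#'   traces: path/to/traces.csv # mutually exclusive with `simulation`
#' simulation:
#'   dt: 5
#'   duration: 600
#'   noise_sigma: 0.02
#'   cohorts:
#'     - group: RHE
#'       n_nuclei: 25
#'       fraction_spiking: 1.0
#'       rate_mean: 9        # spikes per 600 s
#'       rate_sd: 1.0
#'       amplitude_mean: 0.8
#'       amplitude_sd: 0.05
#' spikes:
#'   mode: relative             # or absolute
#'   theta: 0.3
#' stats:
#'   tail: two
#'   alpha_gate: 0.05
#' ```
#'
#' @param config A nested list, or a path to a YAML file.
#' @return The validated config list (class `ca_config`), with defaults
#'   filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop_calspike("config must be a list or a YAML file path",
                  "calspike_invalid_config")
  }
  known_top <- c("seed", "input", "simulation", "spikes", "stats")
  reject_unknown(config, known_top, "top level")
  if (is.null(config$simulation) && is.null(config$input)) {
    stop_calspike("config needs either `simulation` or `input`",
                  "calspike_invalid_config")
  }
  if (!is.null(config$simulation) && !is.null(config$input)) {
    stop_calspike("`simulation` and `input` are mutually exclusive",
                  "calspike_invalid_config")
  }
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    reject_unknown(sim, c("dt", "duration", "noise_sigma", "bleach_tau",
                          "decay_tau", "rise_samples", "refractory",
                          "baseline_f0", "cohorts"), "simulation")
    if (is.null(sim$cohorts) || !length(sim$cohorts)) {
      stop_calspike("simulation config lists no cohorts",
                    "calspike_invalid_config")
    }
    for (co in sim$cohorts) {
      reject_unknown(co, c("group", "n_nuclei", "fraction_spiking",
                           "rate_mean", "rate_sd", "amplitude_mean",
                           "amplitude_sd"), "cohort")
      if (is.null(co$group) || is.null(co$n_nuclei)) {
        stop_calspike("each cohort needs `group` and `n_nuclei`",
                      "calspike_invalid_config")
      }
    }
    if (is.null(config$seed)) {
      stop_calspike("simulation requires a global `seed`",
                    "calspike_invalid_config")
    }
  }
  if (!is.null(config$input)) {
    reject_unknown(config$input, "traces", "input")
  }
  config$spikes <- utils::modifyList(list(mode = "relative", theta = 0.3),
                                     config$spikes %||% list())
  reject_unknown(config$spikes, c("mode", "theta"), "spikes")
  config$stats <- utils::modifyList(list(tail = "two", alpha_gate = 0.05),
                                    config$stats %||% list())
  reject_unknown(config$stats, c("tail", "alpha_gate"), "stats")
  structure(config, class = c("ca_config", "list"))
}

reject_unknown <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop_calspike(sprintf("unknown %s config key(s): %s", where,
                          paste(extra, collapse = ", ")),
                  "calspike_invalid_config")
  }
}

#' Run the full spiking-analysis pipeline
#'
#' Simulates (or ingests) traces, computes SNR and peaks, summarises every
#' nucleus, and runs the statistical decision tree on the per-nucleus
#' amplitude (spiking-capable nuclei only) and frequency (all nuclei)
#' tables. Fully deterministic under the config's seed.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @param output_dir Optional directory; when given, the resolved config
#'   snapshot (`config.yaml`), the per-nucleus summary table
#'   (`summaries.csv`) and the report (`report.json`, `report.md`) are
#'   written there.
#' @return A `ca_report`: list with `summaries` (per-nucleus tibble),
#'   `group_stats` (per-group counts and box-plot summaries for frequency
#'   and amplitude), `tests` (named list of `ca_test`: `amplitude`,
#'   `frequency` where computable), and `provenance`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  config <- pipeline_config(config)

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    shared <- sim[setdiff(names(sim), "cohorts")]
    seeds <- derive_seeds(config$seed, length(sim$cohorts))
    traces <- purrr::imap_dfr(sim$cohorts, function(co, i) {
      args <- c(list(group_label = co$group, n_nuclei = co$n_nuclei,
                     seed = seeds[i]),
                co[setdiff(names(co), c("group", "n_nuclei"))],
                shared)
      do.call(simulate_cohort, args)$traces
    })
  } else {
    traces <- read_traces(config$input$traces)
    if (!"group" %in% names(traces)) {
      stop_calspike("ingested traces need a `group` column for statistics",
                    "calspike_invalid_input")
    }
  }

  summaries <- batch_summaries(traces, mode = config$spikes$mode,
                               theta = config$spikes$theta)
  freq <- frequency_table(summaries)
  amp <- amplitude_table(summaries)

  tests <- list()
  run_if_possible <- function(tab) {
    sizes <- table(tab$group)
    if (length(sizes) >= 2 && all(sizes >= 2)) {
      choose_and_run(tab, tail = config$stats$tail,
                     alpha_gate = config$stats$alpha_gate)
    } else NULL
  }
  tests$frequency <- run_if_possible(freq)
  tests$amplitude <- run_if_possible(amp)

  group_stats <- dplyr::summarise(
    dplyr::group_by(summaries, .data$group),
    n_total = dplyr::n(),
    n_spiking = sum(.data$spiking),
    spiking_label = sprintf("%d/%d", sum(.data$spiking), dplyr::n()),
    frequency = list(five_number(.data$frequency)),
    amplitude = list(five_number(.data$mean_peak_snr[.data$n_peaks > 0])),
    .groups = "drop"
  )

  report <- structure(
    list(summaries = summaries, group_stats = group_stats, tests = tests,
         provenance = list(
           package = "calspike",
           version = as.character(utils::packageVersion("calspike")),
           seed = config$seed,
           config = unclass(config)
         )),
    class = "ca_report"
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(config), file.path(output_dir, "config.yaml"))
    utils::write.csv(summaries, file.path(output_dir, "summaries.csv"),
                     row.names = FALSE)
    writeLines(render_report(report, "json"),
               file.path(output_dir, "report.json"))
    writeLines(render_report(report, "markdown"),
               file.path(output_dir, "report.md"))
  }
  report
}

# Tukey box-plot summary: quartiles, median, mean, whiskers at 1.5 IQR,
# points beyond flagged as outliers.
five_number <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) {
    return(list(n = 0L, q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                mean = NA_real_, whisker_low = NA_real_,
                whisker_high = NA_real_, outliers = numeric(0)))
  }
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75)))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- x[x >= lo & x <= hi]
  list(n = length(x), q1 = q[1], median = q[2], q3 = q[3], mean = mean(x),
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(x[x < lo | x > hi]))
}

#' Render a pipeline report
#'
#' @param report A `ca_report` from [run_pipeline()].
#' @param format `"json"` or `"markdown"`.
#' @return A single string (the document).
#' @export
render_report <- function(report, format = c("json", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "ca_report"))
  tests_out <- purrr::map(
    purrr::compact(report$tests),
    function(t) {
      out <- glance(t)
      out <- as.list(out)
      out$audit <- if (!is.null(t$audit)) t$audit else NULL
      out$posthoc <- t$posthoc
      out
    }
  )
  if (format == "json") {
    return(jsonlite::toJSON(
      list(groups = report$group_stats, tests = tests_out,
           provenance = report$provenance),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
    ))
  }
  gs <- report$group_stats
  lines <- c("# Nuclear Ca2+ spiking report", "",
             "## Groups (spiking / total)", "")
  for (i in seq_len(nrow(gs))) {
    f <- gs$frequency[[i]]; a <- gs$amplitude[[i]]
    lines <- c(lines, sprintf(
      "- **%s**: %s spiking; frequency median %.3g (IQR %.3g-%.3g, n = %d); amplitude median %.3g (IQR %.3g-%.3g, n = %d)",
      gs$group[i], gs$spiking_label[i],
      f$median, f$q1, f$q3, f$n,
      a$median, a$q1, a$q3, a$n))
  }
  lines <- c(lines, "", "## Statistics", "")
  if (!length(purrr::compact(report$tests))) {
    lines <- c(lines, "_No statistical comparison was computable._")
  }
  for (nm in names(purrr::compact(report$tests))) {
    t <- report$tests[[nm]]
    dfs <- if (is.null(t$df)) "" else
      sprintf(", df = %s", paste(format(t$df, digits = 6), collapse = "/"))
    lines <- c(lines, sprintf(
      "- **%s**: %s (%s-tailed, transform %s): %s = %.5g%s, p = %.4g",
      nm, t$test, t$tail, t$transform, t$statistic_symbol, t$statistic,
      dfs, t$p))
  }
  lines <- c(lines, "", sprintf("_seed %s, calspike %s_",
                                report$provenance$seed,
                                report$provenance$version))
  paste(lines, collapse = "\n")
}

#' @export
print.ca_report <- function(x, ...) {
  cat(render_report(x, "markdown"), "\n")
  invisible(x)
}
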