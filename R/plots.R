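#' Plot an SNR series with its called peaks
#'
#' Two aligned panels: the raw fluorescence trace, and the SNR with the
#' peak threshold and apex markers.
#'
#' @param object A `ca_snr` from [compute_snr()].
#' @param theta Peak threshold drawn on the SNR panel and used to mark
#'   apexes (default 0.3).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ca_snr <- function(object, theta = 0.3, ...) {
  peaks <- detect_peaks(object, theta = theta)
  long <- tidyr::pivot_longer(
    tibble(time_s = object$time_s, fluorescence = object$intensity,
           SNR = object$snr),
    -"time_s", names_to = "panel", values_to = "value"
  )
  long$panel <- factor(long$panel, levels = c("fluorescence", "SNR"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::geom_hline(
      data = data.frame(panel = factor("SNR", levels = levels(long$panel)),
                        yint = theta),
      ggplot2::aes(yintercept = .data$yint), linetype = "dashed"
    ) +
    ggplot2::labs(x = "time (s)", y = NULL)
  if (nrow(peaks)) {
    p <- p + ggplot2::geom_point(
      data = data.frame(time_s = peaks$apex_time_s, value = peaks$apex_snr,
                        panel = factor("SNR", levels = levels(long$panel))),
      colour = "red"
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Box plots of per-nucleus frequency and amplitude by group
#'
#' Mirrors the standard presentation of spiking quantifications: Tukey box
#' plots with individual nuclei overlaid; the frequency panel includes
#' every nucleus, the amplitude panel only nuclei with called peaks.
#'
#' @param summaries Output of [batch_summaries()].
#' @return A ggplot object.
#' @export
plot_spiking_summary <- function(summaries) {
  long <- dplyr::bind_rows(
    dplyr::mutate(frequency_table(summaries), metric = "frequency (peaks / 10 min)"),
    dplyr::mutate(amplitude_table(summaries), metric = "amplitude (mean peak SNR)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = 4) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}
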