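# ggplot2 views of simulation results. Figures are a convenience; all
# quantitative use goes through the tibble interfaces.

#' Plot relative female densities of a simulated release
#'
#' Total and competent adult female density relative to the pre-release
#' baseline, on a log scale, with dashed markers at the release onset and
#' end.
#'
#' @param object An [simulate_release()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rr_sim <- function(object, ...) {
  ms <- metric_series(object)
  df <- tidyr::pivot_longer(
    ms[, c("time", "rel_total_female", "rel_competent")],
    -"time", names_to = "series", values_to = "density"
  )
  df$series <- factor(df$series,
                      levels = c("rel_total_female", "rel_competent"),
                      labels = c("total females", "competent vectors"))
  win <- release_window(object)
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$density,
                                         linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "day", y = "relative female density", linetype = NULL)
  if (win["end"] > win["start"]) {
    pl <- pl + ggplot2::geom_vline(xintercept = unname(win),
                                   linetype = "dashed", colour = "grey50")
  }
  pl
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot juvenile allele-frequency trajectories
#'
#' Frequencies of the female-killing (K) and anti-pathogen (A) alleles in the
#' juvenile population, with release-window markers.
#'
#' @param sim An [simulate_release()] result.
#' @return A ggplot object.
#' @export
plot_allele_frequencies <- function(sim) {
  ms <- metric_series(sim)
  df <- tidyr::pivot_longer(ms[, c("time", "freq_K_juv", "freq_A_juv")],
                            -"time", names_to = "allele", values_to = "frequency")
  df$allele <- factor(df$allele, levels = c("freq_K_juv", "freq_A_juv"),
                      labels = c("FK (K)", "AP (A)"))
  win <- release_window(sim)
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$frequency,
                                         colour = .data$allele)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day", y = "juvenile allele frequency", colour = NULL)
  if (win["end"] > win["start"]) {
    pl <- pl + ggplot2::geom_vline(xintercept = unname(win),
                                   linetype = "dashed", colour = "grey50")
  }
  pl
}

#' Plot a ratio-duration sweep
#'
#' @param sweep A tibble from [run_sweep()].
#' @param metric Column to plot (default `competent_at_recovery`).
#' @return A ggplot object with log-scaled axes, one line per sex mode.
#' @export
plot_sweep <- function(sweep, metric = "competent_at_recovery") {
  stopifnot(metric %in% names(sweep))
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$duration,
                                      y = .data[[metric]],
                                      colour = .data$sexes)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "release duration (days; ratio decreases rightward)",
                  y = metric, colour = NULL)
}
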