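#' Plot colony trajectories
#'
#' Cohort counts over time; replicates are drawn as thin lines with the
#' replicate mean on top.
#'
#' @param object A `"beetox_run"` or `"beetox_sim"`.
#' @param cohorts Columns to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.beetox_sim <- function(object,
                                cohorts = c("strength", "adults"), ...) {
  d <- tidy(object)
  if (!"replicate" %in% names(d)) d$replicate <- 1L
  long <- tidyr::pivot_longer(d, dplyr::all_of(cohorts),
                              names_to = "cohort", values_to = "count")
  mean_d <- long |>
    dplyr::group_by(.data$day, .data$cohort) |>
    dplyr::summarise(count = mean(.data$count), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$count,
                                     colour = .data$cohort)) +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$replicate,
                                                        .data$cohort)),
                       alpha = 0.25) +
    ggplot2::geom_line(data = mean_d, linewidth = 1) +
    ggplot2::labs(x = "simulation day", y = "bees",
                  title = "Colony trajectories") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.beetox_sim
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.beetox_run <- autoplot.beetox_sim

#' Plot relative effect sizes of a tunnel experiment
#'
#' Treatment colony strength as a percentage of control (100 % line),
#' with the application day marked — the standard way semifield results
#' are reported.
#'
#' @param object A `"tunnel_effect"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.tunnel_effect <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$abs_day,
                                  100 - .data$rel_effect_pct)) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = object$application_abs_day,
                        colour = "red", linetype = 3) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::labs(x = "day of year",
                  y = "colony strength, % of control",
                  title = "Relative effect size") +
    ggplot2::theme_minimal()
}

#' Plot the pesticide store ledger of a run
#'
#' Daily pesticide mass in each honey compartment and the pollen pool.
#'
#' @param run A `"beetox_run"`.
#' @return A ggplot.
#' @export
plot_store_pesticide <- function(run) {
  d <- tidy(run)
  cols <- c("pest_day0_ug", "pest_day1_ug", "pest_day2_ug", "pest_day3_ug",
            "pest_day4_ug", "pest_capped_ug", "pollen_pest_ug")
  long <- tidyr::pivot_longer(d[, c("day", cols)], dplyr::all_of(cols),
                              names_to = "compartment", values_to = "ug")
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$ug,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "simulation day", y = "pesticide mass (ug)",
                  title = "In-hive pesticide fate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
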