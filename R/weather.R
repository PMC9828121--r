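#' Generate a synthetic daily weather series
#'
#' Emulates a mid-summer central-European series: daily mean temperature
#' is the seasonal level plus AR(1) anomalies, the daily maximum sits a
#' diurnal range above the mean, and daily foraging hours are derived from
#' a daylight budget cut down by cool days and by randomly occurring rain.
#' The generator is reproducible from its seed and its long-run mean
#' temperature converges on `mean_temp_C`.
#'
#' @param n_days Number of days; >= 1.
#' @param start_doy First day of year (1-based).
#' @param mean_temp_C Seasonal mean of the daily mean temperature, deg C.
#' @param temp_sd_C Standard deviation of daily anomalies.
#' @param ar1 AR(1) autocorrelation of the anomalies, in `[0, 1)`.
#' @param diurnal_range_C Daily maximum minus daily mean.
#' @param daylight_h Foraging-daylight budget, h.
#' @param rain_prob Probability a day is rainy (foraging hours scaled by
#'   `1 - rain_severity`).
#' @param rain_severity Fraction of foraging hours lost on a rainy day.
#' @param cold_cutoff_C Below this daily maximum, foraging hours are 0.
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @return A tibble of `WeatherDay` rows: `day` (1..n), `day_of_year`,
#'   `mean_temp_C`, `max_temp_C`, `foraging_hours`.
#' @export
synth_weather <- function(n_days, start_doy = 190, mean_temp_C = 19,
                          temp_sd_C = 2.5, ar1 = 0.7,
                          diurnal_range_C = 7, daylight_h = 14,
                          rain_prob = 0.25, rain_severity = 0.8,
                          cold_cutoff_C = 12, seed = NULL) {
  stopifnot(n_days >= 1, ar1 >= 0, ar1 < 1, daylight_h > 0,
            rain_prob >= 0, rain_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  innov_sd <- temp_sd_C * sqrt(1 - ar1^2)   # stationary sd = temp_sd_C
  anom <- numeric(n_days)
  anom[1] <- stats::rnorm(1, 0, temp_sd_C)
  if (n_days > 1)
    for (i in 2:n_days)
      anom[i] <- ar1 * anom[i - 1] + stats::rnorm(1, 0, innov_sd)
  mean_t <- mean_temp_C + anom
  max_t <- mean_t + diurnal_range_C * stats::runif(n_days, 0.8, 1.2)
  rainy <- stats::runif(n_days) < rain_prob
  warmth <- pmin(1, pmax(0, (max_t - cold_cutoff_C) / 10))
  hours <- daylight_h * warmth * ifelse(rainy, 1 - rain_severity, 1)
  tibble::tibble(
    day = seq_len(n_days),
    day_of_year = ((start_doy - 1 + seq_len(n_days) - 1) %% 365) + 1,
    mean_temp_C = mean_t,
    max_temp_C = max_t,
    foraging_hours = pmin(pmax(hours, 0), daylight_h))
}
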