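#' Tidy a simulation result
#'
#' Returns the daily time series as a tibble, one row per simulated day
#' (and per replicate for `"beetox_sim"`), with cohort counts, stores,
#' concentrations, doses, deaths and the mass-balance ledger columns.
#'
#' @param x A `"beetox_run"`, `"beetox_sim"` or `"tunnel_effect"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.beetox_run <- function(x, ...) x$daily

#' @rdname tidy.beetox_run
#' @export
#' @exportS3Method generics::tidy
tidy.beetox_sim <- function(x, ...) x$daily

#' @rdname tidy.beetox_run
#' @export
#' @exportS3Method generics::tidy
tidy.tunnel_effect <- function(x, ...) x$daily

#' One-row summary of a simulation result
#'
#' For runs: final colony strength, total deaths by cause, cumulative
#' pesticide ledger and the worst daily mass-balance error. For tunnel
#' experiments: the assessment-day relative effects.
#'
#' @param x A `"beetox_run"`, `"beetox_sim"` or `"tunnel_effect"`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
#' @exportS3Method generics::glance
glance.beetox_run <- function(x, ...) {
  d <- x$daily
  last <- d[nrow(d), ]
  denom <- pmax(d$cum_pest_in_ug, 1e-12)
  tibble::tibble(
    days = nrow(d),
    final_strength = last$strength,
    final_adults = last$adults,
    final_honey_kJ = last$honey_total_kJ,
    total_forager_deaths = sum(d$deaths_foragers),
    total_inhive_deaths = sum(d$deaths_inhive),
    total_larvae_deaths = sum(d$deaths_larvae),
    total_pupae_tox_deaths = sum(d$deaths_pupae_tox),
    cum_pest_in_ug = last$cum_pest_in_ug,
    cum_dose_out_ug = last$cum_dose_out_ug,
    max_balance_rel_err = max(abs(d$cum_pest_in_ug - d$cum_dose_out_ug -
                                    d$store_pest_ug) / denom))
}

#' @rdname glance.beetox_run
#' @export
#' @exportS3Method generics::glance
glance.beetox_sim <- function(x, ...) {
  per_rep <- x$daily |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(d) {
      glance.beetox_run(list(daily = d))
    })
  dplyr::summarise(per_rep,
                   replicates = dplyr::n(),
                   days = .data$days[1],
                   mean_final_strength = mean(.data$final_strength),
                   sd_final_strength = stats::sd(.data$final_strength),
                   mean_final_adults = mean(.data$final_adults),
                   max_balance_rel_err = max(.data$max_balance_rel_err))
}

#' @rdname glance.beetox_run
#' @export
#' @exportS3Method generics::glance
glance.tunnel_effect <- function(x, ...) {
  a <- x$assessment
  tibble::tibble(
    application_abs_day = x$application_abs_day,
    assessment_abs_day = x$assessment_abs_day,
    rel_effect_pct = a$rel_effect_pct,
    rel_effect_adults_pct = a$rel_effect_adults_pct,
    rel_effect_brood_pct = a$rel_effect_brood_pct,
    immediate_effect_pct = immediate_effect(x),
    control_strength = a$strength_mean_c,
    treatment_strength = a$strength_mean_t)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
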