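#' Describe a semifield (tunnel) study design
#'
#' Colonies are confined over a treated flowering crop (a single
#' *Phacelia*-type patch at short distance with capped daily forage) for
#' an exposure phase of 9-14 days, sprayed at peak flowering, then
#' relocated to an untreated monitoring site for a total observation of
#' 43-53 days. Clean water is provided in the tunnels, so the validation
#' scenarios carry no water exposure.
#'
#' @param start_doy Day of year the exposure phase starts.
#' @param exposure_phase_days Days in the tunnel (9-14 typical).
#' @param application_day_offset Application day as an offset within the
#'   exposure phase (1 = first tunnel day).
#' @param monitoring_days Days at the monitoring site after relocation.
#' @param tunnel_nectar_L,tunnel_pollen_g Daily forage cap in the tunnel.
#' @param tunnel_distance_m Flight distance to the tunnel crop.
#' @param monitor_nectar_L,monitor_pollen_g,monitor_distance_m The
#'   untreated monitoring site's forage and distance.
#' @param n_eggs,n_larvae,n_pupae,n_adults,honey_kJ,pollen_g Initial hive
#'   condition (even adult age distribution).
#' @param water_clean If `TRUE` (default) bees get clean water (no water
#'   exposure; the water module stays off).
#' @return A list of class `"tunnel_design"`.
#' @export
tunnel_design <- function(start_doy = 195,
                          exposure_phase_days = 12,
                          application_day_offset = 5,
                          monitoring_days = 43,
                          tunnel_nectar_L = 1.5,
                          tunnel_pollen_g = 100,
                          tunnel_distance_m = 30,
                          monitor_nectar_L = 8,
                          monitor_pollen_g = 500,
                          monitor_distance_m = 1500,
                          n_eggs = 2000, n_larvae = 4000, n_pupae = 6000,
                          n_adults = 8000, honey_kJ = 50000,
                          pollen_g = 250,
                          water_clean = TRUE) {
  d <- as.list(environment())
  stopifnot(d$exposure_phase_days >= 1,
            d$application_day_offset >= 1,
            d$application_day_offset <= d$exposure_phase_days)
  structure(d, class = "tunnel_design")
}

#' Study-specific tunnel designs
#'
#' Convenience wrappers for the two validation study layouts: an
#' organophosphate (dimethoate-type) study run July to September with
#' three hives, and an insect-growth-regulator (fenoxycarb-type) study
#' run July to August with four smaller, brood-heavy hives and a longer
#' exposure phase. Dates, phase lengths and observation times follow the
#' published study descriptions; hive condition and forage caps are
#' representative defaults (the study reports carry the exact values).
#'
#' @param ... Overrides passed to [tunnel_design()].
#' @return A `"tunnel_design"`.
#' @export
dimethoate_tunnel_design <- function(...) {
  defaults <- list(start_doy = 208, exposure_phase_days = 12,
                   application_day_offset = 5, monitoring_days = 43,
                   n_eggs = 3000, n_larvae = 5000, n_pupae = 7000,
                   n_adults = 8000, honey_kJ = 50000, pollen_g = 250)
  do.call(tunnel_design, override_args(defaults, list(...)))
}

#' @rdname dimethoate_tunnel_design
#' @export
fenoxycarb_tunnel_design <- function(...) {
  defaults <- list(start_doy = 192, exposure_phase_days = 14,
                   application_day_offset = 3, monitoring_days = 39,
                   n_eggs = 3500, n_larvae = 5500, n_pupae = 8000,
                   n_adults = 6000, honey_kJ = 40000, pollen_g = 250)
  do.call(tunnel_design, override_args(defaults, list(...)))
}

#' Build a runnable scenario from a tunnel design
#'
#' Two landscape phases — tunnel patch only, then the untreated
#' monitoring patch — with the application event inside the tunnel phase,
#' synthetic weather from the seed, and the design's colony
#' initialisation. Passing `pesticide = NULL` yields the paired control
#' with everything else identical.
#'
#' @param design A [tunnel_design()].
#' @param pesticide A [pesticide_profile()], or `NULL` for the control.
#' @param rate_kg_per_ha Application rate, kg a.i./ha (single spray).
#' @param weather_seed Seed for the synthetic weather series (shared by
#'   the paired control so both arms see identical weather).
#' @param options Scenario options override (see [scenario()]).
#' @return A `"beetox_scenario"`.
#' @export
build_tunnel_scenario <- function(design, pesticide, rate_kg_per_ha = 0,
                                  weather_seed = 20120701,
                                  options = list()) {
  stopifnot(inherits(design, "tunnel_design"))
  duration <- design$exposure_phase_days + design$monitoring_days
  start <- design$start_doy
  weather <- synth_weather(duration, start_doy = start, seed = weather_seed)
  tunnel_patch <- landscape_patch(
    id = "tunnel_phacelia", distance_m = design$tunnel_distance_m,
    nectar_L_per_day = design$tunnel_nectar_L,
    pollen_g_per_day = design$tunnel_pollen_g,
    treated = TRUE)
  monitor_patch <- landscape_patch(
    id = "monitoring_site", distance_m = design$monitor_distance_m,
    nectar_L_per_day = design$monitor_nectar_L,
    pollen_g_per_day = design$monitor_pollen_g,
    treated = FALSE)
  phases <- list(
    list(switch_day = start, patches = tunnel_patch),
    list(switch_day = start + design$exposure_phase_days,
         patches = monitor_patch))
  applications <- if (!is.null(pesticide) && rate_kg_per_ha > 0)
    tibble::tibble(day = start + design$application_day_offset - 1L,
                   rate_kg_per_ha = rate_kg_per_ha)
  else NULL
  colony <- init_colony_even(
    n_eggs = design$n_eggs, n_larvae = design$n_larvae,
    n_pupae = design$n_pupae, n_adults = design$n_adults,
    honey_kJ = design$honey_kJ, pollen_g = design$pollen_g)
  scenario(start_day = start, duration = duration, weather = weather,
           landscape_phases = phases, colony_init = colony,
           pesticide = pesticide, applications = applications,
           options = options)
}

#' Run a paired control/treatment tunnel experiment
#'
#' Derives the control by stripping the pesticide from the treatment
#' scenario, runs `n_replicates` of each arm with shared per-replicate
#' seeds (so both arms experience the same demographic randomness), and
#' computes the relative effect on colony strength,
#' `100 * (1 - treatment / control)` %, per day and at the end-of-study
#' assessment day (application day + two 21-day brood cycles, clipped to
#' the run length).
#'
#' @param sc_treat Treatment scenario (must carry a pesticide).
#' @param n_replicates Paired replicates (default 10, the standard
#'   validation protocol).
#' @param seed Master seed.
#' @return A `"tunnel_effect"`: list with `daily` (per-day replicate-mean
#'   strengths, relative effect and per-cohort breakdowns, with
#'   replicate SDs), `assessment` (one row at the assessment day),
#'   `treatment`, `control` (the two `"beetox_sim"` objects).
#' @export
run_paired_experiment <- function(sc_treat, n_replicates = 10, seed = 1) {
  stopifnot(inherits(sc_treat, "beetox_scenario"))
  sc_ctrl <- as_control(sc_treat)
  treat <- run_replicates(sc_treat, n_replicates, seed = seed)
  ctrl <- run_replicates(sc_ctrl, n_replicates, seed = seed)
  cohorts <- c("strength", "adults", "eggs", "larvae", "pupae",
               "inhive", "foragers")
  summarise_arm <- function(sim, arm) {
    sim$daily |>
      dplyr::group_by(.data$day, .data$abs_day) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(cohorts),
                                     list(mean = mean,
                                          sd = stats::sd)),
                       .groups = "drop") |>
      dplyr::mutate(arm = arm)
  }
  wide <- dplyr::inner_join(summarise_arm(treat, "treatment"),
                            summarise_arm(ctrl, "control"),
                            by = c("day", "abs_day"),
                            suffix = c("_t", "_c"))
  daily <- wide |>
    dplyr::mutate(
      rel_effect_pct = ifelse(.data$strength_mean_c > 0,
                              100 * (1 - .data$strength_mean_t /
                                       .data$strength_mean_c), NA_real_),
      rel_effect_adults_pct = ifelse(.data$adults_mean_c > 0,
                                     100 * (1 - .data$adults_mean_t /
                                              .data$adults_mean_c),
                                     NA_real_),
      rel_effect_brood_pct = ifelse(
        .data$eggs_mean_c + .data$larvae_mean_c + .data$pupae_mean_c > 0,
        100 * (1 - (.data$eggs_mean_t + .data$larvae_mean_t +
                      .data$pupae_mean_t) /
                 (.data$eggs_mean_c + .data$larvae_mean_c +
                    .data$pupae_mean_c)), NA_real_),
      control_collapsed = .data$strength_mean_c <= 0) |>
    dplyr::select(-"arm_t", -"arm_c")
  app_day <- if (nrow(sc_treat$applications))
    min(sc_treat$applications$day) else sc_treat$start_day
  assess_abs <- min(app_day + 42L,
                    sc_treat$start_day + sc_treat$duration - 1L)
  assessment <- daily[daily$abs_day == assess_abs, ]
  structure(list(daily = daily, assessment = assessment,
                 application_abs_day = app_day,
                 assessment_abs_day = assess_abs,
                 treatment = treat, control = ctrl),
            class = "tunnel_effect")
}

#' @export
print.tunnel_effect <- function(x, ...) {
  a <- x$assessment
  cat(sprintf(
    "<tunnel_effect> assessment day %d (application day %d)\n  relative effect on colony strength: %.1f%% (adults %.1f%%, brood %.1f%%)\n",
    x$assessment_abs_day, x$application_abs_day,
    a$rel_effect_pct, a$rel_effect_adults_pct, a$rel_effect_brood_pct))
  invisible(x)
}

#' Relative effect directly after application
#'
#' Mean relative effect on colony strength over a short window starting
#' the day after application (default the 3 following days).
#'
#' @param eff A `"tunnel_effect"`.
#' @param window_days Days after application to average over.
#' @return Relative effect, %.
#' @export
immediate_effect <- function(eff, window_days = 3) {
  stopifnot(inherits(eff, "tunnel_effect"))
  d <- eff$daily
  win <- d$abs_day > eff$application_abs_day &
    d$abs_day <= eff$application_abs_day + window_days
  mean(d$rel_effect_pct[win], na.rm = TRUE)
}
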