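#' Colony demography parameters
#'
#' Simplified cohort-model demographic constants, all config-exposed.
#' Development takes 3 d (egg) + 6 d (larva) + 12 d (pupa) = 21 d from egg
#' to emergence; adults work in-hive until `forager_transition_age` and
#' then forage. Each in-hive (nurse) bee can care for
#' `brood_cells_per_nurse` care-dependent brood cells (eggs and larvae);
#' excess brood is terminated and egg laying reduced. Seasonal egg laying
#' follows a Gaussian day-of-year curve. Per-capita food needs are in kJ
#' honey and g pollen per day; larval demand is routed through nurses.
#'
#' @param max_egg_laying_per_day Seasonal peak laying rate, eggs/day.
#' @param laying_peak_doy,laying_sigma_days Centre and width of the
#'   seasonal laying curve (day of year, days).
#' @param egg_dur,larva_dur,pupa_dur Stage durations, days (sum 21).
#' @param brood_cells_per_nurse Care-dependent brood cells one in-hive bee
#'   can handle (default 3).
#' @param forager_transition_age Adult age (days) at which in-hive bees
#'   become foragers when the colony is unstressed (upper bound of the
#'   adaptive transition age).
#' @param min_forager_transition_age Lower bound of the adaptive
#'   transition age: when the forager share of adults falls below its
#'   target, progressively younger in-hive bees are recruited into
#'   foraging (division-of-labour plasticity, one day of age per day),
#'   down to this age; a forager surplus relaxes it back up.
#' @param forager_share_target Fraction of adults the colony tries to
#'   keep in the forager role (social-inhibition set point).
#' @param adult_max_age Maximum adult age, days.
#' @param mort_egg,mort_larva,mort_pupa,mort_inhive,mort_forager Background
#'   daily mortalities, per stage.
#' @param honey_need_per_adult_kJ,larva_honey_need_kJ Honey (energy) needs.
#' @param pollen_need_per_adult_g,larva_pollen_need_g Pollen needs.
#' @param foragers_eat_pollen If `TRUE` (the convention of standard colony models) foragers are
#'   charged the same pollen ration as in-hive bees; set `FALSE` to treat
#'   forager pollen consumption as negligible.
#' @param starvation_severity_honey,starvation_severity_pollen Fraction of
#'   a day's relative food shortfall expressed as extra daily mortality
#'   (honey shortage hits adults and larvae at full severity by default;
#'   the default treats a pollen deficit as fully expressed in larval
#'   losses, the drastic brood response typical of nurse-limited colony
#'   models; lower it to emulate buffering by nurse body reserves).
#' @return A list of class `"demography_params"`.
#' @export
demography_params <- function(max_egg_laying_per_day = 1600,
                              laying_peak_doy = 160,
                              laying_sigma_days = 45,
                              egg_dur = 3, larva_dur = 6, pupa_dur = 12,
                              brood_cells_per_nurse = 3,
                              forager_transition_age = 21,
                              min_forager_transition_age = 7,
                              forager_share_target = 0.33,
                              adult_max_age = 90,
                              mort_egg = 0.03, mort_larva = 0.01,
                              mort_pupa = 0.001, mort_inhive = 0.004,
                              mort_forager = 0.014,
                              honey_need_per_adult_kJ = 0.43,
                              larva_honey_need_kJ = 0.14,
                              pollen_need_per_adult_g = 0.0015,
                              larva_pollen_need_g = 0.024,
                              foragers_eat_pollen = TRUE,
                              starvation_severity_honey = 1,
                              starvation_severity_pollen = 1) {
  p <- as.list(environment())
  stopifnot(p$egg_dur + p$larva_dur + p$pupa_dur == 21,
            p$brood_cells_per_nurse > 0,
            p$forager_transition_age >= 1,
            p$min_forager_transition_age >= 1,
            p$min_forager_transition_age <= p$forager_transition_age,
            p$adult_max_age > p$forager_transition_age)
  probs <- c(mort_egg, mort_larva, mort_pupa, mort_inhive, mort_forager)
  stopifnot(all(probs >= 0), all(probs <= 1))
  structure(p, class = "demography_params")
}

#' Construct a colony state
#'
#' Per-age cohort counts plus the in-hive stores. Ages are 0-based within
#' each stage; adults are one vector with in-hive bees below the forager
#' transition age and foragers at or above it. `larva_dose` carries each
#' larval age class's cumulative per-capita oral dose (ug) and `pupae_q`
#' the daily toxicant hazard a pupal age class carries over from its
#' larval exposure (22-day larval endpoints).
#'
#' @param eggs,larvae,pupae Integer count vectors, lengths = stage
#'   durations (scalars are recycled evenly by [init_colony_even()]).
#' @param adults Integer count vector, length `adult_max_age`.
#' @param honey A [honey_stores()]; `pollen` a [pollen_store()].
#' @param larva_dose,pupae_q Optional exposure carry-overs (default 0).
#' @param params A [demography_params()].
#' @return An object of class `"colony_state"`.
#' @export
colony_structure <- function(eggs, larvae, pupae, adults,
                             honey = honey_stores(),
                             pollen = pollen_store(),
                             larva_dose = NULL, pupae_q = NULL,
                             params = demography_params()) {
  stopifnot(length(eggs) == params$egg_dur,
            length(larvae) == params$larva_dur,
            length(pupae) == params$pupa_dur,
            length(adults) == params$adult_max_age,
            all(c(eggs, larvae, pupae, adults) >= 0))
  structure(
    list(eggs = as.integer(round(eggs)),
         larvae = as.integer(round(larvae)),
         pupae = as.integer(round(pupae)),
         adults = as.integer(round(adults)),
         larva_dose = if (is.null(larva_dose)) numeric(params$larva_dur)
                      else as.numeric(larva_dose),
         pupae_q = if (is.null(pupae_q)) numeric(params$pupa_dur)
                   else as.numeric(pupae_q),
         honey = honey, pollen = pollen),
    class = "colony_state")
}

#' Initialise a colony with even age distributions
#'
#' Spreads each stage total evenly across its age classes — the documented
#' default for semifield-study initialisation, where bee ages cannot be
#' assessed. Pre-existing honey seeds the capped (ripe) compartment.
#'
#' @param n_eggs,n_larvae,n_pupae,n_adults Stage totals.
#' @param adult_age_span Adults are spread evenly over ages
#'   `0..adult_age_span-1` (default 35).
#' @param honey_kJ Initial (clean, capped) honey store, kJ.
#' @param pollen_g Initial pollen pool, g.
#' @param params A [demography_params()].
#' @return A `"colony_state"`.
#' @export
init_colony_even <- function(n_eggs = 2000, n_larvae = 4000, n_pupae = 6000,
                             n_adults = 8000, adult_age_span = 35,
                             honey_kJ = 25000, pollen_g = 200,
                             params = demography_params()) {
  stopifnot(adult_age_span <= params$adult_max_age)
  spread <- function(total, n) {
    base <- rep(floor(total / n), n)
    extra <- total - sum(base)
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1
    base
  }
  adults <- integer(params$adult_max_age)
  adults[seq_len(adult_age_span)] <- spread(n_adults, adult_age_span)
  colony_structure(
    eggs = spread(n_eggs, params$egg_dur),
    larvae = spread(n_larvae, params$larva_dur),
    pupae = spread(n_pupae, params$pupa_dur),
    adults = adults,
    honey = honey_stores(energy_kJ = c(0, 0, 0, 0, 0, honey_kJ)),
    pollen = pollen_store(mass_g = pollen_g),
    params = params)
}

#' @export
print.colony_state <- function(x, ...) {
  cts <- cohort_counts(x)
  cat(sprintf(
    "<colony_state> eggs %d, larvae %d, pupae %d, in-hive %d, foragers %d (strength %d)\n  honey %.0f kJ, pollen %.0f g\n",
    cts$eggs, cts$larvae, cts$pupae, cts$inhive, cts$foragers,
    cts$strength, total_store_energy(x$honey), x$pollen$mass_g))
  invisible(x)
}

#' Cohort totals and colony strength
#'
#' Colony strength is the sum of all cohorts: eggs, larvae, pupae, in-hive
#' bees and foragers.
#'
#' @param state A `"colony_state"`.
#' @param params A [demography_params()].
#' @return A one-row tibble: `eggs`, `larvae`, `pupae`, `inhive`,
#'   `foragers`, `adults`, `strength`.
#' @export
cohort_counts <- function(state, params = demography_params()) {
  ft <- params$forager_transition_age
  inhive <- sum(state$adults[seq_len(min(ft, length(state$adults)))])
  adults <- sum(state$adults)
  tibble::tibble(
    eggs = sum(state$eggs), larvae = sum(state$larvae),
    pupae = sum(state$pupae), inhive = inhive,
    foragers = adults - inhive, adults = adults,
    strength = sum(state$eggs) + sum(state$larvae) + sum(state$pupae) +
      adults)
}

# eggs + larvae: the brood that needs active nursing (capped pupae do not)
care_dependent_brood <- function(state) sum(state$eggs) + sum(state$larvae)

#' Seasonal egg-laying potential
#'
#' Gaussian day-of-year curve,
#' `max_egg_laying_per_day * exp(-((doy - peak)^2) / (2 sigma^2))`.
#'
#' @param day_of_year Day of year (1-based integer).
#' @param params A [demography_params()].
#' @return Potential eggs/day (numeric).
#' @export
seasonal_laying_potential <- function(day_of_year,
                                      params = demography_params()) {
  params$max_egg_laying_per_day *
    exp(-((day_of_year - params$laying_peak_doy)^2) /
          (2 * params$laying_sigma_days^2))
}

#' Eggs laid today
#'
#' The queen lays the seasonal potential, capped by the remaining nursing
#' capacity `max(0, brood_cells_per_nurse * n_inhive - current_brood)`.
#'
#' @param day_of_year Day of year.
#' @param n_inhive Number of in-hive (nurse) bees.
#' @param current_brood Current care-dependent brood (eggs + larvae).
#' @param params A [demography_params()].
#' @return Integer egg count.
#' @export
lay_eggs <- function(day_of_year, n_inhive, current_brood,
                     params = demography_params()) {
  stopifnot(n_inhive >= 0, current_brood >= 0)
  capacity <- max(0, params$brood_cells_per_nurse * n_inhive - current_brood)
  as.integer(floor(min(seasonal_laying_potential(day_of_year, params),
                       capacity)))
}

#' Terminate brood in excess of nursing capacity
#'
#' When there are too few in-hive bees the colony terminates brood,
#' youngest first (eggs from age 0 up, then larvae), until the
#' care-dependent brood fits `brood_cells_per_nurse * n_inhive`.
#'
#' @param state A `"colony_state"`.
#' @param params A [demography_params()].
#' @return List: updated `state`, integer `terminated`.
#' @export
terminate_excess_brood <- function(state, params = demography_params()) {
  ft <- params$forager_transition_age
  n_inhive <- sum(state$adults[seq_len(ft)])
  cap <- params$brood_cells_per_nurse * n_inhive
  excess <- care_dependent_brood(state) - cap
  terminated <- 0L
  if (excess > 0) {
    for (stage in c("eggs", "larvae")) {
      v <- state[[stage]]
      for (i in seq_along(v)) {           # youngest (age 0) first
        if (excess <= 0) break
        take <- min(v[i], excess)
        v[i] <- v[i] - take
        excess <- excess - take
        terminated <- terminated + take
      }
      state[[stage]] <- v
    }
  }
  list(state = state, terminated = as.integer(terminated))
}

#' Age all cohorts one day and apply stage transitions
#'
#' Background mortality is drawn binomially per age class (set the
#' `mort_*` parameters to zero to age without losses), then every cohort
#' ages one day: eggs hatch into larvae, larvae pupate, pupae emerge as
#' age-0 in-hive adults, and adults past `adult_max_age` are removed.
#' Per-capita larval dose histories age with their cohorts; the graduating
#' larval class's carry-over hazard can be installed on the new age-0
#' pupal class via `new_pupae_q`.
#'
#' @param state A `"colony_state"`.
#' @param params A [demography_params()].
#' @param new_pupae_q Daily hazard carried by today's pupating larvae
#'   (default 0; supplied by the effects step for 22-day larval
#'   endpoints).
#' @param new_eggs Eggs laid today, entering the age-0 egg class.
#' @return Updated `"colony_state"`.
#' @export
age_and_transition <- function(state, params = demography_params(),
                               new_pupae_q = 0, new_eggs = 0L) {
  thin <- function(v, p) {
    if (p <= 0) return(v)
    v - stats::rbinom(length(v), v, p)
  }
  eggs <- thin(state$eggs, params$mort_egg)
  larvae <- thin(state$larvae, params$mort_larva)
  pupae <- thin(state$pupae, params$mort_pupa)
  ft <- params$forager_transition_age
  idx_ih <- seq_len(ft)
  adults <- state$adults
  adults[idx_ih] <- thin(adults[idx_ih], params$mort_inhive)
  adults[-idx_ih] <- thin(adults[-idx_ih], params$mort_forager)

  n_e <- length(eggs); n_l <- length(larvae); n_p <- length(pupae)
  hatched <- eggs[n_e]
  pupated <- larvae[n_l]
  emerged <- pupae[n_p]
  state$eggs <- c(as.integer(round(new_eggs)), eggs[-n_e])
  state$larvae <- c(hatched, larvae[-n_l])
  state$larva_dose <- c(0, state$larva_dose[-n_l])
  state$pupae <- c(pupated, pupae[-n_p])
  state$pupae_q <- c(new_pupae_q, state$pupae_q[-n_p])
  state$adults <- c(emerged, adults[-length(adults)])  # oldest age removed
  state
}

#' Daily food demand by consumer class
#'
#' Demand = counts x per-capita needs, reported separately for in-hive
#' adults, foragers, and larvae (larval demand is routed through nurses).
#'
#' @param state A `"colony_state"`.
#' @param params A [demography_params()].
#' @return A tibble with columns `class`, `honey_kJ`, `pollen_g`.
#' @export
daily_demand <- function(state, params = demography_params()) {
  cts <- cohort_counts(state, params)
  forager_pollen <- if (params$foragers_eat_pollen)
    cts$foragers * params$pollen_need_per_adult_g else 0
  tibble::tibble(
    class = c("inhive", "foragers", "larvae"),
    honey_kJ = c(cts$inhive * params$honey_need_per_adult_kJ,
                 cts$foragers * params$honey_need_per_adult_kJ,
                 cts$larvae * params$larva_honey_need_kJ),
    pollen_g = c(cts$inhive * params$pollen_need_per_adult_g,
                 forager_pollen,
                 cts$larvae * params$larva_pollen_need_g))
}
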