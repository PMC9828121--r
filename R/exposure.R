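#' Pesticide concentrations in nectar, pollen and contact matrices
#'
#' At the start of each day the concentration in the bee-relevant matrices
#' is computed from the application history. For an application of
#' `AR` kg a.i./ha on day `a`, the initial concentration in a food matrix
#' is `C0 = AR * RUD * 1000` ug/kg (RUD in mg/kg per kg a.i./ha) and
#' dissipates first-order with the whole-plant half-life:
#' `C(day) = sum over applications of C0 * 2^-((day - a)/DT50)`.
#' The contact matrix (mg/kg insect) is nonzero only on an application
#' day itself (a surface-deposit estimate, not a persistent residue).
#' A measured-concentration time series on the profile overrides the
#' RUD route for the days it covers.
#'
#' @param day Day index (same axis as `applications$day`).
#' @param applications Data frame with columns `day`, `rate_kg_per_ha`.
#' @param profile A [pesticide_profile()] or `NULL` (all zero).
#' @return A one-row tibble: `c_nectar_ug_per_kg`, `c_pollen_ug_per_kg`,
#'   `c_contact_mg_per_kg`, `valid_for_day`.
#' @export
matrix_concentrations <- function(day, applications, profile) {
  zero <- tibble::tibble(c_nectar_ug_per_kg = 0, c_pollen_ug_per_kg = 0,
                         c_contact_mg_per_kg = 0, valid_for_day = day)
  if (is.null(profile) || is.null(applications) || !nrow(applications))
    return(zero)
  mc <- profile$measured_concentrations
  if (!is.null(mc) && day %in% mc$day) {
    row <- mc[mc$day == day, ][1, ]
    past <- applications[applications$day <= day, ]
    contact <- sum(past$rate_kg_per_ha[past$day == day]) *
      profile$rud_contact_foliar
    return(tibble::tibble(c_nectar_ug_per_kg = row$c_nectar_ug_per_kg,
                          c_pollen_ug_per_kg = row$c_pollen_ug_per_kg,
                          c_contact_mg_per_kg = contact,
                          valid_for_day = day))
  }
  past <- applications[applications$day <= day, ]
  if (!nrow(past)) return(zero)
  decay <- 2^(-(day - past$day) / profile$dt50_plant)
  tibble::tibble(
    c_nectar_ug_per_kg = sum(past$rate_kg_per_ha * profile$rud_nectar *
                               1000 * decay),
    c_pollen_ug_per_kg = sum(past$rate_kg_per_ha * profile$rud_pollen *
                               1000 * decay),
    c_contact_mg_per_kg = sum(past$rate_kg_per_ha[past$day == day]) *
      profile$rud_contact_foliar,
    valid_for_day = day)
}

#' Contact dose per forager on an application day
#'
#' The foliar-insect residue (application rate x contact RUD, mg/kg
#' insect) multiplied by the forager body weight gives the dose per bee:
#' `dose_ug = rate * rud_contact_foliar * forager_weight_g`
#' (mg/kg x g = ug). Applied once per forager per application day.
#'
#' @param application_rate_kg_per_ha Application rate, kg a.i./ha; >= 0.
#' @param profile A [pesticide_profile()].
#' @return Dose in ug/bee.
#' @export
contact_dose <- function(application_rate_kg_per_ha, profile) {
  stopifnot(all(application_rate_kg_per_ha >= 0))
  application_rate_kg_per_ha * profile$rud_contact_foliar *
    profile$forager_weight_g
}

#' Accumulate forager oral doses from a day's trip log
#'
#' The forager oral dose is emergent: for every nectar trip from a treated
#' patch, the nectar consumed in flight for energy carries
#' `consumed_kg * c_nectar` ug into the forager. Pollen loads contribute
#' no in-transit dose (foragers do not eat pollen in flight); water-trip
#' doses are produced by the water module and added by the caller.
#'
#' @param trip_log A trip-log tibble from [run_foraging_day()] (columns
#'   incl. `squadron`, `type`, `treated`, `consumed_nectar_kg`,
#'   `c_nectar_ug_per_kg`).
#' @return A tibble `squadron`, `oral_dose_ug` (summed over the day's
#'   trips per squadron).
#' @export
accumulate_forager_oral_doses <- function(trip_log) {
  if (is.null(trip_log) || !nrow(trip_log))
    return(tibble::tibble(squadron = integer(), oral_dose_ug = numeric()))
  trip_log |>
    dplyr::mutate(
      dose = ifelse(.data$type == "nectar" & .data$treated,
                    .data$consumed_nectar_kg * .data$c_nectar_ug_per_kg,
                    0)) |>
    dplyr::group_by(.data$squadron) |>
    dplyr::summarise(oral_dose_ug = sum(.data$dose), .groups = "drop")
}

#' Apply contact knock-down to a day's returning trips
#'
#' On the application day every active forager receives the contact dose
#' once. If the substance knocks down (`profile$knockdown`), contact
#' mortality is drawn *before* hive return: the killed fraction of each
#' squadron is lost in the field and its share of every load never enters
#' the stores. With knock-down off, all loads return and contact mortality
#' is applied at the end of the day instead.
#'
#' @param trip_log The day's trip log.
#' @param squadron_sizes Named integer vector (bees per squadron id).
#' @param contact_dose_ug Contact dose per forager today (0 off
#'   application days).
#' @param profile A [pesticide_profile()].
#' @return List: `trip_log` with a `return_fraction` column applied to
#'   loads, `field_deaths` (tibble squadron, deaths), and
#'   `deferred_contact` logical (TRUE when contact mortality must still be
#'   applied at end of day).
#' @export
apply_knockdown <- function(trip_log, squadron_sizes, contact_dose_ug,
                            profile) {
  n_sq <- length(squadron_sizes)
  deaths <- tibble::tibble(squadron = as.integer(names(squadron_sizes)),
                           deaths = 0L)
  if (is.null(trip_log)) trip_log <- empty_trip_log()
  trip_log$return_fraction <- rep(1, nrow(trip_log))
  if (is.null(profile) || contact_dose_ug <= 0) {
    return(list(trip_log = trip_log, field_deaths = deaths,
                deferred_contact = FALSE))
  }
  q <- contact_mortality_q(contact_dose_ug, profile)
  if (!profile$knockdown || q <= 0) {
    return(list(trip_log = trip_log, field_deaths = deaths,
                deferred_contact = TRUE))
  }
  sizes <- as.integer(squadron_sizes)
  killed <- stats::rbinom(n_sq, sizes, q)
  deaths$deaths <- killed
  surv_frac <- ifelse(sizes > 0, (sizes - killed) / sizes, 1)
  idx <- match(trip_log$squadron, deaths$squadron)
  trip_log$return_fraction <- ifelse(is.na(idx), 1, surv_frac[idx])
  list(trip_log = trip_log, field_deaths = deaths, deferred_contact = FALSE)
}

empty_trip_log <- function() {
  tibble::tibble(squadron = integer(), type = character(),
                 patch_id = character(), load = numeric(),
                 load_kg = numeric(), energy_kJ = numeric(),
                 consumed_nectar_kg = numeric(),
                 flight_distance_m = numeric(), duration_h = numeric(),
                 energy_cost_kJ = numeric(), treated = logical(),
                 c_nectar_ug_per_kg = numeric(),
                 c_pollen_ug_per_kg = numeric(),
                 died_in_transit = logical())
}
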