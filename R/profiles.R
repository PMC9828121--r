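#' Define a pesticide profile
#'
#' All substance-specific exposure and toxicity parameters in one object:
#' 90th-percentile residue-per-unit-dose (RUD) values that convert an
#' application rate (kg a.i./ha) into matrix concentrations, the whole-plant
#' dissipation half-life (DT50), the dose-response endpoint set, and the
#' behavioural flags (immediate knock-down of contact-exposed foragers,
#' nurse filter factor for larval food).
#'
#' Concentrations may alternatively be supplied as a measured time series
#' via `measured_concentrations` (a data frame with columns `day`,
#' `c_nectar_ug_per_kg`, `c_pollen_ug_per_kg`); when present it overrides
#' the RUD x rate x DT50 computation for the days it covers.
#'
#' @param name Substance name.
#' @param rud_nectar,rud_pollen Residue per unit dose in nectar/pollen,
#'   mg/kg per kg a.i./ha.
#' @param rud_contact_foliar RUD for foliar insects, mg/kg insect per
#'   kg a.i./ha (converted to ug/bee via `forager_weight_g`).
#' @param dt50_plant Whole-plant dissipation half-life, days; > 0.
#' @param dose_responses Named list of [dose_response()] objects; names
#'   among `acute_oral`, `chronic_oral`, `contact`, `larval`.
#' @param knockdown Logical; if `TRUE` contact-exposed foragers can be
#'   knocked down in the field on the application day and do not return
#'   (their loads never reach the hive).
#' @param filter_factor Fraction in `[0, 1]` of food-borne pesticide passed
#'   by nurse bees into larval food (1 = no filtering, the default; only
#'   applied when the scenario's `filter_on` option is set).
#' @param forager_weight_g Forager body weight used for the contact dose
#'   conversion, grams (default 0.1).
#' @param water_concentration_ug_per_kg Pesticide concentration in
#'   available water sources, ug/kg (scenario-supplied; default 0).
#' @param measured_concentrations Optional measured-concentration time
#'   series (see above), or `NULL`.
#' @return An object of class `"pesticide_profile"`.
#' @export
pesticide_profile <- function(name,
                              rud_nectar = 0, rud_pollen = 0,
                              rud_contact_foliar = 0,
                              dt50_plant = 3,
                              dose_responses = list(),
                              knockdown = FALSE,
                              filter_factor = 1,
                              forager_weight_g = 0.1,
                              water_concentration_ug_per_kg = 0,
                              measured_concentrations = NULL) {
  stopifnot(rud_nectar >= 0, rud_pollen >= 0, rud_contact_foliar >= 0,
            dt50_plant > 0,
            filter_factor >= 0, filter_factor <= 1,
            forager_weight_g > 0,
            water_concentration_ug_per_kg >= 0)
  if (length(dose_responses)) {
    ok <- vapply(dose_responses, inherits, logical(1), "dose_response")
    if (!all(ok)) stop("dose_responses must all be dose_response objects")
    names(dose_responses) <-
      vapply(dose_responses, function(d) d$endpoint, character(1))
  }
  if (!is.null(measured_concentrations)) {
    measured_concentrations <- tibble::as_tibble(measured_concentrations)
    req <- c("day", "c_nectar_ug_per_kg", "c_pollen_ug_per_kg")
    if (!all(req %in% names(measured_concentrations)))
      stop("measured_concentrations needs columns: ",
           paste(req, collapse = ", "))
  }
  structure(
    list(name = name,
         rud_nectar = rud_nectar, rud_pollen = rud_pollen,
         rud_contact_foliar = rud_contact_foliar,
         dt50_plant = dt50_plant,
         dose_responses = dose_responses,
         knockdown = isTRUE(knockdown),
         filter_factor = filter_factor,
         forager_weight_g = forager_weight_g,
         water_concentration_ug_per_kg = water_concentration_ug_per_kg,
         measured_concentrations = measured_concentrations),
    class = "pesticide_profile")
}

#' @export
print.pesticide_profile <- function(x, ...) {
  cat(sprintf(
    "<pesticide_profile> %s\n  RUD nectar %g, pollen %g, contact %g mg/kg per kg/ha; DT50 %g d\n  knockdown %s, filter_factor %g, endpoints: %s\n",
    x$name, x$rud_nectar, x$rud_pollen, x$rud_contact_foliar, x$dt50_plant,
    x$knockdown, x$filter_factor,
    if (length(x$dose_responses)) paste(names(x$dose_responses),
                                        collapse = ", ") else "none"))
  invisible(x)
}


# replace defaults wholesale by argument name (no recursive merging)
override_args <- function(defaults, args) {
  defaults[names(args)] <- args
  defaults
}

#' Representative dimethoate-like profile (acute adult toxicity)
#'
#' A toxic-standard organophosphate profile: highly toxic to adult bees by
#' both oral and contact routes. Organophosphates act over hours rather
#' than instantaneously, so the knock-down flag is off by default:
#' contact-exposed foragers return with their contaminated loads and die
#' at the end of the day. Endpoint magnitudes follow public regulatory
#' summaries for dimethoate (acute oral LD50 ~0.1 ug/bee, contact
#' ~0.12 ug/bee, chronic daily ~0.25 ug/bee/day); they are representative
#' defaults, not a transcription of any specific study report, and every
#' value can be overridden.
#'
#' @param ... Overrides passed to [pesticide_profile()].
#' @return A `"pesticide_profile"`.
#' @export
dimethoate_profile <- function(...) {
  defaults <- list(
    name = "dimethoate-like",
    rud_nectar = 4.4, rud_pollen = 12.6,
    rud_contact_foliar = 14,
    dt50_plant = 3,
    knockdown = FALSE,
    dose_responses = list(
      dose_response("acute_oral", ld50 = 0.10, slope = 2.5),
      dose_response("contact", ld50 = 0.12, slope = 2.5),
      dose_response("chronic_oral", ld50 = 0.25, slope = 2,
                    test_duration_days = 10),
      dose_response("larval", ld50 = 1.5, slope = 2,
                    test_duration_days = 7)))
  do.call(pesticide_profile, override_args(defaults, list(...)))
}

#' Representative fenoxycarb-like profile (brood toxicity)
#'
#' A juvenile-hormone-analogue profile: practically non-toxic to adult
#' bees, but lethal to brood through larval ingestion with mortality
#' expressed in the pupal stage, hence the 22-day larval endpoint. The
#' larval LD50 magnitude is a representative default for a potent insect
#' growth regulator; override with study-specific values when available.
#'
#' @param ... Overrides passed to [pesticide_profile()].
#' @return A `"pesticide_profile"`.
#' @export
fenoxycarb_profile <- function(...) {
  defaults <- list(
    name = "fenoxycarb-like",
    rud_nectar = 4.4, rud_pollen = 12.6,
    rud_contact_foliar = 14,
    dt50_plant = 4,
    knockdown = FALSE,
    dose_responses = list(
      dose_response("acute_oral", ld50 = 500, slope = 2),
      dose_response("contact", ld50 = 500, slope = 2),
      dose_response("larval", ld50 = 0.02, slope = 2,
                    test_duration_days = 22)))
  do.call(pesticide_profile, override_args(defaults, list(...)))
}

#' Zero-toxicity profile
#'
#' Exposure is computed and ledgered as usual but every dose-response
#' endpoint is absent, so no toxicant mortality arises. Useful for
#' exposure-only runs and for control-equivalence checks.
#'
#' @param ... Overrides passed to [pesticide_profile()].
#' @return A `"pesticide_profile"`.
#' @export
inert_profile <- function(...) {
  defaults <- list(name = "inert", rud_nectar = 4.4, rud_pollen = 12.6,
                   rud_contact_foliar = 14, dt50_plant = 3,
                   dose_responses = list())
  do.call(pesticide_profile, override_args(defaults, list(...)))
}
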