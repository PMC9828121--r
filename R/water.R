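#' Hive thermal parameters for cooling-water demand
#'
#' Evaporative-cooling demand follows a simple conductive heat-load model
#' (after Lindauer's observations of water use on hot days): when ambient
#' temperature exceeds the cooling threshold, heat flows into the hive at
#' `conductance x area x (ambient - target)` and must be removed by
#' evaporating water. The diurnal temperature course is approximated as a
#' triangle between the daily mean and maximum, which determines the
#' time spent above the threshold from daily weather alone.
#'
#' @param surface_area_m2 Hive outer surface area, m^2.
#' @param wall_conductance_W_per_m2K Effective wall conductance, W/(m^2 K).
#' @param cooling_threshold_C Ambient temperature above which the colony
#'   cools actively, deg C.
#' @param target_temp_C Brood-nest target temperature, deg C.
#' @param latent_heat_kJ_per_kg Latent heat of evaporation of water.
#' @return A list of class `"thermal_params"`.
#' @export
hive_thermal_params <- function(surface_area_m2 = 0.68,
                                wall_conductance_W_per_m2K = 0.9,
                                cooling_threshold_C = 30,
                                target_temp_C = 35,
                                latent_heat_kJ_per_kg = 2260) {
  p <- as.list(environment())
  stopifnot(p$surface_area_m2 > 0, p$wall_conductance_W_per_m2K > 0,
            p$latent_heat_kJ_per_kg > 0)
  structure(p, class = "thermal_params")
}

#' Daily cooling-water demand
#'
#' Zero when the daily maximum stays at or below the cooling threshold.
#' Otherwise the fraction of the day above the threshold comes from a
#' triangular diurnal profile between `2 * mean - max` (the implied
#' minimum) and the maximum, the mean ambient excess over the hive target
#' during that window drives the heat load
#' `Q = conductance * area * excess * seconds_above`, and
#' `water = Q / latent_heat` (kg).
#'
#' @param weather_day One weather row (`mean_temp_C`, `max_temp_C`).
#' @param thermal A [hive_thermal_params()].
#' @return Cooling water demand, kg/day.
#' @export
cooling_water_demand <- function(weather_day,
                                 thermal = hive_thermal_params()) {
  tmax <- weather_day$max_temp_C
  tmean <- weather_day$mean_temp_C
  thr <- thermal$cooling_threshold_C
  if (tmax <= thr) return(0)
  tmin <- 2 * tmean - tmax
  frac_above <- if (thr <= tmin || tmax <= tmin) 1
    else (tmax - thr) / (tmax - tmin)
  ambient_above <- (tmax + max(thr, tmin)) / 2
  excess <- max(0, ambient_above - thermal$target_temp_C)
  q_kJ <- thermal$wall_conductance_W_per_m2K * thermal$surface_area_m2 *
    excess * frac_above * 86400 / 1000
  q_kJ / thermal$latent_heat_kJ_per_kg
}

#' Water needed to dilute the day's honey ration for feeding
#'
#' Honey (water content `from` %) is diluted to `to` % water before
#' feeding. Mass balance on the solids gives
#' `water = honey * (solids * to/(100 - to) - from/100)` with
#' `solids = 1 - from/100`; for the standard 20 % -> 50 % dilution this is
#' 0.6 kg water per kg honey.
#'
#' @param honey_consumed_kg Honey consumed today, kg.
#' @param water_from_pct,water_to_pct Initial and target water content, %.
#' @return Dilution water demand, kg/day.
#' @export
dilution_water_demand <- function(honey_consumed_kg, water_from_pct = 20,
                                  water_to_pct = 50) {
  stopifnot(honey_consumed_kg >= 0, water_from_pct >= 0,
            water_from_pct <= water_to_pct, water_to_pct < 100)
  solids <- 1 - water_from_pct / 100
  factor <- solids * water_to_pct / (100 - water_to_pct) -
    water_from_pct / 100
  honey_consumed_kg * max(0, factor)
}

#' Run a day of water foraging
#'
#' Water foragers cover the day's cooling and dilution demand in trips of
#' one crop load each, limited by the sources' daily volumes and the
#' available forager-trip capacity. For every trip with load `m` kg at
#' concentration `C` ug/kg, 10 % of the carried pesticide becomes the
#' carrying forager's oral dose and the remaining 90 % enters the honey
#' being diluted (the day-0 consumption pool) — the split conserves the
#' collected mass exactly. Trips are logged but deterministically: the
#' module's energetic cost is neglected (it is OFF by default and has not
#' been validated against data).
#'
#' @param demand_kg Total water demand today (cooling + dilution), kg.
#' @param water_sources Patch tibble rows with `water_L_per_day > 0`.
#' @param water_concentration_ug_per_kg Pesticide concentration in the
#'   water, ug/kg.
#' @param n_foragers Foragers available for recruitment.
#' @param pars A [foraging_params()] (crop volume = water load).
#' @return List: `trip_log` (water trips), `carrier_dose_ug` (summed oral
#'   dose to carriers), `carrier_trips`, `water_to_honey_pesticide_ug`,
#'   `collected_kg`, `unmet_kg`.
#' @export
run_water_foraging <- function(demand_kg, water_sources,
                               water_concentration_ug_per_kg = 0,
                               n_foragers = 0,
                               pars = foraging_params()) {
  stopifnot(demand_kg >= 0, water_concentration_ug_per_kg >= 0)
  load_kg <- pars$crop_load_uL * 1e-6          # water density 1 kg/L
  empty <- list(trip_log = empty_trip_log(), carrier_dose_ug = 0,
                carrier_trips = 0L, water_to_honey_pesticide_ug = 0,
                collected_kg = 0, unmet_kg = demand_kg)
  if (demand_kg <= 0 || is.null(water_sources) || !nrow(water_sources))
    return(empty)
  avail_kg <- sum(water_sources$water_L_per_day)   # 1 L = 1 kg
  if (avail_kg <= 0 || n_foragers <= 0) return(empty)
  n_trips_needed <- ceiling(demand_kg / load_kg - 1e-9)
  max_trips <- n_foragers * 20L                    # generous trip capacity
  n_trips <- min(n_trips_needed, floor(avail_kg / load_kg), max_trips)
  collected <- n_trips * load_kg
  src <- water_sources[which.max(water_sources$water_L_per_day), ]
  pest_total <- collected * water_concentration_ug_per_kg
  carrier <- 0.10 * pest_total
  to_honey <- 0.90 * pest_total
  trip_log <- tibble::tibble(
    squadron = NA_integer_, type = "water", patch_id = src$id,
    load = load_kg * 1e6,                          # uL
    load_kg = rep(load_kg, n_trips), energy_kJ = 0,
    consumed_nectar_kg = 0,
    flight_distance_m = 2 * src$distance_m,
    duration_h = 2 * src$distance_m / pars$flight_speed_m_per_s / 3600 +
      pars$nectar_handling_h,
    energy_cost_kJ = 2 * src$distance_m * pars$energy_cost_kJ_per_m,
    treated = water_concentration_ug_per_kg > 0,
    c_nectar_ug_per_kg = 0, c_pollen_ug_per_kg = 0,
    died_in_transit = FALSE)
  list(trip_log = trip_log, carrier_dose_ug = carrier,
       carrier_trips = as.integer(n_trips),
       water_to_honey_pesticide_ug = to_honey,
       collected_kg = collected,
       unmet_kg = max(0, demand_kg - collected))
}
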