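#' Foraging parameters
#'
#' Colony-model foraging constants, all config-exposed. Foragers are
#' grouped into squadrons (default 100 bees) that share trip outcomes;
#' each trip carries a fixed crop load of nectar (uL) or pollen load (mg),
#' takes `2 * distance / flight_speed` plus a handling time, costs flight
#' energy per metre, and exposes the squadron to a small per-trip
#' background risk (the whole squadron is lost with its load).
#' The pollen share of the forager force rises linearly from
#' `min_pollen_share` to `max_pollen_share` with the pollen-store deficit.
#'
#' @param squadron_size Bees per forager squadron.
#' @param crop_load_uL Nectar crop load per trip, uL.
#' @param pollen_load_mg Pollen load per trip, mg.
#' @param flight_speed_m_per_s Flight speed, m/s.
#' @param nectar_handling_h,pollen_handling_h Non-flight time per trip
#'   (searching, collecting, unloading and waiting in the hive), h.
#' @param energy_cost_kJ_per_m Flight cost, kJ/m.
#' @param per_trip_mortality Probability a squadron is lost on one trip.
#' @param min_pollen_share,max_pollen_share Bounds on the pollen share.
#' @param pollen_target_days Pollen-store target, days of current demand.
#' @param min_foraging_temp_C No foraging below this daily maximum.
#' @param nectar_density_kg_per_L Nectar density for uL -> kg conversion.
#' @return A list of class `"foraging_params"`.
#' @export
foraging_params <- function(squadron_size = 100,
                            crop_load_uL = 50,
                            pollen_load_mg = 15,
                            flight_speed_m_per_s = 6.5,
                            nectar_handling_h = 0.75,
                            pollen_handling_h = 0.6,
                            energy_cost_kJ_per_m = 0.0000615,
                            per_trip_mortality = 0.003,
                            min_pollen_share = 0.1,
                            max_pollen_share = 0.5,
                            pollen_target_days = 7,
                            min_foraging_temp_C = 12,
                            nectar_density_kg_per_L = 1.1) {
  p <- as.list(environment())
  stopifnot(p$squadron_size >= 1, p$crop_load_uL > 0, p$pollen_load_mg > 0,
            p$per_trip_mortality >= 0, p$per_trip_mortality <= 1,
            p$min_pollen_share >= 0, p$max_pollen_share <= 1,
            p$min_pollen_share <= p$max_pollen_share)
  structure(p, class = "foraging_params")
}

#' Build a landscape patch table
#'
#' One row per patch. Water sources are patches with
#' `water_L_per_day > 0`; their pesticide concentration comes from the
#' profile's `water_concentration_ug_per_kg`.
#'
#' @param id Patch identifier(s).
#' @param distance_m Distance from the hive, m; > 0.
#' @param nectar_L_per_day,pollen_g_per_day Daily forage availability.
#' @param sucrose_mol_per_L Nectar sucrose molarity, mol/L.
#' @param flower_start,flower_end Flowering window (day-of-year bounds).
#' @param treated Logical: does this patch carry the applied pesticide?
#' @param water_L_per_day Daily water availability, L.
#' @return A tibble of patches.
#' @export
landscape_patch <- function(id, distance_m,
                            nectar_L_per_day = 0, pollen_g_per_day = 0,
                            sucrose_mol_per_L = 1.5,
                            flower_start = 1, flower_end = 366,
                            treated = FALSE, water_L_per_day = 0) {
  stopifnot(all(distance_m > 0), all(nectar_L_per_day >= 0),
            all(pollen_g_per_day >= 0), all(water_L_per_day >= 0))
  tibble::tibble(id = as.character(id), distance_m = distance_m,
                 nectar_L_per_day = nectar_L_per_day,
                 pollen_g_per_day = pollen_g_per_day,
                 sucrose_mol_per_L = sucrose_mol_per_L,
                 flower_start = flower_start, flower_end = flower_end,
                 treated = treated, water_L_per_day = water_L_per_day)
}

patch_trip_metrics <- function(patches, pars) {
  e_density <- nectar_energy_density(patches$sucrose_mol_per_L,
                                     pars$nectar_density_kg_per_L)
  crop_kg <- pars$crop_load_uL * 1e-6 * pars$nectar_density_kg_per_L
  dplyr::mutate(
    patches,
    energy_density_kJ_per_kg = e_density,
    nectar_trip_gain_kJ = crop_kg * e_density,
    flight_cost_kJ = 2 * .data$distance_m * pars$energy_cost_kJ_per_m,
    nectar_duration_h = 2 * .data$distance_m /
      pars$flight_speed_m_per_s / 3600 + pars$nectar_handling_h,
    pollen_duration_h = 2 * .data$distance_m /
      pars$flight_speed_m_per_s / 3600 + pars$pollen_handling_h)
}

#' Allocate foragers to nectar and pollen tasks
#'
#' The pollen share interpolates between its configured minimum and
#' maximum with the pollen-store deficit (0 = store at target). Squadrons
#' are filled to `squadron_size`, with one possibly smaller remainder
#' squadron. Patch choice happens per trip inside [run_foraging_day()],
#' proportional to expected energetic efficiency.
#'
#' @param n_foragers Number of foragers available today.
#' @param pollen_deficit_frac Pollen-store deficit as a fraction of target
#'   (clamped to `[0, 1]`).
#' @param pars A [foraging_params()].
#' @return A tibble of squadrons: `squadron`, `size`, `task`.
#' @export
allocate_foragers <- function(n_foragers, pollen_deficit_frac,
                              pars = foraging_params()) {
  stopifnot(n_foragers >= 0)
  if (n_foragers == 0)
    return(tibble::tibble(squadron = integer(), size = integer(),
                          task = character()))
  d <- min(1, max(0, pollen_deficit_frac))
  share <- pars$min_pollen_share +
    d * (pars$max_pollen_share - pars$min_pollen_share)
  n_sq <- ceiling(n_foragers / pars$squadron_size)
  sizes <- rep(pars$squadron_size, n_sq)
  sizes[n_sq] <- n_foragers - pars$squadron_size * (n_sq - 1)
  n_pollen <- round(share * n_sq)
  task <- rep("nectar", n_sq)
  if (n_pollen > 0) task[seq_len(n_pollen)] <- "pollen"
  tibble::tibble(squadron = seq_len(n_sq), size = as.integer(sizes),
                 task = task)
}

#' Run one day of nectar and pollen foraging
#'
#' Squadrons make repeated trips while their share of the daily foraging
#' hours and the patch supplies last. Each trip: the squadron picks an
#' in-season patch with remaining supply (probability proportional to
#' `max(gain - round-trip cost, 0) / duration`, nectar; `load / duration`,
#' pollen), loads up to capacity, depletes the patch, and runs the
#' per-trip background risk. Flight energy for nectar trips is consumed
#' from the carried nectar (this is what makes the forager oral dose on a
#' treated patch emergent); pollen-trip flight energy is drawn from the
#' day-0 honey store and returned as `pollen_flight_cost_kJ`.
#'
#' @param squadrons Assignment tibble from [allocate_foragers()].
#' @param patches Patch tibble ([landscape_patch()] rows).
#' @param weather_day One row of a weather table (needs `day_of_year`,
#'   `max_temp_C`, `foraging_hours`).
#' @param conc Matrix concentrations for the day
#'   ([matrix_concentrations()] output); applied to treated patches only.
#' @param pars A [foraging_params()].
#' @return List: `trip_log` (tibble, one row per squadron-trip),
#'   `squadrons` (with `alive` flag and `trips` count),
#'   `pollen_flight_cost_kJ`.
#' @export
run_foraging_day <- function(squadrons, patches, weather_day, conc,
                             pars = foraging_params()) {
  out_empty <- list(trip_log = empty_trip_log(),
                    squadrons = dplyr::mutate(squadrons, alive = TRUE,
                                              trips = 0L),
                    pollen_flight_cost_kJ = 0)
  hours <- weather_day$foraging_hours
  if (!nrow(squadrons) || hours <= 0 ||
      weather_day$max_temp_C < pars$min_foraging_temp_C)
    return(out_empty)
  doy <- weather_day$day_of_year
  pt <- patch_trip_metrics(patches, pars)
  pt <- pt[pt$flower_start <= doy & doy <= pt$flower_end, ]
  if (!nrow(pt)) return(out_empty)

  nectar_supply_kg <- pt$nectar_L_per_day * pars$nectar_density_kg_per_L
  pollen_supply_g <- pt$pollen_g_per_day
  crop_kg_per_bee <- pars$crop_load_uL * 1e-6 * pars$nectar_density_kg_per_L
  load_g_per_bee <- pars$pollen_load_mg / 1000

  sq <- dplyr::mutate(squadrons, alive = TRUE, trips = 0L,
                      time_left = hours)
  w_nectar <- pmax(pt$nectar_trip_gain_kJ - pt$flight_cost_kJ, 0) /
    pt$nectar_duration_h
  w_pollen <- pt$pollen_g_per_day / pt$pollen_duration_h

  # per-round vectorised trip loop: every active squadron makes one trip
  # per round; within a round supplies are allocated in squadron order
  logs <- list()
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    active <- which(sq$alive & sq$time_left > 0)
    if (!length(active)) break
    n_a <- length(active)
    is_nectar <- sq$task[active] == "nectar"
    # patch choice per squadron: among in-season patches with remaining
    # supply for its resource, probability ~ efficiency; when all
    # supplies are gone trips continue but are unsuccessful
    pick <- integer(n_a)
    unsuccessful <- logical(n_a)
    for (task_nectar in c(TRUE, FALSE)) {
      grp <- which(is_nectar == task_nectar)
      if (!length(grp)) next
      supply <- if (task_nectar) nectar_supply_kg else pollen_supply_g
      w <- if (task_nectar) w_nectar else w_pollen
      cand <- which(supply > 0)
      if (length(cand)) {
        wc <- w[cand]
        if (sum(wc) <= 0) wc <- rep(1, length(cand))
        pick[grp] <- if (length(cand) == 1) rep(cand, length(grp)) else
          cand[sample.int(length(cand), length(grp), replace = TRUE,
                          prob = wc)]
      } else {
        pick[grp] <- if (nrow(pt) == 1) 1L else
          sample.int(nrow(pt), length(grp), replace = TRUE)
        unsuccessful[grp] <- TRUE
      }
    }
    dur <- ifelse(is_nectar, pt$nectar_duration_h[pick],
                  pt$pollen_duration_h[pick])
    feasible <- sq$time_left[active] >= dur
    sq$time_left[active[!feasible]] <- 0
    if (!any(feasible)) next
    active <- active[feasible]
    is_nectar <- is_nectar[feasible]
    pick <- pick[feasible]
    unsuccessful <- unsuccessful[feasible]
    dur <- dur[feasible]
    n_a <- length(active)

    # sequential supply allocation within the round; a squadron carries
    # size x per-bee load
    sz <- sq$size[active]
    take <- numeric(n_a)
    for (k in seq_len(n_a)) {
      j <- pick[k]
      if (unsuccessful[k]) next
      if (is_nectar[k]) {
        take[k] <- min(crop_kg_per_bee * sz[k], nectar_supply_kg[j])
        nectar_supply_kg[j] <- nectar_supply_kg[j] - take[k]
      } else {
        take[k] <- min(load_g_per_bee * sz[k], pollen_supply_g[j])
        pollen_supply_g[j] <- pollen_supply_g[j] - take[k]
      }
    }
    died <- stats::rbinom(n_a, 1, pars$per_trip_mortality) == 1
    squad_flight_kJ <- pt$flight_cost_kJ[pick] * sz
    consumed <- ifelse(is_nectar,
                       pmin(take, squad_flight_kJ /
                              pt$energy_density_kJ_per_kg[pick]), 0)
    logs[[round_i]] <- list(
      squadron = sq$squadron[active],
      type = ifelse(is_nectar, "nectar", "pollen"),
      patch_id = pt$id[pick],
      load = ifelse(is_nectar,
                    take / (1e-6 * pars$nectar_density_kg_per_L),  # uL
                    take * 1000),                                  # mg
      load_kg = ifelse(is_nectar, take, take / 1000),
      energy_kJ = ifelse(is_nectar,
                         take * pt$energy_density_kJ_per_kg[pick], 0),
      consumed_nectar_kg = consumed,
      flight_distance_m = 2 * pt$distance_m[pick],
      duration_h = dur,
      energy_cost_kJ = squad_flight_kJ,
      treated = pt$treated[pick],
      c_nectar_ug_per_kg = ifelse(is_nectar & pt$treated[pick],
                                  conc$c_nectar_ug_per_kg, 0),
      c_pollen_ug_per_kg = ifelse(!is_nectar & pt$treated[pick],
                                  conc$c_pollen_ug_per_kg, 0),
      died_in_transit = died)
    sq$trips[active] <- sq$trips[active] + 1L
    sq$time_left[active] <- sq$time_left[active] - dur
    sq$alive[active[died]] <- FALSE
  }
  logs <- logs[!vapply(logs, is.null, logical(1))]
  trip_log <- if (length(logs)) {
    fields <- names(logs[[1]])
    tibble::as_tibble(stats::setNames(
      lapply(fields, function(f) do.call(c, lapply(logs, `[[`, f))),
      fields))
  } else empty_trip_log()
  pollen_cost <- sum(trip_log$energy_cost_kJ[trip_log$type == "pollen"])
  list(trip_log = trip_log,
       squadrons = sq[, c("squadron", "size", "task", "alive", "trips")],
       pollen_flight_cost_kJ = pollen_cost)
}

#' Store inflows implied by a day's trip log
#'
#' Sums the surviving, returning share of every load: nectar arrives as
#' energy (gross load minus in-flight consumption) with its pesticide
#' mass, pollen as mass with its pesticide mass. Loads of squadrons lost
#' in transit, and the non-returning fraction after knock-down, are
#' excluded.
#'
#' @param trip_log A trip log, optionally carrying a `return_fraction`
#'   column from [apply_knockdown()].
#' @return A one-row tibble: `nectar_energy_kJ`, `nectar_pesticide_ug`,
#'   `pollen_g`, `pollen_pesticide_ug`, `forager_oral_ug` (total
#'   in-flight consumption dose of surviving squadrons).
#' @export
trip_inflows <- function(trip_log) {
  if (is.null(trip_log) || !nrow(trip_log))
    return(tibble::tibble(nectar_energy_kJ = 0, nectar_pesticide_ug = 0,
                          pollen_g = 0, pollen_pesticide_ug = 0,
                          forager_oral_ug = 0))
  rf <- if ("return_fraction" %in% names(trip_log))
    trip_log$return_fraction else rep(1, nrow(trip_log))
  keep <- !trip_log$died_in_transit
  nec <- trip_log$type == "nectar" & keep
  pol <- trip_log$type == "pollen" & keep
  net_kg <- pmax(trip_log$load_kg - trip_log$consumed_nectar_kg, 0)
  e_per_kg <- ifelse(trip_log$load_kg > 0,
                     trip_log$energy_kJ / trip_log$load_kg, 0)
  tibble::tibble(
    nectar_energy_kJ = sum(net_kg[nec] * e_per_kg[nec] * rf[nec]),
    nectar_pesticide_ug = sum(net_kg[nec] *
                                trip_log$c_nectar_ug_per_kg[nec] * rf[nec]),
    pollen_g = sum(trip_log$load_kg[pol] * 1000 * rf[pol]),
    pollen_pesticide_ug = sum(trip_log$load_kg[pol] *
                                trip_log$c_pollen_ug_per_kg[pol] * rf[pol]),
    forager_oral_ug = sum(trip_log$consumed_nectar_kg[nec] *
                            trip_log$c_nectar_ug_per_kg[nec]))
}
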