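#' Assemble a simulation scenario
#'
#' A scenario bundles everything one run needs: the start day-of-year and
#' duration, a daily weather table, an ordered sequence of landscape
#' phases (each a patch set that becomes active on its `switch_day` — this
#' is how relocation into and out of a tunnel is represented), the initial
#' colony structure, an optional pesticide profile with its application
#' events, and module switches.
#'
#' Days: `start_day` is a 1-based day of year; the simulation runs on an
#' absolute day axis `start_day .. start_day + duration - 1` (no leap
#' handling; day-of-year wraps at 365 only for the seasonal curves).
#' `applications$day` and phase `switch_day`s live on that absolute axis.
#'
#' @param start_day Day of year the simulation starts (1-based).
#' @param duration Number of simulated days; >= 1.
#' @param weather Weather tibble with at least `day_of_year`,
#'   `mean_temp_C`, `max_temp_C`, `foraging_hours` for `duration` days.
#' @param landscape_phases List of `list(switch_day =, patches =)` with
#'   strictly increasing switch days inside the simulation window; the
#'   first phase must start at `start_day`.
#' @param colony_init A `"colony_state"` ([colony_structure()] /
#'   [init_colony_even()]).
#' @param pesticide A [pesticide_profile()] or `NULL` (control).
#' @param applications Tibble with `day`, `rate_kg_per_ha` (empty for
#'   control).
#' @param options List overriding any of `water_module_on` (default
#'   `FALSE`), `knockdown_on` (`TRUE`: respect the profile's knock-down
#'   flag), `filter_on` (`FALSE`), `chem_dissipation_dt50` (`Inf`: no
#'   in-hive chemical decay).
#' @param demography,foraging,thermal Parameter sets (defaults used when
#'   omitted).
#' @return An object of class `"beetox_scenario"`.
#' @export
scenario <- function(start_day, duration, weather, landscape_phases,
                     colony_init, pesticide = NULL,
                     applications = NULL, options = list(),
                     demography = demography_params(),
                     foraging = foraging_params(),
                     thermal = hive_thermal_params()) {
  if (is.null(applications))
    applications <- tibble::tibble(day = integer(),
                                   rate_kg_per_ha = numeric())
  opts <- utils::modifyList(
    list(water_module_on = FALSE, knockdown_on = TRUE, filter_on = FALSE,
         chem_dissipation_dt50 = Inf),
    options)
  extra <- setdiff(names(options),
                   c("water_module_on", "knockdown_on", "filter_on",
                     "chem_dissipation_dt50"))
  if (length(extra))
    stop("unknown scenario option(s): ", paste(extra, collapse = ", "))
  sc <- structure(
    list(start_day = as.integer(start_day), duration = as.integer(duration),
         weather = tibble::as_tibble(weather),
         landscape_phases = landscape_phases,
         colony_init = colony_init,
         pesticide = pesticide,
         applications = tibble::as_tibble(applications),
         options = opts,
         demography = demography, foraging = foraging, thermal = thermal),
    class = "beetox_scenario")
  validate_scenario(sc)
}

#' Validate a scenario's invariants
#'
#' @param sc A `"beetox_scenario"`.
#' @return The scenario, invisibly usable; errors name the offending
#'   field.
#' @export
validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "beetox_scenario"))
  err <- function(field, msg) stop(sprintf("scenario$%s: %s", field, msg),
                                   call. = FALSE)
  if (sc$duration < 1) err("duration", "must be >= 1")
  if (sc$start_day < 1 || sc$start_day > 365)
    err("start_day", "must be a day of year in 1..365")
  w <- sc$weather
  need <- c("day_of_year", "mean_temp_C", "max_temp_C", "foraging_hours")
  miss <- setdiff(need, names(w))
  if (length(miss))
    err("weather", paste("missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(w) < sc$duration)
    err("weather", sprintf("needs >= %d rows, has %d", sc$duration, nrow(w)))
  if (any(w$foraging_hours < 0 | w$foraging_hours > 24))
    err("weather$foraging_hours", "must lie in [0, 24]")
  if (any(w$max_temp_C < w$mean_temp_C))
    err("weather$max_temp_C", "must be >= mean_temp_C")
  if (!length(sc$landscape_phases))
    err("landscape_phases", "at least one phase required")
  sdays <- vapply(sc$landscape_phases, `[[`, numeric(1), "switch_day")
  if (sdays[1] != sc$start_day)
    err("landscape_phases", "first phase must start at start_day")
  if (any(diff(sdays) <= 0))
    err("landscape_phases", "switch_days must be strictly increasing")
  if (any(sdays < sc$start_day | sdays > sc$start_day + sc$duration))
    err("landscape_phases", "switch_days must lie in the simulation window")
  for (ph in sc$landscape_phases) {
    p <- ph$patches
    if (!nrow(p)) err("landscape_phases", "phase has an empty patch set")
    if (any(p$distance_m <= 0)) err("landscape_phases", "distance_m <= 0")
    if (any(p$nectar_L_per_day < 0 | p$pollen_g_per_day < 0 |
              p$water_L_per_day < 0))
      err("landscape_phases", "negative patch quantities")
  }
  if (!inherits(sc$colony_init, "colony_state"))
    err("colony_init", "must be a colony_state")
  if (is.null(sc$pesticide)) {
    if (nrow(sc$applications))
      err("applications", "must be empty when no pesticide is defined")
  } else if (nrow(sc$applications)) {
    if (any(sc$applications$rate_kg_per_ha < 0))
      err("applications$rate_kg_per_ha", "must be >= 0")
    lo <- sc$start_day
    hi <- sc$start_day + sc$duration - 1
    if (any(sc$applications$day < lo | sc$applications$day > hi))
      err("applications$day", "outside the simulation window")
  }
  sc
}

#' Strip the pesticide from a scenario
#'
#' Returns the paired control: identical in every respect but with no
#' pesticide and no applications.
#'
#' @param sc A `"beetox_scenario"`.
#' @return The control scenario.
#' @export
as_control <- function(sc) {
  stopifnot(inherits(sc, "beetox_scenario"))
  sc$pesticide <- NULL
  sc$applications <- tibble::tibble(day = integer(),
                                    rate_kg_per_ha = numeric())
  sc
}

#' @export
print.beetox_scenario <- function(x, ...) {
  cat(sprintf(
    "<beetox_scenario> start day %d, %d days, %d landscape phase(s)\n  pesticide: %s; applications: %d; water %s, filter %s\n",
    x$start_day, x$duration, length(x$landscape_phases),
    if (is.null(x$pesticide)) "none (control)" else x$pesticide$name,
    nrow(x$applications),
    ifelse(x$options$water_module_on, "on", "off"),
    ifelse(x$options$filter_on, "on", "off")))
  invisible(x)
}

## ---- config file I/O -------------------------------------------------

scenario_config_keys <- list(
  top = c("simulation", "weather_csv", "landscape_phases", "colony",
          "pesticide", "applications", "options"),
  simulation = c("start_day", "duration"),
  colony = c("eggs", "larvae", "pupae", "adults", "adult_age_span",
             "honey_kJ", "pollen_g"),
  pesticide = c("name", "rud_nectar", "rud_pollen", "rud_contact_foliar",
                "dt50_plant", "knockdown", "filter_factor",
                "forager_weight_g", "water_concentration_ug_per_kg",
                "dose_responses"),
  dose_response = c("endpoint", "ld50", "slope", "test_duration_days",
                    "regime"),
  phase = c("switch_day", "patches_csv"),
  application = c("day", "rate_kg_per_ha"))

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("configuration error in '%s': unknown key(s) %s",
                 where, paste(extra, collapse = ", ")), call. = FALSE)
}

require_key <- function(x, key, where) {
  if (is.null(x[[key]]))
    stop(sprintf("configuration error: missing required key '%s' in '%s'",
                 key, where), call. = FALSE)
  x[[key]]
}

#' Load a scenario from a YAML configuration file
#'
#' The config is a single structured file referencing CSVs (relative to
#' its own location) for weather and per-phase landscape patch tables.
#' Unknown keys are rejected; all invariants are validated on load.
#' Omit the `pesticide` block for a control scenario.
#'
#' @param path Path to the YAML config.
#' @return A validated `"beetox_scenario"`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  check_keys(cfg, scenario_config_keys$top, "top level")
  sim <- require_key(cfg, "simulation", "top level")
  check_keys(sim, scenario_config_keys$simulation, "simulation")
  start_day <- require_key(sim, "start_day", "simulation")
  duration <- require_key(sim, "duration", "simulation")

  wpath <- resolve(require_key(cfg, "weather_csv", "top level"))
  if (!file.exists(wpath)) stop("weather CSV not found: ", wpath)
  weather <- readr::read_csv(wpath, show_col_types = FALSE)

  phases_cfg <- require_key(cfg, "landscape_phases", "top level")
  phases <- lapply(phases_cfg, function(ph) {
    check_keys(ph, scenario_config_keys$phase, "landscape_phases")
    ppath <- resolve(require_key(ph, "patches_csv", "landscape_phases"))
    if (!file.exists(ppath)) stop("patches CSV not found: ", ppath)
    patches <- readr::read_csv(ppath, show_col_types = FALSE)
    for (col in c("nectar_L_per_day", "pollen_g_per_day",
                  "water_L_per_day")) {
      if (is.null(patches[[col]])) patches[[col]] <- 0
    }
    if (is.null(patches$treated)) patches$treated <- FALSE
    if (is.null(patches$sucrose_mol_per_L)) patches$sucrose_mol_per_L <- 1.5
    if (is.null(patches$flower_start)) patches$flower_start <- 1
    if (is.null(patches$flower_end)) patches$flower_end <- 366
    list(switch_day = require_key(ph, "switch_day", "landscape_phases"),
         patches = tibble::as_tibble(patches))
  })

  col_cfg <- require_key(cfg, "colony", "top level")
  check_keys(col_cfg, scenario_config_keys$colony, "colony")
  colony <- init_colony_even(
    n_eggs = require_key(col_cfg, "eggs", "colony"),
    n_larvae = require_key(col_cfg, "larvae", "colony"),
    n_pupae = require_key(col_cfg, "pupae", "colony"),
    n_adults = require_key(col_cfg, "adults", "colony"),
    adult_age_span = col_cfg$adult_age_span %||% 35,
    honey_kJ = col_cfg$honey_kJ %||% 25000,
    pollen_g = col_cfg$pollen_g %||% 200)

  pesticide <- NULL
  if (!is.null(cfg$pesticide)) {
    pc <- cfg$pesticide
    check_keys(pc, scenario_config_keys$pesticide, "pesticide")
    drs <- lapply(pc$dose_responses %||% list(), function(d) {
      check_keys(d, scenario_config_keys$dose_response,
                 "pesticide$dose_responses")
      dose_response(
        endpoint = require_key(d, "endpoint", "dose_responses"),
        ld50 = require_key(d, "ld50", "dose_responses"),
        slope = require_key(d, "slope", "dose_responses"),
        test_duration_days = d$test_duration_days %||%
          switch(d$endpoint, chronic_oral = 10, larval = 7, 2))
    })
    pesticide <- pesticide_profile(
      name = require_key(pc, "name", "pesticide"),
      rud_nectar = pc$rud_nectar %||% 0,
      rud_pollen = pc$rud_pollen %||% 0,
      rud_contact_foliar = pc$rud_contact_foliar %||% 0,
      dt50_plant = pc$dt50_plant %||% 3,
      knockdown = pc$knockdown %||% FALSE,
      filter_factor = pc$filter_factor %||% 1,
      forager_weight_g = pc$forager_weight_g %||% 0.1,
      water_concentration_ug_per_kg =
        pc$water_concentration_ug_per_kg %||% 0,
      dose_responses = drs)
  }

  apps <- cfg$applications %||% list()
  applications <- if (length(apps)) {
    dplyr::bind_rows(lapply(apps, function(a) {
      check_keys(a, scenario_config_keys$application, "applications")
      tibble::tibble(day = require_key(a, "day", "applications"),
                     rate_kg_per_ha = require_key(a, "rate_kg_per_ha",
                                                  "applications"))
    }))
  } else NULL

  scenario(start_day = start_day, duration = duration, weather = weather,
           landscape_phases = phases, colony_init = colony,
           pesticide = pesticide, applications = applications,
           options = cfg$options %||% list())
}

#' Write simulation results to CSV
#'
#' Writes `daily.csv` under `dir`: one row per simulated day per
#' replicate with cohort counts, colony strength, per-compartment store
#' energies and pesticide masses, matrix concentrations, per-cohort
#' daily doses and deaths, and the running pesticide mass-balance ledger.
#' Column names are exactly the columns of `tidy()` on the result.
#'
#' @param result A `"beetox_sim"` ([run_replicates()]) or `"beetox_run"`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path of the written file.
#' @export
write_results <- function(result, dir) {
  daily <- tidy(result)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("cannot write to: ", dir)
  path <- file.path(dir, "daily.csv")
  readr::write_csv(daily, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
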