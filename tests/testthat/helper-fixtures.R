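# Small scenarios built in code so every test is self-contained.

quick_weather <- function(n_days, start_doy = 190, hours = 8,
                          mean_temp = 20, max_temp = 26) {
  tibble::tibble(
    day = seq_len(n_days),
    day_of_year = start_doy + seq_len(n_days) - 1,
    mean_temp_C = mean_temp,
    max_temp_C = max_temp,
    foraging_hours = hours)
}

quick_patches <- function(treated = TRUE, nectar_L = 0.5, pollen_g = 60,
                          distance_m = 100, water_L = 0) {
  landscape_patch("p1", distance_m = distance_m,
                  nectar_L_per_day = nectar_L, pollen_g_per_day = pollen_g,
                  treated = treated, water_L_per_day = water_L)
}

quick_colony <- function(n_adults = 2000, honey_kJ = 20000,
                         pollen_g = 150) {
  init_colony_even(n_eggs = 600, n_larvae = 1200, n_pupae = 1800,
                   n_adults = n_adults, honey_kJ = honey_kJ,
                   pollen_g = pollen_g)
}

quick_scenario <- function(duration = 20, profile = NULL,
                           application_day = 5, rate = 0.4,
                           options = list(), patches = quick_patches(),
                           start_day = 190, ...) {
  apps <- if (!is.null(profile))
    tibble::tibble(day = start_day + application_day - 1,
                   rate_kg_per_ha = rate)
  else NULL
  scenario(start_day = start_day, duration = duration,
           weather = quick_weather(duration, start_doy = start_day),
           landscape_phases = list(list(switch_day = start_day,
                                        patches = patches)),
           colony_init = quick_colony(...),
           pesticide = profile, applications = apps, options = options)
}

# contact-lethal profile with knock-down, for the knock-down contract
knockdown_profile <- function(knockdown = TRUE) {
  pesticide_profile(
    name = "kd-test", rud_nectar = 4, rud_pollen = 10,
    rud_contact_foliar = 20, dt50_plant = 3, knockdown = knockdown,
    dose_responses = list(
      dose_response("contact", ld50 = 0.05, slope = 3),
      dose_response("acute_oral", ld50 = 0.5, slope = 2)))
}

# write a scenario config (YAML + CSVs) into dir and return the yaml path
write_config_fixture <- function(dir, with_pesticide = TRUE,
                                 application_day = 195, rate = 0.4,
                                 duration = 15) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(quick_weather(duration, start_doy = 190),
                   file.path(dir, "weather.csv"))
  readr::write_csv(quick_patches(), file.path(dir, "patches.csv"))
  cfg <- list(
    simulation = list(start_day = 190, duration = duration),
    weather_csv = "weather.csv",
    landscape_phases = list(list(switch_day = 190,
                                 patches_csv = "patches.csv")),
    colony = list(eggs = 600, larvae = 1200, pupae = 1800, adults = 2000,
                  honey_kJ = 20000, pollen_g = 150))
  if (with_pesticide) {
    cfg$pesticide <- list(
      name = "dimethoate-like", rud_nectar = 4.4, rud_pollen = 12.6,
      rud_contact_foliar = 14, dt50_plant = 3,
      dose_responses = list(
        list(endpoint = "acute_oral", ld50 = 0.1, slope = 2.5),
        list(endpoint = "contact", ld50 = 0.12, slope = 2.5)))
    cfg$applications <- list(list(day = application_day,
                                  rate_kg_per_ha = rate))
  }
  path <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(cfg, path)
  path
}
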