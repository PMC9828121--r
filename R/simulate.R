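HONEY_KJ_PER_G <- 12.78   # energy density of ripe honey

# deterministic largest-remainder allocation of n removals across age
# classes, proportional to counts, capped by counts (no RNG, so paired
# runs stay aligned)
allocate_removals <- function(counts, n) {
  n <- min(n, sum(counts))
  if (n <= 0 || !length(counts)) return(integer(length(counts)))
  exact <- counts / sum(counts) * n
  base <- pmin(floor(exact), counts)
  left <- n - sum(base)
  if (left > 0) {
    room <- counts - base
    ord <- order(exact - floor(exact), decreasing = TRUE)
    for (i in ord) {
      if (left <= 0) break
      add <- min(room[i], 1)
      base[i] <- base[i] + add
      left <- left - add
    }
    # any remainder: greedy into whatever room is left
    i <- 1
    while (left > 0 && i <= length(base)) {
      add <- min(counts[i] - base[i], left)
      base[i] <- base[i] + add
      left <- left - add
      i <- i + 1
    }
  }
  as.integer(base)
}

# binomial thinning gated on p > 0 so zero-rate draws never touch the RNG
# (keeps paired control/treatment streams aligned)
gated_binom <- function(sizes, p) {
  if (all(p <= 0)) return(integer(length(sizes)))
  stats::rbinom(length(sizes), sizes, pmin(p, 1))
}

active_patches <- function(sc, abs_day) {
  sdays <- vapply(sc$landscape_phases, `[[`, numeric(1), "switch_day")
  i <- max(which(sdays <= abs_day))
  sc$landscape_phases[[i]]$patches
}

#' Simulate one colony run
#'
#' Runs the daily loop over the scenario: (1) matrix concentrations are
#' computed from the application history; (2) the queen lays; (3)
#' foragers collect nectar and pollen, receiving contact doses (and
#' possibly being knocked down) on application days; (4) the water module
#' runs if switched on; (5) surviving loads are deposited into the day-0
#' honey compartment and the pollen pool; (6) the colony consumes
#' freshest-first, which routes doses to in-hive bees, foragers and
#' larvae; (7) end-of-day dose-response effects and background mortality
#' are applied and ledgers reset; (8) stores age one compartment and all
#' cohorts age one day; excess brood is terminated. A pesticide
#' mass-balance ledger (inflows = delivered doses + store residue) is
#' carried throughout.
#'
#' @param sc A `"beetox_scenario"`.
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @param verbose If `TRUE`, a per-day DEBUG trace of the module ordering
#'   goes to stderr.
#' @return A `"beetox_run"`: list with `daily` (tibble, one row per day),
#'   `final_state`, and the `scenario`.
#' @export
simulate_colony <- function(sc, seed = NULL, verbose = FALSE) {
  sc <- validate_scenario(sc)
  if (!is.null(seed)) set.seed(seed)
  dem <- sc$demography
  fp <- sc$foraging
  profile <- sc$pesticide
  if (!is.null(profile) && !sc$options$knockdown_on)
    profile$knockdown <- FALSE
  opts <- sc$options
  state <- sc$colony_init
  # adaptive division of labour: the in-hive -> forager transition age
  # starts at its unstressed value and is pulled down (younger recruits)
  # by forage shortfalls, up again by surplus days
  ft_cur <- dem$forager_transition_age
  larval_dr <- if (!is.null(profile)) profile$dose_responses[["larval"]]
               else NULL
  pupal_expression <- !is.null(larval_dr) &&
    larval_dr$test_duration_days > 7
  cum_in <- 0
  cum_out <- 0
  rows <- vector("list", sc$duration)

  for (t in seq_len(sc$duration)) {
    dem_day <- dem
    dem_day$forager_transition_age <- ft_cur
    ft <- ft_cur
    idx_forager <- (ft + 1):dem$adult_max_age
    abs_day <- sc$start_day + t - 1L
    doy <- ((abs_day - 1L) %% 365L) + 1L
    wd <- sc$weather[t, ]
    wd$day_of_year <- doy
    patches <- active_patches(sc, abs_day)
    conc <- matrix_concentrations(abs_day, sc$applications, profile)
    if (verbose)
      message(sprintf(
        "DEBUG day %d: concentrations -> laying -> foraging -> water -> deposit -> consume -> effects -> age",
        abs_day))

    cts <- cohort_counts(state, dem_day)
    eggs_laid <- lay_eggs(doy, cts$inhive, care_dependent_brood(state), dem_day)
    demand <- daily_demand(state, dem_day)
    pollen_demand_g <- sum(demand$pollen_g)
    target_g <- fp$pollen_target_days * pollen_demand_g
    deficit <- if (target_g > 0)
      max(0, 1 - state$pollen$mass_g / target_g) else 0

    squadrons <- allocate_foragers(cts$foragers, deficit, fp)
    fday <- run_foraging_day(squadrons, patches, wd, conc, fp)
    sq <- fday$squadrons
    transit_deaths <- sum(sq$size[!sq$alive])

    # contact exposure, once per forager active on a treated patch today
    rate_today <- if (nrow(sc$applications))
      sum(sc$applications$rate_kg_per_ha[sc$applications$day == abs_day])
      else 0
    cdose <- if (!is.null(profile) && rate_today > 0)
      contact_dose(rate_today, profile) else 0
    treated_sq <- unique(fday$trip_log$squadron[fday$trip_log$treated &
                                                  !fday$trip_log$died_in_transit])
    exposed <- sq$alive & sq$squadron %in% treated_sq
    kd_sizes <- stats::setNames(sq$size[exposed],
                                sq$squadron[exposed])
    kd <- apply_knockdown(fday$trip_log,
                          kd_sizes,
                          if (length(kd_sizes)) cdose else 0, profile)
    knock_deaths <- sum(kd$field_deaths$deaths)

    # water module
    wres <- list(carrier_dose_ug = 0, water_to_honey_pesticide_ug = 0,
                 collected_kg = 0, unmet_kg = 0, carrier_trips = 0L)
    honey_demand_kJ <- sum(demand$honey_kJ) + fday$pollen_flight_cost_kJ
    if (opts$water_module_on) {
      sources <- patches[patches$water_L_per_day > 0, ]
      if (nrow(sources)) {
        cool <- cooling_water_demand(wd, sc$thermal)
        dilu <- dilution_water_demand(honey_demand_kJ /
                                        (HONEY_KJ_PER_G * 1000))
        wc <- if (!is.null(profile))
          profile$water_concentration_ug_per_kg else 0
        wres <- run_water_foraging(cool + dilu, sources, wc,
                                   n_foragers = cts$foragers, pars = fp)
      }
    }

    # deposit surviving loads; water-borne pesticide (90 %) joins the
    # honey being diluted, i.e. the day-0 consumption pool
    inflow <- trip_inflows(kd$trip_log)
    dep <- deposit_inflows(
      state$honey, state$pollen,
      nectar_energy_kJ = inflow$nectar_energy_kJ,
      nectar_pesticide_ug = inflow$nectar_pesticide_ug +
        wres$water_to_honey_pesticide_ug,
      pollen_mass_g = inflow$pollen_g,
      pollen_pesticide_ug = inflow$pollen_pesticide_ug)
    state$honey <- dep$stores
    state$pollen <- dep$pollen
    cum_in <- cum_in + inflow$nectar_pesticide_ug +
      inflow$pollen_pesticide_ug + wres$water_to_honey_pesticide_ug

    # consumption, freshest first; doses follow demand shares
    ch <- consume_honey(state$honey, honey_demand_kJ)
    state$honey <- ch$stores
    cum_out <- cum_out + ch$delivered_dose_ug
    h_shares <- if (honey_demand_kJ > 0)
      c(demand$honey_kJ, fday$pollen_flight_cost_kJ) / honey_demand_kJ
      else c(0, 0, 0, 0)
    h_dose <- ch$delivered_dose_ug * h_shares    # inhive, foragers, larvae, flight
    h_short_frac <- if (honey_demand_kJ > 0)
      ch$shortfall_kJ / honey_demand_kJ else 0

    cp <- consume_pollen(state$pollen, pollen_demand_g)
    state$pollen <- cp$pollen
    cum_out <- cum_out + cp$delivered_dose_ug
    p_shares <- if (pollen_demand_g > 0) demand$pollen_g / pollen_demand_g
      else c(0, 0, 0)
    p_dose <- cp$delivered_dose_ug * p_shares
    p_short_frac <- if (pollen_demand_g > 0)
      cp$shortfall_g / pollen_demand_g else 0

    # larval dose, with the optional nurse filter; what the filter holds
    # back stays with the nurses (in-hive oral dose)
    f_eff <- if (opts$filter_on && !is.null(profile))
      profile$filter_factor else 1
    larva_food_dose <- h_dose[3] + p_dose[3]
    larva_dose_total <- f_eff * larva_food_dose
    filter_retained <- (1 - f_eff) * larva_food_dose
    larva_dose_pc <- if (cts$larvae > 0) larva_dose_total / cts$larvae
      else 0
    state$larva_dose <- state$larva_dose + larva_dose_pc

    d_inhive_pc <- if (cts$inhive > 0)
      (h_dose[1] + p_dose[1] + filter_retained) / cts$inhive else 0
    d_forager_hive_pc <- if (cts$foragers > 0)
      (h_dose[2] + p_dose[2] + h_dose[4] + wres$carrier_dose_ug) /
        cts$foragers else 0

    # ---- end-of-day effects ------------------------------------------
    trip_dose <- accumulate_forager_oral_doses(kd$trip_log)
    sq$oral_pc <- d_forager_hive_pc
    if (nrow(trip_dose)) {
      m <- match(sq$squadron, trip_dose$squadron)
      sq$oral_pc <- sq$oral_pc +
        ifelse(is.na(m), 0, trip_dose$oral_dose_ug[m]) / pmax(sq$size, 1)
    }
    sq$contact_pc <- ifelse(sq$squadron %in% names(kd_sizes) &
                              kd$deferred_contact, cdose, 0)
    alive_sizes <- ifelse(sq$alive, sq$size, 0L)
    if (nrow(kd$field_deaths)) {
      m <- match(sq$squadron, kd$field_deaths$squadron)
      alive_sizes <- pmax(alive_sizes -
                            ifelse(is.na(m), 0L, kd$field_deaths$deaths[m]),
                          0L)
    }
    q_sq <- if (!is.null(profile) && nrow(sq))
      adult_daily_mortality(sq$oral_pc, sq$contact_pc, profile,
                            background = 0) else numeric(nrow(sq))
    q_starv_adult <- h_short_frac * dem$starvation_severity_honey
    q_sq <- 1 - (1 - q_sq) * (1 - q_starv_adult)
    forager_tox_deaths <- sum(gated_binom(alive_sizes, q_sq))
    forager_deaths <- transit_deaths + knock_deaths + forager_tox_deaths
    rem <- allocate_removals(state$adults[idx_forager], forager_deaths)
    state$adults[idx_forager] <- state$adults[idx_forager] - rem

    q_inhive <- if (!is.null(profile))
      adult_daily_mortality(d_inhive_pc, 0, profile, background = 0) else 0
    q_inhive <- 1 - (1 - q_inhive) * (1 - q_starv_adult)
    ih <- seq_len(ft)
    d_ih <- gated_binom(state$adults[ih], q_inhive)
    state$adults[ih] <- state$adults[ih] - d_ih
    inhive_deaths <- sum(d_ih)

    q_larva_tox <- if (!pupal_expression)
      larval_mortality_q(larva_dose_pc, profile) else 0
    q_larva <- 1 - (1 - q_larva_tox) *
      (1 - h_short_frac * dem$starvation_severity_honey) *
      (1 - p_short_frac * dem$starvation_severity_pollen)
    d_l <- gated_binom(state$larvae, q_larva)
    state$larvae <- state$larvae - d_l
    larvae_deaths <- sum(d_l)

    d_p <- gated_binom(state$pupae, state$pupae_q)
    state$pupae <- state$pupae - d_p
    pupae_tox_deaths <- sum(d_p)

    new_pupae_q <- 0
    if (pupal_expression) {
      mean_daily <- state$larva_dose[dem$larva_dur] / dem$larva_dur
      if (mean_daily > 0) {
        m22 <- dose_response_mortality(mean_daily, larval_dr)
        new_pupae_q <- 1 - (1 - m22)^(1 / dem$pupa_dur)
      }
    }

    # division-of-labour update for tomorrow: forager losses release
    # social inhibition and pull nurses forward; a surplus restores the
    # unstressed transition age
    adults_now <- sum(state$adults)
    foragers_now <- sum(state$adults[idx_forager])
    target_foragers <- dem$forager_share_target * adults_now
    if (foragers_now < target_foragers) {
      ft_cur <- max(dem$min_forager_transition_age, ft_cur - 1L)
    } else if (foragers_now > 1.2 * target_foragers) {
      ft_cur <- min(dem$forager_transition_age, ft_cur + 1L)
    }

    # ---- aging, store shift, brood cap --------------------------------
    state$honey <- age_stores(state$honey,
                              chem_dt50_days = opts$chem_dissipation_dt50)
    state <- age_and_transition(state, dem, new_pupae_q = new_pupae_q,
                                new_eggs = eggs_laid)
    tb <- terminate_excess_brood(state, dem_day)
    state <- tb$state

    residue <- total_store_pesticide(state$honey, state$pollen)
    cts_end <- cohort_counts(state, dem_day)
    rows[[t]] <- tibble::tibble(
      day = t, abs_day = abs_day, day_of_year = doy,
      transition_age = ft,
      eggs = cts_end$eggs, larvae = cts_end$larvae, pupae = cts_end$pupae,
      inhive = cts_end$inhive, foragers = cts_end$foragers,
      adults = cts_end$adults, strength = cts_end$strength,
      eggs_laid = eggs_laid, terminated_brood = tb$terminated,
      trips = sum(fday$squadrons$trips),
      honey_day0_kJ = state$honey$energy_kJ[["day0"]],
      honey_day1_kJ = state$honey$energy_kJ[["day1"]],
      honey_day2_kJ = state$honey$energy_kJ[["day2"]],
      honey_day3_kJ = state$honey$energy_kJ[["day3"]],
      honey_day4_kJ = state$honey$energy_kJ[["day4"]],
      honey_capped_kJ = state$honey$energy_kJ[["capped"]],
      honey_total_kJ = total_store_energy(state$honey),
      pest_day0_ug = state$honey$pesticide_ug[["day0"]],
      pest_day1_ug = state$honey$pesticide_ug[["day1"]],
      pest_day2_ug = state$honey$pesticide_ug[["day2"]],
      pest_day3_ug = state$honey$pesticide_ug[["day3"]],
      pest_day4_ug = state$honey$pesticide_ug[["day4"]],
      pest_capped_ug = state$honey$pesticide_ug[["capped"]],
      pollen_g = state$pollen$mass_g,
      pollen_pest_ug = state$pollen$pesticide_ug,
      c_nectar_ug_per_kg = conc$c_nectar_ug_per_kg,
      c_pollen_ug_per_kg = conc$c_pollen_ug_per_kg,
      c_contact_mg_per_kg = conc$c_contact_mg_per_kg,
      nectar_in_kJ = inflow$nectar_energy_kJ,
      pollen_in_g = inflow$pollen_g,
      pest_in_ug = inflow$nectar_pesticide_ug +
        inflow$pollen_pesticide_ug + wres$water_to_honey_pesticide_ug,
      dose_forager_trip_ug = inflow$forager_oral_ug,
      dose_forager_hive_pc_ug = d_forager_hive_pc,
      dose_inhive_pc_ug = d_inhive_pc,
      dose_larva_pc_ug = larva_dose_pc,
      contact_dose_pc_ug = cdose,
      deaths_foragers = forager_deaths,
      deaths_field = transit_deaths + knock_deaths,
      deaths_knockdown = knock_deaths,
      deaths_inhive = inhive_deaths,
      deaths_larvae = larvae_deaths,
      deaths_pupae_tox = pupae_tox_deaths,
      honey_shortfall_kJ = ch$shortfall_kJ,
      pollen_shortfall_g = cp$shortfall_g,
      water_collected_kg = wres$collected_kg,
      water_unmet_kg = wres$unmet_kg,
      water_carrier_dose_ug = wres$carrier_dose_ug,
      cum_pest_in_ug = cum_in,
      cum_dose_out_ug = cum_out,
      store_pest_ug = residue)
  }

  structure(list(daily = dplyr::bind_rows(rows), final_state = state,
                 scenario = sc),
            class = "beetox_run")
}

#' Run replicate simulations
#'
#' Derives one sub-seed per replicate deterministically from the master
#' seed, so a fixed `(scenario, seed)` reproduces every output exactly and
#' each replicate is independent of how many others run. Control runs of
#' a paired design reuse the same sub-seeds (see
#' [run_paired_experiment()]).
#'
#' @param sc A `"beetox_scenario"`.
#' @param n_replicates Number of replicate runs (default 10).
#' @param seed Master seed (integer).
#' @param verbose Passed to [simulate_colony()].
#' @return A `"beetox_sim"`: list with `daily` (tibble incl. `replicate`),
#'   `seeds`, `scenario`.
#' @export
run_replicates <- function(sc, n_replicates = 10, seed = 1,
                           verbose = FALSE) {
  seeds <- derive_seeds(seed, n_replicates)
  daily <- purrr::map_dfr(seq_len(n_replicates), function(k) {
    run <- simulate_colony(sc, seed = seeds[k], verbose = verbose)
    dplyr::mutate(run$daily, replicate = k, .before = 1)
  })
  structure(list(daily = daily, seeds = seeds, scenario = sc),
            class = "beetox_sim")
}

# fixed-counter substream derivation; sub-seeds stay below 2^31
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((abs(as.numeric(seed)) * 2011 + 7919 * seq_len(n)) %%
               2147483646 + 1)
}

#' @export
print.beetox_run <- function(x, ...) {
  last <- x$daily[nrow(x$daily), ]
  cat(sprintf(
    "<beetox_run> %d days; final strength %d (adults %d), honey %.0f kJ\n",
    nrow(x$daily), last$strength, last$adults, last$honey_total_kJ))
  invisible(x)
}

#' @export
print.beetox_sim <- function(x, ...) {
  n <- max(x$daily$replicate)
  cat(sprintf("<beetox_sim> %d replicate(s) x %d days\n",
              n, nrow(x$daily) / n))
  invisible(x)
}
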