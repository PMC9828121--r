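test_that("tunnel scenarios carry the study application rates and phases", {
  d_dim <- dimethoate_tunnel_design()
  sc <- build_tunnel_scenario(d_dim, dimethoate_profile(),
                              rate_kg_per_ha = 0.4)
  expect_equal(sc$applications$rate_kg_per_ha, 0.4)
  sc_f <- build_tunnel_scenario(fenoxycarb_tunnel_design(),
                                fenoxycarb_profile(), rate_kg_per_ha = 0.3)
  expect_equal(sc_f$applications$rate_kg_per_ha, 0.3)
  # two phases: treated tunnel patch, then untreated monitoring site
  expect_length(sc$landscape_phases, 2)
  expect_true(sc$landscape_phases[[1]]$patches$treated)
  expect_false(sc$landscape_phases[[2]]$patches$treated)
  expect_equal(sc$landscape_phases[[2]]$switch_day,
               sc$start_day + d_dim$exposure_phase_days)
  # application falls inside the tunnel phase
  expect_gte(sc$applications$day, sc$start_day)
  expect_lt(sc$applications$day, sc$landscape_phases[[2]]$switch_day)
  # a control build differs only by the absent pesticide
  ctrl <- build_tunnel_scenario(d_dim, NULL)
  expect_null(ctrl$pesticide)
  expect_equal(nrow(ctrl$applications), 0)
  expect_identical(ctrl$weather, sc$weather)
  expect_identical(ctrl$colony_init, sc$colony_init)
})

test_that("paired runs with an inert profile show exactly zero effect", {
  design <- tunnel_design(exposure_phase_days = 6, monitoring_days = 10,
                          n_eggs = 600, n_larvae = 1200, n_pupae = 1800,
                          n_adults = 2500)
  sc <- build_tunnel_scenario(design, inert_profile(),
                              rate_kg_per_ha = 0.4)
  eff <- run_paired_experiment(sc, n_replicates = 2, seed = 3)
  expect_true(all(abs(eff$daily$rel_effect_pct) < 1e-12))
  expect_true(all(!eff$daily$control_collapsed))
})

test_that("the relative effect is 100 x (1 - treatment/control)", {
  design <- tunnel_design(exposure_phase_days = 6, monitoring_days = 8,
                          n_adults = 2500)
  sc <- build_tunnel_scenario(design, dimethoate_profile(),
                              rate_kg_per_ha = 0.4)
  eff <- run_paired_experiment(sc, n_replicates = 3, seed = 5)
  d <- eff$daily
  expect_equal(d$rel_effect_pct,
               100 * (1 - d$strength_mean_t / d$strength_mean_c))
  # assessment day: application + two brood cycles, clipped to run end
  expect_equal(eff$assessment_abs_day,
               min(eff$application_abs_day + 42,
                   sc$start_day + sc$duration - 1))
  g <- glance(eff)
  expect_true(all(c("rel_effect_pct", "immediate_effect_pct")
                  %in% names(g)))
})

test_that("a higher application rate does not lessen the colony effect", {
  design <- tunnel_design(exposure_phase_days = 8, monitoring_days = 20,
                          n_adults = 4000)
  lo <- build_tunnel_scenario(design, dimethoate_profile(),
                              rate_kg_per_ha = 0.1)
  hi <- build_tunnel_scenario(design, dimethoate_profile(),
                              rate_kg_per_ha = 0.8)
  e_lo <- run_paired_experiment(lo, n_replicates = 4, seed = 11)
  e_hi <- run_paired_experiment(hi, n_replicates = 4, seed = 11)
  expect_lte(glance(e_lo)$rel_effect_pct,
             glance(e_hi)$rel_effect_pct + 1e-9)
})

test_that("modes of action separate: adult-acute hits adults first, larval hits brood first", {
  e_dim <- run_paired_experiment(
    build_tunnel_scenario(dimethoate_tunnel_design(),
                          dimethoate_profile(), rate_kg_per_ha = 0.4),
    n_replicates = 3, seed = 19)
  e_fen <- run_paired_experiment(
    build_tunnel_scenario(fenoxycarb_tunnel_design(),
                          fenoxycarb_profile(), rate_kg_per_ha = 0.3),
    n_replicates = 3, seed = 19)
  first_day <- function(eff, col) {
    d <- tidy(eff)
    hit <- which(d[[col]] >= 10)
    if (length(hit)) d$day[min(hit)] else Inf
  }
  # dimethoate: adults depressed no later than brood
  expect_lte(first_day(e_dim, "rel_effect_adults_pct"),
             first_day(e_dim, "rel_effect_brood_pct"))
  # fenoxycarb: brood depressed first, adults lag by a development period
  fb <- first_day(e_fen, "rel_effect_brood_pct")
  fa <- first_day(e_fen, "rel_effect_adults_pct")
  expect_lt(fb, fa)
  expect_gte(fa - fb, 5)
})

test_that("autoplot and tidy/glance work on every result type", {
  design <- tunnel_design(exposure_phase_days = 5, monitoring_days = 6,
                          n_adults = 2000)
  sc <- build_tunnel_scenario(design, dimethoate_profile(),
                              rate_kg_per_ha = 0.4)
  run <- simulate_colony(sc, seed = 2)
  sim <- run_replicates(sc, n_replicates = 2, seed = 2)
  eff <- run_paired_experiment(sc, n_replicates = 2, seed = 2)
  expect_s3_class(tidy(run), "tbl_df")
  expect_s3_class(glance(sim), "tbl_df")
  expect_s3_class(tidy(eff), "tbl_df")
  expect_s3_class(ggplot2::autoplot(sim), "ggplot")
  expect_s3_class(ggplot2::autoplot(eff), "ggplot")
  expect_s3_class(plot_store_pesticide(run), "ggplot")
})
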