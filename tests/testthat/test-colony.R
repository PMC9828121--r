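test_that("egg laying is capped by remaining nursing capacity", {
  pars <- demography_params()
  # 100 nurses can handle 300 cells; brood already at 300 -> no laying
  expect_equal(lay_eggs(pars$laying_peak_doy, 100, 300, pars), 0L)
  expect_equal(lay_eggs(pars$laying_peak_doy, 0, 0, pars), 0L)
  # seasonal potential 1600 at the peak, capacity 2000 -> min wins
  expect_equal(lay_eggs(pars$laying_peak_doy, 1000, 1000, pars), 1600L)
  # capacity 500 below potential -> capacity wins
  expect_equal(lay_eggs(pars$laying_peak_doy, 500, 1000, pars), 500L)
})

test_that("excess brood is terminated youngest-first down to the cap", {
  pars <- demography_params()
  st <- colony_structure(
    eggs = c(100, 100, 50), larvae = c(20, 20, 20, 20, 10, 10),
    pupae = rep(0, 12),
    adults = c(rep(0, 20), 100, rep(0, pars$adult_max_age - 21)),
    params = pars)
  # nurses = 100 (ages < 21), cap = 300, brood = 350 -> 50 terminated
  r <- terminate_excess_brood(st, pars)
  expect_equal(r$terminated, 50L)
  expect_equal(sum(r$state$eggs) + sum(r$state$larvae), 300)
  expect_equal(r$state$eggs[1], 50)            # youngest class hit first
  # under the cap -> untouched
  r2 <- terminate_excess_brood(r$state, pars)
  expect_equal(r2$terminated, 0L)
  # no nurses -> all care-dependent brood terminated
  st$adults[] <- 0L
  r3 <- terminate_excess_brood(st, pars)
  expect_equal(sum(r3$state$eggs) + sum(r3$state$larvae), 0)
})

test_that("aging conserves bees and routes stage transitions", {
  pars <- demography_params(mort_egg = 0, mort_larva = 0, mort_pupa = 0,
                            mort_inhive = 0, mort_forager = 0)
  st <- init_colony_even(n_eggs = 300, n_larvae = 600, n_pupae = 1200,
                         n_adults = 2000, params = pars)
  before <- cohort_counts(st, pars)
  oldest_pupae <- st$pupae[pars$pupa_dur]
  oldest_adults <- st$adults[pars$adult_max_age]
  st2 <- age_and_transition(st, pars, new_eggs = 0)
  after <- cohort_counts(st2, pars)
  # with laying and mortality off, only max-age adults leave
  expect_equal(after$strength, before$strength - oldest_adults)
  # emerged pupae appear as age-0 adults
  expect_equal(st2$adults[1], oldest_pupae)
  # forager mortality 1: every forager dies; the only foragers next day
  # are the nurses that crossed the transition age overnight
  pars2 <- demography_params(mort_egg = 0, mort_larva = 0, mort_pupa = 0,
                             mort_inhive = 0, mort_forager = 1)
  st3 <- age_and_transition(st, pars2)
  expect_equal(cohort_counts(st3, pars2)$foragers,
               st$adults[pars2$forager_transition_age])
})

test_that("closed-population bookkeeping holds under stochastic mortality", {
  pars <- demography_params()
  st <- quick_colony()
  thin <- function(v, p) if (p <= 0) v else v - rbinom(length(v), v, p)
  ft <- pars$forager_transition_age
  for (i in 1:10) {
    set.seed(100 + i)
    st2 <- age_and_transition(st, pars, new_eggs = 50)
    # replay the identical draws to count survivors independently
    set.seed(100 + i)
    s_eggs <- thin(st$eggs, pars$mort_egg)
    s_larvae <- thin(st$larvae, pars$mort_larva)
    s_pupae <- thin(st$pupae, pars$mort_pupa)
    s_in <- thin(st$adults[1:ft], pars$mort_inhive)
    s_for <- thin(st$adults[-(1:ft)], pars$mort_forager)
    s_adults <- c(s_in, s_for)
    survivors <- sum(s_eggs) + sum(s_larvae) + sum(s_pupae) + sum(s_adults)
    # exact identity: next-day strength = survivors + eggs laid
    #                 - survivors of the max-age adult class (aged out)
    expect_equal(cohort_counts(st2, pars)$strength,
                 survivors + 50 - s_adults[length(s_adults)])
    st <- st2
  }
})

test_that("daily demand is linear in cohort counts", {
  pars <- demography_params()
  st <- quick_colony(n_adults = 2000)
  d1 <- daily_demand(st, pars)
  expect_equal(sum(d1$honey_kJ[d1$class != "larvae"]),
               2000 * pars$honey_need_per_adult_kJ)
  # empty colony -> zero demand
  st0 <- colony_structure(rep(0, 3), rep(0, 6), rep(0, 12),
                          rep(0, pars$adult_max_age), params = pars)
  expect_true(all(daily_demand(st0, pars)$honey_kJ == 0))
  expect_true(all(daily_demand(st0, pars)$pollen_g == 0))
  # doubling all counts doubles demand
  st2 <- st
  st2$eggs <- 2L * st$eggs; st2$larvae <- 2L * st$larvae
  st2$pupae <- 2L * st$pupae; st2$adults <- 2L * st$adults
  d2 <- daily_demand(st2, pars)
  expect_equal(d2$honey_kJ, 2 * d1$honey_kJ)
  expect_equal(d2$pollen_g, 2 * d1$pollen_g)
  # 10,000 adults at h kJ/day -> 10,000 h kJ
  st3 <- colony_structure(rep(0, 3), rep(0, 6), rep(0, 12),
                          c(rep(250, 40), rep(0, pars$adult_max_age - 40)),
                          params = pars)
  d3 <- daily_demand(st3, pars)
  expect_equal(sum(d3$honey_kJ), 10000 * pars$honey_need_per_adult_kJ)
})
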