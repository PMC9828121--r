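test_that("matrix concentrations follow RUD x rate with first-order decay", {
  prof <- pesticide_profile(name = "x", rud_nectar = 4.4, rud_pollen = 12.6,
                            rud_contact_foliar = 14, dt50_plant = 2)
  apps <- tibble::tibble(day = 10, rate_kg_per_ha = 0.4)
  c0 <- matrix_concentrations(10, apps, prof)
  expect_equal(c0$c_nectar_ug_per_kg, 0.4 * 4.4 * 1000)
  expect_equal(c0$c_pollen_ug_per_kg, 0.4 * 12.6 * 1000)
  expect_equal(c0$c_contact_mg_per_kg, 0.4 * 14)
  # one half-life later the food matrices halve; contact is gone
  c2 <- matrix_concentrations(12, apps, prof)
  expect_equal(c2$c_nectar_ug_per_kg, c0$c_nectar_ug_per_kg / 2)
  expect_equal(c2$c_contact_mg_per_kg, 0)
  # before any application, and with no applications, all zero
  expect_equal(matrix_concentrations(9, apps, prof)$c_nectar_ug_per_kg, 0)
  none <- matrix_concentrations(10, NULL, prof)
  expect_true(all(c(none$c_nectar_ug_per_kg, none$c_pollen_ug_per_kg,
                    none$c_contact_mg_per_kg) == 0))
  # multiple applications superpose
  apps2 <- tibble::tibble(day = c(10, 12), rate_kg_per_ha = c(0.4, 0.4))
  c3 <- matrix_concentrations(12, apps2, prof)
  expect_equal(c3$c_nectar_ug_per_kg, 0.4 * 4.4 * 1000 * (0.5 + 1))
  # monotone non-increasing after the last application
  cc <- vapply(12:20, function(d)
    matrix_concentrations(d, apps2, prof)$c_nectar_ug_per_kg, numeric(1))
  expect_true(all(diff(cc) <= 0))
})

test_that("a measured concentration series overrides the RUD route", {
  mc <- tibble::tibble(day = 10:12, c_nectar_ug_per_kg = c(500, 400, 300),
                       c_pollen_ug_per_kg = c(50, 40, 30))
  prof <- pesticide_profile(name = "x", rud_nectar = 4.4,
                            measured_concentrations = mc)
  apps <- tibble::tibble(day = 10, rate_kg_per_ha = 0.4)
  expect_equal(matrix_concentrations(11, apps, prof)$c_nectar_ug_per_kg,
               400)
  # outside the series the RUD computation resumes
  expect_equal(matrix_concentrations(13, apps, prof)$c_nectar_ug_per_kg,
               0.4 * 4.4 * 1000 * 2^(-3 / prof$dt50_plant))
})

test_that("contact dose converts surface residue through body weight", {
  prof <- pesticide_profile(name = "x", rud_contact_foliar = 10,
                            forager_weight_g = 0.1)
  expect_equal(contact_dose(1, prof), 1.0)       # 10 mg/kg x 0.1 g = 1 ug
  expect_equal(contact_dose(0, prof), 0)
  prof2 <- pesticide_profile(name = "x", rud_contact_foliar = 10,
                             forager_weight_g = 0.2)
  expect_equal(contact_dose(1, prof2), 2 * contact_dose(1, prof))
})

test_that("forager oral doses replay exactly from the trip log", {
  set.seed(8)
  conc <- tibble::tibble(c_nectar_ug_per_kg = 1000,
                         c_pollen_ug_per_kg = 3000,
                         c_contact_mg_per_kg = 0, valid_for_day = 1)
  out <- run_foraging_day(allocate_foragers(600, 0.4), quick_patches(),
                          quick_weather(1)[1, ], conc)
  led <- accumulate_forager_oral_doses(out$trip_log)
  # brute-force oracle over individual trips
  tl <- out$trip_log
  oracle <- tapply(
    ifelse(tl$type == "nectar" & tl$treated,
           tl$consumed_nectar_kg * tl$c_nectar_ug_per_kg, 0),
    tl$squadron, sum)
  expect_equal(led$oral_dose_ug[match(names(oracle), led$squadron)],
               as.numeric(oracle), tolerance = 1e-15)
  # one trip consuming 20 mg nectar at 1,000 ug/kg -> 0.02 ug
  one <- empty_trip_log() |>
    tibble::add_row(squadron = 1L, type = "nectar", patch_id = "p",
                    load = 50, load_kg = 5.5e-5,
                    energy_kJ = 0.4, consumed_nectar_kg = 2e-5,
                    flight_distance_m = 100, duration_h = 0.4,
                    energy_cost_kJ = 0.01, treated = TRUE,
                    c_nectar_ug_per_kg = 1000, c_pollen_ug_per_kg = 0,
                    died_in_transit = FALSE)
  expect_equal(accumulate_forager_oral_doses(one)$oral_dose_ug, 0.02)
  # untreated trips contribute nothing
  one$treated <- FALSE
  expect_equal(accumulate_forager_oral_doses(one)$oral_dose_ug, 0)
})

test_that("knock-down withholds the killed share of returning loads", {
  set.seed(9)
  conc <- tibble::tibble(c_nectar_ug_per_kg = 1000, c_pollen_ug_per_kg = 0,
                         c_contact_mg_per_kg = 0, valid_for_day = 1)
  out <- run_foraging_day(allocate_foragers(500, 0), quick_patches(),
                          quick_weather(1)[1, ], conc)
  sizes <- stats::setNames(out$squadrons$size, out$squadrons$squadron)
  kd_on <- knockdown_profile(TRUE)
  kd_off <- knockdown_profile(FALSE)
  dose <- contact_dose(1, kd_on)           # far above the contact LD50
  set.seed(101)
  r_on <- apply_knockdown(out$trip_log, sizes, dose, kd_on)
  set.seed(101)
  r_off <- apply_knockdown(out$trip_log, sizes, dose, kd_off)
  expect_false(r_on$deferred_contact)
  expect_true(r_off$deferred_contact)
  expect_equal(sum(r_off$field_deaths$deaths), 0)
  expect_gt(sum(r_on$field_deaths$deaths), 0.8 * sum(sizes))
  in_on <- trip_inflows(r_on$trip_log)
  in_off <- trip_inflows(r_off$trip_log)
  expect_lt(in_on$nectar_pesticide_ug, in_off$nectar_pesticide_ug)
  # zero contact dose: both settings identical, full return
  r0 <- apply_knockdown(out$trip_log, sizes, 0, kd_on)
  expect_true(all(r0$trip_log$return_fraction == 1))
  expect_equal(sum(r0$field_deaths$deaths), 0)
})
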