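test_that("nectar energy conversion follows the molarity formula", {
  # 1.5 mol/L at density 1.1: 1.5 * (1000/1.1) * 5.75 kJ/mmol
  expect_equal(nectar_energy_density(1.5, 1.1), 1.5 * 1000 / 1.1 * 5.75)
  expect_equal(nectar_to_energy_concentration(700, 7000), 0.1)
  expect_identical(nectar_to_energy_concentration(0, 5000), 0)
  # halving energy density doubles ug/kJ
  expect_equal(nectar_to_energy_concentration(100, 2500),
               2 * nectar_to_energy_concentration(100, 5000))
  expect_error(nectar_to_energy_concentration(10, 0), "energy density")
})

test_that("deposits go to day 0 and the mixed pollen pool, additively", {
  s <- honey_stores()
  p <- pollen_store(mass_g = 100, pesticide_ug = 10)
  r <- deposit_inflows(s, p, nectar_energy_kJ = 50,
                       nectar_pesticide_ug = 5, pollen_mass_g = 20,
                       pollen_pesticide_ug = 8)
  expect_equal(r$stores$energy_kJ[["day0"]], 50)
  expect_equal(r$stores$pesticide_ug[["day0"]], 5)
  # pollen concentration after mixing = total ug / total g
  expect_equal(r$pollen$pesticide_ug / r$pollen$mass_g, 18 / 120)
  # two deposits commute
  a <- deposit_inflows(r$stores, r$pollen, 10, 1, 5, 2)
  b1 <- deposit_inflows(s, p, 10, 1, 5, 2)
  b <- deposit_inflows(b1$stores, b1$pollen, 50, 5, 20, 8)
  expect_equal(a, b)
})

test_that("honey is consumed freshest-first with proportional dose", {
  s <- honey_stores(energy_kJ = c(10, 5, 0, 0, 0, 0))
  r <- consume_honey(s, 12)
  expect_equal(r$delivered_kJ, 12)
  expect_equal(r$stores$energy_kJ[["day0"]], 0)
  expect_equal(r$stores$energy_kJ[["day1"]], 3)
  # compartment at 0.5 ug/kJ, withdraw 4 kJ -> 2 ug removed
  s2 <- honey_stores(energy_kJ = c(8, 0, 0, 0, 0, 0),
                     pesticide_ug = c(4, 0, 0, 0, 0, 0))
  r2 <- consume_honey(s2, 4)
  expect_equal(r2$delivered_dose_ug, 2)
  expect_equal(r2$stores$pesticide_ug[["day0"]], 2)
  # zero demand is a no-op; shortfall is reported
  expect_equal(consume_honey(s2, 0)$stores, s2)
  expect_equal(consume_honey(s2, 100)$shortfall_kJ, 92)
})

test_that("store aging shifts one compartment per day and conserves mass", {
  s <- honey_stores(energy_kJ = c(10, 0, 0, 0, 0, 0),
                    pesticide_ug = c(3, 0, 0, 0, 0, 0))
  a <- age_stores(s)
  expect_equal(unname(a$energy_kJ), c(0, 10, 0, 0, 0, 0))
  expect_equal(unname(a$pesticide_ug), c(0, 3, 0, 0, 0, 0))
  # five days with no inflow or consumption -> everything capped
  for (i in 1:4) a <- age_stores(a)
  expect_equal(a$energy_kJ[["capped"]], 10)
  expect_equal(a$pesticide_ug[["capped"]], 3)
  # totals unchanged by aging; no chemical decay by default
  set.seed(5)
  s3 <- honey_stores(energy_kJ = runif(6, 0, 50),
                     pesticide_ug = runif(6, 0, 5))
  a3 <- age_stores(s3)
  expect_equal(sum(a3$energy_kJ), sum(s3$energy_kJ))
  expect_equal(sum(a3$pesticide_ug), sum(s3$pesticide_ug))
  # optional in-hive chemical decay is first order
  a4 <- age_stores(s3, chem_dt50_days = 2)
  expect_equal(sum(a4$pesticide_ug), sum(s3$pesticide_ug) * 2^(-1 / 2))
})

test_that("pollen pool withdrawal clamps and carries its concentration", {
  p <- pollen_store(mass_g = 100, pesticide_ug = 20)   # 0.2 ug/g
  r <- consume_pollen(p, 10)
  expect_equal(r$delivered_dose_ug, 2)
  expect_equal(r$pollen$mass_g, 90)
  expect_equal(consume_pollen(pollen_store(), 5)$delivered_g, 0)
  r2 <- consume_pollen(p, 500)
  expect_equal(r2$delivered_g, 100)
  expect_equal(r2$shortfall_g, 400)
})

# independent six-compartment hand model: plain vectors, explicit loops
hand_model <- function(energy, pest, ops) {
  for (op in ops) {
    if (op$kind == "inflow") {
      energy[1] <- energy[1] + op$e
      pest[1] <- pest[1] + op$p
    } else if (op$kind == "consume") {
      left <- op$e
      for (k in 1:6) {
        take <- min(left, energy[k])
        if (take > 0) {
          pest[k] <- pest[k] * (1 - take / energy[k])
          energy[k] <- energy[k] - take
          left <- left - take
        }
      }
    } else {
      energy <- c(0, energy[1:4], energy[5] + energy[6])
      pest <- c(0, pest[1:4], pest[5] + pest[6])
    }
  }
  list(energy = energy, pest = pest)
}

test_that("engine store mechanics match the hand model on random sequences", {
  set.seed(99)
  for (rep in 1:30) {
    e0 <- round(runif(6, 0, 40), 2)
    p0 <- round(runif(6, 0, 4), 3)
    p0[e0 == 0] <- 0
    ops <- lapply(1:12, function(i) {
      kind <- sample(c("inflow", "consume", "age"), 1)
      list(kind = kind, e = round(runif(1, 0, 30), 2),
           p = round(runif(1, 0, 3), 3))
    })
    s <- honey_stores(energy_kJ = e0, pesticide_ug = p0)
    for (op in ops) {
      if (op$kind == "inflow") {
        s <- deposit_inflows(s, pollen_store(), op$e, op$p)$stores
      } else if (op$kind == "consume") {
        s <- consume_honey(s, op$e)$stores
      } else {
        s <- age_stores(s)
      }
    }
    h <- hand_model(e0, p0, ops)
    expect_equal(unname(s$energy_kJ), h$energy, tolerance = 1e-12)
    expect_equal(unname(s$pesticide_ug), h$pest, tolerance = 1e-10)
  }
})

# consume under an arbitrary fixed compartment priority ordering
consume_ordered <- function(energy, pest, demand, order) {
  dose <- 0
  for (k in order) {
    take <- min(demand, energy[k])
    if (take > 0) {
      d <- pest[k] * take / energy[k]
      dose <- dose + d
      pest[k] <- pest[k] - d
      energy[k] <- energy[k] - take
      demand <- demand - take
    }
  }
  dose
}

test_that("freshest-first maximises the application-day delivered dose", {
  # contaminated fresh nectar sits in the youngest compartments; any
  # other consumption priority delivers at most the freshest-first dose
  set.seed(7)
  all_orders <- as.matrix(expand.grid(rep(list(1:6), 6)))
  all_orders <- all_orders[apply(all_orders, 1, function(r)
    length(unique(r)) == 6), , drop = FALSE]          # 720 permutations
  for (case in 1:5) {
    energy <- runif(6, 1, 20)
    # concentration decreasing with compartment age (fresh = most toxic)
    conc <- sort(runif(6, 0, 1), decreasing = TRUE)
    pest <- energy * conc
    demand <- runif(1, 5, sum(energy))
    s <- honey_stores(energy_kJ = energy, pesticide_ug = pest)
    engine_dose <- consume_honey(s, demand)$delivered_dose_ug
    perm_doses <- apply(all_orders, 1, function(ord)
      consume_ordered(energy, pest, demand, ord))
    expect_equal(engine_dose, consume_ordered(energy, pest, demand, 1:6),
                 tolerance = 1e-12)
    expect_true(all(engine_dose >= perm_doses - 1e-10))
  }
})
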