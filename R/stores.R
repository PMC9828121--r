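#' In-hive honey and pollen stores
#'
#' Honey ripens for up to five days before being capped: incoming nectar
#' enters the day-0 compartment, is shifted one compartment per day
#' (day 0 -> day 1 -> ... -> day 4) and finally enters the capped store.
#' Each compartment carries an energy content (kJ) and a pesticide mass
#' (ug) and is fully mixed internally. Honey is accounted in energy units
#' throughout, so nectar ripening needs no explicit evaporation model.
#' The pollen store is a single fully mixed pool (mass in g, pesticide in
#' ug): colonies hold far less pollen than honey, so incoming pesticide
#' immediately contributes to the hive-wide pollen concentration.
#'
#' @param energy_kJ Numeric length 6: energy in compartments day0..day4 and
#'   capped. Pre-existing (ripe) honey should seed the capped compartment.
#' @param pesticide_ug Numeric length 6, pesticide mass per compartment.
#' @return A `"honey_stores"` object.
#' @export
honey_stores <- function(energy_kJ = numeric(6), pesticide_ug = numeric(6)) {
  stopifnot(length(energy_kJ) == 6, length(pesticide_ug) == 6,
            all(energy_kJ >= 0), all(pesticide_ug >= 0))
  nm <- c("day0", "day1", "day2", "day3", "day4", "capped")
  structure(list(energy_kJ = stats::setNames(as.numeric(energy_kJ), nm),
                 pesticide_ug = stats::setNames(as.numeric(pesticide_ug), nm)),
            class = "honey_stores")
}

#' @rdname honey_stores
#' @param mass_g Pollen pool mass, g.
#' @export
pollen_store <- function(mass_g = 0, pesticide_ug = 0) {
  stopifnot(mass_g >= 0, pesticide_ug >= 0)
  structure(list(mass_g = as.numeric(mass_g),
                 pesticide_ug = as.numeric(pesticide_ug)),
            class = "pollen_store")
}

#' @export
print.honey_stores <- function(x, ...) {
  cat("<honey_stores> kJ:", paste(signif(x$energy_kJ, 4), collapse = " "),
      "\n            ug:", paste(signif(x$pesticide_ug, 4), collapse = " "),
      "\n")
  invisible(x)
}

#' Energy density of nectar from its sucrose molarity
#'
#' \eqn{E} (kJ/kg) `= molarity * (1000 / density) * e_sucrose_kJ_per_mmol`,
#' i.e. mmol sucrose per kg of nectar times the combustion energy of one
#' mmol of sucrose (0.3423 g/mmol x 16.8 kJ/g = 5.75 kJ/mmol).
#'
#' @param sucrose_mol_per_L Sucrose molarity, mol/L.
#' @param density_kg_per_L Nectar density, kg/L (default 1.1).
#' @param e_sucrose_kJ_per_mmol Energy per mmol sucrose (default 5.75).
#' @return Energy density, kJ/kg.
#' @export
nectar_energy_density <- function(sucrose_mol_per_L,
                                  density_kg_per_L = 1.1,
                                  e_sucrose_kJ_per_mmol = 5.75) {
  stopifnot(sucrose_mol_per_L >= 0, density_kg_per_L > 0)
  sucrose_mol_per_L * (1000 / density_kg_per_L) * e_sucrose_kJ_per_mmol
}

#' Convert a nectar concentration from ug/kg to ug/kJ
#'
#' Honey consumption is driven by energetic content rather than nectar
#' volume, so in-hive pesticide bookkeeping uses ug per kJ.
#'
#' @param c_nectar_ug_per_kg Concentration in nectar, ug/kg.
#' @param nectar_energy_kJ_per_kg Energy density of that nectar, kJ/kg; > 0.
#' @return Concentration in ug/kJ.
#' @export
nectar_to_energy_concentration <- function(c_nectar_ug_per_kg,
                                           nectar_energy_kJ_per_kg) {
  stopifnot(all(c_nectar_ug_per_kg >= 0))
  if (any(nectar_energy_kJ_per_kg <= 0))
    stop("nectar energy density must be > 0")
  c_nectar_ug_per_kg / nectar_energy_kJ_per_kg
}

#' Deposit the day's foraging inflows into the stores
#'
#' Nectar (as energy plus its pesticide mass) enters the day-0 honey
#' compartment; pollen mixes instantly into the hive-wide pollen pool.
#'
#' @param stores A [honey_stores()] object.
#' @param pollen A [pollen_store()] object.
#' @param nectar_energy_kJ,nectar_pesticide_ug Nectar inflow.
#' @param pollen_mass_g,pollen_pesticide_ug Pollen inflow.
#' @return List with updated `stores` and `pollen`.
#' @export
deposit_inflows <- function(stores, pollen,
                            nectar_energy_kJ = 0, nectar_pesticide_ug = 0,
                            pollen_mass_g = 0, pollen_pesticide_ug = 0) {
  stopifnot(nectar_energy_kJ >= 0, nectar_pesticide_ug >= 0,
            pollen_mass_g >= 0, pollen_pesticide_ug >= 0)
  stores$energy_kJ[["day0"]] <- stores$energy_kJ[["day0"]] + nectar_energy_kJ
  stores$pesticide_ug[["day0"]] <-
    stores$pesticide_ug[["day0"]] + nectar_pesticide_ug
  pollen$mass_g <- pollen$mass_g + pollen_mass_g
  pollen$pesticide_ug <- pollen$pesticide_ug + pollen_pesticide_ug
  list(stores = stores, pollen = pollen)
}

#' Withdraw honey energy, freshest compartment first
#'
#' Bees feed from the day-0 store first and move to day 1, day 2, ... and
#' finally the capped store only as each compartment empties. Within a
#' compartment the withdrawn pesticide dose is proportional to the
#' withdrawn energy (full mixing), so the active ingredient leaves the
#' stores with consumption ("biological dissipation"). This
#' freshest-first preference maximises exposure on and immediately after
#' the application day.
#'
#' @param stores A [honey_stores()] object.
#' @param demand_kJ Energy demand, kJ; >= 0.
#' @return List: `delivered_kJ`, `delivered_dose_ug`, `shortfall_kJ`,
#'   updated `stores`.
#' @export
consume_honey <- function(stores, demand_kJ) {
  stopifnot(demand_kJ >= 0)
  remaining <- demand_kJ
  delivered <- 0
  dose <- 0
  for (k in names(stores$energy_kJ)) {
    if (remaining <= 0) break
    avail <- stores$energy_kJ[[k]]
    if (avail <= 0) next
    take <- min(avail, remaining)
    frac <- take / avail
    d <- stores$pesticide_ug[[k]] * frac
    stores$energy_kJ[[k]] <- avail - take
    stores$pesticide_ug[[k]] <- stores$pesticide_ug[[k]] - d
    if (stores$energy_kJ[[k]] <= 0) stores$pesticide_ug[[k]] <- 0
    delivered <- delivered + take
    dose <- dose + d
    remaining <- remaining - take
  }
  list(delivered_kJ = delivered, delivered_dose_ug = dose,
       shortfall_kJ = max(0, demand_kJ - delivered), stores = stores)
}

#' Age the honey compartments by one day
#'
#' End-of-day shift: whatever remains in day 4 enters the capped store;
#' each younger compartment moves up one day; day 0 empties. Pesticide
#' moves with its energy, so totals are conserved exactly. An optional
#' first-order in-hive chemical decay can be applied after the shift; the
#' default is none, because consumption alone ("biological dissipation")
#' is the defensible default unless data separate biological from
#' chemical dissipation.
#'
#' @param stores A [honey_stores()] object.
#' @param chem_dt50_days In-hive chemical half-life, days; `Inf` (default)
#'   disables chemical decay.
#' @return Updated `honey_stores`.
#' @export
age_stores <- function(stores, chem_dt50_days = Inf) {
  e <- stores$energy_kJ
  p <- stores$pesticide_ug
  e[["capped"]] <- e[["capped"]] + e[["day4"]]
  p[["capped"]] <- p[["capped"]] + p[["day4"]]
  for (k in 5:2) {
    e[[k]] <- e[[k - 1]]
    p[[k]] <- p[[k - 1]]
  }
  e[["day0"]] <- 0
  p[["day0"]] <- 0
  if (is.finite(chem_dt50_days)) {
    stopifnot(chem_dt50_days > 0)
    p <- p * 2^(-1 / chem_dt50_days)
  }
  stores$energy_kJ <- e
  stores$pesticide_ug <- p
  stores
}

#' Withdraw pollen from the fully mixed pool
#'
#' @param pollen A [pollen_store()] object.
#' @param demand_g Pollen demand, g; >= 0.
#' @return List: `delivered_g`, `delivered_dose_ug`, `shortfall_g`,
#'   updated `pollen`.
#' @export
consume_pollen <- function(pollen, demand_g) {
  stopifnot(demand_g >= 0)
  take <- min(demand_g, pollen$mass_g)
  dose <- if (pollen$mass_g > 0) pollen$pesticide_ug * take / pollen$mass_g
          else 0
  pollen$mass_g <- pollen$mass_g - take
  pollen$pesticide_ug <- pollen$pesticide_ug - dose
  if (pollen$mass_g <= 0) pollen$pesticide_ug <- 0
  list(delivered_g = take, delivered_dose_ug = dose,
       shortfall_g = max(0, demand_g - take), pollen = pollen)
}

total_store_pesticide <- function(stores, pollen) {
  sum(stores$pesticide_ug) + pollen$pesticide_ug
}

total_store_energy <- function(stores) sum(stores$energy_kJ)
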