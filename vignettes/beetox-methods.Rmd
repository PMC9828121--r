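---
title: "beetox: model description and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{beetox: model description and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(beetox)
```

`beetox` simulates a honeybee colony through daily time steps and lets
pesticide exposure of every cohort emerge from behaviour: foragers pick
up residues in the field, the hive routes contaminated food through a
ripening chain, and standard-test dose–response curves convert the
resulting doses into survival. This vignette describes the model, its
assumptions and parameters, the synthetic scenarios it ships with, and
the numerical and design choices a user should know about.

## Daily schedule

Each simulated day runs, in order:

1. **Concentrations.** Nectar, pollen and contact-matrix concentrations
   are computed from the application history (or taken from a measured
   time series if the profile carries one).
2. **Laying.** The queen lays `min(seasonal potential, nursing
   capacity)` eggs; capacity is `3 × in-hive bees − care-dependent
   brood`.
3. **Foraging.** Forager squadrons make repeated nectar/pollen trips
   while daily foraging hours and patch supplies last. On an
   application day, every forager active on a treated patch receives
   the contact dose once; a knock-down substance kills in the field
   *before* hive return, so those loads are lost, otherwise foragers
   return with their loads and face contact mortality at the end of
   the day.
4. **Water** (module off by default): cooling and dilution demand are
   covered from water sources; 10 % of carried pesticide doses the
   carrier, 90 % enters the day-0 honey pool.
5. **Deposit.** Surviving loads enter the day-0 honey compartment
   (energy + pesticide) and the fully mixed pollen pool.
6. **Consumption.** The colony's energy and pollen demand is withdrawn
   freshest-first (day 0 → day 4 → capped); delivered doses follow the
   demand shares of in-hive bees, foragers and larvae. The optional
   nurse filter scales the larval dose by `filter_factor`, the withheld
   remainder staying with the nurses.
7. **Effects.** End-of-day dose–response mortality per cohort
   (binomial draws), plus starvation mortality in proportion to any
   food shortfall; exposure ledgers reset.
8. **Aging.** Stores shift one compartment; cohorts age one day; brood
   above the nursing cap is terminated youngest-first.

## Exposure and effects

Initial concentrations use 90th-percentile residue-per-unit-dose (RUD)
factors: `C0 (µg/kg) = rate (kg a.i./ha) × RUD (mg/kg per kg/ha) ×
1000`, decaying with the whole-plant DT50. Contact exposure exists only
on the application day and converts through forager body weight
(`rate × RUD_foliar × 0.1 g` µg/bee). The forager oral dose is emergent:
flight energy on nectar trips is drawn from the carried nectar, so a
trip from a treated patch doses its forager by
`consumed mass × concentration`. Because honey consumption is driven by
energy rather than volume, in-hive concentrations are carried in µg/kJ;
nectar energy density follows its sucrose molarity
(`molarity × 1000/density × 5.75 kJ/mmol`).

Each laboratory endpoint is a two-parameter log-logistic curve,
`M(d) = 1/(1 + (LD50/d)^slope)`, `M(0) = 0`. Multi-day tests scale to a
daily hazard by `q = 1 − (1 − M_T)^{1/T}`; the 48-h acute endpoint is
applied to the day's summed dose directly (splitting it over two days
would double-count a single-dose test). The oral pathway takes the
pointwise maximum of the acute and chronic daily mortalities — the most
conservative endpoint always wins at the evaluated dose. Oral, contact
and background mortality compose as independent hazards. A larval
endpoint read at 7 days acts on feeding larvae day by day; an endpoint
read at 22 days (insect growth regulators whose damage expresses after
feeding) is converted to a per-day hazard spread uniformly over the
12-day pupal stage, parameterised by each cohort's mean daily dose over
its larval feeding period — pupae do not feed, but their numbers carry
the larval exposure.

The in-hive fate rules are deliberately conservative: fresh (most
contaminated) honey is eaten first, each daily compartment is fully
mixed, and no chemical degradation occurs in the hive unless the
`chem_dissipation_dt50` option is set — removal of active ingredient
from the stores is otherwise purely "biological dissipation" through
consumption. Pre-existing honey initialises the *capped* store (ripe
honey), so a clean colony's reserves stay clean until fresh inflow
fails to cover demand.

## Colony core

The demographic core is a simplified, cohort-based reconstruction of a
standard colony model: integer cohorts per age class with binomial
mortality (foragers grouped in squadrons of 100 sharing trip outcomes),
stage durations 3/6/12 days, a Gaussian seasonal laying curve (default
peak 1600 eggs/day at day 160, σ = 45 d), background mortalities per
stage, and per-capita food needs (0.43 kJ honey and 1.5 mg pollen per
adult-day; 0.14 kJ and 24 mg per larva-day, routed through nurses).
Every constant is config-exposed through `demography_params()` and
`foraging_params()`.

Two rules give the colony its characteristic feedbacks. First, brood
care: each in-hive bee handles three care-dependent brood cells; above
that cap brood is terminated youngest-first and laying is suppressed.
Second, division of labour: the nurse→forager transition age adapts
between 7 and 21 days — forager losses pull younger bees into foraging,
a surplus relaxes the age back up. A fixed-threshold rule (the simplest
alternative) is recoverable by setting `min_forager_transition_age =
forager_transition_age`; we kept the adaptive rule because forager
depletion measurably drains the nurse force in real colonies, and the
fixed rule leaves the two castes artificially insulated from each
other. Food shortfalls convert into starvation mortality in proportion
to the unmet fraction (pollen deficits act on larvae).

## Tunnel scenarios and the synthetic generator

`tunnel_design()` (with `dimethoate_tunnel_design()` and
`fenoxycarb_tunnel_design()` presets) describes a semifield study:
confinement on a single treated *Phacelia*-type patch with capped daily
forage, a spray at peak flowering, relocation to an untreated
monitoring site, and 43–53 days of observation. The presets encode the
two published validation layouts: an organophosphate study running
July–September with three hives, and an insect-growth-regulator study
July–August with four smaller, brood-heavier hives. Hive condition
(8000/6000 adults, even age distribution, ~4 kg honey, 250 g pollen),
tunnel forage caps (1.5 L nectar, 100 g pollen per day) and the
monitoring site (1500 m, 8 L, 500 g) are representative defaults chosen
once for this package — the original study reports carry the exact
values, and all of them are arguments.

`synth_weather()` generates the weather: AR(1) temperature anomalies
around a seasonal mean (default 19 °C, σ = 2.5 °C, autocorrelation
0.7), a diurnal range for daily maxima, and foraging hours from a
daylight budget cut by cool days and random rain. It emulates the
statistical texture of a central-European summer, not any particular
year: real weather has fronts, multi-day rain spells and heat waves
with stronger persistence than an AR(1) process. Tests that pass under
this generator therefore demonstrate internal consistency and plausible
sensitivity, not calibration to any specific study season.

The toxicological profiles are likewise representative:
`dimethoate_profile()` uses public regulatory magnitudes for a highly
bee-toxic organophosphate (acute oral LD50 0.1 µg/bee, contact
0.12 µg/bee, chronic 0.25 µg/bee/day, RUDs 4.4/12.6/14, DT50 3 d;
knock-down off, since organophosphates act over hours),
`fenoxycarb_profile()` a juvenile-hormone analogue that is practically
non-toxic to adults but lethal to brood through the 22-day larval
endpoint (0.02 µg/larva/day). They are documented defaults, not
transcriptions of specific study reports.

`run_paired_experiment()` derives the control by stripping the
pesticide, runs both arms with shared per-replicate seeds (every random
draw whose occurrence does not depend on a positive pesticide quantity
happens identically in both arms, so a zero-toxicity treatment
reproduces its control *exactly*), and reports relative effects
`100 × (1 − treatment/control)` on colony strength and per cohort, with
the end-of-study assessment at application day + two 21-day brood
cycles.

## Numerical choices

* Honey energy density 12.78 kJ/g; nectar density 1.1 kg/L; sucrose
  5.75 kJ/mmol.
* The pesticide mass balance (store inflows = delivered doses + store
  residue) is carried in the daily output and closes to better than
  10⁻⁹ relative error; it is pure double arithmetic with no rounding.
* Deaths are allocated across age classes by deterministic
  largest-remainder apportionment where a random split would desync the
  paired control/treatment streams; binomial draws are gated on
  strictly positive rates for the same reason.
* Replicate seeds derive from the master seed by a fixed affine map
  below 2³¹, so replicate *k* is identical regardless of how many
  replicates run.
* Degenerate inputs: empty patches mean no trips (the colony lives off
  stores); a zero-energy compartment carries zero pesticide by
  invariant; a collapsed control (strength 0) flags the relative effect
  as undefined for that day rather than dividing by zero.

## What the model reproduces — and what it does not

With the representative parameterisation, the dimethoate-type scenario
reproduces the *immediate* colony-strength reduction after application
(≈ 20 %, dominated by the contact kill of the active forager force plus
the first days of contaminated stores), the qualitative mode-of-action
signature (adult-acute chemistry depresses adults before brood; a
larval-only chemistry depresses brood first, with the adult decline
lagging by about one development period), and the conservative shape of
the validation studies: post-application decline with depressed brood
during and after exposure.

The *long-term* relative reductions published for the two semifield
validation studies (≈ 48 % and ≈ 50 % at two brood cycles after
application) are **not** reached: this core settles near 10–20 %. The
reason is structural and worth stating plainly. After a one-to-two-week
insult, the treated colony recovers because (i) the pupal bank is
toxicologically shielded (pupae neither feed nor fly) and re-fills the
adult population within about two weeks, (ii) egg laying is
queen-limited and identical across arms once nursing capacity unbinds,
so brood levels reconverge, and (iii) nothing sustains differential
mortality once plant residues (DT50 3–4 d) have decayed and the
freshest-first stores have flushed. Any initial deficit then decays at
the adult turnover rate. Published validations of the original agent-based
implementation instead show the relative effect *growing* through
the monitoring phase, a behaviour that depends on details of its colony
core (and on study parameterisations in supporting material not
reproduced here). We chose to keep the defaults at their independently
documented values rather than push any of them to manufacture the
published end-of-study numbers; the package reports what the mechanism,
as parameterised, actually produces.

Other known limitations: no varroa/virus dynamics, drones, swarming or
queen failure; no toxicokinetic body-burden (dose–response only); no
behavioural (sublethal) effects; water exposure is implemented but
unvalidated (and off by default); cohort squadrons share trip outcomes,
which understates between-bee variance.
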