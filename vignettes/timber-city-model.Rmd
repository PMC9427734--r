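---
title: "The timbercities model: demand, forests, wood-product pools and the emission ledger"
author: "timbercities authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The timbercities model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timbercities)
```

## What the model computes

`timbercities` asks a simple counterfactual question at global scale: if a
fraction PR of the people who move into cities between 2020 and 2100 were
housed in mid-rise buildings whose primary structure and enclosure are
engineered wood (cross-laminated timber and similar products) instead of
cement and steel, what happens to land use and to cumulative CO2 emissions?
Four scenarios (BAU with PR = 0, and PR = 0.1, 0.5, 0.9) are crossed with
three urbanization pathways (SSP1/2/3) on synthetic regional fixtures.

The pipeline has four coupled stages, run per region on an annual timestep:

1. **Demand.** Cumulative engineered-wood demand is
   `M = (P_t* - P_2020) * M_w_c * CW * PR`, where `P_t* - P_2020` is the
   urban population influx up to its peak year `t*`, `M_w_c` the per-capita
   woody biomass in a timber building (tDM/person), `CW = 0.476` tC/tDM the
   carbon-to-wood ratio, and PR the scenario factor. The cumulative value is
   spread over the years up to `t*` with linearly increasing weights (a
   sliding scale concentrating demand near the urbanization peak), and a 50%
   harvesting efficiency doubles the harvest relative to what enters
   buildings.
2. **Forests.** Plantations, secondary forest, primary forest and low-carbon
   "other land" are age-structured pools growing along Chapman–Richards
   curves. Plantations are established one rotation ahead of the demand they
   are meant to serve; harvest cascades from mature plantations to
   unprotected secondary and then primary forest; protected areas are never
   touched; total land area is conserved exactly.
3. **Wood products.** Harvested carbon enters two first-order-decay pools
   (industrial roundwood, half-life 35 y; engineered wood in buildings,
   half-life 60 y) with `k = ln(2)/half-life` and the annual-average inflow
   term, following the tier-1 decay bookkeeping used in national greenhouse
   gas inventories.
4. **Ledger.** Signed emission components: gross land-use change emissions
   (clearing, degradation, and the booking of *all* harvested carbon as
   emitted) are positive; regrowth is negative; wood-product storage is
   re-credited negative and decay releases return positive; manufacturing
   emissions for wood (`b1`) and cement+steel (`b2`) add on top. Identities
   `a3 = a1 + a2`, `b3 = b1 + b2`, `c = a3 + b3` hold to numerical precision
   at every step, annually and cumulatively.

## The synthetic-data generator

No external data are required: `generate_regions()`,
`generate_population()` and `generate_parameters()` produce seeded fixtures
with the statistical structure the analysis assumes.

* **Land.** 12 regions by default, partitioning 12,900 Mha with
  heterogeneous sizes. Initial pools are sampled proportionally to regional
  land with bounded noise and normalised so the 2020 global sums are exact:
  plantations 137 Mha, cropland 1595 Mha, natural forest 3629 Mha. The
  remainder splits into pasture and other land. Per-region protection shares
  (0.1–0.4) remove a fixed fraction of natural forest and other land from
  harvest permanently.
* **Population.** Urban headcounts follow a smooth logistic-style ramp to a
  randomised regional peak year in 2040–2090 and stay flat afterwards.
  Per-region 2100 urban shares are drawn on the logit scale around the SSP
  anchor and recentred by a common logit shift (a one-dimensional root
  find), so the global 2100 urban share equals 92% (SSP1), 80% (SSP2) or
  58% (SSP3) exactly, for any seed. Global totals rise from 7.84 billion to
  8.0/9.0/10.5 billion (SSP1/2/3). The totals are deliberately kept in a
  narrow band: at the region scale of this model, keeping totals similar
  lets urbanization differences dominate, which reproduces the qualitative
  ordering that a strongly urbanizing SSP1 world demands the most building
  material and SSP3 the least. A demographically literal SSP3 (12.6 billion,
  mostly rural) would invert that ordering through sheer population growth —
  a country-level heterogeneity effect this 12-region world cannot resolve.
* **Demand-side constants.** `M_w_c` defaults to 12 tDM per person housed —
  about 30 m2 of floor area at roughly 0.4 t of structural wood per m2,
  i.e. ~5.7 tC stored per person, consistent with published mid-rise CLT
  material studies. It is a fixture default, not an estimated quantity.
  The carbon-to-wood ratio is drawn per region within 0.476 ± 0.04.
  Conventional construction uses 8–12 t cement and 1.0–1.4 t steel per
  person at static emission factors of 0.60 and 1.85 tCO2e/t (0.25 tCO2e/t
  for engineered wood products); no decarbonisation pathway is assumed for
  any material.
* **Exogenous wood demand.** Industrial roundwood entering the long-lived
  product pool is held at 100 MtC/yr globally (about the carbon content of
  current global sawnwood production) and wood fuel at 400 MtC/yr, split
  across regions by population-independent land weights and identical in
  every PR scenario by construction.

What the generator does **not** emulate: country-level detail, trade between
regions, income-driven demand, cost-minimising land allocation, yields from
a vegetation model, or climate feedbacks. Passing tests on these fixtures
demonstrates the internal correctness and qualitative scenario behaviour of
the accounting machinery — not predictive skill on the real land system, and
the absolute desk-scale magnitudes (e.g. cumulative BAU land sink, absolute
plantation expansion) are larger than source-scale estimates because the
simplified allocation has no optimisation damping.

## Forest dynamics in detail

Each vegetated pool carries two area vectors (unprotected, protected)
indexed by integer stand age 0–150; the top bin absorbs older stands. Ages
advance annually; the 5-year age-class grid appears in the rotation rule and
in reports as an aggregation of the annual bins, which keeps the wood-product
equations annual while matching 5-year class conventions.

* **Initial age structure.** Primary forest starts entirely in the highest
  age class; secondary forest is skewed old (60% in the top class, the rest
  spread over ages 50–145), reflecting that standing natural forests are
  mostly mature; plantations are spread uniformly over one rotation of ages
  so a mature cohort is available every year; other land sits at its (low)
  asymptote, below 20 tC/ha by definition of the pool.
* **Rotation.** `rotation_length()` maximises the current annual increment
  (CAI) over 5-year classes, ties toward the smaller age. A `MAI` switch
  implements the culmination of mean annual increment instead, which gives
  longer rotations; the CAI wording is taken literally as the default, and
  the flag exists because the two rules are easily conflated.
* **Establishment.** In year `y` the model provisions the
  plantation-assigned demand of year `y + rotation`: all engineered-wood
  harvest plus 34% of industrial roundwood demand (roughly the plantation
  share of global roundwood production). Establishment area is
  `demand / density(rotation)`, converted first from unprotected other land,
  then unprotected secondary forest; the standing carbon of converted land
  is an up-front clearing emission. Cohorts enter at age 0 and cannot be
  harvested before the rotation elapses, so the establishment lock is
  implied by the maturity rule rather than tracked separately. If
  unprotected land runs out the shortfall is logged and the demand falls
  through to natural-forest harvest.
* **Harvest.** Wood (engineered + roundwood) cascades through mature
  plantations, then unprotected secondary, then primary forest; wood fuel
  through other land, then secondary, then primary — other land supplies
  fuel only. Oldest stands are cut first. Harvested plantation area is
  replanted at age 0; harvested natural forest re-enters secondary forest at
  age 0; harvested other land regrows from age 0 on its own curve (modelling
  other land as an aged pool keeps repeated fuel harvesting mass-consistent
  and counts its regrowth). Wood fuel is assumed fully oxidised in the
  harvest year.
* **Degradation.** 0.1%/yr of unprotected natural forest degrades, releasing
  its standing carbon and re-entering secondary forest at age 0; this folds
  shifting cultivation into a single observed-rate process. Cropland and
  pasture are exogenous and constant; the mature-plantation-to-cropland
  conversion pathway is therefore dormant in this implementation (documented
  here rather than silently dropped).

## Wood-product pools and double counting

The pool update is
`C_{t+1} = e^{-k} C_t + ((1 - e^{-k})/k) inflow_t`; the effective inflow
`((1-e^{-k})/k) inflow` is what enters the stock (inflow decays within its
first year too) and the decay release is the mass-balance residual,
`(1 - e^{-k}) C_t`. Double counting is avoided in three steps: all harvested
carbon is first booked as emitted; industrial-roundwood and engineered-wood
carbon is then re-credited into the decay pools (negative entry, equal to
the effective inflow so that pool mass balance is exact); decay outflows are
added back as positive emissions. Wood fuel and processing residues are
never pooled. Stocks are zero up to 2020; end-of-life disposal beyond decay
is not modelled.

## Numerical choices

* Tolerances: land-area conservation and ledger identities are asserted to
  1e-9 relative; demand annualisation conserves mass to the same tolerance.
* The half-life recovery check allows a 1e-9 relative slack on the halving
  threshold, absorbing floating-point drift in 35–60 repeated `e^{-k}`
  products; after exactly one half-life the simulated stock equals half the
  initial stock to that precision.
* Reporting rounding: percent savings to the nearest integer and annualised
  rates to two decimals, both with R's round-half-to-even.
* Ties in the rotation argmax break toward the smaller age; age-0 stands
  carry no carbon and are never drawn on by the harvest waterfall.
* Cumulative series are baselined at 2020 (flows start in 2021), so every
  cumulative component is zero in 2020 by construction.
* Material CO2e factors are added into a CO2 ledger unchanged (a documented
  approximation); cement carbonation re-uptake is not modelled, consistent
  with static emission factors.

## Problem sizes and runtime

The default configuration is 12 regions, annual steps over 2020–2100, and a
4-scenario x 3-SSP matrix; a full matrix completes in well under a minute on
one CPU, and the engine unit tests use a reduced 3-region, 2020–2060 setup.
These sizes are the package's reference study conditions; all scenario-level
regression properties (orderings in PR, exogenous invariance, the
engineered-wood pool overtaking the roundwood pool in ambitious scenarios)
are asserted on them.

## Known limitations

Beyond the generator's scope notes above: no inter-regional trade, no
optimisation-based land allocation, no pests/fire/storm disturbances, no
albedo or other biophysical feedbacks, no N2O/CH4 or soil carbon, and no
post-peak construction demand (the demand model is defined only up to the
urban peak). The model is an accounting laboratory for the demand-to-ledger
chain, not an integrated assessment model.
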