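# timbercities

Land-use change and carbon accounting for a transition to timber cities.

## The problem

Housing the people who will move into cities between 2020 and 2100 requires
enormous quantities of building material. Cement and steel manufacturing is
a major CO2 source; engineered wood (cross-laminated timber and similar
products) both avoids those process emissions and stores harvested carbon in
buildings for decades — but the wood has to come from somewhere, and growing
it changes land use. `timbercities` is a desk-scale scenario model for
researchers who want a transparent, fully testable implementation of this
demand-to-ledger chain: who demands the wood, which forests supply it, how
long the carbon stays in products, and what the net cumulative emissions are.

## The model

Scenarios house a fraction **PR** ∈ {0, 0.1, 0.5, 0.9} of new urban dwellers
in wood (labels BAU/10pc/50pc/90pc), crossed with SSP1/2/3 urbanization
(global 2100 urban shares 92/80/58%). Per region:

* **Demand** — cumulative engineered-wood carbon demand
  `M = (P_t* − P_2020) · M_w_c · CW · PR` (urban influx to the peak year t*,
  per-capita wood mass `M_w_c`, carbon-to-wood ratio `CW = 0.476` tC/tDM),
  annualised with linearly increasing weights up to t* and doubled by a 50%
  harvesting efficiency.
* **Forests** — age-structured plantation, secondary, primary and other-land
  pools on Chapman–Richards growth curves `A(1 − e^{−k·age})^b`; rotation
  length maximises the current annual increment; plantations are established
  one rotation ahead of the demand they serve; harvest cascades
  plantation → secondary → primary under strict protected-area exclusion and
  exact land-area conservation.
* **Wood products** — first-order-decay pools
  `C_{t+1} = e^{−k} C_t + ((1−e^{−k})/k)·inflow_t` with `k = ln 2/half-life`
  (35 y industrial roundwood, 60 y engineered wood).
* **Ledger** — signed components: gross land-use change emissions (+),
  regrowth (−), product storage (−) and decay release (+) combine into land
  emissions `a3`; wood (`b1`) and cement+steel (`b2`) manufacturing into
  `b3`; overall `c = a3 + b3`. Scenarios are differenced against the BAU of
  their SSP.

All inputs are synthetic, seeded fixtures calibrated to 2020 anchors
(plantations 137 Mha, cropland 1595 Mha, natural forest 3629 Mha; SSP urban
shares hit exactly). See the methods vignette
(`vignettes/timber-city-model.Rmd`) for every assumption and default.

## Worked example

```r
library(timbercities)
m <- run_matrix(ssps = "SSP2", seed = 1)
print(m)
#> Scenario matrix summary
#>  scenario  ssp cum_a3_gt cum_b3_gt cum_c_gt saving_gt percent_saving
#>       BAU SSP2    -103.7    22.237   -81.44      0.00              0
#>      10pc SSP2    -128.4    20.849  -107.51     26.07             32
#>      50pc SSP2    -226.3    15.295  -211.02    129.58            159
#>      90pc SSP2    -324.0     9.742  -314.22    232.78            286
#>  annualized_gt_yr plantation_2100_mha
#>              0.00               186.6
#>              0.33               244.3
#>              1.62               475.5
#>              2.91               706.7
```

Reading the table: `cum_a3_gt` is cumulative land-use change emissions
2020–2100 in Gt CO2 (negative = net sink: regrowth and product storage
exceed gross emissions on these fixtures), `cum_b3_gt` cumulative
manufacturing emissions, `cum_c_gt` their sum. `saving_gt` differences each
scenario against BAU: housing 90% of new urban dwellers in wood saves
232.78 Gt CO2 by 2100 on this fixture (2.91 Gt CO2/yr annualised) while
plantations expand from ~187 to ~707 Mha. Savings rise monotonically with
PR, conventional-material emissions fall, and by 2100 the engineered-wood
pool holds more carbon than the industrial-roundwood pool in the 50pc and
90pc scenarios. Desk-scale magnitudes are larger than source-scale
integrated-assessment estimates (no optimisation damping, no trade); the
orderings and identities are the tested claims.

`write_report(m, "out/")` writes `demand.csv`, `harvest.csv`, `land.csv`,
`hwp.csv`, `emissions.csv` and `summary.csv`. A thin CLI wraps the same
functions: `inst/scripts/timbercities generate|run|matrix|report`.

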