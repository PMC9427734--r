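# Shared in-code fixtures for the unit tests. Everything is generated at test
# time; no files are read.

small_fixture <- function(seed = 1, n_regions = 3, ssp = "SSP2",
                          years = 2020:2100) {
  regions <- generate_regions(n_regions, seed = seed)
  list(
    regions = regions,
    population = generate_population(regions, ssp = ssp, seed = seed,
                                     years = years),
    parameters = generate_parameters(regions, seed = seed, years = years)
  )
}

# A hand-built single-region land state with two plantation cohorts, some
# secondary forest and other land — used for the harvest-waterfall oracle.
# All areas in Mha, flat protection.
toy_state <- function(mature_area = 1, young_area = 1, secondary_area = 10,
                      other_area = 10, prot_share = 0) {
  nfp <- timbercities:::new_forest_pool
  spread <- timbercities:::spread_ages
  curve_p <- growth_curve(100, 0.05, 2)   # rotation 15 under CAI
  curve_n <- growth_curve(120, 0.03, 2)
  curve_o <- growth_curve(10, 0.1, 1.5)
  max_age <- timbercities:::MAX_AGE
  plant <- spread(0, 0L)
  plant[15 + 1L] <- mature_area           # exactly at rotation age
  plant[5 + 1L] <- young_area             # immature cohort
  sec <- spread(secondary_area, max_age) * (1 - prot_share)
  sec_p <- spread(secondary_area, max_age) * prot_share
  pri <- spread(0, max_age)
  oth <- spread(other_area, max_age) * (1 - prot_share)
  oth_p <- spread(other_area, max_age) * prot_share
  state <- list(
    region_id = "TOY", year = 2020L, rotation = 15L,
    cropland_mha = 0, pasture_mha = 0, cropland_tc_ha = 0, pasture_tc_ha = 0,
    pools = list(
      plantation = nfp("plantation", plant, spread(0, 0L), curve_p),
      secondary = nfp("secondary", sec, sec_p, curve_n),
      primary = nfp("primary", pri, spread(0, 0L), curve_n),
      other = nfp("other", oth, oth_p, curve_o)
    )
  )
  class(state) <- "land_state"
  state
}

toy_demand_row <- function(year = 2021, engineered = 0, roundwood = 0,
                           fuel = 0) {
  data.frame(year = year, engineered_inflow_mtc = engineered / 2,
             engineered_harvest_mtc = engineered, roundwood_mtc = roundwood,
             woodfuel_mtc = fuel)
}

# Independent brute-force waterfall oracle: allocate a wood demand across
# pools in priority order given (carbon available per pool) — no age logic,
# just the allocation arithmetic the simulator must reproduce.
waterfall_oracle <- function(demand, available) {
  out <- numeric(length(available))
  names(out) <- names(available)
  rem <- demand
  for (i in seq_along(available)) {
    out[i] <- min(available[i], rem)
    rem <- rem - out[i]
  }
  out
}
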