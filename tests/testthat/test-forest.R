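test_that("harvest allocation follows the sourcing waterfall (brute-force oracle)", {
  st <- toy_state(mature_area = 1, young_area = 1, secondary_area = 10)
  dens15 <- stand_density(15, st$pools$plantation$curve)
  dens_sec <- stand_density(150, st$pools$secondary$curve)
  mature_c <- 1 * dens15
  # demand exceeding the mature plantation stock by 5 MtC
  demand <- mature_c + 5
  oracle <- waterfall_oracle(demand, c(plantation = mature_c,
                                       secondary = 10 * dens_sec,
                                       primary = 0))
  h <- harvest_wood(st, toy_demand_row(engineered = demand))
  expect_equal(h$report$harvest_plantation_mtc, oracle[["plantation"]])
  expect_equal(h$report$harvest_secondary_mtc, oracle[["secondary"]])
  expect_equal(h$report$harvest_secondary_mtc, 5)
  expect_equal(h$report$harvest_primary_mtc, 0)
  expect_equal(h$report$harvest_total_mtc, demand, tolerance = 1e-9)
  # the immature cohort is locked: plantation area drops by the mature hectare
  # only, and it is replanted at age 0
  expect_equal(h$state$pools$plantation$unprot[5 + 1], 1)
  expect_equal(h$state$pools$plantation$unprot[1], 1)
  # harvested secondary re-enters secondary at age 0
  expect_equal(h$state$pools$secondary$unprot[1], 5 / dens_sec)
})

test_that("plantation stock exactly equal to demand leaves natural forest untouched", {
  st <- toy_state(mature_area = 2, young_area = 0, secondary_area = 10)
  mature_c <- 2 * stand_density(15, st$pools$plantation$curve)
  h <- harvest_wood(st, toy_demand_row(engineered = mature_c))
  expect_equal(h$report$harvest_secondary_mtc, 0)
  expect_equal(h$report$harvest_primary_mtc, 0)
})

test_that("zero demand leaves the state unchanged; infeasible demand errors", {
  st <- toy_state()
  h <- harvest_wood(st, toy_demand_row())
  expect_equal(h$state$pools, st$pools)
  expect_equal(h$report$harvest_total_mtc, 0)
  expect_equal(h$report$booking_emissions_mtco2, 0)
  expect_error(harvest_wood(st, toy_demand_row(engineered = 1e9)),
               "infeasible wood demand in region TOY")
})

test_that("wood fuel comes from other land first and never from wood-only logic", {
  st <- toy_state(other_area = 10, secondary_area = 10)
  other_c <- 10 * stand_density(150, st$pools$other$curve)
  h <- harvest_wood(st, toy_demand_row(fuel = other_c / 2))
  expect_equal(h$report$harvest_other_mtc, other_c / 2)
  expect_equal(h$report$harvest_secondary_mtc, 0)
  # beyond other land, fuel falls through to secondary forest
  h2 <- harvest_wood(st, toy_demand_row(fuel = other_c + 5))
  expect_equal(h2$report$harvest_other_mtc, other_c, tolerance = 1e-9)
  expect_equal(h2$report$harvest_secondary_mtc, 5, tolerance = 1e-9)
})

test_that("protected area is never harvested or degraded", {
  st <- toy_state(secondary_area = 10, other_area = 10, prot_share = 0.5)
  unprot_c <- timbercities:::pool_carbon(st$pools$secondary, "unprot") +
    timbercities:::pool_carbon(st$pools$other, "unprot") +
    timbercities:::pool_carbon(st$pools$plantation, "unprot")
  # fuel demand above all unprotected carbon fails rather than touch protection
  expect_error(harvest_wood(st, toy_demand_row(fuel = unprot_c + 10)),
               "infeasible")
  # a feasible harvest leaves every protected vector exactly unchanged
  h <- harvest_wood(st, toy_demand_row(fuel = 5))
  for (nm in names(st$pools))
    expect_identical(h$state$pools[[nm]]$prot, st$pools[[nm]]$prot)
  fully_prot <- toy_state(secondary_area = 10, prot_share = 1)
  d <- degrade_forest(fully_prot, 0.001)
  expect_equal(d$emissions_mtco2, 0)
})

test_that("degradation emits the rate-fraction of unprotected natural carbon", {
  st <- toy_state(secondary_area = 10)
  carbon <- 10 * stand_density(150, st$pools$secondary$curve)
  d <- degrade_forest(st, 0.001)
  expect_equal(d$emissions_mtco2, c_to_co2(0.001 * carbon), tolerance = 1e-12)
  # the worked magnitude: 100 MtC of stock at 0.1%/yr -> 0.3667 MtCO2
  expect_equal(c_to_co2(0.001 * 100), 0.3666667, tolerance = 1e-6)
  expect_equal(degrade_forest(st, 0)$emissions_mtco2, 0)
  expect_error(degrade_forest(st, 0.1), "rate")
  # area is conserved: degraded area re-enters secondary age 0
  expect_equal(total_land_area(d$state), total_land_area(st), tolerance = 1e-12)
})

test_that("regrowth uptake matches the per-bin density increments and is <= 0", {
  # the unit magnitude: 1 Mha stepping up 5 tC/ha stores 18.33 MtCO2
  expect_equal(c_to_co2(5), 18.33333, tolerance = 1e-6)
  st <- toy_state(mature_area = 1, young_area = 1, secondary_area = 5)
  expected <- 0
  for (nm in names(st$pools)) {
    p <- st$pools[[nm]]
    inc <- stand_density(1:151, p$curve) - stand_density(0:150, p$curve)
    expected <- expected - c_to_co2(sum((p$unprot + p$prot) * inc))
  }
  g <- grow_and_age(st)
  expect_equal(g$uptake_mtco2, expected, tolerance = 1e-12)
  expect_lte(g$uptake_mtco2, 0)
  # ages advanced: the age-5 cohort is now at age 6
  expect_equal(g$state$pools$plantation$unprot[6 + 1], 1)
  expect_equal(total_land_area(g$state), total_land_area(st), tolerance = 1e-12)
  # a pool at its asymptote takes up (almost) nothing
  sat <- toy_state(mature_area = 0, young_area = 0, secondary_area = 0,
                   other_area = 10)
  expect_lt(abs(grow_and_age(sat)$uptake_mtco2), 1e-3)
})

test_that("plantation establishment converts the right area from the right pools", {
  st <- toy_state(other_area = 10, secondary_area = 10)
  dens_rot <- stand_density(st$rotation, st$pools$plantation$curve)
  sched <- data.frame(year = 2021:2100, engineered_inflow_mtc = 0,
                      engineered_harvest_mtc = 0, roundwood_mtc = 0,
                      woodfuel_mtc = 0)
  sched$engineered_harvest_mtc[sched$year == 2021 + st$rotation] <- 10
  est <- establish_plantations(st, sched, 2021)
  expect_equal(est$established_mha, 10 / dens_rot)
  expect_equal(est$cleared_other_mha, 10 / dens_rot)  # other land first
  expect_equal(est$cleared_secondary_mha, 0)
  expect_equal(est$state$pools$plantation$unprot[1], 10 / dens_rot)
  # clearing releases the standing carbon of the converted other land
  expect_equal(est$clearing_emissions_mtco2,
               c_to_co2(10 / dens_rot * stand_density(150, st$pools$other$curve)),
               tolerance = 1e-9)
  expect_equal(total_land_area(est$state), total_land_area(st), tolerance = 1e-12)
  # worked magnitude: 10 MtC at 50 tC/ha is 0.2 Mha
  expect_equal(10 / 50, 0.2)
  # zero future demand: nothing happens
  sched0 <- sched; sched0$engineered_harvest_mtc <- 0
  est0 <- establish_plantations(st, sched0, 2021)
  expect_equal(est0$established_mha, 0)
  expect_equal(est0$clearing_emissions_mtco2, 0)
  expect_equal(est0$state$pools, st$pools)
})

test_that("establishing on carbon-free land releases nothing and falls through", {
  st <- toy_state(other_area = 0, secondary_area = 0)
  st$pools$other$unprot[1] <- 10  # bare other land at age 0: no standing carbon
  sched <- data.frame(year = 2021:2100, engineered_inflow_mtc = 0,
                      engineered_harvest_mtc = 0, roundwood_mtc = 0,
                      woodfuel_mtc = 0)
  sched$engineered_harvest_mtc[sched$year == 2021 + st$rotation] <- 10
  est <- establish_plantations(st, sched, 2021)
  expect_gt(est$established_mha, 0)
  expect_equal(est$clearing_emissions_mtco2, 0)
  # exhausting the land reports a shortfall instead of failing
  big <- sched; big$engineered_harvest_mtc[big$year == 2021 + st$rotation] <- 1e6
  est2 <- establish_plantations(st, big, 2021)
  expect_gt(est2$shortfall_mtc, 0)
})
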