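mk_traj <- function(delta_million = 100, peak = 2060, years = 2020:2100) {
  frac <- pmin(pmax((years - 2020) / (peak - 2020), 0), 1)
  data.frame(year = years, urban_million = 500 + delta_million * frac)
}

test_that("cumulative demand follows the population-influx product", {
  traj <- mk_traj(100)
  p0 <- demand_params(M_w_c = 5.5, CW = 0.476, PR = 0)
  expect_equal(cumulative_wood_demand(traj, p0), 0)
  p9 <- demand_params(M_w_c = 5.5, CW = 0.476, PR = 0.9)
  expect_equal(cumulative_wood_demand(traj, p9), 235.62)  # 100e6*5.5*0.476*0.9 tC
  p5 <- demand_params(M_w_c = 5.5, CW = 0.476, PR = 0.5)
  expect_equal(cumulative_wood_demand(traj, p5),
               cumulative_wood_demand(traj, p9) * 5 / 9)
  # declining urban population clamps to zero
  dec <- data.frame(year = 2020:2100, urban_million = seq(600, 500, length.out = 81))
  expect_equal(cumulative_wood_demand(dec, p9, peak_year = 2100), 0)
  expect_error(cumulative_wood_demand(traj[traj$year > 2020, ], p9), "base year")
})

test_that("cumulative demand is nondecreasing in each driver", {
  base <- cumulative_wood_demand(mk_traj(100), demand_params(5.5, 0.476, 0.5))
  expect_gte(cumulative_wood_demand(mk_traj(150), demand_params(5.5, 0.476, 0.5)), base)
  expect_gte(cumulative_wood_demand(mk_traj(100), demand_params(6.5, 0.476, 0.5)), base)
  expect_gte(cumulative_wood_demand(mk_traj(100), demand_params(5.5, 0.516, 0.5)), base)
  expect_gte(cumulative_wood_demand(mk_traj(100), demand_params(5.5, 0.476, 0.9)), base)
})

test_that("sliding-scale annualisation weights linearly and conserves mass", {
  ann <- annualize_demand(100, 2020, 2030)
  expect_equal(ann$year, 2021:2030)
  expect_equal(ann$inflow_mtc[10], 100 * 10 / 55)  # 18.1818...
  expect_true(all(diff(ann$inflow_mtc) > 0))       # strictly increasing
  expect_equal(sum(ann$inflow_mtc), 100, tolerance = 1e-9)
  # conservation across random windows and exponents
  set.seed(42)
  for (i in 1:20) {
    cum <- runif(1, 0, 1e3)
    peak <- sample(2021:2100, 1)
    p <- sample(c(1, 2), 1)
    a <- annualize_demand(cum, 2020, peak, weight_exponent = p)
    expect_equal(sum(a$inflow_mtc), cum, tolerance = 1e-9)
  }
  expect_equal(nrow(annualize_demand(0, 2020, 2020)), 0L)
  expect_true(all(annualize_demand(0, 2020, 2030)$inflow_mtc == 0))
  expect_error(annualize_demand(10, 2030, 2020), "peak_year")
})

test_that("harvest efficiency scales the inflow series", {
  expect_equal(apply_harvest_efficiency(10, 0.5), 20)
  expect_equal(apply_harvest_efficiency(7, 0.25), 28)
  expect_equal(apply_harvest_efficiency(c(1, 2, 3), 1), c(1, 2, 3))
  expect_error(apply_harvest_efficiency(1, 0), "efficiency")
})

test_that("schedules keep exogenous demand invariant across PR and nest in PR", {
  fx <- small_fixture(seed = 3)
  rid <- fx$regions$region_id[1]
  traj <- fx$population[fx$population$region_id == rid, ]
  exog <- fx$parameters$exogenous[fx$parameters$exogenous$region_id == rid, ]
  prow <- fx$parameters$params[1, ]
  sched <- lapply(c(0, 0.1, 0.5, 0.9), function(pr)
    build_schedule(traj, demand_params(prow$M_w_c, prow$CW, pr), exog))
  # exogenous columns identical across scenarios
  for (s in sched[-1]) {
    expect_identical(s$roundwood_mtc, sched[[1]]$roundwood_mtc)
    expect_identical(s$woodfuel_mtc, sched[[1]]$woodfuel_mtc)
  }
  # BAU engineered columns are all zero; harvest nests in PR
  expect_true(all(sched[[1]]$engineered_harvest_mtc == 0))
  expect_true(all(sched[[2]]$engineered_harvest_mtc <=
                    sched[[3]]$engineered_harvest_mtc + 1e-12))
  expect_true(all(sched[[3]]$engineered_harvest_mtc <=
                    sched[[4]]$engineered_harvest_mtc + 1e-12))
  # inflow sums to the Eq-style cumulative value; zero after the peak
  peak <- urban_peak_years(fx$population)[[rid]]
  s9 <- sched[[4]]
  expect_equal(sum(s9$engineered_inflow_mtc),
               cumulative_wood_demand(traj, demand_params(prow$M_w_c, prow$CW, 0.9)),
               tolerance = 1e-9)
  expect_true(all(s9$engineered_inflow_mtc[s9$year > peak] == 0))
  # harvest = inflow / efficiency everywhere
  expect_equal(s9$engineered_harvest_mtc, s9$engineered_inflow_mtc / 0.5)
  # misaligned exogenous years are rejected
  expect_error(build_schedule(traj, demand_params(5, 0.476, 0.5), exog[-1, ]),
               "aligned")
})
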