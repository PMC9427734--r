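# Engine tests run on a reduced problem (3 regions, 2020-2060) to stay fast;
# full-size behaviour is exercised in the acceptance suite.

short_cfg <- function(scenario = "BAU", ssp = "SSP2", seed = 1)
  scenario_config(scenario, ssp, seed = seed, n_regions = 3,
                  years = 2020:2060)

test_that("a BAU run has no engineered wood anywhere", {
  res <- run_scenario(short_cfg("BAU"))
  expect_true(all(res$demand$engineered_inflow_mtc == 0))
  expect_true(all(res$demand$engineered_harvest_mtc == 0))
  expect_true(all(res$emissions$b1 == 0))
  ew <- res$hwp[res$hwp$product == "engineered_wood", ]
  expect_true(all(ew$stock_mtc == 0))
})

test_that("runs are deterministic for a fixed configuration", {
  r1 <- run_scenario(short_cfg("50pc"))
  r2 <- run_scenario(short_cfg("50pc"))
  for (tab in c("demand", "harvest", "land", "hwp", "emissions", "summary"))
    expect_identical(r1[[tab]], r2[[tab]])
})

test_that("land area is conserved per region at every reported step", {
  res <- run_scenario(short_cfg("90pc"))
  lt <- res$land
  for (r in unique(lt$region_id)) {
    tot <- tapply(lt$area_mha[lt$region_id == r], lt$year[lt$region_id == r], sum)
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-9)
  }
  expect_true(all(lt$area_mha >= 0))
})

test_that("ledger identities hold on simulated output", {
  res <- run_scenario(short_cfg("50pc"))
  e <- res$emissions
  expect_equal(e$a3, e$a1 + e$a2, tolerance = 1e-12)
  expect_equal(e$c, e$a3 + e$b3, tolerance = 1e-12)
  expect_true(all(e$gross_luc >= 0))
  expect_true(all(e$regrowth <= 0))
  expect_true(all(e$b1 >= 0) && all(e$b2 >= 0))
})

test_that("the matrix differencing and orderings behave across scenarios", {
  m <- run_matrix(ssps = "SSP2", seed = 1, n_regions = 3,
                  config_base = short_cfg())
  s <- m$summary
  expect_equal(nrow(s), 4L)
  expect_equal(s$saving_gt[s$scenario == "BAU"], 0)
  ord <- match(c("BAU", "10pc", "50pc", "90pc"), s$scenario)
  expect_true(all(diff(s$saving_gt[ord]) >= 0))
  expect_true(all(diff(s$plantation_2100_mha[ord]) >= 0))
  expect_true(all(diff(s$cum_b2_gt[ord]) <= 0))
  expect_true(all(diff(s$cum_b1_gt[ord]) >= 0))
  # exogenous demand identical across PR
  bau <- m$runs$BAU_SSP2$demand
  p90 <- m$runs$`90pc_SSP2`$demand
  expect_identical(bau$roundwood_mtc, p90$roundwood_mtc)
  expect_identical(bau$woodfuel_mtc, p90$woodfuel_mtc)
  expect_error(run_matrix(scenarios = "50pc", ssps = "SSP2", seed = 1,
                          n_regions = 3, config_base = short_cfg()),
               "BAU")
})

test_that("matrix over several SSPs has full cardinality and SSP1 > SSP3 demand", {
  m <- run_matrix(scenarios = c("BAU", "90pc"), ssps = c("SSP1", "SSP3"),
                  seed = 2, n_regions = 3, config_base = short_cfg())
  expect_equal(nrow(m$summary), 4L)
  d1 <- m$runs$`90pc_SSP1`$demand
  d3 <- m$runs$`90pc_SSP3`$demand
  expect_gt(sum(d1$engineered_inflow_mtc), sum(d3$engineered_inflow_mtc))
})

test_that("reports are written, parseable and internally consistent", {
  m <- run_matrix(scenarios = c("BAU", "90pc"), ssps = "SSP2", seed = 1,
                  n_regions = 3, config_base = short_cfg())
  dir <- withr::local_tempdir()
  files <- write_report(m, dir)
  expect_true(all(file.exists(files)))
  em <- utils::read.csv(file.path(dir, "emissions.csv"))
  sm <- utils::read.csv(file.path(dir, "summary.csv"))
  # summary savings match recomputation from the emissions table
  c_end <- function(scn) {
    d <- em[em$scenario == scn & em$component == "c", ]
    d$cumulative_gtco2[which.max(d$year)]
  }
  expect_equal(sm$saving_gt[sm$scenario == "90pc"],
               scenario_saving(c_end("BAU"), c_end("90pc")), tolerance = 1e-9)
  expect_error(write_report(structure(list(runs = list(), summary = NULL),
                                      class = "scenario_matrix"), dir),
               "empty")
})

test_that("YAML configs round-trip through read_scenario_config", {
  path <- system.file("extdata", "default-config.yaml", package = "timbercities")
  cfg <- read_scenario_config(path, scenario = "50pc", n_regions = 3)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$PR, 0.5)
  expect_equal(cfg$half_lives[["engineered"]], 60)
  expect_equal(cfg$years, 2020:2100)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("no_such_key: 1", bad)
  expect_error(read_scenario_config(bad), "unknown keys")
})
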