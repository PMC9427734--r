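## Scenario orchestration: config, single-scenario run (demand ->
## establishment -> annual loop {harvest, degradation, regrowth, HWP update,
## ledger}), the BAU/10pc/50pc/90pc x SSP matrix, and report writing.

SCENARIO_PR <- c(BAU = 0, "10pc" = 0.1, "50pc" = 0.5, "90pc" = 0.9)

#' Scenario configuration
#'
#' Collects every tunable constant of a run. Defaults: PR set
#' {0, 0.1, 0.5, 0.9} keyed by scenario label, carbon-to-wood ratio 0.476
#' (regional values from the parameter table are used unless `CW` is set
#' here), harvesting efficiency 0.5, HWP half-lives 35 y (industrial
#' roundwood) and 60 y (engineered wood), rotation by current annual
#' increment, horizon 2020-2100 with an annual timestep.
#'
#' @param scenario `"BAU"`, `"10pc"`, `"50pc"` or `"90pc"`.
#' @param ssp `"SSP1"`, `"SSP2"` or `"SSP3"`.
#' @param seed master seed for the synthetic fixtures.
#' @param n_regions number of synthetic regions.
#' @param years simulation horizon (must start in 2020).
#' @param half_lives named vector: HWP half-lives in years.
#' @param CW optional global carbon-to-wood ratio override (tC/tDM).
#' @param harvest_efficiency engineered-wood harvesting efficiency.
#' @param rotation_rule `"CAI"` or `"MAI"`.
#' @param weight_exponent sliding-scale weight exponent.
#' @param degradation_rate annual unprotected natural-forest degradation
#'   fraction.
#' @param rw_plantation_share share of industrial roundwood demand
#'   provisioned by plantation establishment.
#' @param report_every land-area reporting interval in years.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("BAU", "10pc", "50pc", "90pc"),
                            ssp = c("SSP2", "SSP1", "SSP3"), seed = 0,
                            n_regions = 12, years = 2020:2100,
                            half_lives = c(roundwood = 35, engineered = 60),
                            CW = NULL, harvest_efficiency = 0.5,
                            rotation_rule = c("CAI", "MAI"),
                            weight_exponent = 1, degradation_rate = 0.001,
                            rw_plantation_share = 0.34, report_every = 5) {
  scenario <- match.arg(scenario)
  ssp <- match.arg(ssp)
  rotation_rule <- match.arg(rotation_rule)
  if (years[1] != 2020)
    stop_invalid("scenario_config: horizon must start in 2020")
  structure(list(
    scenario = scenario, PR = SCENARIO_PR[[scenario]], ssp = ssp, seed = seed,
    n_regions = n_regions, years = years, half_lives = half_lives, CW = CW,
    harvest_efficiency = harvest_efficiency, rotation_rule = rotation_rule,
    weight_exponent = weight_exponent, degradation_rate = degradation_rate,
    rw_plantation_share = rw_plantation_share, report_every = report_every
  ), class = "scenario_config")
}

#' Read a scenario configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [scenario_config()] defaults. The installed file
#' `system.file("extdata", "default-config.yaml", package = "timbercities")`
#' lists every constant.
#'
#' @param path YAML file path.
#' @param ... overrides applied after the file is read.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  dots <- list(...)
  cfg[names(dots)] <- dots
  if ("half_lives" %in% names(cfg)) cfg$half_lives <- unlist(cfg$half_lives)
  if ("years" %in% names(cfg) && length(cfg$years) == 2L)
    cfg$years <- seq(cfg$years[[1]], cfg$years[[2]])
  known <- names(formals(scenario_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop_invalid("read_scenario_config: unknown keys: ",
                 paste(bad, collapse = ", "))
  do.call(scenario_config, cfg)
}

#' Generate the default fixture set for a configuration
#'
#' Regions, one population set per requested SSP, and the parameter tables —
#' all from the configuration's master seed.
#'
#' @param config a [scenario_config()].
#' @param ssps SSP labels to generate populations for (default: the config's
#'   own SSP).
#' @return list with `regions`, `population` (named list by SSP),
#'   `parameters`.
#' @export
default_fixtures <- function(config, ssps = config$ssp) {
  regions <- generate_regions(config$n_regions, seed = config$seed)
  population <- lapply(stats::setNames(ssps, ssps), function(s)
    generate_population(regions, ssp = s, seed = config$seed,
                        years = config$years))
  parameters <- generate_parameters(regions, seed = config$seed,
                                    years = config$years)
  list(regions = regions, population = population, parameters = parameters)
}

#' Run one scenario
#'
#' Executes the full pipeline for one (scenario, SSP) cell: per-region demand
#' schedules, plantation establishment with a rotation lead, the annual
#' harvest/degradation/regrowth loop, HWP pool updates, and the global
#' emission ledger. Deterministic for a fixed configuration and fixtures.
#'
#' @param config a [scenario_config()].
#' @param fixtures a [default_fixtures()] result (or equivalent); the
#'   population entry for `config$ssp` is used. Generated from the config's
#'   seed when omitted.
#' @return a list of class `scenario_result` with tables `demand`, `harvest`,
#'   `land`, `hwp`, `emissions` (global ledger), `summary` (one row),
#'   `shortfalls`, and the `config`.
#' @export
run_scenario <- function(config, fixtures = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(fixtures)) fixtures <- default_fixtures(config)
  population <- fixtures$population[[config$ssp]]
  if (is.null(population))
    stop_invalid("run_scenario: fixtures lack a population set for ", config$ssp)
  regions <- fixtures$regions
  params <- fixtures$parameters$params
  exog <- fixtures$parameters$exogenous
  years <- config$years
  flow_years <- years[-1]
  n_flow <- length(flow_years)
  peaks <- urban_peak_years(population)

  demand_tab <- list(); harvest_tab <- list(); land_tab <- list()
  hwp_tab <- list(); shortfalls <- list()
  gross <- regrow <- credit <- release <- b1 <- b2 <- numeric(n_flow)
  plantation_2100 <- 0

  for (i in seq_len(nrow(regions))) {
    rid <- regions$region_id[i]
    traj <- population[population$region_id == rid, ]
    prow <- params[params$region_id == rid, ]
    erow <- exog[exog$region_id == rid, ]
    dp <- demand_params(M_w_c = prow$M_w_c,
                        CW = if (is.null(config$CW)) prow$CW else config$CW,
                        PR = config$PR,
                        harvest_efficiency = config$harvest_efficiency,
                        weight_exponent = config$weight_exponent)
    schedule <- build_schedule(traj, dp, erow, base_year = years[1],
                               peak_year = peaks[[rid]])
    newcomers <- newcomer_series(traj, base_year = years[1],
                                 peak_year = peaks[[rid]],
                                 weight_exponent = config$weight_exponent)
    man <- manufacturing_emissions(
      newcomers$newcomers_million, PR = config$PR,
      wood_t_cap = prow$M_w_c, cement_t_cap = prow$cement_t_cap,
      steel_t_cap = prow$steel_t_cap, ef_wood = prow$ef_wood,
      ef_cement = prow$ef_cement, ef_steel = prow$ef_steel)

    state <- init_land_state(regions[i, ], prow, config$rotation_rule)
    state$year <- years[1]
    rw_pool <- hwp_pool("industrial_roundwood",
                        half_life = config$half_lives[["roundwood"]])
    ew_pool <- hwp_pool("engineered_wood",
                        half_life = config$half_lives[["engineered"]])

    land_tab[[length(land_tab) + 1L]] <- land_pool_areas(state, years[1])
    hrows <- vector("list", n_flow); hwp_rows <- vector("list", n_flow)

    for (j in seq_len(n_flow)) {
      yr <- flow_years[j]
      est <- establish_plantations(state, schedule, yr,
                                   rw_plantation_share = config$rw_plantation_share,
                                   horizon_end = max(years))
      state <- est$state
      if (est$shortfall_mtc > 1e-9)
        shortfalls[[length(shortfalls) + 1L]] <- data.frame(
          region_id = rid, year = yr, shortfall_mtc = est$shortfall_mtc)

      h <- harvest_wood(state, schedule[schedule$year == yr, ])
      state <- h$state
      hrows[[j]] <- h$report

      deg <- degrade_forest(state, config$degradation_rate)
      state <- deg$state

      g <- grow_and_age(state)
      state <- g$state
      state$year <- yr

      rw_u <- update_pool(rw_pool, schedule$roundwood_mtc[schedule$year == yr])
      rw_pool <- rw_u$pool
      ew_u <- update_pool(ew_pool,
                          schedule$engineered_inflow_mtc[schedule$year == yr])
      ew_pool <- ew_u$pool
      hwp_rows[[j]] <- data.frame(
        region_id = rid, year = yr,
        product = c("industrial_roundwood", "engineered_wood"),
        stock_mtc = c(rw_u$stock_next, ew_u$stock_next),
        inflow_mtc = c(schedule$roundwood_mtc[schedule$year == yr],
                       schedule$engineered_inflow_mtc[schedule$year == yr]),
        release_mtco2 = c(rw_u$release_mtco2, ew_u$release_mtco2))

      gross[j] <- gross[j] + est$clearing_emissions_mtco2 +
        h$report$booking_emissions_mtco2 + deg$emissions_mtco2
      regrow[j] <- regrow[j] + g$uptake_mtco2
      credit[j] <- credit[j] - c_to_co2(rw_u$credit_mtc + ew_u$credit_mtc)
      release[j] <- release[j] + rw_u$release_mtco2 + ew_u$release_mtco2
      idx <- match(yr, newcomers$year)
      b1[j] <- b1[j] + man$b1_mtco2[idx]
      b2[j] <- b2[j] + man$b2_mtco2[idx]

      if ((yr - years[1]) %% config$report_every == 0 || yr == max(years))
        land_tab[[length(land_tab) + 1L]] <- land_pool_areas(state, yr)
    }
    plantation_2100 <- plantation_2100 + pool_area(state$pools$plantation)
    schedule$region_id <- rid
    demand_tab[[i]] <- schedule[, c("region_id", setdiff(names(schedule),
                                                         "region_id"))]
    harvest_tab[[i]] <- do.call(rbind, hrows)
    hwp_tab[[i]] <- do.call(rbind, hwp_rows)
  }

  emissions <- assemble_components(flow_years, gross, regrow, credit, release,
                                   b1, b2)
  last <- emissions[nrow(emissions), ]
  summary <- data.frame(
    scenario = config$scenario, ssp = config$ssp, PR = config$PR,
    seed = config$seed,
    cum_a1_gt = last$cum_a1, cum_a2_gt = last$cum_a2, cum_a3_gt = last$cum_a3,
    cum_b1_gt = last$cum_b1, cum_b2_gt = last$cum_b2, cum_b3_gt = last$cum_b3,
    cum_c_gt = last$cum_c, plantation_2100_mha = plantation_2100,
    stringsAsFactors = FALSE)

  structure(list(
    config = config,
    demand = do.call(rbind, demand_tab),
    harvest = do.call(rbind, harvest_tab),
    land = do.call(rbind, land_tab),
    hwp = do.call(rbind, hwp_tab),
    emissions = emissions,
    summary = summary,
    shortfalls = if (length(shortfalls)) do.call(rbind, shortfalls)
      else data.frame(region_id = character(0), year = integer(0),
                      shortfall_mtc = numeric(0))
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Scenario %s / %s (PR = %.1f, seed %d)\n",
              s$scenario, s$ssp, s$PR, s$seed))
  cat(sprintf("  cumulative 2100 (Gt CO2): a3 = %.1f, b3 = %.1f, c = %.1f\n",
              s$cum_a3_gt, s$cum_b3_gt, s$cum_c_gt))
  cat(sprintf("  plantation area 2100: %.1f Mha\n", s$plantation_2100_mha))
  invisible(x)
}

#' Run the scenario matrix
#'
#' Runs every (scenario, SSP) combination on shared fixtures and differences
#' each scenario against the BAU of its own SSP: saving, percent saving and
#' annualised rate.
#'
#' @param scenarios scenario labels (must include `"BAU"`).
#' @param ssps SSP labels.
#' @param seed master seed for the shared fixtures.
#' @param n_regions number of synthetic regions.
#' @param config_base optional template [scenario_config()] whose non-scenario
#'   settings are reused.
#' @return a list of class `scenario_matrix` with `runs` (named list of
#'   `scenario_result`) and `summary` (one row per combination, including
#'   `saving_gt`, `percent_saving`, `annualized_gt_yr`).
#' @export
run_matrix <- function(scenarios = c("BAU", "10pc", "50pc", "90pc"),
                       ssps = "SSP2", seed = 0, n_regions = 12,
                       config_base = NULL) {
  if (length(scenarios) < 1) stop_invalid("run_matrix: need >= 1 scenario")
  if (!"BAU" %in% scenarios)
    stop_invalid("run_matrix: BAU is required as the differencing baseline")
  make_config <- function(scn, ssp) {
    if (is.null(config_base))
      scenario_config(scenario = scn, ssp = ssp, seed = seed,
                      n_regions = n_regions)
    else {
      cfg <- config_base
      cfg$scenario <- scn; cfg$PR <- SCENARIO_PR[[scn]]; cfg$ssp <- ssp
      cfg$seed <- seed; cfg$n_regions <- n_regions
      cfg
    }
  }
  cfg0 <- make_config(scenarios[1], ssps[1])
  fixtures <- default_fixtures(cfg0, ssps = ssps)
  runs <- list()
  rows <- list()
  horizon <- length(cfg0$years) - 1L
  for (ssp in ssps) {
    bau <- NULL
    for (scn in scenarios) {
      res <- run_scenario(make_config(scn, ssp), fixtures)
      runs[[paste(scn, ssp, sep = "_")]] <- res
      if (scn == "BAU") bau <- res
      rows[[paste(scn, ssp)]] <- res$summary
    }
    for (scn in scenarios) {
      key <- paste(scn, ssp)
      sv <- scenario_saving(bau$summary$cum_c_gt, rows[[key]]$cum_c_gt)
      rows[[key]]$saving_gt <- sv
      rows[[key]]$percent_saving <- percent_saving(sv, bau$summary$cum_c_gt)
      rows[[key]]$annualized_gt_yr <- annualize_rate(sv, horizon)
    }
  }
  summary <- do.call(rbind, rows[paste(rep(scenarios, times = length(ssps)),
                                       rep(ssps, each = length(scenarios)))])
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary, fixtures = fixtures),
            class = "scenario_matrix")
}

#' @export
print.scenario_matrix <- function(x, ...) {
  cat("Scenario matrix summary\n")
  cols <- intersect(c("scenario", "ssp", "cum_a3_gt", "cum_b3_gt", "cum_c_gt",
                      "saving_gt", "percent_saving", "annualized_gt_yr",
                      "plantation_2100_mha"), names(x$summary))
  print(x$summary[, cols], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write all result tables of a matrix run
#'
#' Writes `demand.csv`, `harvest.csv`, `land.csv`, `hwp.csv`, `emissions.csv`
#' (long component format, annual MtCO2 and cumulative GtCO2) and
#' `summary.csv`, plus a human-readable `summary.txt`.
#'
#' @param results a [run_matrix()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_report <- function(results, dir) {
  stopifnot(inherits(results, "scenario_matrix"))
  if (length(results$runs) == 0) stop_invalid("write_report: empty matrix")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grab <- function(what) do.call(rbind, lapply(names(results$runs), function(k) {
    r <- results$runs[[k]]
    d <- r[[what]]
    cbind(scenario = r$config$scenario, ssp = r$config$ssp, d)
  }))
  files <- character(0)
  for (what in c("demand", "harvest", "land", "hwp")) {
    p <- file.path(dir, paste0(what, ".csv"))
    utils::write.csv(grab(what), p, row.names = FALSE)
    files <- c(files, p)
  }
  comp_long <- do.call(rbind, lapply(names(results$runs), function(k) {
    r <- results$runs[[k]]
    e <- r$emissions
    comps <- c("gross_luc", "regrowth", "a1", "a2", "a3", "b1", "b2", "b3", "c")
    do.call(rbind, lapply(comps, function(cm) data.frame(
      scenario = r$config$scenario, ssp = r$config$ssp, region_id = "GLOBAL",
      year = e$year, component = cm, annual_mtco2 = e[[cm]],
      cumulative_gtco2 = e[[paste0("cum_", cm)]])))
  }))
  p <- file.path(dir, "emissions.csv")
  utils::write.csv(comp_long, p, row.names = FALSE)
  files <- c(files, p)
  p <- file.path(dir, "summary.csv")
  utils::write.csv(results$summary, p, row.names = FALSE)
  files <- c(files, p)
  p <- file.path(dir, "summary.txt")
  con <- file(p, "w")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  print(results)
  files <- c(files, p)
  invisible(files)
}
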