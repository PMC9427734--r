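## Engineered-wood demand: cumulative demand from urban population influx,
## sliding-scale annualisation, harvesting efficiency, and the merged
## per-region demand schedule.

#' Demand model parameters
#'
#' @param M_w_c mean woody biomass demand per capita (tDM/person), `> 0`.
#' @param CW carbon-to-wood ratio (tC/tDM), `> 0`; global mean 0.476.
#' @param PR scenario factor: fraction of new urban dwellers housed in
#'   engineered-wood buildings (0 for BAU, 0.1/0.5/0.9 for the timber
#'   scenarios).
#' @param harvest_efficiency fraction of harvested carbon that ends up in the
#'   building product (default 0.5); the rest is processing residue.
#' @param weight_exponent exponent of the sliding-scale annualisation weights
#'   (default 1 = linear; see [annualize_demand()]).
#' @return a list of class `demand_params`.
#' @export
demand_params <- function(M_w_c, CW = 0.476, PR = 0,
                          harvest_efficiency = 0.5, weight_exponent = 1) {
  if (PR < 0 || PR > 1) stop_invalid("demand_params: PR must be in [0, 1]")
  if (harvest_efficiency <= 0 || harvest_efficiency > 1)
    stop_invalid("demand_params: harvest_efficiency must be in (0, 1]")
  if (M_w_c <= 0 || CW <= 0)
    stop_invalid("demand_params: M_w_c and CW must be > 0")
  structure(list(M_w_c = M_w_c, CW = CW, PR = PR,
                 harvest_efficiency = harvest_efficiency,
                 weight_exponent = weight_exponent),
            class = "demand_params")
}

#' Cumulative engineered-wood demand of a region
#'
#' Carbon demand accumulated between 2020 and the peak urban year t*:
#' `(P_t* - P_2020) * M_w_c * CW * PR`, where the population difference is the
#' urban influx in persons. Returns 0 if the urban population declines.
#'
#' @param traj population trajectory of one region: `data.frame` with `year`
#'   and `urban_million`, covering the base year through the peak year.
#' @param params a [demand_params()].
#' @param base_year start of the accounting window (default 2020).
#' @param peak_year year of peak urban population; default the first year the
#'   urban maximum is attained.
#' @return cumulative demand in MtC.
#' @export
cumulative_wood_demand <- function(traj, params, base_year = 2020,
                                   peak_year = NULL) {
  stopifnot(inherits(params, "demand_params"))
  if (!base_year %in% traj$year)
    stop_invalid("cumulative_wood_demand: trajectory is missing the base year ",
                 base_year)
  if (is.null(peak_year)) {
    peak_year <- traj$year[which(traj$urban_million >=
                                   max(traj$urban_million) - 1e-9)[1]]
  }
  if (!peak_year %in% traj$year)
    stop_invalid("cumulative_wood_demand: trajectory is missing the peak year ",
                 peak_year)
  p0 <- traj$urban_million[traj$year == base_year]
  pk <- traj$urban_million[traj$year == peak_year]
  delta_persons <- max(pk - p0, 0) * 1e6
  ## tC -> MtC
  delta_persons * params$M_w_c * params$CW * params$PR / 1e6
}

#' Annualise a cumulative demand with the sliding scale
#'
#' Distributes a cumulative demand over the years `(base_year, peak_year]`
#' with weights proportional to `(t - base_year)^p` (default `p = 1`, linear):
#' strictly increasing weights, so demand concentrates toward the time of
#' peak urban population. The series sums to the cumulative value exactly.
#'
#' @param cumulative cumulative demand (MtC).
#' @param base_year,peak_year window bounds; `peak_year > base_year` unless
#'   the cumulative demand is zero.
#' @param weight_exponent weight exponent `p >= 0`.
#' @return `data.frame` with `year` and `inflow_mtc`.
#' @export
annualize_demand <- function(cumulative, base_year, peak_year,
                             weight_exponent = 1) {
  if (cumulative < 0) stop_invalid("annualize_demand: cumulative must be >= 0")
  if (peak_year <= base_year) {
    if (cumulative > 0)
      stop_invalid("annualize_demand: peak_year must exceed base_year ",
                   "when cumulative demand is positive")
    return(data.frame(year = integer(0), inflow_mtc = numeric(0)))
  }
  years <- seq(base_year + 1L, peak_year)
  w <- (years - base_year)^weight_exponent
  data.frame(year = years, inflow_mtc = cumulative * w / sum(w))
}

#' Convert a building-inflow series into a harvest series
#'
#' Harvest needed = inflow / efficiency (50% efficiency doubles the harvest).
#'
#' @param inflow building inflow series (MtC/yr), `>= 0`.
#' @param efficiency harvesting efficiency in `(0, 1]`.
#' @return harvest series (MtC/yr).
#' @export
apply_harvest_efficiency <- function(inflow, efficiency) {
  if (length(efficiency) != 1L || !is.finite(efficiency) || efficiency <= 0 ||
      efficiency > 1)
    stop_invalid("apply_harvest_efficiency: efficiency must be in (0, 1]")
  inflow / efficiency
}

#' Build the full demand schedule of one region
#'
#' Merges the engineered-wood schedule (cumulative demand annualised with the
#' sliding scale, harvest scaled by the harvesting efficiency) with the
#' exogenous industrial roundwood and wood fuel series, which are identical
#' across PR scenarios. Engineered-wood entries are zero after the peak year.
#'
#' @param traj population trajectory of one region (`year`, `urban_million`).
#' @param params a [demand_params()].
#' @param exogenous `data.frame` with `year`, `roundwood_mtc`, `woodfuel_mtc`
#'   aligned on the trajectory years.
#' @param base_year accounting base year (default 2020).
#' @param peak_year peak urban year; default recomputed from the trajectory.
#' @return `data.frame` of class `demand_schedule`: `year`,
#'   `engineered_inflow_mtc`, `engineered_harvest_mtc`, `roundwood_mtc`,
#'   `woodfuel_mtc`.
#' @export
build_schedule <- function(traj, params, exogenous, base_year = 2020,
                           peak_year = NULL) {
  years <- traj$year
  if (!identical(as.integer(sort(exogenous$year)), as.integer(years)))
    stop_invalid("build_schedule: exogenous series not aligned on trajectory years")
  exogenous <- exogenous[order(exogenous$year), ]
  cum <- cumulative_wood_demand(traj, params, base_year, peak_year)
  if (is.null(peak_year))
    peak_year <- traj$year[which(traj$urban_million >=
                                   max(traj$urban_million) - 1e-9)[1]]
  inflow <- numeric(length(years))
  if (cum > 0) {
    ann <- annualize_demand(cum, base_year, peak_year, params$weight_exponent)
    inflow[match(ann$year, years)] <- ann$inflow_mtc
  }
  out <- data.frame(
    year = years,
    engineered_inflow_mtc = inflow,
    engineered_harvest_mtc = apply_harvest_efficiency(inflow,
                                                      params$harvest_efficiency),
    roundwood_mtc = exogenous$roundwood_mtc,
    woodfuel_mtc = exogenous$woodfuel_mtc
  )
  class(out) <- c("demand_schedule", "data.frame")
  out
}

#' New-urban-dweller (newcomer) series of a region
#'
#' The urban influx `P_t* - P_2020` distributed over `(2020, t*]` with the
#' same sliding-scale weights as the wood demand, so building-material
#' manufacturing aligns in time with wood inflow into buildings.
#'
#' @inheritParams cumulative_wood_demand
#' @param weight_exponent sliding-scale exponent.
#' @return `data.frame` with `year` and `newcomers_million`.
#' @export
newcomer_series <- function(traj, base_year = 2020, peak_year = NULL,
                            weight_exponent = 1) {
  if (is.null(peak_year))
    peak_year <- traj$year[which(traj$urban_million >=
                                   max(traj$urban_million) - 1e-9)[1]]
  p0 <- traj$urban_million[traj$year == base_year]
  pk <- traj$urban_million[traj$year == peak_year]
  delta <- max(pk - p0, 0)
  ann <- annualize_demand(delta, base_year, peak_year, weight_exponent)
  out <- numeric(length(traj$year))
  if (nrow(ann)) out[match(ann$year, traj$year)] <- ann$inflow_mtc
  data.frame(year = traj$year, newcomers_million = out)
}
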