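## The signed emission ledger. Components, per year and in MtCO2:
##   gross_luc (>= 0): land clearing, natural forest degradation, and the
##     harvest booking — all harvested carbon (including wood fuel and
##     processing residues) is first counted as emitted;
##   regrowth (<= 0): carbon uptake in forests and other land;
##   a1 = gross_luc + regrowth            (land and forest management)
##   a2 = hwp_credit + hwp_release        (HWP storage, net of decay)
##   a3 = a1 + a2                         (land-use change emissions)
##   b1: engineered-wood manufacturing;  b2: cement + steel manufacturing;
##   b3 = b1 + b2;  c = a3 + b3          (overall).
## The HWP credit re-books harvested industrial-roundwood and engineered-wood
## carbon into decay pools (negative), and decay outflows return as positive
## emissions — the three-step double-counting avoidance.

#' Manufacturing emissions of new urban housing
#'
#' Splits the year's new urban dwellers by construction material: a fraction
#' PR is housed in engineered-wood buildings, the rest conventionally. Wood
#' manufacturing emissions `b1` scale with the per-capita engineered-wood
#' mass; conventional emissions `b2` with per-capita cement and steel masses.
#' Emission factors are static over time (no decarbonisation pathway).
#'
#' @param newcomers_million new urban dwellers per year (millions, vector).
#' @param PR fraction housed in wood.
#' @param wood_t_cap,cement_t_cap,steel_t_cap per-capita material masses
#'   (t/person).
#' @param ef_wood,ef_cement,ef_steel emission factors (tCO2e/t).
#' @return list with `b1_mtco2` and `b2_mtco2` (MtCO2/yr vectors).
#' @examples
#' manufacturing_emissions(1, PR = 0, wood_t_cap = 12, cement_t_cap = 10,
#'                         steel_t_cap = 1)$b2_mtco2 # 7.85
#' @export
manufacturing_emissions <- function(newcomers_million, PR,
                                    wood_t_cap, cement_t_cap, steel_t_cap,
                                    ef_wood = 0.25, ef_cement = 0.60,
                                    ef_steel = 1.85) {
  vals <- c(wood_t_cap, cement_t_cap, steel_t_cap, ef_wood, ef_cement, ef_steel)
  if (any(vals < 0))
    stop_invalid("manufacturing_emissions: masses and factors must be >= 0")
  if (PR < 0 || PR > 1)
    stop_invalid("manufacturing_emissions: PR must be in [0, 1]")
  persons <- newcomers_million * 1e6
  list(
    b1_mtco2 = persons * PR * wood_t_cap * ef_wood / 1e6,
    b2_mtco2 = persons * (1 - PR) *
      (cement_t_cap * ef_cement + steel_t_cap * ef_steel) / 1e6
  )
}

#' Assemble the annual emission components
#'
#' Combines land fluxes, HWP pool fluxes and manufacturing emissions into the
#' full signed ledger with annual and cumulative series. Cumulative series
#' are baselined at the first year (2020 = 0; flows start the following
#' year).
#'
#' @param years year vector.
#' @param gross_luc positive land emissions (MtCO2/yr): clearing +
#'   degradation + harvest booking.
#' @param regrowth regrowth uptake (MtCO2/yr, `<= 0`).
#' @param hwp_credit HWP storage credit (MtCO2/yr, `<= 0`).
#' @param hwp_release HWP decay release (MtCO2/yr, `>= 0`).
#' @param b1,b2 manufacturing emissions (MtCO2/yr).
#' @return `data.frame` of class `emission_components` with annual columns
#'   `gross_luc`, `regrowth`, `a1`, `a2`, `a3`, `b1`, `b2`, `b3`, `c` and
#'   cumulative counterparts `cum_*` in GtCO2.
#' @export
assemble_components <- function(years, gross_luc, regrowth, hwp_credit,
                                hwp_release, b1, b2) {
  n <- length(years)
  args <- list(gross_luc = gross_luc, regrowth = regrowth,
               hwp_credit = hwp_credit, hwp_release = hwp_release,
               b1 = b1, b2 = b2)
  if (any(vapply(args, length, integer(1)) != n))
    stop_invalid("assemble_components: series not aligned on years")
  a1 <- gross_luc + regrowth
  a2 <- hwp_credit + hwp_release
  a3 <- a1 + a2
  b3 <- b1 + b2
  cc <- a3 + b3
  out <- data.frame(year = years, gross_luc = gross_luc, regrowth = regrowth,
                    a1 = a1, a2 = a2, a3 = a3, b1 = b1, b2 = b2, b3 = b3,
                    c = cc)
  for (nm in c("gross_luc", "regrowth", "a1", "a2", "a3", "b1", "b2", "b3", "c"))
    out[[paste0("cum_", nm)]] <- cumsum(out[[nm]]) / 1000  # MtCO2 -> GtCO2
  class(out) <- c("emission_components", "data.frame")
  out
}

#' Overall cumulative emissions
#'
#' `c = a3 + b3`: land-use change emissions plus raw-material manufacturing,
#' both baselined at 2020.
#'
#' @param a3_cum cumulative land-use change emissions (Gt CO2).
#' @param b3_cum cumulative manufacturing emissions (Gt CO2).
#' @return overall cumulative emissions (Gt CO2).
#' @examples
#' overall_cumulative(-168, 30) # -138
#' @export
overall_cumulative <- function(a3_cum, b3_cum) a3_cum + b3_cum

#' Emission saving of a scenario against BAU
#'
#' @param c_bau,c_scenario cumulative emissions (Gt CO2) over the same
#'   horizon.
#' @return saving in Gt CO2 (positive when the scenario emits less).
#' @examples
#' scenario_saving(-138, -244) # 106
#' @export
scenario_saving <- function(c_bau, c_scenario) c_bau - c_scenario

#' Percent saving relative to the BAU magnitude
#'
#' `100 * saving / |baseline|`, rounded to the nearest integer for reporting
#' (round-half-to-even).
#'
#' @param saving emission saving (Gt CO2).
#' @param baseline_magnitude BAU cumulative emissions (Gt CO2, any sign;
#'   magnitude is used), nonzero.
#' @return percent saving (integer-rounded).
#' @examples
#' percent_saving(106, 138) # 77
#' @export
percent_saving <- function(saving, baseline_magnitude) {
  if (any(baseline_magnitude == 0))
    stop_invalid("percent_saving: baseline must be nonzero")
  round(100 * saving / abs(baseline_magnitude))
}

#' Annualised saving rate
#'
#' Saving divided by the horizon length, rounded to two decimals for
#' reporting.
#'
#' @param saving emission saving (Gt CO2).
#' @param years horizon length in years, `> 0`.
#' @return rate in Gt CO2 per year.
#' @examples
#' annualize_rate(71, 80) # 0.89
#' @export
annualize_rate <- function(saving, years) {
  if (any(years <= 0)) stop_invalid("annualize_rate: years must be > 0")
  round(saving / years, 2)
}
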