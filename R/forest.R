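## Age-class forest and land-pool dynamics: plantation establishment with a
## rotation-length lead, harvest sourcing down a fixed priority waterfall,
## degradation, regrowth, and strict per-region land-area conservation.
##
## Internal representation: each vegetated pool (plantation, secondary,
## primary, other land) carries two area vectors indexed by integer stand age
## 0..150 years (the top age absorbs older stands), one for unprotected and
## one for protected area. Ages advance annually; the 5-year age-class grid of
## the rotation rule and of reports is an aggregation of these annual bins.

MAX_AGE <- 150L

new_forest_pool <- function(label, unprot, prot, curve) {
  stopifnot(length(unprot) == MAX_AGE + 1L, length(prot) == MAX_AGE + 1L)
  list(label = label, unprot = unprot, prot = prot, curve = curve)
}

pool_area <- function(pool) sum(pool$unprot) + sum(pool$prot)

## carbon stock of a pool in MtC (Mha x tC/ha)
pool_carbon <- function(pool, protected = c("all", "unprot", "prot")) {
  protected <- match.arg(protected)
  dens <- stand_density(0:MAX_AGE, pool$curve)
  a <- switch(protected,
    all    = pool$unprot + pool$prot,
    unprot = pool$unprot,
    prot   = pool$prot)
  sum(a * dens)
}

## distribute `area` over ages `ages` uniformly
spread_ages <- function(area, ages) {
  v <- numeric(MAX_AGE + 1L)
  v[ages + 1L] <- area / length(ages)
  v
}

#' Initialise the land state of a region
#'
#' Builds the six land pools from a sampled parameter row. Primary forest is
#' initialised entirely in the highest age class; secondary forest is skewed
#' old (60% in the highest class, the rest spread over ages 50-145);
#' plantations are spread uniformly over one rotation's worth of ages so a
#' mature cohort is available every year; other land sits at its asymptote.
#' The protection share of the region sets aside a fixed fraction of natural
#' forest and other land that is never harvested (it still grows and ages).
#'
#' @param region one row of a [generate_regions()] result.
#' @param params the matching row of `generate_parameters()$params`.
#' @param rotation_rule `"CAI"` or `"MAI"` (see [rotation_length()]).
#' @return a list of class `land_state`.
#' @export
init_land_state <- function(region, params, rotation_rule = "CAI") {
  stopifnot(nrow(region) == 1L, nrow(params) == 1L,
            region$region_id == params$region_id)
  curves <- list(
    plantation = growth_curve(params$plant_A, params$plant_k, params$plant_b),
    natural    = growth_curve(params$nat_A, params$nat_k, params$nat_b),
    other      = growth_curve(params$other_A, params$other_k, params$other_b)
  )
  rotation <- rotation_length(curves$plantation, rotation_rule)
  ps <- params$protection_share

  split_prot <- function(v, share) list(unprot = v * (1 - share), prot = v * share)

  plant_ages <- spread_ages(params$plantation_mha, 0:(rotation))
  sec_ages <- 0.6 * spread_ages(params$secondary_mha, MAX_AGE) +
    0.4 * spread_ages(params$secondary_mha, seq(50L, 145L, by = 5L))
  pri_ages <- spread_ages(params$primary_mha, MAX_AGE)
  oth_ages <- spread_ages(params$other_mha, MAX_AGE)

  sec <- split_prot(sec_ages, ps)
  pri <- split_prot(pri_ages, ps)
  oth <- split_prot(oth_ages, ps)

  state <- list(
    region_id = region$region_id,
    year = NA_integer_,
    rotation = rotation,
    cropland_mha = params$cropland_mha,
    pasture_mha = params$pasture_mha,
    cropland_tc_ha = params$cropland_tc_ha,
    pasture_tc_ha = params$pasture_tc_ha,
    pools = list(
      plantation = new_forest_pool("plantation", plant_ages,
                                   numeric(MAX_AGE + 1L), curves$plantation),
      secondary = new_forest_pool("secondary", sec$unprot, sec$prot,
                                  curves$natural),
      primary = new_forest_pool("primary", pri$unprot, pri$prot,
                                curves$natural),
      other = new_forest_pool("other", oth$unprot, oth$prot, curves$other)
    )
  )
  class(state) <- "land_state"
  state
}

#' @export
print.land_state <- function(x, ...) {
  cat(sprintf("Land state of %s (rotation %d yr)\n", x$region_id, x$rotation))
  areas <- c(cropland = x$cropland_mha, pasture = x$pasture_mha,
             vapply(x$pools, pool_area, numeric(1)))
  for (nm in names(areas))
    cat(sprintf("  %-10s %9.2f Mha\n", nm, areas[nm]))
  cat(sprintf("  total      %9.2f Mha\n", sum(areas)))
  invisible(x)
}

#' Total land area of a region state
#'
#' Sum of all six pools; conserved to machine precision over a simulation.
#'
#' @param state a `land_state`.
#' @return total area (Mha).
#' @export
total_land_area <- function(state) {
  state$cropland_mha + state$pasture_mha +
    sum(vapply(state$pools, pool_area, numeric(1)))
}

## Remove `amount` MtC from a pool's unprotected area, oldest bins first,
## optionally only from bins of age >= min_age. Removed area is returned so
## the caller can re-book it (replanting / conversion to secondary age 0).
## Age-0 bins carry no carbon and are never drawn on.
take_carbon <- function(pool, amount, min_age = 1L) {
  dens <- stand_density(0:MAX_AGE, pool$curve)
  removed_area <- numeric(MAX_AGE + 1L)
  taken <- 0
  if (amount <= 0) return(list(pool = pool, taken = 0, removed_area = removed_area))
  for (i in seq(MAX_AGE + 1L, 1L)) {
    age <- i - 1L
    if (age < min_age || dens[i] <= 0 || pool$unprot[i] <= 0) next
    need_c <- amount - taken
    if (need_c <= 1e-12) break
    a <- min(pool$unprot[i], need_c / dens[i])
    pool$unprot[i] <- pool$unprot[i] - a
    removed_area[i] <- removed_area[i] + a
    taken <- taken + a * dens[i]
  }
  list(pool = pool, taken = taken, removed_area = removed_area)
}

## Remove `area` Mha from a pool's unprotected bins, proportionally across
## ages; returns the standing carbon of the cleared area.
take_area <- function(pool, area) {
  avail <- sum(pool$unprot)
  area <- min(area, avail)
  if (area <= 0 || avail <= 0)
    return(list(pool = pool, cleared = 0, carbon = 0))
  frac <- area / avail
  dens <- stand_density(0:MAX_AGE, pool$curve)
  removed <- pool$unprot * frac
  pool$unprot <- pool$unprot - removed
  list(pool = pool, cleared = area, carbon = sum(removed * dens))
}

#' Establish plantations ahead of future demand
#'
#' At year `y` the model provisions the plantation-assigned demand of year
#' `y + rotation`: all engineered-wood harvest plus a configurable share of
#' industrial roundwood demand in that year. The area established is
#' `demand / density(rotation)`, taken first from unprotected other land,
#' then from unprotected secondary forest. Clearing releases the standing
#' carbon of the converted land. New cohorts enter the plantation pool at age
#' 0; they cannot be harvested before reaching the rotation age, so the
#' rotation-long establishment lock is implied by the maturity rule.
#'
#' @param state a `land_state`.
#' @param schedule the region's [build_schedule()] result.
#' @param year current simulation year.
#' @param rw_plantation_share share of industrial roundwood demand assigned
#'   to plantations (default 0.34, matching the roughly one-third plantation
#'   contribution to global roundwood production).
#' @param horizon_end last year with defined demand; no establishment for
#'   target years beyond it.
#' @return list with `state`, `established_mha`, `cleared_other_mha`,
#'   `cleared_secondary_mha`, `clearing_emissions_mtco2`, `shortfall_mtc`
#'   (demand that could not be provisioned for lack of unprotected land and
#'   will fall through to natural-forest harvest at harvest time).
#' @export
establish_plantations <- function(state, schedule, year,
                                  rw_plantation_share = 0.34,
                                  horizon_end = max(schedule$year)) {
  target <- year + state$rotation
  out <- list(state = state, established_mha = 0, cleared_other_mha = 0,
              cleared_secondary_mha = 0, clearing_emissions_mtco2 = 0,
              shortfall_mtc = 0)
  if (target > horizon_end) return(out)
  row <- schedule[schedule$year == target, ]
  if (nrow(row) != 1L) return(out)
  demand <- row$engineered_harvest_mtc + rw_plantation_share * row$roundwood_mtc
  if (demand <= 0) return(out)
  dens_rot <- stand_density(state$rotation, state$pools$plantation$curve)
  area_needed <- demand / dens_rot

  t1 <- take_area(state$pools$other, area_needed)
  state$pools$other <- t1$pool
  remaining <- area_needed - t1$cleared
  t2 <- take_area(state$pools$secondary, remaining)
  state$pools$secondary <- t2$pool
  established <- t1$cleared + t2$cleared
  state$pools$plantation$unprot[1L] <- state$pools$plantation$unprot[1L] +
    established

  out$state <- state
  out$established_mha <- established
  out$cleared_other_mha <- t1$cleared
  out$cleared_secondary_mha <- t2$cleared
  out$clearing_emissions_mtco2 <- c_to_co2(t1$carbon + t2$carbon)
  out$shortfall_mtc <- max(area_needed - established, 0) * dens_rot
  out
}

#' Harvest one year of wood demand
#'
#' Serves the year's wood demand (engineered harvest + industrial roundwood)
#' from mature plantations first (age >= rotation), then unprotected
#' secondary forest, then unprotected primary forest; wood fuel is served
#' from unprotected other land first, then secondary, then primary. Within a
#' pool, oldest stands are harvested first. Harvested plantation area is
#' replanted at age 0; harvested natural forest becomes secondary forest at
#' age 0; harvested other land re-enters other land at age 0. Protected area
#' is never touched.
#'
#' @param state a `land_state`.
#' @param demand_row one row of a [build_schedule()] result.
#' @return list with `state` and `report` — a one-row `data.frame`:
#'   harvested carbon by source pool (MtC), total harvest, harvested area by
#'   pool (Mha), and the harvest booking emissions (all harvested carbon as
#'   CO2, per the double-counting avoidance scheme).
#' @export
harvest_wood <- function(state, demand_row) {
  stopifnot(nrow(demand_row) == 1L)
  wood <- demand_row$engineered_harvest_mtc + demand_row$roundwood_mtc
  fuel <- demand_row$woodfuel_mtc
  if (wood < 0 || fuel < 0) stop_invalid("harvest_wood: negative demand")

  got <- c(plantation = 0, secondary = 0, primary = 0, other = 0)
  area <- c(plantation = 0, secondary = 0, primary = 0, other = 0)

  draw <- function(pool_name, amount, min_age, dest) {
    r <- take_carbon(state$pools[[pool_name]], amount, min_age)
    state$pools[[pool_name]] <<- r$pool
    a <- sum(r$removed_area)
    if (a > 0) {
      state$pools[[dest]]$unprot[1L] <<- state$pools[[dest]]$unprot[1L] + a
    }
    got[pool_name] <<- got[pool_name] + r$taken
    area[pool_name] <<- area[pool_name] + a
    r$taken
  }

  rem <- wood
  rem <- rem - draw("plantation", rem, state$rotation, "plantation")
  rem <- rem - draw("secondary", rem, 1L, "secondary")
  rem <- rem - draw("primary", rem, 1L, "secondary")
  if (rem > 1e-6)
    stop_invalid(sprintf(
      "harvest_wood: infeasible wood demand in region %s, year %s (short %.3f MtC)",
      state$region_id, demand_row$year, rem))

  remf <- fuel
  remf <- remf - draw("other", remf, 1L, "other")
  remf <- remf - draw("secondary", remf, 1L, "secondary")
  remf <- remf - draw("primary", remf, 1L, "secondary")
  if (remf > 1e-6)
    stop_invalid(sprintf(
      "harvest_wood: infeasible wood fuel demand in region %s, year %s (short %.3f MtC)",
      state$region_id, demand_row$year, remf))

  total <- sum(got)
  report <- data.frame(
    region_id = state$region_id, year = demand_row$year,
    harvest_plantation_mtc = got[["plantation"]],
    harvest_secondary_mtc = got[["secondary"]],
    harvest_primary_mtc = got[["primary"]],
    harvest_other_mtc = got[["other"]],
    harvest_total_mtc = total,
    area_plantation_mha = area[["plantation"]],
    area_secondary_mha = area[["secondary"]],
    area_primary_mha = area[["primary"]],
    area_other_mha = area[["other"]],
    booking_emissions_mtco2 = c_to_co2(total)
  )
  list(state = state, report = report)
}

#' Natural forest degradation emissions
#'
#' A constant fraction of unprotected natural forest (primary and secondary)
#' degrades each year, releasing its standing carbon; the degraded area
#' re-enters secondary forest at age 0 (degradation-then-abandonment, which
#' also folds in shifting cultivation). Protected forest never degrades.
#'
#' @param state a `land_state`.
#' @param rate annual degradation fraction, in `[0, 0.05]`.
#' @return list with `state` and `emissions_mtco2` (`>= 0`).
#' @export
degrade_forest <- function(state, rate) {
  if (rate < 0 || rate > 0.05)
    stop_invalid("degrade_forest: rate must be in [0, 0.05]")
  if (rate == 0) return(list(state = state, emissions_mtco2 = 0))
  carbon <- 0
  moved <- 0
  for (nm in c("primary", "secondary")) {
    pool <- state$pools[[nm]]
    dens <- stand_density(0:MAX_AGE, pool$curve)
    d_area <- pool$unprot * rate
    carbon <- carbon + sum(d_area * dens)
    pool$unprot <- pool$unprot - d_area
    state$pools[[nm]] <- pool
    moved <- moved + sum(d_area)
  }
  state$pools$secondary$unprot[1L] <- state$pools$secondary$unprot[1L] + moved
  list(state = state, emissions_mtco2 = c_to_co2(carbon))
}

#' Annual regrowth uptake and age advance
#'
#' For every age bin of every vegetated pool (protected and unprotected),
#' carbon uptake over one year is `area * (density(age + 1) - density(age))`,
#' reported as a negative CO2 flux; ages then advance by one year with the
#' top age bin absorbing.
#'
#' @param state a `land_state`.
#' @return list with `state` (aged by one year) and `uptake_mtco2` (`<= 0`).
#' @export
grow_and_age <- function(state) {
  uptake_c <- 0
  for (nm in names(state$pools)) {
    pool <- state$pools[[nm]]
    d0 <- stand_density(0:MAX_AGE, pool$curve)
    d1 <- stand_density(1:(MAX_AGE + 1L), pool$curve)
    inc <- d1 - d0
    uptake_c <- uptake_c + sum((pool$unprot + pool$prot) * inc)
    shift <- function(v) {
      s <- c(0, v[1:MAX_AGE])
      s[MAX_AGE + 1L] <- s[MAX_AGE + 1L] + v[MAX_AGE + 1L]
      s
    }
    pool$unprot <- shift(pool$unprot)
    pool$prot <- shift(pool$prot)
    state$pools[[nm]] <- pool
  }
  list(state = state, uptake_mtco2 = -c_to_co2(uptake_c))
}

#' Land pool areas of a region state
#'
#' @param state a `land_state`.
#' @param year reporting year attached to the rows.
#' @return long `data.frame`: `region_id`, `year`, `pool`, `area_mha`.
#' @export
land_pool_areas <- function(state, year = state$year) {
  data.frame(
    region_id = state$region_id, year = year,
    pool = c("cropland", "pasture", "other", "primary", "secondary",
             "plantation"),
    area_mha = c(state$cropland_mha, state$pasture_mha,
                 pool_area(state$pools$other), pool_area(state$pools$primary),
                 pool_area(state$pools$secondary),
                 pool_area(state$pools$plantation))
  )
}
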