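## Synthetic regional fixtures: regions, SSP-style population trajectories and
## regional parameter tables. Everything is deterministic given the master
## seed; substreams are split per generator (see substream_seed()).

## Default global calibration anchors (Mha / millions of persons). The land
## anchors are 2020 global pool areas; the reference total land is what
## generate_regions() allocates by default, so pool fractions are defined
## against it and global sums hit the anchors at default settings.
TC_DEFAULTS <- list(
  total_land_mha      = 12900,
  plantation_mha      = 137,
  cropland_mha        = 1595,
  natural_forest_mha  = 3629,
  pop_2020_million    = 7840,
  urban_share_2020    = 0.56,
  ## SSP-like global totals in 2100 (millions) and urban-share anchors.
  ## Totals are kept in a narrow band so that urbanization differences (not
  ## total population growth) dominate cross-SSP demand differences.
  pop_2100_million    = c(SSP1 = 8000, SSP2 = 9000, SSP3 = 10500),
  urban_share_2100    = c(SSP1 = 0.92, SSP2 = 0.80, SSP3 = 0.58)
)

#' Generate a synthetic region set
#'
#' Partitions a fixed global land area across `n_regions` regions with
#' heterogeneous sizes (normalised Gamma draws, so no region is vanishingly
#' small) and samples a protection share per region: the fraction of natural
#' forest and other land excluded from harvest (protected areas such as
#' strict reserves, frontier forests and biodiversity hotspots).
#'
#' @param n_regions number of regions (`>= 1`), default 12.
#' @param seed master seed.
#' @param total_land global land area to allocate (Mha).
#' @param protection_range range the protection share is drawn from.
#' @return a `data.frame` of class `region_set` with columns `region_id`,
#'   `name`, `total_land_mha`, `protection_share`.
#' @examples
#' generate_regions(3, seed = 1)
#' @export
generate_regions <- function(n_regions = 12, seed = 0,
                             total_land = TC_DEFAULTS$total_land_mha,
                             protection_range = c(0.1, 0.4)) {
  if (length(n_regions) != 1L || !is.finite(n_regions) || n_regions < 1)
    stop_invalid("generate_regions: n_regions must be >= 1")
  n_regions <- as.integer(n_regions)
  stopifnot(total_land > 0, length(protection_range) == 2L)
  with_seed(substream_seed(seed, "regions"), {
    w <- stats::rgamma(n_regions, shape = 5, rate = 1)
    prot <- stats::runif(n_regions, protection_range[1], protection_range[2])
    out <- data.frame(
      region_id = sprintf("R%02d", seq_len(n_regions)),
      name = paste("Region", seq_len(n_regions)),
      total_land_mha = total_land * w / sum(w),
      protection_share = prot,
      stringsAsFactors = FALSE
    )
    class(out) <- c("region_set", "data.frame")
    out
  })
}

#' Generate SSP-style urban/rural population trajectories
#'
#' Annual 2020-2100 urban and rural headcounts per region. Regional urban
#' headcounts rise along a smooth logistic-style ramp to a randomised peak
#' year in 2040-2090 and are held constant afterwards. Per-region 2100 urban
#' shares are drawn on the logit scale around the SSP anchor and then
#' recentred (one-dimensional root find on a common logit shift) so that the
#' global urban share of total population in 2100 equals the anchor exactly:
#' 92% (SSP1), 80% (SSP2), 58% (SSP3). Regional total populations follow a
#' smooth SSP-like global curve scaled by land-proportional 2020 weights.
#'
#' @param regions a [generate_regions()] result.
#' @param ssp `"SSP1"`, `"SSP2"` or `"SSP3"`.
#' @param seed master seed.
#' @param years simulation years (annual).
#' @return a `data.frame` of class `population_set` with columns `region_id`,
#'   `year`, `urban_million`, `rural_million`, plus an attribute `peak_year`
#'   (named integer vector per region). See [urban_peak_years()].
#' @export
generate_population <- function(regions, ssp = c("SSP2", "SSP1", "SSP3"),
                                seed = 0, years = 2020:2100) {
  ssp <- match.arg(ssp)
  stopifnot(inherits(regions, "data.frame"), nrow(regions) >= 1)
  y0 <- years[1]
  yN <- years[length(years)]
  target_share <- TC_DEFAULTS$urban_share_2100[[ssp]]
  ratio <- TC_DEFAULTS$pop_2100_million[[ssp]] / TC_DEFAULTS$pop_2020_million

  with_seed(substream_seed(seed, paste0("population-", ssp)), {
    n <- nrow(regions)
    ## 2020 population: proportional to land with lognormal heterogeneity
    w <- regions$total_land_mha * stats::rlnorm(n, 0, 0.3)
    pop0 <- TC_DEFAULTS$pop_2020_million * w / sum(w)
    share0 <- pmin(pmax(TC_DEFAULTS$urban_share_2020 +
                          stats::runif(n, -0.08, 0.08), 0.2), 0.85)
    peak <- y0 + 20 + round(stats::runif(n) * 50)      # peak year in 2040-2090
    delta <- stats::runif(n, -0.5, 0.5)                # logit-scale spread

    ## total population path per region (same global shape)
    ramp <- smoothstep((years - y0) / (yN - y0))
    pop_t <- outer(ramp, pop0, function(r, p) p * (1 + (ratio - 1) * r))

    ## recentre 2100 urban shares so the population-weighted mean hits the
    ## SSP anchor exactly
    pop_end <- pop_t[length(years), ]
    share_fun <- function(lambda)
      sum(pop_end * stats::plogis(stats::qlogis(target_share) + delta + lambda)) /
        sum(pop_end) - target_share
    lambda <- if (sum(pop_end) > 0)
      stats::uniroot(share_fun, c(-6, 6), tol = 1e-12)$root else 0
    share_end <- stats::plogis(stats::qlogis(target_share) + delta + lambda)

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      if (pop0[i] <= 0) {
        urban <- rural <- numeric(length(years))
      } else {
        u0 <- share0[i] * pop0[i]
        upeak <- max(share_end[i] * pop_end[i], u0)
        frac <- smoothstep((years - y0) / (peak[i] - y0))
        urban <- pmin(u0 + (upeak - u0) * frac, pop_t[, i])
        rural <- pmax(pop_t[, i] - urban, 0)
      }
      rows[[i]] <- data.frame(
        region_id = regions$region_id[i], year = years,
        urban_million = urban, rural_million = rural,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    peaks <- stats::setNames(as.integer(peak), regions$region_id)
    peaks[pop0 <= 0] <- y0
    attr(out, "peak_year") <- peaks
    attr(out, "ssp") <- ssp
    class(out) <- c("population_set", "data.frame")
    out
  })
}

#' Peak urban years of a population set
#'
#' Recomputes, per region, the first year at which the urban headcount attains
#' its maximum (the `t*` of the demand model). Because trajectories are
#' constant after their peak, this equals the generator's drawn peak year.
#'
#' @param population a [generate_population()] result.
#' @return named integer vector of peak years by region.
#' @export
urban_peak_years <- function(population) {
  stopifnot(all(c("region_id", "year", "urban_million") %in% names(population)))
  ids <- unique(population$region_id)
  vapply(ids, function(r) {
    d <- population[population$region_id == r, ]
    ## first year within 1e-9 of the maximum (plateau-safe)
    as.integer(d$year[which(d$urban_million >= max(d$urban_million) - 1e-9)[1]])
  }, integer(1))
}

#' Global urban share in a given year
#'
#' @param population a [generate_population()] result.
#' @param year calendar year (default the last year present).
#' @return urban share of global population, in percent.
#' @export
global_urban_share <- function(population, year = max(population$year)) {
  d <- population[population$year == year, ]
  100 * sum(d$urban_million) / sum(d$urban_million + d$rural_million)
}

#' Generate regional parameter tables
#'
#' Samples, per region: initial land pool areas (cropland, pasture, other
#' land, primary forest, secondary forest, plantation) that sum exactly to the
#' region's total land; Chapman-Richards growth-curve parameters for
#' plantation, natural forest and other-land vegetation; carbon densities for
#' cropland and pasture; per-capita woody biomass demand `M_w_c` and material
#' masses for conventional construction; the carbon-to-wood ratio CW (drawn
#' within 0.476 +/- 0.04); static manufacturing emission factors; and
#' exogenous industrial roundwood and wood fuel demand series.
#'
#' Pool areas are sampled proportionally to regional land with bounded
#' multiplicative noise, normalised so that at default settings the global
#' sums equal the 2020 anchors: plantations 137 Mha, cropland 1595 Mha,
#' natural forest 3629 Mha.
#'
#' @param regions a [generate_regions()] result.
#' @param seed master seed.
#' @param years years covered by the exogenous demand series.
#' @param M_w_c mean per-capita woody biomass demand for the primary structure
#'   and enclosure of a mid-rise timber building (tDM/person). The default 12
#'   corresponds to roughly 30 m2 of floor area per person at ~0.4 t of
#'   structural wood per m2, i.e. about 5.7 tC stored per person housed.
#' @param roundwood_mtc,woodfuel_mtc global exogenous demand (MtC/yr) for
#'   long-lived industrial roundwood products and wood fuel, split across
#'   regions by 2020 land-weighted shares and held flat.
#' @return a list of class `parameter_set` with elements `params` (one row
#'   per region) and `exogenous` (long `data.frame`: region, year, roundwood,
#'   wood fuel).
#' @export
generate_parameters <- function(regions, seed = 0, years = 2020:2100,
                                M_w_c = 12,
                                roundwood_mtc = 100, woodfuel_mtc = 400) {
  stopifnot(inherits(regions, "data.frame"), nrow(regions) >= 1)
  if (any(regions$total_land_mha <= 0))
    stop_invalid("generate_parameters: regions must have positive land")
  anch <- TC_DEFAULTS
  with_seed(substream_seed(seed, "parameters"), {
    n <- nrow(regions)
    w <- regions$total_land_mha

    ## pool fractions against the generator's reference global land, with
    ## land-weighted-normalised noise: global sums hit the anchors exactly at
    ## default settings and areas are homogeneous of degree 1 in total_land
    sample_pool <- function(anchor_mha) {
      nu <- stats::runif(n, 0.7, 1.3)
      nu <- nu * sum(w) / sum(w * nu)
      (anchor_mha / anch$total_land_mha) * w * nu
    }
    plantation <- sample_pool(anch$plantation_mha)
    cropland   <- sample_pool(anch$cropland_mha)
    natural    <- sample_pool(anch$natural_forest_mha)
    primary_frac <- stats::runif(n, 0.25, 0.45)
    primary   <- natural * primary_frac
    secondary <- natural - primary
    remainder <- w - plantation - cropland - natural
    if (any(remainder < 0))
      stop_invalid("generate_parameters: sampled pools exceed regional land")
    pasture <- remainder * stats::runif(n, 0.5, 0.7)
    other   <- remainder - pasture

    params <- data.frame(
      region_id = regions$region_id,
      protection_share = regions$protection_share,
      cropland_mha = cropland, pasture_mha = pasture, other_mha = other,
      primary_mha = primary, secondary_mha = secondary,
      plantation_mha = plantation,
      ## growth curves: fast plantations, slower natural forest, low-carbon
      ## other land (< 20 tC/ha by definition of the pool)
      plant_A = stats::runif(n, 90, 140),
      plant_k = stats::runif(n, 0.05, 0.09),
      plant_b = stats::runif(n, 1.8, 2.6),
      nat_A = stats::runif(n, 100, 160),
      nat_k = stats::runif(n, 0.025, 0.045),
      nat_b = stats::runif(n, 1.8, 2.4),
      other_A = stats::runif(n, 8, 18),
      other_k = stats::runif(n, 0.08, 0.12),
      other_b = stats::runif(n, 1.2, 1.8),
      cropland_tc_ha = stats::runif(n, 3, 7),
      pasture_tc_ha = stats::runif(n, 5, 10),
      M_w_c = M_w_c * stats::runif(n, 0.9, 1.1),
      CW = stats::runif(n, 0.476 - 0.04, 0.476 + 0.04),
      cement_t_cap = stats::runif(n, 8, 12),
      steel_t_cap = stats::runif(n, 1.0, 1.4),
      ef_wood = 0.25, ef_cement = 0.60, ef_steel = 1.85,
      stringsAsFactors = FALSE
    )

    share <- w / sum(w)
    exogenous <- do.call(rbind, lapply(seq_len(n), function(i) data.frame(
      region_id = regions$region_id[i], year = years,
      roundwood_mtc = roundwood_mtc * share[i],
      woodfuel_mtc = woodfuel_mtc * share[i],
      stringsAsFactors = FALSE
    )))
    rownames(exogenous) <- NULL
    structure(list(params = params, exogenous = exogenous),
              class = "parameter_set")
  })
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("Parameter set: %d regions, exogenous demand %d-%d\n",
              nrow(x$params), min(x$exogenous$year), max(x$exogenous$year)))
  cat(sprintf("  global pools (Mha): plantation %.1f, cropland %.1f, natural forest %.1f\n",
              sum(x$params$plantation_mha), sum(x$params$cropland_mha),
              sum(x$params$primary_mha + x$params$secondary_mha)))
  invisible(x)
}

#' Write the synthetic fixture CSVs
#'
#' Writes `regions.csv`, `population.csv` and `parameters.csv` (long format)
#' as plain UTF-8 CSV with '.' decimal separator and a header row.
#'
#' @param regions,population,parameters generator outputs.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_fixtures <- function(regions, population, parameters, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "regions.csv")
  utils::write.csv(as.data.frame(regions), p1, row.names = FALSE)
  p2 <- file.path(dir, "population.csv")
  utils::write.csv(as.data.frame(population), p2, row.names = FALSE)
  p3 <- file.path(dir, "parameters.csv")
  long <- stats::reshape(parameters$params, direction = "long",
                         varying = setdiff(names(parameters$params), "region_id"),
                         v.names = "value", timevar = "parameter",
                         times = setdiff(names(parameters$params), "region_id"),
                         idvar = "region_id")
  long <- long[order(long$region_id, long$parameter),
               c("region_id", "parameter", "value")]
  utils::write.csv(long, p3, row.names = FALSE)
  p4 <- file.path(dir, "exogenous_demand.csv")
  utils::write.csv(parameters$exogenous, p4, row.names = FALSE)
  invisible(c(p1, p2, p3, p4))
}
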