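## Harvested-wood-product carbon pools: IPCC tier-1 first-order decay with
## the annual-average inflow term. Two pools per region: industrial roundwood
## (half-life 35 y) and engineered wood in buildings (half-life 60 y). Stocks
## are zero until 2020.

#' Decay constant from a half-life
#'
#' `k = ln(2) / half_life` (1/yr).
#'
#' @param half_life half-life in years, `> 0`.
#' @return decay constant (1/yr).
#' @examples
#' decay_constant(60) # 0.01155245
#' @export
decay_constant <- function(half_life) {
  if (any(half_life <= 0)) stop_invalid("decay_constant: half_life must be > 0")
  log(2) / half_life
}

#' Create a harvested-wood-product pool
#'
#' @param product `"industrial_roundwood"` or `"engineered_wood"`.
#' @param half_life decay half-life in years (defaults: 35 for industrial
#'   roundwood, 60 for engineered wood).
#' @param stock initial carbon stock (MtC), default 0 (no considerable HWP
#'   stock is assumed to exist before 2020).
#' @return a list of class `hwp_pool` with fields `product`, `half_life`,
#'   `k`, `stock`.
#' @export
hwp_pool <- function(product = c("industrial_roundwood", "engineered_wood"),
                     half_life = NULL, stock = 0) {
  product <- match.arg(product)
  if (is.null(half_life))
    half_life <- switch(product, industrial_roundwood = 35, engineered_wood = 60)
  if (stock < 0) stop_invalid("hwp_pool: stock must be >= 0")
  structure(list(product = product, half_life = half_life,
                 k = decay_constant(half_life), stock = stock),
            class = "hwp_pool")
}

#' @export
print.hwp_pool <- function(x, ...) {
  cat(sprintf("HWP pool '%s': half-life %.4g yr (k = %.6g /yr), stock %.4g MtC\n",
              x$product, x$half_life, x$k, x$stock))
  invisible(x)
}

#' Advance an HWP pool by one year
#'
#' First-order decay with the annual-average inflow term:
#' `C_{t+1} = exp(-k) * C_t + ((1 - exp(-k)) / k) * inflow_t`.
#' The effective inflow `((1 - exp(-k)) / k) * inflow` is what enters the
#' stock (inflow decays within its first year too); the decay release is the
#' mass-balance residual `C_t + effective_inflow - C_{t+1}`, converted to
#' CO2 — always `>= 0`.
#'
#' @param pool an [hwp_pool()].
#' @param inflow carbon inflow during the year (MtC/yr), `>= 0`.
#' @return list with `pool` (stock advanced), `stock_next` (MtC),
#'   `delta_mtc` (stock change `C_{t+1} - C_t`), `credit_mtc` (effective
#'   inflow booked as storage), `release_mtco2` (decay outflow as CO2).
#' @examples
#' p <- hwp_pool("engineered_wood", stock = 100)
#' update_pool(p, 10)$stock_next # 108.794
#' @export
update_pool <- function(pool, inflow) {
  stopifnot(inherits(pool, "hwp_pool"))
  if (inflow < 0) stop_invalid("update_pool: inflow must be >= 0")
  k <- pool$k
  eff_inflow <- (1 - exp(-k)) / k * inflow
  stock_next <- exp(-k) * pool$stock + eff_inflow
  release_c <- pool$stock + eff_inflow - stock_next   # = (1 - e^-k) * C_t
  delta <- stock_next - pool$stock
  pool$stock <- stock_next
  list(pool = pool, stock_next = stock_next, delta_mtc = delta,
       credit_mtc = eff_inflow, release_mtco2 = c_to_co2(max(release_c, 0)))
}

#' Decay release of an HWP pool over one year
#'
#' The CO2 outflow from first-order decay, computed as the mass-balance
#' residual of the pool update for a given inflow (for zero inflow this is
#' `(1 - exp(-k)) * C_t * 44/12`).
#'
#' @param pool an [hwp_pool()].
#' @param inflow carbon inflow during the year (MtC/yr).
#' @return release (MtCO2/yr, `>= 0`).
#' @export
decay_release <- function(pool, inflow = 0) {
  update_pool(pool, inflow)$release_mtco2
}

#' Simulate an HWP pool over an inflow series
#'
#' Iterates [update_pool()] over an annual inflow series and returns the
#' stock, storage credit and decay release per year.
#'
#' @param pool an [hwp_pool()].
#' @param inflow numeric vector of annual carbon inflows (MtC/yr).
#' @param years optional year labels.
#' @return `data.frame` with `year`, `inflow_mtc`, `stock_mtc` (end of
#'   year), `credit_mtc`, `release_mtco2`, `delta_mtc`.
#' @export
simulate_hwp <- function(pool, inflow, years = seq_along(inflow)) {
  stopifnot(length(inflow) == length(years))
  n <- length(inflow)
  stock <- credit <- release <- delta <- numeric(n)
  for (i in seq_len(n)) {
    u <- update_pool(pool, inflow[i])
    pool <- u$pool
    stock[i] <- u$stock_next
    credit[i] <- u$credit_mtc
    release[i] <- u$release_mtco2
    delta[i] <- u$delta_mtc
  }
  data.frame(year = years, inflow_mtc = inflow, stock_mtc = stock,
             credit_mtc = credit, release_mtco2 = release, delta_mtc = delta)
}
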