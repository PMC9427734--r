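#' timbercities: land-use change and carbon accounting for timber-city scenarios
#'
#' Simulates the land-use and CO2 consequences of housing new urban dwellers in
#' engineered-wood buildings over 2020-2100. The pipeline couples four stages:
#' an urbanization-driven demand model for engineered wood, age-class forest
#' plantation dynamics with rotation lengths set by the current annual
#' increment, IPCC tier-1 first-order-decay harvested-wood-product carbon
#' pools, and a signed emission ledger combining land fluxes with building
#' material manufacturing. Scenarios are defined by the fraction PR of new
#' urban dwellers housed in wood (0, 0.1, 0.5, 0.9) crossed with SSP1/2/3
#' urbanization pathways, run on seeded synthetic regional fixtures.
#'
#' @keywords internal
"_PACKAGE"

## Mass conversion: molecular weight ratio CO2/C.
C_TO_CO2 <- 44 / 12

#' Convert carbon mass to CO2 mass
#'
#' Multiplies by the molecular-weight ratio 44/12. Every carbon mass in the
#' model crosses into CO2 exactly once, through this function, inside the
#' emission ledger.
#'
#' @param x carbon mass (any unit).
#' @return CO2 mass in the same unit system.
#' @seealso [co2_to_c()]
#' @export
c_to_co2 <- function(x) x * C_TO_CO2

#' Convert CO2 mass to carbon mass
#'
#' @param x CO2 mass.
#' @return carbon mass.
#' @export
co2_to_c <- function(x) x * 12 / 44

#' Derive a substream seed from a master seed
#'
#' All randomness in the synthetic-data generators flows from one master seed.
#' Substreams (regions, population, parameters, ...) get their own seed via a
#' fixed integer hash of the master seed and a stream label, so adding a new
#' draw to one generator never perturbs another. Results stay within the
#' 32-bit integer range `set.seed()` accepts.
#'
#' @param seed master seed (single integer).
#' @param stream character label of the substream.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729 + 12345) %% 2147483647)
}

## Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
## RNG state is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Smooth monotone ramp on [0, 1] (cubic smoothstep); used for population
## trajectories.
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

stop_invalid <- function(...) stop(..., call. = FALSE)
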