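# Patient transport time costing and CO2 emission accounting.

#' Transport profile of a care model
#'
#' Describes the clinic travel an episode of care requires. Digital care has
#' `mode = "none"` and by construction zero transport time and zero emissions.
#' Per-episode emissions may be given directly (the conventional estimate) or
#' decomposed into distance times an emission factor; when both are supplied
#' they must agree to within 1%.
#'
#' @param mode `"car"`, `"bus"`, or `"none"`.
#' @param round_trip_minutes Average round-trip travel time per visit.
#' @param visits_per_episode Number of clinic visits per episode.
#' @param emission_tons_per_episode Direct per-episode CO2 estimate, tonnes.
#' @param round_trip_km,kg_co2_per_km Optional decomposition of the emission
#'   estimate.
#' @param emission_value_sek_per_ton Optional effective CO2 price (SEK/tonne)
#'   used when valuing this profile's emissions in a cost breakdown; `NULL`
#'   means value at the market [emission_price()].
#' @return An object of class `transport_profile`.
#' @examples
#' transport_profile("car", round_trip_minutes = 52.5, visits_per_episode = 28,
#'                   emission_tons_per_episode = 0.014)
#' @export
transport_profile <- function(mode = c("none", "car", "bus"),
                              round_trip_minutes = 0,
                              visits_per_episode = 0,
                              emission_tons_per_episode = 0,
                              round_trip_km = NULL,
                              kg_co2_per_km = NULL,
                              emission_value_sek_per_ton = NULL) {
  mode <- match.arg(mode)
  check_nonneg(round_trip_minutes, "round_trip_minutes")
  check_nonneg(visits_per_episode, "visits_per_episode")
  check_nonneg(emission_tons_per_episode, "emission_tons_per_episode")
  if (mode == "none" && (round_trip_minutes > 0 || emission_tons_per_episode > 0)) {
    abort_validation("mode \"none\" implies zero travel time and zero emissions")
  }
  structure(
    list(
      mode = mode,
      round_trip_minutes = round_trip_minutes,
      visits_per_episode = visits_per_episode,
      emission_tons_per_episode = emission_tons_per_episode,
      round_trip_km = round_trip_km,
      kg_co2_per_km = kg_co2_per_km,
      emission_value_sek_per_ton = emission_value_sek_per_ton
    ),
    class = "transport_profile"
  )
}

#' CO2 emission price
#'
#' Market price of one tonne of CO2 (EU emissions-trading scale), in USD,
#' converted to SEK at the valuation context's exchange rate.
#'
#' @param usd_per_ton Price per tonne CO2 in USD. Default 220.
#' @return An object of class `emission_price`.
#' @export
emission_price <- function(usd_per_ton = 220) {
  check_nonneg(usd_per_ton, "usd_per_ton")
  structure(list(usd_per_ton = usd_per_ton), class = "emission_price")
}

#' Cost of patient travel time
#'
#' Travel time is leisure time: visits times the round trip, valued at the
#' population gross wage scaled by the leisure fraction.
#'
#' @param profile A [transport_profile()].
#' @param ctx A [valuation_context()].
#' @return Transport time cost per episode, SEK.
#' @examples
#' ctx <- valuation_context(187.2, 100, leisure_fraction = 0.3)
#' transport_time_cost(
#'   transport_profile("car", round_trip_minutes = 60, visits_per_episode = 1),
#'   ctx) # 30
#' @export
transport_time_cost <- function(profile, ctx) {
  stopifnot(inherits(profile, "transport_profile"),
            inherits(ctx, "valuation_context"))
  if (profile$mode == "none") return(0)
  hours <- profile$visits_per_episode * profile$round_trip_minutes / 60
  value_labour_time(hours, ctx$population_gross_hourly_wage,
                    "patient_leisure", ctx)
}

#' Per-episode CO2 emissions of clinic travel
#'
#' Returns the direct per-episode estimate, or computes it from the
#' distance decomposition when one is supplied. If both are present they are
#' cross-validated: a mismatch above 1% is a validation error.
#'
#' @param profile A [transport_profile()].
#' @return Emissions per episode, tonnes CO2.
#' @examples
#' episode_emissions(transport_profile("car", round_trip_minutes = 40,
#'   visits_per_episode = 7, round_trip_km = 10, kg_co2_per_km = 0.2)) # 0.014
#' @export
episode_emissions <- function(profile) {
  stopifnot(inherits(profile, "transport_profile"))
  if (profile$mode == "none") return(0)
  direct <- profile$emission_tons_per_episode
  has_decomp <- !is.null(profile$round_trip_km) && !is.null(profile$kg_co2_per_km)
  if (!has_decomp) return(direct)
  decomposed <- profile$round_trip_km * profile$kg_co2_per_km *
    profile$visits_per_episode / 1000
  if (direct > 0) {
    rel <- abs(decomposed - direct) / direct
    if (rel > 0.01) {
      abort_validation(sprintf(
        "emission decomposition (%.4f t) disagrees with direct estimate (%.4f t) by %.1f%%",
        decomposed, direct, 100 * rel))
    }
    return(direct)
  }
  decomposed
}

#' Cohort-level CO2 emissions
#'
#' @param per_episode Emissions per episode, tonnes CO2.
#' @param n_episodes Number of episodes of care.
#' @return Total emissions, tonnes CO2 (exact product).
#' @examples
#' cohort_emissions(0.014, 9500) # 133
#' @export
cohort_emissions <- function(per_episode, n_episodes) {
  check_nonneg(per_episode, "per_episode")
  check_nonneg(n_episodes, "n_episodes")
  per_episode * n_episodes
}

#' Monetary value of CO2 emissions
#'
#' Values emissions at the USD market price converted to SEK with the
#' context's exchange rate (USD per 100 SEK).
#'
#' @param tons Emissions, tonnes CO2.
#' @param price An [emission_price()].
#' @param ctx A [valuation_context()] supplying the USD exchange rate.
#' @return Value in SEK.
#' @examples
#' ctx <- valuation_context(187.2, 196.58)
#' emissions_value(133, emission_price(220), ctx)
#' @export
emissions_value <- function(tons, price, ctx) {
  check_nonneg(tons, "tons")
  stopifnot(inherits(price, "emission_price"),
            inherits(ctx, "valuation_context"))
  sek_per_ton <- price$usd_per_ton * 100 / ctx$fx_usd_per_100_sek
  tons * sek_per_ton
}
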