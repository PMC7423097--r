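# Valuation context and the elementary time/resource valuation rules.

#' Monetary valuation context
#'
#' Collects every monetary-valuation parameter of the societal costing model
#' in one auditable record: gross hourly wages, the employer social-fee rate,
#' the leisure-time fraction, the facility surcharge applied to on-site staff
#' time, the annual patient user-fee ceiling, the training wage multiplier,
#' and the currency conversion rates used only at report time.
#'
#' @param provider_gross_hourly_wage Gross hourly wage of the care provider
#'   (physiotherapist), SEK/h.
#' @param population_gross_hourly_wage Mean gross hourly wage of the general
#'   population, SEK/h, used to value patient time.
#' @param social_fee_rate Employer non-wage social fees as a fraction of gross
#'   wage. Default 0.3142, the legally mandated minimum rate; an alternative
#'   convention of 0.501 (average fees including collectively agreed ones)
#'   may be supplied instead.
#' @param leisure_fraction Fraction of the gross wage at which patient leisure
#'   time (travel) is valued. Default 0.30.
#' @param facility_surcharge Surcharge on on-site staff time covering facility
#'   rent. Default 0.10.
#' @param user_fee_ceiling Annual out-of-pocket user-fee ceiling, SEK/year;
#'   all patients are assumed to reach it. Default 1100.
#' @param training_wage_multiplier Wage multiplier for provider training time
#'   (trainer plus overheads). Default 1.5.
#' @param fx_usd_per_100_sek,fx_eur_per_100_sek USD and EUR per 100 SEK,
#'   defaults 10.2 and 9.43; used for report-time conversion only.
#' @param reference_year Price year of all monetary values. Default 2018.
#'
#' @return An object of class `valuation_context`.
#' @examples
#' ctx <- valuation_context(187.2, 196.58)
#' ctx$social_fee_rate
#' @export
valuation_context <- function(provider_gross_hourly_wage,
                              population_gross_hourly_wage,
                              social_fee_rate = 0.3142,
                              leisure_fraction = 0.30,
                              facility_surcharge = 0.10,
                              user_fee_ceiling = 1100,
                              training_wage_multiplier = 1.5,
                              fx_usd_per_100_sek = 10.2,
                              fx_eur_per_100_sek = 9.43,
                              reference_year = 2018) {
  check_nonneg(provider_gross_hourly_wage, "provider_gross_hourly_wage")
  check_nonneg(population_gross_hourly_wage, "population_gross_hourly_wage")
  check_fraction(social_fee_rate, "social_fee_rate")
  check_fraction(leisure_fraction, "leisure_fraction")
  check_fraction(facility_surcharge, "facility_surcharge")
  check_nonneg(user_fee_ceiling, "user_fee_ceiling")
  if (!is.numeric(training_wage_multiplier) || training_wage_multiplier < 1) {
    abort_domain("`training_wage_multiplier` must be >= 1")
  }
  if (fx_usd_per_100_sek <= 0 || fx_eur_per_100_sek <= 0) {
    abort_domain("FX rates must be positive")
  }
  structure(
    list(
      provider_gross_hourly_wage = provider_gross_hourly_wage,
      population_gross_hourly_wage = population_gross_hourly_wage,
      social_fee_rate = social_fee_rate,
      leisure_fraction = leisure_fraction,
      facility_surcharge = facility_surcharge,
      user_fee_ceiling = user_fee_ceiling,
      training_wage_multiplier = training_wage_multiplier,
      fx_usd_per_100_sek = fx_usd_per_100_sek,
      fx_eur_per_100_sek = fx_eur_per_100_sek,
      reference_year = reference_year
    ),
    class = "valuation_context"
  )
}

#' @export
print.valuation_context <- function(x, ...) {
  cat("<valuation_context> (reference year ", x$reference_year, ")\n", sep = "")
  cat(sprintf("  provider wage   %8.2f SEK/h  (+%.2f%% social fees)\n",
              x$provider_gross_hourly_wage, 100 * x$social_fee_rate))
  cat(sprintf("  population wage %8.2f SEK/h  (leisure fraction %.0f%%)\n",
              x$population_gross_hourly_wage, 100 * x$leisure_fraction))
  cat(sprintf("  facility surcharge %.0f%%, user-fee ceiling %.0f SEK/yr\n",
              100 * x$facility_surcharge, x$user_fee_ceiling))
  cat(sprintf("  100 SEK = %.2f USD = %.2f EUR\n",
              x$fx_usd_per_100_sek, x$fx_eur_per_100_sek))
  invisible(x)
}

#' Value labour time with the human capital method
#'
#' Provider time is valued at the gross wage plus employer social fees, with a
#' facility surcharge when delivered on site. Patient time is valued at the
#' gross population wage without social fees, either in full (care-contact
#' time) or at the leisure fraction (travel and other leisure time).
#'
#' @param hours Hours of time, >= 0.
#' @param wage Gross hourly wage, SEK/h, >= 0.
#' @param role One of `"provider"`, `"patient_full"`, `"patient_leisure"`.
#' @param ctx A [valuation_context()].
#' @param on_site Does the time accrue on site (triggers the facility
#'   surcharge for providers)? Default `FALSE`.
#'
#' @return Monetary value in SEK (full precision, unrounded).
#' @examples
#' ctx <- valuation_context(187.2, 196.58, social_fee_rate = 0.3142)
#' value_labour_time(1, 200, "provider", ctx)          # 262.84
#' value_labour_time(2, 196.6, "patient_leisure", ctx) # 117.96
#' @export
value_labour_time <- function(hours, wage,
                              role = c("provider", "patient_full", "patient_leisure"),
                              ctx, on_site = FALSE) {
  role <- match.arg(role)
  check_nonneg(hours, "hours")
  check_nonneg(wage, "wage")
  stopifnot(inherits(ctx, "valuation_context"))
  switch(role,
    provider = hours * wage * (1 + ctx$social_fee_rate) *
      (if (isTRUE(on_site)) 1 + ctx$facility_surcharge else 1),
    patient_full = hours * wage,
    patient_leisure = hours * wage * ctx$leisure_fraction
  )
}

#' Allocate a group-session cost to one participant
#'
#' Group-based sessions use the same provider and facility time regardless of
#' attendance, so the per-patient unit cost divides the session cost by the
#' average group size. The undivided session cost remains the payer-perspective
#' figure and should be reported separately.
#'
#' @param session_cost Cost of the whole session, SEK.
#' @param group_size Average number of participants, >= 1.
#' @return Per-participant cost, SEK.
#' @examples
#' allocate_group_session(8778, 14) # 627
#' @export
allocate_group_session <- function(session_cost, group_size) {
  check_nonneg(session_cost, "session_cost")
  if (!is.numeric(group_size) || length(group_size) != 1L || is.na(group_size) ||
      group_size < 1) {
    abort_domain("`group_size` must be >= 1")
  }
  session_cost / group_size
}

#' Per-episode technical support cost
#'
#' The annual support budget is spread over the annual patient volume. The
#' face-to-face comparator, whose support costs are unobserved, is assumed to
#' incur half of the digital model's per-patient support cost (`halved = TRUE`).
#'
#' @param annual_budget Total annual support cost, SEK.
#' @param annual_patients Number of patients served per year, >= 1.
#' @param halved Apply the half-of-comparator assumption? Default `FALSE`.
#' @return Support cost per episode, SEK.
#' @examples
#' technical_support_unit_cost(100000, 1000)               # 100
#' technical_support_unit_cost(100000, 1000, halved = TRUE) # 50
#' @export
technical_support_unit_cost <- function(annual_budget, annual_patients,
                                        halved = FALSE) {
  check_nonneg(annual_budget, "annual_budget")
  if (!is.numeric(annual_patients) || length(annual_patients) != 1L ||
      is.na(annual_patients) || annual_patients < 1) {
    abort_domain("`annual_patients` must be >= 1")
  }
  annual_budget / annual_patients * (if (isTRUE(halved)) 0.5 else 1)
}

#' Amortize one-off provider training over episodes of care
#'
#' Certification/training time is a one-off activity: it is valued at the
#' provider wage times the training multiplier (trainer time and overheads)
#' plus social fees, and spread over the episodes a trained provider delivers.
#' Reported as a separate cost category.
#'
#' @param training_hours Hours of training per provider, >= 0.
#' @param wage Provider gross hourly wage, SEK/h.
#' @param ctx A [valuation_context()] supplying the multiplier and fee rate.
#' @param episodes_per_provider Episodes delivered per trained provider, >= 1.
#' @return Training cost per episode, SEK.
#' @examples
#' ctx <- valuation_context(187.2, 196.58, social_fee_rate = 0)
#' amortize_training(2, 200, ctx, 60) # 10
#' @export
amortize_training <- function(training_hours, wage, ctx, episodes_per_provider) {
  check_nonneg(training_hours, "training_hours")
  check_nonneg(wage, "wage")
  stopifnot(inherits(ctx, "valuation_context"))
  if (!is.numeric(episodes_per_provider) || length(episodes_per_provider) != 1L ||
      is.na(episodes_per_provider) || episodes_per_provider < 1) {
    abort_domain("`episodes_per_provider` must be >= 1")
  }
  training_hours * wage * ctx$training_wage_multiplier *
    (1 + ctx$social_fee_rate) / episodes_per_provider
}
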