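# Shared fixtures: shipped configurations and a plain context for unit tests.

shipped_ctx <- function() read_valuation_context(oacost_example("valuation.yaml"))
shipped_ja <- function() read_care_model(oacost_example("ja.yaml"))
shipped_boa <- function() read_care_model(oacost_example("boa.yaml"))

# A minimal context with transparent numbers for hand-checkable arithmetic.
plain_ctx <- function(...) {
  valuation_context(provider_gross_hourly_wage = 200,
                    population_gross_hourly_wage = 100, ...)
}

# A small fully deterministic care model used in property tests.
toy_model <- function(name = "toy", group_size = 4) {
  care_model_spec(
    name = name,
    contacts = list(
      contact_event("lecture", "in_person", 60, occurrences = 2,
                    group_size = group_size, once_per_episode = TRUE),
      contact_event("session", "in_person", 45, occurrences = 6,
                    group_size = group_size),
      contact_event("call", "telephone", 10, occurrences = 3, on_site = FALSE)
    ),
    admin_overhead = list(system = list(hours = 1), patient = list(hours = 0.5)),
    training_hours_per_provider = 4, episodes_per_provider = 50,
    annual_support_budget = 50000, annual_patient_count = 500,
    facility_based = TRUE, average_group_size = group_size,
    transport = transport_profile("car", round_trip_minutes = 40,
                                  visits_per_episode = 8,
                                  emission_tons_per_episode = 0.004)
  )
}

# Zero-variance cohort configuration: reproduces the deterministic pipeline.
degenerate_config <- function(n, seed = 1, transport_mean = 52.5,
                              pain = list(pre_mean = 5.7, pre_sd = 0,
                                          post_mean = 3.2, post_sd = 0)) {
  cohort_config(n, seed = seed, duration_jitter = 0,
                transport_minutes = list(mean = transport_mean, sd = 0),
                wage_cv = 0, pain = pain,
                participation_rates = list(exercise_session = 1,
                                           copatient_lecture = 1))
}
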