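# Structured configuration files: care models, valuation contexts, cohort
# configurations, and run configurations (YAML), with schema validation that
# names the offending field.

#' Path to a shipped example configuration
#'
#' The package ships the two care-model configurations (`boa.yaml`,
#' `ja.yaml`), the valuation context (`valuation.yaml`), and an example run
#' configuration (`run.yaml`). The numeric parameters in the care-model files
#' are calibrated so that the costing engine reproduces the published unit
#' cost tables; see the package vignette.
#'
#' @param file File name under the package's `extdata` directory; omit to
#'   list available files.
#' @return Full path to the file.
#' @examples
#' oacost_example("ja.yaml")
#' @export
oacost_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "oacost")))
  }
  path <- system.file("extdata", file, package = "oacost")
  if (path == "") abort_validation(sprintf("no shipped example file `%s`", file))
  path
}

require_fields <- function(x, required, what) {
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort_validation(sprintf("%s: missing required field `%s`",
                             what, missing[1]))
  }
}

reject_unknown <- function(x, known, what) {
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    abort_validation(sprintf("%s: unknown field `%s`", what, unknown[1]))
  }
}

read_yaml_checked <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("config file does not exist: %s", path))
  }
  yaml::read_yaml(path)
}

#' Read a care-model configuration
#'
#' Parses and schema-validates a YAML care-model file into a
#' [care_model_spec()]. Validation errors name the offending field.
#'
#' @param path Path to a YAML file; see [oacost_example()] for the shipped
#'   `boa.yaml` and `ja.yaml`.
#' @return A `care_model_spec`.
#' @export
read_care_model <- function(path) {
  y <- read_yaml_checked(path)
  known <- c("name", "episode_weeks", "contacts", "admin_overhead",
             "training_hours_per_provider", "episodes_per_provider",
             "annual_support_budget", "annual_patient_count",
             "support_halving_rule", "facility_based", "average_group_size",
             "provider_contact_hours_override",
             "patient_contact_hours_override", "transport", "effects",
             "notes")
  require_fields(y, c("name", "contacts"), "care model")
  reject_unknown(y, known, "care model")

  ev_known <- c("label", "mode", "duration_minutes", "occurrences",
                "provider_attends", "patient_attends", "group_size",
                "on_site", "once_per_episode", "participation_class")
  contacts <- lapply(y$contacts, function(e) {
    require_fields(e, c("label", "mode", "duration_minutes"), "contact")
    reject_unknown(e, ev_known, sprintf("contact `%s`", e$label %||% "?"))
    contact_event(
      label = e$label, mode = e$mode,
      duration_minutes = unlist(e$duration_minutes),
      occurrences = e$occurrences %||% 1,
      provider_attends = e$provider_attends %||% TRUE,
      patient_attends = e$patient_attends %||% TRUE,
      group_size = e$group_size %||% 1,
      on_site = e$on_site %||% (e$mode == "in_person"),
      once_per_episode = e$once_per_episode %||% FALSE,
      participation_class = e$participation_class
    )
  })

  tp <- y$transport
  transport <- if (is.null(tp)) {
    transport_profile(mode = "none")
  } else {
    tp_known <- c("mode", "round_trip_minutes", "visits_per_episode",
                  "emission_tons_per_episode", "round_trip_km",
                  "kg_co2_per_km", "emission_value_sek_per_ton")
    reject_unknown(tp, tp_known, "transport")
    transport_profile(
      mode = tp$mode %||% "none",
      round_trip_minutes = tp$round_trip_minutes %||% 0,
      visits_per_episode = tp$visits_per_episode %||% 0,
      emission_tons_per_episode = tp$emission_tons_per_episode %||% 0,
      round_trip_km = tp$round_trip_km,
      kg_co2_per_km = tp$kg_co2_per_km,
      emission_value_sek_per_ton = tp$emission_value_sek_per_ton
    )
  }

  care_model_spec(
    name = y$name, contacts = contacts,
    episode_weeks = y$episode_weeks %||% 12,
    admin_overhead = y$admin_overhead %||% list(),
    training_hours_per_provider = y$training_hours_per_provider %||% 0,
    episodes_per_provider = y$episodes_per_provider %||% 1,
    annual_support_budget = y$annual_support_budget %||% 0,
    annual_patient_count = y$annual_patient_count %||% 1,
    support_halving_rule = y$support_halving_rule %||% FALSE,
    facility_based = y$facility_based %||% FALSE,
    average_group_size = y$average_group_size %||% 1,
    provider_contact_hours_override = y$provider_contact_hours_override,
    patient_contact_hours_override = y$patient_contact_hours_override,
    transport = transport,
    effects = y$effects
  )
}

#' Read a valuation context configuration
#'
#' @param path Path to a YAML file; the shipped `valuation.yaml` carries the
#'   2018 Swedish wage and fee parameters.
#' @return A [valuation_context()].
#' @export
read_valuation_context <- function(path) {
  y <- read_yaml_checked(path)
  known <- c("provider_gross_hourly_wage", "population_gross_hourly_wage",
             "social_fee_rate", "leisure_fraction", "facility_surcharge",
             "user_fee_ceiling", "training_wage_multiplier",
             "fx_usd_per_100_sek", "fx_eur_per_100_sek", "reference_year",
             "notes")
  require_fields(y, c("provider_gross_hourly_wage",
                      "population_gross_hourly_wage"), "valuation context")
  reject_unknown(y, known, "valuation context")
  valuation_context(
    provider_gross_hourly_wage = y$provider_gross_hourly_wage,
    population_gross_hourly_wage = y$population_gross_hourly_wage,
    social_fee_rate = y$social_fee_rate %||% 0.3142,
    leisure_fraction = y$leisure_fraction %||% 0.30,
    facility_surcharge = y$facility_surcharge %||% 0.10,
    user_fee_ceiling = y$user_fee_ceiling %||% 1100,
    training_wage_multiplier = y$training_wage_multiplier %||% 1.5,
    fx_usd_per_100_sek = y$fx_usd_per_100_sek %||% 10.2,
    fx_eur_per_100_sek = y$fx_eur_per_100_sek %||% 9.43,
    reference_year = y$reference_year %||% 2018
  )
}

#' Read a synthetic-cohort configuration
#'
#' @param path Path to a YAML file with the [cohort_config()] fields
#'   (`n_patients` and `seed` are required).
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  y <- read_yaml_checked(path)
  known <- c("n_patients", "seed", "duration_jitter", "transport_minutes",
             "wage_cv", "pain", "participation_rates", "notes")
  require_fields(y, c("n_patients", "seed"), "cohort config")
  reject_unknown(y, known, "cohort config")
  defaults <- formals(cohort_config)
  cohort_config(
    n_patients = y$n_patients, seed = y$seed,
    duration_jitter = y$duration_jitter %||% eval(defaults$duration_jitter),
    transport_minutes = y$transport_minutes %||% eval(defaults$transport_minutes),
    wage_cv = y$wage_cv %||% eval(defaults$wage_cv),
    pain = y$pain %||% eval(defaults$pain),
    participation_rates = y$participation_rates %||%
      eval(defaults$participation_rates)
  )
}

RUN_CONFIG_FIELDS <- c("care_models", "valuation", "cohort", "output_dir",
                       "formats", "scenario_mode", "social_fee_rate",
                       "log_level", "seed")

#' Load and validate a run configuration
#'
#' A run configuration ties a whole analysis together: paths to the
#' care-model and valuation configs, an optional cohort config, the output
#' directory, report formats, and mode switches. Relative paths are resolved
#' against the config file's directory. Every resolved value (including
#' defaults) is echoed into the object's `log` attribute for auditability.
#'
#' @param config_path Path to a YAML run configuration.
#' @return An object of class `run_config`.
#' @export
load_and_validate <- function(config_path) {
  y <- read_yaml_checked(config_path)
  reject_unknown(y, RUN_CONFIG_FIELDS, "run config")
  require_fields(y, c("care_models", "valuation"), "run config")
  base <- dirname(normalizePath(config_path))
  resolve <- function(p) {
    if (file.exists(p)) normalizePath(p) else normalizePath(file.path(base, p),
                                                            mustWork = FALSE)
  }
  cfg <- list(
    care_models = vapply(y$care_models, resolve, character(1)),
    valuation = resolve(y$valuation),
    cohort = if (!is.null(y$cohort)) resolve(y$cohort) else NULL,
    output_dir = y$output_dir %||% ".",
    formats = y$formats %||% "csv",
    scenario_mode = y$scenario_mode %||% "standard",
    social_fee_rate = y$social_fee_rate,
    log_level = y$log_level %||% "info",
    seed = y$seed
  )
  for (p in c(cfg$care_models, cfg$valuation, cfg$cohort)) {
    if (!file.exists(p)) {
      abort_validation(sprintf("run config: referenced file does not exist: %s", p))
    }
  }
  if (!cfg$scenario_mode %in% c("standard", "as_printed")) {
    abort_validation("run config: `scenario_mode` must be standard or as_printed")
  }
  bad_fmt <- setdiff(cfg$formats, c("csv", "json"))
  if (length(bad_fmt) > 0) {
    abort_validation(sprintf("run config: unknown format `%s`", bad_fmt[1]))
  }
  defaults_used <- setdiff(c("output_dir", "formats", "scenario_mode",
                             "log_level"), names(y))
  log <- vapply(names(cfg), function(f) {
    sprintf("%s %s = %s%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), f,
            paste(format(cfg[[f]]), collapse = ", "),
            if (f %in% defaults_used) " [default]" else "")
  }, character(1))
  structure(cfg, class = "run_config", log = log)
}

#' Write a run configuration
#'
#' Serializes a `run_config` back to YAML such that
#' [load_and_validate()] on the written file yields an equal configuration.
#'
#' @param config A `run_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1))]
  out$care_models <- as.list(unname(out$care_models))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (line in attr(x, "log")) cat(" ", line, "\n")
  invisible(x)
}
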