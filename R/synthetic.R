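# Synthetic patient-episode generator: individually tailored episodes with
# the statistical structure the costing analysis assumes, so the pipeline is
# testable bottom-up without any patient data. All dispersion parameters are
# synthetic conventions (the published analysis is mean-based) and are
# documented as such.

#' Configuration of a synthetic cohort
#'
#' @param n_patients Number of episodes to generate, >= 0.
#' @param seed Integer seed (required; generation never touches the global
#'   RNG state).
#' @param duration_jitter Contact durations are drawn from a normal
#'   distribution centred on the scheduled duration, truncated to
#'   +/- `duration_jitter` of it (sd = half the truncation width). 0 disables
#'   jitter. Default 0.2.
#' @param transport_minutes `list(mean =, sd =)` of the per-visit round-trip
#'   travel time (truncated at 0). Defaults mean 52.5, sd 15.
#' @param wage_cv Coefficient of variation of the patient's gross hourly wage,
#'   drawn lognormal around the context's population wage. 0 disables.
#'   Default 0.2.
#' @param pain `list(pre_mean =, pre_sd =, post_mean =, post_sd =)` of pain
#'   scores, drawn normal truncated to [0, 10]. Defaults 5.7 (sd 2) pre and
#'   3.2 (sd 2) post, the digital-model means.
#' @param participation_rates Named list mapping a contact's
#'   `participation_class` to the probability of attending each scheduled
#'   occurrence (binomial thinning). Defaults: exercise sessions 0.60,
#'   co-patient lecture 0.44.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, seed,
                          duration_jitter = 0.2,
                          transport_minutes = list(mean = 52.5, sd = 15),
                          wage_cv = 0.2,
                          pain = list(pre_mean = 5.7, pre_sd = 2,
                                      post_mean = 3.2, post_sd = 2),
                          participation_rates = list(exercise_session = 0.60,
                                                     copatient_lecture = 0.44)) {
  check_nonneg(n_patients, "n_patients")
  if (missing(seed) || !is.numeric(seed) || is.na(seed)) {
    abort_validation("an integer `seed` is required")
  }
  check_fraction(duration_jitter, "duration_jitter")
  check_nonneg(transport_minutes$sd, "transport_minutes$sd")
  check_nonneg(wage_cv, "wage_cv")
  for (r in participation_rates) check_fraction(r, "participation rate")
  for (f in c("pre_sd", "post_sd")) check_nonneg(pain[[f]], paste0("pain$", f))
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         duration_jitter = duration_jitter,
         transport_minutes = transport_minutes, wage_cv = wage_cv,
         pain = pain, participation_rates = participation_rates),
    class = "cohort_config"
  )
}

participation_rate_for <- function(config, class) {
  if (is.null(class)) return(1)
  config$participation_rates[[class]] %||% 1
}

#' Generate a synthetic cohort of care episodes
#'
#' Realizes `n_patients` individually tailored episodes of the care model:
#' scheduled occurrences are thinned binomially by the participation rate of
#' their contact class, durations are jittered around the schedule, per-visit
#' travel times and patient wages are drawn per episode, and pre/post pain
#' scores are drawn truncated-normal on the 0--10 scale. A zero-variance
#' configuration (jitter 0, cv 0, sds 0, participation rates 1) reproduces
#' the deterministic schedule exactly.
#'
#' @param config A [cohort_config()].
#' @param spec A [care_model_spec()].
#' @param ctx A [valuation_context()].
#' @return A tibble of class `synthetic_cohort`, one row per episode, with
#'   columns `patient_id`, `model_name`, `wage`, `transport_minutes` (per
#'   visit), `visits`, `contact_count`, `provider_minutes`, `patient_minutes`,
#'   `exercise_sessions`, `pain_pre`, `pain_post`. The generating `spec`,
#'   `config`, and deterministic schedule are attached as attributes.
#' @examples
#' ja <- read_care_model(oacost_example("ja.yaml"))
#' ctx <- read_valuation_context(oacost_example("valuation.yaml"))
#' cohort <- generate_cohort(cohort_config(5, seed = 1), ja, ctx)
#' nrow(cohort)
#' @export
generate_cohort <- function(config, spec, ctx) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(spec, "care_model_spec"),
            inherits(ctx, "valuation_context"))
  n <- config$n_patients
  sched <- build_episode_schedule(spec)

  cohort <- withr::with_seed(config$seed, {
    prov_min <- numeric(n); pat_min <- numeric(n)
    n_contacts <- numeric(n); visits <- numeric(n); exercise <- numeric(n)
    for (ev in spec$contacts) {
      rate <- participation_rate_for(config, ev$participation_class)
      occ <- if (rate < 1) {
        stats::rbinom(n, size = as.integer(ev$occurrences), prob = rate)
      } else {
        rep(ev$occurrences, n)
      }
      dur0 <- resolve_duration(ev)
      dur <- if (config$duration_jitter > 0 && dur0 > 0) {
        w <- config$duration_jitter * dur0
        rtrunc_norm(n, dur0, w / 2, dur0 - w, dur0 + w)
      } else {
        rep(dur0, n)
      }
      if (ev$provider_attends) {
        prov_min <- prov_min + occ * dur
        n_contacts <- n_contacts + occ
      }
      if (ev$patient_attends) pat_min <- pat_min + occ * dur
      if (ev$on_site) visits <- visits + occ
      if (identical(ev$participation_class, "exercise_session")) {
        exercise <- exercise + occ
      }
    }
    tm <- if (spec$transport$mode == "none") {
      rep(0, n)
    } else if (config$transport_minutes$sd > 0) {
      rtrunc_norm(n, config$transport_minutes$mean, config$transport_minutes$sd,
                  lower = 0)
    } else {
      rep(config$transport_minutes$mean, n)
    }
    wage <- if (config$wage_cv > 0) {
      sdlog <- sqrt(log(1 + config$wage_cv^2))
      stats::rlnorm(n, log(ctx$population_gross_hourly_wage) - sdlog^2 / 2, sdlog)
    } else {
      rep(ctx$population_gross_hourly_wage, n)
    }
    tibble::tibble(
      patient_id = seq_len(n),
      model_name = rep(spec$name, n),
      wage = wage, transport_minutes = tm, visits = visits,
      contact_count = n_contacts,
      provider_minutes = prov_min, patient_minutes = pat_min,
      exercise_sessions = exercise,
      pain_pre = rtrunc_norm(n, config$pain$pre_mean, config$pain$pre_sd, 0, 10),
      pain_post = rtrunc_norm(n, config$pain$post_mean, config$pain$post_sd, 0, 10)
    )
  })
  attr(cohort, "spec") <- spec
  attr(cohort, "config") <- config
  attr(cohort, "schedule") <- sched
  class(cohort) <- c("synthetic_cohort", class(cohort))
  cohort
}

# Per-episode societal cost. Scales the deterministic cost lines by each
# episode's realized-to-scheduled time ratios and the patient's own wage;
# fixed lines (support, training, fees) are invariant. At zero variance every
# factor is exactly 1 and the deterministic unit cost is reproduced.
episode_costs <- function(cohort, ctx) {
  spec <- attr(cohort, "spec")
  sched <- attr(cohort, "schedule")
  det <- cost_model(spec, ctx)
  line <- function(domain, category) {
    r <- det$items[det$items$domain == domain & det$items$category == category, ]
    if (nrow(r) == 0L) 0 else r$total[1]
  }
  prov_ratio <- if (sched$provider_minutes > 0) {
    cohort$provider_minutes / sched$provider_minutes
  } else {
    rep(1, nrow(cohort))
  }
  pat_ratio <- if (sched$patient_minutes > 0) {
    cohort$patient_minutes / sched$patient_minutes
  } else {
    rep(1, nrow(cohort))
  }
  wage_ratio <- cohort$wage / ctx$population_gross_hourly_wage
  scale_if_fraction <- function(overhead, ratio) {
    if (!is.null(overhead$fraction_of_contact)) ratio else rep(1, nrow(cohort))
  }
  sched_visits <- sum(vapply(spec$contacts, function(ev) {
    if (ev$on_site) ev$occurrences else 0
  }, numeric(1)))
  visit_ratio <- if (sched_visits > 0) cohort$visits / sched_visits else rep(1, nrow(cohort))

  transport <- vapply(seq_len(nrow(cohort)), function(i) {
    h <- cohort$visits[i] * cohort$transport_minutes[i] / 60
    value_labour_time(h, cohort$wage[i], "patient_leisure", ctx)
  }, numeric(1))

  # Sum per domain, then across domains, mirroring the accumulation order of
  # aggregate_breakdown() so a zero-variance cohort reproduces the
  # deterministic unit cost bit-for-bit.
  sys <- rowSums(cbind(
    line("system", "contacts") * prov_ratio,
    line("system", "administration") *
      scale_if_fraction(spec$admin_overhead$system, prov_ratio),
    line("system", "technical_support"),
    line("system", "training")
  ))
  pat <- rowSums(cbind(
    line("patient", "contacts") * pat_ratio * wage_ratio,
    line("patient", "administration") *
      scale_if_fraction(spec$admin_overhead$patient, pat_ratio) * wage_ratio,
    transport,
    line("patient", "direct_fees")
  ))
  oth <- line("other", "emissions") * visit_ratio
  sys + pat + oth
}

#' Bottom-up unit cost of a synthetic cohort
#'
#' Costs every realized episode with the same valuation rules as
#' [cost_model()] and summarizes the sample. The sample mean is the bottom-up
#' estimator of the deterministic unit cost.
#'
#' @param cohort A [generate_cohort()] result.
#' @param ctx A [valuation_context()].
#' @return A list with `mean`, `sd`, `n`, and the per-episode `costs` vector.
#' @export
cohort_unit_cost <- function(cohort, ctx) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(ctx, "valuation_context"))
  if (nrow(cohort) == 0L) abort_domain("cohort is empty")
  costs <- episode_costs(cohort, ctx)
  list(mean = mean(costs),
       sd = if (length(costs) == 1L) 0 else stats::sd(costs),
       n = nrow(cohort), costs = costs)
}

#' Simulate pain outcomes for several care models
#'
#' Draws pre/post pain scores (normal truncated to [0, 10]) for each model
#' and returns per-model summaries. Zero-variance settings return the
#' configured means exactly, so feeding the summaries to [icer()] recovers
#' the deterministic result.
#'
#' @param models Named list; each element is
#'   `list(pre_mean =, pre_sd =, post_mean =, post_sd =)`.
#' @param n Draws per model, >= 1.
#' @param seed Integer seed.
#' @return A tibble with one row per model: `model`, `n`, `pre_mean`,
#'   `post_mean`, `pre_sd`, `post_sd`, `percent_reduction`.
#' @examples
#' simulate_effects(
#'   list(ja = list(pre_mean = 5.7, pre_sd = 0, post_mean = 3.2, post_sd = 0)),
#'   n = 10, seed = 1)
#' @export
simulate_effects <- function(models, n, seed) {
  if (!is.numeric(n) || n < 1) abort_validation("`n` must be >= 1")
  if (!is.list(models) || is.null(names(models))) {
    abort_validation("`models` must be a named list")
  }
  withr::with_seed(seed, {
    rows <- lapply(names(models), function(m) {
      p <- models[[m]]
      for (f in c("pre_mean", "pre_sd", "post_mean", "post_sd")) {
        if (is.null(p[[f]]) || p[[f]] < 0) {
          abort_validation(sprintf("model %s needs non-negative `%s`", m, f))
        }
      }
      pre <- rtrunc_norm(n, p$pre_mean, p$pre_sd, 0, 10)
      post <- rtrunc_norm(n, p$post_mean, p$post_sd, 0, 10)
      tibble::tibble(
        model = m, n = n,
        pre_mean = mean(pre), post_mean = mean(post),
        pre_sd = stats::sd(pre), post_sd = stats::sd(post),
        percent_reduction = percent_reduction(mean(pre), mean(post))
      )
    })
    do.call(rbind, rows)
  })
}
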