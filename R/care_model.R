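# Care-model specification: contact schedules and episode expansion.

CONTACT_MODES <- c("in_person", "telephone", "platform", "self_administered")

#' Define one scheduled contact of a care model
#'
#' A contact is any scheduled activity of an episode of care: an in-person
#' lecture or group exercise session, a telephone call, an asynchronous
#' platform interaction, or a self-administered home exercise. Durations may
#' be a single number of minutes or a printed range (e.g. 5--8 minutes),
#' resolved later by a midpoint policy.
#'
#' @param label Short description of the activity.
#' @param mode One of `"in_person"`, `"telephone"`, `"platform"`,
#'   `"self_administered"`.
#' @param duration_minutes Scheduled duration in minutes: a single number or a
#'   length-2 numeric `c(low, high)` range.
#' @param occurrences Occurrences per episode of care, >= 0.
#' @param provider_attends,patient_attends Who spends the time.
#' @param group_size Average participants sharing the provider's time
#'   (1 = individual care).
#' @param on_site Does the contact happen at the clinic? Only allowed for
#'   in-person contacts; triggers the facility surcharge and transport.
#' @param once_per_episode One-off activity (introduction/information
#'   sessions) exempt from rescaling when the episode length is changed.
#' @param participation_class Optional label (`"exercise_session"`,
#'   `"copatient_lecture"`) linking the contact to a participation rate in the
#'   synthetic-cohort generator; `NULL` means full participation.
#'
#' @return An object of class `contact_event`.
#' @examples
#' contact_event("weekly follow-up", "platform", c(5, 8), occurrences = 12)
#' @export
contact_event <- function(label, mode, duration_minutes, occurrences = 1,
                          provider_attends = TRUE, patient_attends = TRUE,
                          group_size = 1, on_site = (mode == "in_person"),
                          once_per_episode = FALSE,
                          participation_class = NULL) {
  if (!is.character(label) || length(label) != 1L) {
    abort_validation("`label` must be a single string")
  }
  if (!mode %in% CONTACT_MODES) {
    abort_validation(sprintf("`mode` must be one of %s",
                             paste(CONTACT_MODES, collapse = ", ")))
  }
  if (!is.numeric(duration_minutes) || !length(duration_minutes) %in% 1:2 ||
      any(is.na(duration_minutes)) || any(duration_minutes < 0)) {
    abort_domain("`duration_minutes` must be a non-negative number or c(low, high) range")
  }
  if (length(duration_minutes) == 2L &&
      duration_minutes[1] > duration_minutes[2]) {
    abort_domain("duration range must satisfy low <= high")
  }
  if (!is.numeric(occurrences) || occurrences < 0) {
    abort_domain("`occurrences` must be >= 0")
  }
  if (!is.numeric(group_size) || group_size < 1) {
    abort_domain("`group_size` must be >= 1")
  }
  if (isTRUE(on_site) && mode != "in_person") {
    abort_validation("`on_site` contacts must have mode \"in_person\"")
  }
  structure(
    list(
      label = label, mode = mode,
      duration_minutes = as.numeric(duration_minutes),
      occurrences = occurrences,
      provider_attends = isTRUE(provider_attends),
      patient_attends = isTRUE(patient_attends),
      group_size = group_size, on_site = isTRUE(on_site),
      once_per_episode = isTRUE(once_per_episode),
      participation_class = participation_class
    ),
    class = "contact_event"
  )
}

resolve_duration <- function(event, midpoint_policy = c("midpoint", "low", "high")) {
  midpoint_policy <- match.arg(midpoint_policy)
  d <- event$duration_minutes
  if (length(d) == 1L) return(d)
  switch(midpoint_policy, midpoint = mean(d), low = d[1], high = d[2])
}

#' Define a care model
#'
#' A care model is a named schedule of contacts plus the episode-level
#' costing parameters that cannot be derived from the schedule alone:
#' administrative overhead, provider training requirements, technical-support
#' budget, transport profile, and (where the published accounting splits time
#' differently than the raw schedule) calibrated contact-hour overrides.
#'
#' @param name Model name.
#' @param contacts List of [contact_event()]s.
#' @param episode_weeks Length of one episode of care (default 12 weeks, the
#'   comparability window used for both models).
#' @param admin_overhead Named list with optional elements `system` and
#'   `patient`, each either `list(hours = h)` (fixed hours per episode) or
#'   `list(fraction_of_contact = f)` (fraction of the domain's contact time).
#' @param training_hours_per_provider One-off training hours per provider.
#' @param episodes_per_provider Episodes over which training is amortized.
#' @param annual_support_budget,annual_patient_count Technical-support budget
#'   (SEK/year) and the annual patient volume it serves.
#' @param support_halving_rule Apply the half-of-comparator support assumption?
#' @param facility_based Is care delivered at a facility (applies the facility
#'   surcharge to provider contact and administration time)?
#' @param average_group_size Average group size applied to provider contact
#'   time when `provider_contact_hours_override` is used.
#' @param provider_contact_hours_override,patient_contact_hours_override
#'   Calibrated per-episode contact hours used for costing in place of the
#'   schedule-derived sums (the published accounting books asynchronous
#'   platform time partly under administration; see the package vignette).
#'   `NULL` (default) uses the schedule.
#' @param transport [transport_profile()] for clinic travel; default none.
#' @param effects Optional list with `pain_pre`/`pain_post` mean scores
#'   (0--10 numeric rating scale) used as the model's effect estimate.
#'
#' @return An object of class `care_model_spec`.
#' @seealso [build_episode_schedule()], [cost_model()]
#' @export
care_model_spec <- function(name, contacts, episode_weeks = 12,
                            admin_overhead = list(),
                            training_hours_per_provider = 0,
                            episodes_per_provider = 1,
                            annual_support_budget = 0,
                            annual_patient_count = 1,
                            support_halving_rule = FALSE,
                            facility_based = FALSE,
                            average_group_size = 1,
                            provider_contact_hours_override = NULL,
                            patient_contact_hours_override = NULL,
                            transport = transport_profile(mode = "none"),
                            effects = NULL) {
  if (!is.character(name) || length(name) != 1L) {
    abort_validation("`name` must be a single string")
  }
  if (!is.list(contacts) || !all(vapply(contacts, inherits, TRUE, "contact_event"))) {
    abort_validation("`contacts` must be a list of contact_event objects")
  }
  if (!is.numeric(episode_weeks) || episode_weeks <= 0) {
    abort_domain("`episode_weeks` must be > 0")
  }
  if (annual_support_budget > 0 && annual_patient_count < 1) {
    abort_domain("`annual_patient_count` must be >= 1 when a support budget is used")
  }
  if (average_group_size < 1) abort_domain("`average_group_size` must be >= 1")
  structure(
    list(
      name = name, contacts = contacts, episode_weeks = episode_weeks,
      admin_overhead = admin_overhead,
      training_hours_per_provider = training_hours_per_provider,
      episodes_per_provider = episodes_per_provider,
      annual_support_budget = annual_support_budget,
      annual_patient_count = annual_patient_count,
      support_halving_rule = isTRUE(support_halving_rule),
      facility_based = isTRUE(facility_based),
      average_group_size = average_group_size,
      provider_contact_hours_override = provider_contact_hours_override,
      patient_contact_hours_override = patient_contact_hours_override,
      transport = transport,
      effects = effects
    ),
    class = "care_model_spec"
  )
}

#' @export
print.care_model_spec <- function(x, ...) {
  sched <- build_episode_schedule(x)
  cat(sprintf("<care_model_spec> %s: %d-week episode, %d provider contacts,\n",
              x$name, x$episode_weeks, sched$contact_count))
  cat(sprintf("  %.1f provider min / %.1f patient min per episode (schedule)\n",
              sched$provider_minutes, sched$patient_minutes))
  invisible(x)
}

#' Expand a care model's schedule into one episode of care
#'
#' Expands occurrences, resolves printed duration ranges with the midpoint
#' policy, and sums provider- and patient-attended minutes. The contact count
#' tallies provider-attended activities (interactions with the care provider);
#' self-administered patient activities contribute patient minutes only.
#' When `weeks` differs from the scheduled episode length, recurring contacts
#' are rescaled proportionally while one-off contacts (introduction and
#' information sessions) are counted once.
#'
#' @param spec A [care_model_spec()].
#' @param midpoint_policy How to resolve `c(low, high)` duration ranges:
#'   `"midpoint"` (arithmetic midpoint, default), `"low"`, or `"high"`.
#' @param weeks Episode length to expand to; defaults to the scheduled length.
#'
#' @return A list with `contact_count`, `provider_minutes`, `patient_minutes`
#'   (full precision) and `provider_minutes_rounded`,
#'   `patient_minutes_rounded` (half-up to whole minutes).
#' @examples
#' ja <- read_care_model(oacost_example("ja.yaml"))
#' build_episode_schedule(ja)$contact_count            # 18
#' build_episode_schedule(ja)$provider_minutes_rounded # 143
#' @export
build_episode_schedule <- function(spec,
                                   midpoint_policy = c("midpoint", "low", "high"),
                                   weeks = NULL) {
  stopifnot(inherits(spec, "care_model_spec"))
  midpoint_policy <- match.arg(midpoint_policy)
  weeks <- weeks %||% spec$episode_weeks
  scale <- weeks / spec$episode_weeks
  n_contacts <- 0
  prov_min <- 0
  pat_min <- 0
  for (ev in spec$contacts) {
    occ <- ev$occurrences * (if (ev$once_per_episode) 1 else scale)
    dur <- resolve_duration(ev, midpoint_policy)
    if (ev$provider_attends) {
      n_contacts <- n_contacts + occ
      prov_min <- prov_min + occ * dur
    }
    if (ev$patient_attends) pat_min <- pat_min + occ * dur
  }
  list(
    contact_count = n_contacts,
    provider_minutes = prov_min,
    patient_minutes = pat_min,
    provider_minutes_rounded = round_half_up(prov_min),
    patient_minutes_rounded = round_half_up(pat_min)
  )
}
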