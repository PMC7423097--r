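# Digital first-line care model (app-based exercises with asynchronous
# physiotherapist contact), 12-week episode of care.
#
# The contact schedule is the published treatment protocol: three 15-minute
# telephone contacts plus fifteen 5-8-minute platform contacts (18 activities,
# ~143 minutes at the range midpoint). Daily home exercises are
# self-administered patient time.
#
# Contact-hours overrides and administration hours are calibrated so the
# costing engine reproduces the published per-episode cost lines: the
# physiotherapist's asynchronous platform time is booked largely under
# administration (reading patient reports, preparing responses) in the
# published accounting.
name: "JA (digital)"
episode_weeks: 12
facility_based: false
average_group_size: 1
provider_contact_hours_override: 0.589
patient_contact_hours_override: 3.64
admin_overhead:
  system:
    hours: 1.62
  patient:
    hours: 0.99
training_hours_per_provider: 2      # online training plus certification exam
episodes_per_provider: 67           # calibrated amortization denominator
annual_support_budget: 300000       # SEK/year, technical and other support
annual_patient_count: 1421          # episodes of >= 12 weeks in 2018
support_halving_rule: false
contacts:
  - label: "start-up meeting"
    mode: telephone
    duration_minutes: 15
    occurrences: 1
    once_per_episode: true
  - label: "weekly follow-up"
    mode: platform
    duration_minutes: [5, 8]
    occurrences: 12
  - label: "monthly follow-up session"
    mode: platform
    duration_minutes: [5, 8]
    occurrences: 3
  - label: "6-week follow-up meeting"
    mode: telephone
    duration_minutes: 15
    occurrences: 1
  - label: "3-month follow-up"
    mode: telephone
    duration_minutes: 15
    occurrences: 1
  - label: "daily home exercise"
    mode: self_administered
    duration_minutes: 20
    occurrences: 84
    provider_attends: false
transport:
  mode: none
effects:
  pain_pre: 5.7
  pain_post: 3.2
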