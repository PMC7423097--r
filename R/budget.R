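# Program-level expenditure and substitution-scenario (budget impact) analysis.

#' Program cohort for budget-impact analysis
#'
#' Annual patient volumes and unit costs of the two delivery models, plus the
#' assumed adherence rate. Defaults are the 2018 program volumes (9 465
#' face-to-face, 1 421 digital episodes) and an adherence assumption of 60%.
#'
#' @param n_boa,n_ja Annual episode counts for the face-to-face (BOA) and
#'   digital (JA) models.
#' @param unit_cost_boa,unit_cost_ja Societal unit costs per episode, SEK.
#' @param adherence_rate Fraction of substituted patients assumed to complete
#'   the program; only applied when explicitly requested (see
#'   [substitution_scenario()]).
#' @return An object of class `program_cohort`.
#' @export
program_cohort <- function(n_boa = 9465, n_ja = 1421,
                           unit_cost_boa = 10611, unit_cost_ja = 2776,
                           adherence_rate = 0.60) {
  check_nonneg(n_boa, "n_boa")
  check_nonneg(n_ja, "n_ja")
  check_nonneg(unit_cost_boa, "unit_cost_boa")
  check_nonneg(unit_cost_ja, "unit_cost_ja")
  check_fraction(adherence_rate, "adherence_rate")
  structure(list(n_boa = n_boa, n_ja = n_ja,
                 unit_cost_boa = unit_cost_boa, unit_cost_ja = unit_cost_ja,
                 adherence_rate = adherence_rate),
            class = "program_cohort")
}

#' Total program cost
#'
#' @param n Number of episodes.
#' @param unit_cost Cost per episode, SEK.
#' @return `n * unit_cost`, SEK.
#' @examples
#' total_program_cost(9465, 10611) # 100433115
#' @export
total_program_cost <- function(n, unit_cost) {
  check_nonneg(n, "n")
  check_nonneg(unit_cost, "unit_cost")
  n * unit_cost
}

#' Substitution scenario: expenditure effect of shifting care digital
#'
#' Computes the program-level saving when a fraction `s` of face-to-face
#' episodes is delivered digitally instead.
#'
#' Two arithmetic conventions are implemented. `"standard"` is the natural
#' budget-impact formula: the remaining program cost is
#' `(1 - s) n c_boa + s n c_ja` and the saving is `s n (c_boa - c_ja)`.
#' `"as_printed"` reproduces the published scenario table, whose rows follow
#' `remaining = (1 - s) n c_ja` with a constant row sum equal to the baseline
#' `n c_boa` (savings = baseline - remaining); the package reproduces this
#' arithmetic without asserting its interpretation. In both modes
#' `savings_percent` is the saving relative to the baseline cost.
#'
#' @param cohort A [program_cohort()].
#' @param s Substitution rate in [0, 1].
#' @param mode `"standard"` (default) or `"as_printed"`.
#' @param apply_adherence Multiply the substituted fraction by the cohort's
#'   adherence rate? Default `FALSE` (the published rows show no adherence
#'   effect despite the stated assumption).
#' @return An object of class `scenario_result` with `substitution_rate`,
#'   `remaining_cost`, `savings`, `savings_percent`, `baseline_cost`, `mode`.
#' @examples
#' substitution_scenario(program_cohort(), 0.5)$savings
#' @export
substitution_scenario <- function(cohort, s,
                                  mode = c("standard", "as_printed"),
                                  apply_adherence = FALSE) {
  stopifnot(inherits(cohort, "program_cohort"))
  mode <- match.arg(mode)
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 1) {
    abort_domain("substitution rate `s` must lie in [0, 1]")
  }
  s_eff <- if (isTRUE(apply_adherence)) s * cohort$adherence_rate else s
  baseline <- total_program_cost(cohort$n_boa, cohort$unit_cost_boa)
  if (mode == "standard") {
    savings <- s_eff * cohort$n_boa * (cohort$unit_cost_boa - cohort$unit_cost_ja)
    remaining <- baseline - savings
  } else {
    remaining <- (1 - s_eff) * cohort$n_boa * cohort$unit_cost_ja
    savings <- baseline - remaining
  }
  structure(
    list(substitution_rate = s, remaining_cost = remaining, savings = savings,
         savings_percent = if (baseline > 0) savings / baseline * 100 else 0,
         baseline_cost = baseline, mode = mode),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> s = %.0f%% (%s mode)\n",
              100 * x$substitution_rate, x$mode))
  cat(sprintf("  remaining cost %15.0f SEK\n", round_half_up(x$remaining_cost)))
  cat(sprintf("  savings        %15.0f SEK (%.0f%% of baseline)\n",
              round_half_up(x$savings), x$savings_percent))
  invisible(x)
}

#' Grid of substitution scenarios
#'
#' @param cohort A [program_cohort()].
#' @param s Vector of substitution rates (default the published 25/50/75%).
#' @inheritParams substitution_scenario
#' @return A tibble with one row per rate: `substitution_rate`,
#'   `remaining_cost`, `savings`, `savings_percent`, `mode`.
#' @export
scenario_grid <- function(cohort, s = c(0.25, 0.5, 0.75),
                          mode = c("standard", "as_printed"),
                          apply_adherence = FALSE) {
  mode <- match.arg(mode)
  rows <- lapply(s, function(si) {
    r <- substitution_scenario(cohort, si, mode, apply_adherence)
    tibble::tibble(substitution_rate = si, remaining_cost = r$remaining_cost,
                   savings = r$savings, savings_percent = r$savings_percent,
                   mode = mode)
  })
  do.call(rbind, rows)
}
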