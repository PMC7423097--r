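# Incremental cost-effectiveness analysis and sensitivity analyses.

#' Effect estimate on a 0-10 pain scale
#'
#' @param pain_pre,pain_post Mean pain scores before and after treatment on a
#'   0--10 numeric rating scale (lower is better).
#' @param horizon_weeks Follow-up horizon, default 12 weeks.
#' @return An object of class `effect_estimate`.
#' @examples
#' effect_estimate(5.7, 3.2)
#' @export
effect_estimate <- function(pain_pre, pain_post, horizon_weeks = 12) {
  for (s in c(pain_pre, pain_post)) {
    if (!is.numeric(s) || is.na(s) || s < 0 || s > 10) {
      abort_domain("pain scores must lie in [0, 10]")
    }
  }
  structure(list(pain_pre = pain_pre, pain_post = pain_post,
                 horizon_weeks = horizon_weeks),
            class = "effect_estimate")
}

#' Percent reduction in pain
#'
#' @param pre,post Pain scores; `pre` must be positive.
#' @param round Round half-up to a whole percent (the reporting convention)?
#'   Default `FALSE` (full precision).
#' @return Percent reduction, `(pre - post) / pre * 100`.
#' @examples
#' percent_reduction(5.7, 3.2, round = TRUE) # 44
#' percent_reduction(5.2, 4.1, round = TRUE) # 21
#' @export
percent_reduction <- function(pre, post, round = FALSE) {
  if (!is.numeric(pre) || is.na(pre) || pre <= 0) {
    abort_domain("`pre` must be > 0")
  }
  p <- (pre - post) / pre * 100
  if (isTRUE(round)) round_half_up(p) else p
}

#' Incremental cost-effectiveness ratio
#'
#' Computes cost and effect differences as `a - b` and their ratio. Effects
#' are pain scores where lower is better; the deltas follow the raw
#' post-treatment arithmetic (the published convention), so a negative cost
#' delta together with a negative effect delta means the intervention is both
#' cheaper and better (dominant). The integer reported ratio truncates toward
#' zero, matching how the published figure (8 705 = -7 835 / -0.9, i.e.
#' 8 705.55...) was printed.
#'
#' @param cost_a,cost_b Unit costs of intervention `a` and comparator `b`, SEK.
#' @param effect_a,effect_b Effect values (post-treatment pain scores, or any
#'   scale where lower is better).
#' @return An object of class `icer_result` with `delta_cost`, `delta_effect`,
#'   `ratio` (full precision, `NA` when `delta_effect == 0`),
#'   `ratio_reported` (truncated toward zero), and `quadrant` (one of
#'   `"dominant"`, `"dominated"`, `"tradeoff_NE"`, `"tradeoff_SW"`).
#' @examples
#' icer(2776, 10611, 3.2, 4.1)$ratio_reported # 8705
#' @export
icer <- function(cost_a, cost_b, effect_a, effect_b) {
  dc <- cost_a - cost_b
  de <- effect_a - effect_b
  ratio <- if (de == 0) NA_real_ else dc / de
  quadrant <- if (de == 0) {
    if (dc <= 0) "dominant" else "dominated"
  } else if (dc <= 0 && de <= 0) {
    "dominant"
  } else if (dc >= 0 && de >= 0) {
    "dominated"
  } else if (de < 0) {
    "tradeoff_NE" # costlier but better
  } else {
    "tradeoff_SW" # cheaper but worse
  }
  structure(
    list(delta_cost = dc, delta_effect = de, ratio = ratio,
         ratio_reported = if (is.na(ratio)) NA_real_ else trunc(ratio),
         quadrant = quadrant),
    class = "icer_result"
  )
}

#' @export
print.icer_result <- function(x, ...) {
  cat("<icer_result>\n")
  cat(sprintf("  delta cost   %10.2f SEK\n", x$delta_cost))
  cat(sprintf("  delta effect %10.2f\n", x$delta_effect))
  if (is.na(x$ratio)) {
    cat("  ratio        undefined (no effect difference)\n")
  } else {
    cat(sprintf("  ICER         %10.0f SEK per effect unit (%.2f unrounded)\n",
                x$ratio_reported, x$ratio))
  }
  cat(sprintf("  quadrant     %s\n", x$quadrant))
  invisible(x)
}

#' ICER from effect estimates
#'
#' Convenience wrapper deriving the effect delta either from post-treatment
#' scores (the published convention, default) or from the change from
#' baseline of each arm.
#'
#' @param cost_a,cost_b Unit costs, SEK.
#' @param effects_a,effects_b [effect_estimate()] objects.
#' @param basis `"post_score"` (default) or `"change_from_baseline"`.
#' @return An `icer_result`; see [icer()].
#' @export
icer_from_effects <- function(cost_a, cost_b, effects_a, effects_b,
                              basis = c("post_score", "change_from_baseline")) {
  basis <- match.arg(basis)
  stopifnot(inherits(effects_a, "effect_estimate"),
            inherits(effects_b, "effect_estimate"))
  if (basis == "post_score") {
    icer(cost_a, cost_b, effects_a$pain_post, effects_b$pain_post)
  } else {
    icer(cost_a, cost_b,
         effects_a$pain_post - effects_a$pain_pre,
         effects_b$pain_post - effects_b$pain_pre)
  }
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates an outcome function at the low and high value of each
#' parameter, holding the others at base, and returns a tornado table sorted
#' by output span.
#'
#' @param fn Function taking a named numeric vector of parameters and
#'   returning a single numeric outcome.
#' @param base Named numeric vector of base-case parameter values.
#' @param ranges Data frame with columns `param`, `low`, `high`; every range
#'   must bracket the corresponding base value.
#' @return A tibble with columns `param`, `low`, `high`, `output_low`,
#'   `output_high`, `output_base`, `span`, sorted by decreasing span.
#' @examples
#' fn <- function(p) p[["a"]] + 2 * p[["b"]]
#' one_way_dsa(fn, c(a = 1, b = 1),
#'             data.frame(param = c("a", "b"), low = c(0, 0), high = c(2, 2)))
#' @export
one_way_dsa <- function(fn, base, ranges) {
  stopifnot(is.function(fn), is.numeric(base), !is.null(names(base)))
  if (!all(c("param", "low", "high") %in% names(ranges))) {
    abort_validation("`ranges` needs columns param, low, high")
  }
  missing_par <- setdiff(ranges$param, names(base))
  if (length(missing_par) > 0) {
    abort_validation(sprintf("range given for unknown parameter(s): %s",
                             paste(missing_par, collapse = ", ")))
  }
  base_val <- base[ranges$param]
  bad <- ranges$low > base_val | ranges$high < base_val
  if (any(bad)) {
    abort_validation(sprintf("range for %s does not bracket its base value",
                             paste(ranges$param[bad], collapse = ", ")))
  }
  out_base <- fn(base)
  eval_at <- function(param, value) {
    p <- base
    p[[param]] <- value
    fn(p)
  }
  out_low <- mapply(eval_at, ranges$param, ranges$low)
  out_high <- mapply(eval_at, ranges$param, ranges$high)
  res <- tibble::tibble(
    param = ranges$param, low = ranges$low, high = ranges$high,
    output_low = as.numeric(out_low), output_high = as.numeric(out_high),
    output_base = out_base,
    span = abs(as.numeric(out_high) - as.numeric(out_low))
  )
  res[order(-res$span), ]
}

#' Probabilistic sensitivity analysis
#'
#' Draws unit costs from gamma distributions (parameterized by mean and sd)
#' and post-treatment pain scores from normal distributions truncated to
#' [0, 10], computes the ICER per draw, and returns the cost-effect sample.
#' Zero-variance inputs reproduce the deterministic point estimate in every
#' draw. This probabilistic layer is a package extension beyond the published
#' point-estimate analysis.
#'
#' @param costs List with elements `a` and `b`, each `list(mean =, sd =)`
#'   describing the unit-cost distribution (gamma; sd 0 means fixed).
#' @param effects List with elements `a` and `b`, each `list(mean =, sd =)`
#'   describing the post-treatment pain distribution (normal truncated to
#'   [0, 10]; sd 0 means fixed).
#' @param n_draws Number of Monte Carlo draws, >= 1.
#' @param seed Integer seed; draws are reproducible and do not disturb the
#'   global RNG state.
#' @return An object of class `psa_result`: a list with `sample` (tibble of
#'   per-draw costs, effects, deltas, and ICERs) and the call parameters.
#' @examples
#' p <- psa(costs = list(a = list(mean = 2776, sd = 0),
#'                       b = list(mean = 10611, sd = 0)),
#'          effects = list(a = list(mean = 3.2, sd = 0),
#'                         b = list(mean = 4.1, sd = 0)),
#'          n_draws = 10, seed = 1)
#' unique(p$sample$icer)
#' @export
psa <- function(costs, effects, n_draws = 1000, seed = 1) {
  if (!is.numeric(n_draws) || n_draws < 1) {
    abort_validation("`n_draws` must be >= 1")
  }
  for (side in c("a", "b")) {
    for (blk in list(costs[[side]], effects[[side]])) {
      if (is.null(blk$mean) || is.null(blk$sd) || blk$sd < 0 || blk$mean < 0) {
        abort_validation("each distribution needs non-negative `mean` and `sd`")
      }
    }
  }
  draw_cost <- function(d, n) {
    if (d$sd == 0 || d$mean == 0) return(rep(d$mean, n))
    shape <- (d$mean / d$sd)^2
    stats::rgamma(n, shape = shape, rate = shape / d$mean)
  }
  draw_effect <- function(d, n) rtrunc_norm(n, d$mean, d$sd, 0, 10)
  sample <- withr::with_seed(seed, {
    ca <- draw_cost(costs$a, n_draws)
    cb <- draw_cost(costs$b, n_draws)
    ea <- draw_effect(effects$a, n_draws)
    eb <- draw_effect(effects$b, n_draws)
    tibble::tibble(
      draw = seq_len(n_draws),
      cost_a = ca, cost_b = cb, effect_a = ea, effect_b = eb,
      delta_cost = ca - cb, delta_effect = ea - eb,
      icer = ifelse(ea - eb == 0, NA_real_, (ca - cb) / (ea - eb))
    )
  })
  structure(list(sample = sample, costs = costs, effects = effects,
                 n_draws = n_draws, seed = seed),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability (across PSA draws) that
#' the intervention's net monetary benefit is positive. The effect gain is
#' the pain reduction relative to the comparator, `-(delta_effect)`.
#'
#' @param psa_result A [psa()] result.
#' @param wtp Numeric vector of willingness-to-pay values, SEK per pain point.
#' @return A tibble with columns `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(psa_result, wtp = seq(0, 20000, by = 1000)) {
  stopifnot(inherits(psa_result, "psa_result"))
  s <- psa_result$sample
  probs <- vapply(wtp, function(lambda) {
    nmb <- lambda * (-s$delta_effect) - s$delta_cost
    mean(nmb > 0)
  }, numeric(1))
  tibble::tibble(wtp = wtp, prob_cost_effective = probs)
}
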