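test_that("percent pain reduction matches the published reductions", {
  expect_equal(percent_reduction(5.7, 3.2, round = TRUE), 44)
  expect_equal(percent_reduction(5.2, 4.1, round = TRUE), 21)
  expect_equal(percent_reduction(4, 4), 0)
  expect_error(percent_reduction(0, 1), class = "oacost_domain_error")
  # invariant to rescaling pre/post by a common positive factor
  withr::with_seed(3, {
    for (i in 1:20) {
      pre <- runif(1, 1, 10); post <- runif(1, 0, pre); k <- runif(1, 0.1, 5)
      expect_equal(percent_reduction(k * pre, k * post),
                   percent_reduction(pre, post))
    }
  })
})

test_that("the ICER reproduces the published ratio with truncation", {
  res <- icer(2776, 10611, 3.2, 4.1)
  expect_equal(res$delta_cost, -7835)
  expect_equal(res$delta_effect, -0.9)
  expect_equal(res$ratio, -7835 / -0.9)
  expect_equal(res$ratio_reported, 8705) # 8705.55... truncated toward zero
  expect_equal(res$quadrant, "dominant") # cheaper and less pain
})

test_that("ICER handles ties, quadrants, and undefined ratios", {
  tie <- icer(100, 100, 3, 3)
  expect_true(is.na(tie$ratio))
  expect_equal(tie$delta_cost, 0)
  expect_equal(icer(100, 200, 3.0, 4.0)$quadrant, "dominant")
  expect_equal(icer(200, 100, 4.0, 3.0)$quadrant, "dominated")
  expect_equal(icer(200, 100, 3.0, 4.0)$quadrant, "tradeoff_NE")
  expect_equal(icer(100, 200, 4.0, 3.0)$quadrant, "tradeoff_SW")
  # delta_effect 0: ratio undefined, quadrant classified by cost sign
  expect_equal(icer(100, 200, 3, 3)$quadrant, "dominant")
  expect_equal(icer(200, 100, 3, 3)$quadrant, "dominated")
})

test_that("ICER is antisymmetric and scale-equivariant", {
  withr::with_seed(11, {
    for (i in 1:20) {
      ca <- runif(1, 0, 1e4); cb <- runif(1, 0, 1e4)
      ea <- runif(1, 0, 10); eb <- runif(1, 0, 10)
      if (ea == eb) next
      ab <- icer(ca, cb, ea, eb); ba <- icer(cb, ca, eb, ea)
      expect_equal(ba$delta_cost, -ab$delta_cost)
      expect_equal(ba$delta_effect, -ab$delta_effect)
      expect_equal(ba$ratio, ab$ratio)
      k <- runif(1, 0.1, 10)
      expect_equal(icer(k * ca, k * cb, ea, eb)$ratio, k * ab$ratio)
    }
  })
})

test_that("effect basis can be post-score (published) or change-from-baseline", {
  a <- effect_estimate(5.7, 3.2); b <- effect_estimate(5.2, 4.1)
  post <- icer_from_effects(2776, 10611, a, b, basis = "post_score")
  expect_equal(post$ratio_reported, 8705)
  chg <- icer_from_effects(2776, 10611, a, b, basis = "change_from_baseline")
  expect_equal(chg$delta_effect, -2.5 - (-1.1)) # -1.4 extra points of relief
  expect_equal(chg$ratio_reported, trunc(-7835 / -1.4))
  expect_error(effect_estimate(11, 3), class = "oacost_domain_error")
})

test_that("one-way sensitivity analysis produces a coherent tornado table", {
  fn <- function(p) p[["a"]] + 2 * p[["b"]]
  base <- c(a = 1, b = 1)
  ranges <- data.frame(param = c("a", "b"), low = c(0, 0), high = c(2, 2))
  tor <- one_way_dsa(fn, base, ranges)
  expect_equal(tor$param, c("b", "a")) # sorted by span: b spans 4, a spans 2
  expect_equal(tor$span, c(4, 2))
  # degenerate range gives zero span
  deg <- one_way_dsa(fn, base, data.frame(param = "a", low = 1, high = 1))
  expect_equal(deg$span, 0)
  # non-bracketing range is rejected
  expect_error(one_way_dsa(fn, base, data.frame(param = "a", low = 2, high = 3)),
               class = "oacost_validation_error")
})

test_that("zeroing transport removes exactly the transport line from the total", {
  ctx <- shipped_ctx()
  boa <- shipped_boa()
  base <- cost_model(boa, ctx)
  transport_line <- sum(base$items$total[base$items$category == "transportation"])
  fn <- function(p) {
    spec <- boa
    spec$transport$round_trip_minutes <- p[["rt_minutes"]]
    cost_model(spec, ctx)$total
  }
  tor <- one_way_dsa(fn, c(rt_minutes = 52.5),
                     data.frame(param = "rt_minutes", low = 0, high = 52.5))
  expect_equal(tor$output_base - tor$output_low, transport_line)
})

test_that("support cost is linear: halved vs removed differ by half the line", {
  ctx <- shipped_ctx()
  boa <- shipped_boa()
  with_budget <- function(b) {
    spec <- boa
    spec$annual_support_budget <- b
    cost_model(spec, ctx)$total
  }
  full <- with_budget(boa$annual_support_budget)
  half <- with_budget(boa$annual_support_budget / 2)
  none <- with_budget(0)
  expect_equal(full - half, half - none)
  support_line <- technical_support_unit_cost(boa$annual_support_budget,
                                              boa$annual_patient_count,
                                              halved = TRUE)
  expect_equal(full - none, support_line)
})

test_that("PSA is reproducible, degenerate at zero variance, and convergent", {
  fixed <- list(a = list(mean = 2776, sd = 0), b = list(mean = 10611, sd = 0))
  eff_fixed <- list(a = list(mean = 3.2, sd = 0), b = list(mean = 4.1, sd = 0))
  p0 <- psa(fixed, eff_fixed, n_draws = 25, seed = 9)
  expect_true(all(p0$sample$cost_a == 2776))
  expect_true(all(p0$sample$icer == (2776 - 10611) / (3.2 - 4.1)))
  # same seed twice: identical output
  spread <- list(a = list(mean = 2776, sd = 400), b = list(mean = 10611, sd = 900))
  eff <- list(a = list(mean = 3.2, sd = 0.5), b = list(mean = 4.1, sd = 0.5))
  p1 <- psa(spread, eff, n_draws = 200, seed = 5)
  p2 <- psa(spread, eff, n_draws = 200, seed = 5)
  expect_identical(p1$sample, p2$sample)
  # sample means converge to the point estimates (3 SE bound)
  p3 <- psa(spread, eff, n_draws = 10000, seed = 13)
  for (col in c("cost_a", "cost_b")) {
    mu <- if (col == "cost_a") 2776 else 10611
    se <- sd(p3$sample[[col]]) / sqrt(nrow(p3$sample))
    expect_lt(abs(mean(p3$sample[[col]]) - mu), 3 * se)
  }
  expect_error(psa(list(a = list(mean = -1, sd = 0), b = fixed$b),
                   eff_fixed, 10, 1),
               class = "oacost_validation_error")
})

test_that("the acceptability curve is coherent for a dominant intervention", {
  spread <- list(a = list(mean = 2776, sd = 400), b = list(mean = 10611, sd = 900))
  eff <- list(a = list(mean = 3.2, sd = 0.5), b = list(mean = 4.1, sd = 0.5))
  p <- psa(spread, eff, n_draws = 2000, seed = 2)
  curve <- ceac(p, wtp = c(0, 5000, 10000, 20000, 1e7))
  # cheaper-and-better: cost-effective with probability ~1 already at wtp 0
  expect_gt(curve$prob_cost_effective[1], 0.99)
  # when the intervention saves money, higher willingness-to-pay only makes
  # negative-effect draws count against it: the curve is non-increasing and
  # bounded below by the probability of an effect gain
  expect_true(all(diff(curve$prob_cost_effective) <= 0))
  p_gain <- mean(p$sample$delta_effect < 0)
  expect_gte(min(curve$prob_cost_effective), p_gain)
})
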