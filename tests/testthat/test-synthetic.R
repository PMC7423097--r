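test_that("cohort generation is reproducible and size-correct", {
  ctx <- shipped_ctx(); ja <- shipped_ja()
  empty <- generate_cohort(cohort_config(0, seed = 1), ja, ctx)
  expect_equal(nrow(empty), 0)
  c1 <- generate_cohort(cohort_config(50, seed = 7), ja, ctx)
  c2 <- generate_cohort(cohort_config(50, seed = 7), ja, ctx)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- generate_cohort(cohort_config(50, seed = 8), ja, ctx)
  expect_false(identical(c1$wage, c3$wage))
  # generation does not disturb the global RNG stream
  withr::with_seed(99, {
    before <- runif(1)
  })
  withr::with_seed(99, {
    invisible(generate_cohort(cohort_config(10, seed = 3), ja, ctx))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("a zero-variance cohort reproduces the deterministic episode exactly", {
  ctx <- shipped_ctx()
  for (spec in list(shipped_ja(), shipped_boa())) {
    det <- cost_model(spec, ctx)$total
    cohort <- generate_cohort(degenerate_config(5), spec, ctx)
    u <- cohort_unit_cost(cohort, ctx)
    expect_identical(u$costs, rep(det, 5))
    expect_identical(u$mean, det)
    expect_identical(u$sd, 0)
    sched <- build_episode_schedule(spec)
    expect_true(all(cohort$provider_minutes == sched$provider_minutes))
    expect_true(all(cohort$contact_count == sched$contact_count))
  }
  single <- generate_cohort(degenerate_config(1), shipped_ja(), ctx)
  u1 <- cohort_unit_cost(single, ctx)
  expect_identical(u1$mean, cost_model(shipped_ja(), ctx)$total)
  expect_identical(u1$sd, 0)
})

test_that("empty cohorts cannot be summarized", {
  ctx <- shipped_ctx()
  empty <- generate_cohort(cohort_config(0, seed = 1), shipped_ja(), ctx)
  expect_error(cohort_unit_cost(empty, ctx), class = "oacost_domain_error")
})

test_that("mean bottom-up cost converges to the deterministic unit cost", {
  ctx <- shipped_ctx(); ja <- shipped_ja()
  det <- cost_model(ja, ctx)$total
  cohort <- generate_cohort(cohort_config(10000, seed = 42), ja, ctx)
  u <- cohort_unit_cost(cohort, ctx)
  se <- u$sd / sqrt(u$n)
  expect_lt(abs(u$mean - det), 3 * se)
})

test_that("participation thinning recovers the configured rates", {
  ctx <- shipped_ctx(); boa <- shipped_boa()
  cohort <- generate_cohort(cohort_config(4000, seed = 11), boa, ctx)
  # exercise sessions: Binomial(24, 0.6) per episode
  scheduled <- 24
  rate <- 0.6
  m <- mean(cohort$exercise_sessions)
  se <- sd(cohort$exercise_sessions) / sqrt(nrow(cohort))
  expect_lt(abs(m - rate * scheduled), 3 * se)
  expect_true(all(cohort$exercise_sessions <= scheduled))
})

test_that("wage and transport draws center on the configured means", {
  ctx <- shipped_ctx(); boa <- shipped_boa()
  cohort <- generate_cohort(cohort_config(8000, seed = 23), boa, ctx)
  se_w <- sd(cohort$wage) / sqrt(nrow(cohort))
  expect_lt(abs(mean(cohort$wage) - ctx$population_gross_hourly_wage), 3 * se_w)
  # transport minutes: truncation at 0 is negligible at mean 52.5, sd 15
  se_t <- sd(cohort$transport_minutes) / sqrt(nrow(cohort))
  expect_lt(abs(mean(cohort$transport_minutes) - 52.5), 3 * se_t + 0.05)
})

test_that("simulated effects recover configured means and reductions", {
  models0 <- list(
    ja = list(pre_mean = 5.7, pre_sd = 0, post_mean = 3.2, post_sd = 0),
    boa = list(pre_mean = 5.2, pre_sd = 0, post_mean = 4.1, post_sd = 0)
  )
  eff0 <- simulate_effects(models0, n = 10, seed = 1)
  expect_equal(round_half_up(eff0$percent_reduction), c(44, 21))
  expect_equal(eff0$pre_mean, c(5.7, 5.2))
  # reproducibility
  models <- list(ja = list(pre_mean = 5.7, pre_sd = 1, post_mean = 3.2,
                           post_sd = 1))
  e1 <- simulate_effects(models, n = 100, seed = 4)
  e2 <- simulate_effects(models, n = 100, seed = 4)
  expect_identical(e1, e2)
  # CLT recovery at larger n (sd 1: truncation at [0,10] is negligible)
  e3 <- simulate_effects(models, n = 50000, seed = 6)
  expect_lt(abs(e3$pre_mean - 5.7), 3 * e3$pre_sd / sqrt(50000))
  expect_lt(abs(e3$post_mean - 3.2), 3 * e3$post_sd / sqrt(50000))
  expect_error(simulate_effects(list(x = list(pre_mean = 5)), 10, 1),
               class = "oacost_validation_error")
})

test_that("the zero-variance pipeline reproduces the deterministic ICER", {
  ctx <- shipped_ctx()
  ja <- shipped_ja(); boa <- shipped_boa()
  cja <- cohort_unit_cost(generate_cohort(degenerate_config(3), ja, ctx), ctx)
  cboa <- cohort_unit_cost(generate_cohort(
    degenerate_config(3, pain = list(pre_mean = 5.2, pre_sd = 0,
                                     post_mean = 4.1, post_sd = 0)),
    boa, ctx), ctx)
  eff <- simulate_effects(
    list(ja = list(pre_mean = 5.7, pre_sd = 0, post_mean = 3.2, post_sd = 0),
         boa = list(pre_mean = 5.2, pre_sd = 0, post_mean = 4.1, post_sd = 0)),
    n = 3, seed = 1)
  sim <- icer(round_half_up(cja$mean), round_half_up(cboa$mean),
              eff$post_mean[1], eff$post_mean[2])
  det <- icer(round_half_up(cost_model(ja, ctx)$total),
              round_half_up(cost_model(boa, ctx)$total), 3.2, 4.1)
  expect_identical(sim$ratio, det$ratio)
  expect_identical(sim$ratio_reported, det$ratio_reported)
  expect_equal(sim$ratio_reported, 8705)
})
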