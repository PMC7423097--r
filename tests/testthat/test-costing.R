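test_that("aggregation reproduces the published domain subtotals and totals", {
  # published patient-domain lines of the face-to-face model
  pat <- rbind(cost_item("patient", "contacts", 5504),
               cost_item("patient", "administration", 1204),
               cost_item("patient", "transportation", 1445),
               cost_item("patient", "direct_fees", 1100))
  expect_equal(aggregate_breakdown(pat)$subtotal_patient, 9253)
  # published domain subtotals sum to the grand total
  doms <- rbind(cost_item("system", "contacts", 1299),
                cost_item("patient", "contacts", 9253),
                cost_item("other", "emissions", 59))
  expect_equal(aggregate_breakdown(doms)$total, 10611)
  # single item: subtotal equals the item
  one <- aggregate_breakdown(cost_item("system", "training", 30))
  expect_equal(one$subtotal_system, 30)
  expect_equal(one$total, 30)
  # empty inventory
  empty <- aggregate_breakdown(list())
  expect_equal(empty$total, 0)
  expect_equal(empty$subtotal_patient, 0)
})

test_that("breakdown conservation holds exactly for randomized inventories", {
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- sample(1:20, 1)
      items <- do.call(rbind, lapply(seq_len(n), function(j) {
        cost_item(sample(c("system", "patient", "other"), 1),
                  sample(c("contacts", "administration", "training",
                           "transportation", "direct_fees", "emissions"), 1),
                  total = runif(1, 0, 1e4))
      }))
      b <- aggregate_breakdown(items)
      expect_identical(b$total,
                       b$subtotal_system + b$subtotal_patient + b$subtotal_other)
      expect_equal(b$total, sum(items$total))
    }
  })
})

test_that("items are ordered stably by domain then category", {
  items <- rbind(cost_item("other", "emissions", 1),
                 cost_item("system", "training", 2),
                 cost_item("patient", "contacts", 3),
                 cost_item("system", "contacts", 4))
  b <- aggregate_breakdown(items)
  expect_equal(b$items$domain, c("system", "system", "patient", "other"))
  expect_equal(b$items$category,
               c("contacts", "training", "contacts", "emissions"))
})

test_that("cost items validate totals and quantities", {
  it <- cost_item("system", "contacts", quantity_hours = 2, unit_value = 250)
  expect_equal(it$total, 500)
  expect_error(cost_item("system", "contacts", total = -1),
               class = "oacost_domain_error")
  expect_error(cost_item("bank", "contacts", 1),
               class = "oacost_validation_error")
  expect_error(cost_item("system", "snacks", 1),
               class = "oacost_validation_error")
})

test_that("the shipped models reproduce every published cost line", {
  ctx <- shipped_ctx()
  ja <- cost_model(shipped_ja(), ctx)
  boa <- cost_model(shipped_boa(), ctx)
  line <- function(b, d, cat) {
    sum(b$items$total[b$items$domain == d & b$items$category == cat])
  }
  r <- round_half_up
  # digital model, system domain (administration includes technical support)
  expect_equal(r(line(ja, "system", "contacts")), 145)
  expect_equal(r(line(ja, "system", "administration") +
                   line(ja, "system", "technical_support")), 610)
  expect_equal(r(line(ja, "system", "training")), 11)
  expect_equal(r(ja$subtotal_system), 766)
  # digital model, patient domain
  expect_equal(r(line(ja, "patient", "contacts")), 716)
  expect_equal(r(line(ja, "patient", "administration")), 195)
  expect_equal(line(ja, "patient", "transportation"), 0)
  expect_equal(line(ja, "patient", "direct_fees"), 1100)
  expect_equal(r(ja$subtotal_patient), 2010)
  expect_equal(ja$subtotal_other, 0)
  expect_equal(r(ja$total), 2776)
  # face-to-face model
  expect_equal(r(line(boa, "system", "contacts")), 619)
  expect_equal(r(line(boa, "system", "administration") +
                   line(boa, "system", "technical_support")), 651)
  expect_equal(r(line(boa, "system", "training")), 30)
  expect_equal(r(boa$subtotal_system), 1299)
  expect_equal(r(line(boa, "patient", "contacts")), 5504)
  expect_equal(r(line(boa, "patient", "administration")), 1204)
  expect_equal(r(line(boa, "patient", "transportation")), 1445)
  expect_equal(line(boa, "patient", "direct_fees"), 1100)
  expect_equal(r(boa$subtotal_patient), 9253)
  expect_equal(r(boa$subtotal_other), 59)
  expect_equal(r(boa$total), 10611)
  expect_equal(r(boa$total) - r(ja$total), 7835)
})

test_that("cost_model is monotone in wages, durations, occurrences, multipliers", {
  base_ctx <- plain_ctx()
  base_total <- cost_model(toy_model(), base_ctx)$total
  bump_ctx <- function(field, value) {
    args <- list(provider_gross_hourly_wage = 200,
                 population_gross_hourly_wage = 100)
    args[[field]] <- value
    do.call(valuation_context, args)
  }
  for (case in list(c("provider_gross_hourly_wage", 250),
                    c("population_gross_hourly_wage", 150),
                    c("social_fee_rate", 0.5),
                    c("leisure_fraction", 0.5),
                    c("facility_surcharge", 0.2),
                    c("training_wage_multiplier", 2),
                    c("user_fee_ceiling", 1500))) {
    ctx2 <- bump_ctx(case[1], as.numeric(case[2]))
    expect_gte(cost_model(toy_model(), ctx2)$total, base_total)
  }
  # longer sessions and more occurrences cost at least as much
  longer <- toy_model()
  longer$contacts[[2]]$duration_minutes <- 90
  expect_gte(cost_model(longer, base_ctx)$total, base_total)
  more <- toy_model()
  more$contacts[[2]]$occurrences <- 12
  expect_gte(cost_model(more, base_ctx)$total, base_total)
})

test_that("a zero context leaves only fixed direct-fee items", {
  ctx0 <- valuation_context(0, 0, user_fee_ceiling = 1100)
  b <- cost_model(toy_model(), ctx0)
  fees <- sum(b$items$total[b$items$category == "direct_fees"])
  support <- sum(b$items$total[b$items$category == "technical_support"])
  emis <- sum(b$items$total[b$items$category == "emissions"])
  # time-valued items vanish; fixed fees, budget-based support, and the
  # emission value (not wage-based) remain
  expect_equal(b$total, fees + support + emis)
  expect_equal(fees, 1100)
})

test_that("payer-perspective session cost is never below the allocated cost", {
  ctx <- plain_ctx()
  for (g in c(1, 2, 7, 14)) {
    spec <- toy_model(group_size = g)
    pc <- oacost:::provider_contact_cost(spec, ctx,
                                         build_episode_schedule(spec))
    expect_gte(pc$undivided, pc$cost)
    if (g == 1) expect_equal(pc$undivided, pc$cost)
  }
})

test_that("published figures registry flags non-reproducible values", {
  pf <- published_figures()
  irr <- pf[!pf$reproducible, ]
  expect_true(all(c(117e6, 4.1e6, 555747) %in% irr$value))
  expect_true(all(c(10611, 2776, 8705, 133) %in% pf$value[pf$reproducible]))
})
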