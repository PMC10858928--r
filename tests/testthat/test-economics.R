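test_that("discounting uses geometric sub-annual compounding", {
  expect_equal(discount_factor(0, 0.1), 1)
  expect_equal(discount_factor(12, 0.025), 1 / 1.025)
  expect_equal(discount_factor(36, 0.025), 1.025^-3)
  expect_equal(discount_factor(36, 0.025), 0.928599, tolerance = 1e-6)
  # twelve monthly factors compose one annual factor
  expect_equal(prod(rep(discount_factor(1, 0.025), 12)), 1 / 1.025)
  expect_error(discount_factor(12, -0.01), "Negative")
})

test_that("undiscounted accumulation matches the structural hand result", {
  pars <- model_params(discount_annual = 0)
  trace <- run_cohort(manual_schedule(), "control")
  out <- accumulate_outcomes(trace, pars, "control")
  # 18 months event-free at 0.8 plus 18 months cured at 0.9
  expect_equal(out$ly, 3)
  expect_equal(out$qaly, 1.5 * 0.8 + 1.5 * 0.9)
  # no events and no deaths: entry immunoglobulin, 18 EF months, and the
  # one-off cured-state immunoglobulin cost for the whole cohort
  expect_equal(out$cost, 311 + 18 * 3238 + 412)
})

test_that("a cohort dying in cycle 1 accrues one month of time and cost", {
  pars <- model_params()
  trace <- run_cohort(manual_schedule(p_death_ef = 1), "control")
  out <- accumulate_outcomes(trace, pars, "control")
  d1 <- discount_factor(1, 0.025)
  expect_equal(out$ly, d1 / 12)
  expect_equal(out$cost, 311 + 3238 * d1)
})

test_that("unit utilities collapse QALYs onto life-years", {
  pars <- model_params(utilities = c(event_free = 1, post_event = 1,
                                     cured = 1, dead = 0))
  trace <- run_cohort(random_schedule(5), "control")
  out <- accumulate_outcomes(trace, pars, "control")
  expect_equal(out$qaly, out$ly)
})

test_that("QALY <= LY <= horizon and discounting shrinks everything", {
  sched <- random_schedule(9)
  pars0 <- model_params(discount_annual = 0)
  pars <- model_params(discount_annual = 0.025)
  for (arm in c("control", "intervention")) {
    trace <- run_cohort(sched, arm)
    u0 <- accumulate_outcomes(trace, pars0, arm)
    u1 <- accumulate_outcomes(trace, pars, arm)
    expect_lte(u0$qaly, u0$ly)
    expect_lte(u0$ly, 3)
    expect_lt(u1$ly, u0$ly)
    expect_lt(u1$qaly, u0$qaly)
    expect_lt(u1$cost, u0$cost)
  }
})

test_that("identical arms give exactly zero incremental outcomes", {
  sched <- manual_schedule(p_event = 0.02, p_event_int = 0.02,
                           p_death_ef = 0.01, p_death_pe = 0.05)
  pars <- symmetric_params()
  ctl <- accumulate_outcomes(run_cohort(sched, "control"), pars)
  int <- accumulate_outcomes(run_cohort(sched, "intervention"), pars)
  res <- compare_arms(ctl, int)
  expect_identical(res$delta_e, 0)
  expect_identical(res$delta_c, 0)
  expect_equal(res$inmb, 0)
  expect_equal(res$dominance, "trade-off")
})

test_that("the incremental comparison computes INMB and dominance", {
  ctl <- tibble::tibble(arm = "control", ly = 2.64, qaly = 2.17,
                        cost = 63190)
  int <- tibble::tibble(arm = "intervention", ly = 2.77, qaly = 2.32,
                        cost = 59480)
  res <- compare_arms(ctl, int, wtp = 50000)
  expect_equal(res$delta_e, 0.13, tolerance = 1e-12)
  expect_equal(res$delta_c, -3710)
  expect_equal(res$inmb, 50000 * 0.13 + 3710)
  expect_equal(res$dominance, "intervention dominant")
  expect_true(is.na(res$icer))
  # lambda = 0 reduces the INMB to minus the cost difference
  expect_equal(inmb_at(res, 0), 3710)
  expect_equal(inmb_at(res, c(0, 10000)), c(3710, 0.13 * 10000 + 3710))

  # trade-off quadrant reports an ICER
  worse <- compare_arms(ctl, tibble::tibble(arm = "intervention",
                                            ly = 2.77, qaly = 2.32,
                                            cost = 65000))
  expect_equal(worse$dominance, "trade-off")
  expect_equal(worse$icer, (65000 - 63190) / 0.13)

  # results tables carry the headline quantities
  td <- tidy(res)
  expect_equal(td$difference[td$quantity == "Mean cost per patient, €"],
               -3710)
  expect_equal(glance(res)$dominance, "intervention dominant")
})

test_that("accumulation rejects a horizon mismatch", {
  pars <- model_params(horizon_years = 10)
  trace <- run_cohort(manual_schedule(), "control")  # 36 cycles
  expect_error(accumulate_outcomes(trace, pars, "control"),
               "does not match")
})
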