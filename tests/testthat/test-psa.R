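test_that("sample_params draws match their assigned distributions", {
  base <- model_params()

  # nothing sampled: the base registry comes back unchanged
  expect_identical(sample_params(base, sample = character(0)), base)

  set.seed(10)
  hr <- replicate(20000, sample_params(base, "hr")$hr)
  expect_equal(median(hr), exp(-1.14938), tolerance = 0.01)
  expect_equal(sd(log(hr)), 0.38759, tolerance = 0.02)

  set.seed(11)
  costs <- replicate(20000, sample_params(base, "costs")$monthly_cost_ef_control)
  expect_equal(mean(costs), 198.06 / 0.06116, tolerance = 0.01)
  expect_true(all(costs > 0))

  set.seed(12)
  utils <- t(replicate(5000, sample_params(base, "utilities")$utilities))
  expect_true(all(utils >= 0 & utils <= 1))
  expect_equal(mean(utils[, "event_free"]), 0.8, tolerance = 0.02)
  expect_equal(sd(utils[, "event_free"]), 0.16, tolerance = 0.05)
  expect_true(all(utils[, "dead"] == 0))
})

test_that("infeasible utility uncertainty is clamped with a warning", {
  expect_warning(sh <- curecea:::beta_moments(0.5, 0.6), "clamped")
  expect_true(all(sh > 0))
  # the cured-state utility (mean 0.9, SE 0.18) is feasible as configured
  expect_silent(curecea:::beta_moments(0.9, 0.18))
})

test_that("PSA runs are deterministic given the seed", {
  sched <- build_schedule(small_trial(), model_params())
  a <- run_psa(sched, model_params(), n_sims = 40, seed = 99)
  b <- run_psa(sched, model_params(), n_sims = 40, seed = 99)
  expect_identical(a$draws, b$draws)
  c <- run_psa(sched, model_params(), n_sims = 40, seed = 100)
  expect_false(identical(a$draws$delta_e, c$draws$delta_e))
})

test_that("with every distribution fixed the PSA equals the base case", {
  pars <- model_params()
  sched <- build_schedule(small_trial(), pars)
  psa <- run_psa(sched, pars, n_sims = 3, seed = 1,
                 sample = character(0), sample_transitions = FALSE)
  ctl <- accumulate_outcomes(run_cohort(sched, "control"), pars)
  int <- accumulate_outcomes(run_cohort(sched, "intervention"), pars)
  det <- compare_arms(ctl, int)
  expect_equal(unique(psa$draws$delta_e), det$delta_e)
  expect_equal(unique(psa$draws$delta_c), det$delta_c)
  expect_equal(unique(psa$draws$inmb), det$inmb)
})

test_that("the CEAC is the draw-table exceedance curve", {
  sched <- build_schedule(small_trial(n = 150, seed = 13), model_params())
  psa <- run_psa(sched, model_params(), n_sims = 400, seed = 5)

  # recomputable from the persisted draws at every grid point
  recomputed <- vapply(psa$ceac$wtp, function(l) {
    mean(l * psa$draws$delta_e - psa$draws$delta_c > 0)
  }, numeric(1))
  expect_equal(psa$ceac$prob_cost_effective, recomputed)
  expect_true(all(psa$ceac$prob_cost_effective >= 0 &
                    psa$ceac$prob_cost_effective <= 1))
  expect_equal(prob_cost_effective(psa, 50000),
               mean(psa$draws$inmb > 0))

  # monotone in willingness-to-pay whenever every draw gains effect
  if (min(psa$draws$delta_e) >= 0) {
    expect_true(all(diff(psa$ceac$prob_cost_effective) >= 0))
  }
})

test_that("universal dominance pins the CEAC at 1", {
  # an intervention that cannot lose: strictly better survival at lower
  # cost in every draw (no sampling uncertainty)
  sched <- manual_schedule(p_event = 0.05, hr = 0.3, p_death_pe = 0.2)
  pars <- model_params(monthly_cost_ef_intervention = 500,
                       rituximab_cost = 0)
  psa <- run_psa(sched, pars, n_sims = 30, seed = 2,
                 sample = character(0), sample_transitions = FALSE)
  expect_true(all(psa$draws$delta_e > 0))
  expect_true(all(psa$draws$delta_c < 0))
  expect_true(all(psa$ceac$prob_cost_effective == 1))
})

test_that("scaling utility uncertainty widens the INMB interval", {
  sched <- build_schedule(small_trial(n = 150, seed = 13), model_params())
  width <- function(se_frac) {
    psa <- run_psa(sched, model_params(utility_se_frac = se_frac),
                   n_sims = 300, seed = 21, effect = "qaly")
    s <- psa$summary[psa$summary$quantity == "inmb", ]
    s$upper - s$lower
  }
  expect_gt(width(0.3), width(0.05))
})

test_that("PSA summaries surface in tidy and glance output", {
  sched <- build_schedule(small_trial(), model_params())
  psa <- run_psa(sched, model_params(), n_sims = 50, seed = 3)
  expect_setequal(names(tidy(psa, "draws")),
                  c("sim", "e_control", "e_intervention", "c_control",
                    "c_intervention", "delta_e", "delta_c", "inmb"))
  g <- glance(psa)
  expect_equal(g$n_sims, 50L)
  expect_equal(g$prob_cost_effective, prob_cost_effective(psa))
  expect_lte(g$delta_e_lower, g$delta_e)
})
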