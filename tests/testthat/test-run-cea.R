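test_that("the base-case analysis emits a complete results table", {
  trial <- small_trial(n = 150, seed = 29)
  res <- run_cea(trial, model_params(), n_sims = 60, seed = 2)
  td <- tidy(res)
  expect_true(all(c("Mean survival time (years)", "Mean QALYs (years)",
                    "Mean cost per patient, €") %in% td$quantity))
  expect_true(any(grepl("^INMB", td$quantity)))
  expect_true(any(grepl("Cost-effectiveness probability", td$quantity)))
  expect_true("psa_ci_difference" %in% names(td))
  g <- glance(res)
  expect_equal(g$analysis, "base_ly")
  expect_true(g$prob_cost_effective >= 0 && g$prob_cost_effective <= 1)
})

test_that("a 10-year horizon changes survival but not undiscounted cost", {
  trial <- small_trial(n = 150, seed = 29)
  pars <- model_params(discount_annual = 0)
  res3 <- run_cea(trial, pars, analysis = "base_ly", n_sims = 0)
  res10 <- run_cea(trial, pars, analysis = "horizon_10y", n_sims = 0)

  expect_equal(attr(run_cohort(res10$schedule, "control"),
                    "horizon_cycles"), 120L)
  # no occupant remains in a cost-bearing state after cycle 36, and the
  # cured-state cost is one-off, so undiscounted costs coincide exactly
  expect_equal(res10$deterministic$delta_c, res3$deterministic$delta_c)
  expect_equal(res10$deterministic$control$cost,
               res3$deterministic$control$cost)
  # survivors keep accruing life-years over the longer horizon
  expect_gt(res10$deterministic$control$ly, res3$deterministic$control$ly)
  expect_gt(abs(res10$deterministic$delta_e),
            abs(res3$deterministic$delta_e))
})

test_that("the QALY analysis drives the comparison with utilities", {
  trial <- small_trial(n = 150, seed = 29)
  res <- run_cea(trial, model_params(), analysis = "qaly", n_sims = 40,
                 seed = 6)
  expect_equal(res$effect, "qaly")
  expect_equal(res$deterministic$delta_e, res$deterministic$delta_qaly)
  expect_equal(res$psa$effect, "qaly")
})

test_that("estimation-variant analyses alter only their target inputs", {
  trial <- simulate_cost_records(small_trial(n = 150, seed = 29))
  base <- run_cea(trial, model_params(), n_sims = 0)
  pooled_d <- run_cea(trial, model_params(),
                      analysis = "pooled_ef_death", n_sims = 0)
  split_pe <- run_cea(trial, model_params(),
                      analysis = "split_pe_death", n_sims = 0)
  pooled_c <- run_cea(trial, model_params(),
                      analysis = "pooled_ef_cost", n_sims = 0)

  expect_true(pooled_d$schedule$pool_ef_death)
  expect_true(split_pe$schedule$split_pe_death)
  expect_equal(base$schedule$event, pooled_d$schedule$event)
  # pooled event-free cost applies one monthly cost to both arms
  expect_equal(pooled_c$params$monthly_cost_ef_control,
               pooled_c$params$monthly_cost_ef_intervention)
  est <- estimate_state_costs(trial, pool_ef = TRUE)
  expect_equal(pooled_c$params$monthly_cost_ef_control,
               est$mean_monthly_cost[est$state == "event_free"])
})

test_that("outputs round-trip to disk with a reproducibility manifest", {
  dir <- withr::local_tempdir()
  trial <- small_trial(n = 100, seed = 37)
  res <- run_cea(trial, model_params(), n_sims = 25, seed = 8,
                 run_tornado = TRUE)
  paths <- write_cea_outputs(res, dir)
  expect_true(all(file.exists(paths)))
  expect_setequal(basename(paths),
                  c("summary.csv", "schedule.csv", "draws.csv", "ceac.csv",
                    "tornado.csv", "manifest.json"))

  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 8)
  expect_equal(manifest$n_sims, 25)
  expect_match(manifest$params_hash, "^[0-9a-f]+$")

  # identical seeds reproduce the persisted draws bit for bit
  res2 <- run_cea(trial, model_params(), n_sims = 25, seed = 8)
  expect_identical(res$psa$draws, res2$psa$draws)
  draws_file <- utils::read.csv(file.path(dir, "draws.csv"))
  expect_equal(nrow(draws_file), 25)
})
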