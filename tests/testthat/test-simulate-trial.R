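test_that("generated trials have the configured arm sizes and structure", {
  trial <- simulate_trial(trial_config(seed = 5))
  p <- trial$patients
  expect_equal(nrow(p), 328)
  expect_equal(as.integer(table(p$arm)), c(164L, 164L))

  # structural invariants of the record
  both <- !is.na(p$t_event) & !is.na(p$t_death)
  expect_true(all(p$t_event[both] < p$t_death[both]))
  expect_true(all(p$t_event[!is.na(p$t_event)] <= 18))
  expect_true(all(p$rituximab_mg[p$arm == "control"] == 0))
  expect_true(all(p$rituximab_mg[p$arm == "intervention"] > 0))
  expect_equal(sum(p$in_cost_subgroup), 69)
})

test_that("degenerate rates give an event-free, death-free cohort", {
  cfg <- trial_config(n_per_arm = 30, event_rate_control = 0,
                      death_after_event_rate = 0,
                      death_event_free_rate = 0,
                      cost_subgroup_size = 10, seed = 2)
  p <- simulate_trial(cfg)$patients
  expect_equal(sum(p$event), 0)
  expect_equal(sum(p$death), 0)
  expect_true(all(p$t_censor == cfg$admin_censor_months))
})

test_that("the generator is deterministic given its seed", {
  a <- simulate_cost_records(small_trial(seed = 42))
  b <- simulate_cost_records(small_trial(seed = 42))
  expect_identical(a$patients, b$patients)
  expect_identical(a$costs, b$costs)
  c <- small_trial(seed = 43)
  expect_false(identical(a$patients$t_event, c$patients$t_event))
})

test_that("event proportions converge to the mixture-cure expectation", {
  cfg <- trial_config(n_per_arm = 20000, seed = 8)
  p <- simulate_trial(cfg)$patients
  # every non-cured patient events within 18 months, so the limiting
  # event probability is 1 - cure fraction (less a sliver removed by
  # competing event-free death and pre-event censoring)
  frac_ctl <- mean(p$event[p$arm == "control"])
  frac_int <- mean(p$event[p$arm == "intervention"])
  expect_equal(frac_ctl, 1 - cfg$cure_fraction_control, tolerance = 0.02)
  expect_equal(frac_int, 1 - cfg$cure_fraction_control^cfg$hr_event,
               tolerance = 0.02)
})

test_that("trial config rejects invalid inputs and warns on vacuous truncation", {
  expect_error(trial_config(n_per_arm = 0), "positive")
  expect_error(trial_config(cost_subgroup_size = 500, n_per_arm = 100),
               "cannot exceed")
  expect_warning(trial_config(event_rate_control = 1e-5), "vacuous")
})

test_that("cost records obey the state-attribution windows", {
  trial <- simulate_cost_records(small_trial(n = 300, seed = 21))
  costs <- dplyr::left_join(
    trial$costs,
    dplyr::select(trial$patients, patient_id = id, t_event, t_death,
                  t_censor),
    by = "patient_id"
  )
  ef <- dplyr::filter(costs, state == "event_free")
  pe <- dplyr::filter(costs, state == "post_event")

  # event-free records: never beyond month 18, and every record's month
  # ends at least 7 days before an observed event
  expect_true(all(ef$month >= 1 & ef$month <= 18))
  has_ev <- !is.na(ef$t_event)
  expect_true(all(ef$month[has_ev] <= ef$t_event[has_ev] - 7 / 30.4375))

  # post-event records: all attributed, within 18 months of the event,
  # and only for patients with an event
  expect_true(all(!is.na(pe$t_event)))
  expect_true(all(pe$month - pe$t_event <= 18 + 1))
  expect_true(all(pe$month > pe$t_event - 1))

  # patients with no event have no post-event records
  no_ev <- trial$patients$id[trial$patients$event == 0]
  expect_equal(nrow(dplyr::filter(pe, patient_id %in% no_ev)), 0)
})

test_that("cost re-estimation recovers the configured state means", {
  cfg <- trial_config(n_per_arm = 5000, cost_subgroup_size = 10000,
                      seed = 31)
  trial <- simulate_cost_records(simulate_trial(cfg))
  est <- estimate_state_costs(trial)
  ef_ctl <- est$mean_monthly_cost[est$state == "event_free" &
                                    est$arm == "control"]
  expect_equal(ef_ctl, cfg$cost_params$ef_control$mean, tolerance = 0.02)
  pe <- est$mean_monthly_cost[est$state == "post_event"]
  expect_equal(pe, cfg$cost_params$post_event$mean, tolerance = 0.05)
})

test_that("cost simulation fails on an empty subgroup", {
  trial <- simulate_trial(trial_config(n_per_arm = 10,
                                       cost_subgroup_size = 0, seed = 1))
  expect_error(simulate_cost_records(trial), "empty")
})

test_that("trial data round-trips through CSV files", {
  dir <- withr::local_tempdir()
  trial <- simulate_cost_records(small_trial(seed = 3))
  write_trial_data(trial, dir)
  back <- read_trial_data(dir)
  expect_equal(as.data.frame(back$patients),
               as.data.frame(trial$patients))
  expect_equal(as.data.frame(back$costs), as.data.frame(trial$costs))
})
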