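#' Run a full cost-effectiveness analysis
#'
#' Stitches the pipeline together for one named analysis: builds the
#' transition schedule from patient-level data, runs both cohorts,
#' accumulates discounted outcomes, compares the arms, and (optionally)
#' runs the probabilistic and deterministic sensitivity analyses.
#'
#' Available analyses:
#' * `base_ly` - 3-year horizon, life-years, per-arm event-free death,
#'   pooled post-event death (the base case).
#' * `horizon_10y` - the base case over a 10-year (120-cycle) horizon.
#' * `qaly` - the exploratory analysis with QALYs as the health outcome
#'   (utilities sampled in the PSA, varied in the tornado).
#' * `pooled_ef_death` - event-free death estimated combining both arms.
#' * `split_pe_death` - post-event death estimated per arm.
#' * `pooled_ef_cost` - event-free monthly hospital cost estimated
#'   combining both arms (re-derived from the trial's cost records).
#'
#' @param trial A `trial_data` object ([simulate_trial()] /
#'   [read_trial_data()]).
#' @param params A [model_params()].
#' @param analysis One of the analysis labels above.
#' @param n_sims PSA simulations; `0` skips the PSA.
#' @param seed Seed for the PSA draws.
#' @param run_tornado Also run the one-way deterministic sensitivity
#'   analysis.
#' @return An object of class `cea_analysis`: `deterministic` (a
#'   `cea_result`), `psa` (a `psa_result` or `NULL`), `tornado` (a
#'   `tornado_result` or `NULL`), plus `schedule`, `params`, `analysis`,
#'   `effect`, `seed`.
#' @examples
#' trial <- simulate_trial(trial_config(n_per_arm = 100, seed = 3))
#' res <- run_cea(trial, model_params(), n_sims = 50, seed = 4)
#' tidy(res)
#' @export
run_cea <- function(trial, params = model_params(),
                    analysis = c("base_ly", "horizon_10y", "qaly",
                                 "pooled_ef_death", "split_pe_death",
                                 "pooled_ef_cost"),
                    n_sims = 10000, seed = 1, run_tornado = FALSE) {
  analysis <- match.arg(analysis)
  effect <- if (analysis == "qaly") "qaly" else "ly"

  if (analysis == "horizon_10y") params$horizon_years <- 10
  if (analysis == "pooled_ef_cost") {
    pooled <- estimate_state_costs(trial, pool_ef = TRUE)
    ef_mean <- pooled$mean_monthly_cost[pooled$state == "event_free"]
    params$monthly_cost_ef_control <- ef_mean
    params$monthly_cost_ef_intervention <- ef_mean
  }
  horizon <- round(params$horizon_years * 12)

  schedule <- build_schedule(
    trial, params, horizon_cycles = horizon,
    pool_ef_death = analysis == "pooled_ef_death",
    split_pe_death = analysis == "split_pe_death"
  )

  ctl <- accumulate_outcomes(run_cohort(schedule, "control"), params)
  int <- accumulate_outcomes(run_cohort(schedule, "intervention"), params)
  det <- compare_arms(ctl, int, wtp = params$wtp, effect = effect)

  psa <- if (n_sims > 0) {
    run_psa(schedule, params, n_sims = n_sims, seed = seed,
            effect = effect)
  }
  torn <- if (run_tornado) {
    tornado(schedule, params, wtp = params$wtp, effect = effect)
  }

  structure(
    list(deterministic = det, psa = psa, tornado = torn,
         schedule = schedule, params = params, analysis = analysis,
         effect = effect, seed = as.integer(seed)),
    class = "cea_analysis"
  )
}

#' @export
print.cea_analysis <- function(x, ...) {
  cat(sprintf("<cea_analysis> '%s' (%s, %g-year horizon)\n", x$analysis,
              toupper(x$effect), x$params$horizon_years))
  print(x$deterministic)
  if (!is.null(x$psa)) print(x$psa)
  invisible(x)
}

#' Write analysis outputs to a directory
#'
#' Persists the summary table, PSA draw table, acceptability curve,
#' tornado table (when present) and a reproducibility manifest
#' (analysis label, seed, parameter hash, package version) as plain text.
#'
#' @param result A `cea_analysis` from [run_cea()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_cea_outputs <- function(result, dir) {
  stopifnot(inherits(result, "cea_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    paths[[name]] <<- path
  }
  w(tidy(result), "summary.csv")
  w(tidy(result$schedule), "schedule.csv")
  if (!is.null(result$psa)) {
    w(result$psa$draws, "draws.csv")
    w(result$psa$ceac, "ceac.csv")
  }
  if (!is.null(result$tornado)) w(result$tornado, "tornado.csv")

  manifest <- list(
    analysis = result$analysis, effect = result$effect,
    seed = result$seed,
    n_sims = if (is.null(result$psa)) 0L else result$psa$n_sims,
    n_skipped = if (is.null(result$psa)) 0L else result$psa$n_skipped,
    params_hash = rlang::hash(result$params),
    package_version = as.character(utils::packageVersion("curecea")),
    r_version = R.version.string
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  paths[["manifest.json"]] <- mpath
  invisible(unlist(paths))
}
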