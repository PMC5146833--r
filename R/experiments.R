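default_frailty_spec <- function(model) {
  if (identical(model$model_id, "x1")) frailty_age_dependent()
  else frailty_gamma(1, 1)
}

model_has_annual <- function(model) {
  any(vapply(model$transitions, function(tr) tr$timing == "annual", NA))
}

# Number of yearly entering cohorts needed so the year-1 cohort is fully
# resolved while new cohorts keep entering: 86 for long natural histories
# (annual transitions), 1 for models that resolve within the infection year.
default_cohort_years <- function(model) {
  if (model_has_annual(model)) as.integer(model$max_age) else 1L
}

# Draw the per-cohort-year age vectors for a scenario, applying the
# vaccination filter when requested. One seeded draw per experiment; the
# same ages are reused across replicates and modes so that variant
# comparisons are paired.
scenario_ages <- function(n, cohort_years, seed, vaccination = NULL) {
  set.seed(seed)
  lapply(seq_len(cohort_years), function(y) {
    a <- sample_incident_ages(n)
    if (!is.null(vaccination))
      a <- apply_vaccination(a,
        coverage = vaccination$coverage %||% 0.80,
        target_age_max = vaccination$target_age_max %||% 19,
        herd_multiplier = vaccination$herd_multiplier %||% 1.0)
    a
  })
}

#' Run replicate simulations and summarise the burden distribution
#'
#' Runs `n_reps` independently seeded stochastic simulations (or a single
#' deterministic expectation for `mode = "deterministic"`), computes the
#' year-1 cohort burden of each, and summarises YLD, YLL and DALY by their
#' median and 2.5/97.5% quantiles (inclusive linear interpolation). Incident
#' ages are drawn once per experiment (from `child_seed(master_seed, 0)`) and
#' held fixed across replicates; frailty values and transition selections are
#' redrawn every replicate (from `child_seed(master_seed, r)`).
#'
#' @param model a [disease_model()].
#' @param mode `"uniform"`, `"frailty"` or `"deterministic"`.
#' @param n_reps number of Monte-Carlo replicates (>= 2 for stochastic modes).
#' @param master_seed integer master seed; replicates derive child seeds from
#'   it by a documented splitting rule ([child_seed()]).
#' @param frailty_spec frailty distribution for `"frailty"` mode (default:
#'   age-dependent gamma for model `x1`, `Gamma(1, 1)` otherwise).
#' @param life_table life table for YLL (default: bundled surrogate).
#' @param n incident cases per cohort.
#' @param cohort_years number of consecutive yearly cohorts (default: 86 for
#'   models with annual transitions, 1 otherwise).
#' @param pooling transition accounting across cohorts, see
#'   [run_stochastic()]; experiments default to `"pooled"` (the variant under
#'   which age-independent heterogeneity affects the year-1 cohort's burden).
#' @param vaccination `NULL` or a list with `coverage`, `target_age_max`,
#'   `herd_multiplier` for [apply_vaccination()].
#' @param ages optionally a list of per-cohort-year age vectors, overriding
#'   internal generation (used to pair scenarios across modes).
#' @param keep_last_burden keep the final replicate's `burden_result`
#'   (with decompositions) in the output.
#' @return an object of class `replicate_summary`: `metrics` (one row per
#'   replicate: `rep`, `yld`, `yll`, `daly`, `deaths`, `acute_cases`),
#'   `summary` (metric x median/q2.5/q97.5), plus the run metadata.
#' @export
run_replicates <- function(model, mode = c("uniform", "frailty",
                                           "deterministic"),
                           n_reps = 1000, master_seed = 1,
                           frailty_spec = default_frailty_spec(model),
                           life_table = make_surrogate_life_table(),
                           n = 5000, cohort_years = default_cohort_years(model),
                           pooling = "pooled", vaccination = NULL,
                           ages = NULL, keep_last_burden = FALSE) {
  mode <- match.arg(mode)
  last_burden <- NULL
  if (is.null(ages))
    ages <- scenario_ages(n, cohort_years, child_seed(master_seed, 0),
                          vaccination)
  if (mode == "deterministic") {
    det <- run_deterministic(model, ages[[1L]], life_table)
    metrics <- data.frame(rep = 1L, yld = det$yld, yll = det$yll,
                          daly = det$daly, deaths = det$expected_deaths,
                          acute_cases = length(ages[[1L]]))
  } else {
    if (n_reps < 2) stop("n_reps must be >= 2 for stochastic modes")
    metrics <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
      set.seed(child_seed(master_seed, r))
      cohorts <- lapply(seq_along(ages), function(y) {
        a <- ages[[y]]
        frailty <- if (mode == "frailty") sample_frailties(frailty_spec, a)
                   else rep(1, length(a))
        data.frame(age_at_infection = a, frailty = frailty)
      })
      run <- run_stochastic(model, cohorts, mode = mode, pooling = pooling,
                            resolve = "burden_cohort")
      b <- compute_burden(run, model, life_table)
      if (keep_last_burden && r == n_reps) last_burden <<- b
      data.frame(rep = r, yld = b$yld, yll = b$yll, daly = b$daly,
                 deaths = b$deaths, acute_cases = length(ages[[1L]]))
    }))
  }
  summ <- do.call(rbind, lapply(c("yld", "yll", "daly"), function(mtr) {
    q <- quantile_summary(metrics[[mtr]])
    data.frame(metric = mtr, median = q[["median"]], q2.5 = q[["q2.5"]],
               q97.5 = q[["q97.5"]])
  }))
  structure(list(metrics = metrics, summary = summ, mode = mode,
                 n_reps = nrow(metrics), master_seed = master_seed,
                 model_id = model$model_id, n = n,
                 cohort_years = length(ages), pooling = pooling,
                 acute_cases = length(ages[[1L]]),
                 last_burden = last_burden),
            class = "replicate_summary")
}

#' Extract one summary statistic from a replicate summary
#'
#' @param summary_obj a `replicate_summary`.
#' @param metric `"yld"`, `"yll"` or `"daly"`.
#' @param what `"median"`, `"q2.5"` or `"q97.5"`.
#' @return the requested value.
#' @export
summary_value <- function(summary_obj, metric, what = "median") {
  s <- summary_obj$summary
  s[[what]][s$metric == metric]
}

#' Burden overestimation factor of the no-heterogeneity variant
#'
#' The ratio of the no-heterogeneity (reference) burden to the heterogeneity
#' variant's replicate median, with an interval obtained by dividing the
#' reference by the heterogeneity 97.5% and 2.5% quantiles. Values are
#' reported to two decimals; raw values are retained.
#'
#' @param reference no-heterogeneity burden (a single median value).
#' @param het_median,het_q2.5,het_q97.5 heterogeneity-variant replicate
#'   median and quantiles. Alternatively pass a `replicate_summary` as
#'   `het_median` together with `metric`.
#' @param metric which metric to compare when summaries are supplied.
#' @return an object of class `overestimation_result` with `factor`,
#'   `interval` (low, high), rounded counterparts and the metric tag.
#' @export
overestimation_factor <- function(reference, het_median, het_q2.5 = NA,
                                  het_q97.5 = NA, metric = "daly") {
  if (inherits(reference, "replicate_summary"))
    reference <- summary_value(reference, metric)
  if (inherits(het_median, "replicate_summary")) {
    s <- het_median
    het_q2.5 <- summary_value(s, metric, "q2.5")
    het_q97.5 <- summary_value(s, metric, "q97.5")
    het_median <- summary_value(s, metric, "median")
  }
  if (!is.numeric(reference) || !is.numeric(het_median))
    stop("reference and het_median must be numeric")
  if (het_median == 0) stop("heterogeneity median is zero")
  structure(list(
    factor = reference / het_median,
    interval = c(low = reference / het_q97.5, high = reference / het_q2.5),
    factor_2dp = round(reference / het_median, 2),
    interval_2dp = round(c(low = reference / het_q97.5,
                           high = reference / het_q2.5), 2),
    metric = metric),
    class = "overestimation_result")
}

#' DALYs averted by an intervention
#'
#' Bookkeeping shared by the vaccination experiment: burden averted is the
#' baseline median minus the intervention median, and the percentage averted
#' is relative to baseline (reported to one decimal).
#'
#' @param baseline,intervention median burdens (years).
#' @return list with `averted` and `percent`.
#' @export
daly_averted <- function(baseline, intervention) {
  if (baseline <= 0) stop("baseline burden must be positive")
  list(averted = baseline - intervention,
       percent = round((baseline - intervention) / baseline * 100, 1))
}

#' Age-targeted vaccination experiment
#'
#' Runs baseline and vaccination scenarios under the requested variants and
#' reports median burden, DALYs averted, percentage averted, and acute
#' infections prevented in the year-1 cohort. The vaccination scenario
#' retains each case aged under `target_age_max + 1` with probability
#' `1 - coverage` (default: 80% coverage of the under-20s, no herd effect on
#' older ages).
#'
#' @param model a [disease_model()] (default: the long natural history model).
#' @param coverage,target_age_max,herd_multiplier vaccination filter
#'   parameters, see [apply_vaccination()].
#' @param modes variants to run (`"uniform"` and/or `"frailty"`).
#' @param n_reps,master_seed,frailty_spec,life_table,n,cohort_years,pooling
#'   passed to [run_replicates()].
#' @return an object of class `vaccination_result`: a `results` data frame
#'   (one row per mode: baseline and vaccination DALY medians, `averted`,
#'   `percent`, acute case counts and `cases_prevented`) and the underlying
#'   summaries.
#' @export
vaccination_experiment <- function(model = builtin_model_x2(),
                                   coverage = 0.80, target_age_max = 19,
                                   herd_multiplier = 1.0,
                                   modes = c("uniform", "frailty"),
                                   n_reps = 1000, master_seed = 1,
                                   frailty_spec = default_frailty_spec(model),
                                   life_table = make_surrogate_life_table(),
                                   n = 5000,
                                   cohort_years = default_cohort_years(model),
                                   pooling = "pooled") {
  base_ages <- scenario_ages(n, cohort_years, child_seed(master_seed, 0))
  vac <- list(coverage = coverage, target_age_max = target_age_max,
              herd_multiplier = herd_multiplier)
  vac_ages <- scenario_ages(n, cohort_years, child_seed(master_seed, 0),
                            vaccination = vac)
  summaries <- list()
  rows <- lapply(modes, function(md) {
    s_base <- run_replicates(model, md, n_reps, master_seed,
                             frailty_spec, life_table, n, cohort_years,
                             pooling, ages = base_ages)
    s_vac <- run_replicates(model, md, n_reps, master_seed,
                            frailty_spec, life_table, n, cohort_years,
                            pooling, ages = vac_ages)
    summaries[[md]] <<- list(baseline = s_base, vaccination = s_vac)
    av <- daly_averted(summary_value(s_base, "daly"),
                       summary_value(s_vac, "daly"))
    data.frame(mode = md,
               baseline_daly = summary_value(s_base, "daly"),
               vaccination_daly = summary_value(s_vac, "daly"),
               averted = av$averted, percent = av$percent,
               baseline_cases = s_base$acute_cases,
               vaccination_cases = s_vac$acute_cases,
               cases_prevented = s_base$acute_cases - s_vac$acute_cases)
  })
  structure(list(results = do.call(rbind, rows), summaries = summaries,
                 coverage = coverage, target_age_max = target_age_max),
            class = "vaccination_result")
}

#' Sensitivity of the overestimation factor to annual transition probabilities
#'
#' Rebuilds the long natural history model over a grid of the two annual
#' transition probabilities (chronic to sequela, sequela to death), runs the
#' uniform and frailty variants at each grid cell, and tabulates the
#' median-based DALY (and YLL) overestimation factors.
#'
#' @param p_chronic_sequela,p_sequela_death grids of annual probabilities.
#' @param n_reps,master_seed,frailty_spec,life_table,n,cohort_years,pooling
#'   passed to [run_replicates()].
#' @return long-format data frame: `p_chronic_sequela`, `p_sequela_death`,
#'   `daly_factor`, `daly_low`, `daly_high`, `yll_factor`.
#' @export
sensitivity_grid <- function(p_chronic_sequela = c(0.01, 0.015, 0.02),
                             p_sequela_death = c(0.02, 0.03, 0.04),
                             n_reps = 200, master_seed = 1,
                             frailty_spec = frailty_gamma(1, 1),
                             life_table = make_surrogate_life_table(),
                             n = 5000, cohort_years = 86, pooling = "pooled") {
  stopifnot(all(p_chronic_sequela > 0 & p_chronic_sequela < 1),
            all(p_sequela_death > 0 & p_sequela_death < 1))
  grid <- expand.grid(p_chronic_sequela = p_chronic_sequela,
                      p_sequela_death = p_sequela_death)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    m <- builtin_model_x2(p_chronic_sequela = grid$p_chronic_sequela[i],
                          p_sequela_death = grid$p_sequela_death[i])
    ages <- scenario_ages(n, cohort_years, child_seed(master_seed, 0))
    s_u <- run_replicates(m, "uniform", n_reps, master_seed,
                          frailty_spec, life_table, n, cohort_years, pooling,
                          ages = ages)
    s_f <- run_replicates(m, "frailty", n_reps, master_seed,
                          frailty_spec, life_table, n, cohort_years, pooling,
                          ages = ages)
    ov_d <- overestimation_factor(s_u, s_f, metric = "daly")
    ov_y <- overestimation_factor(s_u, s_f, metric = "yll")
    cbind(grid[i, ], data.frame(
      daly_factor = ov_d$factor, daly_low = ov_d$interval[["low"]],
      daly_high = ov_d$interval[["high"]], yll_factor = ov_y$factor))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Frailty-shape sensitivity experiment
#'
#' Compares the median DALY of the heterogeneity variant under alternative
#' frailty distribution shapes sharing the same mean: the rightward-skewed
#' gamma of the main analysis, a leftward-skewed alternative (many
#' fast-progressors) and a peaked symmetric alternative.
#'
#' @param specs named list of frailty specs; defaults to `right_skew`
#'   Gamma(1,1) (the main analysis), with `left_skew` and `symmetric` sharing
#'   mean 1 and variance 0.25. The alternatives cannot match the Gamma(1,1)
#'   variance: a nonnegative random variable with standard deviation equal to
#'   its mean has skewness >= 0, so neither a left-skewed nor a symmetric
#'   shape exists at mean 1, variance 1 (see the package vignette).
#' @param model,n_reps,master_seed,life_table,n,cohort_years,pooling passed
#'   to [run_replicates()].
#' @return list with `medians` (named median DALY per spec) and `summaries`.
#' @export
frailty_shape_experiment <- function(specs = list(
                                       right_skew = frailty_gamma(1, 1),
                                       left_skew = frailty_alternative(
                                         "left_skew", 1, 0.25),
                                       symmetric = frailty_alternative(
                                         "symmetric", 1, 0.25)),
                                     model = builtin_model_x2(),
                                     n_reps = 200, master_seed = 1,
                                     life_table = make_surrogate_life_table(),
                                     n = 5000,
                                     cohort_years = default_cohort_years(model),
                                     pooling = "pooled") {
  ages <- scenario_ages(n, cohort_years, child_seed(master_seed, 0))
  summaries <- lapply(specs, function(sp)
    run_replicates(model, "frailty", n_reps, master_seed, sp, life_table,
                   n, cohort_years, pooling, ages = ages))
  medians <- vapply(summaries, summary_value, 0, metric = "daly")
  list(medians = medians, summaries = summaries)
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf(
    "Replicate summary: model %s, %s mode, %d replicate(s), n = %d x %d cohort(s)\n",
    x$model_id, x$mode, x$n_reps, x$n, x$cohort_years))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s median %10.1f  (95%% interval %.1f - %.1f)\n",
                toupper(s$metric[i]), s$median[i], s$q2.5[i], s$q97.5[i]))
  invisible(x)
}

#' @export
print.overestimation_result <- function(x, ...) {
  cat(sprintf("Overestimation of %s: %.2f (%.2f - %.2f)\n",
              toupper(x$metric), x$factor, x$interval[["low"]],
              x$interval[["high"]]))
  invisible(x)
}

#' @export
print.vaccination_result <- function(x, ...) {
  cat(sprintf("Age-targeted vaccination (coverage %.0f%%, ages <= %d):\n",
              100 * x$coverage, x$target_age_max))
  print(x$results, row.names = FALSE)
  invisible(x)
}
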