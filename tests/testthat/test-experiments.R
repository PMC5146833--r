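# Small problem sizes keep these orchestration checks fast; the full-scale
# study conditions are exercised in test-acceptance.R.

test_that("replicate summaries are reproducible and ordered", {
  m2 <- builtin_model_x2()
  s1 <- run_replicates(m2, "frailty", n_reps = 4, master_seed = 5, n = 300,
                       cohort_years = 10)
  s2 <- run_replicates(m2, "frailty", n_reps = 4, master_seed = 5, n = 300,
                       cohort_years = 10)
  expect_identical(s1$metrics, s2$metrics)
  expect_identical(s1$summary, s2$summary)
  s3 <- run_replicates(m2, "frailty", n_reps = 4, master_seed = 6, n = 300,
                       cohort_years = 10)
  expect_false(identical(s1$metrics, s3$metrics))
  # quantile sanity on every metric
  expect_true(all(s1$summary$q2.5 <= s1$summary$median))
  expect_true(all(s1$summary$median <= s1$summary$q97.5))
  expect_error(run_replicates(m2, "uniform", n_reps = 1, n = 100), "n_reps")
})

test_that("deterministic mode yields a single zero-width summary", {
  m1 <- builtin_model_x1()
  s <- run_replicates(m1, "deterministic", master_seed = 3, n = 2000)
  expect_equal(s$n_reps, 1L)
  expect_equal(s$summary$q2.5, s$summary$median)
  expect_equal(s$summary$q97.5, s$summary$median)
})

test_that("uniform X2 replicates show genuine spread in YLL", {
  s <- run_replicates(builtin_model_x2(), "uniform", n_reps = 10,
                      master_seed = 7, n = 500, cohort_years = 30)
  yll <- s$summary[s$summary$metric == "yll", ]
  expect_gt(yll$q97.5 - yll$q2.5, 0)
})

test_that("overestimation arithmetic divides reference by quantiles", {
  ov <- overestimation_factor(1318, 1135, 1082, 1192)
  expect_equal(ov$factor, 1318 / 1135)
  expect_equal(unname(ov$interval), c(1318 / 1192, 1318 / 1082))
  expect_equal(overestimation_factor(100, 100, 90, 110)$factor_2dp, 1)
  expect_error(overestimation_factor(100, 0), "zero")
  # constant metrics give a degenerate interval equal to the factor
  ov2 <- overestimation_factor(120, 100, 100, 100)
  expect_equal(unname(ov2$interval), c(1.2, 1.2))
})

test_that("averted-burden bookkeeping is exact", {
  av <- daly_averted(20960, 9280)
  expect_equal(av$averted, 11680)
  expect_equal(av$percent, 55.7)
  expect_error(daly_averted(0, 1), "positive")
})

test_that("report rounding uses years below 10k and tens above", {
  expect_equal(report_round(c(75, 1317.6, 10208, 20963)),
               c(75, 1318, 10210, 20960))
})

test_that("sensitivity grid includes the default cell consistently", {
  g <- sensitivity_grid(p_chronic_sequela = 0.02, p_sequela_death = 0.04,
                        n_reps = 6, master_seed = 9, n = 400,
                        cohort_years = 20)
  expect_equal(nrow(g), 1L)
  # the default grid cell reproduces a direct default-model run
  ages <- dalysim:::scenario_ages(400, 20, child_seed(9, 0))
  su <- run_replicates(builtin_model_x2(), "uniform", 6, 9, n = 400,
                       cohort_years = 20, ages = ages)
  sf <- run_replicates(builtin_model_x2(), "frailty", 6, 9, n = 400,
                       cohort_years = 20, ages = ages)
  expect_equal(g$daly_factor,
               overestimation_factor(su, sf, metric = "daly")$factor)
  expect_error(sensitivity_grid(p_chronic_sequela = 0), "p_chronic_sequela")
})

test_that("vaccination experiment pairs scenarios across modes", {
  v <- vaccination_experiment(n_reps = 4, master_seed = 13, n = 400,
                              cohort_years = 15)
  expect_equal(nrow(v$results), 2L)
  # same baseline cohort in both modes; vaccination removes only under-20s
  expect_equal(v$results$baseline_cases, c(400L, 400L))
  expect_equal(v$results$cases_prevented[1], v$results$cases_prevented[2])
  expect_true(all(v$results$averted ==
                    v$results$baseline_daly - v$results$vaccination_daly))
  # zero coverage averts nothing beyond Monte-Carlo noise
  v0 <- vaccination_experiment(n_reps = 4, master_seed = 13, n = 400,
                               cohort_years = 15, coverage = 0)
  expect_equal(v0$results$cases_prevented, c(0L, 0L))
  expect_lt(max(abs(v0$results$percent)), 8)
})

test_that("summary writer lays out variants with intervals and round-trips", {
  m1 <- builtin_model_x1()
  det <- run_replicates(m1, "deterministic", master_seed = 2, n = 1000)
  het <- run_replicates(m1, "frailty", n_reps = 6, master_seed = 2, n = 1000)
  path <- withr::local_tempfile()
  res <- write_summary(list(nohet = det, frailty = het), path)
  expect_true(file.exists(res$csv) && file.exists(res$json))
  tab <- read.csv(res$csv)
  # interval columns empty for the deterministic variant only
  expect_equal(tab$yll_interval[tab$variant == "nohet"], "")
  expect_match(tab$yll_interval[tab$variant == "frailty"], " - ")
  # overestimation present only on the reference row
  expect_match(tab$overestimation[tab$variant == "nohet"], "\\d\\.\\d\\d")
  expect_equal(tab$overestimation[tab$variant == "frailty"], "")
  js <- jsonlite::read_json(res$json)
  expect_equal(js$frailty$daly,
               het$summary$median[het$summary$metric == "daly"])
  # single-variant summaries omit the overestimation column content
  res2 <- write_summary(list(frailty = het), withr::local_tempfile())
  expect_true(all(res2$table$overestimation == ""))
})
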