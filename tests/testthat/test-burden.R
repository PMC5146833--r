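test_that("surrogate life table is calibrated and monotone", {
  lt <- make_surrogate_life_table()
  expect_s3_class(lt, "life_table")
  expect_lt(abs(residual_life_expectancy(lt, 0) - 75.5), 0.1)
  # expected age at death e(a) + a never decreases with age
  expect_true(all(diff(lt$ex + lt$age) >= 0))
  expect_gte(lt$ex[nrow(lt)], 0)
  expect_equal(lt$age, 0:100)
  # alternative calibration target
  lt2 <- make_surrogate_life_table(e0 = 60)
  expect_lt(abs(residual_life_expectancy(lt2, 0) - 60), 0.1)
})

test_that("residual life expectancy interpolates linearly", {
  lt <- data.frame(age = 0:100, ex = seq(80, 0, length.out = 101))
  class(lt) <- c("life_table", "data.frame")
  lt$ex[41] <- 38; lt$ex[42] <- 37.1
  expect_equal(residual_life_expectancy(lt, 40.5), 37.55)
  expect_equal(residual_life_expectancy(lt, 41), 37.1)
  expect_equal(residual_life_expectancy(lt, 100), lt$ex[101])
  expect_error(residual_life_expectancy(lt, 101), "range")
  expect_error(residual_life_expectancy(lt, -1), "range")
})

test_that("life tables round-trip through the age,ex CSV format", {
  lt <- make_surrogate_life_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, path)
  expect_identical(readLines(path)[1], "\"age\",\"ex\"")
  lt2 <- read_life_table(path)
  expect_equal(lt2$age, lt$age)
  expect_equal(lt2$ex, lt$ex, tolerance = 1e-12)
  bad <- data.frame(age = c(0, 2), ex = c(70, 68))
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_life_table(path), "contiguous")
})

test_that("burden arithmetic follows the YLD/YLL definitions", {
  lt <- make_surrogate_life_table()
  m2 <- builtin_model_x2()
  # hand-built run: one individual, 2 years in chronic (DW 0.15), recovered
  mk_run <- function(entry, exit, death = NA_integer_, cap = NA_integer_,
                     recover = NA_integer_, age = 40) {
    structure(list(
      model_id = "x2", mode = "uniform", pooling = "per_cohort",
      stage_id = m2$stages$stage_id, n = 1, cohort = 1L, entry_year = 0L,
      age_at_infection = age, frailty = 1,
      entry_step = matrix(entry, 1), exit_step = matrix(exit, 1),
      death_step = death, cap_step = cap, recover_step = recover,
      burden_cohort = 1L), class = "progression_run")
  }
  # acute (0.25 y at DW 0.1) then chronic years 0..2, capped out of scope:
  # use recover-style exit by giving chronic an exit at step 2
  r <- mk_run(entry = c(0L, 0L, NA, NA), exit = c(0L, 2L, NA, NA),
              cap = 2L)
  b <- compute_burden(r, m2, lt)
  expect_equal(b$yld, 0.1 * 0.25 + 0.15 * 2)
  expect_equal(b$yll, 0)
  expect_equal(b$daly, b$yld)
  # a death alone contributes the residual life expectancy at age of death
  r2 <- mk_run(entry = c(0L, 0L, 1L, 3L), exit = c(0L, 1L, 3L, NA),
               death = 3L, age = 50)
  b2 <- compute_burden(r2, m2, lt)
  expect_equal(b2$yll, residual_life_expectancy(lt, 53))
  expect_equal(b2$daly, b2$yld + b2$yll)
  # open histories are rejected
  r3 <- mk_run(entry = c(0L, 0L, NA, NA), exit = c(0L, NA, NA, NA))
  expect_error(compute_burden(r3, m2, lt), "open")
})

test_that("fixed-duration stages truncate at the 86th birthday", {
  lt <- make_surrogate_life_table()
  m1 <- builtin_model_x1()
  co <- data.frame(age_at_infection = c(85.6, 40), frailty = c(1, 1))
  r <- run_stochastic(m1, co, mode = "uniform", seed = 1)
  b <- compute_burden(r, m1, lt)
  # acute YLD: full 0.08 y for the 40-year-old, truncated 0.4 y for the
  # 85.6-year-old is still 0.08 (< 0.4), so both accrue in full; chronic
  # (1 y) truncates to 0.4 for the elderly case if they became chronic
  chronic <- !is.na(r$entry_step[, 2])
  expected_chronic_yld <- sum(0.2 * pmin(1, 86 - co$age_at_infection[chronic]))
  expect_equal(b$yld, 2 * 0.1 * 0.08 + expected_chronic_yld)
})

test_that("replacing a death with an older death never increases YLL", {
  lt <- make_surrogate_life_table()
  ages <- seq(0, 85, by = 5)
  yll <- residual_life_expectancy(lt, ages)
  expect_true(all(diff(yll) < 0))
})

test_that("quartile and age-band decompositions partition the total", {
  lt <- make_surrogate_life_table()
  m2 <- builtin_model_x2()
  ages <- sample_incident_ages(2000, seed = 9)
  co <- data.frame(age_at_infection = ages,
                   frailty = sample_frailties(frailty_gamma(1, 1), ages,
                                              seed = 10))
  r <- run_stochastic(m2, co, mode = "frailty", seed = 11)
  b <- compute_burden(r, m2, lt)
  q <- burden_by_frailty_quartile(b)
  expect_equal(nrow(q), 4L)
  expect_equal(sum(q$n), 2000)
  expect_equal(sum(q$yld), b$yld)
  expect_equal(sum(q$yll), b$yll)
  expect_equal(sum(q$daly), b$daly)
  g <- burden_by_age_group(b)
  expect_equal(sum(g$n), 2000)
  expect_equal(sum(g$daly), b$daly)
  # empty bands report zero burden
  empty <- g[g$n == 0, ]
  if (nrow(empty)) expect_true(all(empty$daly == 0))
  # uniform runs carry no frailty information for quartiles
  co_u <- data.frame(age_at_infection = ages, frailty = NA_real_)
  r_u <- run_stochastic(m2, co_u, mode = "uniform", seed = 12)
  b_u <- compute_burden(r_u, m2, lt)
  expect_error(burden_by_frailty_quartile(b_u), "frailty")
})

test_that("the bundled synthetic life table matches the generator", {
  path <- system.file("extdata", "life_table_synthetic_e0_75.5.csv",
                      package = "dalysim")
  expect_true(nzchar(path))
  bundled <- read_life_table(path)
  expect_equal(bundled$ex, make_surrogate_life_table()$ex, tolerance = 1e-6)
})

test_that("burden results export totals and decompositions", {
  lt <- make_surrogate_life_table()
  m2 <- builtin_model_x2()
  ages <- sample_incident_ages(500, seed = 21)
  co <- data.frame(age_at_infection = ages,
                   frailty = sample_frailties(frailty_gamma(1, 1), ages,
                                              seed = 22))
  b <- compute_burden(run_stochastic(m2, co, "frailty", seed = 23), m2, lt)
  base <- file.path(withr::local_tempdir(), "burden")
  files <- write_burden(b, base)
  expect_length(files, 4L)
  expect_true(all(file.exists(files)))
  js <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(js$daly, b$daly)
  expect_equal(js$yld + js$yll, js$daly)
  q <- read.csv(paste0(base, "_quartiles.csv"))
  expect_equal(sum(q$daly), b$daly)
})
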