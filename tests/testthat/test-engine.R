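test_that("expected transition counts floor with carry", {
  expect_equal(expected_transition_count(5000, 0.2, 0),
               list(n = 1000L, carry = 0))
  expect_equal(expected_transition_count(0, 0.7, 0), list(n = 0L, carry = 0))
  # iterated carry at constant occupancy 30, p = 0.02: N cycles 0,1,0,1,...
  carry <- 0
  ns <- integer(0); carries <- numeric(0)
  for (i in 1:4) {
    ec <- expected_transition_count(30, 0.02, carry)
    ns <- c(ns, ec$n); carries <- c(carries, ec$carry); carry <- ec$carry
  }
  expect_equal(ns, c(0L, 1L, 0L, 1L))
  expect_equal(carries, c(0.6, 0.2, 0.8, 0.4))
  # long-run total tracks the expectation within 1
  carry <- 0; total <- 0
  for (i in 1:97) {
    ec <- expected_transition_count(13, 0.037, carry)
    total <- total + ec$n; carry <- ec$carry
  }
  expect_lt(abs(total - 13 * 0.037 * 97), 1)
})

test_that("weighted sampling matches the successive-draw enumeration oracle", {
  set.seed(42)
  expect_setequal(weighted_sample_without_replacement(c(5, 1, 1), 3), 1:3)
  expect_error(weighted_sample_without_replacement(c(1, 1), 3), "between")

  # weights (2,1,1), one draw: item 1 selected half the time
  reps <- 4e4
  one <- vapply(seq_len(reps), function(i)
    weighted_sample_without_replacement(c(2, 1, 1), 1), 0L)
  expect_lt(abs(mean(one == 1) - 0.5), 3 * sqrt(0.25 / reps))

  # weights (2,1,1), two draws: inclusion of item 1 is 5/6 (enumeration)
  incl <- enumerate_inclusion(c(2, 1, 1), 2)
  expect_equal(incl[1], 5 / 6)   # oracle self-check against hand derivation
  two <- t(vapply(seq_len(reps), function(i)
    weighted_sample_without_replacement(c(2, 1, 1), 2), c(0L, 0L)))
  for (j in 1:3)
    expect_lt(abs(mean(two == j) * 2 - incl[j]),
              3 * sqrt(incl[j] * (1 - incl[j]) / reps))

  # full set distribution against enumeration, 4 items choose 2
  w <- c(3, 2, 1, 0.5)
  sets <- enumerate_wswor(w, 2)
  draws <- vapply(seq_len(reps), function(i)
    paste(sort(weighted_sample_without_replacement(w, 2)), collapse = "+"), "")
  emp <- table(factor(draws, levels = names(sets))) / reps
  tv <- sum(abs(emp - sets)) / 2
  expect_lt(tv, 0.02)

  # cross-check against the independent base R implementation of the same
  # successive-draw scheme
  base_draws <- vapply(seq_len(reps), function(i)
    paste(sort(sample.int(4, 2, prob = w)), collapse = "+"), "")
  emp_base <- table(factor(base_draws, levels = names(sets))) / reps
  expect_lt(sum(abs(emp - emp_base)) / 2, 0.03)
})

test_that("uniform mode reproduces the deterministic transition counts", {
  m1 <- builtin_model_x1()
  ages <- sample_incident_ages(5000, seed = 1)
  co <- data.frame(age_at_infection = ages, frailty = rep(1, 5000))
  for (s in c(3, 77)) {
    r <- run_stochastic(m1, co, mode = "uniform", seed = s)
    # chronic cases exactly at the population-averaged expectation
    expect_equal(sum(!is.na(r$entry_step[, 2])), 1000L)
  }
  # frailty mode is constrained to the same count
  cof <- data.frame(age_at_infection = ages,
                    frailty = sample_frailties(frailty_age_dependent(), ages,
                                               seed = 2))
  rf <- run_stochastic(m1, cof, mode = "frailty", seed = 3)
  expect_equal(sum(!is.na(rf$entry_step[, 2])), 1000L)
  # deterministic expectation agrees
  lt <- make_surrogate_life_table()
  det <- run_deterministic(m1, ages, lt)
  expect_equal(unname(det$stage_entries["chronic"]), 1000)
})

test_that("deterministic run matches closed-form tree expectations", {
  lt <- make_surrogate_life_table()
  m1 <- builtin_model_x1()
  # 1000 expected chronic cases aged 70 -> 150 expected deaths (CFR 15%)
  det <- run_deterministic(m1, rep(70, 5000), lt)
  expect_equal(det$expected_deaths, 5000 * 0.2 * 0.15)
  expect_equal(det$yll, 5000 * 0.2 * 0.15 * residual_life_expectancy(lt, 70))
  # YLD: acute for everyone plus chronic for the expected 20%
  expect_equal(det$yld, 5000 * 0.1 * 0.08 + 1000 * 0.2 * 1.0)
  expect_equal(det$daly, det$yld + det$yll)
  # mixed ages: expected deaths = 0.2 * mean CFR
  ages <- c(10, 20, 50, 70)
  det2 <- run_deterministic(m1, ages, lt)
  expect_equal(det2$expected_deaths, 0.2 * sum(c(0.05, 0.01, 0.02, 0.15)))
})

test_that("the 86th-birthday cap precedes annual transitions", {
  lt <- make_surrogate_life_table()
  m2 <- builtin_model_x2()
  # an 85-year-old chronic case exits at the cap before any sequela death
  det <- run_deterministic(m2, 85.5, lt)
  expect_equal(det$expected_deaths, 0)
  expect_equal(unname(det$stage_entries["sequela"]), 0)
  co <- data.frame(age_at_infection = 85.5, frailty = 1)
  r <- run_stochastic(m2, co, mode = "uniform", seed = 1)
  expect_equal(sum(!is.na(r$death_step)), 0L)
  # and no one ever occupies a stage beyond the cap
  ages <- sample_incident_ages(2000, seed = 3)
  co2 <- data.frame(age_at_infection = ages,
                    frailty = rgamma(2000, 1, 1))
  r2 <- run_stochastic(m2, co2, mode = "frailty", seed = 4)
  for (s in 1:4) {
    inn <- !is.na(r2$exit_step[, s])
    expect_true(all(ages[inn] + r2$exit_step[inn, s] <= 86 + 1))
  }
})

test_that("every individual ends in exactly one of stage/death/cap/recovery", {
  m2 <- builtin_model_x2()
  ages <- sample_incident_ages(3000, seed = 5)
  co <- data.frame(age_at_infection = ages, frailty = rgamma(3000, 1, 1))
  r <- run_stochastic(m2, co, mode = "frailty", seed = 6)
  ends <- cbind(!is.na(r$death_step), !is.na(r$cap_step),
                !is.na(r$recover_step))
  expect_true(all(rowSums(ends) == 1L))
  expect_equal(sum(rowSums(ends)), 3000)
  # histories are chronologically ordered along the chain
  for (i in sample.int(3000, 50)) {
    steps <- r$entry_step[i, ]
    steps <- steps[!is.na(steps)]
    expect_true(all(diff(steps) >= 0))
  }
})

test_that("toy-model outcome histories match exhaustive enumeration", {
  # 3 individuals, annual p = 1/2 frailty-weighted death, weights (2,1,1):
  # year 1 selects N = floor(1.5) = 1 death by weight; year 2 has carry 0.5,
  # occupancy 2 -> N = floor(1.5) = 1 more death. Enumerate the oracle over
  # successive draws and compare the joint distribution of (who died year 1,
  # who died year 2).
  w <- c(2, 1, 1)
  oracle <- outer(1:3, 1:3, Vectorize(function(a, b) {
    if (a == b) return(0)
    p_a <- w[a] / sum(w)
    rest <- w[-a]
    p_b <- rest[match(b, (1:3)[-a])] / sum(rest)
    p_a * p_b
  }))
  reps <- 3e4
  counts <- matrix(0, 3, 3)
  m <- toy_model(0.5)
  for (i in seq_len(reps)) {
    r <- run_stochastic(m, toy_cohort(rep(30, 3), w), mode = "frailty",
                        seed = i)
    died <- which(!is.na(r$death_step))
    d1 <- died[r$death_step[died] == 1][1]
    d2 <- died[r$death_step[died] == 2][1]
    counts[d1, d2] <- counts[d1, d2] + 1
  }
  tv <- sum(abs(counts / reps - oracle)) / 2
  expect_lt(tv, 0.02)
})

test_that("run exports produce complete event and occupancy tables", {
  m2 <- builtin_model_x2()
  co <- data.frame(age_at_infection = sample_incident_ages(200, seed = 7),
                   frailty = rgamma(200, 1, 1))
  r <- run_stochastic(m2, co, mode = "frailty", seed = 8)
  ev <- run_events(r)
  expect_true(all(c("id", "cohort_year", "stage", "entry_year", "exit_year",
                    "age_at_entry", "frailty") %in% names(ev)))
  expect_equal(sum(ev$stage == "acute"), 200L)
  occ <- run_occupancy(r)
  # year 0 occupancy: everyone passes through acute
  expect_equal(occ$count[occ$year == 0 & occ$stage == "acute"], 200L)
})

test_that("frailty distributions shift rightward with disease stage", {
  lt <- make_surrogate_life_table()
  # long natural history, pooled competition: sequela entrants are frailer
  # than chronic-only cases, who are frailer than the cohort average
  m2 <- builtin_model_x2()
  set.seed(1)
  ages <- lapply(1:86, function(i) sample_incident_ages(2000))
  cohorts <- lapply(ages, function(a)
    data.frame(age_at_infection = a, frailty = rgamma(length(a), 1, 1)))
  r <- run_stochastic(m2, cohorts, "frailty", "pooled", seed = 2,
                      resolve = "burden_cohort")
  y1 <- which(r$entry_year == 0L)
  chronic <- y1[!is.na(r$entry_step[y1, 2])]
  sequela <- y1[!is.na(r$entry_step[y1, 3])]
  chronic_only <- setdiff(chronic, sequela)
  expect_gt(mean(r$frailty[sequela]), mean(r$frailty[chronic_only]))
  expect_gt(mean(r$frailty[chronic_only]), mean(r$frailty[y1]))

  # short natural history with age-increasing frailty: chronic cases are
  # frailer than the acute cohort
  m1 <- builtin_model_x1()
  a1 <- sample_incident_ages(5000, seed = 3)
  co <- data.frame(age_at_infection = a1,
                   frailty = sample_frailties(frailty_age_dependent(), a1,
                                              seed = 4))
  r1 <- run_stochastic(m1, co, "frailty", seed = 5)
  chronic1 <- !is.na(r1$entry_step[, 2])
  expect_gt(mean(r1$frailty[chronic1]), mean(r1$frailty))
})
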