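#' Sample ages at infection for an incident cohort
#'
#' Ages are drawn from a Gamma(shape = 2, scale = 17.5) distribution (mean 35
#' years, mode around 18), rejection-resampled below `age_cap` so that every
#' incident case is alive (under the 86th-birthday exit rule) at infection.
#' Ages are kept continuous; integer-year binning (5-year groups for frailty,
#' broad bands for case-fatality) is derived by flooring downstream.
#'
#' @param n number of cases (>= 0).
#' @param seed optional integer seed (`NULL`: current RNG stream).
#' @param shape,scale gamma parameters of the incidence age distribution.
#' @param age_cap upper support bound for rejection sampling.
#' @return numeric vector of `n` ages.
#' @export
sample_incident_ages <- function(n, seed = NULL, shape = 2, scale = 17.5,
                                 age_cap = 85.999) {
  if (!is.numeric(n) || length(n) != 1L || n < 0)
    stop("n must be a nonnegative count")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  sample_truncated(n, function(m) stats::rgamma(m, shape = shape, scale = scale),
                   function(x) x < age_cap)
}

#' Generate an incident-case cohort
#'
#' All individuals start in the model's entry stage (acute infection) in the
#' cohort's entry year, with ages from [sample_incident_ages()] and frailty
#' values from [sample_frailties()].
#'
#' @param n cohort size (> 0).
#' @param frailty_spec a [frailty_gamma()]-style spec, or `NULL` to skip
#'   frailty assignment (no-heterogeneity use).
#' @param entry_year simulation year in which the cohort enters.
#' @param seed optional integer seed.
#' @param ages optionally, pre-drawn ages (overrides sampling).
#' @param label scenario tag.
#' @return a data frame of class `cohort` with columns `id`,
#'   `age_at_infection`, `frailty`, plus attributes `entry_year` and `label`.
#' @export
make_cohort <- function(n, frailty_spec = NULL, entry_year = 0, seed = NULL,
                        ages = NULL, label = "baseline") {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ages)) ages <- sample_incident_ages(n)
  if (length(ages) == 0L) stop("cohort size must be > 0")
  frailty <- if (is.null(frailty_spec)) rep(NA_real_, length(ages))
             else sample_frailties(frailty_spec, ages)
  out <- data.frame(id = seq_along(ages), age_at_infection = ages,
                    frailty = frailty)
  attr(out, "entry_year") <- entry_year
  attr(out, "label") <- label
  class(out) <- c("cohort", "data.frame")
  out
}

#' Apply the age-targeted vaccination filter to incident ages
#'
#' Emulates high-coverage vaccination of the young: each potential case with
#' `floor(age) <= target_age_max` (i.e. aged under `target_age_max + 1`) is
#' retained independently with probability `1 - coverage`; older cases are
#' retained with probability `herd_multiplier` (default 1: no herd effect).
#' The default scenario is 80% coverage of the under-20s.
#'
#' @param ages candidate ages at infection.
#' @param coverage vaccination coverage in `[0, 1]`.
#' @param target_age_max last integer age (in years) targeted by vaccination.
#' @param herd_multiplier retention probability for cases above the target
#'   ages, a crude stand-in for herd-immunity effects; scalar in `[0, 1]`.
#' @param seed optional integer seed.
#' @return the retained subset of `ages`.
#' @export
apply_vaccination <- function(ages, coverage = 0.80, target_age_max = 19,
                              herd_multiplier = 1.0, seed = NULL) {
  if (!is.numeric(coverage) || coverage < 0 || coverage > 1)
    stop("coverage must be in [0, 1]")
  if (herd_multiplier < 0 || herd_multiplier > 1)
    stop("herd_multiplier must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  young <- floor(ages) <= target_age_max
  p_keep <- ifelse(young, 1 - coverage, herd_multiplier)
  ages[stats::runif(length(ages)) < p_keep]
}

#' Herd-effect multiplier reproducing a target caseload
#'
#' The vaccination filter leaves older ages untouched by default. If a target
#' number of retained acute cases is known (for instance from an external
#' scenario), this helper returns the uniform retention multiplier for the
#' non-targeted ages whose expected retained count matches it.
#'
#' @param ages candidate ages at infection.
#' @param target_cases desired expected number of retained cases.
#' @param coverage,target_age_max as in [apply_vaccination()].
#' @return scalar multiplier in `[0, 1]`.
#' @export
calibrate_herd_multiplier <- function(ages, target_cases, coverage = 0.80,
                                      target_age_max = 19) {
  n_young <- sum(floor(ages) <= target_age_max)
  n_old <- length(ages) - n_young
  if (n_old == 0L) stop("no cases above the target ages to calibrate on")
  m <- (target_cases - (1 - coverage) * n_young) / n_old
  if (m < 0 || m > 1)
    stop("target_cases ", target_cases, " not reachable: implied multiplier ",
         round(m, 3), " outside [0, 1]")
  m
}

#' Write / read a cohort as CSV
#'
#' Columns `id, age_at_infection, frailty, scenario`; round-trips with
#' [read_cohort()].
#'
#' @param cohort a `cohort` data frame.
#' @param path CSV file path.
#' @return `path` (write) or a `cohort` (read).
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$scenario <- attr(cohort, "label") %||% "baseline"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  out <- df[c("id", "age_at_infection", "frailty")]
  attr(out, "entry_year") <- 0
  attr(out, "label") <- df$scenario[1L] %||% "baseline"
  class(out) <- c("cohort", "data.frame")
  out
}
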