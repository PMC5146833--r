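#' Surrogate period life table from a Gompertz mortality law
#'
#' Builds a smooth synthetic period life table with residual life expectancy
#' declining from `e0` at age 0. Adult mortality follows a Gompertz hazard
#' `mu(x) = A * exp(B * x)`; `A` is calibrated by root finding so that the
#' period life expectancy at birth equals `e0`. This is a bundled synthetic
#' stand-in for a national life table (any real table can be supplied via
#' [read_life_table()]); absolute YLL values are table-dependent, ratios
#' between model variants are the supported comparison.
#'
#' @param e0 target life expectancy at birth in years.
#' @param terminal_age last tabulated age.
#' @param gompertz_b slope of log-mortality per year of age; the default is
#'   the textbook adult mortality doubling time of 7 years
#'   (`log(2) / 7`).
#' @return an object of class `life_table`: data frame with columns `age`
#'   (integer years 0..`terminal_age`) and `ex` (residual life expectancy),
#'   plus a `provenance` attribute.
#' @export
make_surrogate_life_table <- function(e0 = 75.5, terminal_age = 100,
                                      gompertz_b = log(2) / 7) {
  stopifnot(e0 > 0, terminal_age > 0)
  grid <- seq(0, terminal_age + 30, by = 0.25)   # integrate well past table end
  e0_of <- function(a) {
    H <- a / gompertz_b * (exp(gompertz_b * grid) - 1)   # cumulative hazard
    S <- exp(-H)
    sum((S + c(S[-1], 0)) / 2) * 0.25                    # trapezoid, as below
  }
  a <- tryCatch(
    stats::uniroot(function(a) e0_of(a) - e0, lower = 1e-8, upper = 1e-1,
                   tol = 1e-12)$root,
    error = function(e) stop("life-table calibration infeasible for e0 = ", e0))
  H <- a / gompertz_b * (exp(gompertz_b * grid) - 1)
  S <- exp(-H)
  # residual expectancy e(x) = int_x S(t) dt / S(x), trapezoid on the grid
  tail_int <- rev(cumsum(rev((S + c(S[-1], 0)) / 2 * 0.25)))
  ages <- 0:terminal_age
  idx <- match(ages, grid)
  ex <- tail_int[idx] / S[idx]
  tab <- data.frame(age = ages, ex = ex)
  attr(tab, "provenance") <- sprintf(
    "synthetic Gompertz life table (e0 = %g, B = %g)", e0, gompertz_b)
  class(tab) <- c("life_table", "data.frame")
  tab
}

#' Read / write a life table as CSV
#'
#' The CSV format is one header line `age,ex` followed by one row per integer
#' age; this is the interchange format for supplying real national life
#' tables. A copy of the default synthetic table ships with the package:
#' `system.file("extdata", "life_table_synthetic_e0_75.5.csv",
#' package = "dalysim")`.
#'
#' @param path CSV file path.
#' @param table a `life_table`.
#' @return a `life_table` (read) or `path` (write).
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("age", "ex") %in% names(df)))
    stop("life table CSV must have columns 'age' and 'ex'")
  df <- df[order(df$age), c("age", "ex")]
  if (!all(diff(df$age) == 1L))
    stop("life table ages must be contiguous integer years")
  if (any(df$ex < 0)) stop("residual life expectancy must be nonnegative")
  attr(df, "provenance") <- path
  class(df) <- c("life_table", "data.frame")
  df
}

#' @rdname read_life_table
#' @export
write_life_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[c("age", "ex")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Residual life expectancy at an exact age
#'
#' Linear interpolation of the life table between integer ages; exact at
#' table rows. Used as the YLL contribution of a death at that age.
#'
#' @param table a `life_table`.
#' @param age age(s) in years within the table range.
#' @return residual life expectancy in years.
#' @export
residual_life_expectancy <- function(table, age) {
  rng <- range(table$age)
  if (any(age < rng[1L] | age > rng[2L]))
    stop("age outside the life-table range [", rng[1L], ", ", rng[2L], "]")
  stats::approx(table$age, table$ex, xout = age, method = "linear")$y
}
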