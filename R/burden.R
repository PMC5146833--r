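#' Compute YLD, YLL and DALY from a completed run
#'
#' Burden accounting for the cohort flagged for burden (the simulation year 1
#' cohort in multi-cohort runs):
#'
#' * YLD: for fixed-duration stages, disability weight times
#'   `min(duration, time to the 86th-birthday cap)` for every entrant; for
#'   while-occupied stages, disability weight times whole years occupied
#'   (entry to exit, truncated by the cap).
#' * YLL: residual life expectancy (from the life table, interpolated at the
#'   exact age at death) summed over disease deaths. Cap exits contribute no
#'   YLL.
#' * DALY = YLD + YLL, with no discounting and no age weighting.
#'
#' @param run a `progression_run` from [run_stochastic()].
#' @param model the [disease_model()] that produced it.
#' @param life_table a `life_table` for YLL.
#' @return an object of class `burden_result`: totals `yld`, `yll`, `daly`,
#'   per-stage YLD, and a per-individual data frame (`id`,
#'   `age_at_infection`, `frailty`, `yld`, `yll`, `died`) used by the
#'   decomposition helpers.
#' @export
compute_burden <- function(run, model, life_table) {
  stopifnot(inherits(run, "progression_run"))
  keep <- which(run$entry_year == run$burden_cohort - 1L)
  st <- model$stages
  open <- vapply(seq_along(run$stage_id), function(s) {
    ent <- run$entry_step[keep, s]
    any(!is.na(ent) & is.na(run$exit_step[keep, s]) &
          !st$is_terminal[s])
  }, NA)
  if (any(open)) stop("run has open stage histories; simulate to resolution")

  age0 <- run$age_at_infection[keep]
  ey <- run$entry_year[keep]
  yld_i <- numeric(length(keep))
  per_stage_yld <- stats::setNames(numeric(nrow(st)), st$stage_id)
  for (s in seq_len(nrow(st))) {
    if (st$is_terminal[s] || st$disability_weight[s] == 0) next
    ent <- run$entry_step[keep, s]
    inn <- !is.na(ent)
    if (!any(inn)) next
    if (!is.na(st$duration[s])) {       # fixed duration, truncated at the cap
      age_entry <- age0[inn] + (ent[inn] - ey[inn])
      dur <- pmax(pmin(st$duration[s], model$max_age - age_entry), 0)
    } else {                            # while occupied, whole years
      dur <- run$exit_step[keep, s][inn] - ent[inn]
    }
    contrib <- st$disability_weight[s] * dur
    yld_i[inn] <- yld_i[inn] + contrib
    per_stage_yld[s] <- sum(contrib)
  }
  died <- !is.na(run$death_step[keep])
  yll_i <- numeric(length(keep))
  if (any(died)) {
    age_death <- age0[died] + (run$death_step[keep][died] - ey[died])
    yll_i[died] <- residual_life_expectancy(life_table, age_death)
  }
  individuals <- data.frame(
    id = keep, age_at_infection = age0, frailty = run$frailty[keep],
    yld = yld_i, yll = yll_i, died = died)
  structure(list(yld = sum(yld_i), yll = sum(yll_i),
                 daly = sum(yld_i) + sum(yll_i),
                 per_stage_yld = per_stage_yld,
                 deaths = sum(died), individuals = individuals),
            class = "burden_result")
}

sum_burden_rows <- function(df) {
  list(yld = sum(df$yld), yll = sum(df$yll), daly = sum(df$yld) + sum(df$yll),
       deaths = sum(df$died), n = nrow(df))
}

#' Burden decomposition by cohort frailty quartile
#'
#' Partitions the burden cohort into four equal-sized groups by frailty rank
#' (ties broken by id order) and sums YLD/YLL within each; the four parts add
#' up to the total result.
#'
#' @param burden a `burden_result` from a frailty-mode run.
#' @return data frame with one row per quartile: `quartile`, `n`, `yld`,
#'   `yll`, `daly`, `deaths`.
#' @export
burden_by_frailty_quartile <- function(burden) {
  df <- burden$individuals
  if (anyNA(df$frailty))
    stop("frailty quartile decomposition needs a frailty-mode run")
  r <- rank(df$frailty, ties.method = "first")
  q <- ceiling(4 * r / nrow(df))
  out <- do.call(rbind, lapply(1:4, function(k)
    as.data.frame(sum_burden_rows(df[q == k, ]))))
  cbind(quartile = paste0("Q", 1:4), out)
}

#' Burden decomposition by age group at acute infection
#'
#' @param burden a `burden_result`.
#' @param band_width width of the age bands in years (default 5).
#' @return data frame with one row per nonempty-or-covered band:
#'   `min_age`, `max_age`, `n`, `yld`, `yll`, `daly`, `deaths`.
#' @export
burden_by_age_group <- function(burden, band_width = 5) {
  df <- burden$individuals
  lo <- seq(0, 85, by = band_width)
  band <- findInterval(df$age_at_infection, lo)
  out <- do.call(rbind, lapply(seq_along(lo), function(k)
    as.data.frame(sum_burden_rows(df[band == k, , drop = FALSE]))))
  cbind(min_age = lo, max_age = pmin(lo + band_width, 86), out)
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("Burden: YLD %.1f + YLL %.1f = DALY %.1f (%d deaths, n = %d)\n",
              x$yld, x$yll, x$daly, x$deaths, nrow(x$individuals)))
  invisible(x)
}

#' Export a burden result with its decompositions
#'
#' Writes `<base>.json` (totals, per-stage YLD, death count), the
#' per-individual table `<base>_individuals.csv`, the age-group
#' decomposition `<base>_age_groups.csv`, and — when the run carried frailty
#' values — the frailty-quartile decomposition `<base>_quartiles.csv`.
#'
#' @param burden a `burden_result`.
#' @param path output path base (a `.json`/`.csv` extension is stripped).
#' @return invisible character vector of the files written.
#' @export
write_burden <- function(burden, path) {
  stopifnot(inherits(burden, "burden_result"))
  base <- sub("\\.(json|csv)$", "", path)
  files <- paste0(base, ".json")
  jsonlite::write_json(list(
    yld = burden$yld, yll = burden$yll, daly = burden$daly,
    deaths = burden$deaths, n = nrow(burden$individuals),
    per_stage_yld = as.list(burden$per_stage_yld)),
    files, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  f <- paste0(base, "_individuals.csv")
  utils::write.csv(burden$individuals, f, row.names = FALSE)
  files <- c(files, f)
  f <- paste0(base, "_age_groups.csv")
  utils::write.csv(burden_by_age_group(burden), f, row.names = FALSE)
  files <- c(files, f)
  if (!anyNA(burden$individuals$frailty)) {
    f <- paste0(base, "_quartiles.csv")
    utils::write.csv(burden_by_frailty_quartile(burden), f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
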