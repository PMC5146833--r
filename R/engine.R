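#' Constrained expected transition count with fractional carry
#'
#' The number of individuals making a transition in a given year is
#' constrained to the expectation under the population-averaged probability:
#' `e = occupancy * p + carry`, `N = floor(e)`, with the fractional remainder
#' carried into the next year so that cumulative transitions track the
#' cumulative expectation within 1 over any horizon (floor-with-carry is
#' unbiased in the long run, unlike rounding).
#'
#' @param occupancy current number of individuals in the source stage.
#' @param p population-averaged transition probability in `[0, 1]`.
#' @param carry fractional accumulator from previous years (in `[0, 1)`).
#' @return list with integer `n` and `carry`.
#' @export
expected_transition_count <- function(occupancy, p, carry = 0) {
  stopifnot(occupancy >= 0, p >= 0, p <= 1)
  e <- occupancy * p + carry
  n <- floor(e + 1e-9)               # guard against 1000 - eps from binary p
  list(n = as.integer(n), carry = max(e - n, 0))
}

#' Weighted sampling without replacement (successive draws)
#'
#' Selects `n` distinct items with probability proportional to weight at each
#' successive draw. Implemented with exponential race keys (`rexp(1) /
#' weight`, smallest keys win), which is distributionally equivalent to
#' successive probability-proportional-to-weight draws. Zero-weight items get
#' infinite keys and are selected only if unavoidable. Equal weights reduce
#' to simple random sampling.
#'
#' @param weights nonnegative selection weights, one per candidate.
#' @param n number of items to select (`0 <= n <= length(weights)`).
#' @param seed optional integer seed (`NULL`: current RNG stream).
#' @return integer vector of `n` selected indices.
#' @export
weighted_sample_without_replacement <- function(weights, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(weights)
  if (n < 0 || n > m) stop("n must be between 0 and length(weights)")
  if (n == 0L) return(integer(0))
  if (any(weights < 0)) stop("weights must be nonnegative")
  keys <- stats::rexp(m) / weights
  head(order(keys), n)
}

# Internal selection step shared by the engine: pick n of ids, weighted or
# uniform. Consumes the current RNG stream. The weighted branch selects the
# n smallest exponential-race keys via a partial sort (keys are continuous,
# so ties have probability zero; a defensive trim handles them anyway).
select_transitioners <- function(ids, n, weights = NULL) {
  m <- length(ids)
  if (n <= 0L) return(integer(0))
  if (n >= m) return(ids)
  if (is.null(weights)) return(ids[sample.int(m, n)])
  keys <- stats::rexp(m) / weights
  kth <- sort.int(keys, partial = n)[n]
  hit <- which(keys <= kth)
  if (length(hit) > n) hit <- hit[order(keys[hit])][seq_len(n)]
  ids[hit]
}

# Preprocess a model into indexed form for the simulation loops.
compile_model <- function(model) {
  st <- model$stages
  ns <- nrow(st)
  idx <- function(id) match(id, st$stage_id)
  edges <- lapply(model$transitions, function(tr) {
    banded <- transition_is_banded(tr)
    b <- if (banded) tr$probability[order(tr$probability$min_age), ] else NULL
    list(from = idx(tr$from), to = idx(tr$to),
         immediate = tr$timing == "immediate",
         fw = isTRUE(tr$frailty_weighted),
         banded = banded,
         p = if (banded) b$p else tr$probability,
         band_breaks = if (banded) c(b$min_age, utils::tail(b$max_age, 1L)))
  })
  from_i <- vapply(edges, `[[`, 0L, "from")
  to_i <- vapply(edges, `[[`, 0L, "to")
  topo <- topo_order(ns, from_i, to_i)
  pos <- match(seq_len(ns), topo)
  annual <- which(!vapply(edges, `[[`, NA, "immediate"))
  immediate <- which(vapply(edges, `[[`, NA, "immediate"))
  # annual edges most-downstream first; immediate edges upstream first so
  # that same-cycle cascades (entry -> chronic -> death in one infection
  # year) resolve on entry.
  annual <- annual[order(-pos[from_i[annual]])]
  immediate <- immediate[order(pos[from_i[immediate]])]
  has_annual_out <- vapply(seq_len(ns), function(s)
    any(from_i == s & !vapply(edges, `[[`, NA, "immediate")), NA)
  transient <- which(!st$is_terminal & !has_annual_out)
  list(ns = ns, stage_id = st$stage_id, dw = st$disability_weight,
       dur = st$duration, terminal = which(st$is_terminal),
       entry = idx(model$entry_stage), edges = edges,
       annual = annual, immediate = immediate, transient = transient,
       max_age = model$max_age)
}

#' Stochastic individual-based disease progression
#'
#' Runs one or more incident cohorts through an outcome tree on a shared
#' annual clock until every individual has died, exited at the
#' `max_age` birthday cap, or recovered. Each yearly cycle proceeds in a
#' fixed order: (1) birthday-cap exits; (2) annual transitions from the most
#' downstream edge upward (death first, so nobody makes two annual moves in
#' one year), each edge's count constrained by
#' [expected_transition_count()] on its current occupancy and its
#' transitioners chosen by frailty-weighted (mode `"frailty"`) or equal-weight
#' (mode `"uniform"`) sampling without replacement; (3) immediate transitions
#' cascading downstream for this year's stage entrants; (4) ageing by one
#' year. Individuals left in a stage whose only exits are immediate recover
#' at the end of their entry cycle.
#'
#' With `pooling = "per_cohort"` (default) expected counts and weighted
#' selection are computed within each cohort; with `"pooled"` all cohorts
#' present in a stage compete in one weighted selection, which is how
#' individual heterogeneity in an age-independent frailty distribution comes
#' to matter for a single cohort's burden (see the package vignette).
#'
#' @param model a [disease_model()].
#' @param cohorts a `cohort` data frame, or a list of them entering in
#'   consecutive years (first = simulation year 1 cohort, the one flagged for
#'   burden accounting).
#' @param mode `"uniform"` (no-heterogeneity selection) or `"frailty"`.
#' @param pooling `"per_cohort"` or `"pooled"` transition accounting.
#' @param horizon maximum number of yearly cycles before an unresolved-run
#'   error.
#' @param seed optional integer seed.
#' @param resolve `"all"` iterates until every individual in every cohort is
#'   resolved; `"burden_cohort"` stops as soon as the year-1 cohort is
#'   resolved (later cohorts only influence the pooled selection while the
#'   year-1 cohort is still in the model, so burden results are unchanged
#'   and long multi-cohort runs finish roughly twice as fast).
#' @return an object of class `progression_run` with per-individual history
#'   (stage entry/exit steps, death / cap-exit / recovery years), ages,
#'   frailty values, cohort membership and the `burden_cohort` flag.
#' @export
run_stochastic <- function(model, cohorts, mode = c("uniform", "frailty"),
                           pooling = c("per_cohort", "pooled"),
                           horizon = 200L, seed = NULL,
                           resolve = c("all", "burden_cohort")) {
  mode <- match.arg(mode)
  pooling <- match.arg(pooling)
  resolve <- match.arg(resolve)
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(cohorts)) cohorts <- list(cohorts)
  cm <- compile_model(model)
  ns <- cm$ns

  n_c <- vapply(cohorts, nrow, 0L)
  n_tot <- sum(n_c)
  coh <- rep.int(seq_along(cohorts), n_c)
  entry_year <- coh - 1L
  age0 <- unlist(lapply(cohorts, `[[`, "age_at_infection"), use.names = FALSE)
  frl <- unlist(lapply(cohorts, `[[`, "frailty"), use.names = FALSE)
  if (mode == "frailty" && anyNA(frl))
    stop("frailty mode requires frailty values for every individual")
  if (any(age0 < 0 | age0 >= cm$max_age))
    stop("ages at infection must lie in [0, max_age)")

  E <- matrix(NA_integer_, n_tot, ns)     # stage entry step
  X <- matrix(NA_integer_, n_tot, ns)     # stage exit step
  entry_cur <- rep(NA_integer_, n_tot)
  death_step <- cap_step <- recover_step <- rep(NA_integer_, n_tot)
  pool <- rep(list(integer(0)), ns)

  n_groups <- if (pooling == "pooled") 1L else length(cohorts)
  carries <- lapply(cm$edges, function(e)
    matrix(0, n_groups, if (e$banded) length(e$p) else 1L))
  shortfall <- 0L
  n_open_burden <- n_c[1L]

  run_edge <- function(ei, elig, t) {
    e <- cm$edges[[ei]]
    if (!length(elig)) return(invisible())
    weighted <- e$fw && mode == "frailty"
    if (pooling == "pooled" && !e$banded) {      # fast path: one cell
      ec <- expected_transition_count(length(elig), e$p, carries[[ei]][1L, 1L])
      carries[[ei]][1L, 1L] <<- ec$carry
      sel_all <- select_transitioners(elig, ec$n,
                                      if (weighted) frl[elig])
    } else {
      grp <- if (pooling == "pooled") rep.int(1L, length(elig)) else coh[elig]
      band <- if (e$banded)
        findInterval(floor(age0[elig] + (t - entry_year[elig])), e$band_breaks,
                     rightmost.closed = TRUE)
      else rep.int(1L, length(elig))
      sel_all <- integer(0)
      for (g in unique(grp)) {
        for (b in unique(band[grp == g])) {
          ids <- elig[grp == g & band == b]
          ec <- expected_transition_count(length(ids), e$p[b],
                                          carries[[ei]][g, b])
          carries[[ei]][g, b] <<- ec$carry
          if (ec$n > length(ids)) { # cannot happen with p <= 1, kept defensive
            shortfall <<- shortfall + (ec$n - length(ids))
            ec$n <- length(ids)
          }
          w <- if (e$fw && mode == "frailty") frl[ids] else NULL
          sel_all <- c(sel_all, select_transitioners(ids, ec$n, w))
        }
      }
    }
    if (length(sel_all)) {
      X[sel_all, e$from] <<- t
      E[sel_all, e$to] <<- t
      entry_cur[sel_all] <<- t
      keep <- pool[[e$from]]
      pool[[e$from]] <<- keep[is.na(match(keep, sel_all))]
      if (e$to == cm$terminal) {
        death_step[sel_all] <<- t
        n_open_burden <<- n_open_burden - sum(coh[sel_all] == 1L)
      } else pool[[e$to]] <<- c(pool[[e$to]], sel_all)
    }
    invisible()
  }

  last_entry <- length(cohorts) - 1L
  for (t in 0:horizon) {
    if (t <= last_entry) {
      ids <- which(entry_year == t)
      E[ids, cm$entry] <- t
      entry_cur[ids] <- t
      pool[[cm$entry]] <- c(pool[[cm$entry]], ids)
    } else if (all(lengths(pool) == 0L)) break

    # 1. birthday-cap exits
    for (s in seq_len(ns)) {
      ids <- pool[[s]]
      if (!length(ids)) next
      capped <- ids[age0[ids] + (t - entry_year[ids]) >= cm$max_age]
      if (length(capped)) {
        cap_step[capped] <- t
        X[capped, s] <- t
        pool[[s]] <- ids[is.na(match(ids, capped))]
        n_open_burden <- n_open_burden - sum(coh[capped] == 1L)
      }
    }
    # 2. annual transitions, downstream first
    for (ei in cm$annual) {
      ids <- pool[[cm$edges[[ei]]$from]]
      run_edge(ei, ids[entry_cur[ids] < t], t)
    }
    # 3. immediate transitions, cascading downstream
    for (ei in cm$immediate) {
      ids <- pool[[cm$edges[[ei]]$from]]
      run_edge(ei, ids[entry_cur[ids] == t], t)
    }
    # 4. recovery from stages with no annual exits
    for (s in cm$transient) {
      ids <- pool[[s]]
      if (!length(ids)) next
      recover_step[ids] <- t
      X[ids, s] <- t
      pool[[s]] <- integer(0)
      n_open_burden <- n_open_burden - sum(coh[ids] == 1L)
    }
    if (resolve == "burden_cohort" && n_open_burden == 0L)
      break
  }
  if (resolve == "all" && any(lengths(pool) > 0L))
    stop("horizon of ", horizon, " years too short: ",
         sum(lengths(pool)), " individuals unresolved")
  if (shortfall > 0L)
    warning("eligible pool fell short of the expected transition count ",
            "for ", shortfall, " transition(s)")

  structure(list(
    model_id = model$model_id, mode = mode, pooling = pooling,
    stage_id = cm$stage_id, n = n_tot, cohort = coh,
    entry_year = entry_year, age_at_infection = age0, frailty = frl,
    entry_step = E, exit_step = X, death_step = death_step,
    cap_step = cap_step, recover_step = recover_step,
    burden_cohort = 1L), class = "progression_run")
}

#' Deterministic expected-count disease progression
#'
#' Propagates real-valued expected occupancy for a single cohort through the
#' outcome tree year by year: immediate transitions resolve on stage entry
#' (cascading within the cycle), annual transitions remove `p * occupancy`
#' per year, and all remaining mass exits at the `max_age` birthday. This is
#' the analytic expectation underlying the no-heterogeneity variant; the
#' uniform stochastic mode reproduces its yearly transition counts up to the
#' floor-with-carry integerisation.
#'
#' @param model a [disease_model()].
#' @param ages ages at infection (one entry per individual; expected results
#'   are per-individual probability masses summed over the cohort).
#' @param life_table a [make_surrogate_life_table()]-style life table used
#'   for expected YLL.
#' @param horizon maximum number of yearly cycles.
#' @return an object of class `deterministic_run`: expected `yld`, `yll`,
#'   `daly`, expected entries per stage (`stage_entries`), per-stage YLD,
#'   expected deaths with their expected YLL by individual, and expected
#'   person-years per while-occupied stage.
#' @export
run_deterministic <- function(model, ages, life_table, horizon = 200L) {
  cm <- compile_model(model)
  ns <- cm$ns
  n <- length(ages)
  if (any(ages < 0 | ages >= cm$max_age))
    stop("ages at infection must lie in [0, max_age)")

  M_set <- matrix(0, n, ns)    # mass settled in a stage before this cycle
  M_new <- matrix(0, n, ns)    # mass that arrived this cycle
  py <- matrix(0, n, ns)       # person-years in while-occupied stages
  yld_fixed <- numeric(n)      # fixed-duration stage YLD, booked on entry
  yld_fixed_stage <- numeric(ns)
  yll <- numeric(n)
  death_mass <- numeric(n)
  entries <- numeric(ns)
  active <- rep(TRUE, n)
  fixed <- !is.na(cm$dur)

  book_entry <- function(stage, mass, t) {
    entries[stage] <<- entries[stage] + sum(mass)
    if (fixed[stage] && cm$dw[stage] > 0) {
      dur <- pmax(pmin(cm$dur[stage], cm$max_age - (ages + t)), 0)
      contrib <- mass * cm$dw[stage] * dur
      yld_fixed <<- yld_fixed + contrib
      yld_fixed_stage[stage] <<- yld_fixed_stage[stage] + sum(contrib)
    }
  }
  edge_p <- function(e, t) {
    if (!e$banded) return(e$p)
    e$p[findInterval(floor(ages + t), e$band_breaks, rightmost.closed = TRUE)]
  }

  for (t in 0:horizon) {
    if (t == 0L) {
      M_new[, cm$entry] <- 1
      book_entry(cm$entry, rep(1, n), 0)
    } else if (!any(M_set > 1e-15) && !any(M_new > 1e-15)) break
    # person-years accrue for settled mass, then birthday caps remove it
    py <- py + M_set
    capped <- active & (ages + t >= cm$max_age)
    if (any(capped)) {
      M_set[capped, ] <- 0
      M_new[capped, ] <- 0
      active[capped] <- FALSE
    }
    for (ei in cm$annual) {
      e <- cm$edges[[ei]]
      flow <- M_set[, e$from] * edge_p(e, t)
      M_set[, e$from] <- M_set[, e$from] - flow
      M_new[, e$to] <- M_new[, e$to] + flow
      book_entry(e$to, flow, t)
      if (e$to == cm$terminal) {
        yll <- yll + flow * residual_life_expectancy(life_table, ages + t)
        death_mass <- death_mass + flow
        M_new[, e$to] <- 0
      }
    }
    for (ei in cm$immediate) {
      e <- cm$edges[[ei]]
      flow <- M_new[, e$from] * edge_p(e, t)
      M_new[, e$from] <- M_new[, e$from] - flow
      M_new[, e$to] <- M_new[, e$to] + flow
      book_entry(e$to, flow, t)
      if (e$to == cm$terminal) {
        yll <- yll + flow * residual_life_expectancy(life_table, ages + t)
        death_mass <- death_mass + flow
        M_new[, e$to] <- 0
      }
    }
    M_new[, cm$transient] <- 0          # recovery
    M_set <- M_set + M_new
    M_new[] <- 0
  }
  if (any(M_set > 1e-12))
    stop("horizon of ", horizon, " years too short to resolve the cohort")

  yld_occ <- sweep(py, 2L, cm$dw, `*`)
  yld_occ[, fixed] <- 0
  yld_i <- yld_fixed + rowSums(yld_occ)
  per_stage_yld <- ifelse(fixed, yld_fixed_stage, cm$dw * colSums(py))
  names(per_stage_yld) <- cm$stage_id
  names(entries) <- cm$stage_id

  structure(list(
    model_id = model$model_id, mode = "deterministic", n = n,
    yld = sum(yld_i), yll = sum(yll), daly = sum(yld_i) + sum(yll),
    yld_i = yld_i, yll_i = yll, death_prob = death_mass,
    expected_deaths = sum(death_mass), stage_entries = entries,
    per_stage_yld = per_stage_yld,
    person_years = colSums(py), stage_id = cm$stage_id),
    class = "deterministic_run")
}

#' Per-individual event history of a stochastic run
#'
#' @param run a `progression_run`.
#' @return data frame with one row per stage occupancy: `id`, `cohort_year`,
#'   `stage`, `entry_year`, `exit_year`, `age_at_entry`, `frailty`.
#' @export
run_events <- function(run) {
  stopifnot(inherits(run, "progression_run"))
  out <- do.call(rbind, lapply(seq_along(run$stage_id), function(s) {
    i <- which(!is.na(run$entry_step[, s]))
    if (!length(i)) return(NULL)
    data.frame(id = i, cohort_year = run$entry_year[i] + 1L,
               stage = run$stage_id[s],
               entry_year = run$entry_step[i, s],
               exit_year = run$exit_step[i, s],
               age_at_entry = run$age_at_infection[i] +
                 (run$entry_step[i, s] - run$entry_year[i]),
               frailty = run$frailty[i])
  }))
  out[order(out$id, out$entry_year), ]
}

#' Per-year stage occupancy of a stochastic run
#'
#' @param run a `progression_run`.
#' @return data frame `year`, `stage`, `count` (individuals occupying the
#'   stage at any point during that yearly cycle).
#' @export
run_occupancy <- function(run) {
  stopifnot(inherits(run, "progression_run"))
  years <- 0:max(run$exit_step, run$entry_step, na.rm = TRUE)
  out <- expand.grid(year = years, stage = run$stage_id,
                     stringsAsFactors = FALSE)
  out$count <- mapply(function(y, s) {
    si <- match(s, run$stage_id)
    sum(!is.na(run$entry_step[, si]) & run$entry_step[, si] <= y &
          (is.na(run$exit_step[, si]) | run$exit_step[, si] >= y))
  }, out$year, out$stage)
  out
}

#' @export
print.progression_run <- function(x, ...) {
  cat("Individual-based progression run (", x$mode, ", ", x$pooling,
      ") of model '", x$model_id, "'\n", sep = "")
  cat("  individuals:", x$n, "in", max(x$entry_year) + 1L, "cohort(s)\n")
  cat("  deaths:", sum(!is.na(x$death_step)),
      " cap exits:", sum(!is.na(x$cap_step)),
      " recoveries:", sum(!is.na(x$recover_step)), "\n")
  invisible(x)
}

#' @export
print.deterministic_run <- function(x, ...) {
  cat("Deterministic expected-count run of model '", x$model_id, "'\n",
      sep = "")
  cat(sprintf("  YLD %.1f  YLL %.1f  DALY %.1f  expected deaths %.1f\n",
              x$yld, x$yll, x$daly, x$expected_deaths))
  invisible(x)
}
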