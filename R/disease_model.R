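#' Outcome-tree disease models
#'
#' A disease model is an acyclic "outcome tree": health stages (each with a
#' disability weight and either a fixed duration in years or a
#' while-occupied duration that emerges from the simulation) connected by
#' transitions carrying an immediate or annual probability, optionally
#' age-banded, and a flag saying whether individual frailty weights who is
#' selected to transition.
#'
#' @param model_id character label.
#' @param stages data frame with columns `stage_id`, `disability_weight`,
#'   `duration` (years for fixed-duration stages, `NA` for while-occupied
#'   stages), `is_terminal`.
#' @param transitions list of transitions as returned by [transition()].
#' @param entry_stage stage id where incident cases enter.
#' @param max_age all-cause exit age in years; individuals leave the model at
#'   this birthday with stage durations truncated.
#' @return an object of class `disease_model`.
#' @seealso [builtin_model_x1()], [builtin_model_x2()], [validate_disease_model()]
#' @export
disease_model <- function(model_id, stages, transitions, entry_stage,
                          max_age = 86) {
  m <- structure(
    list(model_id = model_id, stages = stages, transitions = transitions,
         entry_stage = entry_stage, max_age = max_age),
    class = "disease_model")
  validate_disease_model(m)
  m
}

#' Define one stage of an outcome tree
#'
#' @param stage_id symbolic stage name.
#' @param disability_weight severity weight in `[0, 1]`.
#' @param duration fixed stage duration in years, or `NA` for stages whose
#'   duration is however long the simulation keeps the individual there.
#' @param is_terminal `TRUE` for the death stage.
#' @return one-row data frame.
#' @export
stage_params <- function(stage_id, disability_weight = 0, duration = NA_real_,
                         is_terminal = FALSE) {
  data.frame(stage_id = stage_id, disability_weight = disability_weight,
             duration = duration, is_terminal = is_terminal,
             stringsAsFactors = FALSE)
}

#' Define a transition between two stages
#'
#' @param from,to stage ids.
#' @param probability either a single probability in `[0, 1]`, or a data frame
#'   with columns `min_age`, `max_age`, `p` giving age-banded probabilities on
#'   half-open integer-year intervals `[min_age, max_age)` that partition
#'   `[0, max_age_of_model)`.
#' @param timing `"immediate"` (resolves in the same yearly cycle as entry
#'   into `from`) or `"annual"` (evaluated once per simulated year).
#' @param frailty_weighted should individual frailty values weight who is
#'   selected to make this transition in the heterogeneity variant?
#' @return a `transition` list.
#' @export
transition <- function(from, to, probability, timing = c("annual", "immediate"),
                       frailty_weighted = FALSE) {
  timing <- match.arg(timing)
  structure(list(from = from, to = to, probability = probability,
                 timing = timing, frailty_weighted = frailty_weighted),
            class = "dalysim_transition")
}

transition_is_banded <- function(tr) is.data.frame(tr$probability)

#' Validate a disease model
#'
#' Checks the outcome-tree invariants: disability weights in `[0, 1]`;
#' nonnegative fixed durations; exactly one terminal death stage; transition
#' probabilities in `[0, 1]`; age bands that partition `[0, max_age)` without
#' overlap; an acyclic transition graph reachable from the entry stage; and a
#' total annual exit probability of at most 1 per stage.
#'
#' @param model a [disease_model()].
#' @return the model, invisibly; errors name the offending field.
#' @export
validate_disease_model <- function(model) {
  st <- model$stages
  if (!all(c("stage_id", "disability_weight", "duration", "is_terminal")
           %in% names(st)))
    stop("stages must have stage_id, disability_weight, duration, is_terminal")
  if (anyDuplicated(st$stage_id))
    stop("duplicate stage_id in stages")
  if (any(st$disability_weight < 0 | st$disability_weight > 1))
    stop("disability_weight outside [0, 1] for stage(s): ",
         paste(st$stage_id[st$disability_weight < 0 | st$disability_weight > 1],
               collapse = ", "))
  fixed <- !is.na(st$duration)
  if (any(st$duration[fixed] < 0))
    stop("negative fixed duration for stage(s): ",
         paste(st$stage_id[fixed & st$duration < 0], collapse = ", "))
  if (sum(st$is_terminal) != 1L)
    stop("model must have exactly one terminal (death) stage, found ",
         sum(st$is_terminal))
  if (!model$entry_stage %in% st$stage_id)
    stop("entry_stage '", model$entry_stage, "' is not a stage")
  if (!is.numeric(model$max_age) || model$max_age <= 0)
    stop("max_age must be a positive number of years")

  idx <- function(id) match(id, st$stage_id)
  for (tr in model$transitions) {
    lab <- paste0(tr$from, " -> ", tr$to)
    if (is.na(idx(tr$from)) || is.na(idx(tr$to)))
      stop("transition ", lab, " references an unknown stage")
    if (transition_is_banded(tr)) {
      b <- tr$probability
      if (!all(c("min_age", "max_age", "p") %in% names(b)))
        stop("age-banded probability of ", lab,
             " needs columns min_age, max_age, p")
      b <- b[order(b$min_age), , drop = FALSE]
      if (any(b$p < 0 | b$p > 1))
        stop("probability outside [0, 1] in transition ", lab)
      if (b$min_age[1L] != 0 || utils::tail(b$max_age, 1L) < model$max_age)
        stop("age bands of ", lab, " must cover [0, ", model$max_age, ")")
      if (nrow(b) > 1L && any(b$min_age[-1L] != b$max_age[-nrow(b)]))
        stop("age bands of ", lab, " overlap or leave gaps")
    } else {
      if (!is.numeric(tr$probability) || length(tr$probability) != 1L ||
          tr$probability < 0 || tr$probability > 1)
        stop("probability outside [0, 1] in transition ", lab)
    }
    if (st$is_terminal[idx(tr$from)])
      stop("transition ", lab, " leaves the terminal stage")
  }

  from_i <- vapply(model$transitions, function(tr) idx(tr$from), 0L)
  to_i <- vapply(model$transitions, function(tr) idx(tr$to), 0L)
  if (is.null(topo_order(nrow(st), from_i, to_i)))
    stop("transition graph has a cycle; outcome trees must be acyclic")

  # total annual exit probability <= 1 for every stage, at every age
  for (s in seq_len(nrow(st))) {
    ann <- model$transitions[from_i == s &
      vapply(model$transitions, function(tr) tr$timing == "annual", NA)]
    if (length(ann)) {
      tot <- sum(vapply(ann, function(tr)
        if (transition_is_banded(tr)) max(tr$probability$p) else tr$probability,
        0))
      if (tot > 1 + 1e-12)
        stop("total annual exit probability ", tot, " > 1 for stage ",
             st$stage_id[s])
    }
  }
  invisible(model)
}

#' Built-in disease model X1 (short natural history)
#'
#' Three health outcomes: acute infection, chronic infection, death. Acutely
#' infected individuals develop chronic infection with an age-independent
#' probability of 20%, resolved immediately (within the infection year) and
#' frailty-weighted in the heterogeneity variant. Death following chronic
#' infection is also immediate, with age-banded case-fatality ratios of 5, 1,
#' 2 and 15% for ages <15, 15-44, 45-64 and 65+, and is not frailty-weighted
#' (heterogeneity acts on who becomes chronic, which with age-increasing
#' frailty shifts the chronic age mix).
#'
#' Disability weights and durations are calibration knobs, not authoritative
#' values: acute 0.10 for 0.08 years, chronic 0.20 for 1.0 year by default.
#' Absolute YLD/DALY outputs depend on them; comparisons between variants are
#' the supported use.
#'
#' @param p_acute_chronic acute-to-chronic probability (default 0.20).
#' @param cfr named or ordered numeric vector of 4 case-fatality ratios for
#'   bands `[0,15)`, `[15,45)`, `[45,65)`, `[65,86)`.
#' @param dw_acute,dd_acute,dw_chronic,dd_chronic disability weights/durations.
#' @return a `disease_model`.
#' @export
builtin_model_x1 <- function(p_acute_chronic = 0.20,
                             cfr = c(0.05, 0.01, 0.02, 0.15),
                             dw_acute = 0.10, dd_acute = 0.08,
                             dw_chronic = 0.20, dd_chronic = 1.0) {
  stopifnot(length(cfr) == 4L)
  stages <- rbind(
    stage_params("acute", dw_acute, dd_acute),
    stage_params("chronic", dw_chronic, dd_chronic),
    stage_params("death", 0, 0, is_terminal = TRUE))
  bands <- data.frame(min_age = c(0, 15, 45, 65),
                      max_age = c(15, 45, 65, 86),
                      p = as.numeric(cfr))
  disease_model(
    "x1", stages,
    transitions = list(
      transition("acute", "chronic", p_acute_chronic, timing = "immediate",
                 frailty_weighted = TRUE),
      transition("chronic", "death", bands, timing = "immediate",
                 frailty_weighted = FALSE)),
    entry_stage = "acute", max_age = 86)
}

#' Built-in disease model X2 (long natural history)
#'
#' Four health outcomes: acute infection, chronic infection, severe sequela,
#' death. Acute-to-chronic is immediate with probability 20%; chronic to
#' severe sequela proceeds at 2% per year and sequela to death at 4% per
#' year, both age-independent. All three transitions are frailty-weighted in
#' the heterogeneity variant. Individuals exit the model at their 86th
#' birthday with stage durations truncated.
#'
#' Default disability weights/durations (calibration knobs): acute 0.10 for
#' 0.25 years; chronic 0.15 and severe sequela 0.40 per year occupied.
#'
#' @param p_acute_chronic acute-to-chronic probability (default 0.20).
#' @param p_chronic_sequela annual chronic-to-sequela probability (default 0.02).
#' @param p_sequela_death annual sequela-to-death probability (default 0.04).
#' @param dw_acute,dd_acute,dw_chronic,dw_sequela disability parameters.
#' @return a `disease_model`.
#' @export
builtin_model_x2 <- function(p_acute_chronic = 0.20,
                             p_chronic_sequela = 0.02,
                             p_sequela_death = 0.04,
                             dw_acute = 0.10, dd_acute = 0.25,
                             dw_chronic = 0.15, dw_sequela = 0.40) {
  stages <- rbind(
    stage_params("acute", dw_acute, dd_acute),
    stage_params("chronic", dw_chronic, NA_real_),
    stage_params("sequela", dw_sequela, NA_real_),
    stage_params("death", 0, 0, is_terminal = TRUE))
  disease_model(
    "x2", stages,
    transitions = list(
      transition("acute", "chronic", p_acute_chronic, timing = "immediate",
                 frailty_weighted = TRUE),
      transition("chronic", "sequela", p_chronic_sequela, timing = "annual",
                 frailty_weighted = TRUE),
      transition("sequela", "death", p_sequela_death, timing = "annual",
                 frailty_weighted = TRUE)),
    entry_stage = "acute", max_age = 86)
}

#' Look up a transition probability at a given age
#'
#' @param model a `disease_model`.
#' @param from,to stage ids identifying the transition.
#' @param age age in years (only used for age-banded transitions).
#' @return the probability.
#' @export
transition_probability <- function(model, from, to, age = NULL) {
  for (tr in model$transitions) {
    if (tr$from == from && tr$to == to) {
      if (!transition_is_banded(tr)) return(tr$probability)
      if (is.null(age)) stop("transition ", from, " -> ", to,
                             " is age-banded; supply age")
      b <- tr$probability
      hit <- which(b$min_age <= age & age < b$max_age)
      if (!length(hit)) stop("age ", age, " outside the band partition")
      return(b$p[hit])
    }
  }
  stop("no transition ", from, " -> ", to, " in model ", model$model_id)
}

#' @export
print.disease_model <- function(x, ...) {
  cat("Outcome-tree disease model '", x$model_id, "' (exit at age ",
      x$max_age, ")\n", sep = "")
  cat("Stages:\n")
  print(x$stages, row.names = FALSE)
  cat("Transitions:\n")
  for (tr in x$transitions) {
    p <- if (transition_is_banded(tr))
      paste0("age-banded {",
             paste(sprintf("[%g,%g): %g", tr$probability$min_age,
                           tr$probability$max_age, tr$probability$p),
                   collapse = ", "), "}")
    else format(tr$probability)
    cat(sprintf("  %s -> %s  p = %s (%s%s)\n", tr$from, tr$to, p, tr$timing,
                if (tr$frailty_weighted) ", frailty-weighted" else ""))
  }
  invisible(x)
}
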