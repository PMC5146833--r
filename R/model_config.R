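#' Write a disease model to a YAML or JSON configuration file
#'
#' The schema mirrors the model structure: `model_id`, `entry_stage`,
#' `max_age`, `stages` (list of `{id, disability_weight, duration |
#' "while_occupied", terminal}`) and `transitions` (list of `{from, to,
#' timing, frailty_weighted, probability}`, where `probability` is a number
#' or a list of `{min_age, max_age, p}` bands).
#'
#' @param model a [disease_model()].
#' @param path output file; the format follows the extension (`.yaml`/`.yml`
#'   or `.json`).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  st <- model$stages
  doc <- list(
    model_id = model$model_id,
    entry_stage = model$entry_stage,
    max_age = model$max_age,
    stages = lapply(seq_len(nrow(st)), function(i) list(
      id = st$stage_id[i],
      disability_weight = st$disability_weight[i],
      duration = if (is.na(st$duration[i])) "while_occupied" else st$duration[i],
      terminal = st$is_terminal[i])),
    transitions = lapply(model$transitions, function(tr) list(
      from = tr$from, to = tr$to, timing = tr$timing,
      frailty_weighted = tr$frailty_weighted,
      probability = if (transition_is_banded(tr))
        lapply(seq_len(nrow(tr$probability)), function(j)
          as.list(tr$probability[j, c("min_age", "max_age", "p")]))
      else tr$probability)))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' Read and validate a disease model configuration
#'
#' Counterpart of [write_model_config()]; `read_model_config(write_model_config(m))`
#' reproduces `m`. The document is validated with
#' [validate_disease_model()], so schema violations (probabilities outside
#' `[0, 1]`, overlapping age bands, missing fields) raise errors naming the
#' offending field.
#'
#' @param path a YAML or JSON file following the documented schema.
#' @return a validated `disease_model`.
#' @export
read_model_config <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  for (field in c("model_id", "entry_stage", "stages", "transitions"))
    if (is.null(doc[[field]])) stop("config is missing field '", field, "'")

  stages <- do.call(rbind, lapply(doc$stages, function(s) {
    if (is.null(s$id)) stop("a stage entry is missing field 'id'")
    dur <- s$duration %||% NA_real_
    if (identical(dur, "while_occupied")) dur <- NA_real_
    stage_params(s$id,
                 disability_weight = s$disability_weight %||% 0,
                 duration = as.numeric(dur),
                 is_terminal = isTRUE(s$terminal))
  }))
  transitions <- lapply(doc$transitions, function(tr) {
    for (field in c("from", "to", "probability"))
      if (is.null(tr[[field]]))
        stop("a transition entry is missing field '", field, "'")
    p <- tr$probability
    if (is.list(p)) {
      p <- do.call(rbind, lapply(p, function(b)
        data.frame(min_age = as.numeric(b$min_age),
                   max_age = as.numeric(b$max_age),
                   p = as.numeric(b$p))))
    } else {
      p <- as.numeric(p)
    }
    transition(tr$from, tr$to, p, timing = tr$timing %||% "annual",
               frailty_weighted = isTRUE(tr$frailty_weighted))
  })
  disease_model(doc$model_id, stages, transitions, doc$entry_stage,
                max_age = doc$max_age %||% 86)
}
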