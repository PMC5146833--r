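# Independent oracles used across tests.

# Exact distribution over *sets* selected by successive
# probability-proportional-to-weight draws without replacement, by
# enumerating every ordered draw path. Returns a named vector of
# probabilities; names are sorted index sets like "1+3".
enumerate_wswor <- function(weights, n) {
  recurse <- function(remaining, chosen, prob) {
    if (length(chosen) == n) {
      key <- paste(sort(chosen), collapse = "+")
      out[[key]] <<- (out[[key]] %||% 0) + prob
      return(invisible())
    }
    tot <- sum(weights[remaining])
    for (i in remaining)
      recurse(setdiff(remaining, i), c(chosen, i), prob * weights[i] / tot)
  }
  out <- list()
  `%||%` <- function(a, b) if (is.null(a)) b else a
  recurse(seq_along(weights), integer(0), 1)
  unlist(out)
}

# Exact inclusion probability of each item under the same scheme.
enumerate_inclusion <- function(weights, n) {
  sets <- enumerate_wswor(weights, n)
  incl <- numeric(length(weights))
  for (key in names(sets)) {
    idx <- as.integer(strsplit(key, "+", fixed = TRUE)[[1]])
    incl[idx] <- incl[idx] + sets[[key]]
  }
  incl
}

# Tiny two-stage toy model: entry "sick" with an annual 50% frailty-weighted
# transition to death; used for exhaustive-history comparisons.
toy_model <- function(p = 0.5) {
  disease_model(
    "toy",
    stages = rbind(
      stage_params("sick", 0.1, NA_real_),
      stage_params("death", 0, 0, is_terminal = TRUE)),
    transitions = list(
      transition("sick", "death", p, timing = "annual",
                 frailty_weighted = TRUE)),
    entry_stage = "sick", max_age = 86)
}

toy_cohort <- function(ages, frailty) {
  data.frame(age_at_infection = ages, frailty = frailty)
}

sample_skewness <- function(x) {
  mean((x - mean(x))^3) / stats::sd(x)^3
}
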