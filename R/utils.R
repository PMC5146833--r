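#' Derive a child random seed from a master seed
#'
#' A documented splitting rule used everywhere the package needs several
#' independent, individually reproducible random streams (one per Monte-Carlo
#' replicate, one for cohort generation, ...). The rule is a fixed affine hash
#' modulo 2^31 - 1, so every derived seed is a valid positive R integer seed
#' and the mapping is stable across platforms.
#'
#' @param master integer master seed.
#' @param index nonnegative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), all(index >= 0))
  v <- (abs(as.numeric(master)) %% 2147483647) * 48271 +
    as.numeric(index) * 69621 + 1
  as.integer(v %% 2147483646) + 1L
}

# Topological order of stage indices for an acyclic transition graph.
# Returns NULL if the graph has a cycle. Kahn's algorithm on a handful of
# nodes; no graph dependency warranted at this size.
topo_order <- function(n_stages, from, to) {
  indeg <- integer(n_stages)
  for (t in to) indeg[t] <- indeg[t] + 1L
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    hit <- which(from == v)
    for (t in to[hit]) {
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) queue <- c(queue, t)
    }
  }
  if (length(out) < n_stages) NULL else out
}

# Quantile summary used for all replicate distributions: inclusive linear
# interpolation (stats::quantile type 7, the R default).
quantile_summary <- function(x) {
  q <- stats::quantile(x, probs = c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  c(q2.5 = q[1L], median = q[2L], q97.5 = q[3L])
}

#' Round a burden value for tabular reports
#'
#' Values of 10,000 years or more are rounded to the nearest 10 years,
#' smaller values to the nearest year. Raw values are always kept alongside;
#' this rounding only affects printed report tables.
#'
#' @param x numeric vector of burden values (years).
#' @return rounded numeric vector.
#' @export
report_round <- function(x) {
  ifelse(abs(x) >= 10000, round(x / 10) * 10, round(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
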