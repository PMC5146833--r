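#' Gamma parameters from mean and variance
#'
#' Moment inversion for the gamma distribution: `shape = mean^2 / variance`,
#' `scale = variance / mean`, so that `shape * scale = mean` and
#' `shape * scale^2 = variance`.
#'
#' @param mean,variance positive targets.
#' @return list with `shape` and `scale`.
#' @export
gamma_from_mean_variance <- function(mean, variance) {
  if (!is.numeric(mean) || mean <= 0) stop("mean must be > 0")
  if (!is.numeric(variance) || variance <= 0) stop("variance must be > 0")
  list(shape = mean^2 / variance, scale = variance / mean)
}

# 5-year frailty age groups: <1, 1-4, 5-9, ..., 80-84, 85+  (19 groups).
frailty_group_breaks <- c(0, 1, seq(5, 85, by = 5), Inf)

frailty_group_index <- function(ages) {
  findInterval(ages, frailty_group_breaks, rightmost.closed = FALSE)
}

new_frailty_spec <- function(kind, params) {
  structure(c(list(kind = kind), params), class = "frailty_spec")
}

#' Age-independent gamma frailty
#'
#' The default heterogeneity assumption for long natural history simulations:
#' every individual's frailty is drawn from one gamma distribution,
#' `Gamma(shape = 1, scale = 1)` by default (unity mean and variance).
#' Frailty is a dimensionless, nonnegative multiplier of an individual's
#' propensity to progress; it is assigned once and never changes.
#'
#' @param shape,scale gamma parameters (both > 0).
#' @return a `frailty_spec`.
#' @export
frailty_gamma <- function(shape = 1, scale = 1) {
  stopifnot(shape > 0, scale > 0)
  new_frailty_spec("gamma", list(shape = shape, scale = scale,
                                 mean = shape * scale,
                                 target_variance = shape * scale^2))
}

#' Age-dependent gamma frailty with exponentially increasing mean
#'
#' One gamma distribution per 5-year age group (<1, 1-4, 5-9, ..., 80-84,
#' 85+; group index g = 0..18). The shape parameter grows exponentially with
#' the group index, `shape_g = baseline_shape * exp(growth_rate * g)`, while
#' the scale is adjusted per group so the variance stays constant at
#' `variance`; the mean `sqrt(shape_g * variance)` therefore increases
#' strictly with age group whenever `growth_rate > 0`. An individual's group
#' is fixed at infection (frailty is assigned once, "at birth" semantics; no
#' re-draw on ageing).
#'
#' @param baseline_shape shape at group 0 (> 0).
#' @param growth_rate exponential growth per 5-year group; negative values
#'   are allowed for experimentation but flagged with a warning.
#' @param variance constant variance across groups (> 0).
#' @return a `frailty_spec`.
#' @export
frailty_age_dependent <- function(baseline_shape = 1, growth_rate = 0.25,
                                  variance = 1) {
  stopifnot(baseline_shape > 0, variance > 0)
  if (growth_rate < 0)
    warning("growth_rate < 0: mean frailty will decrease with age")
  g <- 0:18
  shape <- baseline_shape * exp(growth_rate * g)
  scale <- sqrt(variance / shape)
  new_frailty_spec("age_dependent_gamma", list(
    baseline_shape = baseline_shape, growth_rate = growth_rate,
    target_variance = variance, group_shape = shape, group_scale = scale,
    group_mean = shape * scale))
}

# Central moments of b - G truncated to [0, b], G ~ Gamma(shape, scale),
# via numerical integration of the truncated density.
reflected_gamma_moments <- function(shape, scale, b) {
  Fb <- stats::pgamma(b, shape, scale = scale)
  if (Fb < 1e-10) return(c(mean = NA_real_, var = NA_real_, skew = NA_real_))
  mom <- function(k, centre = 0)
    stats::integrate(function(g) (b - g - centre)^k *
                       stats::dgamma(g, shape, scale = scale),
                     0, b, rel.tol = 1e-10)$value / Fb
  m1 <- mom(1)
  v <- mom(2, m1)
  c(mean = m1, var = v, skew = mom(3, m1) / v^1.5)
}

#' Alternative frailty shapes for sensitivity analysis
#'
#' Two alternatives to the rightward-skewed gamma, with matched mean and
#' variance:
#'
#' * `left_skew`: the distribution of `b - G` with `G` gamma, truncated to
#'   `[0, b]` (few slow-progressors, many fast-progressors; negative
#'   skewness). The gamma parameters are calibrated numerically so that the
#'   *post-truncation* mean and variance hit the targets, and the calibrated
#'   skewness is checked to be negative. The upper bound `b` controls how
#'   long the left tail is; the default `mean + 2 * sd` keeps the bulk of
#'   the mass near the bound (bounds much larger than the mean make the
#'   truncated reflection lose its left skew, and are rejected).
#' * `symmetric`: a normal distribution truncated symmetrically to
#'   `[0, 2 * mean]` (equal, low numbers of slow- and fast-progressors), with
#'   the scale solved so the truncated variance hits the target. Feasible
#'   only for `variance < mean^2 / 3` (the uniform limit on that support).
#'
#' @param kind `"left_skew"` or `"symmetric"`.
#' @param mean,variance positive moment targets.
#' @param upper_bound for `left_skew`: finite support bound `b > mean`.
#' @return a `frailty_spec`.
#' @export
frailty_alternative <- function(kind = c("left_skew", "symmetric"),
                                mean = 1, variance = 1, upper_bound = NULL) {
  kind <- match.arg(kind)
  stopifnot(mean > 0, variance > 0)
  if (kind == "left_skew") {
    b <- upper_bound %||% (mean + 2 * sqrt(variance))
    if (!(b > mean)) stop("upper_bound must exceed the target mean")
    if (variance >= mean * (b - mean))
      stop("infeasible moment combination: variance too large for [0, b]")
    obj <- function(par) {
      mm <- reflected_gamma_moments(exp(par[1]), exp(par[2]), b)
      if (anyNA(mm)) return(1e6)
      (mm[["mean"]] - mean)^2 / mean^2 + (mm[["var"]] - variance)^2 / variance^2
    }
    g0 <- gamma_from_mean_variance(b - mean, variance)
    fit <- stats::optim(log(c(g0$shape, g0$scale)), obj,
                        control = list(maxit = 2000, reltol = 1e-14))
    if (fit$value > 1e-6)
      stop("infeasible moment combination for left_skew frailty")
    mm <- reflected_gamma_moments(exp(fit$par[1]), exp(fit$par[2]), b)
    if (mm[["skew"]] >= 0)
      stop("calibrated distribution is not left-skewed (skewness ",
           round(mm[["skew"]], 2), "); choose an upper_bound closer to ",
           "the mean")
    new_frailty_spec("left_skew", list(
      mean = mean, target_variance = variance, upper_bound = b,
      gamma_shape = exp(fit$par[1]), gamma_scale = exp(fit$par[2]),
      skewness = mm[["skew"]]))
  } else {
    if (variance >= mean^2 / 3)
      stop("infeasible moment combination: a symmetric distribution on ",
           "[0, 2*mean] has variance < mean^2 / 3")
    half <- mean
    trunc_var <- function(sigma) {
      a <- half / sigma
      z <- 2 * stats::pnorm(a) - 1
      sigma^2 * (1 - 2 * a * stats::dnorm(a) / z)
    }
    sigma <- stats::uniroot(function(s) trunc_var(s) - variance,
                            lower = 1e-6 * half, upper = 1e3 * half,
                            tol = 1e-12)$root
    new_frailty_spec("symmetric", list(
      mean = mean, target_variance = variance, sd = sigma, half_width = half))
  }
}

# Rejection sampler on a restricted support; vectorised with top-up redraws.
sample_truncated <- function(n, rdraw, keep) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rdraw(max(n - length(out), 16L) * 2L)
    out <- c(out, x[keep(x)])
  }
  out[seq_len(n)]
}

#' Sample individual frailty values
#'
#' Draws one nonnegative frailty value per individual from the distribution
#' given by `spec` (for the age-dependent spec, from the gamma of the
#' individual's 5-year age group at infection). Values are assigned once and
#' treated as immutable afterwards.
#'
#' @param spec a `frailty_spec`.
#' @param ages ages at infection in `[0, 86)` (continuous years allowed).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (so callers embedding this in a larger seeded simulation stay
#'   reproducible).
#' @return numeric vector of frailty values, one per age.
#' @export
sample_frailties <- function(spec, ages, seed = NULL) {
  stopifnot(inherits(spec, "frailty_spec"))
  if (length(ages) && (min(ages) < 0 || max(ages) >= 86))
    stop("ages must lie in [0, 86)")
  if (!is.null(seed)) set.seed(seed)
  n <- length(ages)
  switch(spec$kind,
    gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
    age_dependent_gamma = {
      g <- frailty_group_index(ages)
      stats::rgamma(n, shape = spec$group_shape[g], scale = spec$group_scale[g])
    },
    left_skew = {
      b <- spec$upper_bound
      g <- sample_truncated(n,
        function(m) stats::rgamma(m, shape = spec$gamma_shape,
                                  scale = spec$gamma_scale),
        function(x) x <= b)
      b - g
    },
    symmetric = sample_truncated(n,
      function(m) stats::rnorm(m, mean = spec$mean, sd = spec$sd),
      function(x) abs(x - spec$mean) <= spec$half_width),
    stop("unknown frailty spec kind: ", spec$kind))
}

#' Theoretical mean of a frailty spec
#'
#' For the age-dependent spec a vector over the 19 age groups; otherwise a
#' scalar.
#'
#' @param spec a `frailty_spec`.
#' @return numeric mean(s).
#' @export
frailty_mean <- function(spec) {
  switch(spec$kind,
    gamma = spec$mean,
    age_dependent_gamma = spec$group_mean,
    left_skew = spec$mean,
    symmetric = spec$mean)
}

#' @export
print.frailty_spec <- function(x, ...) {
  cat("Frailty spec:", x$kind, "\n")
  p <- x[setdiff(names(x), c("kind", "group_shape", "group_scale",
                             "group_mean"))]
  for (nm in names(p)) cat(" ", nm, "=", format(p[[nm]]), "\n")
  if (x$kind == "age_dependent_gamma")
    cat("  group means:", paste(round(x$group_mean, 3), collapse = " "), "\n")
  invisible(x)
}

#' Serialize / restore a frailty spec
#'
#' Converts a frailty spec to a plain list of its defining parameters (kind
#' plus constructor arguments), suitable for embedding in YAML/JSON
#' configuration, and back. Derived quantities (per-group shapes, calibrated
#' gamma parameters) are reconstructed by the constructors, so a restored
#' spec is identical to one built directly.
#'
#' @param spec a `frailty_spec`.
#' @param config a list as produced by `frailty_spec_to_list()` (or read
#'   from YAML/JSON).
#' @return a list (`frailty_spec_to_list`) or a `frailty_spec`
#'   (`frailty_spec_from_list`).
#' @export
frailty_spec_to_list <- function(spec) {
  stopifnot(inherits(spec, "frailty_spec"))
  switch(spec$kind,
    gamma = list(kind = "gamma", shape = spec$shape, scale = spec$scale),
    age_dependent_gamma = list(
      kind = "age_dependent_gamma", baseline_shape = spec$baseline_shape,
      growth_rate = spec$growth_rate, variance = spec$target_variance),
    left_skew = list(kind = "left_skew", mean = spec$mean,
                     variance = spec$target_variance,
                     upper_bound = spec$upper_bound),
    symmetric = list(kind = "symmetric", mean = spec$mean,
                     variance = spec$target_variance))
}

#' @rdname frailty_spec_to_list
#' @export
frailty_spec_from_list <- function(config) {
  if (is.null(config$kind)) stop("frailty config is missing field 'kind'")
  switch(config$kind,
    gamma = frailty_gamma(config$shape %||% 1, config$scale %||% 1),
    age_dependent_gamma = frailty_age_dependent(
      config$baseline_shape %||% 1, config$growth_rate %||% 0.25,
      config$variance %||% 1),
    left_skew = frailty_alternative("left_skew", config$mean %||% 1,
                                    config$variance %||% 0.25,
                                    config$upper_bound),
    symmetric = frailty_alternative("symmetric", config$mean %||% 1,
                                    config$variance %||% 0.25),
    stop("unknown frailty kind '", config$kind, "'"))
}
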