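#' Cumulative sampling intensity of the accumulator process
#'
#' Expected number of relevant events sampled by age `t` under the power-law
#' rate model, `Lambda(t) = delta * t^D`. The instantaneous sampling rate is
#' `lambda(t) = delta * D * t^(D-1)`: constant when `D = 1`, accelerating for
#' `D > 1`, decelerating for `D < 1`.
#'
#' @param params A [learning_params()] object.
#' @param t Age in months, `t >= 0`; vectorized.
#' @return Expected event count(s), `>= 0`.
#' @export
cumulative_intensity <- function(params, t) {
  stopifnot(inherits(params, "learning_params"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be finite and >= 0", call. = FALSE)
  }
  params$delta * t^params$D
}

#' Distribution functions of the age-of-acquisition models
#'
#' @description
#' `aoa_cdf()` gives the probability that a child has acquired the word by
#' age `t`; `aoa_pdf()` the density of acquisition ages; `aoa_hazard()` the
#' instantaneous acquisition rate among children who have not yet acquired
#' the word, `f(t) / (1 - F(t))`; `aoa_mean()` the expected acquisition age;
#' and `aoa_quantile()` the age by which a fraction `q` of children have
#' acquired the word.
#'
#' For accumulator models the acquisition age is the time of the N-th event
#' of a process with cumulative intensity `Lambda(t) = delta * t^D`, so
#' `F(t) = P(N, delta * t^D)` (regularized lower incomplete gamma function),
#' with density `f(t) = D * delta^N * t^(N*D - 1) * exp(-delta * t^D) / Gamma(N)`
#' and mean `delta^(-1/D) * Gamma(N + 1/D) / Gamma(N)`. Special cases:
#' `D = 1` is the gamma distribution, `N = 1` the Weibull, `N = D = 1` the
#' exponential. The logistic model has `F(t) = plogis(slope * t - intercept)`
#' and mean `intercept / slope`.
#'
#' @param params A [learning_params()] or [logistic_params()] object.
#' @param t Age in months (vectorized). Accumulator kinds require `t >= 0`
#'   for the CDF and `t > 0` for the density and hazard; the logistic model
#'   accepts any real `t`.
#' @param q Probability in (0, 1) (vectorized), for `aoa_quantile()`.
#' @return Numeric vector: probabilities for `aoa_cdf()`, densities
#'   (month^-1) for `aoa_pdf()`, rates (month^-1) for `aoa_hazard()`
#'   (`Inf` where the survival probability underflows to 0), months for
#'   `aoa_mean()` and `aoa_quantile()`.
#' @examples
#' gp <- learning_params(N = 5, D = 1, delta = 1)
#' aoa_cdf(gp, 5)       # 0.5595, the Poisson tail P(X >= 5), X ~ Pois(5)
#' aoa_mean(gp)         # 5 = N / delta
#' aoa_quantile(gp, 0.5)
#' @name aoa_distribution
NULL

#' @rdname aoa_distribution
#' @export
aoa_cdf <- function(params, t) UseMethod("aoa_cdf")

#' @export
aoa_cdf.learning_params <- function(params, t) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be finite and >= 0 for accumulator models", call. = FALSE)
  }
  stats::pgamma(params$delta * t^params$D, shape = params$N, rate = 1)
}

#' @export
aoa_cdf.logistic_params <- function(params, t) {
  stats::plogis(params$slope * t - params$intercept)
}

#' @rdname aoa_distribution
#' @export
aoa_pdf <- function(params, t) UseMethod("aoa_pdf")

#' @export
aoa_pdf.learning_params <- function(params, t) {
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("'t' must be finite and > 0 for accumulator densities", call. = FALSE)
  }
  # log-scale for stability at large N or extreme delta
  exp(log(params$D) + params$N * log(params$delta) +
        (params$N * params$D - 1) * log(t) -
        params$delta * t^params$D - lgamma(params$N))
}

#' @export
aoa_pdf.logistic_params <- function(params, t) {
  params$slope * stats::dlogis(params$slope * t - params$intercept)
}

#' @rdname aoa_distribution
#' @export
aoa_hazard <- function(params, t) UseMethod("aoa_hazard")

#' @export
aoa_hazard.learning_params <- function(params, t) {
  surv <- stats::pgamma(params$delta * t^params$D, shape = params$N,
                        rate = 1, lower.tail = FALSE)
  f <- aoa_pdf(params, t)
  ifelse(surv > 0, f / surv, Inf)
}

#' @export
aoa_hazard.logistic_params <- function(params, t) {
  # f/(1-F) simplifies to slope * F(t) for the logistic law
  params$slope * stats::plogis(params$slope * t - params$intercept)
}

#' @rdname aoa_distribution
#' @export
aoa_mean <- function(params) UseMethod("aoa_mean")

#' @export
aoa_mean.learning_params <- function(params) {
  exp(-log(params$delta) / params$D +
        lgamma(params$N + 1 / params$D) - lgamma(params$N))
}

#' @export
aoa_mean.logistic_params <- function(params) {
  params$intercept / params$slope
}

#' @rdname aoa_distribution
#' @export
aoa_quantile <- function(params, q) UseMethod("aoa_quantile")

check_prob_open <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1)) {
    stop("'q' must lie strictly in (0, 1)", call. = FALSE)
  }
}

#' @export
aoa_quantile.learning_params <- function(params, q) {
  check_prob_open(q)
  # invert F(t) = P(N, delta t^D) through the gamma quantile function
  (stats::qgamma(q, shape = params$N, rate = 1) / params$delta)^(1 / params$D)
}

#' @export
aoa_quantile.logistic_params <- function(params, q) {
  check_prob_open(q)
  (stats::qlogis(q) + params$intercept) / params$slope
}

#' Solve the base learning rate for a target mean acquisition age
#'
#' Inverts the closed-form mean of the accumulator model,
#' `E[T] = delta^(-1/D) * Gamma(N + 1/D) / Gamma(N)`, for `delta`. Useful for
#' constructing models with a prescribed mean (e.g. comparable families with
#' an identical mean) and for setting per-word rates in the synthetic norms
#' generator.
#'
#' @param N Accumulation, > 0.
#' @param D Change-of-rate exponent, > 0.
#' @param mean_aoa Target mean acquisition age in months, > 0.
#' @return The base rate `delta` (month^-D).
#' @examples
#' d <- rate_for_mean(N = 8, D = 0.5, mean_aoa = 5)
#' aoa_mean(learning_params(8, 0.5, d))  # 5
#' @export
rate_for_mean <- function(N, D, mean_aoa) {
  N <- check_scalar_pos(N, "N")
  D <- check_scalar_pos(D, "D")
  mean_aoa <- check_scalar_pos(mean_aoa, "mean_aoa")
  exp(D * (lgamma(N + 1 / D) - lgamma(N) - log(mean_aoa)))
}

#' Classify the shape of an accumulator model's hazard function
#'
#' The generalized-gamma hazard of the accumulator model takes one of a small
#' number of qualitative shapes, determined by the change-of-rate exponent
#' `D` and the product `N * D` (the power of `t` in the density):
#'
#' * `constant` — `N = D = 1` (exponential; hazard identically `delta`);
#' * `monotone_increasing` — `D >= 1` and `N * D >= 1` (not both 1); for
#'   `D = 1` the hazard rises towards the asymptote `delta`;
#' * `monotone_decreasing` — `D <= 1` and `N * D <= 1` (not both 1);
#' * `peaked` — `D < 1` with `N * D > 1`: the hazard rises to a unique
#'   interior maximum then falls (late learners acquire ever more slowly);
#' * `bathtub` — `D > 1` with `N * D < 1` (sub-unit accumulation with an
#'   accelerating rate): the hazard falls from infinity then rises. This
#'   regime is outside the four shapes the learning families are meant to
#'   express but is reachable for `N < 1`, so it is reported honestly rather
#'   than forced into another label.
#'
#' Boundary ties (e.g. `D = 1` exactly with `N > 1`) are resolved with a
#' relative tolerance of `tol` and classified as monotone.
#'
#' @param params A [learning_params()] object.
#' @param tol Tolerance on `D - 1` and `N * D - 1` for tie handling.
#' @return One of `"constant"`, `"monotone_increasing"`,
#'   `"monotone_decreasing"`, `"peaked"`, `"bathtub"`.
#' @examples
#' classify_hazard_shape(learning_params(8, 0.5, 1))  # "peaked"
#' classify_hazard_shape(learning_params(5, 1, 1))    # "monotone_increasing"
#' @export
classify_hazard_shape <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "learning_params"))
  D <- params$D
  ND <- params$N * params$D
  d_flat <- abs(D - 1) <= tol
  nd_flat <- abs(ND - 1) <= tol
  if (d_flat && nd_flat) return("constant")
  if (D >= 1 - tol && ND >= 1 - tol) return("monotone_increasing")
  if (D <= 1 + tol && ND <= 1 + tol) return("monotone_decreasing")
  if (D < 1) "peaked" else "bathtub"
}
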