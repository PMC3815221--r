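#' Model families for age-of-acquisition distributions
#'
#' Four model families are supported. Three arise from the accumulator
#' process (acquisition at the N-th sampled event under a power-law sampling
#' intensity): `"gamma"` (cumulative learning, constant rate, `D = 1`),
#' `"weibull"` (rate-change learning, one-shot accumulator, `N = 1`) and
#' `"weibull_gamma"` (cumulative-and-rate-change learning, the generalized
#' gamma family containing the other two). The fourth, `"logistic"`, is the
#' conventional S-curve alternative.
#'
#' @return Character vector of the four family names.
#' @export
model_kinds <- function() {
  c("gamma", "weibull", "weibull_gamma", "logistic")
}

#' Number of free parameters of a model family
#'
#' The Weibull-gamma family has three free parameters (N, D, delta); the
#' gamma (D fixed at 1), Weibull (N fixed at 1) and logistic families have
#' two each. Used for the BIC penalty.
#'
#' @param kind One of [model_kinds()].
#' @return Integer parameter count.
#' @export
n_params <- function(kind) {
  kind <- match.arg(kind, model_kinds())
  if (kind == "weibull_gamma") 3L else 2L
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single finite number > 0 (got %s)",
                 name, deparse(x)), call. = FALSE)
  }
  as.numeric(x)
}

#' Learning parameters of the accumulator model
#'
#' Bundles the triple that defines one accumulator model of word learning:
#' `N`, the accumulation (number of sampled relevant events needed for
#' acquisition; continuous, need not be an integer); `D`, the
#' change-of-learning-rate exponent (`D = 1` constant rate, `D > 1`
#' accelerating, `D < 1` decelerating); and `delta`, the base learning rate
#' (scale of the sampling intensity, units month^-D). The cumulative event
#' intensity is `Lambda(t) = delta * t^D`, so the age at the N-th event
#' follows a generalized gamma law.
#'
#' @param N Accumulation, real > 0.
#' @param D Change-of-rate exponent, real > 0.
#' @param delta Base learning rate, real > 0 (month^-D).
#' @return An object of class `learning_params`.
#' @examples
#' learning_params(N = 5, D = 1, delta = 0.25)  # gamma family, mean 20 months
#' @export
learning_params <- function(N, D, delta) {
  structure(
    list(N = check_scalar_pos(N, "N"),
         D = check_scalar_pos(D, "D"),
         delta = check_scalar_pos(delta, "delta")),
    class = "learning_params"
  )
}

#' Logistic model parameters
#'
#' The alternative logistic AoA model,
#' `F(t) = 1 / (1 + exp(-(slope * t - intercept)))`, with mean
#' `intercept / slope` months.
#'
#' @param slope Real > 0, month^-1.
#' @param intercept Real, dimensionless.
#' @return An object of class `logistic_params`.
#' @export
logistic_params <- function(slope, intercept) {
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept)) {
    stop("'intercept' must be a single finite number", call. = FALSE)
  }
  structure(
    list(slope = check_scalar_pos(slope, "slope"),
         intercept = as.numeric(intercept)),
    class = "logistic_params"
  )
}

#' Recover the model family implied by learning parameters
#'
#' `D = 1` implies the gamma (cumulative) family, `N = 1` the Weibull
#' (rate-change) family, otherwise Weibull-gamma. Exact exponential
#' parameters (`N = D = 1`) are reported as `"weibull"` (the exponential lies
#' in both subfamilies; Weibull is the conventional label for a 1-accumulator).
#'
#' @param params A `learning_params` or `logistic_params` object.
#' @param tol Relative tolerance for the `N = 1` / `D = 1` tests.
#' @return One of [model_kinds()].
#' @export
kind_of <- function(params, tol = 1e-9) {
  if (inherits(params, "logistic_params")) return("logistic")
  stopifnot(inherits(params, "learning_params"))
  if (abs(params$N - 1) <= tol) "weibull"
  else if (abs(params$D - 1) <= tol) "gamma"
  else "weibull_gamma"
}

#' @export
print.learning_params <- function(x, ...) {
  cat(sprintf("<learning_params> N = %g, D = %g, delta = %g  [%s family]\n",
              x$N, x$D, x$delta, kind_of(x)))
  invisible(x)
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("<logistic_params> slope = %g, intercept = %g (mean %g months)\n",
              x$slope, x$intercept, x$intercept / x$slope))
  invisible(x)
}
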