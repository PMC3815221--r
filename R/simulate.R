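#' Population specification for simulated norms
#'
#' Describes the cohort over which per-word acquisition proportions are
#' computed: the effective number of children per word and the monthly
#' reporting window. Defaults follow the MCDI norms setting: about 1000
#' sampled children and the ages 16 through 30 months.
#'
#' @param n_children Positive integer, children per word.
#' @param months Strictly increasing integer ages (months).
#' @param seed Optional integer seed applied before simulation.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_children = 1000L, months = 16:30, seed = NULL) {
  n_children <- as.integer(n_children)
  if (is.na(n_children) || n_children < 1L) {
    stop("'n_children' must be a positive integer", call. = FALSE)
  }
  if (length(months) < 1L || any(diff(months) <= 0)) {
    stop("'months' must be non-empty and strictly increasing", call. = FALSE)
  }
  structure(list(n_children = n_children, months = as.numeric(months),
                 seed = seed),
            class = "population_spec")
}

#' Draw acquisition ages from the accumulator process
#'
#' Simulates ages at which individual learners acquire a word. For the
#' accumulator model the age of the N-th event under cumulative intensity
#' `Lambda(t) = delta * t^D` is `T = (G / delta)^(1/D)` where `G` is a
#' gamma(N, 1) accumulated load — the time-change of a unit-rate process.
#' The logistic model draws directly from the logistic law. Uses R's global
#' RNG; call `set.seed()` for reproducibility.
#'
#' @param params A [learning_params()] or [logistic_params()] object.
#' @param n Number of learners to draw.
#' @return Numeric vector of `n` acquisition ages (months).
#' @examples
#' set.seed(1)
#' mean(draw_acquisition_age(learning_params(1, 1, 1), 1e4))  # ~1
#' @export
draw_acquisition_age <- function(params, n = 1L) UseMethod("draw_acquisition_age")

#' @export
draw_acquisition_age.learning_params <- function(params, n = 1L) {
  (stats::rgamma(n, shape = params$N, rate = 1) / params$delta)^(1 / params$D)
}

#' @export
draw_acquisition_age.logistic_params <- function(params, n = 1L) {
  stats::rlogis(n, location = params$intercept / params$slope,
                scale = 1 / params$slope)
}

spec_params <- function(row) {
  if (row$kind == "logistic") {
    logistic_params(row$slope, row$intercept)
  } else {
    learning_params(row$N, row$D, row$delta)
  }
}

#' Simulate an MCDI-style norms table from known word specifications
#'
#' For each word, draws one acquisition age per child and reports the
#' proportion of children who have acquired the word by the end of each
#' month (`age <= m`). Because each child's age is drawn once and
#' thresholded at every month, the monthly proportions of a word are
#' dependent across months exactly as in a real cohort; each row is
#' non-decreasing by construction.
#'
#' @param specs Data frame of true word specifications with columns `word`,
#'   `class`, `kind`, `N`, `D`, `delta`, `slope`, `intercept` (accumulator
#'   columns may be `NA` for logistic words and vice versa), as produced by
#'   [make_mcdi_fixture()].
#' @param pop A [population_spec()].
#' @return A norms data frame with columns `word`, `class` and one `p<m>`
#'   column per month, plus attributes `n_children` and `months`.
#' @export
simulate_norms <- function(specs, pop = population_spec()) {
  stopifnot(inherits(pop, "population_spec"))
  if (!is.data.frame(specs) || nrow(specs) == 0L) {
    stop("'specs' must be a non-empty data frame of word specifications",
         call. = FALSE)
  }
  if (!is.null(pop$seed)) set.seed(pop$seed)
  months <- pop$months
  pm <- matrix(NA_real_, nrow = nrow(specs), ncol = length(months))
  for (i in seq_len(nrow(specs))) {
    ages <- draw_acquisition_age(spec_params(specs[i, ]), pop$n_children)
    pm[i, ] <- vapply(months, function(m) mean(ages <= m), numeric(1))
  }
  colnames(pm) <- sprintf("p%d", as.integer(months))
  norms <- data.frame(word = specs$word, class = specs$class, pm,
                      stringsAsFactors = FALSE)
  attr(norms, "n_children") <- pop$n_children
  attr(norms, "months") <- months
  norms
}

#' Extract the month grid of a norms table
#'
#' @param norms A norms data frame (columns `p16`, ..., `p30`).
#' @return Numeric vector of months.
#' @export
norms_months <- function(norms) {
  pcols <- grep("^p[0-9]+$", names(norms), value = TRUE)
  if (length(pcols) == 0L) stop("no p<month> columns found", call. = FALSE)
  as.numeric(sub("^p", "", pcols))
}

default_class_sizes <- function() {
  c(noun = 389L, verb = 102L, adjective = 63L, closed = 98L, other = 2L)
}

# class-conditional mixture over true model families; rows sum to 1.
# Skews follow the fitted-share pattern on real norms: nouns towards the
# full cumulative-and-rate-change family, closed-class words towards the
# rate-change (Weibull) family, cumulative learning common everywhere.
default_kind_mix <- function() {
  mix <- rbind(
    noun      = c(gamma = 0.35, weibull = 0.10, weibull_gamma = 0.45, logistic = 0.10),
    verb      = c(gamma = 0.40, weibull = 0.15, weibull_gamma = 0.30, logistic = 0.15),
    adjective = c(gamma = 0.40, weibull = 0.15, weibull_gamma = 0.30, logistic = 0.15),
    closed    = c(gamma = 0.30, weibull = 0.40, weibull_gamma = 0.15, logistic = 0.15),
    other     = c(gamma = 0.30, weibull = 0.40, weibull_gamma = 0.15, logistic = 0.15)
  )
  mix
}

#' Generate a synthetic MCDI-style fixture with known ground truth
#'
#' Emits a full synthetic analogue of the MCDI norms: 654 words in four word
#' classes (389 nouns, 102 verbs, 63 adjectives, 98 closed-class) plus 2
#' agrammatical items labelled `other` that class-based analyses exclude.
#' Each word carries a true model family drawn from a class-conditional
#' mixture and true parameters; monthly proportions are then simulated for
#' `n_children` learners.
#'
#' Accumulator parameters are placed along the near-collinear cloud observed
#' for real words in (log10 N, log10 D) space: for the full Weibull-gamma
#' family `log10 N ~ U(0, 3)` and `log10 D = 0.5 - log10 N + eps`,
#' `eps ~ N(0, 0.1)`; gamma words sit on the `D = 1` line and Weibull words
#' on the `N = 1` line, scattered around the points where that line crosses
#' them. The base rate `delta` is solved per word so true mean acquisition
#' ages span roughly 16-40 months (uniform), placing some words beyond the
#' observed window as in real norms.
#'
#' @param seed Integer seed; the fixture is fully reproducible from it.
#' @param n_children Children per word for the simulated proportions.
#' @param months Reporting window (months).
#' @param class_sizes Named integer vector of words per class. Defaults to
#'   the MCDI composition; scale it down for quick demonstrations.
#' @param kind_mix Matrix of per-class mixture weights over
#'   [model_kinds()] (rows = classes, columns = kinds).
#' @return List with `norms` (the simulated norms table) and `truth` (the
#'   word specification data frame with true kinds and parameters).
#' @examples
#' fx <- make_mcdi_fixture(seed = 1, n_children = 50,
#'                         class_sizes = c(noun = 6, verb = 2, adjective = 2,
#'                                         closed = 2, other = 0))
#' @export
make_mcdi_fixture <- function(seed, n_children = 1000L, months = 16:30,
                              class_sizes = default_class_sizes(),
                              kind_mix = default_kind_mix()) {
  set.seed(seed)
  classes <- rep(names(class_sizes), times = class_sizes)
  n <- length(classes)
  word <- sprintf("w%04d_%s", seq_len(n), substr(classes, 1, 3))

  kind <- character(n)
  N <- D <- delta <- slope <- intercept <- rep(NA_real_, n)
  mean_target <- stats::runif(n, 16, 40)
  for (i in seq_len(n)) {
    kind[i] <- sample(colnames(kind_mix), 1L, prob = kind_mix[classes[i], ])
    if (kind[i] == "logistic") {
      slope[i] <- stats::runif(1, 0.4, 1.2)
      intercept[i] <- slope[i] * mean_target[i]
    } else {
      if (kind[i] == "weibull_gamma") {
        l10N <- stats::runif(1, 0, 3)
        l10D <- 0.5 - l10N + stats::rnorm(1, 0, 0.1)
      } else if (kind[i] == "gamma") {
        l10N <- stats::rnorm(1, 0.5, 0.25)  # line crossing of D = 1
        l10D <- 0
      } else {                               # weibull: N = 1 line
        l10N <- 0
        l10D <- stats::rnorm(1, 0.5, 0.25)
      }
      N[i] <- 10^l10N
      D[i] <- 10^l10D
      delta[i] <- rate_for_mean(N[i], D[i], mean_target[i])
    }
  }
  truth <- data.frame(word = word, class = classes, kind = kind,
                      N = N, D = D, delta = delta,
                      slope = slope, intercept = intercept,
                      mean_aoa = mean_target, stringsAsFactors = FALSE)
  pop <- population_spec(n_children = n_children, months = months, seed = NULL)
  norms <- simulate_norms(truth, pop)
  list(norms = norms, truth = truth)
}
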