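#' Configuration of the per-word maximum-likelihood fit
#'
#' @param n_children Effective number of sampled children entering the
#'   binomial likelihood weight (the norms' reported cohort size; 1000 for
#'   MCDI-style norms).
#' @param n0 Degrees of freedom of the data used in the BIC penalty: the
#'   number of monthly observations per word (15 for the 16-30 month
#'   window). Note the deliberate asymmetry with `n_children`: the
#'   likelihood is weighted by the cohort size while the BIC penalty uses
#'   the number of months, mirroring the published fitting recipe.
#' @param eps Clamp applied to model proportions before taking logs,
#'   in (0, 1e-3].
#' @param reltol Relative convergence tolerance on the objective.
#' @param grid_points Number of grid values per free coordinate in the
#'   multistart (the default 4 gives a 4x4(x4) log-grid plus a
#'   moment-matched start).
#' @param log10_bounds Named list of log10 box bounds for `N`, `D` and
#'   `delta`. Defaults: accumulation is constrained to `N >= 1` (a word
#'   cannot require fewer than one exposure; this also places the
#'   rate-change submodel on the boundary of the full family, which keeps
#'   its spurious BIC selection in check). The delta box is much wider than
#'   the shape boxes because `delta = scale^-D`: a Weibull with scale 23
#'   months and `D = 5` has `delta` near 1e-7, so clamping delta at 1e-3
#'   would exclude the truth for steep rate-change words.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_children = 1000L, n0 = 15L, eps = 1e-9,
                       reltol = 1e-8, grid_points = 4L,
                       log10_bounds = list(N = c(0, 4), D = c(-3, 4),
                                           delta = c(-25, 10))) {
  if (eps <= 0 || eps > 1e-3) stop("'eps' must be in (0, 1e-3]", call. = FALSE)
  if (n_children < 1L) stop("'n_children' must be >= 1", call. = FALSE)
  structure(list(n_children = as.integer(n_children), n0 = as.integer(n0),
                 eps = eps, reltol = reltol,
                 grid_points = as.integer(grid_points),
                 log10_bounds = log10_bounds),
            class = "fit_config")
}

#' Binomial cross-entropy log-likelihood of a word's monthly proportions
#'
#' The likelihood of observed acquisition proportions `p_m` under model
#' proportions `q_m = F(m)` treats each month as an independent binomial
#' observation on `n` children:
#' `L = n * sum_m [ p_m log q_m + (1 - p_m) log(1 - q_m) ]`.
#' Model proportions are clamped to `[eps, 1 - eps]` before the logs so that
#' boundary observations (p of exactly 0 or 1) remain finite. Monthly
#' dependence induced by the cumulative design is ignored, a deliberate
#' modelling approximation.
#'
#' @param kind One of [model_kinds()] (determines nothing here beyond
#'   validation; the model enters through `params`).
#' @param params Parameter object matching `kind`.
#' @param p Observed proportions, one per month, each in \[0, 1\].
#' @param months Ages (months) aligned with `p`.
#' @param config A [fit_config()].
#' @return The log-likelihood (real; 0 when the model reproduces degenerate
#'   data exactly up to the clamp).
#' @export
word_loglik <- function(kind, params, p, months, config = fit_config()) {
  kind <- match.arg(kind, model_kinds())
  if (length(p) != length(months)) {
    stop("'p' and 'months' must have equal length", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("'p' must lie in [0, 1]", call. = FALSE)
  }
  q <- aoa_cdf(params, months)
  q <- pmin(pmax(q, config$eps), 1 - config$eps)
  config$n_children * sum(p * log(q) + (1 - p) * log1p(-q))
}

#' Bayesian Information Criterion for a fitted word
#'
#' `BIC = -2 * loglik + k * log(n0)` with `k` the number of free parameters
#' and `n0` the degrees of freedom of the data (number of monthly
#' observations). Smaller is better.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters (>= 1).
#' @param n0 Data degrees of freedom (>= 2).
#' @return The BIC value.
#' @export
bic <- function(loglik, k, n0 = 15L) {
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  if (n0 < 2L) stop("'n0' must be >= 2", call. = FALSE)
  -2 * loglik + k * log(n0)
}

# --- internal optimisation machinery -------------------------------------

# moment estimates of the acquisition-age distribution from a monotone-ified
# proportion row; tail mass beyond the window is placed a little past it.
moment_guess <- function(p, months) {
  pm <- cummax(pmin(pmax(p, 0), 1))
  inc <- c(pm[1], diff(pm))
  tail_mass <- 1 - pm[length(pm)]
  tail_age <- max(months) + 6
  w <- c(inc, tail_mass)
  a <- c(months, tail_age)
  m <- sum(w * a) / sum(w)
  v <- sum(w * (a - m)^2) / sum(w)
  list(mean = max(m, 1e-3), var = max(v, 0.25))
}

# map an unconstrained coordinate vector to a params object, per kind
theta_to_params <- function(kind, theta) {
  switch(kind,
    gamma = learning_params(N = exp(theta[1]), D = 1, delta = exp(theta[2])),
    weibull = learning_params(N = 1, D = exp(theta[1]), delta = exp(theta[2])),
    weibull_gamma = learning_params(N = exp(theta[1]), D = exp(theta[2]),
                                    delta = exp(theta[3])),
    logistic = logistic_params(slope = exp(theta[1]), intercept = theta[2])
  )
}

# starting grid in the unconstrained coordinates; a (g x g (x g)) spread
# plus one moment-matched start. delta coordinates are anchored by solving
# the closed-form mean for targets spread around the moment mean, which
# conditions the grid far better than a fixed log-delta lattice.
start_grid <- function(kind, p, months, config) {
  g <- config$grid_points
  mom <- moment_guess(p, months)
  mean_f <- exp(seq(log(0.6), log(2.2), length.out = g)) * mom$mean
  starts <- list()
  if (kind == "gamma") {
    Ns <- 10^seq(0, 2.25, length.out = g)
    for (Nv in Ns) for (mv in mean_f) {
      starts[[length(starts) + 1L]] <- log(c(Nv, Nv / mv))
    }
    N0 <- max(mom$mean^2 / mom$var, 1.01)
    starts[[length(starts) + 1L]] <- log(c(N0, N0 / mom$mean))
  } else if (kind == "weibull") {
    Ds <- 10^seq(-1, 0.75, length.out = g)
    for (Dv in Ds) for (mv in mean_f) {
      starts[[length(starts) + 1L]] <- log(c(Dv, rate_for_mean(1, Dv, mv)))
    }
    starts[[length(starts) + 1L]] <- log(c(1, 1 / mom$mean))
  } else if (kind == "weibull_gamma") {
    Ns <- 10^seq(0, 2.25, length.out = g)
    Ds <- 10^seq(-1.2, 0.7, length.out = g)
    for (Nv in Ns) for (Dv in Ds) for (mv in mean_f) {
      starts[[length(starts) + 1L]] <-
        log(c(Nv, Dv, rate_for_mean(Nv, Dv, mv)))
    }
    N0 <- max(mom$mean^2 / mom$var, 1.01)
    starts[[length(starts) + 1L]] <- log(c(N0, 1, N0 / mom$mean))
  } else { # logistic
    slopes <- 10^seq(-1.2, 0.3, length.out = g)
    for (sv in slopes) for (mv in mean_f) {
      starts[[length(starts) + 1L]] <- c(log(sv), sv * mv)
    }
    s0 <- pi / sqrt(3 * mom$var)
    starts[[length(starts) + 1L]] <- c(log(s0), s0 * mom$mean)
  }
  starts
}

theta_bounds <- function(kind, config) {
  b <- lapply(config$log10_bounds, function(x) x * log(10))
  switch(kind,
    gamma = list(lower = c(b$N[1], b$delta[1]), upper = c(b$N[2], b$delta[2])),
    weibull = list(lower = c(b$D[1], b$delta[1]), upper = c(b$D[2], b$delta[2])),
    weibull_gamma = list(lower = c(b$N[1], b$D[1], b$delta[1]),
                         upper = c(b$N[2], b$D[2], b$delta[2])),
    logistic = list(lower = c(b$D[1], -1000), upper = c(b$D[2], 1000))
  )
}

#' Fit one model family to a word's monthly proportions
#'
#' Maximizes the binomial cross-entropy likelihood over the family's free
#' parameters in log space (intercept linear for the logistic), using
#' box-bounded quasi-Newton refinement from a multistart grid plus a
#' moment-matched start. Deterministic: the start grid is a fixed function
#' of the data and configuration.
#'
#' Rows with no proportion strictly inside (0, 1) are unidentifiable (any
#' sufficiently extreme model reproduces them up to the clamp); the fit is
#' still returned but flagged `converged = FALSE`.
#'
#' @param kind One of [model_kinds()].
#' @param p Observed monthly proportions.
#' @param months Ages aligned with `p`.
#' @param config A [fit_config()].
#' @param word Optional word identifier carried into the result.
#' @param extra_starts Optional list of additional start vectors in the
#'   unconstrained coordinates (used by [select_model()] to warm-start the
#'   Weibull-gamma fit from its fitted submodels, which guarantees
#'   nested-model dominance up to optimizer tolerance).
#' @return A `word_fit` list: `word`, `kind`, `params`, `loglik`, `bic`,
#'   `converged`, `n_starts_used`.
#' @export
fit_word <- function(kind, p, months, config = fit_config(),
                     word = NA_character_, extra_starts = list()) {
  kind <- match.arg(kind, model_kinds())
  if (length(p) != length(months) || length(p) == 0L) {
    stop("'p' and 'months' must be non-empty and of equal length", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("'p' must lie in [0, 1]", call. = FALSE)
  }
  identifiable <- any(p > 0 & p < 1)

  negll <- function(theta) {
    params <- tryCatch(theta_to_params(kind, theta), error = function(e) NULL)
    if (is.null(params)) return(1e12)
    v <- -word_loglik(kind, params, p, months, config)
    if (!is.finite(v)) 1e12 else v
  }
  bounds <- theta_bounds(kind, config)
  starts <- c(start_grid(kind, p, months, config), extra_starts)

  run_start <- function(theta0, maxit, factr, ndeps = 1e-3) {
    tryCatch(
      stats::optim(theta0, negll, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = maxit, factr = factr,
                                  ndeps = rep(ndeps, length(theta0)))),
      error = function(e) NULL)
  }

  # screening pass: a cheap budget from every grid start, then a tight
  # refinement of the most promising basins only
  screened <- lapply(starts, function(theta0) {
    theta0 <- pmin(pmax(theta0, bounds$lower), bounds$upper)
    run_start(theta0, maxit = 40L, factr = 1e10)
  })
  screened <- screened[!vapply(screened, is.null, logical(1))]
  if (length(screened) == 0L) {
    stop(sprintf("all optimizer starts failed for kind '%s'", kind),
         call. = FALSE)
  }
  vals <- vapply(screened, function(r) r$value, numeric(1))
  top <- screened[order(vals)[seq_len(min(3L, length(screened)))]]

  best <- NULL
  any_conv <- FALSE
  for (cand in top) {
    # tight final tolerance: the likelihood is O(n * months), so a loose
    # relative factr would leave absolute errors above the 1e-6 contract;
    # the smaller difference step keeps the numeric gradient bias below it
    res <- run_start(cand$par, maxit = 500L, factr = 1e2, ndeps = 1e-5)
    if (is.null(res)) res <- cand
    if (res$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  params <- theta_to_params(kind, best$par)
  ll <- word_loglik(kind, params, p, months, config)
  structure(list(word = word, kind = kind, params = params,
                 loglik = ll, bic = bic(ll, n_params(kind), config$n0),
                 converged = any_conv && identifiable,
                 n_starts_used = length(starts)),
            class = "word_fit")
}

#' @export
print.word_fit <- function(x, ...) {
  cat(sprintf("<word_fit> %s [%s] loglik = %.3f, BIC = %.3f%s\n",
              x$word, x$kind, x$loglik, x$bic,
              if (x$converged) "" else " (not converged)"))
  print(x$params)
  invisible(x)
}

kind_tie_order <- function() {
  c(gamma = 1L, weibull = 2L, logistic = 3L, weibull_gamma = 4L)
}

#' Fit all four model families to one word and select the best by BIC
#'
#' Fits the gamma (cumulative), Weibull (rate-change), Weibull-gamma
#' (cumulative-and-rate-change) and logistic families and declares the
#' family with the smallest BIC the winner. BIC ties (within `1e-9`) are
#' broken towards fewer parameters, then by the fixed order gamma, weibull,
#' logistic, weibull_gamma. A family whose fit fails outright is excluded
#' with a warning.
#'
#' @inheritParams fit_word
#' @return List with `winner` (a `word_fit`) and `candidates` (named list of
#'   all successful `word_fit`s).
#' @export
select_model <- function(p, months, config = fit_config(), word = NA_character_) {
  fits <- list()
  for (kind in c("gamma", "weibull", "logistic", "weibull_gamma")) {
    extra <- list()
    if (kind == "weibull_gamma") {
      # warm-start the full family from its fitted submodels so its maximum
      # dominates theirs up to optimizer tolerance
      if (!is.null(fits$gamma)) {
        pg <- fits$gamma$params
        extra <- c(extra, list(log(c(pg$N, 1, pg$delta))))
      }
      if (!is.null(fits$weibull)) {
        pw <- fits$weibull$params
        extra <- c(extra, list(log(c(1, pw$D, pw$delta))))
      }
    }
    f <- tryCatch(fit_word(kind, p, months, config, word = word,
                           extra_starts = extra),
                  error = function(e) {
                    warning(sprintf("fit of kind '%s' failed for word '%s': %s",
                                    kind, word, conditionMessage(e)),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(f)) fits[[kind]] <- f
  }
  if (length(fits) == 0L) stop("no model family could be fitted", call. = FALSE)
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  tied <- names(fits)[bics <= min(bics) + 1e-9]
  ks <- vapply(tied, n_params, integer(1))
  tied <- tied[ks == min(ks)]
  winner <- tied[order(kind_tie_order()[tied])][1]
  list(winner = fits[[winner]], candidates = fits)
}

fit_row <- function(f, class = NA_character_, winner_flag = FALSE) {
  pr <- f$params
  data.frame(word = f$word, class = class, kind = f$kind,
             N = if (inherits(pr, "learning_params")) pr$N else NA_real_,
             D = if (inherits(pr, "learning_params")) pr$D else NA_real_,
             delta = if (inherits(pr, "learning_params")) pr$delta else NA_real_,
             slope = if (inherits(pr, "logistic_params")) pr$slope else NA_real_,
             intercept = if (inherits(pr, "logistic_params")) pr$intercept else NA_real_,
             loglik = f$loglik, bic = f$bic, converged = f$converged,
             winner_flag = winner_flag, stringsAsFactors = FALSE)
}

#' Fit and select models for every word of a norms table
#'
#' Runs [select_model()] for each row of a norms table and collects all
#' candidate fits into one long data frame, with the BIC winner flagged.
#' Progress is reported every 50 words.
#'
#' @param norms Norms data frame as returned by [simulate_norms()] or
#'   [read_norms()].
#' @param config A [fit_config()].
#' @param quiet Suppress progress messages.
#' @return Data frame with one row per word x fitted family: columns `word`,
#'   `class`, `kind`, `N`, `D`, `delta`, `slope`, `intercept`, `loglik`,
#'   `bic`, `converged`, `winner_flag`.
#' @export
fit_norms <- function(norms, config = fit_config(), quiet = FALSE) {
  months <- norms_months(norms)
  pcols <- sprintf("p%d", as.integer(months))
  out <- vector("list", nrow(norms))
  for (i in seq_len(nrow(norms))) {
    p <- as.numeric(norms[i, pcols])
    sel <- select_model(p, months, config, word = norms$word[i])
    rows <- lapply(sel$candidates, fit_row, class = norms$class[i])
    df <- do.call(rbind, rows)
    df$winner_flag <- df$kind == sel$winner$kind
    out[[i]] <- df
    if (!quiet && i %% 50L == 0L) {
      message(sprintf("fitted %d / %d words", i, nrow(norms)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rebuild the parameter object of one fits-table row
#'
#' @param row One row of the data frame returned by [fit_norms()].
#' @return A [learning_params()] or [logistic_params()] object.
#' @export
params_of_fit <- function(row) {
  if (row$kind == "logistic") logistic_params(row$slope, row$intercept)
  else learning_params(row$N, row$D, row$delta)
}
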