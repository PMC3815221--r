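# independent oracles and shared fixture builders for the test suite

# numeric-scan hazard-shape oracle: classifies by inspecting the hazard on a
# dense grid, independent of the analytic rules in the package
scan_hazard_shape <- function(params) {
  # quantile-based grid so both tails are resolved: boundary-regime shapes
  # (e.g. a bathtub minimum) can sit beyond the bulk of the distribution
  qs <- unique(sort(c(10^seq(-6, -2, length.out = 300),
                      seq(0.01, 0.99, length.out = 3000),
                      1 - 10^seq(-6, -2, length.out = 300))))
  ts <- aoa_quantile(params, qs)
  h <- aoa_hazard(params, ts)
  h <- h[is.finite(h)]
  d <- diff(h)
  tol <- 1e-9 * max(abs(h))
  inc <- d > tol
  dec <- d < -tol
  if (!any(inc) && !any(dec)) return("constant")
  if (!any(dec)) return("monotone_increasing")
  if (!any(inc)) return("monotone_decreasing")
  # single sign change: up-then-down = peaked, down-then-up = bathtub
  first_dec <- which(dec)[1]
  if (any(inc[first_dec:length(d)])) "bathtub" else "peaked"
}

# random valid learning params spanning the regimes used throughout
random_learning_params <- function() {
  learning_params(N = 10^stats::runif(1, -0.3, 1.5),
                  D = 10^stats::runif(1, -0.6, 0.6),
                  delta = rate_for_mean(1, 1, 1) * 10^stats::runif(1, -1, 1))
}

# truth specifications for the well-separated model-selection benchmark:
# each family in a regime whose best wrong-family approximation over the
# 16-30 month window is clearly worse than the truth (see the methods
# vignette for the reasoning)
benchmark_specs <- function(n_per_kind = 50) {
  mk <- function(kind, i) {
    m <- stats::runif(1, 22, 26)
    if (kind == "gamma") {
      N <- stats::runif(1, 10, 18); D <- 1
    } else if (kind == "weibull") {
      N <- 1; D <- stats::runif(1, 5.5, 7)
    } else if (kind == "weibull_gamma") {
      N <- stats::runif(1, 3, 8); D <- stats::runif(1, 2.2, 3.5)
    } else {
      s <- stats::runif(1, 0.5, 1.1)
      return(data.frame(word = sprintf("%s%03d", kind, i), class = "noun",
                        kind = kind, N = NA, D = NA, delta = NA,
                        slope = s, intercept = s * m))
    }
    data.frame(word = sprintf("%s%03d", kind, i), class = "noun", kind = kind,
               N = N, D = D, delta = rate_for_mean(N, D, m),
               slope = NA, intercept = NA)
  }
  do.call(rbind, lapply(model_kinds(), function(k) {
    do.call(rbind, lapply(seq_len(n_per_kind), function(i) mk(k, i)))
  }))
}
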