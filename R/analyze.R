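#' Median age of acquisition of a word
#'
#' The first month at which the reported acquisition proportion reaches 50%.
#' Words that never reach 50% within the observed window are censored and
#' coded as `max(months) + 1` (31 for the standard 16-30 window).
#'
#' @param p Monthly acquisition proportions.
#' @param months Ages aligned with `p`.
#' @return The median AoA in months, or the censoring sentinel.
#' @export
median_aoa <- function(p, months) {
  if (length(p) == 0L || length(p) != length(months)) {
    stop("'p' must be non-empty and aligned with 'months'", call. = FALSE)
  }
  hit <- which(p >= 0.5)
  if (length(hit) == 0L) max(months) + 1 else months[hit[1]]
}

#' Mean acquisition age implied by a fitted model
#'
#' Delegates to [aoa_mean()] on the fitted parameters. Because parameters
#' are estimated from the truncated 16-30 month window, the implied mean may
#' exceed the window (no clipping is applied). For a logistic fit the mean
#' is `intercept / slope`.
#'
#' @param fit A `word_fit` (from [fit_word()]) or one row of a [fit_norms()]
#'   table.
#' @return Expected acquisition age in months.
#' @export
estimated_mean_aoa <- function(fit) {
  if (inherits(fit, "word_fit")) return(aoa_mean(fit$params))
  aoa_mean(params_of_fit(fit))
}

#' Cross-tabulate winning model families by group
#'
#' Counts, for each group (word class, or median-AoA bin), how many words
#' each model family fits best. Groups with no words are retained as zero
#' rows so that the full axis (e.g. every month bin) is represented.
#'
#' @param groups Group label per word (character or factor; e.g. class, or
#'   median AoA coerced to character).
#' @param kinds Winning family per word (values from [model_kinds()]).
#' @param group_levels Optional explicit row ordering / universe of groups.
#' @return List with `counts` (groups x kinds integer matrix) and
#'   `proportions` (rows normalized to 1; `NaN` rows for empty groups).
#' @export
crosstab_selection <- function(groups, kinds, group_levels = NULL) {
  if (length(groups) != length(kinds)) {
    stop("'groups' and 'kinds' must be aligned", call. = FALSE)
  }
  bad <- setdiff(unique(kinds), model_kinds())
  if (length(bad) > 0L) {
    stop(sprintf("unknown model kind(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(group_levels)) group_levels <- sort(unique(as.character(groups)))
  gf <- factor(as.character(groups), levels = group_levels)
  if (anyNA(gf)) {
    stop(sprintf("group label(s) outside 'group_levels': %s",
                 paste(unique(groups[is.na(gf)]), collapse = ", ")),
         call. = FALSE)
  }
  kf <- factor(kinds, levels = model_kinds())
  counts <- table(gf, kf)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  props <- counts / rowSums(counts)
  list(counts = counts, proportions = props)
}

#' Chi-square test of independence for a contingency table
#'
#' Pearson's statistic `sum((O - E)^2 / E)` with expected counts from the
#' product of row and column margins, `df = (r - 1)(c - 1)`, and the p-value
#' from the upper tail of the chi-square distribution. No continuity
#' correction.
#'
#' @param table Numeric matrix of non-negative counts (at least 2x2 after
#'   dropping nothing; zero margins are an error naming the offender).
#' @return List with `statistic`, `df`, `p_value` and `expected`.
#' @examples
#' chi_square_independence(rbind(c(10, 20), c(20, 10)))  # X2 = 6.667, df 1
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(!is.finite(table))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("need at least a 2x2 table", call. = FALSE)
  }
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0)) {
    stop(sprintf("zero row margin in row(s): %s",
                 paste(which(rs == 0), collapse = ", ")), call. = FALSE)
  }
  if (any(cs == 0)) {
    stop(sprintf("zero column margin in column(s): %s",
                 paste(which(cs == 0), collapse = ", ")), call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(table)
  statistic <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
       expected = expected)
}

#' Pearson correlation with a Fisher-transform confidence interval
#'
#' @param x,y Aligned numeric vectors, `n >= 4`, neither constant.
#' @param conf_level Confidence level (default 95%).
#' @return List with `r`, `ci` (length-2), `n`.
#' @examples
#' # r = 0.5 at n = 100 gives the interval (0.3366, 0.6334)
#' @export
pearson_ci <- function(x, y, conf_level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  r <- stats::cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(r = r, ci = tanh(c(z - zq * se, z + zq * se)), n = n)
}

#' Correlate fitted learning parameters with word attributes
#'
#' Joins per-word fitted parameters of one model family with a word
#' attribute table (inner join: only shared words are analyzed, as when
#' norms and attribute corpora cover different vocabularies) and reports the
#' Pearson correlation with its 95% Fisher interval. Parameters `N`, `D`,
#' `delta` are log-transformed by default (they live on ratio scales and are
#' analyzed on log axes); `median_aoa` is used raw. The attribute may also
#' be log-transformed (conventional for corpus frequency, not for
#' imageability ratings).
#'
#' @param fits A [fit_norms()] data frame, or any data frame with columns
#'   `word`, `kind` and the parameter columns.
#' @param attributes Data frame with columns `word`, `value` (one attribute)
#'   or `word` plus a named attribute column given by `attribute`.
#' @param param One of `"N"`, `"D"`, `"delta"`, `"median_aoa"`.
#' @param kind Which model family's fitted parameters to use (ignored for
#'   `median_aoa`, which is model-free). All words fitted under that family
#'   are used by default; set `winners_only = TRUE` to restrict to words the
#'   family won.
#' @param attribute Column of `attributes` holding the attribute value.
#' @param log_param,log_attribute Log-transform flags.
#' @param winners_only Restrict to best-fit words of `kind`.
#' @return As [pearson_ci()].
#' @export
correlate_with_attributes <- function(fits, attributes,
                                      param = c("N", "D", "delta", "median_aoa"),
                                      kind = "weibull_gamma",
                                      attribute = "value",
                                      log_param = param != "median_aoa",
                                      log_attribute = FALSE,
                                      winners_only = FALSE) {
  param <- match.arg(param)
  if (!attribute %in% names(attributes)) {
    stop(sprintf("attribute column '%s' not found", attribute), call. = FALSE)
  }
  if (param == "median_aoa") {
    if (!"median_aoa" %in% names(fits)) {
      stop("fits must carry a 'median_aoa' column for param = 'median_aoa'",
           call. = FALSE)
    }
    sub <- fits[!duplicated(fits$word), c("word", "median_aoa")]
    names(sub)[2] <- "pval"
  } else {
    kind <- match.arg(kind, model_kinds())
    sub <- fits[fits$kind == kind, , drop = FALSE]
    if (winners_only) sub <- sub[sub$winner_flag, , drop = FALSE]
    sub <- sub[, c("word", param)]
    names(sub)[2] <- "pval"
  }
  merged <- merge(sub, attributes[, c("word", attribute)], by = "word")
  if (nrow(merged) < 4L) stop("fewer than 4 shared words after join", call. = FALSE)
  x <- merged$pval
  y <- merged[[attribute]]
  if (log_param) x <- log10(x)
  if (log_attribute) y <- log10(y)
  pearson_ci(x, y)
}

#' Moving-average developmental trend of a fitted parameter
#'
#' Orders the words of one class by the mean acquisition age implied by
#' their fits and smooths a parameter along that order with an asymmetric
#' moving window covering ranks `t - 9` through `t + 10` (20 words; 9
#' earlier-learned and 10 later-learned neighbours). Windows are truncated
#' at the sequence boundaries so every word receives a value.
#'
#' @param fits Data frame of fits for the words of one class (typically the
#'   Weibull-gamma rows of a [fit_norms()] table).
#' @param param Column to smooth (e.g. `"N"` or `"D"`).
#' @param log10_values Smooth on the log10 scale (parameters are displayed
#'   on log axes).
#' @param before,after Window reach in ranks (defaults 9 and 10).
#' @return Data frame ordered by estimated mean AoA with columns `word`,
#'   `rank`, `mean_aoa`, `value`, `trend`.
#' @export
moving_average_trend <- function(fits, param = "N", log10_values = TRUE,
                                 before = 9L, after = 10L) {
  if (nrow(fits) < 1L) stop("need at least one word", call. = FALSE)
  mean_aoa <- vapply(seq_len(nrow(fits)),
                     function(i) estimated_mean_aoa(fits[i, ]), numeric(1))
  ord <- order(mean_aoa)
  v <- fits[[param]][ord]
  if (log10_values) v <- log10(v)
  nw <- length(v)
  trend <- vapply(seq_len(nw), function(t) {
    lo <- max(1L, t - before)
    hi <- min(nw, t + after)
    mean(v[lo:hi])
  }, numeric(1))
  data.frame(word = fits$word[ord], rank = seq_len(nw),
             mean_aoa = mean_aoa[ord], value = v, trend = trend,
             stringsAsFactors = FALSE)
}

#' Per-word median AoA of a norms table
#'
#' Convenience wrapper applying [median_aoa()] to every row.
#'
#' @param norms Norms data frame.
#' @return Named numeric vector of median AoAs (censored words coded
#'   `max(months) + 1`).
#' @export
norms_median_aoa <- function(norms) {
  months <- norms_months(norms)
  pcols <- sprintf("p%d", as.integer(months))
  out <- vapply(seq_len(nrow(norms)),
                function(i) median_aoa(as.numeric(norms[i, pcols]), months),
                numeric(1))
  names(out) <- norms$word
  out
}
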