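# tiny FNV-1a hash over a string; used to stamp output headers with a
# config fingerprint without pulling in a digest dependency
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor only touches the low byte; keep operands in integer range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply in halves (h * p overflows 2^53 otherwise)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a(paste(deparse(config, control = "all"), collapse = ""))
}

output_header <- function(seed = NULL, config = NULL) {
  v <- as.character(utils::packageVersion("aoalearn"))
  c(sprintf("# aoalearn %s", v),
    if (!is.null(seed)) sprintf("# seed: %s", seed),
    if (!is.null(config)) sprintf("# config: %s", config_hash(config)))
}

write_csv_with_header <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(output_header(seed, config), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a norms table to CSV
#'
#' Plain CSV with columns `word`, `class`, `p16` ... `p30`, preceded by `#`
#' comment lines carrying the package version, seed and configuration hash
#' for provenance. Rereading with [read_norms()] round-trips the table.
#'
#' @param norms Norms data frame.
#' @param path Output file.
#' @param seed Optional seed to record in the header.
#' @param config Optional configuration object to fingerprint in the header.
#' @return The path, invisibly.
#' @export
write_norms <- function(norms, path, seed = NULL, config = NULL) {
  write_csv_with_header(norms, path, seed, config)
}

#' Read and validate a norms table
#'
#' Expects a CSV with a `word` column, a `class` column with values in
#' noun/verb/adjective/closed/other, and 15 proportion columns `p16`..`p30`
#' (more generally `p<month>`). Validation: no duplicate words; all
#' proportions numeric in \[0, 1\] (violations are errors naming the row);
#' rows whose proportions decrease across months are accepted — real
#' parent-report norms are noisy — but reported with a warning.
#'
#' @param path CSV file (lines starting with `#` are ignored).
#' @return Norms data frame with a `months` attribute.
#' @export
read_norms <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("word", "class")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  pcols <- grep("^p[0-9]+$", names(df), value = TRUE)
  if (length(pcols) == 0L) {
    stop("no p<month> proportion columns found", call. = FALSE)
  }
  dup <- df$word[duplicated(df$word)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate word key(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  bad_class <- setdiff(unique(df$class),
                       c("noun", "verb", "adjective", "closed", "other"))
  if (length(bad_class) > 0L) {
    stop(sprintf("unknown class label(s): %s",
                 paste(bad_class, collapse = ", ")), call. = FALSE)
  }
  for (cl in pcols) {
    v <- df[[cl]]
    if (!is.numeric(v) || anyNA(v)) {
      stop(sprintf("column %s contains non-numeric or missing values", cl),
           call. = FALSE)
    }
    bad <- which(v < 0 | v > 1)
    if (length(bad) > 0L) {
      stop(sprintf("proportion out of [0,1] in column %s, row %d (value %g)",
                   cl, bad[1], v[bad[1]]), call. = FALSE)
    }
  }
  months <- as.numeric(sub("^p", "", pcols))
  pm <- as.matrix(df[, pcols])
  nonmono <- which(apply(pm, 1, function(r) any(diff(r) < 0)))
  if (length(nonmono) > 0L) {
    warning(sprintf("%d row(s) have non-monotone proportions (e.g. row %d, word '%s')",
                    length(nonmono), nonmono[1], df$word[nonmono[1]]),
            call. = FALSE)
  }
  attr(df, "months") <- months
  df
}

#' Write per-word fit results to CSV
#'
#' One row per word x fitted family with the winner flagged; see
#' [fit_norms()] for the columns.
#'
#' @inheritParams write_norms
#' @param fits Fits data frame.
#' @export
write_fits <- function(fits, path, seed = NULL, config = NULL) {
  write_csv_with_header(fits, path, seed, config)
}

#' Read a fits CSV written by [write_fits()]
#'
#' @param path CSV file.
#' @return Fits data frame.
#' @export
read_fits <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a word-attribute table
#'
#' CSV with a `word` column and one or more numeric attribute columns
#' (e.g. `frequency`, `imageability`).
#'
#' @param path CSV file.
#' @return Attribute data frame.
#' @export
read_attributes <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"word" %in% names(df)) stop("missing 'word' column", call. = FALSE)
  df
}
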