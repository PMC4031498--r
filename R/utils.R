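# Internal helpers shared across modules. All intervals are 0-based half-open.

# nearest-rank percentile: value at index ceil(p/100 * n) of the sorted vector
nearest_rank <- function(x, p) {
  stopifnot(length(x) >= 1, p >= 0, p <= 100)
  s <- sort(x)
  s[max(1L, as.integer(ceiling(p / 100 * length(s))))]
}

# threshold for "above the p-th percentile": smallest value with at least
# floor(p/100 * n) values strictly below it in rank terms; ties at the
# threshold are kept by the caller's >= comparison
percentile_cutoff <- function(x, p) {
  stopifnot(length(x) >= 1, p >= 0, p <= 100)
  s <- sort(x)
  s[min(length(s), as.integer(floor(p / 100 * length(s))) + 1L)]
}

# convert 0-based half-open (start, end) to an IRanges (1-based closed)
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# union-normalize a set of 0-based half-open intervals (two-column data frame)
normalize_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  r <- IRanges::reduce(as_iranges0(df$start, df$end))
  tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

interval_total_width <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(0L)
  sum(df$end - df$start)
}

# stop with a format-error class used by all parsers
format_error <- function(msg) {
  abort(msg, class = "mirsites_format_error")
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    format_error(sprintf(
      "%s is missing mandatory column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# parse a character column to double; error cites the first offending line
# (1-based data line numbers, header excluded)
parse_numeric_column <- function(x, col, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    format_error(sprintf(
      "%s: non-numeric value '%s' in column '%s' at line %d",
      what, as.character(x[bad[1]]), col, bad[1] + 1L
    ))
  }
  out
}

clip01 <- function(x) pmin(1, pmax(0, x))

`%n%` <- function(a, b) if (is.null(a)) b else a
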