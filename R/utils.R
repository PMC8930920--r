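# Internal helpers shared across the pipeline stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Integer rounding used for all reported percentages and ratios. Ties are
#' rounded away from zero (65.5 becomes 66), unlike [base::round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @return integer vector of the same length.
#' @export
#' @examples
#' round_half_away(c(65.5, 3.2, -2.5))
round_half_away <- function(x) {
  stopifnot(is.numeric(x))
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Collapse runs of whitespace and trim. Keeps verbatim content otherwise.
squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Diacritic stripping for matching keys only; verbatim strings are never
# altered. Unicode NFKD-style transliteration to ASCII.
strip_diacritics <- function(x) {
  stringi::stri_trans_general(x, "Latin-ASCII")
}

# UTF-8 CSV read/write (RFC 4180). `comment` writes a leading comment line
# documenting the sheet contract; reads skip "#" lines.
write_csv_utf8 <- function(df, path, comment = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

read_csv_utf8 <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                  comment.char = "#", check.names = FALSE,
                  colClasses = "character", na.strings = character())
}

# Stable semicolon-joined set representation used in summary sheets so that
# CSV round-trips are exact.
join_set <- function(x) paste(sort(unique(x[nzchar(x)])), collapse = ";")
split_set <- function(x) {
  if (!nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}
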