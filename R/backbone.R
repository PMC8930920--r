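# Taxonomic backbone: a local WoRMS-like reference table of accepted names,
# authorities, classification, marine flags and synonyms. All alignment is
# against this table; there are no live registry lookups.

#' Construct a taxonomic backbone
#'
#' @param df a data.frame with columns `acceptedName`, `authority`, `rank`,
#'   `phylum`, `class`, `order`, `family`, `genus`, `isMarine` (logical) and
#'   `synonyms` (a list column of character vectors, or a character column of
#'   pipe-delimited names).
#' @return an object of class `taxon_backbone`.
#' @export
taxon_backbone <- function(df) {
  req <- c("acceptedName", "authority", "rank", "phylum", "class", "order",
           "family", "genus", "isMarine", "synonyms")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("backbone is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.character(df$synonyms))
    df$synonyms <- lapply(df$synonyms, function(s)
      if (!nzchar(s)) character(0) else trimws(strsplit(s, "|", fixed = TRUE)[[1]]))
  df$isMarine <- as.logical(df$isMarine)

  dup <- df$acceptedName[duplicated(df$acceptedName)]
  if (length(dup))
    stop("duplicate accepted names in backbone: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)

  syn <- data.frame(
    synonym = unlist(df$synonyms, use.names = FALSE) %||% character(0),
    accepted = rep(df$acceptedName, lengths(df$synonyms)),
    stringsAsFactors = FALSE)
  if (nrow(syn)) {
    bad <- unique(syn$synonym[duplicated(syn$synonym)])
    if (length(bad))
      stop("synonyms mapped to more than one accepted name: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }

  # Key-based lookup index: accepted names take precedence over synonyms.
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(syn))
    for (i in seq_len(nrow(syn)))
      assign(canonical_key(syn$synonym[i]),
             list(status = "synonym", accepted = syn$accepted[i]), envir = idx)
  for (i in seq_len(nrow(df)))
    assign(canonical_key(df$acceptedName[i]),
           list(status = "accepted", accepted = df$acceptedName[i], row = i),
           envir = idx)

  structure(list(table = df, index = idx), class = "taxon_backbone")
}

#' Read a backbone from CSV
#'
#' Expects UTF-8 RFC 4180 CSV with a header row and columns `acceptedName`,
#' `authority`, `rank`, `phylum`, `class`, `order`, `family`, `genus`,
#' `isMarine`, `synonyms` (pipe-delimited).
#'
#' @param path path to the CSV file.
#' @return a `taxon_backbone`.
#' @export
read_backbone <- function(path) {
  df <- read_csv_utf8(path)
  df$isMarine <- tolower(df$isMarine) %in% c("true", "t", "1", "yes")
  taxon_backbone(df)
}

#' Look up a name in the backbone
#'
#' Matches on the canonical key, so spelling-level variants (diacritics,
#' spacing) of the same name resolve identically. Accepted names shadow
#' synonyms on key collision.
#'
#' @param backbone a `taxon_backbone`.
#' @param name a verbatim scientific name.
#' @return a list with `status` (`"accepted"`, `"synonym"` or `"unknown"`),
#'   `accepted` (the accepted name, or `NA`), and `row` (the backbone row for
#'   the accepted name, or `NULL`).
#' @export
lookup_taxon <- function(backbone, name) {
  stopifnot(inherits(backbone, "taxon_backbone"))
  key <- tryCatch(canonical_key(name), error = function(e) NA_character_)
  if (is.na(key) || !exists(key, envir = backbone$index, inherits = FALSE))
    return(list(status = "unknown", accepted = NA_character_, row = NULL))
  hit <- get(key, envir = backbone$index, inherits = FALSE)
  row_i <- match(hit$accepted, backbone$table$acceptedName)
  list(status = hit$status, accepted = hit$accepted,
       row = backbone$table[row_i, , drop = FALSE])
}

#' @export
print.taxon_backbone <- function(x, ...) {
  n_syn <- sum(lengths(x$table$synonyms))
  cat("<taxon_backbone> ", nrow(x$table), " accepted names, ",
      n_syn, " synonyms, ", sum(x$table$isMarine), " marine\n", sep = "")
  invisible(x)
}
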