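# The occurrence catalogue container: a data.frame of Darwin Core-subset
# records plus an append-only modification log carried as an attribute.
# Every correction the pipeline applies (name resolution, coordinate
# promotion, geo patches, filters) is logged with its justification, so the
# full curation history is reconstructible from the catalogue itself.

CORE_FIELDS <- c("occurrenceID", "datasetID", "sourceCategory",
                 "reportedName", "resolvedName", "taxonRank",
                 "phylum", "class", "order", "family", "genus",
                 "authority", "eventDate",
                 "decimalLatitude", "decimalLongitude",
                 "privateLatitude", "privateLongitude",
                 "coordinateNote", "recordedBy", "basisOfRecord")

NUMERIC_FIELDS <- c("decimalLatitude", "decimalLongitude",
                    "privateLatitude", "privateLongitude")

empty_log <- function() {
  data.frame(stage = character(0), datasetID = character(0),
             occurrenceID = character(0), field = character(0),
             oldValue = character(0), newValue = character(0),
             justification = character(0), stringsAsFactors = FALSE)
}

#' Construct an occurrence catalogue
#'
#' Fills in any missing core fields, coerces coordinate fields to numeric and
#' validates coordinate ranges and occurrenceID uniqueness within each
#' dataset. Extra columns (verbatim or auxiliary fields) are preserved.
#'
#' @param df a data.frame; any subset of the core Darwin Core fields plus
#'   arbitrary extra columns. `occurrenceID`, `datasetID` and `reportedName`
#'   must be present and non-empty.
#' @param log an existing modification log to attach (internal use).
#' @return an object of class `occ_catalogue` (a data.frame).
#' @export
occ_catalogue <- function(df, log = empty_log()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (f in CORE_FIELDS)
    if (is.null(df[[f]]))
      df[[f]] <- if (f %in% NUMERIC_FIELDS) rep(NA_real_, nrow(df))
                 else rep("", nrow(df))
  for (f in NUMERIC_FIELDS)
    df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  df <- df[, c(CORE_FIELDS, setdiff(names(df), CORE_FIELDS)), drop = FALSE]
  rownames(df) <- NULL

  key <- paste(df$datasetID, df$occurrenceID, sep = "\r")
  dup <- unique(df$occurrenceID[duplicated(key)])
  if (length(dup))
    stop("duplicate occurrenceID within a dataset: ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)

  bad_lat <- which(!is.na(df$decimalLatitude) &
                   abs(df$decimalLatitude) > 90)
  bad_lon <- which(!is.na(df$decimalLongitude) &
                   abs(df$decimalLongitude) > 180)
  if (length(bad_lat) || length(bad_lon))
    stop("coordinates out of range for records: ",
         paste(utils::head(df$occurrenceID[union(bad_lat, bad_lon)], 10),
               collapse = ", "), call. = FALSE)

  structure(df, modification_log = log,
            class = c("occ_catalogue", "data.frame"))
}

#' The modification log of a catalogue
#'
#' An append-only table of `(stage, datasetID, occurrenceID, field, oldValue,
#' newValue, justification)` rows, one per field change applied by the
#' pipeline.
#'
#' @param cat an `occ_catalogue`.
#' @return a data.frame.
#' @export
modification_log <- function(cat) {
  attr(cat, "modification_log") %||% empty_log()
}

# Append rows to a catalogue's log. `ids` is a data.frame with datasetID and
# occurrenceID columns aligned with old/new.
append_log <- function(cat, stage, ids, field, old, new, justification) {
  if (!nrow(ids)) return(cat)
  entry <- data.frame(stage = stage, datasetID = ids$datasetID,
                      occurrenceID = ids$occurrenceID, field = field,
                      oldValue = as.character(old), newValue = as.character(new),
                      justification = justification, stringsAsFactors = FALSE)
  attr(cat, "modification_log") <- rbind(modification_log(cat), entry)
  cat
}

# Row-subset a catalogue, keeping the log restricted to surviving records.
cat_subset <- function(cat, idx) {
  df <- as.data.frame(cat, stringsAsFactors = FALSE)[idx, , drop = FALSE]
  rownames(df) <- NULL
  log <- modification_log(cat)
  if (nrow(log)) {
    keep <- paste(df$datasetID, df$occurrenceID, sep = "\r")
    log <- log[paste(log$datasetID, log$occurrenceID, sep = "\r") %in% keep, ,
               drop = FALSE]
    rownames(log) <- NULL
  }
  structure(df, modification_log = log,
            class = c("occ_catalogue", "data.frame"))
}

#' @export
print.occ_catalogue <- function(x, ...) {
  cat("<occ_catalogue> ", nrow(x), " records, ",
      length(unique(x$datasetID)), " dataset(s); ",
      nrow(modification_log(x)), " logged modification(s)\n", sep = "")
  if (nrow(x)) {
    show <- utils::head(as.data.frame(x)[, c("occurrenceID", "datasetID",
      "reportedName", "resolvedName", "decimalLatitude", "decimalLongitude",
      "eventDate")], 6)
    print(show)
    if (nrow(x) > 6) cat("... and ", nrow(x) - 6, " more rows\n", sep = "")
  }
  invisible(x)
}

#' Write a catalogue to Darwin Core CSV
#'
#' Emits UTF-8 RFC 4180 CSV with Darwin Core term headers. `scientificName`
#' carries the resolved name (falling back to the reported name where no
#' resolution applied) and `verbatimIdentification` the as-reported name.
#'
#' @param cat an `occ_catalogue`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_catalogue <- function(cat, path) {
  df <- as.data.frame(cat, stringsAsFactors = FALSE)
  out <- data.frame(
    occurrenceID = df$occurrenceID, datasetID = df$datasetID,
    scientificName = ifelse(nzchar(df$resolvedName), df$resolvedName,
                            df$reportedName),
    verbatimIdentification = df$reportedName,
    scientificNameAuthorship = df$authority, taxonRank = df$taxonRank,
    phylum = df$phylum, class = df$class, order = df$order,
    family = df$family, genus = df$genus,
    decimalLatitude = df$decimalLatitude,
    decimalLongitude = df$decimalLongitude,
    eventDate = df$eventDate, recordedBy = df$recordedBy,
    basisOfRecord = df$basisOfRecord,
    stringsAsFactors = FALSE, check.names = FALSE)
  write_csv_utf8(out, path)
}
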