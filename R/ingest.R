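# Ingest: map heterogeneous source-catalogue columns onto the Darwin Core
# core field subset, assign dataset IDs, merge sources into a master
# catalogue, and filter to the taxa of interest. Column matching is
# deliberately case-sensitive and exact — silent case-folding would hide the
# upstream schema drift this framework exists to surface.

#' Declare how a source catalogue's columns map to the core fields
#'
#' @param datasetID identifier assigned to every record of this source.
#' @param sourceCategory one of `"pmls"`, `"collection"`, `"crowd"`,
#'   `"ecological"`, `"literature"`.
#' @param columnMap named character vector `source column -> core field`
#'   (names are source columns, values are core field names). A mapping to
#'   `reportedName` is mandatory; each core field may be targeted at most
#'   once.
#' @param privateCoordinateColumns optional length-2 character vector naming
#'   the source columns holding obscured latitude and longitude.
#' @param constants optional named list of fixed core-field values applied to
#'   every record (e.g. `basisOfRecord`).
#' @return an object of class `column_mapping`.
#' @export
column_mapping <- function(datasetID, sourceCategory, columnMap,
                           privateCoordinateColumns = NULL,
                           constants = list()) {
  stopifnot(is.character(columnMap), !is.null(names(columnMap)))
  categories <- c("pmls", "collection", "crowd", "ecological", "literature")
  if (!sourceCategory %in% categories)
    stop("sourceCategory must be one of: ", paste(categories, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(columnMap, CORE_FIELDS)
  if (length(bad))
    stop("columnMap targets unknown core fields: ",
         paste(bad, collapse = ", "), call. = FALSE)
  dup <- unique(columnMap[duplicated(columnMap)])
  if (length(dup))
    stop("core field targeted more than once: ",
         paste(dup, collapse = ", "), call. = FALSE)
  if (!"reportedName" %in% columnMap)
    stop("columnMap must target reportedName", call. = FALSE)
  if (!is.null(privateCoordinateColumns))
    stopifnot(length(privateCoordinateColumns) == 2L)
  structure(list(datasetID = datasetID, sourceCategory = sourceCategory,
                 columnMap = columnMap,
                 privateCoordinateColumns = privateCoordinateColumns,
                 constants = constants),
            class = "column_mapping")
}

#' Read a column mapping from a declarative YAML file
#'
#' Keys: `datasetID`, `sourceCategory`, `columnMap` (mapping of source column
#' to core field), optional `privateCoordinateColumns` (list of lat, lon
#' source columns) and `constants`.
#'
#' @param path path to the YAML file.
#' @return a `column_mapping`.
#' @export
read_column_mapping <- function(path) {
  y <- yaml::read_yaml(path)
  column_mapping(
    datasetID = y$datasetID, sourceCategory = y$sourceCategory,
    columnMap = unlist(y$columnMap),
    privateCoordinateColumns =
      if (!is.null(y$privateCoordinateColumns))
        unlist(y$privateCoordinateColumns),
    constants = y$constants %||% list())
}

#' Map a raw source table onto the core field set
#'
#' Produces one record per input row in the input order. Unmapped source
#' columns are preserved verbatim (prefixed `verbatim_`), not dropped.
#' Records without an `occurrenceID` mapping get one synthesised as
#' `datasetID:ordinal`.
#'
#' @param rawTable a data.frame with a header-derived set of columns.
#' @param mapping a [column_mapping()].
#' @return an `occ_catalogue` for this source.
#' @export
map_columns <- function(rawTable, mapping) {
  stopifnot(inherits(mapping, "column_mapping"))
  rawTable <- as.data.frame(rawTable, stringsAsFactors = FALSE)

  need <- names(mapping$columnMap)
  if (!is.null(mapping$privateCoordinateColumns))
    need <- c(need, mapping$privateCoordinateColumns)
  absent <- setdiff(need, names(rawTable))
  if (length(absent))
    stop("mapping names column(s) absent from the table: ",
         paste(absent, collapse = ", "), call. = FALSE)

  n <- nrow(rawTable)
  df <- data.frame(row.names = seq_len(n))
  for (src in names(mapping$columnMap))
    df[[mapping$columnMap[[src]]]] <- as.character(rawTable[[src]])
  if (!is.null(mapping$privateCoordinateColumns)) {
    df$privateLatitude <- rawTable[[mapping$privateCoordinateColumns[1]]]
    df$privateLongitude <- rawTable[[mapping$privateCoordinateColumns[2]]]
  }
  for (f in names(mapping$constants)) df[[f]] <- mapping$constants[[f]]

  df$datasetID <- mapping$datasetID
  df$sourceCategory <- mapping$sourceCategory
  if (is.null(df$occurrenceID) || !any(nzchar(df$occurrenceID)))
    df$occurrenceID <- paste0(mapping$datasetID, ":", seq_len(n))

  unmapped <- setdiff(names(rawTable), need)
  for (col in unmapped)
    df[[paste0("verbatim_", col)]] <- as.character(rawTable[[col]])

  occ_catalogue(df)
}

#' Merge source catalogues into a master catalogue
#'
#' Record count is conserved; records are ordered by `(datasetID, original
#' row order)`; `(datasetID, occurrenceID)` must be unique. Modification logs
#' of the inputs are concatenated.
#'
#' @param catalogues a list of `occ_catalogue` objects.
#' @return the master `occ_catalogue`.
#' @export
merge_catalogues <- function(catalogues) {
  stopifnot(is.list(catalogues))
  catalogues <- Filter(function(x) !is.null(x), catalogues)
  if (!length(catalogues)) return(occ_catalogue(data.frame(
    occurrenceID = character(0), datasetID = character(0),
    reportedName = character(0))))
  for (cc in catalogues) stopifnot(inherits(cc, "occ_catalogue"))

  ids <- vapply(catalogues, function(cc)
    if (nrow(cc)) unique(cc$datasetID)[1] else NA_character_, character(1))
  dup <- unique(ids[!is.na(ids)][duplicated(ids[!is.na(ids)])])
  if (length(dup))
    stop("duplicate datasetID across catalogues: ",
         paste(dup, collapse = ", "), call. = FALSE)

  ord <- order(ids, na.last = TRUE)
  catalogues <- catalogues[ord]
  all_cols <- Reduce(union, lapply(catalogues, names))
  frames <- lapply(catalogues, function(cc) {
    df <- as.data.frame(cc, stringsAsFactors = FALSE)
    for (col in setdiff(all_cols, names(df)))
      df[[col]] <- if (col %in% NUMERIC_FIELDS) NA_real_ else ""
    df[, all_cols, drop = FALSE]
  })
  df <- do.call(rbind, frames)
  log <- do.call(rbind, lapply(catalogues, modification_log))
  occ_catalogue(df, log = log)
}

#' Describe the taxa-of-interest filter
#'
#' The filter is positive-evidence based: a record is excluded only when the
#' backbone affirmatively places its taxon out of scope (non-marine, or in a
#' phylum outside `phyla` when given). Names absent from the backbone are
#' kept and flagged `unresolved` for curator review.
#'
#' @param phyla optional character vector of in-scope phyla; `NULL` means all.
#' @param require_marine exclude taxa whose backbone row has
#'   `isMarine = FALSE`.
#' @return an object of class `taxa_scope`.
#' @export
taxa_scope <- function(phyla = NULL, require_marine = TRUE) {
  structure(list(phyla = phyla, require_marine = require_marine),
            class = "taxa_scope")
}

#' Partition a catalogue into taxa of interest and excluded records
#'
#' @param master an `occ_catalogue` (resolution should already be applied so
#'   preferred names are matched).
#' @param backbone a `taxon_backbone`.
#' @param scope a [taxa_scope()].
#' @return a list with `kept` and `excluded` catalogues;
#'   `nrow(kept) + nrow(excluded) == nrow(master)`. Excluded records carry an
#'   `exclusionRule` column and a log entry; kept records whose name is not
#'   in the backbone carry `taxonFlag == "unresolved"`.
#' @export
filter_taxa_of_interest <- function(master, backbone, scope = taxa_scope()) {
  stopifnot(inherits(master, "occ_catalogue"),
            inherits(backbone, "taxon_backbone"),
            inherits(scope, "taxa_scope"))
  n <- nrow(master)
  rule <- character(n)
  flag <- character(n)
  name <- ifelse(nzchar(master$resolvedName), master$resolvedName,
                 master$reportedName)
  for (key in unique(name)) {
    hit <- lookup_taxon(backbone, key)
    sel <- name == key
    if (hit$status == "unknown") {
      flag[sel] <- "unresolved"
    } else {
      row <- hit$row
      if (scope$require_marine && !isTRUE(row$isMarine))
        rule[sel] <- "not marine"
      else if (!is.null(scope$phyla) && !row$phylum %in% scope$phyla)
        rule[sel] <- "phylum out of scope"
    }
  }

  keep <- !nzchar(rule)
  kept <- cat_subset(master, keep)
  if (any(nzchar(flag[keep]))) {
    kept$taxonFlag <- flag[keep]
  }
  excluded <- cat_subset(master, !keep)
  excluded$exclusionRule <- rule[!keep]
  excluded <- append_log(
    excluded, "taxa_filter",
    as.data.frame(excluded)[, c("datasetID", "occurrenceID")],
    field = "excluded", old = "", new = rule[!keep],
    justification = "taxa-of-interest filter")
  list(kept = kept, excluded = excluded)
}
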