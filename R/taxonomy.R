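# Taxon resolution: the "swaps" lens file mapping reported names to
# preferred names. Rules are explicit and human-authored (typos, synonyms,
# concept changes, misidentifications); applying them never mutates the
# as-reported name, and every change is logged, so the lens can be
# re-applied whenever a source catalogue is refreshed — the institutional
# memory of curation.

RESOLUTION_REASONS <- c("typo", "synonym", "conceptChange", "misidentification")

#' Construct a taxon-resolution table
#'
#' @param df data.frame with columns `reportedName`, `preferredName`,
#'   `reason` (one of `typo`, `synonym`, `conceptChange`,
#'   `misidentification`), `note`, `addedBy`, `dateAdded` and optionally
#'   `datasetID` (a misidentification rule scoped to one source applies only
#'   to that source's records).
#' @return an object of class `taxon_resolution`.
#' @export
taxon_resolution <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("note", "addedBy", "dateAdded", "datasetID"))
    if (is.null(df[[col]])) df[[col]] <- rep("", nrow(df))
  req <- c("reportedName", "preferredName", "reason")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("resolution table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[, c(req, "note", "addedBy", "dateAdded", "datasetID"), drop = FALSE]
  rownames(df) <- NULL

  if (nrow(df)) {
    bad <- setdiff(unique(df$reason), RESOLUTION_REASONS)
    if (length(bad))
      stop("unknown resolution reason(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    dup <- unique(df$reportedName[duplicated(
      paste(df$reportedName, df$datasetID, sep = "\r"))])
    if (length(dup))
      stop("reportedName duplicated in resolution table: ",
           paste(dup, collapse = ", "), call. = FALSE)
    self <- df$reportedName == df$preferredName
    if (any(self))
      stop("rule maps a name to itself: ",
           paste(df$reportedName[self], collapse = ", "), call. = FALSE)
    cyc <- find_resolution_cycle(df)
    if (!is.null(cyc))
      stop("cycle in resolution table: ", paste(cyc, collapse = " -> "),
           call. = FALSE)
  }
  structure(df, class = c("taxon_resolution", "data.frame"))
}

# Detect a cycle in the reportedName -> preferredName graph (ignoring
# dataset scoping, which can only remove edges). Returns the cycle path or
# NULL.
find_resolution_cycle <- function(df) {
  nxt <- stats::setNames(df$preferredName, df$reportedName)
  for (start in df$reportedName) {
    seen <- character(0)
    cur <- start
    while (cur %in% names(nxt)) {
      if (cur %in% seen)
        return(c(seen[which(seen == cur):length(seen)], cur))
      seen <- c(seen, cur)
      cur <- nxt[[cur]]
    }
  }
  NULL
}

#' Read a taxon-resolution table from CSV
#'
#' Columns: `reportedName`, `preferredName`, `reason`, `note`, `addedBy`,
#' `dateAdded`, optional `datasetID`. Fails at load on cycles, duplicate
#' reported names or self-maps.
#'
#' @param path path to the CSV.
#' @return a `taxon_resolution`.
#' @export
read_resolution_table <- function(path) taxon_resolution(read_csv_utf8(path))

#' @export
print.taxon_resolution <- function(x, ...) {
  cat("<taxon_resolution> ", nrow(x), " rule(s)\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x)[, 1:3], 8))
  invisible(x)
}

# Resolve one name through the rule chain. Verbatim rules fire first; if no
# verbatim rule applies, a canonical-key rule may. Scoped rules fire only for
# their datasetID. Chains are followed transitively to the terminal name.
resolve_chain <- function(name, datasetID, verb_global, verb_scoped,
                          key_global, key_scoped, max_chain) {
  path <- name
  cur <- name
  repeat {
    nxt <- verb_scoped[[paste(datasetID, cur, sep = "\r")]] %||%
      verb_global[[cur]]
    if (is.null(nxt)) {
      key <- tryCatch(canonical_key(cur), error = function(e) NULL)
      if (!is.null(key))
        nxt <- key_scoped[[paste(datasetID, key, sep = "\r")]] %||%
          key_global[[key]]
    }
    if (is.null(nxt) || nxt == cur) return(cur)
    path <- c(path, nxt)
    if (length(path) > max_chain)
      stop("resolution chain exceeds ", max_chain, " steps (suspected data ",
           "error): ", paste(utils::head(path, 6), collapse = " -> "),
           " ...", call. = FALSE)
    cur <- nxt
  }
}

#' Apply the taxon-resolution lens to a catalogue
#'
#' Sets each record's `resolvedName` to the terminal name of the rule chain
#' starting from its `reportedName` (rules are followed transitively);
#' records with no applicable rule get `resolvedName == reportedName`.
#' Verbatim-string rules take precedence over canonical-key rules, and rules
#' scoped to a `datasetID` apply only to that source. The operation is
#' idempotent and never alters `reportedName`.
#'
#' @param master an `occ_catalogue`.
#' @param table a `taxon_resolution`.
#' @param max_chain chain-length bound; a longer chain is treated as a data
#'   error.
#' @return a list with `catalogue` (the resolved catalogue) and `log` (a
#'   data.frame of `occurrenceID`, `datasetID`, `reportedName`,
#'   `resolvedName`, `reason` for every changed record).
#' @export
apply_taxon_resolution <- function(master, table, max_chain = 20L) {
  stopifnot(inherits(master, "occ_catalogue"),
            inherits(table, "taxon_resolution"))
  df <- as.data.frame(master, stringsAsFactors = FALSE)

  verb_global <- list(); verb_scoped <- list()
  key_global <- list(); key_scoped <- list()
  reason_of <- list()
  if (nrow(table)) for (i in seq_len(nrow(table))) {
    rn <- table$reportedName[i]; pn <- table$preferredName[i]
    key <- tryCatch(canonical_key(rn), error = function(e) NULL)
    if (nzchar(table$datasetID[i])) {
      verb_scoped[[paste(table$datasetID[i], rn, sep = "\r")]] <- pn
      if (!is.null(key))
        key_scoped[[paste(table$datasetID[i], key, sep = "\r")]] <- pn
    } else {
      verb_global[[rn]] <- pn
      if (!is.null(key)) key_global[[key]] <- pn
    }
    reason_of[[paste(rn, pn, sep = "\r")]] <- table$reason[i]
  }

  # Resolve each distinct (datasetID, reportedName) pair once.
  pair <- paste(df$datasetID, df$reportedName, sep = "\r")
  resolved <- character(nrow(df))
  for (p in unique(pair)) {
    sel <- pair == p
    dsid <- df$datasetID[sel][1]
    nm <- df$reportedName[sel][1]
    resolved[sel] <- resolve_chain(nm, dsid, verb_global, verb_scoped,
                                   key_global, key_scoped, max_chain)
  }

  changed <- resolved != df$reportedName & nzchar(df$reportedName)
  old_resolved <- df$resolvedName
  df$resolvedName <- resolved
  out <- occ_catalogue(df, log = modification_log(master))

  reasons <- vapply(which(changed), function(i) {
    reason_of[[paste(df$reportedName[i], resolved[i], sep = "\r")]] %||%
      "chain"
  }, character(1))
  log <- data.frame(
    occurrenceID = df$occurrenceID[changed],
    datasetID = df$datasetID[changed],
    reportedName = df$reportedName[changed],
    resolvedName = resolved[changed],
    reason = if (any(changed)) reasons else character(0),
    stringsAsFactors = FALSE)

  newly <- changed & (old_resolved != resolved)
  out <- append_log(out, "taxon_resolution",
                    df[newly, c("datasetID", "occurrenceID"), drop = FALSE],
                    field = "resolvedName",
                    old = old_resolved[newly], new = resolved[newly],
                    justification = "taxon resolution lens")
  list(catalogue = out, log = log)
}

#' Validate resolved names and authorities against the backbone
#'
#' Classifies every distinct resolved taxon as `accepted`,
#' `synonymOfAccepted` (with a pointer to the accepted name) or `unknown`,
#' and attaches the [match_authority()] verdict for its claimed authority.
#' The report lists unknowns for curator action; nothing is auto-corrected.
#'
#' @param x an `occ_catalogue` or a `taxon_summaries` data.frame.
#' @param backbone a `taxon_backbone`.
#' @return a data.frame with one row per distinct resolved taxon: `name`,
#'   `status`, `acceptedName`, `claimedAuthority`, `backboneAuthority`,
#'   `authorityCheck`.
#' @export
validate_against_backbone <- function(x, backbone) {
  stopifnot(inherits(backbone, "taxon_backbone"))
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  rn <- df$resolvedName %||% rep("", nrow(df))
  rep_n <- df$reportedName %||% rep("", nrow(df))
  name <- ifelse(nzchar(rn), rn, rep_n)
  auth <- df$authority %||% rep("", nrow(df))
  first <- !duplicated(name)
  names_u <- name[first]
  auth_u <- auth[first]

  rows <- lapply(seq_along(names_u), function(i) {
    hit <- lookup_taxon(backbone, names_u[i])
    status <- switch(hit$status, accepted = "accepted",
                     synonym = "synonymOfAccepted", "unknown")
    bb_auth <- if (!is.null(hit$row)) hit$row$authority else ""
    data.frame(name = names_u[i], status = status,
               acceptedName = hit$accepted %||% NA_character_,
               claimedAuthority = auth_u[i], backboneAuthority = bb_auth,
               authorityCheck = if (status == "unknown") "missing"
                                else match_authority(auth_u[i], bb_auth),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
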