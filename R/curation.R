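# Expert curation round-trip: the filtered master catalogue is summarised to
# one row per distinct taxon, split into per-phylum sheets for subject-matter
# experts, re-integrated after editing, diffed against the pre-curation
# summary, and the whole pipeline iterated until a pass raises no further
# discrepancies. The transport (live spreadsheets in real use) is a detail;
# the semantics are the diff/reconcile loop, so the curation step is a
# pluggable function.

SHEET_EDITABLE <- c("preferredName", "authority", "editReason", "curationNote")
SHEET_KEY <- "resolvedName"

#' Summarise a catalogue to one row per distinct taxon
#'
#' Groups records by the canonical key of their resolved name (reported name
#' where no resolution applied). Record counts over the summaries sum to the
#' catalogue size.
#'
#' @param master an `occ_catalogue`, normally the inside partition after
#'   resolution, georeferencing and area filtering.
#' @param backbone optional `taxon_backbone`; when given, each summary gets a
#'   `validationStatus` from [validate_against_backbone()].
#' @return a data.frame of class `taxon_summaries`: columns `taxonKey`,
#'   `resolvedName`, `genus`, `epithet`, `qualifier`, `authority`,
#'   `taxonRank`, `phylum`, `class`, `order`, `family`,
#'   `reportingDatasetIDs` and `reportingCategories` (semicolon-joined sorted
#'   sets), `recordCount`, `firstDate`, `lastDate`, `curationNote`,
#'   `validationStatus`.
#' @export
summarize_taxa <- function(master, backbone = NULL) {
  stopifnot(inherits(master, "occ_catalogue"))
  df <- as.data.frame(master, stringsAsFactors = FALSE)
  name <- ifelse(nzchar(df$resolvedName), df$resolvedName, df$reportedName)
  keys <- vapply(name, function(n) canonical_key(n), character(1),
                 USE.NAMES = FALSE)

  first_nonempty <- function(x) {
    x <- x[nzchar(x)]
    if (length(x)) x[1] else ""
  }
  groups <- split(seq_len(nrow(df)), keys)
  # preserve first-appearance order of taxa
  groups <- groups[order(vapply(groups, min, integer(1)))]

  rows <- lapply(groups, function(idx) {
    nm <- first_nonempty(name[idx])
    p <- parse_scientific_name(nm)
    dates <- df$eventDate[idx][nzchar(df$eventDate[idx])]
    data.frame(
      taxonKey = canonical_key(p),
      resolvedName = nm,
      genus = p$genus, epithet = p$epithet, qualifier = p$qualifier,
      authority = first_nonempty(c(df$authority[idx], p$authority)),
      taxonRank = first_nonempty(df$taxonRank[idx]),
      phylum = first_nonempty(df$phylum[idx]),
      class = first_nonempty(df$class[idx]),
      order = first_nonempty(df$order[idx]),
      family = first_nonempty(df$family[idx]),
      reportingDatasetIDs = join_set(df$datasetID[idx]),
      reportingCategories = join_set(df$sourceCategory[idx]),
      recordCount = length(idx),
      firstDate = if (length(dates)) min(dates) else "",
      lastDate = if (length(dates)) max(dates) else "",
      curationNote = "",
      validationStatus = "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(
    taxonKey = character(0), resolvedName = character(0),
    genus = character(0), epithet = character(0), qualifier = character(0),
    authority = character(0), taxonRank = character(0),
    phylum = character(0), class = character(0), order = character(0),
    family = character(0), reportingDatasetIDs = character(0),
    reportingCategories = character(0), recordCount = integer(0),
    firstDate = character(0), lastDate = character(0),
    curationNote = character(0), validationStatus = character(0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL

  if (!is.null(backbone)) {
    report <- validate_against_backbone(out, backbone)
    out$validationStatus <- report$status[match(out$resolvedName, report$name)]
  }
  class(out) <- c("taxon_summaries", "data.frame")
  out
}

#' Split summaries into per-phylum expert sheets
#'
#' Each sheet partitions the summaries; summaries without a phylum go to the
#' `incertae` sheet. Within a sheet, rows are ordered by classification then
#' name. Sheets carry the editable columns `preferredName` (initialised to
#' the resolved name), `authority`, `editReason` and `curationNote`; all
#' other columns are computed and ignored on re-import.
#'
#' @param summaries a `taxon_summaries` data.frame.
#' @return a named list of sheet data.frames, one per phylum.
#' @export
split_by_phylum <- function(summaries) {
  df <- as.data.frame(summaries, stringsAsFactors = FALSE)
  phylum <- ifelse(nzchar(df$phylum), df$phylum, "incertae")
  df$preferredName <- df$resolvedName
  df$editReason <- ""
  cols <- c(SHEET_KEY, SHEET_EDITABLE,
            setdiff(names(df), c(SHEET_KEY, SHEET_EDITABLE)))
  df <- df[, cols, drop = FALSE]
  sheets <- split(df, phylum)
  lapply(sheets, function(s) {
    s <- s[order(s$class, s$order, s$family, s$genus, s$resolvedName), ,
           drop = FALSE]
    rownames(s) <- NULL
    s
  })
}

#' Write expert sheets to a directory of CSV files
#'
#' One UTF-8 CSV per phylum; a leading comment line documents which columns
#' are editable versus computed.
#'
#' @param sheets named list from [split_by_phylum()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sheets <- function(sheets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ph in names(sheets))
    write_csv_utf8(sheets[[ph]], file.path(dir, paste0(ph, ".csv")),
                   comment = paste0("editable columns: ",
                                    paste(SHEET_EDITABLE, collapse = ", "),
                                    "; all other columns are computed"))
  invisible(dir)
}

#' Read expert sheets back from a directory
#'
#' @param dir directory of per-phylum CSVs written by [write_sheets()].
#' @return a named list of sheet data.frames.
#' @export
read_sheets <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  sheets <- lapply(files, function(f) {
    s <- read_csv_utf8(f)
    s$recordCount <- as.integer(s$recordCount)
    s
  })
  stats::setNames(sheets, sub("\\.csv$", "", basename(files)))
}

#' Re-integrate edited expert sheets
#'
#' The key column (`resolvedName`) must be intact: a deleted or duplicated
#' key row fails naming the sheet and row. Edits to `preferredName` are
#' returned as proposed taxon-resolution rows (and reflected in the
#' re-integrated summaries); a rename without an `editReason` is an error.
#' Edits to `authority` and `curationNote` update the summaries directly.
#' Edits to computed columns are ignored.
#'
#' @param sheets named list of (possibly edited) sheets.
#' @param summaries the `taxon_summaries` the sheets were split from.
#' @param addedBy attribution recorded on proposed resolution rows.
#' @param dateAdded date recorded on proposed rows (empty by default so that
#'   pipeline outputs are deterministic; pass a date in interactive use).
#' @return a list with `summaries` (updated `taxon_summaries`) and
#'   `proposals` (a `taxon_resolution` of proposed rows, possibly empty).
#' @export
reintegrate_sheets <- function(sheets, summaries, addedBy = "curation",
                               dateAdded = "") {
  df <- as.data.frame(summaries, stringsAsFactors = FALSE)
  expected <- split_by_phylum(summaries)

  proposals <- list()
  for (ph in names(expected)) {
    sheet <- sheets[[ph]]
    if (is.null(sheet))
      stop("missing sheet on re-integration: ", ph, call. = FALSE)
    exp_keys <- sort(expected[[ph]][[SHEET_KEY]])
    got_keys <- sheet[[SHEET_KEY]]
    dup <- unique(got_keys[duplicated(got_keys)])
    if (length(dup))
      stop("sheet ", sQuote(ph), ": duplicated key row(s): ",
           paste(dup, collapse = ", "), call. = FALSE)
    gone <- setdiff(exp_keys, got_keys)
    extra <- setdiff(got_keys, exp_keys)
    if (length(gone) || length(extra))
      stop("sheet ", sQuote(ph), ": key column altered (",
           if (length(gone)) paste("deleted:", paste(gone, collapse = ", ")),
           if (length(gone) && length(extra)) "; ",
           if (length(extra)) paste("added:", paste(extra, collapse = ", ")),
           ")", call. = FALSE)

    pos <- match(sheet[[SHEET_KEY]], df$resolvedName)
    renamed <- sheet$preferredName != sheet[[SHEET_KEY]]
    if (any(renamed & !nzchar(trimws(sheet$editReason))))
      stop("sheet ", sQuote(ph), ": rename without a reason code for: ",
           paste(sheet[[SHEET_KEY]][renamed & !nzchar(trimws(sheet$editReason))],
                 collapse = ", "), call. = FALSE)
    if (any(renamed))
      proposals[[ph]] <- data.frame(
        reportedName = sheet[[SHEET_KEY]][renamed],
        preferredName = sheet$preferredName[renamed],
        reason = sheet$editReason[renamed],
        note = sheet$curationNote[renamed],
        addedBy = addedBy, dateAdded = dateAdded, datasetID = "",
        stringsAsFactors = FALSE)

    df$authority[pos] <- sheet$authority
    df$curationNote[pos] <- sheet$curationNote
    df$resolvedName[pos] <- sheet$preferredName
  }

  changed <- df$resolvedName != summaries$resolvedName
  if (any(changed)) {
    df$taxonKey[changed] <- vapply(df$resolvedName[changed], canonical_key,
                                   character(1), USE.NAMES = FALSE)
    parsed <- lapply(df$resolvedName[changed], parse_scientific_name)
    df$genus[changed] <- vapply(parsed, `[[`, character(1), "genus")
    df$epithet[changed] <- vapply(parsed, `[[`, character(1), "epithet")
    df$qualifier[changed] <- vapply(parsed, `[[`, character(1), "qualifier")
  }
  class(df) <- c("taxon_summaries", "data.frame")
  props <- if (length(proposals)) do.call(rbind, proposals)
           else data.frame(reportedName = character(0),
                           preferredName = character(0),
                           reason = character(0), note = character(0),
                           addedBy = character(0), dateAdded = character(0),
                           datasetID = character(0), stringsAsFactors = FALSE)
  rownames(props) <- NULL
  list(summaries = df, proposals = taxon_resolution(props))
}

#' Diff two taxon-summary sets
#'
#' Semantic comparison by canonical taxon key, ignoring row order and
#' computed columns. A removed key and an added key with the same record
#' signature (reporting datasets, record count, date span) are reported as a
#' single `renamedTaxon`; same-key differences in authority or curation note
#' are `changedAuthority`/`changedNote`. The report is empty iff the two
#' summary sets are semantically identical.
#'
#' @param a,b `taxon_summaries` data.frames.
#' @return a data.frame of class `summary_diff` with columns `kind`, `key`,
#'   `before`, `after`, `sheet`.
#' @export
diff_summaries <- function(a, b) {
  a <- as.data.frame(a, stringsAsFactors = FALSE)
  b <- as.data.frame(b, stringsAsFactors = FALSE)
  entries <- list()
  add <- function(kind, key, before, after, sheet)
    entries[[length(entries) + 1L]] <<- data.frame(
      kind = kind, key = key, before = before, after = after, sheet = sheet,
      stringsAsFactors = FALSE)

  common <- intersect(a$taxonKey, b$taxonKey)
  ia <- match(common, a$taxonKey); ib <- match(common, b$taxonKey)
  for (j in seq_along(common)) {
    if (!identical(a$authority[ia[j]], b$authority[ib[j]]))
      add("changedAuthority", common[j], a$authority[ia[j]],
          b$authority[ib[j]], b$phylum[ib[j]])
    if (!identical(a$curationNote[ia[j]], b$curationNote[ib[j]]))
      add("changedNote", common[j], a$curationNote[ia[j]],
          b$curationNote[ib[j]], b$phylum[ib[j]])
  }

  sig <- function(df, i) paste(df$reportingDatasetIDs[i], df$recordCount[i],
                               df$firstDate[i], df$lastDate[i], sep = "\r")
  removed <- setdiff(a$taxonKey, b$taxonKey)
  added <- setdiff(b$taxonKey, a$taxonKey)
  rem_i <- match(removed, a$taxonKey)
  add_i <- match(added, b$taxonKey)
  rem_sig <- vapply(rem_i, function(i) sig(a, i), character(1))
  add_sig <- vapply(add_i, function(i) sig(b, i), character(1))
  used_added <- logical(length(added))
  for (j in seq_along(removed)) {
    hits <- which(add_sig == rem_sig[j] & !used_added)
    if (length(hits) == 1L && sum(rem_sig == rem_sig[j]) == 1L) {
      used_added[hits] <- TRUE
      add("renamedTaxon", removed[j], a$resolvedName[rem_i[j]],
          b$resolvedName[add_i[hits]], b$phylum[add_i[hits]])
    } else {
      add("removedTaxon", removed[j], a$resolvedName[rem_i[j]], "",
          a$phylum[rem_i[j]])
    }
  }
  for (j in which(!used_added))
    add("addedTaxon", added[j], "", b$resolvedName[add_i[j]],
        b$phylum[add_i[j]])

  out <- if (length(entries)) do.call(rbind, entries)
         else data.frame(kind = character(0), key = character(0),
                         before = character(0), after = character(0),
                         sheet = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("summary_diff", "data.frame")
  out
}

#' @export
print.summary_diff <- function(x, ...) {
  if (!nrow(x)) cat("<summary_diff> no discrepancies\n")
  else {
    cat("<summary_diff> ", nrow(x), " discrepanc",
        if (nrow(x) == 1) "y" else "ies", "\n", sep = "")
    print(as.data.frame(x))
  }
  invisible(x)
}

#' Run the curation pipeline to a fixed point
#'
#' One pass applies the resolution lens, the taxa-of-interest filter,
#' coordinate promotion, geo patches and the area filter, summarises the
#' inside partition, splits it into expert sheets, applies the curation
#' function, re-integrates, and diffs the re-integrated summaries against
#' the pre-curation summaries. Proposed resolutions are folded into the
#' resolution table and the pass repeats until the diff is empty. The
#' resolution table only grows; a proposal whose addition would create a
#' cycle is refused with a warning (and the loop, by construction, fails at
#' `max_iter` if the editor keeps oscillating).
#'
#' @param sources list of mapped source `occ_catalogue`s (or a single master
#'   catalogue).
#' @param resolution a `taxon_resolution` (may be empty).
#' @param patches a `geo_patches` table (may be empty).
#' @param area a `project_area`.
#' @param backbone a `taxon_backbone`.
#' @param curation_fun `NULL` for no edits, or `function(sheets, iteration)`
#'   returning edited sheets (a scripted stand-in for the expert round-trip).
#' @param scope a [taxa_scope()].
#' @param max_iter maximum number of passes before failing loudly with the
#'   residual diff.
#' @return a list with `catalogue` (final inside partition), `summaries`,
#'   `iterations`, `history` (list of `summary_diff`s, one per pass),
#'   `resolution` (the grown resolution table) and `partitions` (record
#'   counts inside/outside/noCoordinates of the final pass).
#' @export
run_to_fixed_point <- function(sources, resolution, patches, area, backbone,
                               curation_fun = NULL, scope = taxa_scope(),
                               max_iter = 10L) {
  stopifnot(max_iter >= 1L)
  master0 <- if (inherits(sources, "occ_catalogue")) sources
             else merge_catalogues(sources)
  history <- list()

  for (iter in seq_len(max_iter)) {
    res <- apply_taxon_resolution(master0, resolution)
    kept <- filter_taxa_of_interest(res$catalogue, backbone, scope)$kept
    kept <- promote_private_coordinates(kept)
    patched <- apply_geo_patches(kept, patches)$catalogue
    parts <- filter_by_area(patched, area)
    summaries <- summarize_taxa(parts$inside, backbone = backbone)

    sheets <- split_by_phylum(summaries)
    edited <- if (is.null(curation_fun)) sheets
              else curation_fun(sheets, iter)
    ri <- reintegrate_sheets(edited, summaries)
    d <- diff_summaries(summaries, ri$summaries)
    history[[iter]] <- d

    if (!nrow(d))
      return(list(catalogue = parts$inside, summaries = summaries,
                  iterations = iter, history = history,
                  resolution = resolution,
                  partitions = c(inside = nrow(parts$inside),
                                 outside = nrow(parts$outside),
                                 noCoordinates = nrow(parts$noCoordinates))))

    if (nrow(ri$proposals)) {
      candidate <- rbind(as.data.frame(resolution),
                        as.data.frame(ri$proposals))
      candidate <- candidate[!duplicated(
        paste(candidate$reportedName, candidate$datasetID, sep = "\r")), ,
        drop = FALSE]
      grown <- tryCatch(taxon_resolution(candidate), error = function(e) e)
      if (inherits(grown, "error")) {
        warning("refusing curation proposal(s) that would corrupt the ",
                "resolution table: ", conditionMessage(grown), call. = FALSE)
      } else {
        resolution <- grown
      }
    }
  }

  residual <- history[[length(history)]]
  stop("no fixed point after ", max_iter, " iteration(s); ",
       nrow(residual), " residual discrepanc",
       if (nrow(residual) == 1) "y" else "ies", ":\n",
       paste(utils::capture.output(print(as.data.frame(residual))),
             collapse = "\n"), call. = FALSE)
}
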