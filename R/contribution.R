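# Source-contribution analysis: how much does each kind of sampling effort
# (systematic dive surveys, museum collections, crowd-sourced observations,
# ecological surveys, literature reports) add to the cumulative species
# list? A taxon reported by exactly one source category is an exclusive
# ("novel") report; taxa reported by two or more categories are shared.
# Percentages and 1:n ratios are integer-rounded half away from zero.

SOURCE_CATEGORIES <- c("pmls", "collection", "crowd", "ecological",
                       "literature")

#' The default display grouping of source categories
#'
#' Maps each source category to the display group used for percentages and
#' ratios: `pmls -> PMLS`, `collection -> Collections`, `crowd -> Crowd`,
#' and `ecological`/`literature` combined into `Other`.
#'
#' @param map named character vector `category -> display group`; must map
#'   every category it is used with.
#' @return an object of class `display_grouping` (a named character vector).
#' @export
display_grouping <- function(map = c(pmls = "PMLS", collection = "Collections",
                                     crowd = "Crowd", ecological = "Other",
                                     literature = "Other")) {
  stopifnot(is.character(map), !is.null(names(map)))
  structure(map, class = "display_grouping")
}

categories_of <- function(summaries)
  lapply(summaries$reportingCategories, split_set)

#' Per-source record, taxon and exclusive-report tallies
#'
#' @param summaries a `taxon_summaries` data.frame.
#' @param master the `occ_catalogue` the summaries were computed from.
#' @return a data.frame with one row per source category present: `category`,
#'   `recordCount`, `taxonCount` (taxa whose reporting categories include
#'   the category), `exclusiveCount` (taxa reported by that category alone).
#' @export
tally_sources <- function(summaries, master) {
  stopifnot(inherits(master, "occ_catalogue"))
  cats <- categories_of(summaries)
  present <- sort(unique(c(unlist(cats), master$sourceCategory)))
  present <- present[nzchar(present)]
  rec <- table(factor(master$sourceCategory, levels = present))
  out <- data.frame(
    category = present,
    recordCount = as.integer(rec[present]),
    taxonCount = vapply(present, function(cc)
      sum(vapply(cats, function(s) cc %in% s, logical(1))), integer(1)),
    exclusiveCount = vapply(present, function(cc)
      sum(vapply(cats, function(s) identical(s, cc), logical(1))),
      integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify taxa as source-exclusive or shared
#'
#' A taxon is exclusive to a category iff that category is the only one
#' reporting it; shared iff two or more categories report it. Exclusives
#' plus shared always partition the taxon list.
#'
#' @param summaries a `taxon_summaries` data.frame with non-empty
#'   `reportingCategories`.
#' @return a list with `exclusive` (named integer vector per category),
#'   `shared` (count of taxa in >= 2 categories) and `total`.
#' @export
classify_exclusive_shared <- function(summaries) {
  cats <- categories_of(summaries)
  if (any(lengths(cats) == 0L))
    stop("summaries with empty reportingCategories", call. = FALSE)
  n_cat <- lengths(cats)
  excl_cat <- unlist(cats[n_cat == 1L])
  present <- sort(unique(unlist(cats)))
  exclusive <- vapply(present, function(cc) sum(excl_cat == cc), integer(1))
  list(exclusive = exclusive, shared = sum(n_cat >= 2L),
       total = length(cats))
}

#' Grouped novelty percentages
#'
#' Groups per-category exclusive counts by display group and expresses each
#' group as an integer percentage of all exclusive reports, rounded half
#' away from zero.
#'
#' @param exclusive named integer vector of exclusive counts per category.
#' @param grouping a [display_grouping()]; categories may also be left
#'   ungrouped by passing an identity mapping.
#' @return named integer vector of percentages per display group, in
#'   first-appearance order of the grouping.
#' @export
#' @examples
#' novelty_percentages(
#'   c(pmls = 241, collection = 77, ecological = 11, literature = 2,
#'     crowd = 72))
novelty_percentages <- function(exclusive, grouping = display_grouping()) {
  total <- sum(exclusive)
  if (total <= 0) stop("no exclusive reports to percentage", call. = FALSE)
  unmapped <- setdiff(names(exclusive), names(grouping))
  if (length(unmapped))
    stop("grouping does not map categor(ies): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  groups <- unique(unname(grouping[names(exclusive)]))
  grouped <- vapply(groups, function(g)
    sum(exclusive[names(exclusive)[grouping[names(exclusive)] == g]]),
    numeric(1))
  stats::setNames(round_half_away(100 * grouped / total), groups)
}

#' Records per novel report (the "n" in a 1:n ratio)
#'
#' How many occurrence records a source contributes per taxon it alone
#' reports. Lower is a more "efficient" source of novelty.
#'
#' @param recordCount,exclusiveCount integer vectors (recycled to equal
#'   length); `exclusiveCount` must be positive.
#' @return integer vector, `recordCount / exclusiveCount` rounded half away
#'   from zero.
#' @export
#' @examples
#' records_per_novel_ratio(16150, 241) # 1:67
#' records_per_novel_ratio(272, 77)    # 1:4
records_per_novel_ratio <- function(recordCount, exclusiveCount) {
  if (any(exclusiveCount <= 0))
    stop("ratio undefined for zero exclusive reports", call. = FALSE)
  round_half_away(recordCount / exclusiveCount)
}

#' Distinct classification counts within a phylum
#'
#' Counts distinct non-empty classes, orders, families and genera among a
#' phylum's species-rank summaries, plus the species count itself — the
#' checklist-header style "c classes: o orders: g genera: s species".
#'
#' @param summaries a `taxon_summaries` data.frame.
#' @param phylum phylum name.
#' @return named integer vector `classes`, `orders`, `families`, `genera`,
#'   `species`.
#' @export
classification_counts <- function(summaries, phylum) {
  df <- as.data.frame(summaries, stringsAsFactors = FALSE)
  sel <- df$phylum == phylum &
    (df$taxonRank %in% c("species", "") | !nzchar(df$taxonRank))
  df <- df[sel, , drop = FALSE]
  n_distinct <- function(x) length(unique(x[nzchar(x)]))
  c(classes = n_distinct(df$class), orders = n_distinct(df$order),
    families = n_distinct(df$family), genera = n_distinct(df$genus),
    species = nrow(df))
}

#' Full contribution statistics for a curated catalogue
#'
#' @param summaries a `taxon_summaries` data.frame.
#' @param master the `occ_catalogue` behind the summaries.
#' @param grouping a [display_grouping()].
#' @return an object of class `contribution_stats`: `perSource` (data.frame
#'   from [tally_sources()]), `sharedCount`, `totalTaxa`, `totalRecords`,
#'   `groupedPercentages` and `ratios` (named integer vectors per display
#'   group; ratios use group-summed records and exclusives).
#' @export
contribution_stats <- function(summaries, master,
                               grouping = display_grouping()) {
  per <- tally_sources(summaries, master)
  cls <- classify_exclusive_shared(summaries)
  exclusive <- cls$exclusive
  pct <- novelty_percentages(exclusive, grouping)

  groups <- names(pct)
  grp_records <- vapply(groups, function(g)
    sum(per$recordCount[grouping[per$category] == g]), numeric(1))
  grp_excl <- vapply(groups, function(g)
    sum(exclusive[grouping[names(exclusive)] == g]), numeric(1))
  ratios <- stats::setNames(
    records_per_novel_ratio(grp_records[grp_excl > 0], grp_excl[grp_excl > 0]),
    groups[grp_excl > 0])

  structure(list(perSource = per, sharedCount = cls$shared,
                 totalTaxa = cls$total, totalRecords = nrow(master),
                 groupedPercentages = pct, ratios = ratios,
                 grouping = grouping),
            class = "contribution_stats")
}

#' @export
print.contribution_stats <- function(x, ...) {
  cat("<contribution_stats> ", x$totalRecords, " records, ", x$totalTaxa,
      " taxa (", sum(x$perSource$exclusiveCount), " exclusive + ",
      x$sharedCount, " shared)\n", sep = "")
  print(x$perSource)
  cat("novelty percentages: ",
      paste(names(x$groupedPercentages), x$groupedPercentages, sep = " ",
            collapse = ", "), "\n", sep = "")
  cat("records per novel report: ",
      paste0(names(x$ratios), " 1:", x$ratios, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Write contribution statistics to CSV and JSON
#'
#' @param stats a `contribution_stats`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return `stats`, invisibly.
#' @export
write_contribution_stats <- function(stats, csv_path = NULL,
                                     json_path = NULL) {
  stopifnot(inherits(stats, "contribution_stats"))
  if (!is.null(csv_path)) {
    groups <- names(stats$groupedPercentages)
    df <- data.frame(
      displayGroup = groups,
      recordCount = vapply(groups, function(g) sum(
        stats$perSource$recordCount[
          stats$grouping[stats$perSource$category] == g]), numeric(1)),
      exclusiveCount = vapply(groups, function(g) sum(
        stats$perSource$exclusiveCount[
          stats$grouping[stats$perSource$category] == g]), numeric(1)),
      percentNovel = as.integer(stats$groupedPercentages[groups]),
      recordsPerNovel = as.integer(stats$ratios[groups]),
      stringsAsFactors = FALSE)
    write_csv_utf8(df, csv_path)
  }
  if (!is.null(json_path))
    jsonlite::write_json(
      list(perSource = stats$perSource, sharedCount = stats$sharedCount,
           totalTaxa = stats$totalTaxa, totalRecords = stats$totalRecords,
           groupedPercentages = as.list(stats$groupedPercentages),
           ratios = as.list(stats$ratios)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stats)
}
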