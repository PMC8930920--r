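# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths for the quantities
# they check.

# Winding-number point-in-polygon oracle (nonzero rule; for simple polygons
# away from the boundary it agrees with the even-odd rule).
winding_inside <- function(px, py, ring) {
  wn <- 0L
  n <- nrow(ring) - 1L
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    if (y1 <= py) {
      if (y2 > py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) > 0)
        wn <- wn + 1L
    } else {
      if (y2 <= py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) < 0)
        wn <- wn - 1L
    }
  }
  wn != 0L
}

# Star-shaped simple polygon with `n` vertices around (cx, cy).
random_simple_polygon <- function(n = 12L, cx = 0, cy = 0) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  rad <- stats::runif(n, 0.5, 1.5)
  ring <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
  rbind(ring, ring[1, ])
}

# Brute-force taxon resolution by exhaustive chain walking over verbatim
# rules only.
brute_resolve <- function(name, reported, preferred, cap = 1000L) {
  cur <- name
  for (i in seq_len(cap)) {
    j <- match(cur, reported)
    if (is.na(j)) return(cur)
    cur <- preferred[j]
  }
  stop("brute_resolve: no terminal after ", cap, " steps")
}

# Random acyclic resolution table over a pool of generated names; rules map
# earlier pool entries to strictly later ones, so acyclicity is structural.
random_acyclic_rules <- function(n_rules, pool_size = n_rules * 2L) {
  pool <- character(0)
  while (length(pool) < pool_size) {
    nm <- paste0(sample(LETTERS, 1),
                 paste(sample(letters, 6, TRUE), collapse = ""), " ",
                 paste(sample(letters, 7, TRUE), collapse = ""))
    if (!nm %in% pool) pool <- c(pool, nm)
  }
  from <- sample(seq_len(pool_size - 1L), n_rules)
  to <- vapply(from, function(i) sample((i + 1L):pool_size, 1L), integer(1))
  data.frame(reportedName = pool[from], preferredName = pool[to],
             reason = "synonym", stringsAsFactors = FALSE)
}

# Minimal catalogue builder.
toy_catalogue <- function(n, datasetID = "TOY", category = "pmls",
                          names = sprintf("Genusa species%d", seq_len(n)),
                          lat = rep(48.9, n), lon = rep(-123.4, n),
                          dates = rep("2020-06-01", n), ...) {
  occ_catalogue(data.frame(
    occurrenceID = sprintf("%s-%d", datasetID, seq_len(n)),
    datasetID = rep(datasetID, n),
    sourceCategory = rep(category, n), reportedName = names,
    decimalLatitude = lat, decimalLongitude = lon, eventDate = dates,
    ..., stringsAsFactors = FALSE))
}

# Build summaries straight from a category-membership list (taxon name ->
# character vector of categories) without running the pipeline, for
# contribution-module oracle comparisons.
summaries_from_membership <- function(membership) {
  df <- data.frame(
    taxonKey = tolower(names(membership)),
    resolvedName = names(membership),
    genus = vapply(strsplit(names(membership), " "), `[`, character(1), 1),
    epithet = "", qualifier = "none", authority = "", taxonRank = "species",
    phylum = "Mollusca", class = "Gastropoda", order = "Nudibranchia",
    family = "Facelinidae",
    reportingDatasetIDs = vapply(membership, paste, character(1),
                                 collapse = ";"),
    reportingCategories = vapply(membership, function(m)
      paste(sort(unique(m)), collapse = ";"), character(1)),
    recordCount = 1L, firstDate = "", lastDate = "", curationNote = "",
    validationStatus = "", stringsAsFactors = FALSE)
  class(df) <- c("taxon_summaries", "data.frame")
  df
}

# Record-level view of a catalogue: the modification log is append-only by
# design, so "identical catalogue" assertions compare the record table.
plain_df <- function(x) {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  attr(df, "modification_log") <- NULL
  class(df) <- "data.frame"
  rownames(df) <- NULL
  df
}

# Plain CSV reader (all-character) for re-ingesting written fixtures.
read_csv_utf8_test <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                  check.names = FALSE, colClasses = "character",
                  comment.char = "#", na.strings = "")

# A tiny all-marine backbone covering the given names.
toy_backbone <- function(names, isMarine = TRUE, phylum = "Mollusca",
                         synonyms = rep("", length(names))) {
  genus <- vapply(strsplit(names, " "), `[`, character(1), 1)
  taxon_backbone(data.frame(
    acceptedName = names, authority = "(Toy, 1900)", rank = "species",
    phylum = phylum, class = "Gastropoda", order = "Nudibranchia",
    family = paste0(genus, "idae"), genus = genus,
    isMarine = isMarine, synonyms = synonyms, stringsAsFactors = FALSE))
}
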