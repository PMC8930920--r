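# Synthetic fixture generation. Emulates a five-source occurrence dataset —
# a systematic dive survey, museum voucher collections, crowd-sourced
# observations, an ecological (ROV) survey and a small literature source —
# with controlled exclusive/shared taxon structure, injected single-character
# name typos matched by a known resolution table, injected coordinate errors
# matched by a known patch table, out-of-area and coordinate-free records,
# and obscured (private) coordinates on crowd records. Taxon names come from
# a Latin-like CV-syllable grammar so no real nomenclature is shipped.
# Ground truth for every downstream statistic is recorded at generation time
# by direct enumeration, independently of the pipeline's code paths.

FIXTURE_PHYLA <- c("Porifera", "Cnidaria", "Annelida", "Mollusca",
                   "Arthropoda", "Echinodermata", "Chordata", "Bryozoa")

#' Default synthetic project area
#'
#' An irregular hexagon (synthetic; roughly island-scale, ~0.35 x 0.23
#' degrees) in the northeast Pacific used by the fixture generator.
#'
#' @return a `project_area`.
#' @export
default_project_area <- function() {
  project_area(list(cbind(
    lon = c(-123.60, -123.45, -123.25, -123.22, -123.45, -123.62),
    lat = c(48.85, 48.80, 48.88, 49.00, 49.03, 48.97))),
    name = "synthetic island waters")
}

#' Fixture generator configuration
#'
#' Defaults emulate the five-source structure of a community-integrated
#' marine checklist at one-tenth scale: exclusive taxa per category
#' (24, 8, 1, 1, 7), 26 shared taxa (67 taxa in all) and roughly 2,000
#' records distributed as (1615, 27, 84, 3, 275) across the pmls,
#' collection, ecological, literature and crowd categories. Each
#' (source, taxon) pair gets at least one record, so a source's record count
#' is never below its taxon count.
#'
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @param exclusive named integer vector of source-exclusive taxon targets
#'   per category.
#' @param shared number of taxa reported by two or more categories.
#' @param records_target named integer vector of per-category record-count
#'   targets.
#' @param typo_rate probability a record reports a typo form of its name.
#' @param coord_error_rate probability a record's published coordinates are
#'   wrong (to be corrected by the patch table).
#' @param out_of_area_rate probability a record genuinely lies outside the
#'   project area.
#' @param missing_coord_rate probability a record has no coordinates.
#' @param private_coord_rate probability a crowd record carries obscured
#'   public coordinates plus precise private ones.
#' @param area a `project_area`.
#' @return an object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           exclusive = c(pmls = 24L, collection = 8L,
                                         ecological = 1L, literature = 1L,
                                         crowd = 7L),
                           shared = 26L,
                           records_target = c(pmls = 1615L, collection = 27L,
                                              ecological = 84L,
                                              literature = 3L, crowd = 275L),
                           typo_rate = 0.05, coord_error_rate = 0.02,
                           out_of_area_rate = 0.02,
                           missing_coord_rate = 0.02,
                           private_coord_rate = 0.3,
                           area = default_project_area()) {
  rates <- c(typo_rate, coord_error_rate, out_of_area_rate,
             missing_coord_rate, private_coord_rate)
  stopifnot(all(rates >= 0 & rates <= 1), shared >= 0, all(exclusive >= 0),
            inherits(area, "project_area"),
            setequal(names(exclusive), names(records_target)))
  if (shared > 0 && length(exclusive) < 2L)
    stop("shared taxa require at least two source categories", call. = FALSE)
  if (sum(exclusive) + shared < 1L)
    stop("fixture must contain at least one taxon", call. = FALSE)
  structure(list(seed = as.integer(seed), exclusive = exclusive,
                 shared = as.integer(shared),
                 records_target = records_target, typo_rate = typo_rate,
                 coord_error_rate = coord_error_rate,
                 out_of_area_rate = out_of_area_rate,
                 missing_coord_rate = missing_coord_rate,
                 private_coord_rate = private_coord_rate, area = area),
            class = "fixture_config")
}

# Latin-like name grammar: CV syllables, capitalised genus.
syllable <- function(n) {
  cons <- c("b", "c", "d", "g", "l", "m", "n", "p", "r", "s", "t", "th", "v")
  vow <- c("a", "e", "i", "o", "u")
  paste0(sample(cons, n, replace = TRUE), sample(vow, n, replace = TRUE),
         collapse = "")
}
make_word <- function(min_syl = 3L, max_syl = 4L)
  syllable(sample(min_syl:max_syl, 1L))
capitalize <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

bbox_of <- function(area) {
  all_v <- do.call(rbind, area$rings)
  list(lon = range(all_v[, 1]), lat = range(all_v[, 2]))
}

sample_point_inside <- function(area, bb) {
  repeat {
    lon <- stats::runif(1, bb$lon[1], bb$lon[2])
    lat <- stats::runif(1, bb$lat[1], bb$lat[2])
    if (isTRUE(point_in_area(lat, lon, area))) return(c(lat = lat, lon = lon))
  }
}

# A point guaranteed outside: reflect an inside point beyond the bbox edge.
sample_point_outside <- function(area, bb) {
  p <- sample_point_inside(area, bb)
  side <- sample(4L, 1L)
  off <- stats::runif(1, 0.05, 0.4)
  lon <- p["lon"]; lat <- p["lat"]
  if (side == 1L) lon <- bb$lon[2] + off
  else if (side == 2L) lon <- bb$lon[1] - off
  else if (side == 3L) lat <- bb$lat[2] + off
  else lat <- bb$lat[1] - off
  c(lat = unname(lat), lon = unname(lon))
}

# Single-character epithet edit giving a canonical key not present in `taken`.
make_typo <- function(name, taken) {
  repeat {
    chars <- strsplit(name, "")[[1]]
    cand_pos <- which(grepl("[a-z]", chars))
    i <- sample(cand_pos, 1L)
    repl <- sample(setdiff(letters, chars[i]), 1L)
    chars[i] <- repl
    typo <- paste(chars, collapse = "")
    key <- tryCatch(canonical_key(typo), error = function(e) NULL)
    if (!is.null(key) && !key %in% taken) return(typo)
  }
}

#' Generate a synthetic multi-source fixture with ground truth
#'
#' Deterministic under the config seed. The injected typos are exactly the
#' domain of the returned resolution table, the injected coordinate errors
#' exactly the domain of the patch table, and the expected statistics are
#' computed by direct enumeration ([oracle_stats()]) at generation time.
#'
#' @param config a [fixture_config()].
#' @return a list with `sources` (named list of `occ_catalogue`s, one per
#'   category; each carries auxiliary ground-truth columns `trueTaxon` and
#'   `trueInside`), `backbone` (a `taxon_backbone` covering all true taxa
#'   plus non-marine decoys), and `truth`: `taxa` (data.frame of true taxa
#'   with classification and reporting categories), `resolution`
#'   (`taxon_resolution` of injected typos), `patches` (`geo_patches` of
#'   injected coordinate errors), `expected_partition` (named counts
#'   inside/outside/noCoordinates), `expected_stats` (from [oracle_stats()])
#'   and `area`.
#' @export
generate_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  categories <- names(config$exclusive)
  n_taxa <- sum(config$exclusive) + config$shared
  area <- config$area
  bb <- bbox_of(area)

  # --- taxon pool with classification -------------------------------------
  genera <- character(0); epithets <- character(0)
  while (length(genera) < n_taxa) {
    g <- capitalize(make_word())
    e <- make_word()
    if (!paste(g, e) %in% paste(genera, epithets)) {
      genera <- c(genera, g); epithets <- c(epithets, e)
    }
  }
  name <- paste(genera, epithets)
  phylum <- sample(FIXTURE_PHYLA, n_taxa, replace = TRUE)
  cls <- paste0(capitalize(substr(phylum, 1, 4)),
                sample(c("oida", "acea", "omorpha"), n_taxa, replace = TRUE))
  ord <- paste0(capitalize(vapply(seq_len(n_taxa), function(i)
    make_word(2L, 3L), character(1))), "ida")
  fam <- paste0(genera, "idae")
  authority <- paste0(capitalize(vapply(seq_len(n_taxa), function(i)
    make_word(2L, 3L), character(1))), ", ", sample(1850:2015, n_taxa,
                                                    replace = TRUE))
  authority <- ifelse(stats::runif(n_taxa) < 0.5,
                      paste0("(", authority, ")"), authority)

  # --- membership: which categories report which taxon --------------------
  membership <- vector("list", n_taxa)
  i <- 0L
  for (cc in categories) {
    k <- config$exclusive[[cc]]
    if (k > 0L) for (j in seq_len(k)) {
      i <- i + 1L
      membership[[i]] <- cc
    }
  }
  if (config$shared > 0L) for (j in seq_len(config$shared)) {
    i <- i + 1L
    max_size <- min(5L, length(categories))
    size <- if (max_size == 2L) 2L else
      sample(2:max_size, 1L,
             prob = c(0.55, 0.25, 0.15, 0.05)[seq_len(max_size - 1L)])
    membership[[i]] <- sort(sample(categories, size))
  }

  taxa <- data.frame(name = name, genus = genera, epithet = epithets,
                     authority = authority, rank = "species",
                     phylum = phylum, class = cls, order = ord, family = fam,
                     categories = vapply(membership, paste, character(1),
                                         collapse = ";"),
                     stringsAsFactors = FALSE)

  # --- backbone: all true taxa marine, plus non-marine decoys -------------
  n_decoy <- 3L
  decoy_g <- vapply(seq_len(n_decoy), function(i)
    capitalize(make_word()), character(1))
  decoy <- data.frame(
    acceptedName = paste(decoy_g, "fluviatilis"),
    authority = "Decoy, 1900", rank = "species", phylum = "Chordata",
    class = "Actinopteri", order = "Decoyiformes",
    family = paste0(decoy_g, "idae"), genus = decoy_g,
    isMarine = FALSE, synonyms = "", stringsAsFactors = FALSE)
  backbone <- taxon_backbone(rbind(
    data.frame(acceptedName = taxa$name, authority = taxa$authority,
               rank = taxa$rank, phylum = taxa$phylum, class = taxa$class,
               order = taxa$order, family = taxa$family, genus = taxa$genus,
               isMarine = TRUE, synonyms = "", stringsAsFactors = FALSE),
    decoy))

  # --- records ------------------------------------------------------------
  dataset_of <- stats::setNames(
    paste0(toupper(categories), "-SRC"), categories)
  observers <- vapply(1:12, function(i)
    paste(capitalize(make_word(2L, 3L)), capitalize(make_word(2L, 3L))),
    character(1))
  taken_keys <- vapply(taxa$name, function(n) canonical_key(n), character(1))
  typo_of <- list()           # taxon name -> its (single) typo form
  patch_rows <- list()
  sources <- list()

  for (cc in categories) {
    members <- which(vapply(membership, function(m) cc %in% m, logical(1)))
    if (!length(members)) next
    target <- config$records_target[[cc]]
    n_extra <- max(0L, target - length(members))
    extra <- if (n_extra > 0L)
      as.integer(stats::rmultinom(1, n_extra,
                                  rep(1, length(members))))
    else rep(0L, length(members))
    counts <- 1L + extra
    tax_idx <- rep(members, counts)
    n_rec <- length(tax_idx)
    dsid <- dataset_of[[cc]]

    lat <- numeric(n_rec); lon <- numeric(n_rec)
    plat <- rep(NA_real_, n_rec); plon <- rep(NA_real_, n_rec)
    reported <- taxa$name[tax_idx]
    inside_flag <- logical(n_rec); outside_flag <- logical(n_rec)
    missing_flag <- logical(n_rec)
    coord_note <- character(n_rec)

    for (r in seq_len(n_rec)) {
      oid <- paste0(dsid, "-", r)
      if (stats::runif(1) < config$out_of_area_rate) {
        p <- sample_point_outside(area, bb)
        lat[r] <- p["lat"]; lon[r] <- p["lon"]
        outside_flag[r] <- TRUE
      } else if (stats::runif(1) < config$missing_coord_rate) {
        lat[r] <- NA_real_; lon[r] <- NA_real_
        missing_flag[r] <- TRUE
        coord_note[r] <- "no coordinates in source"
      } else {
        p <- sample_point_inside(area, bb)
        true_lat <- p["lat"]; true_lon <- p["lon"]
        inside_flag[r] <- TRUE
        if (stats::runif(1) < config$coord_error_rate) {
          # published coordinates are wrong; the patch restores the truth
          lat[r] <- true_lat + stats::runif(1, 0.5, 1.5) *
            sample(c(-1, 1), 1)
          lon[r] <- true_lon + stats::runif(1, 0.5, 1.5) *
            sample(c(-1, 1), 1)
          patch_rows[[length(patch_rows) + 1L]] <- data.frame(
            datasetID = dsid, occurrenceID = oid,
            newLatitude = unname(true_lat), newLongitude = unname(true_lon),
            note = "injected georeferencing error (synthetic)",
            stringsAsFactors = FALSE)
        } else if (cc == "crowd" &&
                   stats::runif(1) < config$private_coord_rate) {
          plat[r] <- true_lat; plon[r] <- true_lon
          lat[r] <- round(true_lat, 1); lon[r] <- round(true_lon, 1)
          coord_note[r] <- "coordinates obscured; precise values private"
        } else {
          lat[r] <- true_lat; lon[r] <- true_lon
        }
      }
      if (stats::runif(1) < config$typo_rate) {
        nm <- taxa$name[tax_idx[r]]
        if (is.null(typo_of[[nm]])) {
          typo_of[[nm]] <- make_typo(nm, taken_keys)
          taken_keys <- c(taken_keys, canonical_key(typo_of[[nm]]))
        }
        reported[r] <- typo_of[[nm]]
      }
    }

    dates <- sprintf("%04d-%02d-%02d", sample(1980:2021, n_rec, TRUE),
                     sample(1:12, n_rec, TRUE), sample(1:28, n_rec, TRUE))
    df <- data.frame(
      occurrenceID = paste0(dsid, "-", seq_len(n_rec)),
      datasetID = dsid, sourceCategory = cc,
      reportedName = reported, taxonRank = "species",
      phylum = taxa$phylum[tax_idx], class = taxa$class[tax_idx],
      order = taxa$order[tax_idx], family = taxa$family[tax_idx],
      genus = taxa$genus[tax_idx], authority = taxa$authority[tax_idx],
      eventDate = dates, decimalLatitude = lat, decimalLongitude = lon,
      privateLatitude = plat, privateLongitude = plon,
      coordinateNote = coord_note,
      recordedBy = sample(observers, n_rec, TRUE),
      basisOfRecord = switch(cc, collection = "PreservedSpecimen",
                             literature = "MaterialCitation",
                             "HumanObservation"),
      trueTaxon = taxa$name[tax_idx],
      trueInside = inside_flag,
      stringsAsFactors = FALSE)
    sources[[cc]] <- occ_catalogue(df)
  }

  resolution <- taxon_resolution(if (length(typo_of)) data.frame(
    reportedName = unlist(typo_of, use.names = FALSE),
    preferredName = names(typo_of), reason = "typo",
    note = "injected single-character typo (synthetic)",
    addedBy = "generator", dateAdded = "", datasetID = "",
    stringsAsFactors = FALSE)
  else data.frame(reportedName = character(0),
                  preferredName = character(0), reason = character(0),
                  stringsAsFactors = FALSE))
  patches <- geo_patches(if (length(patch_rows)) do.call(rbind, patch_rows)
                         else data.frame(datasetID = character(0),
                                         occurrenceID = character(0),
                                         newLatitude = numeric(0),
                                         newLongitude = numeric(0),
                                         note = character(0),
                                         stringsAsFactors = FALSE))

  all_rec <- do.call(rbind, lapply(sources, function(s)
    as.data.frame(s)[, c("sourceCategory", "trueTaxon", "trueInside",
                         "decimalLatitude")]))
  expected_partition <- c(
    inside = sum(all_rec$trueInside),
    outside = sum(!all_rec$trueInside & !is.na(all_rec$decimalLatitude)),
    noCoordinates = sum(is.na(all_rec$decimalLatitude)))
  expected_stats <- oracle_stats(sources)

  list(sources = sources, backbone = backbone,
       truth = list(taxa = taxa, resolution = resolution, patches = patches,
                    expected_partition = expected_partition,
                    expected_stats = expected_stats, area = area))
}

#' Brute-force contribution statistics from ground-truth labels
#'
#' Enumerates, independently of every pipeline code path, the per-category
#' record and taxon tallies and the exclusive/shared classification over the
#' records whose true location is inside the project area (the auxiliary
#' `trueTaxon`/`trueInside` columns written by [generate_fixture()]).
#'
#' @param sources named list of generated `occ_catalogue`s carrying
#'   `trueTaxon` and `trueInside` columns.
#' @return a list with `perSource` (data.frame `category`, `recordCount`,
#'   `taxonCount`, `exclusiveCount`), `exclusive` (named vector), `shared`,
#'   `totalTaxa`, `totalRecords`.
#' @export
oracle_stats <- function(sources) {
  recs <- do.call(rbind, lapply(sources, function(s) {
    df <- as.data.frame(s, stringsAsFactors = FALSE)
    stopifnot(!is.null(df$trueTaxon), !is.null(df$trueInside))
    df[df$trueInside %in% TRUE, c("sourceCategory", "trueTaxon"),
       drop = FALSE]
  }))
  cats <- sort(unique(recs$sourceCategory))
  taxa <- unique(recs$trueTaxon)
  cat_sets <- lapply(taxa, function(tx)
    sort(unique(recs$sourceCategory[recs$trueTaxon == tx])))
  per <- data.frame(
    category = cats,
    recordCount = vapply(cats, function(cc)
      sum(recs$sourceCategory == cc), integer(1)),
    taxonCount = vapply(cats, function(cc)
      sum(vapply(cat_sets, function(s) cc %in% s, logical(1))), integer(1)),
    exclusiveCount = vapply(cats, function(cc)
      sum(vapply(cat_sets, function(s) identical(s, cc), logical(1))),
      integer(1)),
    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  list(perSource = per,
       exclusive = stats::setNames(per$exclusiveCount, per$category),
       shared = sum(lengths(cat_sets) >= 2L),
       totalTaxa = length(taxa), totalRecords = nrow(recs))
}

#' Write a generated fixture to a directory of plain-text files
#'
#' Writes one raw CSV per source (with mildly heterogeneous column names and
#' a matching YAML column mapping, so the ingest stage is exercised end to
#' end), plus the backbone CSV, resolution CSV, patch CSV, the project-area
#' GeoJSON and a ground-truth JSON.
#'
#' @param fixture result of [generate_fixture()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  raw_names <- c(occurrenceID = "id", reportedName = "taxon_name",
                 decimalLatitude = "latitude", decimalLongitude = "longitude",
                 eventDate = "date_observed", recordedBy = "observer",
                 taxonRank = "rank", phylum = "phylum", class = "class",
                 order = "order", family = "family", genus = "genus",
                 authority = "authority", coordinateNote = "coord_note")
  for (cc in names(fixture$sources)) {
    src <- as.data.frame(fixture$sources[[cc]], stringsAsFactors = FALSE)
    raw <- src[, names(raw_names)]
    names(raw) <- unname(raw_names)
    has_private <- cc == "crowd"
    if (has_private) {
      raw$private_latitude <- src$privateLatitude
      raw$private_longitude <- src$privateLongitude
    }
    write_csv_utf8(raw, file.path(dir, paste0(cc, ".csv")))
    mapping <- list(
      datasetID = unique(src$datasetID), sourceCategory = cc,
      columnMap = as.list(stats::setNames(names(raw_names),
                                          unname(raw_names))),
      constants = list(basisOfRecord = unique(src$basisOfRecord)))
    if (has_private)
      mapping$privateCoordinateColumns <-
        list("private_latitude", "private_longitude")
    yaml::write_yaml(mapping, file.path(dir, paste0(cc, ".mapping.yml")))
  }
  bb <- fixture$backbone$table
  bb$synonyms <- vapply(bb$synonyms, paste, character(1), collapse = "|")
  write_csv_utf8(bb, file.path(dir, "backbone.csv"))
  write_csv_utf8(as.data.frame(fixture$truth$resolution),
                 file.path(dir, "resolution.csv"))
  write_csv_utf8(as.data.frame(fixture$truth$patches),
                 file.path(dir, "patches.csv"))
  ring <- fixture$truth$area$rings[[1]]
  jsonlite::write_json(list(
    type = "Feature",
    properties = list(name = fixture$truth$area$name),
    geometry = list(type = "Polygon",
                    coordinates = list(lapply(seq_len(nrow(ring)),
                                              function(i) ring[i, ])))),
    file.path(dir, "area.geojson"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    expected_partition = as.list(fixture$truth$expected_partition),
    expected_stats = fixture$truth$expected_stats,
    taxa = fixture$truth$taxa),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
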