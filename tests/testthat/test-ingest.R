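test_that("column mapping populates core fields row by row", {
  raw <- data.frame(species = c("Aeolidia papillosa", "Hermissenda crassicornis",
                                "Doris montereyensis"),
                    lat = c(48.91, 48.92, 48.93), lon = c(-123.4, -123.41, -123.42),
                    date = c("2019-05-01", "2019-05-02", "2019-05-03"),
                    diver = c("DG", "CG", "AL"), stringsAsFactors = FALSE)
  mapping <- column_mapping("DIVES", "pmls",
                            c(species = "reportedName", lat = "decimalLatitude",
                              lon = "decimalLongitude", date = "eventDate"))
  cat <- map_columns(raw, mapping)
  expect_s3_class(cat, "occ_catalogue")
  expect_equal(nrow(cat), 3L)
  expect_equal(cat$reportedName, raw$species)
  expect_equal(cat$decimalLatitude, raw$lat)
  expect_equal(cat$eventDate, raw$date)
  expect_equal(cat$datasetID, rep("DIVES", 3))
  # synthesized occurrenceIDs are datasetID + ordinal
  expect_equal(cat$occurrenceID, c("DIVES:1", "DIVES:2", "DIVES:3"))
  # unmapped columns are preserved, not dropped
  expect_equal(cat$verbatim_diver, raw$diver)
})

test_that("identity mapping of an already-core table is byte-faithful", {
  raw <- data.frame(occurrenceID = c("a", "b"), reportedName = c("X y", "Z w"),
                    eventDate = c("2001", "2002-03"), stringsAsFactors = FALSE)
  mapping <- column_mapping("ID1", "collection",
                            c(occurrenceID = "occurrenceID",
                              reportedName = "reportedName",
                              eventDate = "eventDate"))
  cat <- map_columns(raw, mapping)
  expect_identical(cat$occurrenceID, raw$occurrenceID)
  expect_identical(cat$reportedName, raw$reportedName)
  expect_identical(cat$eventDate, raw$eventDate)
})

test_that("column matching is case-sensitive and fails naming the column", {
  raw <- data.frame(species = "A b", stringsAsFactors = FALSE)
  mapping <- column_mapping("D", "crowd", c(Species = "reportedName"))
  expect_error(map_columns(raw, mapping), "Species")
})

test_that("mapping validation rejects bad maps", {
  expect_error(column_mapping("D", "crowd", c(a = "decimalLatitude")),
               "reportedName")
  expect_error(column_mapping("D", "crowd",
                              c(a = "reportedName", b = "reportedName")),
               "more than once")
  expect_error(column_mapping("D", "bogus", c(a = "reportedName")),
               "sourceCategory")
  expect_error(column_mapping("D", "crowd", c(a = "notAField")), "unknown")
})

test_that("duplicate occurrenceIDs within a catalogue fail listing them", {
  raw <- data.frame(occurrenceID = c("x", "x"), sp = c("A b", "C d"),
                    stringsAsFactors = FALSE)
  mapping <- column_mapping("D", "crowd", c(occurrenceID = "occurrenceID",
                                            sp = "reportedName"))
  expect_error(map_columns(raw, mapping), "duplicate occurrenceID.*x")
})

test_that("merging conserves record counts and orders by dataset", {
  cats <- list(toy_catalogue(5, "B"), toy_catalogue(3, "A"),
               toy_catalogue(2, "C"))
  m <- merge_catalogues(cats)
  expect_equal(nrow(m), 10L)
  expect_equal(unique(m$datasetID), c("A", "B", "C"))
  expect_error(merge_catalogues(list(toy_catalogue(2, "A"),
                                     toy_catalogue(2, "A"))),
               "duplicate datasetID")
  # an empty catalogue contributes nothing and raises no error
  m2 <- merge_catalogues(c(cats, list(toy_catalogue(0, "Z"))))
  expect_equal(nrow(m2), 10L)
})

test_that("a five-source miniature merges to the expected total", {
  sizes <- c(pmls = 161, collection = 3, ecological = 8, literature = 1,
             crowd = 27)
  cats <- lapply(names(sizes), function(cc)
    toy_catalogue(sizes[[cc]], toupper(cc), category = cc))
  expect_equal(nrow(merge_catalogues(cats)), 200L)
})

test_that("merging is associative up to record order", {
  a <- toy_catalogue(4, "A"); b <- toy_catalogue(3, "B")
  c3 <- toy_catalogue(5, "C")
  key <- function(m) sort(paste(m$datasetID, m$occurrenceID))
  expect_equal(key(merge_catalogues(list(merge_catalogues(list(a, b)), c3))),
               key(merge_catalogues(list(a, merge_catalogues(list(b, c3))))))
})

test_that("ingest is deterministic on identical inputs", {
  raw <- data.frame(sp = c("A b", "C d"), stringsAsFactors = FALSE)
  mapping <- column_mapping("D", "crowd", c(sp = "reportedName"))
  expect_identical(plain_df(map_columns(raw, mapping)),
                   plain_df(map_columns(raw, mapping)))
})

test_that("taxa filter excludes only on positive backbone evidence", {
  bb <- toy_backbone(c("Marina salsa", "Dulcis aqua"),
                     isMarine = c(TRUE, FALSE))
  cat <- toy_catalogue(3, names = c("Marina salsa", "Dulcis aqua",
                                    "Ignota incognita"))
  parts <- filter_taxa_of_interest(cat, bb)
  expect_equal(nrow(parts$kept) + nrow(parts$excluded), 3L)
  expect_equal(parts$excluded$reportedName, "Dulcis aqua")
  expect_equal(parts$excluded$exclusionRule, "not marine")
  # unknown names are kept and flagged for curators
  unknown <- parts$kept[parts$kept$reportedName == "Ignota incognita", ]
  expect_equal(unknown$taxonFlag, "unresolved")
  # the exclusion is logged
  log <- modification_log(parts$excluded)
  expect_true(any(log$stage == "taxa_filter"))
})

test_that("an all-marine catalogue passes the taxa filter untouched", {
  bb <- toy_backbone(c("Marina salsa", "Pelagia nota"))
  cat <- toy_catalogue(4, names = rep(c("Marina salsa", "Pelagia nota"), 2))
  parts <- filter_taxa_of_interest(cat, bb)
  expect_equal(nrow(parts$excluded), 0L)
  expect_equal(nrow(parts$kept), 4L)
})

test_that("phylum scoping excludes out-of-scope phyla", {
  bb <- toy_backbone(c("Marina salsa", "Aves volans"))
  bb$table$phylum[2] <- "Chordata"
  bb <- taxon_backbone(bb$table)
  cat <- toy_catalogue(2, names = c("Marina salsa", "Aves volans"))
  parts <- filter_taxa_of_interest(cat, bb, taxa_scope(phyla = "Mollusca"))
  expect_equal(parts$excluded$exclusionRule, "phylum out of scope")
})

test_that("taxa-filter partition conserves arbitrary random inputs", {
  set.seed(99)
  bb <- toy_backbone(paste("Gena", paste0("sp", 1:10)),
                     isMarine = rep(c(TRUE, FALSE), 5))
  for (i in 1:20) {
    n <- sample(1:40, 1)
    cat <- toy_catalogue(n, names = sample(
      c(paste("Gena", paste0("sp", 1:10)), "Alia res"), n, TRUE))
    parts <- filter_taxa_of_interest(cat, bb)
    expect_equal(nrow(parts$kept) + nrow(parts$excluded), n)
  }
})
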