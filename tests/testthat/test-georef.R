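unit_square <- project_area(list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))

test_that("private coordinates overwrite the principal fields and are logged", {
  cat <- occ_catalogue(data.frame(
    occurrenceID = "c-1", datasetID = "CROWD", sourceCategory = "crowd",
    reportedName = "Obscura cauta", decimalLatitude = 48.90,
    decimalLongitude = -123.40, privateLatitude = 48.9236,
    privateLongitude = -123.4415, stringsAsFactors = FALSE))
  out <- promote_private_coordinates(cat)
  expect_equal(out$decimalLatitude, 48.9236)
  expect_equal(out$decimalLongitude, -123.4415)
  log <- modification_log(out)
  expect_equal(log$stage, "coordinate_promotion")
  expect_match(log$oldValue, "48.9")
})

test_that("records without private fields pass through identically", {
  cat <- toy_catalogue(2)
  expect_identical(plain_df(promote_private_coordinates(cat)),
                   plain_df(cat))
})

test_that("out-of-range private coordinates fail naming the record", {
  cat <- occ_catalogue(data.frame(
    occurrenceID = "bad-1", datasetID = "D", sourceCategory = "crowd",
    reportedName = "A b", privateLatitude = 95.0, privateLongitude = -123.4,
    stringsAsFactors = FALSE))
  expect_error(promote_private_coordinates(cat), "bad-1")
})

test_that("geo patches apply with notes, log originals, and invert exactly", {
  cat <- toy_catalogue(3, lat = c(49.00, 48.95, 48.90),
                       lon = c(-123.00, -123.10, -123.20))
  patches <- geo_patches(data.frame(
    datasetID = "TOY", occurrenceID = "TOY-1", newLatitude = 48.92,
    newLongitude = -123.44, note = "historical locality refined",
    stringsAsFactors = FALSE))
  out <- apply_geo_patches(cat, patches)
  expect_equal(out$catalogue$decimalLatitude[1], 48.92)
  expect_equal(out$patchLog$oldLatitude, 49.00)
  expect_equal(out$patchLog$note, "historical locality refined")
  log <- modification_log(out$catalogue)
  expect_true(any(log$stage == "geo_patch" & grepl("49", log$oldValue)))

  restored <- invert_geo_patches(out$catalogue, out$patchLog)
  expect_equal(as.data.frame(restored)[, c("decimalLatitude", "decimalLongitude")],
               as.data.frame(cat)[, c("decimalLatitude", "decimalLongitude")])
})

test_that("patch validation and orphan patches fail loudly", {
  expect_error(geo_patches(data.frame(
    datasetID = "D", occurrenceID = "x", newLatitude = 91,
    newLongitude = 0, note = "n", stringsAsFactors = FALSE)), "range")
  expect_error(geo_patches(data.frame(
    datasetID = "D", occurrenceID = "x", newLatitude = 10,
    newLongitude = 0, note = " ", stringsAsFactors = FALSE)),
    "justification")
  cat <- toy_catalogue(2)
  orphan <- geo_patches(data.frame(
    datasetID = "TOY", occurrenceID = "TOY-99", newLatitude = 48,
    newLongitude = -123, note = "n", stringsAsFactors = FALSE))
  expect_error(apply_geo_patches(cat, orphan), "TOY/TOY-99")
})

test_that("an empty patch table leaves the master unchanged", {
  cat <- toy_catalogue(4)
  empty <- geo_patches(data.frame(datasetID = character(0),
                                  occurrenceID = character(0),
                                  newLatitude = numeric(0),
                                  newLongitude = numeric(0),
                                  note = character(0)))
  out <- apply_geo_patches(cat, empty)
  expect_identical(plain_df(out$catalogue), plain_df(cat))
  expect_identical(plain_df(invert_geo_patches(out$catalogue,
                                                    out$patchLog)),
                   plain_df(cat))
})

test_that("patching is idempotent and reversibility holds under randomness", {
  set.seed(77)
  for (trial in 1:3) {
    n <- 500L
    cat <- toy_catalogue(n, lat = round(stats::runif(n, 48, 50), 4),
                         lon = round(stats::runif(n, -124, -122), 4))
    idx <- sample(n, 100L)
    patches <- geo_patches(data.frame(
      datasetID = "TOY", occurrenceID = paste0("TOY-", idx),
      newLatitude = round(stats::runif(100, 48, 50), 4),
      newLongitude = round(stats::runif(100, -124, -122), 4),
      note = "randomized correction", stringsAsFactors = FALSE))
    once <- apply_geo_patches(cat, patches)
    twice <- apply_geo_patches(once$catalogue, patches)
    expect_identical(plain_df(twice$catalogue),
                     plain_df(once$catalogue))
    back <- invert_geo_patches(once$catalogue, once$patchLog)
    expect_identical(plain_df(back), plain_df(cat))
  }
})

test_that("inverting against a drifted catalogue fails", {
  cat <- toy_catalogue(2, lat = c(48.5, 48.6), lon = c(-123.5, -123.6))
  patches <- geo_patches(data.frame(
    datasetID = "TOY", occurrenceID = "TOY-1", newLatitude = 48.9,
    newLongitude = -123.9, note = "n", stringsAsFactors = FALSE))
  out <- apply_geo_patches(cat, patches)
  drifted <- out$catalogue
  drifted$decimalLatitude[1] <- 40
  drifted <- occ_catalogue(as.data.frame(drifted))
  expect_error(invert_geo_patches(drifted, out$patchLog), "match")
})

test_that("point-in-area follows the even-odd rule with inclusive boundary", {
  expect_true(point_in_area(0.5, 0.5, unit_square))
  expect_false(point_in_area(2, 2, unit_square))
  # boundary and vertex points count as inside
  expect_true(point_in_area(0, 0.5, unit_square))
  expect_true(point_in_area(1, 1, unit_square))
  # NA coordinates propagate
  expect_true(is.na(point_in_area(NA, 0.5, unit_square)))
  # degenerate rings are rejected at load
  expect_error(project_area(list(cbind(c(0, 1), c(0, 1)))), "degenerate")
})

test_that("a polygon with a hole excludes the hole by the even-odd rule", {
  donut <- project_area(list(
    cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)),
    cbind(c(1, 3, 3, 1), c(1, 1, 3, 3))))
  expect_true(point_in_area(0.5, 0.5, donut))
  expect_false(point_in_area(2, 2, donut))
})

test_that("point-in-area agrees with a winding-number oracle", {
  set.seed(2024)
  for (trial in 1:4) {
    ring <- random_simple_polygon(12L)
    area <- project_area(list(ring))
    px <- stats::runif(500, -2, 2)
    py <- stats::runif(500, -2, 2)
    got <- point_in_area(py, px, area)
    want <- vapply(seq_along(px), function(i)
      winding_inside(px[i], py[i], ring), logical(1))
    expect_identical(got, want)
  }
})

test_that("area filter three-way partitions without loss", {
  area <- project_area(list(cbind(c(-124, -123, -123, -124),
                                  c(48.5, 48.5, 49.5, 49.5))))
  lat <- c(rep(49.0, 15), rep(50.5, 3), NA, NA)
  lon <- c(rep(-123.5, 15), rep(-123.5, 3), NA, NA)
  cat <- toy_catalogue(20, lat = lat, lon = lon)
  parts <- filter_by_area(cat, area)
  expect_equal(nrow(parts$inside), 15L)
  expect_equal(nrow(parts$outside), 3L)
  expect_equal(nrow(parts$noCoordinates), 2L)

  all_in <- filter_by_area(toy_catalogue(5, lat = rep(49, 5),
                                         lon = rep(-123.5, 5)), area)
  expect_equal(nrow(all_in$outside), 0L)
  expect_equal(nrow(all_in$noCoordinates), 0L)

  none <- filter_by_area(toy_catalogue(0), area)
  expect_equal(vapply(none, nrow, integer(1)),
               c(inside = 0L, outside = 0L, noCoordinates = 0L))
})
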