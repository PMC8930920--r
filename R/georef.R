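# Georeferencing: promotion of private/obscured coordinates, reversible
# coordinate patches with justification notes, and the project-area polygon
# filter. Coordinates are WGS84 decimal degrees throughout; the polygon test
# is planar on raw degrees (even-odd rule, boundary points inside), which is
# deterministic and adequate at the scale of a single island's waters.

#' Construct a project area from polygon rings
#'
#' @param rings a list of matrices/data.frames, each with two columns
#'   `(longitude, latitude)` giving ring vertices in order. Rings are closed
#'   automatically; each must have at least 3 distinct vertices. Holes are
#'   handled implicitly by the even-odd rule.
#' @param name area label.
#' @return an object of class `project_area`.
#' @export
project_area <- function(rings, name = "project area") {
  stopifnot(is.list(rings), length(rings) >= 1L)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    stopifnot(ncol(r) == 2L)
    storage.mode(r) <- "double"
    # close the ring
    if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
    if (nrow(unique(r[-nrow(r), , drop = FALSE])) < 3L)
      stop("degenerate ring: fewer than 3 distinct vertices", call. = FALSE)
    colnames(r) <- c("lon", "lat")
    r
  })
  structure(list(rings = rings, name = name), class = "project_area")
}

#' Read a project area from GeoJSON
#'
#' Accepts a `Polygon` or `MultiPolygon` geometry, possibly wrapped in a
#' `Feature` or `FeatureCollection` (the first feature is used).
#'
#' @param path path to a GeoJSON file.
#' @return a `project_area`.
#' @export
read_project_area <- function(path) {
  g <- jsonlite::read_json(path)
  name <- "project area"
  if (identical(g$type, "FeatureCollection")) g <- g$features[[1]]
  if (identical(g$type, "Feature")) {
    name <- g$properties$name %||% name
    g <- g$geometry
  }
  coords_to_ring <- function(ring)
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  rings <- switch(
    g$type,
    Polygon = lapply(g$coordinates, coords_to_ring),
    MultiPolygon = unlist(lapply(g$coordinates, function(poly)
      lapply(poly, coords_to_ring)), recursive = FALSE),
    stop("unsupported GeoJSON geometry type: ", g$type, call. = FALSE))
  project_area(rings, name = name)
}

#' @export
print.project_area <- function(x, ...) {
  cat("<project_area> ", x$name, ": ", length(x$rings), " ring(s), ",
      sum(vapply(x$rings, nrow, integer(1))) - length(x$rings),
      " vertices\n", sep = "")
  invisible(x)
}

# Is (lat, lon) on the segment (x1,y1)-(x2,y2)? (x = lon, y = lat)
on_segment <- function(px, py, x1, y1, x2, y2, eps = 1e-12) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  if (abs(cross) > eps * max(1, abs(x2 - x1), abs(y2 - y1))) return(FALSE)
  px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
    py >= min(y1, y2) - eps && py <= max(y1, y2) + eps
}

point_in_ring <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    if (on_segment(px, py, x1, y1, x2, y2)) return(NA) # boundary marker
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

#' Point-in-area membership test
#'
#' Even-odd (ray crossing) rule on raw WGS84 degrees; points on a ring
#' boundary count as inside — a shoreline record on the area outline is part
#' of the project area.
#'
#' @param lat,lon numeric vectors of equal length, degrees.
#' @param area a `project_area`.
#' @return logical vector; `NA` coordinates give `NA`.
#' @export
#' @examples
#' sq <- project_area(list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
#' point_in_area(0.5, 0.5, sq)
#' point_in_area(2, 2, sq)
point_in_area <- function(lat, lon, area) {
  stopifnot(inherits(area, "project_area"), length(lat) == length(lon))
  ok <- !is.na(lat) & !is.na(lon)
  if (any(abs(lat[ok]) > 90) || any(abs(lon[ok]) > 180))
    stop("coordinates out of range", call. = FALSE)
  vapply(seq_along(lat), function(i) {
    if (!ok[i]) return(NA)
    crossings <- FALSE
    for (ring in area$rings) {
      r <- point_in_ring(lon[i], lat[i], ring)
      if (is.na(r)) return(TRUE)        # on a boundary: inside by contract
      crossings <- xor(crossings, r)    # even-odd across rings (holes)
    }
    crossings
  }, logical(1))
}

#' Promote private/obscured coordinates into the principal fields
#'
#' Crowd-sourced platforms obscure sensitive localities; the precise values
#' are carried in project-specific private fields. Where present, they
#' overwrite `decimalLatitude`/`decimalLongitude`, and the change is logged.
#'
#' @param cat an `occ_catalogue` (also accepts a single-record catalogue).
#' @return the catalogue with promoted coordinates.
#' @export
promote_private_coordinates <- function(cat) {
  stopifnot(inherits(cat, "occ_catalogue"))
  df <- as.data.frame(cat, stringsAsFactors = FALSE)
  has <- !is.na(df$privateLatitude) & !is.na(df$privateLongitude)
  bad <- has & (abs(df$privateLatitude) > 90 | abs(df$privateLongitude) > 180)
  if (any(bad))
    stop("private coordinates out of range for record(s): ",
         paste(df$occurrenceID[bad], collapse = ", "), call. = FALSE)
  promote <- has & (is.na(df$decimalLatitude) |
                    is.na(df$decimalLongitude) |
                    df$decimalLatitude != df$privateLatitude |
                    df$decimalLongitude != df$privateLongitude)
  if (!any(promote)) return(cat)
  old <- paste(df$decimalLatitude[promote], df$decimalLongitude[promote])
  df$decimalLatitude[promote] <- df$privateLatitude[promote]
  df$decimalLongitude[promote] <- df$privateLongitude[promote]
  out <- occ_catalogue(df, log = modification_log(cat))
  append_log(out, "coordinate_promotion",
             df[promote, c("datasetID", "occurrenceID"), drop = FALSE],
             field = "decimalLatitude/decimalLongitude", old = old,
             new = paste(df$decimalLatitude[promote],
                         df$decimalLongitude[promote]),
             justification = "private coordinates promoted")
}

#' Construct a georeferencing patch table
#'
#' Record-keyed coordinate corrections with mandatory justification notes —
#' the reversible georeferencing lens.
#'
#' @param df data.frame with columns `datasetID`, `occurrenceID`,
#'   `newLatitude`, `newLongitude`, `note` (non-empty).
#' @return an object of class `geo_patches`.
#' @export
geo_patches <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("datasetID", "occurrenceID", "newLatitude", "newLongitude", "note")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("patch table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[, req, drop = FALSE]
  df$newLatitude <- as.numeric(df$newLatitude)
  df$newLongitude <- as.numeric(df$newLongitude)
  if (nrow(df)) {
    key <- paste(df$datasetID, df$occurrenceID, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (datasetID, occurrenceID) in patch table", call. = FALSE)
    if (any(abs(df$newLatitude) > 90 | abs(df$newLongitude) > 180,
            na.rm = TRUE) || anyNA(df$newLatitude) || anyNA(df$newLongitude))
      stop("patch coordinates out of range or missing", call. = FALSE)
    if (any(!nzchar(trimws(df$note))))
      stop("every patch requires a justification note", call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("geo_patches", "data.frame"))
}

#' Read a georeferencing patch table from CSV
#'
#' @param path path to a CSV with columns `datasetID`, `occurrenceID`,
#'   `newLatitude`, `newLongitude`, `note`.
#' @return a `geo_patches`.
#' @export
read_geo_patches <- function(path) geo_patches(read_csv_utf8(path))

#' Apply georeferencing patches to a catalogue
#'
#' Targeted records receive the patched coordinates; their previous
#' coordinates are retained in the modification log and in the returned
#' patch log, so the operation is exactly invertible. A patch targeting a
#' record that does not exist is an error: orphan patches are how upstream
#' drift is surfaced. Applying the same patches twice equals applying them
#' once.
#'
#' @param master an `occ_catalogue`.
#' @param patches a `geo_patches` table.
#' @return a list with `catalogue` and `patchLog` (data.frame `datasetID`,
#'   `occurrenceID`, `oldLatitude`, `oldLongitude`, `newLatitude`,
#'   `newLongitude`, `note`).
#' @export
apply_geo_patches <- function(master, patches) {
  stopifnot(inherits(master, "occ_catalogue"), inherits(patches, "geo_patches"))
  df <- as.data.frame(master, stringsAsFactors = FALSE)
  key <- paste(df$datasetID, df$occurrenceID, sep = "\r")
  pkey <- paste(patches$datasetID, patches$occurrenceID, sep = "\r")
  pos <- match(pkey, key)
  if (anyNA(pos))
    stop("patch(es) target records absent from the catalogue: ",
         paste(paste(patches$datasetID[is.na(pos)],
                     patches$occurrenceID[is.na(pos)], sep = "/"),
               collapse = ", "), call. = FALSE)
  if (!nrow(patches))
    return(list(catalogue = master, patchLog = data.frame(
      datasetID = character(0), occurrenceID = character(0),
      oldLatitude = numeric(0), oldLongitude = numeric(0),
      newLatitude = numeric(0), newLongitude = numeric(0),
      note = character(0), stringsAsFactors = FALSE)))

  old_lat <- df$decimalLatitude[pos]
  old_lon <- df$decimalLongitude[pos]
  changed <- is.na(old_lat) | is.na(old_lon) |
    old_lat != patches$newLatitude | old_lon != patches$newLongitude
  df$decimalLatitude[pos] <- patches$newLatitude
  df$decimalLongitude[pos] <- patches$newLongitude
  out <- occ_catalogue(df, log = modification_log(master))
  out <- append_log(out, "geo_patch",
                    df[pos[changed], c("datasetID", "occurrenceID"),
                       drop = FALSE],
                    field = "decimalLatitude/decimalLongitude",
                    old = paste(old_lat[changed], old_lon[changed]),
                    new = paste(patches$newLatitude[changed],
                                patches$newLongitude[changed]),
                    justification = patches$note[changed])
  patchLog <- data.frame(
    datasetID = patches$datasetID, occurrenceID = patches$occurrenceID,
    oldLatitude = old_lat, oldLongitude = old_lon,
    newLatitude = patches$newLatitude, newLongitude = patches$newLongitude,
    note = patches$note, stringsAsFactors = FALSE)
  list(catalogue = out, patchLog = patchLog)
}

#' Invert previously applied georeferencing patches
#'
#' Restores pre-patch coordinates exactly, using the patch log returned by
#' [apply_geo_patches()]. The catalogue must still carry the patched
#' coordinates; a mismatch is an error.
#'
#' @param master the patched `occ_catalogue`.
#' @param patchLog the log returned by [apply_geo_patches()].
#' @return the restored `occ_catalogue`.
#' @export
invert_geo_patches <- function(master, patchLog) {
  stopifnot(inherits(master, "occ_catalogue"))
  if (!nrow(patchLog)) return(master)
  df <- as.data.frame(master, stringsAsFactors = FALSE)
  key <- paste(df$datasetID, df$occurrenceID, sep = "\r")
  pos <- match(paste(patchLog$datasetID, patchLog$occurrenceID, sep = "\r"),
               key)
  if (anyNA(pos))
    stop("patch log references records absent from the catalogue",
         call. = FALSE)
  cur_lat <- df$decimalLatitude[pos]
  cur_lon <- df$decimalLongitude[pos]
  if (any(cur_lat != patchLog$newLatitude |
          cur_lon != patchLog$newLongitude, na.rm = TRUE) ||
      anyNA(cur_lat) || anyNA(cur_lon))
    stop("catalogue coordinates do not match the patch log; ",
         "cannot invert", call. = FALSE)
  df$decimalLatitude[pos] <- patchLog$oldLatitude
  df$decimalLongitude[pos] <- patchLog$oldLongitude
  out <- occ_catalogue(df, log = modification_log(master))
  append_log(out, "geo_patch_invert",
             df[pos, c("datasetID", "occurrenceID"), drop = FALSE],
             field = "decimalLatitude/decimalLongitude",
             old = paste(patchLog$newLatitude, patchLog$newLongitude),
             new = paste(patchLog$oldLatitude, patchLog$oldLongitude),
             justification = "patch inverted")
}

#' Partition a catalogue by the project-area polygon
#'
#' Records without coordinates go to a review bucket, never silently
#' dropped: historical specimens of limited spatial resolution still
#' contribute taxa and need curator eyes.
#'
#' @param master an `occ_catalogue`.
#' @param area a `project_area`.
#' @return a list of catalogues `inside`, `outside`, `noCoordinates`; the
#'   three parts partition the input.
#' @export
filter_by_area <- function(master, area) {
  stopifnot(inherits(master, "occ_catalogue"))
  inside <- point_in_area(master$decimalLatitude, master$decimalLongitude,
                          area)
  list(inside = cat_subset(master, !is.na(inside) & inside),
       outside = cat_subset(master, !is.na(inside) & !inside),
       noCoordinates = cat_subset(master, is.na(inside)))
}
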