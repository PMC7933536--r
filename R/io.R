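# Readers and writers for the exchange formats: GeoJSON annotations, TIFF
# label masks, CSV detections/outcomes/measures, YAML cohort manifests.
# CSV dialect everywhere: comma-separated, UTF-8, '.' decimal, header row.

#' Write a tumour-bulk annotation as GeoJSON
#'
#' Coordinates are micrometres (CRS-less, property `unit: "um"`). A single
#' ring is written as a Polygon; multiple rings as a MultiPolygon with one
#' polygon per ring (rings are interpreted by the even-odd rule on read, so
#' holes survive the round trip).
#'
#' @param bulk Ring matrix or list of rings.
#' @param path Output path.
#' @param case_id Stored as a feature property.
#' @export
write_bulk_geojson <- function(bulk, path, case_id = NA_character_) {
  rings <- as_rings(bulk)
  close_ring <- function(r) unname(rbind(r, r[1, ]))
  geom <- if (length(rings) == 1L) {
    list(type = "Polygon", coordinates = list(close_ring(rings[[1]])))
  } else {
    list(type = "MultiPolygon",
         coordinates = lapply(rings, function(r) list(close_ring(r))))
  }
  fc <- list(type = "FeatureCollection",
             features = list(list(type = "Feature",
                                  properties = list(unit = "um", case_id = case_id),
                                  geometry = geom)))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
}

#' Read a tumour-bulk annotation from GeoJSON
#'
#' Accepts Polygon or MultiPolygon geometry in the first feature; all rings
#' (exteriors and holes) are returned as a flat even-odd ring list.
#'
#' @param path GeoJSON file path.
#' @return List with `rings` and `case_id`.
#' @export
read_bulk_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(fc$type, "FeatureCollection")) fc$features else list(fc)
  if (!length(feats)) stop("GeoJSON contains no features: ", path)
  ft <- feats[[1]]
  geom <- if (identical(ft$type, "Feature")) ft$geometry else ft
  coord_ring <- function(cr) {
    m <- do.call(rbind, lapply(cr, function(p) c(p[[1]], p[[2]])))
    as_rings(m)[[1]]
  }
  rings <- switch(geom$type,
    Polygon = lapply(geom$coordinates, coord_ring),
    MultiPolygon = unlist(lapply(geom$coordinates,
                                 function(poly) lapply(poly, coord_ring)),
                          recursive = FALSE),
    stop("unsupported GeoJSON geometry type: ", geom$type))
  props <- if (identical(ft$type, "Feature")) ft$properties else list()
  unit <- props$unit %||% "um"
  if (!identical(unit, "um"))
    stop(sprintf("annotation '%s' has unit '%s'; micrometres required", path, unit))
  list(rings = rings, case_id = props$case_id %||% NA_character_)
}

#' Write / read a compartment label mask as single-channel TIFF
#'
#' Labels 0 (background), 1 (epithelium), 2 (stroma) stored as 8-bit grey
#' values; the micrometre-per-pixel resolution lives in the cohort manifest.
#' @param mask Integer matrix with values in 0..2.
#' @param path TIFF path.
#' @export
write_mask_tiff <- function(mask, path) {
  mask <- as.matrix(mask)
  if (!all(mask %in% 0:2)) stop("mask labels must be 0, 1 or 2")
  tiff::writeTIFF(mask / 255, path, bits.per.sample = 8L)
}

#' @rdname write_mask_tiff
#' @return `read_mask_tiff`: integer label matrix.
#' @export
read_mask_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  if (!all(m %in% 0:2)) stop("mask TIFF contains labels other than 0/1/2: ", path)
  m
}

#' Write / read marker detections as CSV
#'
#' Columns (header mandatory): case_id, marker, x_um, y_um.
#' @param detections A [detection_set()], a list of them, or a data.frame in
#'   the CSV layout.
#' @param path CSV path.
#' @export
write_detections_csv <- function(detections, path) {
  df <- detections_to_df(detections)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

detections_to_df <- function(detections) {
  if (is.data.frame(detections)) return(detections)
  if (inherits(detections, "detection_set")) detections <- list(detections)
  do.call(rbind, lapply(detections, function(d) {
    if (nrow(d$points))
      data.frame(case_id = d$case_id, marker = d$marker,
                 x_um = d$points[, 1], y_um = d$points[, 2],
                 stringsAsFactors = FALSE)
    else
      data.frame(case_id = character(0), marker = character(0),
                 x_um = numeric(0), y_um = numeric(0))
  }))
}

#' @rdname write_detections_csv
#' @param case_id If given, restrict to this case.
#' @return `read_detections_csv`: named list marker -> [detection_set()]
#'   per case (a list keyed by case_id; a single case's list if `case_id`
#'   given).
#' @export
read_detections_csv <- function(path, case_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "marker", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("detections CSV must have header columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$marker), TIL_MARKERS)
  if (length(bad)) stop("unknown marker(s) in ", path, ": ", paste(bad, collapse = ", "))
  if (!is.null(case_id)) df <- df[df$case_id == case_id, , drop = FALSE]
  out <- lapply(split(df, df$case_id), function(dc) {
    sets <- lapply(split(dc, dc$marker), function(dm)
      detection_set(dm$case_id[1], dm$marker[1], cbind(dm$x_um, dm$y_um)))
    sets[intersect(TIL_MARKERS, names(sets))]
  })
  if (!is.null(case_id)) out[[case_id]] %||% list() else out
}

#' Write / read per-patient outcomes as CSV
#'
#' Columns: case_id, rfs_months, rfs_event, os_months, os_event.
#' @param outcomes data.frame in the outcome layout.
#' @param path CSV path.
#' @export
write_outcomes_csv <- function(outcomes, path) {
  need <- c("case_id", "rfs_months", "rfs_event", "os_months", "os_event")
  stopifnot(all(need %in% names(outcomes)))
  utils::write.csv(outcomes[need], path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_outcomes_csv
#' @export
read_outcomes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "rfs_months", "rfs_event", "os_months", "os_event")
  if (!all(need %in% names(df)))
    stop("outcomes CSV must have header columns: ", paste(need, collapse = ", "))
  stopifnot(all(df$rfs_event %in% 0:1), all(df$os_event %in% 0:1),
            all(df$rfs_months >= 0), all(df$os_months >= 0))
  df
}

#' Write a cohort to disk in the exchange formats
#'
#' Emits per-case GeoJSON bulk annotations and TIFF compartment masks, a
#' cohort-wide detections CSV and outcomes CSV, and a `manifest.yaml` binding
#' them together.
#'
#' @param cohort A `til_cohort` (from [generate_cohort()]) or a list with
#'   `cases`, `detections`, and optionally `outcomes`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  all_det <- list()
  for (k in seq_along(cohort$cases)) {
    cs <- cohort$cases[[k]]
    bulk_file <- sprintf("%s_bulk.geojson", cs$case_id)
    mask_file <- sprintf("%s_mask.tif", cs$case_id)
    write_bulk_geojson(cs$bulk, file.path(dir, bulk_file), cs$case_id)
    if (!is.null(cs$compartment_mask))
      write_mask_tiff(cs$compartment_mask, file.path(dir, mask_file))
    entries[[k]] <- list(case_id = cs$case_id,
                         bulk = bulk_file,
                         mask = if (is.null(cs$compartment_mask)) NULL else mask_file,
                         resolution_um_per_px = cs$resolution_um_per_px,
                         frame = list(x0 = cs$frame$x0, y0 = cs$frame$y0,
                                      nr = cs$frame$nr, nc = cs$frame$nc),
                         detections = "detections.csv")
    all_det <- c(all_det, unname(cohort$detections[[k]]))
  }
  write_detections_csv(all_det, file.path(dir, "detections.csv"))
  manifest <- list(cases = entries, detections = "detections.csv")
  if (!is.null(cohort$outcomes)) {
    write_outcomes_csv(cohort$outcomes, file.path(dir, "outcomes.csv"))
    manifest$outcomes <- "outcomes.csv"
  }
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Load and validate a cohort from a manifest
#'
#' Reads every case referenced by the YAML manifest, applying any per-case
#' 2 x 3 affine transform to its detections. Invalid cases (duplicate id,
#' missing or unreadable files, label errors) are rejected individually with
#' a machine-readable error record; the run proceeds on the valid cases.
#'
#' @param manifest_path Path to `manifest.yaml`.
#' @return List of class `til_cohort`: `cases`, `detections`, `outcomes`
#'   (may be `NULL`), and `errors` (data.frame case_id/error; zero rows when
#'   all cases load).
#' @export
load_cohort <- function(manifest_path) {
  mf <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  if (!length(mf$cases)) stop("manifest lists no cases: ", manifest_path)
  det_cache <- new.env(parent = emptyenv())
  read_det <- function(rel) {
    if (is.null(rel)) return(list())
    key <- rel
    if (!exists(key, det_cache))
      assign(key, read_detections_csv(file.path(base, rel)), det_cache)
    get(key, det_cache)
  }
  cases <- list(); detections <- list(); errs <- list()
  seen <- character(0)
  for (entry in mf$cases) {
    cid <- entry$case_id %||% NA_character_
    rec <- tryCatch(suppressWarnings({
      if (is.na(cid) || !nzchar(cid)) stop("missing case_id")
      if (cid %in% seen) stop("duplicate case_id")
      bulk <- read_bulk_geojson(file.path(base, entry$bulk))
      res <- entry$resolution_um_per_px %||%
        stop("missing resolution_um_per_px")
      frame <- if (!is.null(entry$frame))
        raster_frame(entry$frame$x0, entry$frame$y0, res, entry$frame$nr, entry$frame$nc)
      mask <- if (!is.null(entry$mask)) read_mask_tiff(file.path(base, entry$mask))
      cs <- tissue_case(cid, bulk$rings, res, compartment_mask = mask, frame = frame)
      dets <- read_det(entry$detections %||% mf$detections)[[cid]] %||% list()
      if (!is.null(entry$transform)) {
        tr <- matrix(unlist(entry$transform), 2, 3, byrow = TRUE)
        dets <- lapply(dets, function(d)
          detection_set(d$case_id, d$marker, apply_affine(d$points, tr)))
      }
      list(case = cs, detections = dets)
    }), error = function(e) e)
    if (inherits(rec, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(case_id = cid,
                                              error = conditionMessage(rec),
                                              stringsAsFactors = FALSE)
    } else {
      seen <- c(seen, cid)
      cases[[length(cases) + 1L]] <- rec$case
      detections[[length(detections) + 1L]] <- rec$detections
    }
  }
  outcomes <- if (!is.null(mf$outcomes))
    tryCatch(read_outcomes_csv(file.path(base, mf$outcomes)),
             error = function(e) { errs[[length(errs) + 1L]] <<-
               data.frame(case_id = "<outcomes>", error = conditionMessage(e),
                          stringsAsFactors = FALSE); NULL })
  errors <- if (length(errs)) do.call(rbind, errs)
            else data.frame(case_id = character(0), error = character(0))
  structure(list(cases = cases, detections = detections, outcomes = outcomes,
                 measures = NULL, errors = errors, config = NULL),
            class = "til_cohort")
}
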