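# Region geometry: raster frames, polygon rasterization, margin bands.
#
# All coordinates are micrometres, origin at the top-left of the frame,
# y increasing downward. Polygons are lists of open rings (2-column x/y
# matrices) filled by the even-odd rule, so holes are simply additional
# rings. Rasters sample at pixel centres: pixel (i, j) covers the half-open
# cell [x0+(j-1)res, x0+j res) x [y0+(i-1)res, y0+i res) and its centre is
# (x0+(j-0.5)res, y0+(i-0.5)res).

#' Define a raster frame
#'
#' A frame fixes the pixel grid shared by every raster in a case: origin
#' (top-left corner, micrometres), resolution (micrometres per pixel) and
#' grid dimensions.
#'
#' @param x0,y0 Coordinates of the top-left frame corner, in micrometres.
#' @param res_um_per_px Pixel side length in micrometres; must be positive.
#' @param nr,nc Number of pixel rows and columns.
#' @return An object of class `til_frame`.
#' @export
raster_frame <- function(x0, y0, res_um_per_px, nr, nc) {
  stopifnot(is.finite(x0), is.finite(y0), res_um_per_px > 0, nr >= 1, nc >= 1)
  structure(list(x0 = x0, y0 = y0, res = res_um_per_px,
                 nr = as.integer(nr), nc = as.integer(nc)),
            class = "til_frame")
}

#' @export
print.til_frame <- function(x, ...) {
  cat(sprintf("<til_frame> %d x %d px @ %g um/px, origin (%g, %g) um\n",
              x$nr, x$nc, x$res, x$x0, x$y0))
  invisible(x)
}

# Frame covering a bounding box plus a pad, snapped to whole pixels.
frame_from_bbox <- function(xlim, ylim, res_um_per_px, pad_um = 0) {
  x0 <- xlim[1] - pad_um
  y0 <- ylim[1] - pad_um
  nc <- ceiling((xlim[2] + pad_um - x0) / res_um_per_px)
  nr <- ceiling((ylim[2] + pad_um - y0) / res_um_per_px)
  raster_frame(x0, y0, res_um_per_px, nr, nc)
}

as_rings <- function(polygons) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  lapply(polygons, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2) stop("each polygon ring must be a 2-column (x, y) matrix")
    # drop a duplicated closing vertex if present
    n <- nrow(r)
    if (n >= 2 && all(r[1, ] == r[n, ])) r <- r[-n, , drop = FALSE]
    if (nrow(r) < 3) stop("polygon ring has fewer than 3 distinct vertices")
    storage.mode(r) <- "double"
    unname(r)
  })
}

ring_signed_area_um2 <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

rings_bbox <- function(rings) {
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  list(xlim = range(xs), ylim = range(ys))
}

# Proper-crossing test between segment sets; used for simplicity validation.
segments_cross <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) {
    (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])
  }
  d1 <- o(q1, q2, p1); d2 <- o(q1, q2, p2)
  d3 <- o(p1, p2, q1); d4 <- o(p1, p2, q2)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

validate_rings <- function(rings, what = "bulk") {
  for (k in seq_along(rings)) {
    r <- rings[[k]]
    if (!all(is.finite(r))) stop(sprintf("%s ring %d has non-finite coordinates", what, k))
    if (abs(ring_signed_area_um2(r)) <= 0)
      stop(sprintf("%s ring %d has zero area", what, k))
    n <- nrow(r)
    a <- r; b <- r[c(2:n, 1), , drop = FALSE]
    for (i in seq_len(n - 2)) {
      js <- (i + 2):n
      js <- js[!(i == 1 & js == n)]   # skip edges sharing a vertex with edge i
      if (!length(js)) next
      p1 <- matrix(a[i, ], length(js), 2, byrow = TRUE)
      p2 <- matrix(b[i, ], length(js), 2, byrow = TRUE)
      if (any(segments_cross(p1, p2, a[js, , drop = FALSE], b[js, , drop = FALSE])))
        stop(sprintf("%s ring %d is self-intersecting", what, k))
    }
  }
  invisible(TRUE)
}

#' Rasterize polygons onto a frame
#'
#' Even-odd scanline fill with pixel-centre sampling: a pixel belongs to the
#' polygon set iff its centre does. Horizontal-edge and vertex degeneracies
#' are resolved by the half-open rule (an edge covers `min(y) <= y < max(y)`).
#'
#' @param polygons A ring matrix or list of ring matrices (micrometre
#'   coordinates, even-odd fill).
#' @param frame A [raster_frame()].
#' @return Logical matrix of dimension `frame$nr` x `frame$nc`.
#' @export
rasterize_polygons <- function(polygons, frame) {
  rings <- as_rings(polygons)
  m <- matrix(FALSE, frame$nr, frame$nc)
  a <- do.call(rbind, rings)
  b <- do.call(rbind, lapply(rings, function(r) r[c(2:nrow(r), 1), , drop = FALSE]))
  x1 <- a[, 1]; y1 <- a[, 2]; x2 <- b[, 1]; y2 <- b[, 2]
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
  res <- frame$res
  for (i in seq_len(frame$nr)) {
    y <- frame$y0 + (i - 0.5) * res
    sel <- ylo <= y & y < yhi
    if (!any(sel)) next
    xs <- sort(x1[sel] + (y - y1[sel]) * (x2[sel] - x1[sel]) / (y2[sel] - y1[sel]))
    for (p in seq(1, length(xs) - 1, by = 2)) {
      j1 <- max(1L, ceiling((xs[p] - frame$x0) / res + 0.5))
      j2 <- min(frame$nc, ceiling((xs[p + 1] - frame$x0) / res + 0.5) - 1L)
      if (j1 <= j2) m[i, j1:j2] <- TRUE
    }
  }
  m
}

#' Test points against a polygon set
#'
#' Even-odd (crossing-number) membership with an inclusive boundary: a point
#' exactly on a ring edge or vertex counts as inside (the "inner side wins"
#' tie rule used when assigning detections to the tumour side of a boundary).
#'
#' @param points An n x 2 matrix of (x, y) micrometre coordinates.
#' @param polygons Ring matrix or list of rings, even-odd fill.
#' @param boundary_tol Distance (um) within which a point is snapped to the
#'   boundary and counted inside; defaults to exact (0) arithmetic on the
#'   crossing test plus an explicit on-segment check.
#' @return Logical vector of length n.
#' @export
points_in_polygon <- function(points, polygons, boundary_tol = 1e-9) {
  rings <- as_rings(polygons)
  pts <- as.matrix(points)
  if (!nrow(pts)) return(logical(0))
  px <- pts[, 1]; py <- pts[, 2]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (r in rings) {
    n <- nrow(r)
    x1 <- r[, 1]; y1 <- r[, 2]
    x2 <- r[c(2:n, 1), 1]; y2 <- r[c(2:n, 1), 2]
    for (e in seq_len(n)) {
      crosses <- (y1[e] <= py & py < y2[e]) | (y2[e] <= py & py < y1[e])
      if (any(crosses)) {
        xc <- x1[e] + (py - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
        inside[crosses] <- xor(inside[crosses], px[crosses] < xc[crosses])
      }
      # boundary check: squared distance from point to segment
      vx <- x2[e] - x1[e]; vy <- y2[e] - y1[e]
      L2 <- vx * vx + vy * vy
      t <- pmin(1, pmax(0, ((px - x1[e]) * vx + (py - y1[e]) * vy) / L2))
      d2 <- (px - (x1[e] + t * vx))^2 + (py - (y1[e] + t * vy))^2
      on_edge <- on_edge | d2 <= boundary_tol^2
    }
  }
  inside | on_edge
}

# Euclidean distance (um) from each TRUE pixel's centre to the nearest
# boundary between TRUE and FALSE pixels. distmap() returns centre-to-centre
# distances to the nearest FALSE pixel; subtracting half a pixel places the
# zero at the pixel interface, so a straight boundary yields exact widths.
dist_to_boundary_um <- function(mask, res) {
  d <- as.matrix(EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask))))
  (d - 0.5) * res
}

#' Bundle the geometry of one tumour case
#'
#' @param case_id Identifier string.
#' @param bulk Tumour-bulk outline: a ring matrix or list of rings in
#'   micrometre coordinates (even-odd fill; holes allowed).
#' @param resolution_um_per_px Pixel size of the case rasters, um/px.
#' @param compartment_mask Integer matrix over the frame (or over the bulk
#'   bounding box, which is then embedded): 0 background, 1 epithelium,
#'   2 stroma. Pixels inside the bulk must be 1 or 2; a segmenter emitting a
#'   third class (e.g. fat) must have it merged before input. May be `NULL`
#'   when only margin measures are needed.
#' @param tissue_extent Optional polygon ring(s) bounding the scanned tissue;
#'   defaults to the full frame rectangle. Outer margin bands are clipped to
#'   it so tumours abutting the section edge keep honest areas.
#' @param frame Optional [raster_frame()]; defaults to the bulk bounding box
#'   padded by `pad_um`.
#' @param pad_um Frame padding around the bulk, um. Must cover the widest
#'   margin band to be measured (default 1200 covers the 1 mm band).
#' @param validate Check rings for self-intersection and positive area.
#' @return An object of class `tissue_case`.
#' @export
tissue_case <- function(case_id, bulk, resolution_um_per_px,
                        compartment_mask = NULL, tissue_extent = NULL,
                        frame = NULL, pad_um = 1200, validate = TRUE) {
  if (!is.character(case_id) || length(case_id) != 1L)
    stop("case_id must be a single string")
  if (!is.numeric(resolution_um_per_px) || resolution_um_per_px <= 0)
    stop("resolution_um_per_px must be a positive number")
  bulk <- as_rings(bulk)
  if (validate) validate_rings(bulk, "bulk")
  if (is.null(frame)) {
    bb <- rings_bbox(bulk)
    frame <- frame_from_bbox(bb$xlim, bb$ylim, resolution_um_per_px, pad_um)
  }
  bulk_mask <- rasterize_polygons(bulk, frame)
  if (!any(bulk_mask)) stop("bulk polygon rasterizes to an empty mask at this resolution")

  tissue_mask <- if (is.null(tissue_extent)) {
    matrix(TRUE, frame$nr, frame$nc)
  } else {
    rasterize_polygons(tissue_extent, frame)
  }

  if (!is.null(compartment_mask)) {
    compartment_mask <- embed_compartment_mask(compartment_mask, bulk_mask, frame)
  }

  structure(list(case_id = case_id,
                 resolution_um_per_px = resolution_um_per_px,
                 bulk = bulk,
                 bulk_mask = bulk_mask,
                 tissue_extent = tissue_extent,
                 tissue_mask = tissue_mask,
                 compartment_mask = compartment_mask,
                 frame = frame),
            class = "tissue_case")
}

# Accept a mask on the case frame, or on the bulk bounding box (embedded at
# the bulk's pixel offset); anything else is a frame mismatch.
embed_compartment_mask <- function(mask, bulk_mask, frame) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  if (!all(mask %in% 0:2))
    stop("compartment mask may only contain labels 0 (background), 1 (epithelium), 2 (stroma)")
  if (!all(dim(mask) == c(frame$nr, frame$nc))) {
    idx <- which(bulk_mask, arr.ind = TRUE)
    ri <- range(idx[, 1]); rj <- range(idx[, 2])
    if (all(dim(mask) == c(ri[2] - ri[1] + 1L, rj[2] - rj[1] + 1L))) {
      full <- matrix(0L, frame$nr, frame$nc)
      full[ri[1]:ri[2], rj[1]:rj[2]] <- mask
      mask <- full
    } else {
      stop(sprintf(
        "compartment mask (%d x %d) matches neither the case frame (%d x %d) nor the bulk bounding box",
        nrow(mask), ncol(mask), frame$nr, frame$nc))
    }
  }
  mask[!bulk_mask] <- 0L
  if (any(mask[bulk_mask] == 0L))
    stop("compartment mask has background pixels inside the tumour bulk; merge third classes before input")
  mask
}

#' @export
print.tissue_case <- function(x, ...) {
  cat(sprintf("<tissue_case> %s: %d bulk ring(s), bulk area %.3f mm2, frame %d x %d @ %g um/px\n",
              x$case_id, length(x$bulk),
              sum(x$bulk_mask) * (x$resolution_um_per_px / 1000)^2,
              x$frame$nr, x$frame$nc, x$resolution_um_per_px))
  invisible(x)
}

new_region <- function(mask, frame, name, case_id) {
  structure(list(mask = mask, frame = frame, name = name, case_id = case_id),
            class = "til_region")
}

#' Area of a region in square millimetres
#'
#' For raster regions, `pixel count * (res_um / 1000)^2`; for polygon rings,
#' the signed shoelace sum (GeoJSON winding: holes opposite orientation).
#' Empty regions have area 0.
#'
#' @param x A `til_region`, logical matrix, or polygon ring list.
#' @param res_um_per_px Pixel size, required when `x` is a bare matrix.
#' @param ... Unused.
#' @return Nonnegative area in mm^2.
#' @export
area_mm2 <- function(x, ...) UseMethod("area_mm2")

#' @rdname area_mm2
#' @export
area_mm2.til_region <- function(x, ...) sum(x$mask) * (x$frame$res / 1000)^2

#' @rdname area_mm2
#' @export
area_mm2.matrix <- function(x, res_um_per_px, ...) {
  stopifnot(res_um_per_px > 0)
  sum(x != 0) * (res_um_per_px / 1000)^2
}

#' @rdname area_mm2
#' @export
area_mm2.list <- function(x, ...) {
  if (!length(x)) return(0)
  abs(sum(vapply(as_rings(x), ring_signed_area_um2, numeric(1)))) / 1e6
}

#' @rdname area_mm2
#' @export
area_mm2.NULL <- function(x, ...) 0

#' Build an invasive-margin band around the tumour boundary
#'
#' The bulk outline is dilated to both sides by `half_width_um`, following
#' the Euclidean-distance definition of the margin (isotropic width): the
#' inner half is every bulk pixel within `half_width_um` of the boundary, the
#' outer half every non-bulk pixel within `half_width_um`, clipped to the
#' tissue extent. A half width of 500 um yields an effective 1 mm margin
#' (IM1); 1 mm yields a 2 mm margin (IM2).
#'
#' A tumour thinner than twice the half width is not an error: the inner half
#' then covers the whole bulk and the result is flagged
#' (`inner_covers_bulk = TRUE`).
#'
#' @param case A [tissue_case()].
#' @param half_width_um Positive dilation distance, micrometres.
#' @return A list of class `margin_band` with `til_region`s `inner` and
#'   `outer`, their areas, and the `inner_covers_bulk` flag.
#' @export
build_margin_band <- function(case, half_width_um) {
  stopifnot(inherits(case, "tissue_case"))
  if (!is.numeric(half_width_um) || length(half_width_um) != 1L || half_width_um <= 0)
    stop("half_width_um must be a single positive number")
  res <- case$resolution_um_per_px
  din <- dist_to_boundary_um(case$bulk_mask, res)
  dout <- dist_to_boundary_um(!case$bulk_mask, res)
  inner <- case$bulk_mask & din <= half_width_um
  outer <- !case$bulk_mask & dout <= half_width_um & case$tissue_mask
  band <- list(
    inner = new_region(inner, case$frame, "inner", case$case_id),
    outer = new_region(outer, case$frame, "outer", case$case_id),
    half_width_um = half_width_um,
    inner_covers_bulk = all(inner == case$bulk_mask))
  band$inner_area_mm2 <- area_mm2(band$inner)
  band$outer_area_mm2 <- area_mm2(band$outer)
  class(band) <- "margin_band"
  band
}

#' Split the intratumoural area into epithelial and stromal compartments
#'
#' Overlays the compartment label mask on the tumour bulk: ITT is the set of
#' epithelium-labelled pixels inside the bulk, ITS the stroma-labelled ones.
#' Because the mask partitions the bulk, `area(ITT) + area(ITS) = area(ITA)`
#' exactly (same pixel grid).
#'
#' @param case A [tissue_case()] with a compartment mask.
#' @return List with `til_region`s `ITT` and `ITS`.
#' @export
overlay_compartments <- function(case) {
  stopifnot(inherits(case, "tissue_case"))
  if (is.null(case$compartment_mask))
    stop("case has no compartment mask; ITT/ITS are unavailable")
  list(ITT = new_region(case$compartment_mask == 1L & case$bulk_mask,
                        case$frame, "ITT", case$case_id),
       ITS = new_region(case$compartment_mask == 2L & case$bulk_mask,
                        case$frame, "ITS", case$case_id))
}

#' Build the full set of TIL measurement regions for a case
#'
#' Constructs the intratumoural area (ITA) and its epithelial (ITT) and
#' stromal (ITS) subdivision, plus the invasive-margin bands: IM1 (+/- 500 um
#' of the bulk boundary, effective width 1 mm) and IM2 (+/- 1 mm, effective
#' width 2 mm), each split into inner (tumour-side) and outer halves. Outer
#' halves are clipped to the tissue extent. For multi-focal tumours the bands
#' of all components merge naturally on the shared raster (overlap counted
#' once).
#'
#' @param case A [tissue_case()].
#' @param im_half_widths_um Named vector of band half widths; default
#'   `c(IM1 = 500, IM2 = 1000)`.
#' @return An object of class `region_set`: regions, areas (mm^2) and flags.
#' @export
build_regions <- function(case, im_half_widths_um = c(IM1 = 500, IM2 = 1000)) {
  stopifnot(inherits(case, "tissue_case"))
  regions <- list(ITA = new_region(case$bulk_mask, case$frame, "ITA", case$case_id))
  if (!is.null(case$compartment_mask)) {
    comp <- overlay_compartments(case)
    regions$ITT <- comp$ITT
    regions$ITS <- comp$ITS
  }
  flags <- list()
  res <- case$resolution_um_per_px
  din <- dist_to_boundary_um(case$bulk_mask, res)
  dout <- dist_to_boundary_um(!case$bulk_mask, res)
  for (nm in names(im_half_widths_um)) {
    hw <- im_half_widths_um[[nm]]
    if (hw <= 0) stop("band half widths must be positive")
    inner <- case$bulk_mask & din <= hw
    outer <- !case$bulk_mask & dout <= hw & case$tissue_mask
    regions[[paste0(nm, "_inner")]] <- new_region(inner, case$frame, paste0(nm, "_inner"), case$case_id)
    regions[[paste0(nm, "_outer")]] <- new_region(outer, case$frame, paste0(nm, "_outer"), case$case_id)
    regions[[nm]] <- new_region(inner | outer, case$frame, nm, case$case_id)
    flags[[paste0("inner_covers_bulk_", nm)]] <- all(inner == case$bulk_mask)
  }
  areas <- vapply(regions, area_mm2, numeric(1))
  structure(list(case_id = case$case_id, frame = case$frame,
                 regions = regions, areas = areas, flags = flags,
                 im_half_widths_um = im_half_widths_um),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %s\n", x$case_id))
  for (nm in names(x$areas)) cat(sprintf("  %-10s %8.3f mm2\n", nm, x$areas[[nm]]))
  fl <- names(Filter(isTRUE, x$flags))
  if (length(fl)) cat("  flags:", paste(fl, collapse = ", "), "\n")
  invisible(x)
}
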