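# Marker-wise TIL quantification: region counts, densities per mm2, scaled
# covariates, inner/outer margin ratios, between-marker ratios, heatmaps.

#' Lymphocyte markers recognised by the pipeline
#' @export
TIL_MARKERS <- c("CD3", "CD8", "FOXP3")

# Increment used to scale density covariates for regression: CD3/CD8 are
# evaluated per 100 positive cells, FOXP3 (sparse) per 10.
MARKER_INCREMENT <- c(CD3 = 100, CD8 = 100, FOXP3 = 10)

#' Create a detection set
#'
#' Point detections of marker-positive lymphocytes for one case, in
#' micrometre slide coordinates (the H&E annotation frame). An optional
#' affine transform — e.g. the output of a slide co-registration — is applied
#' to the points at construction.
#'
#' @param case_id Case identifier.
#' @param marker One of `r paste(TIL_MARKERS, collapse = ", ")`.
#' @param points n x 2 matrix (x_um, y_um); may have zero rows.
#' @param transform Optional 2 x 3 affine matrix `[A | b]` mapping
#'   `(x, y) -> A %*% c(x, y) + b`, micrometre units.
#' @return Object of class `detection_set`.
#' @export
detection_set <- function(case_id, marker, points, transform = NULL) {
  marker <- match.arg(marker, TIL_MARKERS)
  points <- as.matrix(points)
  if (!nrow(points)) points <- matrix(numeric(0), 0, 2)
  if (ncol(points) != 2) stop("points must be a 2-column (x_um, y_um) matrix")
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop("detection coordinates must be finite")
  if (!is.null(transform)) points <- apply_affine(points, transform)
  structure(list(case_id = case_id, marker = marker, points = unname(points)),
            class = "detection_set")
}

#' Apply a 2 x 3 affine transform to point coordinates
#' @param points n x 2 matrix.
#' @param transform 2 x 3 matrix `[A | b]`.
#' @return Transformed n x 2 matrix.
#' @export
apply_affine <- function(points, transform) {
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(2, 3))) stop("transform must be a 2 x 3 matrix")
  points <- as.matrix(points)
  if (!nrow(points)) return(points)
  t(transform[, 1:2] %*% t(points) + transform[, 3])
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set> %s %s: %d points\n", x$case_id, x$marker, nrow(x$points)))
  invisible(x)
}

# Map points to pixel indices on a frame; points on a pixel gridline fall to
# the pixel on the right/below (consistent with half-open pixel cells).
points_to_pixels <- function(points, frame) {
  j <- floor((points[, 1] - frame$x0) / frame$res) + 1L
  i <- floor((points[, 2] - frame$y0) / frame$res) + 1L
  cbind(i = i, j = j)
}

#' Count detections falling inside a region
#'
#' Raster regions count a point when its containing pixel belongs to the
#' region mask; since the pixel grid partitions the frame, every point lands
#' in exactly one of ITA/ITT/ITS or inner/outer, which is what makes the
#' count-conservation invariant exact. Polygon regions use even-odd
#' membership with an inclusive boundary ("inner side wins").
#'
#' @param detections A [detection_set()] (or bare n x 2 matrix).
#' @param region A `til_region` (raster) or polygon ring list.
#' @return Nonnegative integer count.
#' @export
count_in_region <- function(detections, region) {
  pts <- if (inherits(detections, "detection_set")) detections$points else as.matrix(detections)
  if (inherits(detections, "detection_set") && inherits(region, "til_region") &&
      !identical(detections$case_id, region$case_id))
    stop(sprintf("case_id mismatch: detections are '%s', region is '%s'",
                 detections$case_id, region$case_id))
  if (!nrow(pts)) return(0L)
  if (inherits(region, "til_region")) {
    ij <- points_to_pixels(pts, region$frame)
    ok <- ij[, 1] >= 1 & ij[, 1] <= region$frame$nr &
          ij[, 2] >= 1 & ij[, 2] <= region$frame$nc
    sum(region$mask[ij[ok, , drop = FALSE]])
  } else {
    sum(points_in_polygon(pts, region))
  }
}

#' Density of cells per square millimetre
#'
#' @param count Nonnegative cell count.
#' @param area_mm2 Region area. A zero (or empty) area makes the density
#'   undefined for that case, returned as `NA` — not 0 and not infinity — and
#'   the case is excluded (and counted) downstream.
#' @return `count / area_mm2`, or `NA_real_` when the area is zero.
#' @export
density_per_mm2 <- function(count, area_mm2) {
  stopifnot(count >= 0, area_mm2 >= 0)
  ifelse(area_mm2 > 0, count / area_mm2, NA_real_)
}

#' Scale a density into its regression covariate
#'
#' CD3 and CD8 densities enter the survival models per increment of 100
#' positive cells; FOXP3, being sparse, per increment of 10.
#'
#' @param density Density in cells/mm^2 (vectorised).
#' @param marker One of `r paste(TIL_MARKERS, collapse = ", ")`.
#' @return `density / increment`.
#' @export
scaled_covariate <- function(density, marker) {
  marker <- match.arg(marker, TIL_MARKERS)
  stopifnot(all(density >= 0, na.rm = TRUE))
  density / MARKER_INCREMENT[[marker]]
}

#' Ratio of inner to outer margin density
#'
#' @param inner_density,outer_density Densities of the same marker in the
#'   inner (tumour-side) and outer halves of a margin band.
#' @return `inner / outer`; `NA` (undefined) when the outer density is zero
#'   or either input is undefined. Undefinedness propagates: such cases are
#'   excluded from downstream models, with exclusions counted.
#' @export
inner_outer_ratio <- function(inner_density, outer_density) {
  if (any(c(inner_density, outer_density) < 0, na.rm = TRUE))
    stop("densities must be nonnegative")
  ifelse(!is.na(inner_density) & !is.na(outer_density) & outer_density > 0,
         inner_density / outer_density, NA_real_)
}

#' Ratio between the absolute counts of two markers
#'
#' Marker-pair ratios (CD8/CD3, FOXP3/CD3, CD8/FOXP3) are computed from the
#' absolute numbers of positive cells in the same region.
#'
#' @param count_a,count_b Nonnegative counts from the same region and case.
#' @return `count_a / count_b`; `NA` (undefined) when `count_b` is 0.
#' @export
marker_ratio <- function(count_a, count_b) {
  if (any(c(count_a, count_b) < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  ifelse(!is.na(count_a) & !is.na(count_b) & count_b > 0,
         count_a / count_b, NA_real_)
}

MARKER_PAIRS <- list(c("CD8", "CD3"), c("FOXP3", "CD3"), c("CD8", "FOXP3"))
COUNT_REGIONS <- c("ITA", "ITT", "ITS", "IM1", "IM2")

#' Names of all per-case TIL measure columns
#'
#' The covariate and ratio columns of the measures table: per marker the five
#' region covariates (`CD3_ITA`, ..., `CD3_IM2`) and the two inner/outer
#' ratios (`CD3_IM1IO`, `CD3_IM2IO`); per marker pair the count ratios per
#' region plus the ratio of inner/outer ratios
#' (`CD8_CD3_ratio_ITA`, ..., `CD8_CD3_ratio_IM2IO`).
#' @return Character vector of column names.
#' @export
measure_names <- function() {
  per_marker <- unlist(lapply(TIL_MARKERS, function(m)
    paste0(m, "_", c(COUNT_REGIONS, "IM1IO", "IM2IO"))))
  pairs <- unlist(lapply(MARKER_PAIRS, function(p)
    paste0(p[1], "_", p[2], "_ratio_", c(COUNT_REGIONS, "IM1IO", "IM2IO"))))
  c(per_marker, pairs)
}

#' Compute the full per-case vector of TIL measures
#'
#' For each marker and region: count, density per mm^2 and scaled covariate;
#' per marker the IM1IO/IM2IO inner/outer density ratios; per marker pair the
#' count ratios. Covariate columns are named `<marker>_<measure>`
#' (e.g. `CD3_ITA`), with `_count` and `_density` companions.
#'
#' @param case A [tissue_case()].
#' @param detections Named list of [detection_set()]s (names from
#'   `TIL_MARKERS`); a missing marker yields `NA` columns with a warning.
#' @param regions Optional precomputed [build_regions()] result.
#' @return One-row data.frame.
#' @export
compute_til_measures <- function(case, detections, regions = NULL) {
  if (is.null(regions)) regions <- build_regions(case)
  stopifnot(inherits(regions, "region_set"), identical(regions$case_id, case$case_id))
  out <- list(case_id = case$case_id)
  counts <- list()
  for (m in TIL_MARKERS) {
    det <- detections[[m]]
    if (is.null(det)) {
      warning(sprintf("case %s: no %s detections; measures set to NA", case$case_id, m))
    } else if (!identical(det$case_id, case$case_id)) {
      stop(sprintf("case_id mismatch: case '%s' vs detections '%s'", case$case_id, det$case_id))
    }
    for (r in c(COUNT_REGIONS, "IM1_inner", "IM1_outer", "IM2_inner", "IM2_outer")) {
      reg <- regions$regions[[r]]
      cnt <- if (is.null(det) || is.null(reg)) NA_integer_ else count_in_region(det, reg)
      dens <- if (is.null(reg)) NA_real_ else density_per_mm2(ifelse(is.na(cnt), 0L, cnt),
                                                             regions$areas[[r]])
      if (is.na(cnt)) dens <- NA_real_
      counts[[paste0(m, "_", r)]] <- cnt
      out[[paste0(m, "_", r, "_count")]] <- cnt
      out[[paste0(m, "_", r, "_density")]] <- dens
      if (r %in% COUNT_REGIONS)
        out[[paste0(m, "_", r)]] <- scaled_covariate(dens, m)
    }
    out[[paste0(m, "_IM1IO")]] <- inner_outer_ratio(out[[paste0(m, "_IM1_inner_density")]],
                                                    out[[paste0(m, "_IM1_outer_density")]])
    out[[paste0(m, "_IM2IO")]] <- inner_outer_ratio(out[[paste0(m, "_IM2_inner_density")]],
                                                    out[[paste0(m, "_IM2_outer_density")]])
  }
  for (p in MARKER_PAIRS) {
    for (r in COUNT_REGIONS) {
      out[[paste0(p[1], "_", p[2], "_ratio_", r)]] <-
        marker_ratio(counts[[paste0(p[1], "_", r)]], counts[[paste0(p[2], "_", r)]])
    }
    for (io in c("IM1IO", "IM2IO")) {
      a <- out[[paste0(p[1], "_", io)]]; b <- out[[paste0(p[2], "_", io)]]
      out[[paste0(p[1], "_", p[2], "_ratio_", io)]] <-
        ifelse(!is.na(a) & !is.na(b) & b > 0, a / b, NA_real_)
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Compute measures for a whole cohort
#'
#' @param cases List of [tissue_case()]s.
#' @param detections List (parallel to `cases`) of named marker ->
#'   [detection_set()] lists.
#' @return data.frame, one row per case.
#' @export
cohort_measures <- function(cases, detections) {
  stopifnot(length(cases) == length(detections))
  do.call(rbind, lapply(seq_along(cases), function(k)
    compute_til_measures(cases[[k]], detections[[k]])))
}

# Area (mm2) of a disk intersected with the frame rectangle, by quadrature
# over x; exact pi*r^2 when the disk lies fully inside.
disk_in_rect_area_mm2 <- function(cx, cy, r_um, frame, nquad = 400) {
  X0 <- frame$x0; X1 <- frame$x0 + frame$nc * frame$res
  Y0 <- frame$y0; Y1 <- frame$y0 + frame$nr * frame$res
  if (cx - r_um >= X0 && cx + r_um <= X1 && cy - r_um >= Y0 && cy + r_um <= Y1)
    return(pi * (r_um / 1000)^2)
  xa <- max(cx - r_um, X0); xb <- min(cx + r_um, X1)
  if (xa >= xb) return(0)
  x <- seq(xa, xb, length.out = nquad + 1)
  h <- sqrt(pmax(0, r_um^2 - (x - cx)^2))
  ylen <- pmax(0, pmin(cy + h, Y1) - pmax(cy - h, Y0))
  # trapezoid rule
  sum((ylen[-1] + ylen[-length(ylen)]) / 2 * diff(x)) / 1e6
}

#' Sliding-window density heatmap
#'
#' Density of detections inside a circle-shaped sliding window (default area
#' 1 mm^2, radius `sqrt(1/pi)` mm, about 564.19 um) evaluated on a regular
#' grid of node positions. Windows overhanging the frame use the clipped
#' window area, so edge nodes are not biased low.
#'
#' @param detections A [detection_set()] or n x 2 point matrix.
#' @param frame The [raster_frame()] (tissue extent) to cover.
#' @param window_area_mm2 Window area; density maps conventionally use 1 mm^2.
#' @param stride_um Node spacing; visualization granularity only.
#' @return Object of class `til_heatmap`: `values` (density matrix, nodes as
#'   rows/cols), node coordinates `xs`, `ys`, `radius_um`.
#' @export
density_heatmap <- function(detections, frame, window_area_mm2 = 1, stride_um = 250) {
  stopifnot(window_area_mm2 > 0, stride_um > 0)
  pts <- if (inherits(detections, "detection_set")) detections$points else as.matrix(detections)
  r_um <- sqrt(window_area_mm2 / pi) * 1000
  xs <- seq(frame$x0 + stride_um / 2, frame$x0 + frame$nc * frame$res, by = stride_um)
  ys <- seq(frame$y0 + stride_um / 2, frame$y0 + frame$nr * frame$res, by = stride_um)
  vals <- matrix(0, length(ys), length(xs))
  for (iy in seq_along(ys)) {
    if (nrow(pts)) {
      near <- abs(pts[, 2] - ys[iy]) <= r_um
      py <- pts[near, , drop = FALSE]
    } else py <- pts
    for (ix in seq_along(xs)) {
      a <- disk_in_rect_area_mm2(xs[ix], ys[iy], r_um, frame)
      if (a <= 0) { vals[iy, ix] <- 0; next }
      n <- if (nrow(py)) sum((py[, 1] - xs[ix])^2 + (py[, 2] - ys[iy])^2 <= r_um^2) else 0
      vals[iy, ix] <- n / a
    }
  }
  structure(list(values = vals, xs = xs, ys = ys, radius_um = r_um,
                 stride_um = stride_um, window_area_mm2 = window_area_mm2,
                 frame = frame,
                 case_id = if (inherits(detections, "detection_set")) detections$case_id else NA,
                 marker = if (inherits(detections, "detection_set")) detections$marker else NA),
            class = "til_heatmap")
}

#' Write a heatmap as TIFF (raw) and PNG (colour-ramped rendering)
#'
#' The TIFF stores densities scaled to `[0, 1]` by the map's maximum (the
#' scale is returned and written to a JSON sidecar); the PNG renders the
#' green -> yellow -> red ramp used for density maps.
#'
#' @param heatmap A [density_heatmap()] result.
#' @param tiff_path,png_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the density value mapped to 1.0 in the TIFF.
#' @export
write_heatmap <- function(heatmap, tiff_path = NULL, png_path = NULL) {
  v <- heatmap$values
  vmax <- max(v, 1e-12)
  if (!is.null(tiff_path)) {
    tiff::writeTIFF(v / vmax, tiff_path, bits.per.sample = 32L)
    jsonlite::write_json(list(density_at_1 = vmax, window_area_mm2 = heatmap$window_area_mm2,
                              stride_um = heatmap$stride_um),
                         paste0(tiff_path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(png_path)) {
    ramp <- grDevices::colorRamp(c("green", "yellow", "red"))
    rgb <- ramp(as.vector(v / vmax)) / 255
    arr <- array(rgb, dim = c(nrow(v), ncol(v), 3))
    png::writePNG(arr, png_path)
  }
  invisible(vmax)
}
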