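test_that("region counting matches point-in-polygon semantics", {
  sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  pts <- rbind(c(100, 100), c(500, 900), c(999, 1), c(1500, 500), c(-10, 200))
  expect_equal(count_in_region(pts, list(sq)), 3)
  # boundary tie rule: a point exactly on the edge counts on the inner side
  expect_equal(count_in_region(rbind(c(1000, 500)), list(sq)), 1)
  expect_equal(count_in_region(rbind(c(0, 0)), list(sq)), 1)
  # raster path: the same square as a region mask
  fr <- raster_frame(0, 0, 10, 100, 100)
  cs <- tissue_case("sq", sq, 10, frame = fr)
  reg <- build_regions(cs)$regions$ITA
  det <- detection_set("sq", "CD3", pts[1:3, ])
  expect_equal(count_in_region(det, reg), 3)
  det_bad <- detection_set("other", "CD3", pts[1:3, ])
  expect_error(count_in_region(det_bad, reg), "case_id mismatch")
})

test_that("polygon counting agrees exactly with an independent oracle", {
  skip_if_not_installed("mgcv")
  set.seed(5)
  ring <- star_polygon(12)
  pts <- cbind(runif(10000, -1600, 1600), runif(10000, -1600, 1600))
  ours <- points_in_polygon(pts, list(ring))
  oracle <- mgcv::in.out(rbind(ring, ring[1, ]), pts)
  expect_identical(ours, oracle)
  expect_equal(count_in_region(pts, list(ring)), sum(oracle))
})

test_that("densities, covariates and ratios follow their contracts", {
  expect_equal(density_per_mm2(250, 2.5), 100)
  expect_equal(density_per_mm2(0, 3.7), 0)
  expect_true(is.na(density_per_mm2(5, 0)))   # undefined, not 0 or Inf

  expect_equal(scaled_covariate(250, "CD3"), 2.5)
  expect_equal(scaled_covariate(250, "CD8"), 2.5)
  expect_equal(scaled_covariate(25, "FOXP3"), 2.5)
  expect_equal(scaled_covariate(0, "CD3"), 0)
  expect_error(scaled_covariate(10, "CD20"))

  expect_equal(inner_outer_ratio(50, 25), 2)
  expect_equal(inner_outer_ratio(42, 42), 1)
  expect_true(is.na(inner_outer_ratio(10, 0)))
  expect_error(inner_outer_ratio(-1, 5), "nonnegative")

  expect_equal(marker_ratio(40, 80), 0.5)
  expect_true(is.na(marker_ratio(3, 0)))
  expect_equal(marker_ratio(17, 17), 1)
  expect_error(marker_ratio(-2, 5), "nonnegative")
})

test_that("density estimates recover a homogeneous Poisson intensity", {
  # lambda = 100/mm2 over a 10 mm2 square: estimate within 3*sqrt(lambda/A)
  lam <- 100; A <- 10
  side <- sqrt(A) * 1000
  sq <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  hits <- 0L
  for (s in 1:25) {
    set.seed(s)
    n <- rpois(1, lam * A)
    pts <- cbind(runif(n, 0, side), runif(n, 0, side))
    est <- density_per_mm2(count_in_region(pts, list(sq)), A)
    if (abs(est - lam) <= 3 * sqrt(lam / A)) hits <- hits + 1L
  }
  expect_gte(hits, 24L)
})

test_that("per-case measures conserve counts and react to added points", {
  cfg <- quick_config(seed = 21)
  g <- generate_case(cfg, 77)
  rs <- build_regions(g$case)
  m <- compute_til_measures(g$case, g$detections, rs)
  for (mk in c("CD3", "CD8", "FOXP3")) {
    expect_equal(m[[paste0(mk, "_ITA_count")]],
                 m[[paste0(mk, "_ITT_count")]] + m[[paste0(mk, "_ITS_count")]])
    expect_equal(m[[paste0(mk, "_ITA")]],
                 m[[paste0(mk, "_ITA_density")]] / 100 * ifelse(mk == "FOXP3", 10, 1))
  }
  # monotonicity: a point added inside ITA raises its density
  idx <- which(g$case$bulk_mask, arr.ind = TRUE)[1, ]
  fr <- g$case$frame
  extra <- c(fr$x0 + (idx[2] - 0.5) * fr$res, fr$y0 + (idx[1] - 0.5) * fr$res)
  det2 <- g$detections
  det2$CD3 <- detection_set(g$case$case_id, "CD3", rbind(g$detections$CD3$points, extra))
  m2 <- compute_til_measures(g$case, det2, rs)
  expect_equal(m2$CD3_ITA_count, m$CD3_ITA_count + 1)
  expect_gt(m2$CD3_ITA_density, m$CD3_ITA_density)
})

test_that("measures are invariant under joint translation", {
  cfg <- quick_config(seed = 31)
  g <- generate_case(cfg, 55)
  m1 <- compute_til_measures(g$case, g$detections)
  shift <- c(12345, -6789)
  ring2 <- sweep(g$case$bulk[[1]], 2, -shift)
  fr <- g$case$frame
  fr2 <- raster_frame(fr$x0 + shift[1], fr$y0 + shift[2], fr$res, fr$nr, fr$nc)
  case2 <- tissue_case(g$case$case_id, ring2, g$case$resolution_um_per_px,
                       compartment_mask = g$case$compartment_mask, frame = fr2,
                       validate = FALSE)
  det2 <- lapply(g$detections, function(d)
    detection_set(d$case_id, d$marker, sweep(d$points, 2, -shift)))
  m2 <- compute_til_measures(case2, det2)
  expect_equal(m1[setdiff(names(m1), "case_id")], m2[setdiff(names(m2), "case_id")])
})

test_that("sliding-window heatmap estimates densities with edge correction", {
  fr <- raster_frame(0, 0, 10, 300, 300)  # 3 x 3 mm
  # empty detections: all-zero grid
  h0 <- density_heatmap(matrix(numeric(0), 0, 2), fr, stride_um = 500)
  expect_true(all(h0$values == 0))
  expect_equal(h0$radius_um, sqrt(1 / pi) * 1000)
  # homogeneous Poisson lambda = 50/mm2: grid mean within 3 SE of 50
  lam <- 50
  set.seed(9)
  n <- rpois(1, lam * 9)
  pts <- cbind(runif(n, 0, 3000), runif(n, 0, 3000))
  h <- density_heatmap(pts, fr, stride_um = 250)
  se <- sqrt(lam / 1) / sqrt(length(h$values))  # per-window Poisson SE, crude pooling
  expect_lt(abs(mean(h$values) - lam), 3 * sqrt(lam))  # conservative bound per window
  expect_lt(abs(mean(h$values) - lam), 0.15 * lam)
  # edge windows use clipped areas, so corners are unbiased too
  corner <- h$values[1, 1]
  expect_gt(corner, 0)
})

test_that("heatmap files round-trip through TIFF", {
  fr <- raster_frame(0, 0, 10, 100, 100)
  set.seed(2)
  pts <- cbind(runif(200, 0, 1000), runif(200, 0, 1000))
  h <- density_heatmap(pts, fr, stride_um = 250)
  tf <- tempfile(fileext = ".tif"); pf <- tempfile(fileext = ".png")
  vmax <- write_heatmap(h, tf, pf)
  expect_true(file.exists(tf) && file.exists(pf))
  back <- tiff::readTIFF(tf)
  expect_equal(back * vmax, h$values, tolerance = 1e-5)
})
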