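test_that("area accounting converts pixels and polygons to mm2", {
  # 1000 x 1000 um square at 4 um/px
  fr <- raster_frame(0, 0, 4, 250, 250)
  m <- matrix(TRUE, 250, 250)
  expect_equal(area_mm2(m, res_um_per_px = 4), 1.0)
  expect_equal(area_mm2(matrix(FALSE, 5, 5), res_um_per_px = 4), 0)
  expect_equal(area_mm2(NULL), 0)
  # raster disk of radius 564.19 um (area 1 mm2) at 2 um/px
  cs <- tissue_case("d", circle_ring(564.19, n = 720), 2, pad_um = 20)
  expect_equal(area_mm2(cs$bulk_mask, 2), 1.0, tolerance = 0.005)
  # polygon shoelace path
  sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  expect_equal(area_mm2(list(sq)), 1.0)
})

test_that("invalid polygons and parameters are rejected with diagnostics", {
  bowtie <- rbind(c(0, 0), c(1000, 1000), c(1000, 0), c(0, 1000))
  expect_error(tissue_case("x", bowtie, 5), "zero area")
  crossed <- rbind(c(0, 0), c(2000, 0), c(0, 1000), c(1000, 1500))
  expect_error(tissue_case("x", crossed, 5), "self-intersecting")
  sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  cs <- tissue_case("x", sq, 5)
  expect_error(build_margin_band(cs, 0), "positive")
  expect_error(build_margin_band(cs, -100), "positive")
  expect_error(tissue_case("x", sq, -5), "positive")
})

test_that("margin band on a disk matches the analytic annulus", {
  # disk radius 2 mm, half width 500 um: band = annulus between 1.5 and 2.5 mm
  cs <- tissue_case("disk", circle_ring(2000, n = 720), 5)
  b <- build_margin_band(cs, 500)
  expect_equal(b$inner_area_mm2 + b$outer_area_mm2, 4 * pi, tolerance = 0.01)
  expect_equal(b$inner_area_mm2, pi * (2^2 - 1.5^2), tolerance = 0.01)
  expect_equal(b$outer_area_mm2, pi * (2.5^2 - 2^2), tolerance = 0.01)
  expect_false(b$inner_covers_bulk)
})

test_that("straight tumour boundary yields the stated effective margin widths", {
  fr <- raster_frame(0, 0, 5, 900, 60)
  # side edges kept far outside the frame so only the straight top boundary
  # (y = 2250, on the pixel grid) is in play
  bulk <- rbind(c(-5000, -2000), c(5300, -2000), c(5300, 2250), c(-5000, 2250))
  cs <- tissue_case("hp", bulk, 5, frame = fr)
  for (hw in c(500, 1000)) {
    b <- build_margin_band(cs, hw)
    width_um <- (sum(b$inner$mask[, 30]) + sum(b$outer$mask[, 30])) * 5
    expect_equal(width_um, 2 * hw)
  }
})

test_that("a tumour thinner than twice the half width is flagged, not an error", {
  thin <- rbind(c(0, 0), c(3000, 0), c(3000, 400), c(0, 400))
  cs <- tissue_case("thin", thin, 5)
  b <- build_margin_band(cs, 500)
  expect_true(b$inner_covers_bulk)
  expect_equal(sum(b$inner$mask), sum(cs$bulk_mask))
})

test_that("band construction agrees with a brute-force distance oracle", {
  skip_if_not_installed("mgcv")
  set.seed(42)
  ring <- star_polygon(12)
  cs <- tissue_case("poly", ring, 5)
  rs <- build_regions(cs)
  fr <- cs$frame
  xs <- fr$x0 + (seq_len(fr$nc) - 0.5) * fr$res
  ys <- fr$y0 + (seq_len(fr$nr) - 0.5) * fr$res
  pts <- cbind(rep(xs, each = fr$nr), rep(ys, times = fr$nc))
  d <- dist_to_ring_um(pts, ring)
  inside <- mgcv::in.out(rbind(ring, ring[1, ]), pts)
  oracle <- ifelse(d > 500, "neither", ifelse(inside, "inner", "outer"))
  ours <- ifelse(rs$regions$IM1_inner$mask, "inner",
                 ifelse(rs$regions$IM1_outer$mask, "outer", "neither"))
  ours <- as.vector(ours)  # column-major matches pts construction
  agree <- mean(ours == oracle)
  expect_gt(agree, 0.995)
  # disagreements confined to one grid pitch of the band edge (or the outline)
  bad <- which(ours != oracle)
  expect_true(all(pmin(abs(d[bad] - 500), d[bad]) <= 2 * fr$res))
})

test_that("compartment overlay partitions the intratumoural area", {
  sq <- rbind(c(0, 0), c(2000, 0), c(2000, 2000), c(0, 2000))
  fr <- raster_frame(-100, -100, 10, 220, 220)
  # all epithelium inside bulk: ITT = ITA, ITS empty
  bulkpix <- rasterize_polygons(sq, fr)
  mask <- matrix(0L, 220, 220); mask[bulkpix] <- 1L
  cs <- tissue_case("ep", sq, 10, compartment_mask = mask, frame = fr)
  comp <- overlay_compartments(cs)
  expect_equal(area_mm2(comp$ITT), area_mm2(cs$bulk_mask, 10))
  expect_equal(area_mm2(comp$ITS), 0)

  # checkerboard on a 2 x 2 mm square: each compartment 2.0 mm2
  chk <- matrix(0L, 220, 220)
  chk[bulkpix] <- ifelse((row(chk)[bulkpix] + col(chk)[bulkpix]) %% 2 == 0, 1L, 2L)
  cs2 <- tissue_case("chk", sq, 10, compartment_mask = chk, frame = fr)
  comp2 <- overlay_compartments(cs2)
  px <- (10 / 1000)^2
  expect_equal(area_mm2(comp2$ITT), 2.0, tolerance = 220 * px)  # one pixel row
  expect_equal(area_mm2(comp2$ITS), 2.0, tolerance = 220 * px)

  # random blob mask: epithelium area fraction equals the pixel fraction
  set.seed(3)
  blob <- matrix(0L, 220, 220)
  blob[bulkpix] <- sample(1:2, sum(bulkpix), replace = TRUE, prob = c(0.37, 0.63))
  cs3 <- tissue_case("blob", sq, 10, compartment_mask = blob, frame = fr)
  comp3 <- overlay_compartments(cs3)
  frac <- mean(blob[bulkpix] == 1L)
  expect_equal(area_mm2(comp3$ITT) / area_mm2(cs3$bulk_mask, 10), frac, tolerance = 1e-4)
})

test_that("compartment masks with foreign labels or frames are rejected", {
  sq <- rbind(c(0, 0), c(500, 0), c(500, 500), c(0, 500))
  expect_error(tissue_case("x", sq, 10, compartment_mask = matrix(3L, 90, 90)),
               "labels")
  expect_error(tissue_case("x", sq, 10, compartment_mask = matrix(1L, 7, 9)),
               "matches neither")
})

test_that("region set obeys partition, nesting and scale covariance", {
  cfg <- quick_config(seed = 11)
  for (s in c(101, 202)) {
    g <- generate_case(cfg, s)
    rs <- build_regions(g$case)
    px <- (g$case$resolution_um_per_px / 1000)^2
    expect_equal(rs$areas[["ITA"]], rs$areas[["ITT"]] + rs$areas[["ITS"]])
    # every bulk pixel is in exactly one compartment
    expect_true(all(xor(rs$regions$ITT$mask[g$case$bulk_mask],
                        rs$regions$ITS$mask[g$case$bulk_mask])))
    # nesting of bands
    expect_true(all(rs$regions$IM2_inner$mask[rs$regions$IM1_inner$mask]))
    expect_true(all(rs$regions$IM2_outer$mask[rs$regions$IM1_outer$mask]))
    # inner inside bulk, outer outside
    expect_true(all(g$case$bulk_mask[rs$regions$IM1_inner$mask]))
    expect_false(any(g$case$bulk_mask[rs$regions$IM1_outer$mask]))
  }
  # scale covariance: scaling every coordinate-valued input (outline, band
  # widths, resolution, pad) by s scales each area by exactly s^2
  ring <- circle_ring(1000, n = 128)
  a1 <- area_mm2(build_regions(tissue_case("a", ring, 8, pad_um = 1200))$regions$IM1)
  a2 <- area_mm2(build_regions(tissue_case("b", 2 * ring, 16, pad_um = 2400),
                               im_half_widths_um = c(IM1 = 1000, IM2 = 2000))$regions$IM1)
  expect_equal(a2, 4 * a1)
})
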