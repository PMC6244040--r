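test_that("vegetation indices follow their normalized-difference definitions", {
  g <- flat_raster(0.2); r <- flat_raster(0.2)
  expect_true(all(compute_ngrdi(g, r)$values == 0))
  g2 <- flat_raster(0.12); r2 <- flat_raster(0.06)
  expect_equal(compute_ngrdi(g2, r2)$values[1, 1], 0.06 / 0.18)
  expect_equal(round(compute_ngrdi(g2, r2)$values[1, 1], 4), 0.3333)
  g3 <- flat_raster(0.10); r3 <- flat_raster(0.12)
  expect_equal(round(compute_ngrdi(g3, r3)$values[1, 1], 4), -0.0909)
  nir <- flat_raster(0.45)
  expect_equal(round(compute_ndvi(nir, r2)$values[1, 1], 4), 0.7647)
  nir2 <- flat_raster(0.14)
  expect_equal(round(compute_ndvi(nir2, r3)$values[1, 1], 4), 0.0769)
  # zero band sum -> nodata; all defined values within [-1, 1]
  z <- flat_raster(0)
  expect_true(all(is.na(compute_ndvi(z, z)$values)))
  set.seed(4)
  ga <- flat_raster(0); gb <- flat_raster(0)
  ga$values[] <- runif(100); gb$values[] <- runif(100)
  v <- compute_ngrdi(ga, gb)$values
  expect_true(all(v >= -1 & v <= 1, na.rm = TRUE))
})

test_that("segmentation masks use strict thresholds and keep nodata", {
  neg <- flat_raster(-0.2)
  expect_true(all(plant_mask_from_ngrdi(neg)$values == 0))
  zero <- flat_raster(0)
  expect_true(all(plant_mask_from_ngrdi(zero)$values == 0))
  pos <- flat_raster(0.3)
  expect_true(all(plant_mask_from_ngrdi(pos)$values == 1))
  at_thresh <- flat_raster(0.1)
  expect_true(all(plant_mask_from_ndvi(at_thresh)$values == 0))
  above <- flat_raster(0.5)
  expect_true(all(plant_mask_from_ndvi(above)$values == 1))
  with_na <- flat_raster(0.4)
  with_na$values[1, 1] <- NA
  expect_true(is.na(plant_mask_from_ndvi(with_na)$values[1, 1]))
})

test_that("masks on a synthetic scene equal the true plant-pixel set", {
  sc <- generate_field_scene(tiny_scene_cfg(cell_size = 4), seed = 6)
  st <- sc$stages$S2
  truth_mask <- (st$dsm$values - sc$dem$values) > 0
  m1 <- plant_mask_from_ngrdi(compute_ngrdi(st$bands$green, st$bands$red))
  m2 <- plant_mask_from_ndvi(compute_ndvi(st$bands$nir, st$bands$red))
  expect_identical(m1$values == 1, truth_mask)
  expect_identical(m2$values == 1, truth_mask)
})

test_that("crop surface model is the DSM-DEM difference", {
  dem <- flat_raster(500)
  expect_true(all(compute_csm(dem, dem)$values == 0))
  dsm <- dem
  dsm$values[3, 4] <- 650
  csm <- compute_csm(dsm, dem)
  expect_equal(csm$values[3, 4], 150)
  expect_equal(sum(csm$values != 0), 1L)
})

test_that("block maxima picks the highest pixel of each window", {
  # single valid pixel
  v <- matrix(NA_real_, 6, 6)
  v[2, 5] <- 120
  r <- trait_raster(v, cell_size = 5, origin = c(0, 0.3))
  pts <- block_maxima(r, resample_cell = 5, window = 3)
  expect_equal(nrow(pts), 1L)
  expect_equal(pts$z, 120)
  cc <- phenocurves:::cell_centers(r)
  expect_equal(pts$x, cc$x[5]); expect_equal(pts$y, cc$y[2])

  # 6x6 distinct values, window 3, no resampling: 4 quadrant maxima
  set.seed(10)
  v2 <- matrix(sample(1:36), 6, 6)
  r2 <- trait_raster(v2, cell_size = 5, origin = c(0, 0.3))
  pts2 <- block_maxima(r2, resample_cell = 5, window = 3)
  expect_equal(nrow(pts2), 4L)
  brute <- sort(c(max(v2[1:3, 1:3]), max(v2[1:3, 4:6]),
                  max(v2[4:6, 1:3]), max(v2[4:6, 4:6])))
  expect_equal(sort(pts2$z), brute)

  # max-preserving resampling: 2x coarsening then 3x3 windows = 6x6 blocks
  pts3 <- block_maxima(r2, resample_cell = 10, window = 3)
  expect_equal(nrow(pts3), 1L)
  expect_equal(pts3$z, 36)

  # partial edge blocks are kept
  v4 <- matrix(seq_len(16), 4, 4)
  r4 <- trait_raster(v4, cell_size = 5, origin = c(0, 0.2))
  pts4 <- block_maxima(r4, resample_cell = 5, window = 3)
  expect_equal(nrow(pts4), 4L)  # 3x3 block + two edge strips + corner

  # all-nodata input raises the typed no-plant error
  roi <- plot_roi("P009", polygon = rect_ring_test(c(0, 2.4), c(0, 2)))
  empty <- trait_raster(matrix(NA_real_, 6, 6), 5, c(0, 0.3))
  expect_error(block_maxima(empty, roi), class = "no_plant_error")
  err <- tryCatch(block_maxima(empty, roi), no_plant_error = identity)
  expect_equal(err$plot_id, "P009")
})

test_that("kriged plot height is an exact interpolator above its inputs", {
  # constant field: kriging of a constant is that constant
  set.seed(2)
  pts <- data.frame(x = runif(12, 0, 2), y = runif(12, 0, 2), z = 200)
  expect_equal(krige_plot_height(pts, grid_cell = 10), 200)

  # any point set: surface max never falls below the highest data point
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:40, 1)
    pts <- data.frame(x = runif(n, 0, 2), y = runif(n, 0, 2),
                      z = 100 + 50 * runif(n))
    expect_gte(krige_plot_height(pts, grid_cell = 10), max(pts$z) - 1e-8)
  }

  # under 5 points the maximum is returned directly
  few <- data.frame(x = c(0, 1, 2), y = c(0, 1, 0), z = c(10, 30, 20))
  expect_equal(krige_plot_height(few), 30)
  expect_error(krige_plot_height(few[0, ]), "empty")
})

test_that("plot height extraction recovers construction heights", {
  # single-plant plot with known apex: recovered within 5%
  sc <- generate_field_scene(single_plant_cfg(apex = 150), seed = 4)
  st <- sc$stages$S4
  ph <- extract_plot_ph(st$dsm, sc$dem, st$bands$green, st$bands$red,
                        sc$plots[[1]])
  expect_equal(ph$ph_status, "ok")
  expect_lt(abs(ph$ph - 150) / 150, 0.05)

  # two plants, apexes 100 and 160: the maximum governs, not the mean
  dem <- trait_raster(matrix(0, 110, 130), 2, c(0, 2.2))
  canopy <- matrix(0, 110, 130)
  cc <- phenocurves:::cell_centers(dem)
  add_crown <- function(canopy, px, py, h, re = 0.35) {
    d2 <- outer((cc$y - py)^2, (cc$x - px)^2, `+`)
    pmax(canopy, h * pmax(0, 1 - d2 / re^2))
  }
  canopy <- add_crown(canopy, 0.8, 1.1, 100)
  canopy <- add_crown(canopy, 1.7, 1.1, 160)
  dsm <- trait_raster(canopy, 2, c(0, 2.2))
  band <- function(pv, sv) {
    v <- matrix(sv, 110, 130); v[canopy > 0] <- pv
    trait_raster(v, 2, c(0, 2.2))
  }
  roi <- plot_roi("P001", polygon = rect_ring_test(c(0.1, 2.5), c(0.1, 2.1)))
  ph2 <- extract_plot_ph(dsm, dem, band(0.12, 0.10), band(0.06, 0.12), roi)
  expect_lt(abs(ph2$ph - 160) / 160, 0.05)

  # bare plot: a missing record with the no-plant reason, not an error
  bare <- trait_raster(matrix(0, 110, 130), 2, c(0, 2.2))
  soil_g <- flat_raster(0.10, 110, 130, 2, c(0, 2.2))
  soil_r <- flat_raster(0.12, 110, 130, 2, c(0, 2.2))
  ph3 <- extract_plot_ph(bare, dem, soil_g, soil_r, roi)
  expect_true(is.na(ph3$ph))
  expect_equal(ph3$ph_status, "no-plant")
})

test_that("canopy cover and mean NDVI are counting and averaging statistics", {
  r <- trait_raster(matrix(0.5, 12, 12), 25, c(0, 3))
  roi <- plot_roi("P001", polygon = rect_ring_test(c(0.25, 2.75),
                                                   c(0.25, 2.75)),
                  border_shrink = 0)
  full <- plant_mask_from_ndvi(r)             # all plant
  expect_equal(plot_cc(full, roi), 1.0)
  none <- plant_mask_from_ndvi(trait_raster(matrix(0, 12, 12), 25, c(0, 3)))
  expect_equal(plot_cc(none, roi), 0.0)

  # 30 plant pixels among 120 ROI pixels -> 0.25
  m <- matrix(0, 12, 12)
  roi_mask <- polygon_mask(r, roi)
  expect_equal(sum(roi_mask), 100L)  # 10x10 centres inside
  idx <- which(roi_mask)[1:25]
  m[idx] <- 1
  cc_val <- plot_cc(trait_raster(m, 25, c(0, 3)), roi)
  expect_equal(cc_val, 0.25)

  # mean NDVI over plant pixels only
  nd <- trait_raster(matrix(0.2, 12, 12), 25, c(0, 3))
  nd$values[idx[1:12]] <- 0.6
  mask2 <- trait_raster(m, 25, c(0, 3))
  expect_equal(plot_mean_ndvi(nd, mask2, roi),
               mean(c(rep(0.6, 12), rep(0.2, 13))))
  # empty mask -> NA flagged
  out <- plot_mean_ndvi(nd, none, roi)
  expect_true(is.na(out))
  expect_equal(attr(out, "status"), "no-plant")
})

test_that("extracted canopy cover and NDVI match scene ground truth", {
  sc <- generate_field_scene(tiny_scene_cfg(cell_size = 4), seed = 5)
  tr <- extract_stage_traits(sc, "S3")
  truth <- sc$truth[sc$truth$stage == "S3", ]
  expect_equal(tr$cc, truth$true_cc[match(tr$plot_id, truth$plot_id)])
  # uniform plant reflectance: plot mean NDVI equals the configured value
  pr <- tiny_scene_cfg()$plant_reflectance
  expect_equal(tr$ndvi, rep((pr[["nir"]] - pr[["red"]]) /
                              (pr[["nir"]] + pr[["red"]]), nrow(tr)))
  # determinism of the full extraction
  tr2 <- extract_stage_traits(sc, "S3")
  expect_identical(tr, tr2)
})
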