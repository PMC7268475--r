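test_that("generators are byte-identical under a fixed seed", {
  spec <- field_spec(2, 2, seed = 5)
  tr <- simulate_plot_truths(spec)
  expect_identical(tr, simulate_plot_truths(spec))
  o1 <- generate_orthomosaic(spec, tr, "DAP61")
  o2 <- generate_orthomosaic(spec, tr, "DAP61")
  expect_identical(o1$bands, o2$bands)
  c1 <- generate_clouds(spec, tr)
  c2 <- generate_clouds(spec, tr)
  expect_identical(c1$canopy_d1$points, c2$canopy_d1$points)
  expect_identical(c1$bars, c2$bars)
})

test_that("truth-mask canopy cover matches cc_frac within pixel quantization", {
  spec <- field_spec(3, 2, seed = 9)
  tr <- simulate_plot_truths(spec)
  o <- generate_orthomosaic(spec, tr, "DAP61")
  lay <- o$layout
  for (i in seq_len(nrow(lay))) {
    pr <- clip_raster(o, lay[i, ])
    measured <- mean(pr$truth_mask)
    # each of the 6 row stripes can be quantized by at most one pixel width
    tol <- spec$rows_per_plot * spec$gsd_msi_m / spec$plot_width_m
    expect_lt(abs(measured - tr$cc_frac[tr$plot_id == lay$plot_id[i]]), tol)
  }
})

test_that("full cover makes every in-plot pixel vegetation", {
  spec <- field_spec(2, 2, seed = 3)
  tr <- simulate_plot_truths(spec)
  tr$cc_frac[] <- 1
  o <- generate_orthomosaic(spec, tr, "DAP61")
  pr <- clip_raster(o, o$layout[1, ])
  expect_true(all(pr$truth_mask))
})

test_that("NIR histogram over a plot is bimodal at the stated band levels", {
  spec <- field_spec(2, 2, seed = 13)
  tr <- simulate_plot_truths(spec)
  o <- generate_orthomosaic(spec, tr, "DAP61")
  pr <- clip_raster(o, o$layout[1, ])
  nir <- raster_band(pr, "NIR")
  veg_mode <- median(nir[pr$truth_mask])
  soil_mode <- median(nir[!pr$truth_mask])
  chl <- tr$chl[tr$plot_id == o$layout$plot_id[1]]
  expect_lt(abs(veg_mode - 55.42 * (1 + 0.15 * (chl - 1))), 1)
  expect_lt(abs(soil_mode - 15), 1)
  # separation is many times the pixel noise, so clustering has a clean optimum
  expect_gt(veg_mode - soil_mode, 10 * 1.0)
})

test_that("vegetation median NIR reproduces the late-July canopy scale", {
  spec <- field_spec(2, 2, seed = 17)
  tr <- simulate_plot_truths(spec)
  tr$chl[] <- 1
  o <- generate_orthomosaic(spec, tr, "DAP61")
  nir <- raster_band(o, "NIR")
  expect_lt(abs(median(nir[o$truth_mask]) - 55.42), 0.5)
})

test_that("orthomosaic generation validates its inputs", {
  spec <- field_spec(2, 2, seed = 1)
  tr <- simulate_plot_truths(spec)
  lay <- build_plot_polygons(spec)
  lay[1, c("min_x", "min_y", "max_x", "max_y")] <-
    lay[2, c("min_x", "min_y", "max_x", "max_y")]   # coincident footprints
  expect_error(generate_orthomosaic(spec, tr, layout = lay), "layout error")
  expect_error(generate_orthomosaic(spec, tr[-1, ]), "cover every plot")
})

test_that("point density meets the photogrammetric floor", {
  spec <- field_spec(2, 2, seed = 19)
  tr <- simulate_plot_truths(spec)
  cl <- generate_clouds(spec, tr, density = 100)
  ext <- uasyield:::field_extent(spec)
  area <- (ext[["xmax"]] - ext[["xmin"]]) * (ext[["ymax"]] - ext[["ymin"]])
  expect_gte(nrow(cl$terrain$points) / area, 100)
  expect_gte(nrow(cl$canopy_d1$points) / area, 100)
})

test_that("zero canopy height collapses the canopy cloud onto the terrain", {
  spec <- field_spec(2, 2, seed = 23)
  tr <- simulate_plot_truths(spec)
  tr$height_d1[] <- 0
  tr$height_d2[] <- 0
  cl <- generate_clouds(spec, tr, outlier_frac = 0, noise_z = 0.005,
                        perturb = list(list(yaw_deg = 0, t = c(0, 0, 0)),
                                       list(yaw_deg = 0, t = c(0, 0, 0))))
  p <- cl$canopy_d1$points
  truth <- uasyield:::.surface_z(cl$terrain$meta$terrain_coef, p[, 1], p[, 2],
                                 0.02, 1.5)
  dz <- (p[, 3] - truth)[seq_len(nrow(p) - 200)]  # trailing 200 are bar points
  expect_lt(max(abs(dz)), 5 * 0.005)
})

test_that("injected outlier fraction is recoverable from the cloud", {
  spec <- field_spec(2, 2, seed = 29)
  tr <- simulate_plot_truths(spec)
  tr$height_d1[] <- 0                  # bare field: surface is the terrain
  tr$height_d2[] <- 0
  frac <- 0.02
  cl <- generate_clouds(spec, tr, outlier_frac = frac,
                        perturb = list(list(yaw_deg = 0, t = c(0, 0, 0)),
                                       list(yaw_deg = 0, t = c(0, 0, 0))))
  can <- cl$canopy_d1
  notbar <- seq_len(nrow(can$points) - 200)    # trailing 200 are bar returns
  p <- can$points[notbar, , drop = FALSE]
  surf <- uasyield:::.surface_z(cl$terrain$meta$terrain_coef, p[, 1], p[, 2],
                                0.02, 1.5)
  gross <- abs(p[, 3] - surf) > 5 * 0.008      # 5 sigma off the local surface
  n <- nrow(p)
  expect_lt(abs(sum(gross) - frac * n), 4 * sqrt(n * frac * (1 - frac)) + 5)
  expect_gt(mean(can$meta$outlier[notbar][gross]), 0.95)
})

test_that("yield generation follows the latent-trait model", {
  spec <- field_spec(30, 30, seed = 11)
  tr <- simulate_plot_truths(spec)
  y0 <- generate_yield(tr, coeffs = c(1234, 0, 0, 0), sigma = 0)
  expect_true(all(y0$yield_kg_ha == 1234))
  expect_error(generate_yield(tr, sigma = -1), "sigma")
  y <- generate_yield(tr)
  se <- sd(y$yield_kg_ha) / sqrt(nrow(y))
  expect_lt(abs(mean(y$yield_kg_ha) - 3783.409), 3 * se)
  expect_lt(abs(sd(y$yield_kg_ha) - 769.627), 100)
})

test_that("field products round-trip through their file formats", {
  spec <- field_spec(2, 2, seed = 37)
  tr <- simulate_plot_truths(spec)
  cl <- generate_clouds(spec, tr, density = 20)
  tmp <- withr::local_tempdir()
  ply <- file.path(tmp, "t.ply")
  write_ply(cl$terrain, ply)
  back <- read_ply(ply)
  expect_equal(back$points, cl$terrain$points, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$role, "terrain")
  o <- generate_orthomosaic(spec, tr, "DAP61")
  tif <- file.path(tmp, "o.tif")
  write_orthomosaic(o, tif)
  ob <- read_orthomosaic(tif)
  expect_equal(ob$bands, o$bands, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(ob$gsd, o$gsd, tolerance = 1e-12)
  expect_equal(ob$xmin, o$xmin, tolerance = 1e-9)
})
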