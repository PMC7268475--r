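test_that("robust statistics reproduce their defining identities", {
  s <- robust_stats(c(1, 2, 3))
  expect_equal(s$mad, 1)
  expect_equal(s$nmad, 1.4826)
  expect_equal(s$mean, 2)
  expect_equal(s$std, 1)
  const <- robust_stats(rep(5, 4))
  expect_equal(const$mad, 0)
  expect_equal(const$nmad, 0)
  expect_equal(const$bwmv_sqrt, 0)
  expect_equal(const$iqr, 0)
  expect_equal(const$ipr90, 0)
  expect_equal(const$ipr99, 0)
  expect_error(robust_stats(1), "sample-size")
  set.seed(50)
  for (k in 1:5) {
    x <- rnorm(50, sd = runif(1, 0.5, 5))
    s <- robust_stats(x)
    expect_equal(s$bwmv_sqrt, bwmv_oracle(x), tolerance = 1e-12)
    expect_equal(s$nmad, 1.4826 * s$mad)
    expect_true(s$ipr99 >= s$ipr90 && s$ipr90 >= s$iqr && s$iqr >= 0)
    expect_equal(s$iqr, s$q75 - s$q25)
  }
})

test_that("NMAD is a consistent Gaussian scale estimator", {
  set.seed(123)
  x <- rnorm(1e5)
  s <- robust_stats(x)
  expect_gt(s$nmad, 0.98)
  expect_lt(s$nmad, 1.02)
  expect_lt(abs(s$mean - s$median), 0.02)
  expect_lt(abs(s$std - s$nmad), 0.02)
})

test_that("a single gross outlier barely moves NMAD but inflates the SD", {
  set.seed(77)
  x <- rnorm(100)
  xo <- c(x, 50)
  expect_lt(abs(robust_stats(xo)$nmad / robust_stats(x)$nmad - 1), 0.05)
  expect_gt(sd(xo) / sd(x) - 1, 0.20)
})

test_that("gaussian_stats matches the textbook estimators", {
  g <- gaussian_stats(c(1, 2, 3))
  expect_equal(g$mean, 2)
  expect_equal(g$std, 1)
  expect_equal(gaussian_stats(rep(3, 5))$std, 0)
  set.seed(8)
  x <- runif(40)
  expect_equal(gaussian_stats(x)$std, sqrt(sum((x - mean(x))^2) / 39))
  expect_error(gaussian_stats(3), "sample-size")
})

test_that("NIR k-means separates the end-members and is affine-invariant", {
  spec <- field_spec(2, 2, seed = 43)
  tr <- simulate_plot_truths(spec)
  o <- generate_orthomosaic(spec, tr, "DAP61")
  pr <- clip_raster(o, o$layout[1, ])
  nir <- raster_band(pr, "NIR")
  seg <- segment_vegetation(nir)
  expect_gte(mean(seg$mask == pr$truth_mask), 0.99)
  expect_true(seg$centers["soybean"] > seg$centers["soil"])
  expect_true(seg$threshold > seg$centers["soil"] &&
                seg$threshold < seg$centers["soybean"])
  seg2 <- segment_vegetation(3 * nir + 7)
  expect_identical(seg2$mask, seg$mask)
  expect_error(segment_vegetation(matrix(5, 4, 4)), "degenerate-clustering")
  expect_error(segment_vegetation(nir, k = 3), "k = 2")
})

test_that("canopy cover converts pixel counts to area and percent", {
  mask <- matrix(FALSE, 20, 20)
  mask[1:10, 1:10] <- TRUE
  cc <- canopy_cover(mask, 0.0508)
  expect_equal(cc$area_m2, 100 * 0.0508^2)
  expect_equal(cc$pct, 25)
  expect_equal(canopy_cover(matrix(FALSE, 3, 3), 0.1)$pct, 0)
  expect_equal(canopy_cover(matrix(TRUE, 3, 3), 0.1)$pct, 100)
})

test_that("edge-projected row counting recovers the planted row number", {
  mk <- function(rows_per_plot, seed) {
    spec <- field_spec(2, 2, rows_per_plot = rows_per_plot, seed = seed)
    tr <- simulate_plot_truths(spec)
    tr$cc_frac[] <- 0.55              # rows clearly separated pre-closure
    o <- generate_orthomosaic(spec, tr, "DAP61")
    lapply(seq_len(4), function(i) clip_raster(o, o$layout[i, ]))
  }
  for (pr in mk(6L, 5)) expect_equal(count_rows(raster_band(pr, "NIR")), 6L)
  for (pr in mk(8L, 6)) expect_equal(count_rows(raster_band(pr, "NIR")), 8L)
  expect_equal(count_rows(matrix(0, 30, 30)), 0L)
})

test_that("row length is the projected extent along the first eigenvector", {
  mask <- matrix(FALSE, 20, 60)
  mask[10, 11:50] <- TRUE                      # 40-pixel stripe
  len <- row_length(mask, 0.05)
  expect_gte(len, 1.95); expect_lte(len, 2.00)
  two <- matrix(FALSE, 5, 20)
  two[3, c(4, 14)] <- TRUE                     # two pixels 10 apart
  expect_equal(row_length(two, 0.05), 0.5)
  disc <- outer(seq_len(41) - 21, seq_len(41) - 21,
                function(i, j) i^2 + j^2 <= 15^2)
  expect_lt(abs(row_length(disc, 1) - 30), 2)  # isotropic: length ~ diameter
  expect_error(row_length(matrix(FALSE, 3, 3), 0.05), "sample-size")
})

test_that("vegetation indices match hand-derived values on canopy medians", {
  med <- c(G = 6.19, R = 2.51, RE = 32.03, NIR = 55.42)
  vi <- compute_vis(med)
  expect_equal(unname(vi["NDVI"]), (55.42 - 2.51) / (55.42 + 2.51))
  expect_equal(unname(vi["NDVI"]), 0.9133, tolerance = 1e-4)
  expect_equal(unname(vi["RVI"]), 22.08, tolerance = 1e-3)
  expect_equal(unname(vi["CIre"]), 0.7302, tolerance = 1e-4)
  expect_equal(unname(vi["DVI"]), 52.91)
  expect_equal(unname(vi["TVI"]),
               0.5 * (120 * (55.42 - 6.19) - 200 * (2.51 - 6.19)))
  expect_equal(unname(vi["SAVI"]),
               1.5 * 52.91 / (55.42 + 2.51 + 0.5))
  expect_equal(unname(vi["RDVI"]), 52.91 / sqrt(57.93))
  expect_equal(unname(vi["VARI"]), (6.19 - 2.51) / (6.19 + 2.51))
  expect_equal(unname(vi["CIg"]), 55.42 / 6.19 - 1)
  vip <- compute_vis(med, vi_params(cig_as_printed = TRUE))
  expect_equal(unname(vip["CIg"]), (55.42 - 6.19) - 1)
  same <- compute_vis(c(G = 5, R = 10, RE = 20, NIR = 10))
  expect_equal(unname(same["NDVI"]), 0)
  expect_equal(unname(same["DVI"]), 0)
  expect_error(compute_vis(c(G = 1, R = 0, RE = 1, NIR = 0)), "numeric-domain")
})

test_that("per-plot radiometric extraction emits the 24-column feature row", {
  spec <- field_spec(2, 2, seed = 47)
  tr <- simulate_plot_truths(spec)
  o <- generate_orthomosaic(spec, tr, "DAP61")
  pr <- clip_raster(o, o$layout[1, ])
  f <- plot_radiometric_features(pr, plot_id = "P0001")
  model_cols <- setdiff(names(f), c("plot_id", grep("^aux_", names(f), value = TRUE)))
  expect_length(model_cols, 24L)
  truth_cc <- 100 * mean(pr$truth_mask)
  expect_lt(abs(f$cc_pct - truth_cc), 0.5)
  expect_length(attr(f, "robust"), 4L)
  soil <- ms_raster(array(15 + rnorm(900 * 4, 0, 0.5), c(30, 30, 4)))
  expect_error(plot_radiometric_features(soil, plot_id = "X"), "X")
})

test_that("cross-plot summaries carry the full robust-statistics vector", {
  spec <- field_spec(3, 2, seed = 53)
  tr <- simulate_plot_truths(spec)
  o <- generate_orthomosaic(spec, tr, "DAP61")
  tab <- radiometric_feature_table(o, o$layout)
  expect_equal(nrow(tab), 6L)
  sm <- summarize_radiometric(tab)
  expect_true(all(c("feature", "nmad", "bwmv_sqrt", "ipr99") %in% names(sm)))
  expect_equal(sm$mean[sm$feature == "cc_pct"], mean(tab$cc_pct))
})
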