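test_that("neighborhood-statistics filtering removes exactly the isolated point", {
  g <- as.matrix(expand.grid(x = seq(0, 1, 0.05), y = seq(0, 1, 0.05)))
  pts <- cbind(g, z = 0)
  cloud <- point_cloud(rbind(pts, c(0.5, 0.5, 10)))
  filt <- filter_outliers(cloud, k_neighbors = 8, n_sigma = 2)
  expect_equal(filt$meta$removed_idx, nrow(pts) + 1L)
  # direct-distance oracle: the removed point is the one whose mean 8-NN
  # distance is extreme
  d <- as.matrix(dist(cloud$points))
  mean_knn <- apply(d, 1, function(r) mean(sort(r)[2:9]))
  expect_equal(unname(which.max(mean_knn)), nrow(pts) + 1L)
  # a clean random cloud loses at most the Gaussian tail of the rule
  set.seed(7)
  clean <- point_cloud(cbind(runif(500), runif(500), rnorm(500, 0, 0.01)))
  expect_lte(length(filter_outliers(clean)$meta$removed_idx), 0.05 * 500)
  expect_error(filter_outliers(point_cloud(pts[1:5, ])), "parameter error")
})

test_that("injected gross outliers are removed from generated clouds", {
  spec <- field_spec(2, 2, seed = 59)
  tr <- simulate_plot_truths(spec)
  cl <- generate_clouds(spec, tr, outlier_frac = 0.01)
  can <- cl$canopy_d1
  filt <- filter_outliers(can)
  injected <- which(can$meta$outlier)
  expect_gte(mean(injected %in% filt$meta$removed_idx), 0.95)
  # guard warns when the removal fraction is implausible
  expect_warning(filter_outliers(can, max_removed_frac = 0.001),
                 "data-quality")
})

test_that("ICP recovers rigid perturbations of a terrain cloud", {
  spec <- field_spec(3, 3, plot_length_m = 2.5, seed = 61)
  tr <- simulate_plot_truths(spec)
  cl <- generate_clouds(spec, tr, density = 80)
  terrain <- cl$terrain$points

  # identity perturbation: identity recovered, RMS at the noise level
  tf0 <- icp_register(terrain, terrain, tol = 1e-9)
  expect_lt(max(abs(tf0$R - diag(3))), 1e-9)
  expect_lt(max(abs(tf0$t)), 1e-9)
  expect_lt(tf0$rms_m, 1e-9)

  ties <- cbind(cl$bars$x, cl$bars$y, cl$bars$height_m + 100)
  # pure translation: recovered within a millimeter
  R1 <- diag(3); t1 <- c(0.5, 0.3, 0.1)
  tf1 <- icp_register(apply_rigid(terrain, R1, t1), terrain,
                      init = coarse_align(apply_rigid(ties, R1, t1), ties),
                      tol = 1e-9)
  expect_lt(max(abs(tf1$t - (-t1))), 1e-3)
  expect_lt(max(abs(tf1$R - diag(3))), 1e-5)

  # 5 degree yaw + translation: within 0.1 degree and a centimeter
  R2 <- uasyield:::.yaw_matrix(5); t2 <- c(0.3, -0.2, 0.05)
  tf2 <- icp_register(apply_rigid(terrain, R2, t2), terrain,
                      init = coarse_align(apply_rigid(ties, R2, t2), ties),
                      tol = 1e-9)
  yaw_err <- atan2(tf2$R[2, 1], tf2$R[1, 1]) * 180 / pi + 5
  expect_lt(abs(yaw_err), 0.1)
  expect_lt(max(abs(tf2$t - as.numeric(-t(R2) %*% t2))), 1e-2)
})

test_that("ICP aligns independently sampled flights to survey accuracy", {
  spec <- field_spec(3, 3, plot_length_m = 2.5, seed = 67)
  tr <- simulate_plot_truths(spec)
  cl <- generate_clouds(spec, tr,
                        perturb = list(list(yaw_deg = 1.0, t = c(0.3, 0.2, 0.05)),
                                       list(yaw_deg = 0, t = c(0, 0, 0))))
  lay <- build_plot_polygons(spec)
  terrain <- filter_outliers(cl$terrain)
  can <- filter_outliers(cl$canopy_d1)
  ground <- !uasyield:::points_in_layout(can$points, lay)
  init <- coarse_align(can$meta$tie_moving, can$meta$tie_fixed)
  tf <- icp_register(can$points[ground, , drop = FALSE], terrain$points,
                     init = init, tol = 1e-7)
  pb <- can$meta$perturbation
  tinv <- as.numeric(pb$center - t(pb$R) %*% (pb$center + pb$t))
  expect_lt(max(abs(tf$t - tinv)), 0.05)
  expect_lt(abs(atan2(tf$R[2, 1], tf$R[1, 1]) * 180 / pi + pb$yaw_deg), 0.2)
  expect_lt(tf$rms_m, 0.1)
})

test_that("height deviation measures canopy height above the local quadric", {
  set.seed(71)
  # flat terrain at z = 0, canopy at 0.8: all heights 0.8
  txy <- cbind(runif(3000, 0, 5), runif(3000, 0, 5))
  terrain <- point_cloud(cbind(txy, 0), role = "terrain")
  cxy <- cbind(runif(500, 1, 4), runif(500, 1, 4))
  canopy <- point_cloud(cbind(cxy, 0.8))
  hf <- height_deviation(canopy, terrain)
  expect_equal(hf$height, rep(0.8, 500), tolerance = 1e-9)
  # canopy below the terrain clamps at zero
  below <- point_cloud(cbind(cxy, -0.3))
  expect_true(all(height_deviation(below, terrain)$height == 0))
})

test_that("quadric terrain from the generator is recovered within noise", {
  spec <- field_spec(2, 2, seed = 73)
  tr <- simulate_plot_truths(spec)
  noise <- 0.008
  cl <- generate_clouds(spec, tr, noise_z = noise, outlier_frac = 0,
                        perturb = list(list(yaw_deg = 0, t = c(0, 0, 0)),
                                       list(yaw_deg = 0, t = c(0, 0, 0))))
  tmodel <- remove_bar_vicinity(cl$terrain, cl$bars, 0.2)
  can <- cl$canopy_d1
  keep <- seq_len(nrow(can$points) - 200)     # drop bar points
  sub <- point_cloud(can$points[keep, , drop = FALSE])
  hf <- height_deviation(sub, tmodel)
  lay <- build_plot_polygons(spec)
  for (i in seq_len(nrow(lay))) {
    ph <- uasyield:::.clip_height_field(hf, lay[i, ])
    veg <- ph$height > 0.15
    h_true <- tr$height_d1[tr$plot_id == lay$plot_id[i]]
    expect_lt(abs(mean(ph$height[veg]) - h_true), max(3 * noise, 0.05 * h_true))
  }
})

test_that("bar calibration recovers an injected reconstruction bias", {
  spec <- field_spec(2, 2, seed = 79)
  tr <- simulate_plot_truths(spec)
  for (bias in c(0, 0.05)) {
    cl <- generate_clouds(spec, tr, height_bias_m = bias, outlier_frac = 0,
                          perturb = list(list(yaw_deg = 0, t = c(0, 0, 0)),
                                         list(yaw_deg = 0, t = c(0, 0, 0))))
    tmodel <- remove_bar_vicinity(cl$terrain, cl$bars, 0.2)
    hf <- height_deviation(cl$canopy_d1, tmodel)
    cal <- calibrate_heights(hf, cl$bars)
    expect_lt(abs(cal$calibration_offset_m - (-bias)), 0.015)
    expect_lt(mean(abs(attr(cal, "bar_residuals_m"))), 0.025)
  }
  expect_error(calibrate_heights(height_field(cbind(0, 0), 1), data.frame()),
               "bar")
})

test_that("mesh volume integrates analytic surfaces", {
  set.seed(83)
  xy <- cbind(runif(800, 0, 2), runif(800, 0, 2))
  poly <- list(min_x = 0, min_y = 0, max_x = 2, max_y = 2)
  # uniform 1 m canopy over a 2 x 2 m plot: 4 m^3 = 4000 dm^3
  mv <- mesh_volume(height_field(xy, rep(1, 800)), poly)
  expect_lt(abs(mv$volume_dm3 - 4000) / 4000, 0.02)
  expect_equal(mesh_volume(height_field(xy, rep(0, 800)), poly)$volume_dm3, 0)
  # hemispherical mound vs fine-grid Riemann oracle
  xy2 <- cbind(runif(4000, 0, 5), runif(4000, 0, 5))
  r2 <- (xy2[, 1] - 2.5)^2 + (xy2[, 2] - 2.5)^2
  h2 <- ifelse(r2 < 4, sqrt(pmax(4 - r2, 0)), 0)
  poly5 <- list(min_x = 0, min_y = 0, max_x = 5, max_y = 5)
  vol <- mesh_volume(height_field(xy2, h2), poly5)$volume_dm3
  gg <- expand.grid(x = seq(0.005, 4.995, 0.01), y = seq(0.005, 4.995, 0.01))
  rr <- (gg$x - 2.5)^2 + (gg$y - 2.5)^2
  riemann <- sum(sqrt(pmax(4 - rr, 0)) * 0.01^2) * 1000
  expect_lt(abs(vol - riemann) / riemann, 0.05)
  # degenerate (collinear) support cannot be meshed
  line <- height_field(cbind(seq(0, 1, 0.1), 0.5), rep(1, 11))
  expect_error(mesh_volume(line, poly), "meshing error")
})

test_that("mesh volume is invariant under in-plane rotation", {
  set.seed(89)
  xy <- cbind(runif(1500, -1, 1), runif(1500, -1, 1))
  h <- 0.5 + 0.3 * exp(-(xy[, 1]^2 + xy[, 2]^2))
  poly <- list(min_x = -0.7, min_y = -0.7, max_x = 0.7, max_y = 0.7)
  v1 <- mesh_volume(height_field(xy, h), poly)$volume_dm3
  th <- 30 * pi / 180
  rot <- xy %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  v2 <- mesh_volume(height_field(rot, h), poly)$volume_dm3
  expect_lt(abs(v2 - v1) / v1, 0.02)
})

test_that("increment features difference the two dates point-wise", {
  set.seed(97)
  xy <- cbind(runif(600, 0, 2), runif(600, 0, 2))
  h1 <- runif(600, 0.4, 0.6)
  hf1 <- height_field(xy, h1, date_tag = "DAP61")
  # identical clouds: increment identically zero
  inc0 <- height_increment(hf1, hf1)
  expect_true(all(inc0$height == 0))
  # uniform +0.2 m growth on a jittered support
  xy2 <- xy + matrix(runif(1200, -0.02, 0.02), ncol = 2)
  hf2 <- height_field(xy2, h1 + 0.2, date_tag = "DAP70")
  inc <- height_increment(hf2, hf1)
  expect_gt(length(inc$height), 500)
  expect_lt(abs(mean(inc$height) - 0.2), 0.05)
  # far-apart supports do not pair
  far <- height_field(xy + 100, h1)
  expect_length(height_increment(far, hf1)$height, 0L)
})

test_that("per-plot geometric features cover each source with 4 model columns", {
  res <- small_pipeline()
  geo <- res$geo
  model_cols <- grep("^(cv_dm3|hmax_cm|cv_var_pct|hmax_var_pct)_", names(geo),
                     value = TRUE)
  expect_length(model_cols, 12L)
  expect_true(all(c("aux_hmean_cm_d61", "aux_hstd_cm_inc") %in% names(geo)))
  field <- small_field()
  # volumes scale with true cover x height; correlation must be strong
  truth <- field$truths[match(geo$plot_id, field$truths$plot_id), ]
  expect_gt(cor(geo$cv_dm3_d61, truth$cc_frac * truth$height_d1), 0.95)
  expect_gt(cor(geo$hmax_cm_d70, truth$height_d2), 0.8)
  # increment heights track the true growth
  expect_gt(cor(geo$hmax_cm_inc, 100 * (truth$height_d2 - truth$height_d1)), 0.7)
})
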