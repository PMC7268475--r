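# Point-in-layout lookup for regular grids: plots share column x-extents and
# row y-extents, so membership reduces to two interval searches.
points_in_layout <- function(points, layout) {
  xs <- sort(unique(layout$min_x)); xe <- layout$max_x[match(xs, layout$min_x)]
  ys <- sort(unique(layout$min_y)); ye <- layout$max_y[match(ys, layout$min_y)]
  ci <- findInterval(points[, 1], xs)
  ri <- findInterval(points[, 2], ys)
  okc <- ci >= 1 & points[, 1] < xe[pmax(ci, 1)]
  okr <- ri >= 1 & points[, 2] < ye[pmax(ri, 1)]
  okc & okr
}

#' Run the full synthetic-field analysis pipeline
#'
#' End-to-end orchestration over a simulated field: per-plot radiometric
#' features from the two orthomosaics; point-cloud outlier filtering, ICP
#' registration of each study date onto the terrain reference (using points
#' outside the plot grid — alleys, borders and calibration bars — as the
#' terrain set), quadric height differencing, bar calibration, growth
#' increment and per-plot geometric features; feature-table assembly, split,
#' and both ensemble-tree yield models with their evaluations.
#'
#' @param field a field list from [simulate_field()].
#' @param split_seed seed fixing the train/test assignment.
#' @param test_fraction withheld fraction of plots.
#' @param model_seed seed for tree randomness.
#' @param grid_m volume-integration grid, meters.
#' @param vi vegetation-index parameters ([vi_params()]).
#' @param calib_tol_m bar-calibration tolerance, meters.
#' @param fit_models fit and evaluate the regressions (disable to stop after
#'   feature extraction).
#' @return List: `features` (the assembled table with split), `msi`
#'   (radiometric tables), `geo` (geometric table), `registration` (per-date
#'   [rigid_transform]s), `height_fields`, `fits`, `evaluations`,
#'   `accuracy` (data.frame of per-model accuracy and MAE).
#' @export
run_field_pipeline <- function(field, split_seed = 42L, test_fraction = 0.15,
                               model_seed = 42L, grid_m = 0.45,
                               vi = vi_params(), calib_tol_m = 0.025,
                               fit_models = TRUE) {
  layout <- field$layout
  msi <- lapply(field$ortho, radiometric_feature_table, layout = layout,
                params = vi)

  terrain <- filter_outliers(field$clouds$terrain)
  bars <- field$bars
  terrain_model <- remove_bar_vicinity(terrain, bars, radius = 0.2)

  process_date <- function(canopy) {
    canopy <- filter_outliers(canopy)
    ground <- !points_in_layout(canopy$points, layout)
    init <- if (!is.null(canopy$meta$tie_moving))
      coarse_align(canopy$meta$tie_moving, canopy$meta$tie_fixed)
    else rigid_transform()
    tf <- icp_register(canopy$points[ground, , drop = FALSE], terrain$points,
                       init = init)
    reg <- point_cloud(transform_points(tf, canopy$points),
                       date_tag = canopy$date_tag, role = "canopy",
                       meta = canopy$meta)
    # restrict height evaluation to plot interiors plus the bar sites
    nnb <- RANN::nn2(as.matrix(bars[, c("x", "y")]),
                     reg$points[, 1:2, drop = FALSE], k = 1L)
    keep <- points_in_layout(reg$points, layout) | nnb$nn.dists[, 1L] <= 0.2
    sub <- point_cloud(reg$points[keep, , drop = FALSE],
                       date_tag = reg$date_tag, role = "canopy")
    hf <- height_deviation(sub, terrain_model)
    hf <- calibrate_heights(hf, bars, tol_m = calib_tol_m)
    list(transform = tf, hf = hf)
  }
  d61 <- process_date(field$clouds$canopy_d1)
  d70 <- process_date(field$clouds$canopy_d2)
  hfs <- list(d61 = d61$hf, d70 = d70$hf,
              inc = height_increment(d70$hf, d61$hf))
  geo <- geometric_feature_table(hfs, layout, grid_m = grid_m)

  tab <- assemble_feature_table(msi[[1]], msi[[2]], geo, field$yields)
  tab <- split_train_test(tab, test_fraction = test_fraction, seed = split_seed)

  out <- list(features = tab, msi = msi, geo = geo,
              registration = list(d61 = d61$transform, d70 = d70$transform),
              height_fields = hfs)
  if (fit_models) {
    cfgs <- list(
      `bagged-forest` = model_config("bagged-forest", seed = model_seed,
                                     test_fraction = test_fraction),
      `boosted-trees` = model_config("boosted-trees", seed = model_seed,
                                     test_fraction = test_fraction))
    fits <- lapply(cfgs, fit_model, table = tab)
    out$fits <- fits
    out$evaluations <- lapply(fits, evaluate_model)
    out$accuracy <- do.call(rbind, lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      pr <- f$predictions[f$predictions$split == "test", ]
      data.frame(model = nm, acc_pct = f$acc_pct, acc_abs_pct = f$acc_abs_pct,
                 test_ae_pct = mean(abs(100 * (pr$predicted - pr$actual) / pr$actual)),
                 mae_kg_ha = f$mae_kg_ha, stringsAsFactors = FALSE)
    }))
  }
  out
}

#' Write a model report as JSON
#'
#' @param fit a `fit_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(fit, path) {
  rep <- list(config = unclass(fit$config),
              acc_pct = fit$acc_pct, acc_abs_pct = fit$acc_abs_pct,
              mae_kg_ha = fit$mae_kg_ha,
              importance = as.list(fit$importance))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
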