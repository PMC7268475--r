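#' Field specification for the synthetic breeding trial
#'
#' Describes a rectangular grid of rectangular plots. Plot length runs along
#' x; crop rows are stripes along x spaced `row_spacing_m` apart across the
#' plot width (y). Defaults follow a soybean yield trial: rows 0.76 m apart,
#' 6 or 8 rows per plot, 5.08 cm multispectral and 2.54 cm RGB ground sample
#' distance.
#'
#' @param n_cols,n_rows number of plot columns (along x) and rows (along y).
#' @param plot_length_m,plot_width_m plot footprint in meters. `plot_width_m`
#'   defaults to `rows_per_plot * row_spacing_m`.
#' @param alley_m gap between adjacent plots, meters.
#' @param row_spacing_m crop row spacing within a plot, meters.
#' @param rows_per_plot crop rows per plot (6 or 8).
#' @param gsd_msi_m,gsd_rgb_m ground sample distances, meters/pixel.
#' @param border_m bare-soil margin around the plot grid, meters.
#' @param seed integer RNG seed driving all generators for this field.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(n_cols, n_rows, plot_length_m = 2, plot_width_m = NULL,
                       alley_m = 0.6, row_spacing_m = 0.76, rows_per_plot = 6L,
                       gsd_msi_m = 0.0508, gsd_rgb_m = 0.0254, border_m = 1.5,
                       seed = 1L) {
  if (is.null(plot_width_m)) plot_width_m <- rows_per_plot * row_spacing_m
  vals <- c(n_cols, n_rows, plot_length_m, plot_width_m, alley_m,
            row_spacing_m, rows_per_plot, gsd_msi_m, gsd_rgb_m)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all field dimensions must be positive")
  if (!rows_per_plot %in% c(6L, 8L))
    warning("rows_per_plot is usually 6 or 8")
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 plot_length_m = plot_length_m, plot_width_m = plot_width_m,
                 alley_m = alley_m, row_spacing_m = row_spacing_m,
                 rows_per_plot = as.integer(rows_per_plot),
                 gsd_msi_m = gsd_msi_m, gsd_rgb_m = gsd_rgb_m,
                 border_m = border_m, seed = as.integer(seed)),
            class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field_spec> %d x %d plots (%.2f x %.2f m, alley %.2f m), %d rows @ %.2f m\n",
              x$n_cols, x$n_rows, x$plot_length_m, x$plot_width_m, x$alley_m,
              x$rows_per_plot, x$row_spacing_m))
  invisible(x)
}

field_extent <- function(spec) {
  w <- spec$n_cols * spec$plot_length_m + (spec$n_cols - 1) * spec$alley_m
  h <- spec$n_rows * spec$plot_width_m + (spec$n_rows - 1) * spec$alley_m
  c(xmin = 0, ymin = 0,
    xmax = w + 2 * spec$border_m, ymax = h + 2 * spec$border_m)
}

#' Default family panel
#'
#' Round-robin family labels for synthetic plots; includes three named soybean
#' families commonly reported in breeding panels plus numbered fillers.
#'
#' @param n number of family labels.
#' @return Character vector of length `n`.
#' @export
default_families <- function(n = 28L) {
  base <- c("PI404188A", "Prohio", "LG90-2550")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("FAM-%02d", seq_len(n - length(base))))
}

# Date-tagged vegetation reflectance medians (percent) on the Parrot-Sequoia
# band set, at the scale of a late-R4/early-R5 soybean canopy.
.veg_reflectance <- function(date_tag) {
  switch(date_tag,
         DAP61 = c(G = 6.19, R = 2.51, RE = 32.03, NIR = 55.42),
         DAP70 = c(G = 5.85, R = 2.60, RE = 32.22, NIR = 55.58),
         c(G = 6.0, R = 2.55, RE = 32.1, NIR = 55.5))
}

.soil_reflectance <- c(G = 10, R = 12, RE = 14, NIR = 15)
.band_noise_veg <- c(G = 0.4, R = 0.2, RE = 1.5, NIR = 1.0)
.band_noise_soil <- c(G = 0.5, R = 0.5, RE = 0.8, NIR = 1.0)

#' Generate per-plot latent truths
#'
#' Draws the latent traits that drive every synthetic product: canopy cover
#' fraction, per-date mean canopy height, and a chlorophyll scalar scaling the
#' NIR/G contrast. Canopy cover is Beta-distributed with mean 0.80; heights
#' center on 0.578 m (first study date) growing to 0.798 m (second); the
#' chlorophyll scalar is N(1, 0.15) truncated below at 0.5.
#'
#' @param spec a [field_spec].
#' @param families character vector of family labels, assigned round-robin.
#' @param height_mean_m per-date mean canopy heights (length 2).
#' @param height_sd_m plot-to-plot SD of first-date height.
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return data.frame with one row per plot (`plot_id`, `family`, `cc_frac`,
#'   `height_d1`, `height_d2`, `chl`).
#' @export
simulate_plot_truths <- function(spec, families = default_families(),
                                 height_mean_m = c(0.578, 0.798),
                                 height_sd_m = 0.10, seed = spec$seed) {
  n <- spec$n_cols * spec$n_rows
  set.seed(seed)
  cc <- stats::rbeta(n, 19.2, 4.8)                      # mean .8, sd .08
  h1 <- pmax(stats::rnorm(n, height_mean_m[1], height_sd_m), 0.05)
  growth <- height_mean_m[2] / height_mean_m[1]
  h2 <- pmax(h1 * growth + stats::rnorm(n, 0, 0.03), h1)
  chl <- pmax(stats::rnorm(n, 1, 0.15), 0.5)
  data.frame(plot_id = sprintf("P%04d", seq_len(n)),
             family = rep_len(families, n),
             cc_frac = cc, height_d1 = h1, height_d2 = h2, chl = chl,
             stringsAsFactors = FALSE)
}

# y-centers of the crop rows of one plot (min_y..max_y footprint)
.row_centers <- function(spec, min_y, max_y) {
  mid <- (min_y + max_y) / 2
  k <- seq_len(spec$rows_per_plot)
  mid + (k - (spec$rows_per_plot + 1) / 2) * spec$row_spacing_m
}

.stripe_halfwidth <- function(spec, cc_frac) {
  pmin(cc_frac * spec$plot_width_m / spec$rows_per_plot,
       spec$row_spacing_m) / 2
}

.check_layout_disjoint <- function(layout) {
  n <- nrow(layout)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) {
    j <- seq(i + 1, n)
    ovl <- layout$min_x[i] < layout$max_x[j] & layout$max_x[i] > layout$min_x[j] &
           layout$min_y[i] < layout$max_y[j] & layout$max_y[i] > layout$min_y[j]
    if (any(ovl))
      stop("layout error: overlapping plot footprints (", layout$plot_id[i],
           " and ", layout$plot_id[j][which(ovl)[1]], ")")
  }
  invisible(TRUE)
}

#' Generate a four-band synthetic orthomosaic
#'
#' Renders the field as a G/R/RE/NIR percent-reflectance raster: bare soil
#' everywhere, with each plot's crop rows drawn as stripes of vegetation
#' reflectance whose total width realizes the plot's true canopy-cover
#' fraction. The per-plot chlorophyll scalar modulates the NIR/G contrast.
#' Per-pixel Gaussian noise is added and truncated at zero; vegetation and
#' soil NIR are separated by far more than the noise SD so the end-member
#' clustering downstream has a well-defined optimum.
#'
#' @param spec a [field_spec].
#' @param truths data.frame from [simulate_plot_truths()], one row per plot.
#' @param date_tag `"DAP61"` or `"DAP70"` (selects band medians).
#' @param layout optional plot layout (defaults to [build_plot_polygons()]).
#' @param veg,soil named per-band medians (percent); defaults are date-tagged.
#' @param noise_veg,noise_soil named per-band noise SDs (percent).
#' @param seed RNG seed; default derives from `spec$seed` and the date.
#' @return An [ms_raster] with the per-pixel truth vegetation mask in
#'   `$truth_mask` and the layout in `$layout`.
#' @export
generate_orthomosaic <- function(spec, truths, date_tag = "DAP61",
                                 layout = NULL,
                                 veg = .veg_reflectance(date_tag),
                                 soil = .soil_reflectance,
                                 noise_veg = .band_noise_veg,
                                 noise_soil = .band_noise_soil,
                                 seed = NULL) {
  if (is.null(layout)) layout <- build_plot_polygons(spec)
  .check_layout_disjoint(layout)
  if (nrow(truths) < nrow(layout))
    stop("truths must cover every plot in the layout")
  truths <- truths[match(layout$plot_id, truths$plot_id), ]
  if (anyNA(truths$cc_frac)) stop("truths must cover every plot in the layout")
  if (is.null(seed))
    seed <- (spec$seed + 1000L * (utf8ToInt(substr(date_tag, nchar(date_tag), nchar(date_tag))))) %% .Machine$integer.max
  set.seed(seed)

  ext <- field_extent(spec)
  g <- spec$gsd_msi_m
  nc <- ceiling((ext["xmax"] - ext["xmin"]) / g)
  nr <- ceiling((ext["ymax"] - ext["ymin"]) / g)
  xc <- ext[["xmin"]] + (seq_len(nc) - 0.5) * g
  yc <- ext[["ymax"]] - (seq_len(nr) - 0.5) * g   # top to bottom
  bn <- c("G", "R", "RE", "NIR")

  bands <- array(NA_real_, c(nr, nc, 4L), dimnames = list(NULL, NULL, bn))
  for (b in seq_along(bn))
    bands[, , b] <- soil[bn[b]] + matrix(stats::rnorm(nr * nc, 0, noise_soil[bn[b]]), nr, nc)

  mask <- matrix(FALSE, nr, nc)
  for (p in seq_len(nrow(layout))) {
    ix <- which(xc >= layout$min_x[p] & xc < layout$max_x[p])
    iy <- which(yc >= layout$min_y[p] & yc < layout$max_y[p])
    if (!length(ix) || !length(iy)) next
    ctr <- .row_centers(spec, layout$min_y[p], layout$max_y[p])
    hw <- .stripe_halfwidth(spec, truths$cc_frac[p])
    inrow <- vapply(yc[iy], function(y) any(abs(y - ctr) < hw), logical(1))
    if (!any(inrow)) next
    iyv <- iy[inrow]
    mask[iyv, ix] <- TRUE
    chl <- truths$chl[p]
    mod <- c(G = 1 - 0.15 * (chl - 1), R = 1, RE = 1, NIR = 1 + 0.15 * (chl - 1))
    for (b in seq_along(bn)) {
      mu <- veg[bn[b]] * mod[bn[b]]
      bands[iyv, ix, b] <- mu + matrix(stats::rnorm(length(iyv) * length(ix), 0,
                                                    noise_veg[bn[b]]),
                                       length(iyv), length(ix))
    }
  }
  bands[bands < 0] <- 0
  r <- ms_raster(bands, xmin = ext[["xmin"]], ymax = ext[["ymax"]], gsd = g,
                 band_names = bn)
  r$truth_mask <- mask
  r$layout <- layout
  r$date_tag <- date_tag
  r
}

.quadric_z <- function(coef, x, y)
  coef[1] + coef[2] * x + coef[3] * y + coef[4] * x^2 + coef[5] * x * y + coef[6] * y^2

# terrain surface = gentle quadric + tillage-scale micro-relief. The
# micro-relief is a sum of three obliquely oriented, incommensurate
# sinusoids (aperiodic in aggregate), which is what makes terrain point
# clouds horizontally informative for registration.
.surface_z <- function(coef, x, y, rough_amp = 0, rough_wl = 1.5) {
  z <- .quadric_z(coef, x, y)
  if (rough_amp > 0) {
    amp <- rough_amp * c(1, 0.6, 0.35)
    wl <- rough_wl * c(3.42, 1.54, 0.713)
    th <- c(0.40, 1.73, 2.91)
    ph <- c(0.3, 2.2, 4.1)
    for (i in 1:3)
      z <- z + amp[i] * sin(2 * pi * (cos(th[i]) * x + sin(th[i]) * y) / wl[i] + ph[i])
  }
  z
}

.yaw_matrix <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

apply_rigid <- function(points, R, t, center = c(0, 0, 0)) {
  sweep(sweep(points, 2, center) %*% t(R), 2, center + t, "+")
}

#' Generate synthetic terrain and canopy point clouds
#'
#' The terrain reference samples a gently curved quadric surface
#' `z = c0 + c1 x + c2 y + c3 x^2 + c4 xy + c5 y^2` over the field at the
#' requested density. Canopy clouds for the two study dates sample the same
#' terrain plus, over each plot's crop-row stripes, the plot's true canopy
#' height with within-plot variation. Five fixed calibration bars of known
#' height are rendered as point discs in the alleys of every cloud. Each
#' canopy cloud receives (i) an optional global height bias, (ii) a known
#' rigid perturbation (yaw about the field center plus translation) recorded
#' in `meta$perturbation` so registration can be exercised, and (iii) a
#' configurable fraction of gross z-outliers, labeled in `meta$outlier`.
#'
#' @param spec a [field_spec].
#' @param truths data.frame from [simulate_plot_truths()].
#' @param density points per square meter (the photogrammetric products this
#'   emulates exceed 100 points/m^2).
#' @param noise_z vertical noise SD, meters.
#' @param height_cv within-plot coefficient of variation of canopy height.
#' @param outlier_frac fraction of points displaced into gross z-outliers.
#' @param height_bias_m global height bias added to canopy clouds (recovered
#'   downstream by bar calibration).
#' @param rough_amp_m,rough_wl_m amplitude and wavelength of the tillage-scale
#'   terrain micro-relief superimposed on the quadric (soil-surface texture;
#'   also what makes the terrain horizontally informative for registration).
#' @param perturb list with `yaw_deg` and `t` (length-3 translation) per date,
#'   or `NULL` for small random perturbations.
#' @param terrain_coef the six quadric coefficients.
#' @param bar_heights_m heights of the five fixed bars, meters.
#' @param seed RNG seed; defaults to `spec$seed + 7`.
#' @return List with `terrain`, `canopy_d1`, `canopy_d2` ([point_cloud]s) and
#'   `bars` (data.frame `bar_id`, `x`, `y`, `height_m`).
#' @export
generate_clouds <- function(spec, truths, density = 120, noise_z = 0.008,
                            height_cv = 0.15, outlier_frac = 0.01,
                            height_bias_m = 0, rough_amp_m = 0.02,
                            rough_wl_m = 1.5, perturb = NULL,
                            terrain_coef = c(100, 0.010, -0.008, 2e-4, -1.5e-4, 1.2e-4),
                            bar_heights_m = c(0.9, 1.1, 1.3, 0.7, 1.5),
                            seed = NULL) {
  if (is.null(seed)) seed <- (spec$seed + 7L) %% .Machine$integer.max
  set.seed(seed)
  layout <- build_plot_polygons(spec)
  truths <- truths[match(layout$plot_id, truths$plot_id), ]
  ext <- field_extent(spec)
  area <- (ext[["xmax"]] - ext[["xmin"]]) * (ext[["ymax"]] - ext[["ymin"]])
  ctr <- c((ext[["xmin"]] + ext[["xmax"]]) / 2, (ext[["ymin"]] + ext[["ymax"]]) / 2, 0)

  # fixed bars placed in the border margin (left/right/top/bottom/center-gap)
  nb <- length(bar_heights_m)
  bx <- ext[["xmin"]] + stats::runif(nb) * (ext[["xmax"]] - ext[["xmin"]])
  by <- rep(c(ext[["ymin"]] + spec$border_m / 2, ext[["ymax"]] - spec$border_m / 2),
            length.out = nb)
  bars <- data.frame(bar_id = sprintf("B%d", seq_len(nb)), x = bx, y = by,
                     height_m = bar_heights_m)

  surf <- function(x, y) .surface_z(terrain_coef, x, y, rough_amp_m, rough_wl_m)
  sample_surface <- function(n) {
    x <- stats::runif(n, ext[["xmin"]], ext[["xmax"]])
    y <- stats::runif(n, ext[["ymin"]], ext[["ymax"]])
    cbind(x = x, y = y, z = surf(x, y) + stats::rnorm(n, 0, noise_z))
  }
  bar_points <- function() {
    do.call(rbind, lapply(seq_len(nb), function(i) {
      m <- 40L
      r <- 0.05 * sqrt(stats::runif(m)); a <- stats::runif(m, 0, 2 * pi)
      x <- bars$x[i] + r * cos(a); y <- bars$y[i] + r * sin(a)
      cbind(x = x, y = y,
            z = surf(bars$x[i], bars$y[i]) + bars$height_m[i] +
              stats::rnorm(m, 0, noise_z))
    }))
  }

  n_ground <- round(area * density)
  terrain <- point_cloud(rbind(sample_surface(n_ground), bar_points()),
                         date_tag = "DAP15", role = "terrain",
                         meta = list(terrain_coef = terrain_coef))

  canopy_one <- function(date_idx, date_tag) {
    pts <- sample_surface(round(area * density))
    veg <- rep(FALSE, nrow(pts))
    h_col <- if (date_idx == 1) truths$height_d1 else truths$height_d2
    for (p in seq_len(nrow(layout))) {
      inplot <- pts[, 1] >= layout$min_x[p] & pts[, 1] < layout$max_x[p] &
                pts[, 2] >= layout$min_y[p] & pts[, 2] < layout$max_y[p]
      if (!any(inplot)) next
      rc <- .row_centers(spec, layout$min_y[p], layout$max_y[p])
      hw <- .stripe_halfwidth(spec, truths$cc_frac[p])
      dy <- abs(outer(pts[inplot, 2], rc, "-"))
      instripe <- apply(dy < hw, 1, any)
      idx <- which(inplot)[instripe]
      if (!length(idx)) next
      veg[idx] <- TRUE
      h <- h_col[p] * pmax(1 + stats::rnorm(length(idx), 0, height_cv), 0)
      pts[idx, 3] <- pts[idx, 3] + h
    }
    bp <- bar_points()
    pts <- rbind(pts, bp)
    veg <- c(veg, rep(FALSE, nrow(bp)))
    ground <- !veg
    ground[seq(nrow(pts) - nrow(bp) + 1, nrow(pts))] <- TRUE  # bars join ICP set

    n_out <- round(outlier_frac * nrow(pts))
    outlier <- rep(FALSE, nrow(pts))
    if (n_out > 0) {
      oi <- sample.int(nrow(pts), n_out)
      pts[oi, 3] <- pts[oi, 3] + sample(c(-1, 1), n_out, replace = TRUE) *
        stats::runif(n_out, 1.5, 5)
      outlier[oi] <- TRUE
    }
    # reconstruction height bias affects elevated surfaces (canopy, bars),
    # not the bare ground, so registration cannot absorb it and the bar
    # calibration downstream has to
    elevated <- veg | c(rep(FALSE, nrow(pts) - nrow(bp)), rep(TRUE, nrow(bp)))
    pts[elevated, 3] <- pts[elevated, 3] + height_bias_m

    # tie points: bar-top centers, the GCP-like features picked for coarse
    # registration (fixed-frame mates in meta$tie_fixed)
    tie_fixed <- cbind(bars$x, bars$y, surf(bars$x, bars$y) + bars$height_m)
    tie_moving <- cbind(bars$x, bars$y,
                        surf(bars$x, bars$y) + bars$height_m + height_bias_m)

    if (is.null(perturb)) {
      pb <- list(yaw_deg = stats::runif(1, -1.5, 1.5),
                 t = c(stats::runif(2, -0.3, 0.3), stats::runif(1, -0.05, 0.05)))
    } else pb <- perturb[[date_idx]]
    R <- .yaw_matrix(pb$yaw_deg)
    pts <- apply_rigid(pts, R, pb$t, center = ctr)
    tie_moving <- apply_rigid(tie_moving, R, pb$t, center = ctr)
    point_cloud(pts, date_tag = date_tag, role = "canopy",
                meta = list(perturbation = list(R = R, t = pb$t, center = ctr,
                                                yaw_deg = pb$yaw_deg),
                            height_bias_m = height_bias_m,
                            tie_moving = tie_moving, tie_fixed = tie_fixed,
                            veg = veg, ground = ground, outlier = outlier))
  }

  list(terrain = terrain,
       canopy_d1 = canopy_one(1, "DAP61"),
       canopy_d2 = canopy_one(2, "DAP70"),
       bars = bars)
}

#' Generate ground-truth grain yields
#'
#' Yields are a linear combination of the latent traits plus Gaussian noise:
#' `yield = b0 + b1 cc_frac + b2 height_mean + b3 chl + N(0, sigma)`, in
#' kg/ha. Defaults are tuned so the marginal distribution matches a rainfed
#' soybean trial: mean about 3783 kg/ha, SD about 770 kg/ha.
#'
#' @param truths data.frame from [simulate_plot_truths()].
#' @param coeffs numeric length 4: intercept and coefficients on `cc_frac`,
#'   mean height (m) and `chl`.
#' @param sigma residual SD, kg/ha (>= 0).
#' @param seed RNG seed.
#' @return data.frame `plot_id`, `family`, `yield_kg_ha`.
#' @export
generate_yield <- function(truths, coeffs = c(-4624.591, 4000, 3500, 2800),
                           sigma = 350, seed = 1L) {
  if (length(coeffs) != 4L) stop("coeffs must be (intercept, cc, height, chl)")
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  set.seed(seed)
  hmean <- (truths$height_d1 + truths$height_d2) / 2
  y <- coeffs[1] + coeffs[2] * truths$cc_frac + coeffs[3] * hmean +
    coeffs[4] * truths$chl + stats::rnorm(nrow(truths), 0, sigma)
  data.frame(plot_id = truths$plot_id, family = truths$family,
             yield_kg_ha = pmax(y, 1), stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic field
#'
#' One-call wrapper producing everything the pipeline consumes: layout,
#' truths, two orthomosaics, three point clouds, bars and yields.
#'
#' @param spec a [field_spec].
#' @param families family label panel.
#' @param yield_coeffs,yield_sigma passed to [generate_yield()].
#' @param ... passed to [generate_clouds()].
#' @return List `spec`, `layout`, `truths`, `ortho` (list of two
#'   [ms_raster]s), `clouds`, `bars`, `yields`.
#' @export
simulate_field <- function(spec, families = default_families(),
                           yield_coeffs = c(-4624.591, 4000, 3500, 2800),
                           yield_sigma = 350, ...) {
  layout <- build_plot_polygons(spec)
  truths <- simulate_plot_truths(spec, families)
  ortho <- list(DAP61 = generate_orthomosaic(spec, truths, "DAP61", layout = layout),
                DAP70 = generate_orthomosaic(spec, truths, "DAP70", layout = layout))
  clouds <- generate_clouds(spec, truths, ...)
  yields <- generate_yield(truths, coeffs = yield_coeffs, sigma = yield_sigma,
                           seed = (spec$seed + 99L) %% .Machine$integer.max)
  list(spec = spec, layout = layout, truths = truths, ortho = ortho,
       clouds = clouds[c("terrain", "canopy_d1", "canopy_d2")],
       bars = clouds$bars, yields = yields)
}

#' Write a simulated field to a directory
#'
#' Writes the layout as GeoJSON, orthomosaics as TIFF + world file, clouds as
#' ASCII PLY, and bars/yields as CSV.
#'
#' @param field result of [simulate_field()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_field <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_layout_geojson(field$layout, file.path(dir, "plots.geojson"))
  write_orthomosaic(field$ortho$DAP61, file.path(dir, "msi_dap61.tif"))
  write_orthomosaic(field$ortho$DAP70, file.path(dir, "msi_dap70.tif"))
  write_ply(field$clouds$terrain, file.path(dir, "terrain_dap15.ply"))
  write_ply(field$clouds$canopy_d1, file.path(dir, "canopy_dap61.ply"))
  write_ply(field$clouds$canopy_d2, file.path(dir, "canopy_dap70.ply"))
  utils::write.csv(field$bars, file.path(dir, "bars.csv"), row.names = FALSE)
  utils::write.csv(field$yields, file.path(dir, "yields.csv"), row.names = FALSE)
  # tie points (GCP-like bar-top picks) per study date, for coarse registration
  for (d in c("canopy_d1", "canopy_d2")) {
    m <- field$clouds[[d]]$meta
    if (!is.null(m$tie_moving)) {
      tie <- data.frame(mx = m$tie_moving[, 1], my = m$tie_moving[, 2],
                        mz = m$tie_moving[, 3], fx = m$tie_fixed[, 1],
                        fy = m$tie_fixed[, 2], fz = m$tie_fixed[, 3])
      utils::write.csv(tie, file.path(dir, paste0("tie_points_",
                                                  tolower(field$clouds[[d]]$date_tag),
                                                  ".csv")), row.names = FALSE)
    }
  }
  invisible(dir)
}
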