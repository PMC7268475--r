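#' Robust statistics of a reflectance sample
#'
#' Computes the Gaussian moments together with the robust estimators used for
#' per-plot reflectance analysis: median, MAD, normalized MAD
#' (`NMAD = 1.4826 * MAD`, consistent with the Gaussian SD), the square root
#' of the biweight midvariance, percentiles at 2.5/25/75/97.5%, and absolute
#' interpercentile ranges at 50% (IQR), 90% (`P95 - P5`) and 99%
#' (`P99.5 - P0.5`) confidence. Percentiles use the linear-interpolation
#' convention between order statistics.
#'
#' The biweight midvariance downweights points far from the median:
#' `BwMv = n * sum(a_i (x_i - m)^2 (1 - U_i^2)^4) /
#'         (sum(a_i (1 - U_i^2)(1 - 5 U_i^2)))^2`
#' with `U_i = (x_i - m) / (9 MAD)` and `a_i = 1` iff `|U_i| < 1`. For a
#' constant sample (MAD = 0) all dispersion estimates are defined as 0.
#'
#' @param values numeric vector, length >= 2.
#' @return Object of class `robust_stats`: named list `mean`, `std`, `median`,
#'   `mad`, `nmad`, `bwmv_sqrt`, `p2_5`, `q25`, `q75`, `p97_5`, `iqr`,
#'   `ipr90`, `ipr99`.
#' @export
robust_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values))
    stop("sample-size error: need >= 2 finite values")
  m <- stats::median(values)
  madv <- stats::median(abs(values - m))       # raw MAD (no consistency factor)
  nmad <- 1.4826 * madv
  if (madv > 0) {
    U <- (values - m) / (9 * madv)
    a <- as.numeric(abs(U) < 1)
    num <- length(values) * sum(a * (values - m)^2 * (1 - U^2)^4)
    den <- sum(a * (1 - U^2) * (1 - 5 * U^2))^2
    bwmv <- num / den
  } else bwmv <- 0
  q <- stats::quantile(values, c(0.005, 0.025, 0.05, 0.25, 0.75, 0.95, 0.975, 0.995),
                       names = FALSE, type = 7)
  structure(list(mean = mean(values), std = stats::sd(values), median = m,
                 mad = madv, nmad = nmad, bwmv_sqrt = sqrt(bwmv),
                 p2_5 = q[2], q25 = q[4], q75 = q[5], p97_5 = q[7],
                 iqr = q[5] - q[4], ipr90 = q[6] - q[3], ipr99 = q[8] - q[1]),
            class = "robust_stats")
}

#' @export
print.robust_stats <- function(x, ...) {
  cat(sprintf("<robust_stats> mean %.4g sd %.4g | median %.4g NMAD %.4g sqrt(BwMv) %.4g | IQR %.4g IPR90 %.4g IPR99 %.4g\n",
              x$mean, x$std, x$median, x$nmad, x$bwmv_sqrt, x$iqr, x$ipr90, x$ipr99))
  invisible(x)
}

#' Gaussian statistics
#' @param values numeric vector, length >= 2.
#' @return List `mean`, `std` (sample SD, n-1 denominator).
#' @export
gaussian_stats <- function(values) {
  if (length(values) < 2L || anyNA(values))
    stop("sample-size error: need >= 2 finite values")
  list(mean = mean(values), std = stats::sd(values))
}

#' Segment soybean from soil on the NIR band
#'
#' One-dimensional two-class k-means on the near-infrared pixel values (the
#' band with the largest spectral separation between the end-members). The
#' cluster with the higher centroid is labeled soybean; the returned threshold
#' is the midpoint between the two centroids. Initialization is deterministic
#' at the sample's 10th and 90th percentiles (Lloyd iterations, tolerance
#' 1e-6, at most 100 iterations), so segmentation is seed-free and invariant
#' to affine rescaling of the band.
#'
#' @param nir_band numeric matrix of NIR values.
#' @param k number of classes; only 2 is supported.
#' @param min_sep_ratio degenerate-clustering guard: the distance between
#'   the two centroids must exceed this multiple of the pooled
#'   within-cluster SD. A unimodal Gaussian splits with a ratio near 2.7, a
#'   genuine soil/canopy NIR contrast scores far above 10, so the default
#'   rejects plots with no vegetation (or no soil) end-member.
#' @return List `mask` (logical matrix, TRUE = soybean), `threshold`,
#'   `centers` (soil, soybean).
#' @export
segment_vegetation <- function(nir_band, k = 2L, min_sep_ratio = 4) {
  if (k != 2L) stop("only k = 2 (vegetation and ground) is supported")
  x <- as.numeric(nir_band)
  if (length(x) < 2L || diff(range(x)) == 0)
    stop("degenerate-clustering error: constant NIR band")
  ctr <- stats::quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
  if (ctr[1] == ctr[2]) ctr <- range(x)
  for (it in seq_len(100L)) {
    thr <- mean(ctr)
    hi <- x > thr
    if (!any(hi) || all(hi))
      stop("degenerate-clustering error: single cluster")
    new <- c(mean(x[!hi]), mean(x[hi]))
    if (max(abs(new - ctr)) < 1e-6) { ctr <- new; break }
    ctr <- new
  }
  thr <- mean(ctr)
  hi <- x > thr
  within <- sqrt((sum((x[!hi] - ctr[1])^2) + sum((x[hi] - ctr[2])^2)) /
                   length(x))
  if (within > 0 && (ctr[2] - ctr[1]) / within < min_sep_ratio)
    stop("degenerate-clustering error: end-members not separable on NIR")
  list(mask = matrix(as.numeric(nir_band) > thr, nrow(nir_band), ncol(nir_band)),
       threshold = thr, centers = c(soil = ctr[1], soybean = ctr[2]))
}

#' Canopy cover from a vegetation mask
#'
#' @param mask logical matrix (TRUE = soybean pixel).
#' @param gsd_m ground sample distance, meters/pixel.
#' @return List `area_m2` (`count * gsd^2`) and `pct`
#'   (`100 * count / total`).
#' @export
canopy_cover <- function(mask, gsd_m) {
  if (!length(mask)) stop("mask is empty")
  n_veg <- sum(mask)
  list(area_m2 = n_veg * gsd_m^2, pct = 100 * n_veg / length(mask))
}

#' Count complete crop rows in a plot
#'
#' Computes a Canny edge map of the plot's NIR band, projects the edge
#' responses across the row direction, and counts the edge lines whose
#' support spans at least `completeness` of the plot length; each complete
#' crop row contributes its two boundary lines, so the row count is half the
#' number of qualifying lines. Rows are assumed to run along x (the plot
#' length), i.e. along the image columns.
#'
#' @param nir_band numeric matrix of NIR values for one clipped plot.
#' @param completeness fraction of the plot length an edge line must span to
#'   mark a complete row.
#' @param sigma Canny smoothing SD, pixels.
#' @return Integer row count (0 allowed).
#' @export
count_rows <- function(nir_band, completeness = 0.9, sigma = 1) {
  if (!length(nir_band) || diff(range(nir_band)) == 0) return(0L)
  edges <- canny_edges(nir_band, sigma = sigma)
  if (!any(edges)) return(0L)
  # tolerate 1-px vertical jitter of the edge line before projecting
  e <- edges
  if (nrow(e) > 2L) {
    e[-1, ] <- e[-1, ] | edges[-nrow(edges), ]
    e[-nrow(e), ] <- e[-nrow(e), ] | edges[-1, ]
  }
  support <- rowMeans(e)
  qualify <- support >= completeness
  runs <- rle(qualify)
  n_lines <- sum(runs$values)
  as.integer(n_lines %/% 2L)
}

#' Row length via principal component analysis
#'
#' PCA of the soybean-pixel coordinates; the row length is the range of the
#' projections onto the first eigenvector of the coordinate covariance
#' matrix, scaled by the ground sample distance.
#'
#' @param mask logical matrix (TRUE = soybean pixel).
#' @param gsd_m meters/pixel.
#' @return Length in meters.
#' @export
row_length <- function(mask, gsd_m) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2L) stop("sample-size error: need >= 2 vegetation pixels")
  xy <- cbind(idx[, 2], idx[, 1])                 # x = col, y = row
  ev <- eigen(stats::cov(xy), symmetric = TRUE)$vectors[, 1]
  pr <- xy %*% ev
  (max(pr) - min(pr)) * gsd_m
}

#' Vegetation-index parameters
#'
#' @param L SAVI soil-adjustment factor.
#' @param a,b,z GESAVI soil-line parameters (soil line `NIR = a * R + b`).
#' @param cig_as_printed use the subtractive green chlorophyll index
#'   `(NIR - G) - 1` instead of the ratio form `NIR/G - 1`.
#' @return List of parameters for [compute_vis()].
#' @export
vi_params <- function(L = 0.5, a = 1.0, b = 0.0, z = 0.35,
                      cig_as_printed = FALSE) {
  if (L < 0) stop("L must be >= 0")
  list(L = L, a = a, b = b, z = z, cig_as_printed = cig_as_printed)
}

#' Vegetation indices from median reflectances
#'
#' Computes the eleven indices used as model inputs, from the per-band median
#' reflectances of the soybean end-member: NDVI, SAVI, MSAVI, GESAVI, CIre,
#' CIg, VARI, RVI, DVI, RDVI and TVI. MSAVI uses the canonical
#' `(2 NIR + 1 - sqrt((2 NIR + 1)^2 - 8 (NIR - R))) / 2` form and GESAVI the
#' soil-line form `(NIR - b - a R) / (R + z)`. The green chlorophyll index
#' defaults to `NIR/G - 1`, with the subtractive variant available via
#' [vi_params()].
#'
#' @param medians named numeric vector with `G`, `R`, `RE`, `NIR` (percent
#'   reflectance).
#' @param params a [vi_params()] list.
#' @return Named numeric vector of the 11 indices.
#' @export
compute_vis <- function(medians, params = vi_params()) {
  G <- medians[["G"]]; R <- medians[["R"]]
  RE <- medians[["RE"]]; NIR <- medians[["NIR"]]
  if (any(c(G, R, RE, NIR) < 0)) stop("numeric-domain error: negative reflectance")
  if (NIR + R == 0 || G + R == 0 || RE == 0 || R == 0 || G == 0 ||
      R + params$z == 0)
    stop("numeric-domain error: zero denominator in vegetation index")
  disc <- (2 * NIR + 1)^2 - 8 * (NIR - R)
  if (disc < 0) stop("numeric-domain error: negative MSAVI discriminant")
  cig <- if (params$cig_as_printed) (NIR - G) - 1 else NIR / G - 1
  c(NDVI = (NIR - R) / (NIR + R),
    SAVI = (1 + params$L) * (NIR - R) / (NIR + R + params$L),
    MSAVI = (2 * NIR + 1 - sqrt(disc)) / 2,
    GESAVI = (NIR - params$b - params$a * R) / (R + params$z),
    CIre = NIR / RE - 1,
    CIg = cig,
    VARI = (G - R) / (G + R),
    RVI = NIR / R,
    DVI = NIR - R,
    RDVI = (NIR - R) / sqrt(NIR + R),
    TVI = 0.5 * (120 * (NIR - G) - 200 * (R - G)))
}

#' Radiometric features of one clipped plot
#'
#' Orchestrates the per-plot radiometric stage: NIR k-means end-member
#' segmentation, Gaussian and robust statistics of each band over the soybean
#' pixels only, canopy cover, crop-row count and length, and the vegetation
#' indices from the median reflectances. The model feature set per date is 24
#' columns (canopy cover, mean/median/SD for each of the four bands, 11
#' indices); row count, row length, cover area and the full robust statistics
#' are carried as auxiliary outputs.
#'
#' @param plot_raster an [ms_raster] clipped to one plot.
#' @param params a [vi_params()] list.
#' @param plot_id identifier copied into the output row.
#' @return One-row data.frame of features; the per-band [robust_stats] live
#'   in `attr(, "robust")`.
#' @export
plot_radiometric_features <- function(plot_raster, params = vi_params(),
                                      plot_id = NA_character_) {
  seg <- tryCatch(segment_vegetation(raster_band(plot_raster, "NIR")),
                  error = function(e)
                    stop("plot ", plot_id, ": ", conditionMessage(e), call. = FALSE))
  cov <- canopy_cover(seg$mask, plot_raster$gsd)
  bn <- c("G", "R", "RE", "NIR")
  rs <- lapply(bn, function(b) robust_stats(raster_band(plot_raster, b)[seg$mask]))
  names(rs) <- bn
  med <- vapply(rs, `[[`, numeric(1), "median")
  vis <- compute_vis(med, params)
  out <- data.frame(plot_id = plot_id, cc_pct = cov$pct, stringsAsFactors = FALSE)
  for (b in bn) {
    out[[paste0(b, "_mean")]] <- rs[[b]]$mean
    out[[paste0(b, "_median")]] <- rs[[b]]$median
    out[[paste0(b, "_std")]] <- rs[[b]]$std
  }
  for (v in names(vis)) out[[v]] <- unname(vis[v])
  out$aux_cc_m2 <- cov$area_m2
  out$aux_n_rows <- count_rows(raster_band(plot_raster, "NIR"))
  out$aux_row_length_m <- tryCatch(row_length(seg$mask, plot_raster$gsd),
                                   error = function(e) NA_real_)
  attr(out, "robust") <- rs
  out
}

#' Radiometric features for every plot of an orthomosaic
#'
#' @param raster full-field [ms_raster].
#' @param layout plot layout from [build_plot_polygons()].
#' @param params a [vi_params()] list.
#' @return data.frame, one row per plot, ordered as the layout.
#' @export
radiometric_feature_table <- function(raster, layout, params = vi_params()) {
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    pr <- clip_raster(raster, layout[i, ])
    plot_radiometric_features(pr, params, plot_id = layout$plot_id[i])
  })
  do.call(rbind, rows)
}

#' Cross-plot summary of radiometric features
#'
#' Summarizes each numeric per-plot feature across plots with the full
#' [robust_stats] vector — the per-plot-then-aggregate reading of a trial
#' summary table. (Pooling all pixels before summarizing is the other
#' reading; pass the pooled band values straight to [robust_stats()] for
#' that.)
#'
#' @param features data.frame from [radiometric_feature_table()].
#' @return data.frame, one row per feature.
#' @export
summarize_radiometric <- function(features) {
  num <- features[vapply(features, is.numeric, logical(1))]
  rows <- lapply(names(num), function(nm) {
    s <- robust_stats(num[[nm]])
    cbind(data.frame(feature = nm, stringsAsFactors = FALSE),
          as.data.frame(unclass(s)))
  })
  do.call(rbind, rows)
}
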