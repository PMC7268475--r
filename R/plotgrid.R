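#' Build the per-plot polygon grid
#'
#' Builds axis-aligned rectangular plot footprints from the field layout,
#' starting at the top-right plot and proceeding row-major toward the
#' bottom-left, skipping the alley between plots — the ordering a field-map
#' script produces. An optional symmetric shrink margin trims every footprint
#' to suppress border effects.
#'
#' @param spec a [field_spec].
#' @param margin_m symmetric border shrink applied to every side, meters.
#' @param families optional family labels assigned round-robin in plot order.
#' @return data.frame with columns `plot_id`, `family`, `min_x`, `min_y`,
#'   `max_x`, `max_y`, `rows_per_plot`, ordered top-right to bottom-left.
#' @export
build_plot_polygons <- function(spec, margin_m = 0, families = default_families()) {
  stopifnot(inherits(spec, "field_spec"))
  if (spec$alley_m <= 0 || spec$plot_length_m <= 0 || spec$plot_width_m <= 0)
    stop("plot size and alley must be positive")
  if (2 * margin_m >= min(spec$plot_length_m, spec$plot_width_m))
    stop("shrink margin consumes the whole plot")
  n <- spec$n_cols * spec$n_rows
  # grid indices: r = 1 at top, c = 1 at the right
  r <- rep(seq_len(spec$n_rows), each = spec$n_cols)
  cc <- rep(seq_len(spec$n_cols), times = spec$n_rows)
  b <- spec$border_m
  pitch_x <- spec$plot_length_m + spec$alley_m
  pitch_y <- spec$plot_width_m + spec$alley_m
  min_x <- b + (spec$n_cols - cc) * pitch_x
  max_y <- b + spec$n_rows * spec$plot_width_m + (spec$n_rows - 1) * spec$alley_m -
    (r - 1) * pitch_y
  out <- data.frame(
    plot_id = sprintf("P%04d", seq_len(n)),
    family = rep_len(families, n),
    min_x = min_x + margin_m,
    min_y = max_y - spec$plot_width_m + margin_m,
    max_x = min_x + spec$plot_length_m - margin_m,
    max_y = max_y - margin_m,
    rows_per_plot = spec$rows_per_plot,
    stringsAsFactors = FALSE)
  stopifnot(all(out$max_x > out$min_x), all(out$max_y > out$min_y))
  out
}

#' Clip a raster to one plot polygon
#'
#' Keeps exactly the pixels whose centers fall inside the polygon under the
#' half-open `[min, max)` center-in rule, so adjacent plots partition the
#' raster. Georeferencing is preserved.
#'
#' @param raster an [ms_raster].
#' @param poly one-row data.frame (or list) with `min_x`, `min_y`, `max_x`,
#'   `max_y`.
#' @return An [ms_raster] covering the clipped pixels (with `truth_mask`
#'   subset alongside if the raster carries one).
#' @export
clip_raster <- function(raster, poly) {
  stopifnot(inherits(raster, "ms_raster"))
  ctr <- pixel_centers(raster)
  ix <- which(ctr$x >= poly$min_x & ctr$x < poly$max_x)
  iy <- which(ctr$y >= poly$min_y & ctr$y < poly$max_y)
  if (!length(ix) || !length(iy))
    stop("empty-clip error: polygon does not intersect raster")
  out <- ms_raster(raster$bands[iy, ix, , drop = FALSE],
                   xmin = raster$xmin + (min(ix) - 1) * raster$gsd,
                   ymax = raster$ymax - (min(iy) - 1) * raster$gsd,
                   gsd = raster$gsd,
                   band_names = dimnames(raster$bands)[[3]],
                   crs = raster$crs)
  if (!is.null(raster$truth_mask))
    out$truth_mask <- raster$truth_mask[iy, ix, drop = FALSE]
  out
}

#' Clip a point cloud to one plot polygon
#'
#' Retains points with `min_x <= x < max_x` and `min_y <= y < max_y`
#' (half-open bounds, so clipping against an adjacent-plot tiling partitions
#' the cloud and a point on the upper boundary is excluded). An empty result
#' is allowed.
#'
#' @param cloud a [point_cloud].
#' @param poly as in [clip_raster()].
#' @return A [point_cloud]; per-point metadata vectors are subset alongside.
#' @export
clip_cloud <- function(cloud, poly) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0L) stop("cloud is empty")
  p <- cloud$points
  keep <- p[, 1] >= poly$min_x & p[, 1] < poly$max_x &
          p[, 2] >= poly$min_y & p[, 2] < poly$max_y
  meta <- lapply(cloud$meta, function(m)
    if (is.atomic(m) && length(m) == nrow(p)) m[keep] else m)
  point_cloud(p[keep, , drop = FALSE], date_tag = cloud$date_tag,
              role = cloud$role, meta = meta)
}

#' Read / write plot layouts as GeoJSON
#'
#' Layouts are exchanged as a GeoJSON FeatureCollection of axis-aligned
#' polygons with properties `plot_id`, `family` and `rows_per_plot`.
#'
#' @param layout data.frame as returned by [build_plot_polygons()].
#' @param path file path.
#' @return `path` invisibly; `read_layout_geojson()` returns the layout
#'   data.frame.
#' @export
write_layout_geojson <- function(layout, path) {
  feat <- lapply(seq_len(nrow(layout)), function(i) {
    p <- layout[i, ]
    ring <- list(c(p$min_x, p$min_y), c(p$max_x, p$min_y),
                 c(p$max_x, p$max_y), c(p$min_x, p$max_y), c(p$min_x, p$min_y))
    list(type = "Feature",
         properties = list(plot_id = p$plot_id, family = p$family,
                           rows_per_plot = p$rows_per_plot),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_geojson
#' @export
read_layout_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(fc$features, function(f) {
    xy <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    data.frame(plot_id = f$properties$plot_id,
               family = f$properties$family %||% NA_character_,
               min_x = min(xy[, 1]), min_y = min(xy[, 2]),
               max_x = max(xy[, 1]), max_y = max(xy[, 2]),
               rows_per_plot = f$properties$rows_per_plot %||% NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
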