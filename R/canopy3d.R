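#' Statistical outlier filtering of a point cloud
#'
#' Removes isolated points by the neighborhood-statistics rule: for every
#' point the mean distance to its `k_neighbors` nearest neighbors is
#' computed; assuming these distances are Gaussian across the cloud, points
#' whose mean neighbor distance exceeds the global mean plus
#' `n_sigma` standard deviations are discarded.
#'
#' @param cloud a [point_cloud].
#' @param k_neighbors neighborhood size.
#' @param n_sigma rejection threshold in SD units.
#' @param max_removed_frac data-quality guard: a warning is raised when more
#'   than this fraction of the cloud is removed.
#' @return The filtered [point_cloud]; indices of removed points in
#'   `meta$removed_idx`, per-point metadata vectors subset alongside.
#' @export
filter_outliers <- function(cloud, k_neighbors = 8L, n_sigma = 2,
                            max_removed_frac = 0.05) {
  n <- n_points(cloud)
  if (n <= k_neighbors)
    stop("parameter error: cloud has too few points for k_neighbors")
  nn <- RANN::nn2(cloud$points, k = k_neighbors + 1L)
  d <- rowMeans(nn$nn.dists[, -1L, drop = FALSE])
  keep <- d <= mean(d) + n_sigma * stats::sd(d)
  frac <- mean(!keep)
  if (frac > max_removed_frac)
    warning(sprintf("data-quality warning: %.1f%% of points removed (max %.1f%%)",
                    100 * frac, 100 * max_removed_frac))
  meta <- lapply(cloud$meta, function(m)
    if (is.atomic(m) && length(m) == n) m[keep] else m)
  meta$removed_idx <- which(!keep)
  point_cloud(cloud$points[keep, , drop = FALSE], date_tag = cloud$date_tag,
              role = cloud$role, meta = meta)
}

#' Rigid transform constructor
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation, meters.
#' @param rms_m post-fit closest-point RMS, meters.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0), rms_m = NA_real_) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3L, 3L)), length(t) == 3L)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("R must be a proper rotation")
  structure(list(R = R, t = as.numeric(t), rms_m = rms_m),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform].
#' @param points N x 3 matrix.
#' @return Transformed N x 3 matrix.
#' @export
transform_points <- function(transform, points)
  sweep(points %*% t(transform$R), 2, transform$t, "+")

#' @export
print.rigid_transform <- function(x, ...) {
  yaw <- atan2(x$R[2, 1], x$R[1, 1]) * 180 / pi
  cat(sprintf("<rigid_transform> yaw %.4f deg, t = (%.4f, %.4f, %.4f) m, rms %.4g m\n",
              yaw, x$t[1], x$t[2], x$t[3], x$rms_m))
  invisible(x)
}

#' Coarse rigid alignment from tie points
#'
#' Closed-form rigid (Kabsch) alignment of matched tie points — the
#' coarse-registration step from manually picked ground control points that
#' precedes ICP refinement.
#'
#' @param tie_moving,tie_fixed matched N x 3 tie-point coordinates (N >= 3).
#' @return A [rigid_transform] mapping the moving frame onto the fixed one.
#' @export
coarse_align <- function(tie_moving, tie_fixed) {
  tie_moving <- as.matrix(tie_moving); tie_fixed <- as.matrix(tie_fixed)
  stopifnot(nrow(tie_moving) >= 3L, nrow(tie_moving) == nrow(tie_fixed))
  fit <- .kabsch(tie_moving, tie_fixed)
  r <- transform_points(list(R = fit$R, t = fit$t), tie_moving) - tie_fixed
  rigid_transform(fit$R, fit$t, rms_m = sqrt(mean(rowSums(r^2))))
}

# Kabsch solve: rotation + translation minimizing ||R p + t - q||^2
.kabsch <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  H <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(cq - R %*% cp))
}

#' Iterative closest point registration
#'
#' Point-to-point ICP of a moving cloud onto a fixed cloud, restricted to a
#' rigid (rotation + translation) transform: per iteration, nearest-neighbor
#' correspondences are found in the fixed cloud and the closed-form rigid
#' solve updates the pose, until the closest-point RMS changes by less than
#' `tol` or `max_iter` is reached. The caller supplies clouds already reduced
#' to terrain points (study-date canopy surfaces would otherwise bias the
#' fit); a coarse initialization can be supplied from tie points. Large
#' moving clouds are deterministically subsampled to `max_points`
#' correspondences.
#'
#' @param moving,fixed [point_cloud]s or N x 3 matrices (terrain points).
#' @param init a [rigid_transform] starting pose for the moving cloud.
#' @param max_iter,tol iteration cap and RMS-change stopping tolerance (m).
#' @param max_points correspondence budget.
#' @param reject_mult correspondences farther than `reject_mult` times the
#'   median closest-point distance are discarded each iteration (guards
#'   against border points with no overlap without biasing the inlier set).
#' @return A [rigid_transform] mapping moving into the fixed frame, with
#'   final RMS in `$rms_m` and iteration count in `attr(,"iterations")`.
#'   Warns (`registration-failure`) when the RMS does not improve on the
#'   initial pose.
#' @export
icp_register <- function(moving, fixed, init = rigid_transform(),
                         max_iter = 50L, tol = 1e-6, max_points = 50000L,
                         reject_mult = 3) {
  P <- if (inherits(moving, "point_cloud")) moving$points else as.matrix(moving)
  Q <- if (inherits(fixed, "point_cloud")) fixed$points else as.matrix(fixed)
  if (!nrow(P) || !nrow(Q)) stop("both clouds must be non-empty")
  if (nrow(P) > max_points)
    P <- P[round(seq(1L, nrow(P), length.out = max_points)), , drop = FALSE]
  cur <- init
  rms0 <- NA_real_
  prev <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    Pt <- transform_points(cur, P)
    nn <- RANN::nn2(Q, Pt, k = 1L)
    keep <- nn$nn.dists[, 1L] <= reject_mult * stats::median(nn$nn.dists[, 1L])
    rms <- sqrt(mean(nn$nn.dists[keep, 1L]^2))
    if (it == 1L) rms0 <- rms
    if (abs(prev - rms) < tol || it >= max_iter) {
      cur$rms_m <- rms
      break
    }
    prev <- rms
    fit <- .kabsch(P[keep, , drop = FALSE],
                   Q[nn$nn.idx[keep, 1L], , drop = FALSE])
    cur <- rigid_transform(fit$R, fit$t)
  }
  if (cur$rms_m > rms0 + max(1e-3, 0.01 * rms0))
    warning("registration-failure: ICP did not improve on the initial pose")
  attr(cur, "iterations") <- it
  cur
}

#' Height field constructor
#'
#' Per-point canopy height above the terrain reference, tied to the (x, y)
#' support of the canopy cloud.
#'
#' @param xy N x 2 matrix of point locations, meters.
#' @param height numeric vector of heights, meters.
#' @param flagged logical: points whose terrain model fell back from the
#'   quadric fit.
#' @param calibration_offset_m constant offset applied by bar calibration.
#' @param date_tag acquisition tag.
#' @return Object of class `height_field`.
#' @export
height_field <- function(xy, height, flagged = logical(length(height)),
                         calibration_offset_m = 0, date_tag = NA_character_) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L, nrow(xy) == length(height))
  colnames(xy) <- c("x", "y")
  structure(list(xy = xy, height = as.numeric(height), flagged = flagged,
                 calibration_offset_m = calibration_offset_m,
                 date_tag = date_tag),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  cat(sprintf("<height_field> %d points, height %.3f-%.3f m (mean %.3f), offset %.4f m\n",
              length(x$height), min(x$height), max(x$height), mean(x$height),
              x$calibration_offset_m))
  invisible(x)
}

#' Remove the vicinity of calibration bars from a cloud
#'
#' The terrain reference also images the fixed bars; before it serves as the
#' local terrain model, points within `radius` of a known bar location are
#' dropped so the bars do not contaminate the ground surface.
#'
#' @param cloud a [point_cloud].
#' @param bars data.frame with `x`, `y` bar locations.
#' @param radius exclusion radius, meters.
#' @return The cleaned [point_cloud].
#' @export
remove_bar_vicinity <- function(cloud, bars, radius = 0.2) {
  if (!nrow(bars)) return(cloud)
  nn <- RANN::nn2(as.matrix(bars[, c("x", "y")]), cloud$points[, 1:2, drop = FALSE],
                  k = 1L)
  keep <- nn$nn.dists[, 1L] > radius
  meta <- lapply(cloud$meta, function(m)
    if (is.atomic(m) && length(m) == n_points(cloud)) m[keep] else m)
  point_cloud(cloud$points[keep, , drop = FALSE], date_tag = cloud$date_tag,
              role = cloud$role, meta = meta)
}

#' Canopy height above the terrain reference
#'
#' Computes the deviation cloud between a registered canopy cloud and the
#' terrain reference: for each canopy point a quadric surface
#' `z(x, y)` is fit to its `k` nearest terrain points (nearest in the
#' horizontal plane) and the height is the canopy z minus the quadric z at
#' the point, clamped below at 0 m. Points whose local fit degenerates fall
#' back to a plane (then mean-z) and are flagged.
#'
#' @param canopy a [point_cloud] already registered into the terrain frame.
#' @param terrain the terrain-reference [point_cloud] (bars removed; see
#'   [remove_bar_vicinity()]).
#' @param k terrain neighbors per local fit (>= 6 for the 6-coefficient
#'   quadric).
#' @param clamp clamp heights below at 0 m.
#' @return A [height_field] on the canopy support.
#' @export
height_deviation <- function(canopy, terrain, k = 12L, clamp = TRUE) {
  stopifnot(inherits(canopy, "point_cloud"), inherits(terrain, "point_cloud"))
  if (n_points(terrain) < 3L) stop("terrain cloud too small")
  k <- min(k, n_points(terrain))
  nn <- RANN::nn2(terrain$points[, 1:2, drop = FALSE],
                  canopy$points[, 1:2, drop = FALSE], k = k)
  fit <- quadric_surface_z(canopy$points[, 1:2, drop = FALSE],
                           terrain$points, nn$nn.idx)
  h <- canopy$points[, 3L] - fit$z
  if (clamp) h <- pmax(h, 0)
  height_field(canopy$points[, 1:2, drop = FALSE], h, flagged = fit$flagged,
               date_tag = canopy$date_tag)
}

#' Calibrate a height field against fixed bars
#'
#' Estimates the height of each fixed bar from the height field (median
#' height within `radius` of the bar location), applies the constant offset
#' `mean(measured - estimated)`, and verifies that the post-calibration mean
#' absolute bar residual is below `tol_m`.
#'
#' @param hf a [height_field].
#' @param bars data.frame with `x`, `y`, `height_m` (ruler-measured).
#' @param radius match radius around each bar, meters.
#' @param tol_m acceptance tolerance on the mean absolute bar residual.
#' @return The calibrated [height_field]; offset in `$calibration_offset_m`,
#'   per-bar residuals in `attr(,"bar_residuals_m")`.
#' @export
calibrate_heights <- function(hf, bars, radius = 0.12, tol_m = 0.025) {
  stopifnot(inherits(hf, "height_field"))
  if (!nrow(bars)) stop("need >= 1 bar")
  est <- vapply(seq_len(nrow(bars)), function(i) {
    d2 <- (hf$xy[, 1] - bars$x[i])^2 + (hf$xy[, 2] - bars$y[i])^2
    sel <- d2 <= radius^2
    if (!any(sel)) return(NA_real_)
    stats::median(hf$height[sel])
  }, numeric(1))
  if (anyNA(est)) stop("calibration-failure: no height-field points at some bars")
  offset <- mean(bars$height_m - est)
  resid <- bars$height_m - (est + offset)
  if (mean(abs(resid)) > tol_m)
    stop(sprintf("calibration-failure: mean absolute bar residual %.3f m exceeds %.3f m",
                 mean(abs(resid)), tol_m))
  out <- height_field(hf$xy, pmax(hf$height + offset, 0), flagged = hf$flagged,
                      calibration_offset_m = hf$calibration_offset_m + offset,
                      date_tag = hf$date_tag)
  attr(out, "bar_residuals_m") <- resid
  out
}

# Clip a height field to a polygon (half-open bounds, as clip_cloud)
.clip_height_field <- function(hf, poly) {
  keep <- hf$xy[, 1] >= poly$min_x & hf$xy[, 1] < poly$max_x &
          hf$xy[, 2] >= poly$min_y & hf$xy[, 2] < poly$max_y
  height_field(hf$xy[keep, , drop = FALSE], hf$height[keep],
               flagged = hf$flagged[keep],
               calibration_offset_m = hf$calibration_offset_m,
               date_tag = hf$date_tag)
}

#' Mesh-integrated canopy volume of one plot
#'
#' Triangulates the per-point heights over the plot (2.5-D Delaunay), applies
#' one pass of Laplacian smoothing of the vertex heights (`lambda` = 0.5),
#' and integrates the surface as prisms over a regular grid covering the plot
#' footprint: each grid cell (clipped to the footprint) contributes its area
#' times the interpolated height at its center. Cells outside the convex
#' hull of the points — holes in the mesh — are filled from the nearest
#' vertex height (planar fill).
#'
#' @param hf a [height_field] clipped to the plot.
#' @param poly plot polygon (`min_x`, `min_y`, `max_x`, `max_y`).
#' @param grid_m integration grid spacing, meters (0.45 m default trades
#'   resolution against cost).
#' @param lambda,passes Laplacian smoothing weight and passes.
#' @return List `volume_dm3`, `cell_volumes_dm3` (vector over grid cells)
#'   and `heights_m` (smoothed vertex heights).
#' @export
mesh_volume <- function(hf, poly, grid_m = 0.45, lambda = 0.5, passes = 1L) {
  x <- hf$xy[, 1]; y <- hf$xy[, 2]; h <- hf$height
  if (length(h) < 3L) stop("meshing error: need >= 3 points")
  tm <- tryCatch(interp::tri.mesh(x, y),
                 error = function(e) stop("meshing error: degenerate point set"))
  tr <- interp::triangles(tm)
  # Laplacian smoothing over triangulation edges
  if (passes > 0L && nrow(tr) > 0L) {
    a <- c(tr[, 1], tr[, 2], tr[, 1]); b <- c(tr[, 2], tr[, 3], tr[, 3])
    lo <- pmin(a, b); hi <- pmax(a, b)
    dup <- duplicated(lo * (length(h) + 1) + hi)   # integer-coded edge ids
    lo <- lo[!dup]; hi <- hi[!dup]
    ii <- c(lo, hi); jj <- c(hi, lo)
    for (p in seq_len(passes)) {
      s <- rowsum(h[jj], ii)
      cnt <- rowsum(rep(1, length(jj)), ii)
      nbmean <- h
      nbmean[as.integer(rownames(s))] <- s / cnt
      h <- h + lambda * (nbmean - h)
    }
  }
  # integration grid over the footprint, last cell clipped
  xe <- unique(c(seq(poly$min_x, poly$max_x, by = grid_m), poly$max_x))
  ye <- unique(c(seq(poly$min_y, poly$max_y, by = grid_m), poly$max_y))
  if (length(xe) < 2L) xe <- c(poly$min_x, poly$max_x)
  if (length(ye) < 2L) ye <- c(poly$min_y, poly$max_y)
  cw <- diff(xe); ch <- diff(ye)
  cx <- (xe[-1] + xe[-length(xe)]) / 2
  cy <- (ye[-1] + ye[-length(ye)]) / 2
  g <- expand.grid(x = cx, y = cy)
  area <- as.numeric(outer(cw, ch))          # matches expand.grid order
  zi <- suppressWarnings(
    interp::interpp(x, y, h, xo = g$x, yo = g$y, duplicate = "mean"))$z
  if (anyNA(zi)) {                           # planar fill outside the hull
    nn <- RANN::nn2(cbind(x, y), cbind(g$x[is.na(zi)], g$y[is.na(zi)]), k = 1L)
    zi[is.na(zi)] <- h[nn$nn.idx[, 1L]]
  }
  cellv <- zi * area * 1000                  # m^3 -> dm^3
  list(volume_dm3 = sum(cellv), cell_volumes_dm3 = cellv, heights_m = h)
}

#' Increment height field between two dates
#'
#' Realizes the growth-increment cloud as per-point height differences on
#' the support of the later date: each later-date point is paired with its
#' horizontally nearest earlier-date point within `max_dist` and carries the
#' height difference (later minus earlier); unmatched points are dropped.
#'
#' @param hf_late,hf_early [height_field]s of the two dates, same frame.
#' @param max_dist pairing radius, meters.
#' @return A [height_field] of height differences, tagged
#'   `"<late>-<early>"`.
#' @export
height_increment <- function(hf_late, hf_early, max_dist = 0.10) {
  nn <- RANN::nn2(hf_early$xy, hf_late$xy, k = 1L)
  keep <- nn$nn.dists[, 1L] <= max_dist
  height_field(hf_late$xy[keep, , drop = FALSE],
               hf_late$height[keep] - hf_early$height[nn$nn.idx[keep, 1L]],
               flagged = hf_late$flagged[keep],
               date_tag = paste0(hf_late$date_tag, "-", hf_early$date_tag))
}

#' Geometric features of every plot
#'
#' Per plot and per source (each study date plus the increment between
#' them): mesh canopy volume (dm^3), maximum height (cm) and the within-plot
#' variation percentages of both (100 * SD / mean of the grid-cell volumes
#' and of the point heights). Mean and SD of height are retained as
#' auxiliary columns. Twelve model features per plot result from the default
#' two dates + increment. Plots with no cloud support are flagged and
#' returned with missing features so the modeling stage can drop them.
#'
#' @param hfs named list of [height_field]s, e.g.
#'   `list(d61 = ..., d70 = ..., inc = ...)`.
#' @param layout plot layout from [build_plot_polygons()].
#' @param grid_m integration grid spacing, meters.
#' @return data.frame keyed by `plot_id` with columns
#'   `cv_dm3_<src>`, `hmax_cm_<src>`, `cv_var_pct_<src>`,
#'   `hmax_var_pct_<src>` and auxiliary `aux_hmean_cm_<src>`,
#'   `aux_hstd_cm_<src>`.
#' @export
geometric_feature_table <- function(hfs, layout, grid_m = 0.45) {
  out <- data.frame(plot_id = layout$plot_id, stringsAsFactors = FALSE)
  dropped <- character(0)
  for (src in names(hfs)) {
    cv <- hmax <- cvv <- hmv <- hme <- hsd <- rep(NA_real_, nrow(layout))
    for (i in seq_len(nrow(layout))) {
      ph <- .clip_height_field(hfs[[src]], layout[i, ])
      if (length(ph$height) < 3L) {
        dropped <- c(dropped, paste0(layout$plot_id[i], ":", src))
        next
      }
      mv <- mesh_volume(ph, layout[i, ], grid_m = grid_m)
      cv[i] <- mv$volume_dm3
      hmax[i] <- max(ph$height) * 100
      hme[i] <- mean(ph$height) * 100
      hsd[i] <- stats::sd(ph$height) * 100
      cvv[i] <- if (mean(mv$cell_volumes_dm3) != 0)
        100 * stats::sd(mv$cell_volumes_dm3) / abs(mean(mv$cell_volumes_dm3)) else NA_real_
      hmv[i] <- if (hme[i] != 0) 100 * hsd[i] / abs(hme[i]) else NA_real_
    }
    out[[paste0("cv_dm3_", src)]] <- cv
    out[[paste0("hmax_cm_", src)]] <- hmax
    out[[paste0("cv_var_pct_", src)]] <- cvv
    out[[paste0("hmax_var_pct_", src)]] <- hmv
    out[[paste0("aux_hmean_cm_", src)]] <- hme
    out[[paste0("aux_hstd_cm_", src)]] <- hsd
  }
  if (length(dropped)) {
    message("missing-feature flag for ", length(dropped), " plot/source pairs")
    attr(out, "dropped") <- dropped
  }
  out
}
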