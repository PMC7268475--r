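#' Point cloud container
#'
#' Photogrammetric point clouds are held as an `N x 3` matrix of meters in the
#' local planar CRS, tagged with an acquisition date and a role (terrain
#' reference vs canopy study date).
#'
#' @param points numeric `N x 3` matrix (x, y, z in meters).
#' @param date_tag character tag, e.g. `"DAP15"`.
#' @param role `"terrain"` or `"canopy"`.
#' @param meta optional named list of metadata (e.g. the rigid perturbation a
#'   generator applied, or truth labels used only by tests).
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, date_tag = NA_character_,
                        role = c("canopy", "terrain"), meta = list()) {
  role <- match.arg(role)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an N x 3 matrix")
  if (nrow(points) > 0L && !all(is.finite(points)))
    stop("point coordinates must be finite")
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, date_tag = date_tag, role = role, meta = meta),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, role %s, date %s\n",
              nrow(x$points), x$role, x$date_tag))
  invisible(x)
}

n_points <- function(cloud) nrow(cloud$points)

#' Write / read a point cloud as ASCII PLY
#'
#' A minimal ASCII PLY writer/reader carrying x, y, z and optionally one
#' per-point scalar (e.g. canopy height). Used in place of LAS, for which no
#' installed reader exists.
#'
#' @param cloud a [point_cloud].
#' @param path file path ending in `.ply`.
#' @param scalar optional numeric vector (length N) written as property
#'   `scalar_value`.
#' @return `path` invisibly; `read_ply()` returns a [point_cloud] with the
#'   scalar (if present) in `meta$scalar`.
#' @export
write_ply <- function(cloud, path, scalar = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("comment date_tag %s role %s", cloud$date_tag, cloud$role),
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z")
  if (!is.null(scalar)) {
    stopifnot(length(scalar) == n)
    hdr <- c(hdr, "property float scalar_value")
  }
  hdr <- c(hdr, "end_header")
  m <- if (is.null(scalar)) cloud$points else cbind(cloud$points, scalar)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(m, digits = 9, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not an ASCII PLY file: ", path)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)[1]))
  props <- sub("^property \\S+ ", "", grep("^property", hdr, value = TRUE))
  cm <- grep("^comment date_tag", hdr, value = TRUE)
  date_tag <- NA_character_; role <- "canopy"
  if (length(cm)) {
    tok <- strsplit(cm[1], " ")[[1]]
    date_tag <- tok[3]; role <- tok[5]
  }
  body <- lines[seq(end + 1L, length.out = nv)]
  m <- matrix(scan(text = body, quiet = TRUE), nrow = nv, byrow = TRUE)
  colnames(m) <- props
  meta <- list()
  if ("scalar_value" %in% props) meta$scalar <- m[, "scalar_value"]
  point_cloud(m[, c("x", "y", "z"), drop = FALSE], date_tag = date_tag,
              role = role, meta = meta)
}
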