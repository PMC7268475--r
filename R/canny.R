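# Edge detection internals for crop-row counting: Gaussian smoothing, Sobel
# gradients, non-maximum suppression and Otsu-derived hysteresis thresholds.

.gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# replicate-padded separable convolution
.conv_sep <- function(img, k) {
  r <- (length(k) - 1L) / 2L
  pad_rows <- function(m) m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)), , drop = FALSE]
  conv_cols <- function(m) {
    out <- matrix(0, nrow(m) - 2L * r, ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * m[seq(i, i + nrow(out) - 1L), , drop = FALSE]
    out
  }
  v <- conv_cols(pad_rows(img))
  t(conv_cols(pad_rows(t(v))))
}

.shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(-Inf, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Otsu threshold of a numeric sample (histogram with `nbins` bins)
otsu_threshold <- function(values, nbins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(values, breaks = seq(rng[1], rng[2], length.out = nbins + 1L),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Canny edge map
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and two-threshold hysteresis. The high
#' threshold defaults to the Otsu threshold of the gradient magnitudes and
#' the low threshold to half of it.
#'
#' @param img numeric matrix (one band).
#' @param sigma smoothing SD in pixels.
#' @param high,low hysteresis thresholds on gradient magnitude; `NULL` uses
#'   Otsu and `0.5 * high`.
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(img, sigma = 1, high = NULL, low = NULL) {
  if (nrow(img) < 3L || ncol(img) < 3L) return(matrix(FALSE, nrow(img), ncol(img)))
  sm <- .conv_sep(img, .gaussian_kernel1d(sigma))
  sx <- matrix(0, nrow(sm), ncol(sm)); sy <- sx
  # Sobel via shifted sums (x = columns, y = rows)
  s <- function(dr, dc) { m <- .shift_mat(sm, dr, dc); m[!is.finite(m)] <- sm[!is.finite(m)]; m }
  gx <- (s(-1, -1) + 2 * s(0, -1) + s(1, -1)) - (s(-1, 1) + 2 * s(0, 1) + s(1, 1))
  gy <- (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1)) - (s(1, -1) + 2 * s(1, 0) + s(1, 1))
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi
  # non-maximum suppression along 4 quantized directions
  dir <- findInterval(ang, c(pi / 8, 3 * pi / 8, 5 * pi / 8, 7 * pi / 8)) %% 4L
  nbr <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (d in 0:3) {
    off <- nbr[[d + 1L]]
    m1 <- .shift_mat(mag, off[1], off[2])
    m2 <- .shift_mat(mag, -off[1], -off[2])
    keep <- keep | (dir == d & mag >= m1 & mag >= m2)
  }
  magn <- ifelse(keep, mag, 0)
  if (is.null(high)) high <- otsu_threshold(mag[mag > 0])
  if (is.null(low)) low <- 0.5 * high
  strong <- magn >= high
  weak <- magn >= low
  # hysteresis: grow strong edges into connected weak pixels
  repeat {
    grown <- strong
    for (dr in -1:1) for (dc in -1:1)
      if (dr || dc) grown <- grown | (.shift_mat(strong, dr, dc) > 0 & weak)
    if (identical(grown, strong)) break
    strong <- grown
  }
  strong
}
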