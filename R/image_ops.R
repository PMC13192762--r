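# Low-level 3D image primitives shared by the renderer and the
# segmentation pipeline. Arrays are indexed [y, x, z].

# Replicate-edge shift-and-add separable Gaussian convolution.
# sigma is in voxels, one value per axis (y, x, z); 0 skips the axis.
gaussian_smooth3d <- function(a, sigma) {
  stopifnot(length(sigma) == 3L)
  for (axis in 1:3) a <- convolve_axis(a, sigma[axis], axis)
  a
}

convolve_axis <- function(a, sigma, axis) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  d <- dim(a)
  n <- d[axis]
  out <- array(0, d)
  base <- seq_len(n)
  for (k in -r:r) {
    idx <- pmin(pmax(base + k, 1L), n)
    shifted <- switch(axis,
                      a[idx, , , drop = FALSE],
                      a[, idx, , drop = FALSE],
                      a[, , idx, drop = FALSE])
    out <- out + w[k + r + 1L] * shifted
  }
  out
}

#' Otsu threshold of an intensity sample
#'
#' Histogram-based Otsu threshold: the cut maximizing between-class
#' variance over `n_bins` equal-width bins spanning the data range.
#' Values strictly above the returned threshold are foreground.
#'
#' @param x Numeric vector (or array) of intensities.
#' @param n_bins Number of histogram bins.
#' @return The threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  lo <- min(x); hi <- max(x)
  if (!length(x) || hi <= lo)
    abort("cannot threshold a constant (or empty) intensity sample.")
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-n_bins]) # cut below the last bin at most
  edges[k + 1L]
}

# 26- (or 6-) connected component labeling of a logical 3D array.
label_components <- function(mask, connectivity = 26L) {
  stopifnot(length(dim(mask)) == 3L, connectivity %in% c(6L, 26L))
  .label3d_cpp(as.logical(mask), as.integer(dim(mask)),
               as.integer(connectivity))
}

# Fill internal cavities: background is labeled 6-connected and any
# background component not touching the array border becomes foreground.
fill_holes3d <- function(mask) {
  bg <- label_components(!mask, connectivity = 6L)
  d <- dim(mask)
  border <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ],
                     bg[, , c(1, d[3])]))
  border <- border[border > 0L]
  mask | (bg > 0L & !(bg %in% border))
}

# Mark spheres of physical radius r (um) around a set of voxel centers.
# centers: integer matrix [n x 3] of (y, x, z) voxel indices.
# Returns the logical support array with those spheres set TRUE.
stamp_spheres <- function(support, centers, r, dx, dy, dz) {
  if (!nrow(centers)) return(support)
  d <- dim(support)
  ry <- floor(r / dy); rx <- floor(r / dx); rz <- floor(r / dz)
  off <- expand.grid(oy = -ry:ry, ox = -rx:rx, oz = -rz:rz)
  keep <- (off$oy * dy)^2 + (off$ox * dx)^2 + (off$oz * dz)^2 <= r^2
  off <- off[keep, , drop = FALSE]
  yy <- rep(centers[, 1], each = nrow(off)) + off$oy
  xx <- rep(centers[, 2], each = nrow(off)) + off$ox
  zz <- rep(centers[, 3], each = nrow(off)) + off$oz
  ok <- yy >= 1L & yy <= d[1] & xx >= 1L & xx <= d[2] & zz >= 1L & zz <= d[3]
  idx <- (zz[ok] - 1) * (d[1] * d[2]) + (xx[ok] - 1) * d[1] + yy[ok]
  support[unique(idx)] <- TRUE
  support
}
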