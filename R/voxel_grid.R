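#' Voxel grid: a 3D intensity volume with physical voxel sizes
#'
#' The unit of all image I/O in the package. `data` is indexed
#' `[y, x, z]` (R's matrix convention per slice, slices ordered
#' bottom-to-top); `dx`, `dy`, `dz` are voxel edge lengths in microns.
#'
#' @param data Numeric 3D array of non-negative intensities.
#' @param dx,dy,dz Voxel edge lengths (um), all > 0.
#' @return A `voxel_grid` object.
#' @examples
#' vg <- voxel_grid(array(0, c(8, 8, 4)), dx = 0.11, dy = 0.11, dz = 0.2)
#' voxel_volume(vg)
#' @export
voxel_grid <- function(data, dx, dy = dx, dz) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3D array.")
  if (any(dim(data) < 1L)) abort("all grid dimensions must be >= 1.")
  for (nm in c("dx", "dy", "dz")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      abort(sprintf("`%s` must be a single positive number (um).", nm))
  }
  structure(list(data = data, dx = dx, dy = dy, dz = dz),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels (y, x, z), %g x %g x %g um\n",
              d[1], d[2], d[3], x$dy, x$dx, x$dz))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Physical volume of one voxel (um^3)
#' @param x A [voxel_grid].
#' @return Voxel volume in um^3.
#' @export
voxel_volume <- function(x) {
  stopifnot(inherits(x, "voxel_grid"))
  x$dx * x$dy * x$dz
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

# internal: check two grids share geometry
check_same_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      a$dx != b$dx || a$dy != b$dy || a$dz != b$dz)
    abort("voxel grids have mismatched dimensions or voxel sizes.")
  invisible(TRUE)
}
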