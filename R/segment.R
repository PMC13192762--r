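#' Segmentation parameters
#'
#' @param smooth_sigma_px Gaussian denoising sd in xy pixels; the z sd
#'   is scaled by `dx/dz` so smoothing is physically isotropic.
#' @param min_volume_um3 Minimum connected-component volume retained as
#'   a cell (um^3); rejects debris and noise blobs.
#' @param n_bins Histogram bins for the Otsu threshold.
#' @return A `segment_params` list.
#' @export
segment_params <- function(smooth_sigma_px = 1, min_volume_um3 = 4,
                           n_bins = 256L) {
  structure(list(smooth_sigma_px = smooth_sigma_px,
                 min_volume_um3 = min_volume_um3, n_bins = n_bins),
            class = "segment_params")
}

#' Segment cells from the cytosolic volume-marker channel
#'
#' The cytosolic channel is Gaussian-smoothed, globally Otsu-thresholded,
#' 26-connected components are labeled, components below the minimum
#' volume are discarded, and internal holes (e.g. vacuole shadows in the
#' cytosolic signal) are filled in 3D. Cell volume is voxel count times
#' voxel volume.
#'
#' @param cytosol A [voxel_grid] of the cytosolic marker.
#' @param params A [segment_params()].
#' @return A `cell_segmentation`: integer `labels` array (0 background),
#'   logical `mask`, a `cells` tibble (`cell_label`, `n_voxels`,
#'   `volume_um3`), and the Otsu `threshold` used.
#' @export
segment_cell <- function(cytosol, params = segment_params()) {
  stopifnot(inherits(cytosol, "voxel_grid"))
  sig_xy <- params$smooth_sigma_px
  sig <- c(sig_xy, sig_xy, sig_xy * cytosol$dx / cytosol$dz)
  sm <- gaussian_smooth3d(cytosol$data, sig)
  if (max(sm) <= min(sm))
    abort("no cell found: the cytosolic channel is constant.",
          class = "orgscale_no_cell")
  thr <- otsu_threshold(sm, params$n_bins)
  mask <- sm > thr
  labels <- label_components(mask, 26L)
  vv <- voxel_volume(cytosol)
  counts <- tabulate(labels[labels > 0L])
  keep <- which(counts * vv >= params$min_volume_um3)
  if (!length(keep))
    abort("no cell found: no component above the minimum cell volume.",
          class = "orgscale_no_cell")
  mask <- array(labels %in% keep, dim(labels))
  mask <- fill_holes3d(mask)
  labels <- label_components(mask, 26L)
  counts <- tabulate(labels[labels > 0L])
  cells <- tibble::tibble(cell_label = seq_along(counts),
                          n_voxels = counts,
                          volume_um3 = counts * vv)
  structure(list(labels = labels, mask = labels > 0L, cells = cells,
                 threshold = thr, voxel_volume = vv),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("<cell_segmentation> %d cell(s); volumes (um^3): %s\n",
              nrow(x$cells),
              paste(sprintf("%.1f", x$cells$volume_um3), collapse = ", ")))
  invisible(x)
}

#' Subtract extracellular background from a stack
#'
#' The background level is the mean intensity over voxels outside the
#' cell mask; it is subtracted from every voxel and negative results are
#' clipped to zero.
#'
#' @param stack A [voxel_grid].
#' @param cell_mask Logical array matching the stack (TRUE inside any
#'   cell).
#' @return The corrected [voxel_grid]; the estimated level is attached
#'   as attribute `background`.
#' @export
subtract_background <- function(stack, cell_mask) {
  stopifnot(inherits(stack, "voxel_grid"))
  outside <- !cell_mask
  if (!any(outside))
    abort("cell mask covers the entire stack; no background region.")
  bg <- mean(stack$data[outside])
  out <- voxel_grid(pmax(stack$data - bg, 0), stack$dx, stack$dy, stack$dz)
  attr(out, "background") <- bg
  out
}

#' Segment the organelle channel within a cell
#'
#' Otsu threshold computed over in-cell voxels only (the extracellular
#' region would otherwise dominate the histogram), applied to the
#' smoothed background-subtracted organelle channel and restricted to
#' the cell mask.
#'
#' @param corrected Background-subtracted organelle [voxel_grid].
#' @param cell_mask Logical array (TRUE inside the cell).
#' @param params A [segment_params()].
#' @param threshold Optional manual threshold overriding Otsu.
#' @return Logical organelle mask (always a subset of `cell_mask`).
#' @export
segment_organelle <- function(corrected, cell_mask,
                              params = segment_params(),
                              threshold = NULL) {
  stopifnot(inherits(corrected, "voxel_grid"))
  sig_xy <- params$smooth_sigma_px
  sig <- c(sig_xy, sig_xy, sig_xy * corrected$dx / corrected$dz)
  sm <- gaussian_smooth3d(corrected$data, sig)
  vals <- sm[cell_mask]
  if (!length(vals) || max(vals) <= min(vals))
    abort("no organelle signal: in-cell intensity is constant.",
          class = "orgscale_no_organelle")
  thr <- threshold %||% otsu_threshold(vals, params$n_bins)
  array(sm > thr & cell_mask, dim(cell_mask))
}

#' Total organelle content of one cell
#'
#' Sum of the background-subtracted organelle intensities over voxels in
#' both the cell mask and the organelle mask (in-cell voxels outside the
#' organelle mask are zeroed, i.e. excluded from the sum).
#'
#' @param corrected Background-subtracted organelle [voxel_grid].
#' @param cell_mask,organelle_mask Logical arrays matching the stack.
#' @return Total content (a.u.).
#' @export
total_content <- function(corrected, cell_mask, organelle_mask) {
  stopifnot(inherits(corrected, "voxel_grid"),
            identical(dim(corrected$data), dim(cell_mask)),
            identical(dim(corrected$data), dim(organelle_mask)))
  sum(corrected$data[cell_mask & organelle_mask])
}

#' Vacuole volumetry with sub-resolution exclusion
#'
#' Labels 26-connected components of the organelle (lumen) mask,
#' converts voxel counts to physical volumes, and excludes components
#' whose equivalent spherical diameter `d = (6 V / pi)^(1/3)` falls
#' below `d_min` — by default 0.46 um, below which compartment sizes
#' cannot be trusted at light-microscope resolution. A component with
#' `d` exactly equal to `d_min` is retained.
#'
#' @param corrected Background-subtracted lumen [voxel_grid].
#' @param cell_mask Logical array for one cell.
#' @param d_min Exclusion diameter (um, >= 0).
#' @param organelle_mask Optional precomputed lumen mask; segmented via
#'   [segment_organelle()] when absent.
#' @param params A [segment_params()].
#' @return A list: `vacuoles` tibble (`label`, `volume_um3`,
#'   `diameter_um`, `retained`), `volumes` (retained, um^3),
#'   `vacuole_fraction` (retained volume / cell volume).
#' @export
measure_vacuoles <- function(corrected, cell_mask, d_min = 0.46,
                             organelle_mask = NULL,
                             params = segment_params()) {
  if (d_min < 0) abort("`d_min` must be >= 0.")
  if (is.null(organelle_mask))
    organelle_mask <- segment_organelle(corrected, cell_mask, params)
  vv <- voxel_volume(corrected)
  cell_volume <- sum(cell_mask) * vv
  labels <- label_components(organelle_mask & cell_mask, 26L)
  counts <- tabulate(labels[labels > 0L], nbins = max(labels))
  if (!length(counts)) {
    return(list(vacuoles = tibble::tibble(label = integer(),
                                          volume_um3 = numeric(),
                                          diameter_um = numeric(),
                                          retained = logical()),
                volumes = numeric(), vacuole_fraction = 0))
  }
  vols <- counts * vv
  diam <- (6 * vols / pi)^(1 / 3)
  retained <- diam >= d_min
  list(vacuoles = tibble::tibble(label = seq_along(vols),
                                 volume_um3 = vols,
                                 diameter_um = diam,
                                 retained = retained),
       volumes = vols[retained],
       vacuole_fraction = sum(vols[retained]) / cell_volume)
}

#' Locate the glancing cortical slice of a cell
#'
#' An automated proxy for the first z-slice in focus at the cell cortex:
#' the lowest slice whose in-mask cross-sectional area lies between
#' `lower` and `upper` of the maximal cross-sectional area — a cap slice
#' grazing the cortex, where cortical structures appear en face.
#'
#' @param cell_mask Logical 3D array for one cell.
#' @param lower,upper Area band as fractions of the maximal
#'   cross-section (defaults 0.1 and 0.4).
#' @return The slice index (1-based, bottom-to-top).
#' @export
find_glancing_slice <- function(cell_mask, lower = 0.1, upper = 0.4) {
  if (!any(cell_mask)) abort("cell mask is empty.")
  areas <- apply(cell_mask, 3, sum)
  a_max <- max(areas)
  band <- which(areas > 0 & areas >= lower * a_max & areas <= upper * a_max)
  if (!length(band))
    abort(sprintf(
      "no glancing slice: no cross-section within [%g, %g] of the maximum (%d voxels); slice areas: %s",
      lower, upper, a_max, paste(areas, collapse = " ")))
  band[1]
}

#' Cortical density from a single glancing slice
#'
#' Mean background-subtracted intensity over in-mask pixels of one
#' z-slice; reported as the density of cortical signal (a.u. per pixel).
#'
#' @param corrected Background-subtracted [voxel_grid].
#' @param cell_mask Logical 3D array for the cell.
#' @param z Slice index, e.g. from [find_glancing_slice()].
#' @return Mean in-mask intensity of the slice (a.u./pixel).
#' @export
cortical_density <- function(corrected, cell_mask, z) {
  stopifnot(inherits(corrected, "voxel_grid"))
  m <- cell_mask[, , z]
  if (!any(m)) abort("empty in-slice mask at the requested z.")
  mean(corrected$data[, , z][m])
}
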