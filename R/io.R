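#' Write a two-channel stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered z-major, channel-fastest (z1c1, z1c2, z2c1, ...),
#' i.e. axis order (z, c, y, x). Intensities are stored as 32-bit float
#' scaled into the unit range; the scale factor, voxel sizes and the cell's
#' ground truth are recorded in a JSON sidecar next to the TIFF
#' (`<stem>.json`), which serves as the stack's metadata.
#'
#' @param stack A `cell_stack`.
#' @param path Output TIFF path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_cell_stack <- function(stack, path) {
  ch1 <- stack$cytosol$data; ch2 <- stack$organelle$data
  scale <- max(max(ch1), max(ch2), 1e-12)
  nz <- dim(ch1)[3]
  pages <- vector("list", 2L * nz)
  for (z in seq_len(nz)) {
    pages[[2L * z - 1L]] <- ch1[, , z] / scale
    pages[[2L * z]] <- ch2[, , z] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(
    n_channels = 2L, n_z = nz,
    dx_um = stack$cytosol$dx, dy_um = stack$cytosol$dy,
    dz_um = stack$cytosol$dz,
    intensity_scale = scale,
    cell_id = stack$truth$cell_id %||% NA,
    volume_um3 = stack$truth$volume_um3 %||% NA,
    content_au = stack$truth$content_au %||% NA,
    organelle_volumes = stack$truth$organelle_volumes %||% numeric(),
    seed = stack$truth$cell_seed %||% NA,
    scenario = stack$scenario$name %||% NA,
    geometry = stack$scenario$geometry %||% NA)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

#' Read a two-channel stack from TIFF (+ sidecar or explicit voxel sizes)
#'
#' Accepts any multi-page TIFF with pages ordered z-major,
#' channel-fastest. Voxel sizes come from the JSON sidecar written by
#' [write_cell_stack()] or from the `dx`/`dy`/`dz` arguments (which take
#' precedence); if neither is available, this is an error — voxel sizes
#' are never silently defaulted.
#'
#' @param path TIFF path.
#' @param dx,dy,dz Voxel sizes (um), overriding sidecar metadata.
#' @param n_channels Number of interleaved channels (default 2).
#' @return A `cell_stack` with `cytosol` (channel 1) and `organelle`
#'   (channel 2) [voxel_grid]s; ground truth fields from the sidecar,
#'   when present, are attached as `truth`.
#' @export
read_stack <- function(path, dx = NULL, dy = NULL, dz = NULL,
                       n_channels = 2L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  n_channels <- meta$n_channels %||% n_channels
  if (n_channels < 2L || length(pages) %% n_channels != 0L)
    abort(sprintf("expected %d interleaved channels but file has %d page(s).",
                  max(2L, n_channels), length(pages)))
  dx <- dx %||% meta$dx_um
  dy <- dy %||% meta$dy_um
  dz <- dz %||% meta$dz_um
  if (is.null(dx) || is.null(dy) || is.null(dz))
    abort("voxel sizes unavailable: no JSON sidecar and no dx/dy/dz supplied.")
  scale <- meta$intensity_scale %||% 1
  nz <- length(pages) %/% n_channels
  d <- dim(pages[[1]])
  grab <- function(ch) {
    a <- array(0, c(d[1], d[2], nz))
    for (z in seq_len(nz)) a[, , z] <- pages[[(z - 1L) * n_channels + ch]]
    a * scale
  }
  truth <- if (is.null(meta)) list() else
    list(cell_id = meta$cell_id, volume_um3 = meta$volume_um3,
         content_au = meta$content_au,
         organelle_volumes = meta$organelle_volumes,
         cell_seed = meta$seed)
  structure(
    list(cytosol = voxel_grid(grab(1L), dx, dy, dz),
         organelle = voxel_grid(grab(2L), dx, dy, dz),
         truth = truth,
         scenario = list(name = meta$scenario %||% NA_character_,
                         geometry = meta$geometry %||% NA_character_)),
    class = "cell_stack")
}

#' Write a per-cell measurement table to CSV
#'
#' Column layout: `cell_id`, `cell_volume_um3`, `total_content_au`,
#' `density_au_per_um3`, `vacuole_fraction`, `n_vacuoles`,
#' `cortical_density_au`, `glancing_z` (plus any extra columns present).
#'
#' @param measurements Tibble from [measure_stack()]/[measure_stacks()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(measurements, path) {
  lead <- intersect(c("cell_id", "cell_volume_um3", "total_content_au",
                      "density_au_per_um3", "vacuole_fraction", "n_vacuoles",
                      "cortical_density_au", "glancing_z"),
                    names(measurements))
  readr::write_csv(dplyr::relocate(measurements, dplyr::all_of(lead)), path)
  invisible(path)
}
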