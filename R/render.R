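#' Rendering configuration for the in-silico microscope
#'
#' Controls voxel geometry, optics and noise of [render_cell_stack()].
#' Defaults emulate a spinning-disk setup: 0.11 um xy pixels, 0.2 um
#' z-steps, a constant camera background offset, additive Gaussian read
#' noise, and a mild Gaussian blur standing in for the microscope PSF.
#'
#' @param dx,dy,dz Voxel edge lengths (um).
#' @param pad_um Clearance between the cell and the stack border (um).
#' @param dims Optional fixed stack dimensions `c(ny, nx, nz)`; by
#'   default the field of view is sized to the cell. A cell that does
#'   not fit in a fixed field of view is a geometry error.
#' @param cytosol_intensity Constant cytosol signal, channel 1 (a.u.).
#' @param background Constant camera offset added to both channels (a.u.).
#' @param noise_sd Additive Gaussian camera noise sd (a.u.); 0 disables.
#' @param blur_sigma_um Isotropic Gaussian PSF proxy sd (um); 0 disables.
#' @param tubule_radius_um,tubule_length_per_um3 Mitochondrial tubule
#'   radius (um) and skeleton length per um^3 of cell volume (um/um^3).
#' @param membrane_thickness_um Painted thickness of membrane shells
#'   (vacuole membrane, nuclear envelope), um.
#' @param perox_radius_um Peroxisome radius (um).
#' @param perox_min_sep_um Minimum separation attempted between
#'   peroxisome centers (um).
#' @param er_tubule_length_per_um3 ER tubule skeleton length density.
#' @param er_cortical_thickness_um Physical thickness of the cortical
#'   ER rind (um).
#' @param er_cortical_intensity Optional fixed per-voxel intensity for
#'   the cortical-ER sheets (a.u.); by default all ER structures share
#'   the cell's total content uniformly.
#' @return A `render_config` list.
#' @export
render_config <- function(dx = 0.11, dy = 0.11, dz = 0.2,
                          pad_um = 0.8, dims = NULL,
                          cytosol_intensity = 40, background = 10,
                          noise_sd = 2, blur_sigma_um = 0.1,
                          tubule_radius_um = 0.3,
                          tubule_length_per_um3 = 0.9,
                          membrane_thickness_um = 0.22,
                          perox_radius_um = 0.2,
                          perox_min_sep_um = 1.0,
                          er_tubule_length_per_um3 = 0.25,
                          er_cortical_thickness_um = 0.25,
                          er_cortical_intensity = NULL) {
  structure(as.list(environment()), class = "render_config")
}

#' Render one synthetic two-channel 3D stack
#'
#' The in-silico microscope: paints one ovoid cell (channel 1, constant
#' cytosol signal) and its organelle (channel 2) onto a voxel grid.
#' Channel-2 signal is distributed over the organelle support so that
#' the summed in-cell intensity above background equals the cell's
#' ground-truth content exactly before blur and noise (and within the
#' quantization tolerance after the default mild blur). Organelle
#' geometry follows the scenario tag: a space-filling tubular network
#' (mitochondria), nuclear-envelope shell + tubules + cortical sheets
#' (ER), globular compartments of heterogeneous size (vacuole lumen) or
#' their bounding shells (vacuole membrane), or small puncta
#' (peroxisomes). Only total intensity is contractual; the geometric
#' detail is cosmetic.
#'
#' @param truth One row of a [sample_population()] tibble (or a list
#'   with the same fields).
#' @param scenario The `org_scenario` the cell was drawn from (or a
#'   packaged scenario name).
#' @param cfg A [render_config()].
#' @param seed Integer seed; defaults to the cell's `cell_seed`.
#' @return A `cell_stack`: `cytosol` and `organelle` [voxel_grid]s plus
#'   ground truth (`truth`, `scenario`), the voxelized true cell mask
#'   (`cell_mask_true`) and organelle support (`support`).
#' @export
render_cell_stack <- function(truth, scenario, cfg = render_config(),
                              seed = NULL) {
  sc <- as_scenario(scenario)
  truth <- as.list(truth)
  if (is.list(truth$organelle_volumes) && length(truth$organelle_volumes) == 1L &&
      is.numeric(truth$organelle_volumes[[1]]))
    truth$organelle_volumes <- truth$organelle_volumes[[1]]
  seed <- as.integer(seed %||% truth$cell_seed %||% 1L)
  axes <- c(truth$sa_x_um, truth$sa_y_um, truth$sa_z_um)

  if (is.null(cfg$dims)) {
    nx <- ceiling((2 * axes[1] + 2 * cfg$pad_um) / cfg$dx)
    ny <- ceiling((2 * axes[2] + 2 * cfg$pad_um) / cfg$dy)
    nz <- ceiling((2 * axes[3] + 2 * cfg$pad_um) / cfg$dz)
  } else {
    ny <- cfg$dims[1]; nx <- cfg$dims[2]; nz <- cfg$dims[3]
    if (2 * axes[1] + 2 * cfg$pad_um > nx * cfg$dx ||
        2 * axes[2] + 2 * cfg$pad_um > ny * cfg$dy ||
        2 * axes[3] + 2 * cfg$pad_um > nz * cfg$dz)
      abort("cell does not fit in the requested field of view.",
            class = "orgscale_geometry_error")
  }

  xs <- (seq_len(nx) - (nx + 1) / 2) * cfg$dx
  ys <- (seq_len(ny) - (ny + 1) / 2) * cfg$dy
  zs <- (seq_len(nz) - (nz + 1) / 2) * cfg$dz
  # squared normalized ellipsoid coordinate at every voxel center
  e2 <- outer(outer((ys / axes[2])^2, (xs / axes[1])^2, "+"),
              (zs / axes[3])^2, "+")
  cell <- e2 <= 1

  geom <- withr::with_seed(seed, {
    paint_organelle(sc$geometry, truth, axes, e2, cell,
                    xs, ys, zs, cfg)
  })
  support <- geom$support & cell
  if (!any(support)) { # degenerate fallback: a single central voxel
    support[ceiling(ny / 2), ceiling(nx / 2), ceiling(nz / 2)] <- TRUE
  }

  ch2 <- array(0, dim(cell))
  if (!is.null(geom$fixed) && any(geom$fixed & support)) {
    fixed_vox <- geom$fixed & support
    ch2[fixed_vox] <- geom$fixed_intensity
    rest <- support & !fixed_vox
    rem <- max(0, truth$content_au - sum(ch2))
    if (any(rest)) ch2[rest] <- rem / sum(rest)
  } else {
    ch2[support] <- truth$content_au / sum(support)
  }
  ch1 <- array(0, dim(cell))
  ch1[cell] <- cfg$cytosol_intensity

  if (cfg$blur_sigma_um > 0) {
    sig <- cfg$blur_sigma_um / c(cfg$dy, cfg$dx, cfg$dz)
    ch1 <- gaussian_smooth3d(ch1, sig)
    ch2 <- gaussian_smooth3d(ch2, sig)
  }
  nvox <- length(ch1)
  withr::with_seed(seed + 1L, {
    if (cfg$noise_sd > 0) {
      ch1 <- ch1 + rnorm(nvox, 0, cfg$noise_sd)
      ch2 <- ch2 + rnorm(nvox, 0, cfg$noise_sd)
    }
  })
  ch1 <- pmax(0, ch1 + cfg$background)
  ch2 <- pmax(0, ch2 + cfg$background)
  dim(ch1) <- dim(ch2) <- c(ny, nx, nz)

  structure(
    list(cytosol = voxel_grid(ch1, cfg$dx, cfg$dy, cfg$dz),
         organelle = voxel_grid(ch2, cfg$dx, cfg$dy, cfg$dz),
         truth = truth, scenario = sc, config = cfg,
         cell_mask_true = cell, support = support),
    class = "cell_stack")
}

#' @export
print.cell_stack <- function(x, ...) {
  d <- dim(x$cytosol$data)
  cat(sprintf("<cell_stack> %s cell %s: V = %.1f um^3, content = %.0f a.u., %d x %d x %d voxels\n",
              x$scenario$geometry, x$truth$cell_id %||% "?",
              x$truth$volume_um3, x$truth$content_au, d[1], d[2], d[3]))
  invisible(x)
}

# ---- geometry painters ----------------------------------------------------

paint_organelle <- function(geometry, truth, axes, e2, cell, xs, ys, zs, cfg) {
  switch(geometry,
    mitochondria = list(support = paint_tubules(
      truth$volume_um3 * cfg$tubule_length_per_um3,
      cfg$tubule_radius_um, axes, dim(cell), xs, ys, zs, cfg)),
    er = paint_er(truth, axes, e2, cell, xs, ys, zs, cfg),
    vacuole_lumen = list(support = paint_vacuoles(
      truth$organelle_volumes, axes, dim(cell), xs, ys, zs, cfg,
      shell = FALSE)),
    vacuole_membrane = list(support = paint_vacuoles(
      truth$organelle_volumes, axes, dim(cell), xs, ys, zs, cfg,
      shell = TRUE)),
    peroxisome = list(support = paint_puncta(
      truth$n_organelles, axes, dim(cell), xs, ys, zs, cfg)),
    abort(sprintf("unknown geometry '%s'", geometry))
  )
}

# nearest voxel index of physical points (n x 3 matrix of x, y, z in um)
points_to_voxels <- function(p, xs, ys, zs) {
  cbind(round((p[, 2] - ys[1]) / (ys[2] - ys[1])) + 1L,
        round((p[, 1] - xs[1]) / (xs[2] - xs[1])) + 1L,
        round((p[, 3] - zs[1]) / (zs[2] - zs[1])) + 1L)
}

# Persistent random-walk skeleton of total length L inside the ellipsoid,
# dilated to radius r_t. Emulates an interconnected tubular network that
# extends throughout the cell volume.
paint_tubules <- function(length_um, r_t, axes, d, xs, ys, zs, cfg,
                          inner = 0.92) {
  ds <- min(cfg$dx, cfg$dz) / 1.5
  n_steps <- max(10L, ceiling(length_um / ds))
  p <- matrix(0, n_steps, 3)
  pos <- runif(3, -0.3, 0.3) * axes
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  for (i in seq_len(n_steps)) {
    dir <- 0.75 * dir + 0.25 * rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    cand <- pos + ds * dir
    if (sum((cand / (inner * axes))^2) > 1) {
      # bounce back toward the centre
      dir <- -pos / sqrt(sum(pos^2)) + 0.5 * rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cand <- pos + ds * dir
    }
    pos <- cand
    p[i, ] <- pos
  }
  support <- array(FALSE, d)
  stamp_spheres(support, points_to_voxels(p, xs, ys, zs), r_t,
                cfg$dx, cfg$dy, cfg$dz)
}

# ER: nuclear-envelope shell + tubules + cortical sheets.
paint_er <- function(truth, axes, e2, cell, xs, ys, zs, cfg) {
  d <- dim(cell)
  r_cell <- (prod(axes))^(1 / 3)
  r_nuc <- 0.3 * r_cell # nuclear radius ~30% of the mean cell radius
  t_m <- cfg$membrane_thickness_um
  r2 <- outer(outer(ys^2, xs^2, "+"), zs^2, "+")
  envelope <- r2 <= r_nuc^2 & r2 >= max(0, r_nuc - t_m)^2

  # cortical sheets: a subcortical rind of fixed physical thickness,
  # restricted to angular patches
  t_c <- cfg$er_cortical_thickness_um
  e2_inner <- outer(outer((ys / max(axes[2] - t_c, 0.1))^2,
                          (xs / max(axes[1] - t_c, 0.1))^2, "+"),
                    (zs / max(axes[3] - t_c, 0.1))^2, "+")
  rind <- e2 <= 1 & e2_inner > 1
  qy <- outer(outer(ys / axes[2], xs * 0, "+"), zs * 0, "+")
  qx <- outer(outer(ys * 0, xs / axes[1], "+"), zs * 0, "+")
  qz <- outer(outer(ys * 0, xs * 0, "+"), zs / axes[3], "+")
  qn <- sqrt(qy^2 + qx^2 + qz^2)
  patch <- array(FALSE, d)
  for (j in 1:3) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    patch <- patch | (qy * u[1] + qx * u[2] + qz * u[3]) / pmax(qn, 1e-9) > 0.6
  }
  cortical <- rind & patch

  tubules <- paint_tubules(truth$volume_um3 * cfg$er_tubule_length_per_um3,
                           0.25, axes, d, xs, ys, zs, cfg)
  support <- envelope | cortical | tubules
  out <- list(support = support)
  if (!is.null(cfg$er_cortical_intensity)) {
    out$fixed <- cortical
    out$fixed_intensity <- cfg$er_cortical_intensity
  }
  out$cortical <- cortical
  out
}

# Globular vacuoles: spheres with the per-cell ground-truth volumes,
# placed inside the cell with best-effort overlap avoidance.
paint_vacuoles <- function(vols, axes, d, xs, ys, zs, cfg, shell = FALSE) {
  support <- array(FALSE, d)
  if (is.null(vols) || !length(vols)) return(support)
  radii <- (3 * vols / (4 * pi))^(1 / 3)
  centers <- matrix(NA_real_, length(vols), 3)
  for (i in seq_along(radii)) {
    best <- NULL
    for (try in 1:25) {
      q <- rnorm(3); q <- q / sqrt(sum(q^2)) * runif(1)^(1 / 3)
      shrink <- pmax(0.05, 1 - radii[i] / pmin(axes, radii[i] + axes * 0.99))
      shrink <- pmax(0.05, 1 - radii[i] / axes)
      cand <- q * axes * shrink
      sep_ok <- TRUE
      if (i > 1) {
        prev <- centers[seq_len(i - 1), , drop = FALSE]
        dists <- sqrt(rowSums(t(t(prev) - cand)^2))
        sep_ok <- all(dists > 0.75 * (radii[seq_len(i - 1)] + radii[i]))
      }
      best <- cand
      if (sep_ok) break
    }
    centers[i, ] <- best
  }
  for (i in seq_along(radii)) {
    sph <- sphere_mask(centers[i, ], radii[i], xs, ys, zs, d)
    if (shell) {
      inner <- sphere_mask(centers[i, ], max(0, radii[i] -
                           cfg$membrane_thickness_um), xs, ys, zs, d)
      sph <- sph & !inner
    }
    support <- support | sph
  }
  support
}

# voxelized sphere via bounding box (fast for small spheres)
sphere_mask <- function(center, r, xs, ys, zs, d) {
  m <- array(FALSE, d)
  if (r <= 0) return(m)
  iy <- which(abs(ys - center[2]) <= r + (ys[2] - ys[1]))
  ix <- which(abs(xs - center[1]) <= r + (xs[2] - xs[1]))
  iz <- which(abs(zs - center[3]) <= r + (zs[2] - zs[1]))
  if (!length(iy) || !length(ix) || !length(iz)) return(m)
  sub <- outer(outer((ys[iy] - center[2])^2, (xs[ix] - center[1])^2, "+"),
               (zs[iz] - center[3])^2, "+") <= r^2
  m[iy, ix, iz] <- sub
  m
}

# Peroxisomes: n small puncta with best-effort minimum separation.
paint_puncta <- function(n, axes, d, xs, ys, zs, cfg) {
  centers <- matrix(NA_real_, n, 3)
  placed <- 0L
  for (i in seq_len(n)) {
    for (try in 1:50) {
      q <- rnorm(3); q <- q / sqrt(sum(q^2)) * runif(1)^(1 / 3)
      cand <- q * axes * 0.85
      ok <- TRUE
      if (placed > 0) {
        prev <- centers[seq_len(placed), , drop = FALSE]
        ok <- all(sqrt(rowSums(t(t(prev) - cand)^2)) > cfg$perox_min_sep_um)
      }
      if (ok || try == 50L) {
        placed <- placed + 1L
        centers[placed, ] <- cand
        break
      }
    }
  }
  support <- array(FALSE, d)
  stamp_spheres(support, points_to_voxels(centers, xs, ys, zs),
                cfg$perox_radius_um, cfg$dx, cfg$dy, cfg$dz)
}
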