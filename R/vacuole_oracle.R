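#' Analytic spherical-vacuole geometry table
#'
#' Generates the closed-form geometry behind two limiting vacuole-biogenesis
#' regimes. In `fixed_number` mode every cell holds `k` equal spheres whose
#' summed membrane area is exactly proportional to cell volume
#' (`A = c_area * V`); sphere radius is then `sqrt(c_area * V / (4 pi k))`
#' and total vacuole volume `k * (4/3) pi r^3` grows as `V^1.5` — membrane
#' scaling with slope 1 forces volume superscaling with slope 1.5. In
#' `fixed_size` mode sphere radius is constant and the count grows in
#' proportion to cell volume, so membrane area and vacuole volume both
#' scale with slope 1.
#'
#' @param mode `"fixed_number"` or `"fixed_size"`.
#' @param n_cells Number of cells (>= 3); volumes are log-spaced on
#'   `[v_min, v_max]`, which must span more than one decade.
#' @param k Spheres per cell (`fixed_number` mode; > 0).
#' @param c_area Membrane area per unit cell volume, um^-1
#'   (`fixed_number`; > 0).
#' @param r_sphere Constant sphere radius, um (`fixed_size`; > 0).
#' @param c_count Sphere count per unit cell volume, um^-3
#'   (`fixed_size`; > 0).
#' @param v_min,v_max Cell volume range (um^3).
#' @param quantize In `fixed_size` mode, round the sphere count to an
#'   integer (`TRUE`) or keep the continuous expected count (`FALSE`,
#'   default — preserves the exact slope-1 relationship).
#' @param sigma_log Optional lognormal jitter applied to both outputs
#'   (default 0: the table is exact).
#' @param seed Seed used only when `sigma_log > 0`.
#' @return A tibble: `cell_volume_um3`, `n_vacuoles`,
#'   `total_membrane_area_um2`, `total_vacuole_volume_um3`.
#' @examples
#' tab <- spherical_vacuole_oracle("fixed_number", n_cells = 10)
#' fit <- loglog_fit(tab, cell_volume_um3, total_vacuole_volume_um3)
#' fit$slope # 1.5 exactly
#' @export
spherical_vacuole_oracle <- function(mode = c("fixed_number", "fixed_size"),
                                     n_cells = 20,
                                     k = 4, c_area = 0.5,
                                     r_sphere = 0.6, c_count = 0.05,
                                     v_min = 8, v_max = 800,
                                     quantize = FALSE,
                                     sigma_log = 0, seed = 1L) {
  mode <- match.arg(mode)
  if (n_cells < 3) abort("`n_cells` must be >= 3.")
  if (v_max / v_min <= 10) abort("cell volumes must span more than one decade.")
  if (k <= 0 || c_area <= 0 || r_sphere <= 0 || c_count <= 0)
    abort("`k`, `c_area`, `r_sphere` and `c_count` must all be > 0.")

  v <- exp(seq(log(v_min), log(v_max), length.out = n_cells))
  if (mode == "fixed_number") {
    area <- c_area * v
    r <- sqrt(area / (4 * pi * k))
    vol <- k * (4 / 3) * pi * r^3
    n_vac <- rep(k, n_cells)
  } else {
    n_vac <- c_count * v
    if (quantize) n_vac <- pmax(1, round(n_vac))
    area <- n_vac * 4 * pi * r_sphere^2
    vol <- n_vac * (4 / 3) * pi * r_sphere^3
  }
  if (sigma_log > 0) {
    withr::with_seed(as.integer(seed), {
      area <- area * exp(rnorm(n_cells, 0, sigma_log))
      vol <- vol * exp(rnorm(n_cells, 0, sigma_log))
    })
  }
  tibble::tibble(
    cell_volume_um3 = v,
    n_vacuoles = n_vac,
    total_membrane_area_um2 = area,
    total_vacuole_volume_um3 = vol
  )
}
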