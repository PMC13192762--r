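#' Sample a ground-truthed synthetic cell population
#'
#' Draws `n` cells from a scaling scenario: volumes log-uniform on
#' `[v_min, v_max]`, contents `amplitude * V^beta * exp(e)` with
#' lognormal noise, plus the per-cell geometric ground truth needed to
#' render stacks (ellipsoid semi-axes, organelle counts, per-vacuole
#' volumes). The cells are approximately ovoid: one semi-axis is
#' stretched by an aspect factor drawn uniformly on 1 to 1.5.
#'
#' Identical `(scenario, n, seed)` yields identical output.
#'
#' @param scenario An `org_scenario` (see [scenario()]) or the name of a
#'   packaged scenario (see [default_scenarios()]).
#' @param n Number of cells (>= 1).
#' @param seed Integer seed; all randomness flows from it.
#' @return A tibble (class `cell_population`) with one row per cell:
#'   `cell_id`, `volume_um3`, `content_au`, semi-axes `sa_x_um`,
#'   `sa_y_um`, `sa_z_um`, `n_organelles`, `organelle_volumes`
#'   (list-column, um^3; vacuole geometries only), `cell_seed`,
#'   `scenario`.
#' @examples
#' pop <- sample_population("mitochondria", n = 5, seed = 1)
#' pop$content_au / pop$volume_um3 # roughly constant density
#' @export
sample_population <- function(scenario, n, seed) {
  sc <- as_scenario(scenario)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    abort("`n` must be a positive count.")
  n <- as.integer(n)
  if (!is.numeric(seed) || length(seed) != 1L)
    abort("`seed` must be a single integer.")
  seed <- as.integer(seed)

  withr::with_seed(seed, {
    v <- exp(runif(n, log(sc$v_min), log(sc$v_max)))
    sig <- pmax(0, sc$sigma_log + sc$sigma_log_slope * log10(v / sc$v_min))
    content <- sc$amplitude * v^sc$beta * exp(rnorm(n, 0, sig))
    aspect <- runif(n, 1, 1.5)
    r0 <- (3 * v / (4 * pi * aspect))^(1 / 3)
    n_org <- organelle_count(sc, v, content)
    org_vols <- organelle_volumes(sc, v, n_org)
  })

  tibble::new_tibble(
    tibble::tibble(
      cell_id = sprintf("cell_%04d", seq_len(n)),
      volume_um3 = v,
      content_au = content,
      sa_x_um = aspect * r0,
      sa_y_um = r0,
      sa_z_um = r0,
      n_organelles = n_org,
      organelle_volumes = org_vols,
      cell_seed = (seed + 104729L * seq_len(n)) %% .Machine$integer.max,
      scenario = sc$name
    ),
    class = "cell_population", scenario = sc)
}

# Geometry-dependent organelle counts.
# Networks (mitochondria, ER) are one connected object; peroxisomes come
# in fixed-content units so their number, not size, carries the scaling;
# vacuole number rises gently with cell volume.
organelle_count <- function(sc, v, content) {
  switch(sc$geometry,
    mitochondria = ,
    er = rep(1L, length(v)),
    peroxisome = pmax(1L, as.integer(round(content / sc$amplitude))),
    vacuole_membrane = ,
    vacuole_lumen = pmin(12L, pmax(2L, as.integer(round(1.5 * v^(1 / 3)))))
  )
}

# Per-vacuole volumes: total vacuole volume follows the volume-fraction
# model frac = f8 * sqrt(V / 8) with f8 = 2% at 8 um^3 (so ~20% at
# 800 um^3), split across compartments by a Dirichlet(0.8) draw so large
# cells typically carry one dominant vacuole.
organelle_volumes <- function(sc, v, n_org, dirichlet_alpha = 0.8) {
  if (!sc$geometry %in% c("vacuole_membrane", "vacuole_lumen"))
    return(vector("list", length(v)))
  f8 <- 0.02
  total <- f8 * sqrt(v / 8) * v
  purrr::map2(total, n_org, function(tot, k) {
    w <- rgamma(k, shape = dirichlet_alpha)
    sort(tot * w / sum(w), decreasing = TRUE)
  })
}

#' Write a population table to CSV
#'
#' Writes the tabular columns (`cell_id`, `volume_um3`, `content_au`,
#' `scenario`, `cell_seed`); geometric ground truth lives in the per-stack
#' JSON sidecars written by [write_cell_stack()].
#'
#' @param pop A `cell_population` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(pop, path) {
  readr::write_csv(
    dplyr::select(pop, "cell_id", "volume_um3", "content_au",
                  "scenario", "cell_seed"),
    path)
  invisible(path)
}
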