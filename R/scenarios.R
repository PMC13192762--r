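#' Define an organelle scaling scenario
#'
#' A scenario is the generative regime for one organelle: total content
#' follows `content = amplitude * V^beta * exp(e)`, `e ~ N(0, sigma_log^2)`,
#' with cell volume `V` drawn log-uniformly on `[v_min, v_max]` so every
#' decade of the size range carries equal leverage in log-log fits.
#'
#' @param name Text label.
#' @param beta Scaling exponent (dimensionless, > 0). 1 is isometric
#'   scaling, < 1 subscaling, > 1 superscaling.
#' @param amplitude Content per um^3^beta (arbitrary fluorescence units).
#' @param sigma_log Standard deviation of the multiplicative lognormal
#'   noise on content, natural-log scale (>= 0).
#' @param v_min,v_max Cell volume range (um^3); defaults span the
#'   ~100-fold range 8-800 um^3.
#' @param geometry Organelle geometry tag used by the stack renderer;
#'   one of `"mitochondria"`, `"er"`, `"vacuole_membrane"`,
#'   `"vacuole_lumen"`, `"peroxisome"`.
#' @param sigma_log_slope Optional size dependence of the noise:
#'   `sigma(V) = max(0, sigma_log + sigma_log_slope * log10(V / v_min))`.
#'   Default 0 (size-independent noise).
#' @return An `org_scenario` object (named list).
#' @seealso [default_scenarios()], [sample_population()]
#' @export
scenario <- function(name, beta, amplitude, sigma_log = 0.2,
                     v_min = 8, v_max = 800,
                     geometry = c("mitochondria", "er", "vacuole_membrane",
                                  "vacuole_lumen", "peroxisome"),
                     sigma_log_slope = 0) {
  geometry <- match.arg(geometry)
  if (!is.numeric(beta) || beta <= 0) abort("`beta` must be > 0.")
  if (!is.numeric(amplitude) || amplitude <= 0) abort("`amplitude` must be > 0.")
  if (!is.numeric(sigma_log) || sigma_log < 0) abort("`sigma_log` must be >= 0.")
  if (v_min <= 0 || v_max <= 0 || v_min >= v_max)
    abort("need 0 < v_min < v_max.")
  structure(
    list(name = as.character(name), beta = beta, amplitude = amplitude,
         sigma_log = sigma_log, v_min = v_min, v_max = v_max,
         geometry = geometry, sigma_log_slope = sigma_log_slope),
    class = "org_scenario")
}

#' @export
print.org_scenario <- function(x, ...) {
  cat(sprintf("<org_scenario> %s: content = %g * V^%g, sigma_log = %g, V in [%g, %g] um^3, geometry = %s\n",
              x$name, x$amplitude, x$beta, x$sigma_log, x$v_min, x$v_max,
              x$geometry))
  invisible(x)
}

#' Packaged organelle scaling scenarios
#'
#' The five default regimes. The exponents are the measured population
#' slopes for each marker: mitochondria scale isometrically (slope 1),
#' ER nearly so (0.96), vacuole membrane slightly superscales (1.1), and
#' peroxisome content subscales (0.75). The vacuole lumen regime encodes
#' a vacuole volume fraction rising from ~2% in 8 um^3 cells to ~20% in
#' 800 um^3 cells, i.e. an exponent of 1.5. Amplitudes are arbitrary
#' fluorescence units chosen so rendered stacks have realistic
#' signal-to-noise under the default render settings; peroxisome noise is
#' larger, matching the higher cell-to-cell variability of that marker.
#'
#' @return A tibble with one row per scenario.
#' @examples
#' default_scenarios()
#' @export
default_scenarios <- function() {
  tibble::tribble(
    ~name,              ~beta, ~amplitude, ~sigma_log, ~geometry,
    "mitochondria",      1.00,     2000,       0.20,   "mitochondria",
    "er",                0.96,     2000,       0.20,   "er",
    "vacuole_membrane",  1.10,      800,       0.20,   "vacuole_membrane",
    "vacuole_lumen",     1.50,       60,       0.20,   "vacuole_lumen",
    "peroxisome",        0.75,      300,       0.35,   "peroxisome"
  ) |>
    dplyr::mutate(v_min = 8, v_max = 800)
}

#' Fetch one packaged scenario by name
#'
#' @param name One of the names in [default_scenarios()].
#' @return An `org_scenario`.
#' @examples
#' packaged_scenario("peroxisome")
#' @export
packaged_scenario <- function(name) {
  tab <- default_scenarios()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L)
    abort(sprintf("unknown scenario '%s'; packaged: %s", name,
                  paste(tab$name, collapse = ", ")))
  scenario(row$name, beta = row$beta, amplitude = row$amplitude,
           sigma_log = row$sigma_log, v_min = row$v_min, v_max = row$v_max,
           geometry = row$geometry)
}

as_scenario <- function(x) {
  if (inherits(x, "org_scenario")) return(x)
  if (is.character(x) && length(x) == 1L) return(packaged_scenario(x))
  abort("expected an `org_scenario` or a packaged scenario name.")
}
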