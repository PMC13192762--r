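# Shared fixtures, built in code. Rendered stacks are cached per test
# run because rendering mid-sized cells costs a few hundred ms each.

.fixture_cache <- new.env(parent = emptyenv())

# One rendered cell of moderate size under controllable noise/blur.
fixture_stack <- function(scenario = "mitochondria", volume = 60,
                          noise_sd = 2, blur = 0.1, seed = 7) {
  key <- paste(scenario, volume, noise_sd, blur, seed, sep = "|")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  truth <- fixture_truth(scenario, volume, seed)
  cfg <- render_config(noise_sd = noise_sd, blur_sigma_um = blur)
  st <- render_cell_stack(truth, scenario, cfg)
  .fixture_cache[[key]] <- st
  st
}

# A single ground-truth cell of a given volume (sphere-ish, seeded).
fixture_truth <- function(scenario = "mitochondria", volume = 60, seed = 7) {
  sc <- packaged_scenario(scenario)
  pop <- sample_population(
    scenario(sc$name, beta = sc$beta, amplitude = sc$amplitude,
             sigma_log = 0, v_min = volume - 1e-9, v_max = volume + 1e-6,
             geometry = sc$geometry),
    n = 1, seed = seed)
  pop[1, ]
}

# Hand-built two-channel stack: an ellipsoid cell (axes um) with an
# arbitrary organelle intensity field painter.
toy_stack <- function(axes = c(2, 2, 2), pad = 0.8,
                      dx = 0.11, dz = 0.2,
                      cytosol = 40, background = 10,
                      paint = function(xs, ys, zs) 0) {
  nx <- ceiling((2 * axes[1] + 2 * pad) / dx)
  ny <- ceiling((2 * axes[2] + 2 * pad) / dx)
  nz <- ceiling((2 * axes[3] + 2 * pad) / dz)
  xs <- (seq_len(nx) - (nx + 1) / 2) * dx
  ys <- (seq_len(ny) - (ny + 1) / 2) * dx
  zs <- (seq_len(nz) - (nz + 1) / 2) * dz
  e2 <- outer(outer((ys / axes[2])^2, (xs / axes[1])^2, "+"),
              (zs / axes[3])^2, "+")
  cell <- e2 <= 1
  ch1 <- array(cytosol * cell + background, dim(cell))
  ch2 <- array(paint(xs, ys, zs) + background, dim(cell))
  list(cytosol = voxel_grid(ch1, dx, dx, dz),
       organelle = voxel_grid(ch2, dx, dx, dz),
       cell = cell, xs = xs, ys = ys, zs = zs,
       dx = dx, dz = dz, background = background)
}

# Sphere indicator field centred at `center` (um), intensity `value`.
sphere_field <- function(center, r, value) {
  function(xs, ys, zs) {
    value * (outer(outer((ys - center[2])^2, (xs - center[1])^2, "+"),
                   (zs - center[3])^2, "+") <= r^2)
  }
}
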