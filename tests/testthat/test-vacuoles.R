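test_that("a 1-um-radius vacuole is measured near its analytic volume", {
  ts <- toy_stack(axes = c(2.2, 2.2, 2.2),
                  paint = sphere_field(c(0, 0, 0), 1, 25))
  seg <- segment_cell(ts$cytosol)
  corr <- subtract_background(ts$organelle, seg$mask)
  vac <- measure_vacuoles(corr, seg$mask)
  expect_length(vac$volumes, 1L)
  expect_equal(vac$volumes, 4 / 3 * pi, tolerance = 0.10)
  expect_equal(vac$vacuole_fraction,
               vac$volumes / seg$cells$volume_um3[1], tolerance = 1e-9)
})

test_that("compartments below 460 nm equivalent diameter are excluded", {
  # one resolvable vacuole plus one 0.40-um-diameter speck
  ts <- toy_stack(axes = c(2.2, 2.2, 2.2), paint = function(xs, ys, zs) {
    sphere_field(c(-1, 0, 0), 0.8, 25)(xs, ys, zs) +
      sphere_field(c(1.2, 0, 0), 0.20, 25)(xs, ys, zs)
  })
  seg <- segment_cell(ts$cytosol)
  corr <- subtract_background(ts$organelle, seg$mask)
  vac <- measure_vacuoles(corr, seg$mask, d_min = 0.46)
  expect_equal(nrow(vac$vacuoles), 2L)
  expect_equal(sum(!vac$vacuoles$retained), 1L)
  excluded <- vac$vacuoles[!vac$vacuoles$retained, ]
  expect_lt(excluded$diameter_um, 0.46)
  # the speck contributes nothing to the retained volume
  expect_length(vac$volumes, 1L)
  expect_equal(sum(vac$volumes),
               sum(vac$vacuoles$volume_um3[vac$vacuoles$retained]))
})

test_that("a compartment exactly at the threshold diameter is retained", {
  ts <- toy_stack(axes = c(1.8, 1.8, 1.8),
                  paint = sphere_field(c(0, 0, 0), 0.5, 25))
  seg <- segment_cell(ts$cytosol)
  corr <- subtract_background(ts$organelle, seg$mask)
  probe <- measure_vacuoles(corr, seg$mask, d_min = 0)
  d_obs <- probe$vacuoles$diameter_um[1]
  at_cut <- measure_vacuoles(corr, seg$mask, d_min = d_obs)
  expect_true(at_cut$vacuoles$retained[1])
  above <- measure_vacuoles(corr, seg$mask, d_min = d_obs + 1e-9)
  expect_false(above$vacuoles$retained[1])
})

test_that("vacuole fraction is non-decreasing as the exclusion threshold shrinks", {
  st <- fixture_stack("vacuole_lumen", volume = 40)
  seg <- segment_cell(st$cytosol)
  corr <- subtract_background(st$organelle, seg$mask)
  om <- segment_organelle(corr, seg$mask)
  fracs <- vapply(c(1.2, 0.8, 0.46, 0.2, 0), function(dm) {
    measure_vacuoles(corr, seg$mask, d_min = dm,
                     organelle_mask = om)$vacuole_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  expect_true(all(fracs >= 0 & fracs < 1))
})

test_that("a cell with no lumen signal above threshold yields an empty inventory", {
  ts <- toy_stack(axes = c(1.5, 1.5, 1.5))
  seg <- segment_cell(ts$cytosol)
  corr <- subtract_background(ts$organelle, seg$mask)
  vac <- measure_vacuoles(corr, seg$mask,
                          organelle_mask = array(FALSE, dim(seg$mask)))
  expect_equal(nrow(vac$vacuoles), 0L)
  expect_identical(vac$vacuole_fraction, 0)
  expect_error(measure_vacuoles(corr, seg$mask, d_min = -1), "d_min")
})
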