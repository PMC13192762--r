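test_that("cell volume is recovered within 5% from a rendered cell", {
  st <- fixture_stack("mitochondria", volume = 60, noise_sd = 0, blur = 0)
  seg <- segment_cell(st$cytosol)
  expect_equal(nrow(seg$cells), 1L)
  expect_equal(seg$cells$volume_um3, st$truth$volume_um3, tolerance = 0.05)
  # default noisy/blurred render still segments to the same tolerance
  stn <- fixture_stack("mitochondria", volume = 60)
  segn <- segment_cell(stn$cytosol)
  expect_equal(segn$cells$volume_um3, stn$truth$volume_um3, tolerance = 0.05)
})

test_that("stacks without cells raise a 'no cell found' error", {
  blank <- voxel_grid(array(0, c(20, 20, 10)), 0.11, 0.11, 0.2)
  expect_error(segment_cell(blank), class = "orgscale_no_cell")
  tiny <- voxel_grid(array(c(rep(0, 3999), 50, rep(0, 4000)), c(20, 20, 20)),
                     0.11, 0.11, 0.2)
  expect_error(segment_cell(tiny), class = "orgscale_no_cell")
})

test_that("two disjoint cells are segmented and matched to their volumes", {
  dx <- 0.11; dz <- 0.2
  nx <- 120; ny <- 60; nz <- 40
  xs <- (seq_len(nx) - (nx + 1) / 2) * dx
  ys <- (seq_len(ny) - (ny + 1) / 2) * dx
  zs <- (seq_len(nz) - (nz + 1) / 2) * dz
  r1 <- 1.6; r2 <- 2.4 # true volumes 17.16 and 57.91 um^3
  e1 <- outer(outer(ys^2, (xs + 3.4)^2, "+"), zs^2, "+") <= r1^2
  e2 <- outer(outer(ys^2, (xs - 3.0)^2, "+"), zs^2, "+") <= r2^2
  ch1 <- voxel_grid(array(40 * (e1 | e2) + 10, c(ny, nx, nz)), dx, dx, dz)
  seg <- segment_cell(ch1)
  expect_equal(nrow(seg$cells), 2L)
  vols <- sort(seg$cells$volume_um3)
  expect_equal(vols[1], 4 / 3 * pi * r1^3, tolerance = 0.05)
  expect_equal(vols[2], 4 / 3 * pi * r2^3, tolerance = 0.05)
})

test_that("background subtraction follows the outside-mask mean, clipped at zero", {
  g <- function(v) voxel_grid(array(v, c(3, 3, 3)), 0.1, 0.1, 0.1)
  mask <- array(FALSE, c(3, 3, 3)); mask[2, 2, 2] <- TRUE
  # uniform stack: everything becomes zero
  expect_true(all(subtract_background(g(5), mask)$data == 0))
  # outside voxels {2,...}, one inside voxel 10 -> 8
  a <- array(2, c(3, 3, 3)); a[2, 2, 2] <- 10
  out <- subtract_background(voxel_grid(a, 0.1, 0.1, 0.1), mask)
  expect_equal(out$data[2, 2, 2], 8)
  expect_equal(attr(out, "background"), 2)
  # inside voxel below background clips to 0, never negative
  b <- array(3, c(3, 3, 3)); b[2, 2, 2] <- 1
  outb <- subtract_background(voxel_grid(b, 0.1, 0.1, 0.1), mask)
  expect_equal(outb$data[2, 2, 2], 0)
  expect_true(all(outb$data >= 0))
  # a mask covering everything leaves no background region
  expect_error(subtract_background(g(5), array(TRUE, c(3, 3, 3))),
               "background")
})

test_that("background subtraction is idempotent on clean stacks", {
  st <- fixture_stack("er", volume = 45, noise_sd = 0, blur = 0)
  seg <- segment_cell(st$cytosol)
  once <- subtract_background(st$organelle, seg$mask)
  twice <- subtract_background(once, seg$mask)
  expect_lt(sum(abs(twice$data - once$data)), 1e-6 * sum(once$data))
})

test_that("organelle mask is confined to the cell and needs in-cell contrast", {
  st <- fixture_stack("mitochondria", volume = 60)
  seg <- segment_cell(st$cytosol)
  corr <- subtract_background(st$organelle, seg$mask)
  om <- segment_organelle(corr, seg$mask)
  expect_true(all(!(om & !seg$mask)))
  flat <- voxel_grid(array(7, dim(seg$mask)), st$organelle$dx,
                     st$organelle$dy, st$organelle$dz)
  expect_error(segment_organelle(flat, seg$mask),
               class = "orgscale_no_organelle")
})

test_that("raising the organelle threshold can only shrink total content", {
  st <- fixture_stack("mitochondria", volume = 60)
  seg <- segment_cell(st$cytosol)
  corr <- subtract_background(st$organelle, seg$mask)
  thr0 <- otsu_threshold(corr$data[seg$mask])
  contents <- vapply(c(0.5, 1, 2, 4) * thr0, function(th) {
    m <- segment_organelle(corr, seg$mask, threshold = th)
    total_content(corr, seg$mask, m)
  }, numeric(1))
  expect_true(all(diff(contents) <= 0))
})

test_that("total content matches hand sums on a 3x3x3 toy", {
  a <- array(0, c(3, 3, 3))
  cmask <- array(FALSE, c(3, 3, 3)); omask <- array(FALSE, c(3, 3, 3))
  a[1, 1, 1] <- 4; a[2, 1, 1] <- 6 # organelle voxels
  a[3, 3, 3] <- 1; a[1, 3, 2] <- 1 # in-cell, outside organelle mask
  cmask[1, 1, 1] <- cmask[2, 1, 1] <- cmask[3, 3, 3] <- cmask[1, 3, 2] <- TRUE
  omask[1, 1, 1] <- omask[2, 1, 1] <- TRUE
  vg <- voxel_grid(a, 0.1, 0.1, 0.1)
  expect_equal(total_content(vg, cmask, omask), 10)
  expect_equal(total_content(vg, cmask, array(FALSE, c(3, 3, 3))), 0)
})

test_that("the full chain recovers the true content of a clean rendered cell", {
  st <- fixture_stack("mitochondria", volume = 60, noise_sd = 0, blur = 0)
  m <- measure_stack(st)
  expect_equal(m$total_content_au, st$truth$content_au, tolerance = 0.05)
  expect_equal(m$density_au_per_um3 * m$cell_volume_um3, m$total_content_au,
               tolerance = 1e-6)
})
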