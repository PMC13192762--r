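test_that("noise-free growth doubles on schedule", {
  tr <- generate_growth_trace(td = 169, v0 = 10, duration = 338)
  expect_equal(tail(tr$volume_um3, 1), 40, tolerance = 1e-9)
  expect_true(all(diff(tr$volume_um3) > 0))
})

test_that("mother volume is frozen across a budding interval", {
  ev <- growth_events(budding_intervals = list(c(100, 180)),
                      transfer_fraction = 0.3)
  tr <- generate_growth_trace(td = 169, v0 = 10, duration = 400, events = ev)
  v_start <- tr$volume_um3[tr$time_min == 100]
  v_end <- tr$volume_um3[tr$time_min == 180]
  expect_equal(v_start, v_end)
  inside <- tr$volume_um3[tr$time_min > 100 & tr$time_min <= 180]
  expect_true(all(inside == v_start))
  outside <- !(tr$time_min > 100 & tr$time_min <= 180)
  expect_true(all(diff(tr$volume_um3[outside]) > 0))
})

test_that("content declines during budding only when transfer is configured", {
  ev0 <- growth_events(budding_intervals = list(c(100, 180)),
                       transfer_fraction = 0)
  tr0 <- generate_growth_trace(td = 169, v0 = 10, duration = 400,
                               events = ev0)
  expect_true(all(diff(tr0$content_au) > 0))
  ev <- growth_events(budding_intervals = list(c(100, 180)),
                      transfer_fraction = 0.5)
  tr <- generate_growth_trace(td = 169, v0 = 10, duration = 400, events = ev)
  c_in <- tr$content_au[tr$time_min %in% c(100, 180)]
  expect_lt(c_in[2], c_in[1])
})

test_that("doubling time is recovered exactly from a clean trace", {
  tr <- generate_growth_trace(td = 169, v0 = 10, duration = 338)
  fit <- fit_exponential_growth(tr)
  expect_true(fit$growth_detected)
  expect_equal(fit$doubling_time, 169, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("a constant-volume trace yields no growth, not a spurious estimate", {
  tr <- tibble::tibble(time_min = seq(0, 100, 10),
                       volume_um3 = rep(25, 11))
  fit <- fit_exponential_growth(tr)
  expect_false(fit$growth_detected)
  expect_true(is.na(fit$doubling_time))
})

test_that("budding timepoints are excluded from the growth fit", {
  ev <- growth_events(budding_intervals = list(c(100, 180)))
  tr <- generate_growth_trace(td = 169, v0 = 10, duration = 400, events = ev)
  fit <- fit_exponential_growth(tr)
  expect_equal(fit$n_points, sum(!tr$budding))
  expect_error(
    fit_exponential_growth(tibble::tibble(time_min = c(0, 10, 20),
                                          volume_um3 = c(1, 2, 3))),
    "at least 4")
})

test_that("trace generation rejects non-positive rate parameters", {
  expect_error(generate_growth_trace(td = -5), "td")
  expect_error(generate_growth_trace(v0 = 0), "v0")
  expect_error(generate_growth_trace(duration = 3), "duration")
})

test_that("measurement noise is seeded and multiplicative", {
  a <- generate_growth_trace(noise_cv = 0.05, seed = 2)
  b <- generate_growth_trace(noise_cv = 0.05, seed = 2)
  expect_identical(a$volume_um3, b$volume_um3)
  c <- generate_growth_trace(noise_cv = 0.05, seed = 3)
  expect_false(identical(a$volume_um3, c$volume_um3))
  expect_true(all(a$volume_um3 > 0))
})
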