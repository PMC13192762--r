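test_that("an exact power law is fit exactly", {
  d <- tibble::tibble(volume_um3 = c(1, 10, 100),
                      content_au = 2 * volume_um3^1.5)
  f <- loglog_fit(d)
  expect_equal(f$slope, 1.5, tolerance = 1e-12)
  expect_equal(f$intercept, log10(2), tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # constant content: slope 0
  f0 <- loglog_fit(tibble::tibble(volume_um3 = c(2, 20, 200, 2000),
                                  content_au = 7))
  expect_equal(f0$slope, 0, tolerance = 1e-12)
})

test_that("log-log OLS matches the closed-form solution on a 5-point table", {
  d <- tibble::tibble(volume_um3 = c(5, 18, 40, 150, 600),
                      content_au = c(90, 260, 700, 2100, 9500))
  f <- loglog_fit(d)
  # independent closed-form OLS
  x <- log10(d$volume_um3); y <- log10(d$content_au); n <- 5
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  res <- y - (a + b * x)
  s2 <- sum(res^2) / (n - 2)
  se_b <- sqrt(s2 / sxx)
  tval <- b / se_b
  p <- 2 * pt(abs(tval), n - 2, lower.tail = FALSE)
  expect_equal(f$slope, b, tolerance = 1e-10)
  expect_equal(f$intercept, a, tolerance = 1e-10)
  expect_equal(f$slope_se, se_b, tolerance = 1e-10)
  expect_equal(f$f_statistic, tval^2, tolerance = 1e-8)
  expect_equal(f$p_value, p, tolerance = 1e-10)
  expect_equal(f$n, 5L)
})

test_that("non-positive pairs are dropped with a warning, and too few fail", {
  d <- tibble::tibble(volume_um3 = c(1, 10, 100, -5, 20),
                      content_au = c(2, 20, 200, 3, 0))
  expect_warning(f <- loglog_fit(d), "dropped 2")
  expect_equal(f$n, 3L)
  expect_equal(f$n_dropped, 2L)
  expect_error(suppressWarnings(
    loglog_fit(tibble::tibble(volume_um3 = c(1, -2, 3),
                              content_au = c(1, 1, -1)))),
    "at least 3")
})

test_that("log-log fit is scale-equivariant and exchangeable", {
  pop <- sample_population("er", 120, seed = 21)
  f1 <- loglog_fit(pop)
  scaled <- dplyr::mutate(pop, content_au = content_au * 37)
  f2 <- loglog_fit(scaled)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, f1$intercept + log10(37), tolerance = 1e-10)
  perm <- pop[sample.int(nrow(pop)), ]
  f3 <- loglog_fit(perm)
  expect_equal(f3$slope, f1$slope, tolerance = 1e-12)
  expect_equal(f3$slope_se, f1$slope_se, tolerance = 1e-12)
  expect_equal(f3$r_squared, f1$r_squared, tolerance = 1e-12)
})

test_that("density trend test behaves at both extremes", {
  d0 <- tibble::tibble(volume_um3 = seq(10, 700, length.out = 12),
                       density_au_per_um3 = 5)
  f0 <- density_slope_test(d0)
  expect_equal(f0$slope, 0, tolerance = 1e-12)
  d1 <- tibble::tibble(volume_um3 = seq(10, 700, length.out = 10),
                       density_au_per_um3 = 1 + 0.01 * volume_um3)
  f1 <- density_slope_test(d1)
  expect_lt(f1$p_value, 1e-6)
  expect_equal(f1$slope, 0.01, tolerance = 1e-10)
})

test_that("group comparison matches a textbook pooled t-test", {
  d <- tibble::tibble(volume_um3 = c(50, 60, 70, 500, 600, 700),
                      density_au_per_um3 = c(1, 2, 3, 4, 5, 6))
  g <- compare_groups(d)
  # hand computation for {1,2,3} vs {4,5,6}
  m1 <- 2; m2 <- 5; s2p <- (2 + 2) / 4 # pooled variance, each ss = 2
  t_hand <- (m1 - m2) / sqrt(s2p * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(abs(t_hand), 4, lower.tail = FALSE)
  expect_equal(g$t_statistic, t_hand, tolerance = 1e-10)
  expect_equal(g$t_pvalue, p_hand, tolerance = 1e-10)
  expect_equal(g$n_small, 3L)
  expect_equal(g$n_large, 3L)
  # identical groups: t = 0, p = 1
  di <- tibble::tibble(volume_um3 = c(50, 60, 70, 500, 600, 700),
                       density_au_per_um3 = c(1, 2, 3, 1, 2, 3))
  gi <- compare_groups(di)
  expect_equal(gi$t_statistic, 0, tolerance = 1e-12)
  expect_equal(gi$t_pvalue, 1, tolerance = 1e-12)
})

test_that("Welch statistics agree with the brute-force t-distribution evaluation", {
  d <- tibble::tibble(
    volume_um3 = c(rep(50, 6), rep(500, 4)),
    density_au_per_um3 = c(3.1, 2.7, 3.5, 2.9, 3.3, 2.6, 5.2, 4.1, 6.3, 4.9))
  gw <- compare_groups(d, welch = TRUE)
  x <- d$density_au_per_um3[1:6]; y <- d$density_au_per_um3[7:10]
  vx <- stats::var(x) / 6; vy <- stats::var(y) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_hand <- (vx + vy)^2 / (vx^2 / 5 + vy^2 / 3)
  p_hand <- 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE)
  expect_equal(gw$t_statistic, t_hand, tolerance = 1e-10)
  expect_equal(gw$df, df_hand, tolerance = 1e-10)
  expect_equal(gw$t_pvalue, p_hand, tolerance = 1e-10)
  # the variance F-test against its closed form
  f_hand <- stats::var(x) / stats::var(y)
  pf_hand <- 2 * min(pf(f_hand, 5, 3), pf(f_hand, 5, 3, lower.tail = FALSE))
  expect_equal(gw$var_f, f_hand, tolerance = 1e-10)
  expect_equal(gw$var_f_pvalue, pf_hand, tolerance = 1e-10)
})

test_that("cutoffs partition correctly, including the cortical-ER 200/600 pair", {
  d <- tibble::tibble(volume_um3 = c(150, 190, 250, 500, 650, 700),
                      density_au_per_um3 = c(1, 2, 9, 9, 3, 4))
  g <- compare_groups(d, small_cutoff = 200, large_cutoff = 600)
  expect_equal(g$n_small, 2L) # 150, 190
  expect_equal(g$n_large, 2L) # 650, 700
  expect_equal(g$mean_small, 1.5)
  expect_equal(g$mean_large, 3.5)
  expect_error(compare_groups(d, small_cutoff = 100, large_cutoff = 400),
               "small cutoff")
  expect_error(compare_groups(d, small_cutoff = 300, large_cutoff = 200),
               "below")
})

test_that("tidy and glance methods return well-formed tibbles", {
  pop <- sample_population("mitochondria", 50, seed = 2)
  f <- loglog_fit(pop)
  td <- tidy(f)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate[2], f$slope)
  gl <- glance(f)
  expect_equal(nrow(gl), 1L)
  tr <- generate_growth_trace()
  gf <- fit_exponential_growth(tr)
  expect_equal(glance(gf)$doubling_time, gf$doubling_time)
})
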