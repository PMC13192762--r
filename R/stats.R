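#' Log-log power-law fit of organelle content against cell volume
#'
#' Ordinary least squares of `log10(content)` on `log10(volume)`. The
#' slope is the allometric scaling exponent (1 = isometric scaling,
#' < 1 subscaling, > 1 superscaling); the regression F-test asks whether
#' the slope differs from zero. Pairs with a non-positive volume or
#' content cannot be log-transformed and are dropped with a warning.
#'
#' @param data A data frame.
#' @param volume,content Columns holding cell volume (um^3) and content
#'   (a.u.); unquoted names. Defaults `volume_um3`, `content_au`.
#' @return A `scaling_fit`: `slope`, `intercept`, `r_squared`,
#'   `slope_se`, `f_statistic`, `p_value`, `n`, `n_dropped`,
#'   `log_base = 10`, plus the underlying `lm` in `$model`.
#' @examples
#' d <- tibble::tibble(volume_um3 = c(1, 10, 100),
#'                     content_au = 2 * volume_um3^1.5)
#' loglog_fit(d)$slope # 1.5
#' @export
loglog_fit <- function(data, volume = volume_um3, content = content_au) {
  v <- dplyr::pull(data, {{ volume }})
  y <- dplyr::pull(data, {{ content }})
  ok <- is.finite(v) & is.finite(y) & v > 0 & y > 0
  if (any(!ok))
    warn(sprintf("dropped %d pair(s) with non-positive or missing values.",
                 sum(!ok)))
  if (sum(ok) < 3L) abort("need at least 3 valid (volume, content) pairs.")
  fit <- lm(log10(y[ok]) ~ log10(v[ok]))
  new_scaling_fit(fit, n = sum(ok), n_dropped = sum(!ok), scale = "log10")
}

#' Test for a linear trend of organelle density with cell volume
#'
#' Ordinary least squares of density on volume on the linear scale
#' (matching how density is plotted against volume), with the regression
#' F-test of zero slope. Under isometric scaling density is constant and
#' the test holds its nominal size.
#'
#' @param data A data frame.
#' @param volume,density Unquoted column names. Defaults `volume_um3`,
#'   `density_au_per_um3`.
#' @return A `scaling_fit` with `scale = "linear"`.
#' @export
density_slope_test <- function(data, volume = volume_um3,
                               density = density_au_per_um3) {
  v <- dplyr::pull(data, {{ volume }})
  y <- dplyr::pull(data, {{ density }})
  ok <- is.finite(v) & is.finite(y)
  if (sum(ok) < 3L) abort("need at least 3 valid (volume, density) pairs.")
  fit <- lm(y[ok] ~ v[ok])
  new_scaling_fit(fit, n = sum(ok), n_dropped = sum(!ok), scale = "linear")
}

new_scaling_fit <- function(fit, n, n_dropped, scale) {
  # exact power laws are legitimate inputs; silence the perfect-fit notice
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- sm$coefficients
  # regression F-test; with one predictor F = t^2 on the slope
  fstat <- unname(sm$fstatistic)
  f_value <- if (is.null(fstat)) NA_real_ else fstat[1]
  p_value <- if (is.null(fstat)) NA_real_ else
    pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(
    list(slope = unname(co[2, "Estimate"]),
         intercept = unname(co[1, "Estimate"]),
         r_squared = sm$r.squared,
         slope_se = unname(co[2, "Std. Error"]),
         f_statistic = f_value,
         p_value = p_value,
         n = n, n_dropped = n_dropped,
         log_base = if (scale == "log10") 10 else NA_real_,
         scale = scale, model = fit),
    class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  lab <- if (identical(x$scale, "log10")) "log-log" else "linear"
  cat(sprintf("<scaling_fit> %s slope = %.4f (SE %.4f), R^2 = %.3f, F = %.2f, p = %.3g, n = %d\n",
              lab, x$slope, x$slope_se, x$r_squared, x$f_statistic,
              x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.scaling_fit <- function(x, ...) {
  co <- summary(x$model)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = unname(co[, "Estimate"]),
                 std.error = unname(co[, "Std. Error"]),
                 statistic = unname(co[, "t value"]),
                 p.value = unname(co[, "Pr(>|t|)"]))
}

#' @export
glance.scaling_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, slope_se = x$slope_se,
                 intercept = x$intercept, r.squared = x$r_squared,
                 f.statistic = x$f_statistic, p.value = x$p_value,
                 n = x$n, n_dropped = x$n_dropped, scale = x$scale)
}

#' Compare a value between small and large cells
#'
#' Splits cells into a small group (volume below `small_cutoff`) and a
#' large group (volume above `large_cutoff`); cells in between are
#' excluded. Runs a two-sided two-sample t-test (pooled, or Welch when
#' `welch = TRUE`) plus a two-sample F-test on the group variances.
#' The conventional cutoffs are 100 and 400 um^3; the cortical-ER
#' contrast uses 200 and 600 um^3.
#'
#' @param data A data frame.
#' @param volume,value Unquoted column names; defaults `volume_um3` and
#'   `density_au_per_um3`.
#' @param small_cutoff,large_cutoff Volume cutoffs (um^3),
#'   `small_cutoff < large_cutoff`.
#' @param welch Use Welch's correction for unequal variances.
#' @return A `group_comparison` object.
#' @export
compare_groups <- function(data, volume = volume_um3,
                           value = density_au_per_um3,
                           small_cutoff = 100, large_cutoff = 400,
                           welch = FALSE) {
  if (small_cutoff >= large_cutoff)
    abort("`small_cutoff` must be below `large_cutoff`.")
  v <- dplyr::pull(data, {{ volume }})
  y <- dplyr::pull(data, {{ value }})
  small <- y[v < small_cutoff]
  large <- y[v > large_cutoff]
  if (length(small) < 2L)
    abort(sprintf("fewer than 2 cells below the small cutoff (%g um^3).",
                  small_cutoff))
  if (length(large) < 2L)
    abort(sprintf("fewer than 2 cells above the large cutoff (%g um^3).",
                  large_cutoff))
  tt <- t.test(small, large, var.equal = !welch)
  vt <- var.test(small, large)
  structure(
    list(small_cutoff = small_cutoff, large_cutoff = large_cutoff,
         n_small = length(small), n_large = length(large),
         mean_small = mean(small), mean_large = mean(large),
         sd_small = stats::sd(small), sd_large = stats::sd(large),
         t_statistic = unname(tt$statistic), t_pvalue = tt$p.value,
         df = unname(tt$parameter), welch = welch,
         var_f = unname(vt$statistic), var_f_pvalue = vt$p.value),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> small (<%g um^3, n=%d): %.3g +/- %.3g | large (>%g um^3, n=%d): %.3g +/- %.3g\n",
              x$small_cutoff, x$n_small, x$mean_small, x$sd_small,
              x$large_cutoff, x$n_large, x$mean_large, x$sd_large))
  cat(sprintf("  %s t = %.3f, p = %.3g; variance F = %.3f, p = %.3g\n",
              if (x$welch) "Welch" else "pooled", x$t_statistic, x$t_pvalue,
              x$var_f, x$var_f_pvalue))
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(group = c("small", "large"),
                 cutoff_um3 = c(x$small_cutoff, x$large_cutoff),
                 n = c(x$n_small, x$n_large),
                 mean = c(x$mean_small, x$mean_large),
                 sd = c(x$sd_small, x$sd_large))
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(t.statistic = x$t_statistic, t.pvalue = x$t_pvalue,
                 df = x$df, welch = x$welch,
                 var.f = x$var_f, var.f.pvalue = x$var_f_pvalue,
                 n_small = x$n_small, n_large = x$n_large)
}
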