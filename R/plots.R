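# ggplot2 displays for the main result types.

#' @describeIn loglog_fit Scatter of the fitted data with the best-fit
#'   line; log-log fits are drawn on decade-scaled axes.
#' @param object A `scaling_fit`.
#' @param ... Unused.
#' @export
autoplot.scaling_fit <- function(object, ...) {
  mf <- stats::model.frame(object$model)
  d <- tibble::tibble(x = mf[[2]], y = mf[[1]])
  lab <- if (identical(object$scale, "log10"))
    list(x = "log10 cell volume (um^3)", y = "log10 content (a.u.)")
  else
    list(x = "cell volume (um^3)", y = "density (a.u./um^3)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "#d5542c") +
    ggplot2::labs(
      x = lab$x, y = lab$y,
      subtitle = sprintf("slope = %.3f (SE %.3f), R^2 = %.3f, n = %d",
                         object$slope, object$slope_se,
                         object$r_squared, object$n)) +
    ggplot2::theme_minimal()
}

#' @describeIn generate_growth_trace Volume and content of a trace over
#'   time; budded intervals are shaded, mitoses marked.
#' @param object A `growth_trace`.
#' @param ... Unused.
#' @export
autoplot.growth_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("volume_um3", "content_au"),
                              names_to = "quantity")
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal()
  for (iv in attr(object, "budding_intervals") %||% list())
    p <- p + ggplot2::annotate("rect", xmin = iv[1], xmax = iv[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  for (mt in attr(object, "mitosis_times") %||% numeric())
    p <- p + ggplot2::geom_vline(xintercept = mt, linetype = 3,
                                 colour = "#b03030")
  p
}

#' @describeIn compare_groups Jittered group values with mean +/- sd.
#' @param object A `group_comparison`.
#' @param data The data frame the comparison was computed from.
#' @param volume,value Unquoted column names as in [compare_groups()].
#' @param ... Unused.
#' @export
autoplot.group_comparison <- function(object, data, volume = volume_um3,
                                      value = density_au_per_um3, ...) {
  v <- dplyr::pull(data, {{ volume }})
  y <- dplyr::pull(data, {{ value }})
  grp <- dplyr::case_when(v < object$small_cutoff ~ "small",
                          v > object$large_cutoff ~ "large",
                          TRUE ~ NA_character_)
  d <- tibble::tibble(group = factor(grp, c("small", "large")), y = y) |>
    dplyr::filter(!is.na(.data$group))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$y)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1),
                          colour = "#d5542c") +
    ggplot2::labs(
      x = sprintf("cell size group (<%g / >%g um^3)",
                  object$small_cutoff, object$large_cutoff),
      y = "value",
      subtitle = sprintf("%s t = %.2f, p = %.3g",
                         if (object$welch) "Welch" else "pooled",
                         object$t_statistic, object$t_pvalue)) +
    ggplot2::theme_minimal()
}

#' Maximum-intensity projection of one channel of a stack
#'
#' @param stack A `cell_stack`.
#' @param channel `"organelle"` or `"cytosol"`.
#' @return A ggplot raster of the xy maximum-intensity projection.
#' @export
plot_projection <- function(stack, channel = c("organelle", "cytosol")) {
  channel <- match.arg(channel)
  a <- stack[[channel]]$data
  mip <- apply(a, c(1, 2), max)
  d <- expand.grid(y = seq_len(nrow(mip)), x = seq_len(ncol(mip)))
  d$intensity <- as.vector(mip)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (max projection)", channel)) +
    ggplot2::theme_void()
}
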