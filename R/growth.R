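#' Configure proliferation events for a growth trace
#'
#' @param budding_intervals List of `c(start, end)` pairs (minutes) during
#'   which the mother cell volume is frozen and organelle content is
#'   transferred to the bud.
#' @param mitosis_times Numeric vector of mitosis times (minutes);
#'   annotation only, growth is unaffected.
#' @param transfer_fraction Fraction of the mother's organelle content
#'   handed to the bud over each budding interval, linearly in time
#'   (0 to < 1).
#' @return A `growth_events` list.
#' @export
growth_events <- function(budding_intervals = list(),
                          mitosis_times = numeric(),
                          transfer_fraction = 0.3) {
  if (transfer_fraction < 0 || transfer_fraction >= 1)
    abort("`transfer_fraction` must be in [0, 1).")
  for (iv in budding_intervals)
    if (length(iv) != 2L || iv[2] <= iv[1])
      abort("each budding interval must be c(start, end) with end > start.")
  structure(list(budding_intervals = budding_intervals,
                 mitosis_times = mitosis_times,
                 transfer_fraction = transfer_fraction),
            class = "growth_events")
}

#' Generate a single-cell exponential growth trace
#'
#' Emulates time-lapse measurements of one cell sampled every `dt`
#' minutes. Outside budding intervals the cell grows exponentially,
#' `V(t) = V(t0) * 2^((t - t0)/td)`, and content grows in step (constant
#' density). Within a budding interval the mother volume is frozen and
#' content declines linearly by the configured transfer fraction,
#' emulating organelle transfer to the bud. Optional multiplicative
#' lognormal measurement noise is applied to the reported volumes and
#' contents only; the underlying trajectory is noise-free.
#'
#' @param td Doubling time (minutes, > 0). Default 169, the measured
#'   population mean for cells in nuclear cycles.
#' @param v0 Initial volume (um^3, > 0).
#' @param duration Total duration (minutes, >= `dt`).
#' @param events A [growth_events()] configuration.
#' @param noise_cv Multiplicative measurement noise (sd of log, e.g.
#'   0.05 for ~5% noise). Default 0.
#' @param content0 Initial organelle content (a.u.).
#' @param dt Sampling interval (minutes). Default 10.
#' @param seed Integer seed (used only when `noise_cv > 0`).
#' @return A tibble (class `growth_trace`): `time_min`, `volume_um3`,
#'   `content_au`, `budding`; attributes `mitosis_times`,
#'   `budding_intervals`, `td`, `dt`.
#' @examples
#' tr <- generate_growth_trace(td = 169, v0 = 10, duration = 338)
#' tail(tr$volume_um3, 1) # 40: two doublings
#' @export
generate_growth_trace <- function(td = 169, v0 = 10, duration = 600,
                                  events = growth_events(),
                                  noise_cv = 0, content0 = 100,
                                  dt = 10, seed = 1L) {
  if (!is.numeric(td) || td <= 0) abort("`td` must be a positive doubling time.")
  if (!is.numeric(v0) || v0 <= 0) abort("`v0` must be > 0.")
  if (duration < dt) abort("`duration` must cover at least one sampling interval.")
  times <- seq(0, duration, by = dt)
  if (tail(times, 1) < duration) times <- c(times, duration)
  nt <- length(times)

  in_budding <- function(t) {
    for (iv in events$budding_intervals)
      if (t > iv[1] && t <= iv[2]) return(TRUE)
    FALSE
  }
  budding <- vapply(times, in_budding, logical(1))

  vol <- numeric(nt); con <- numeric(nt)
  vol[1] <- v0; con[1] <- content0
  step_loss <- 0
  for (i in seq_len(nt - 1L)) {
    g <- 2^((times[i + 1L] - times[i]) / td)
    if (budding[i + 1L]) {
      # mother volume frozen; synthesis continues but content is handed
      # to the bud as a linear-in-time loss over the interval
      vol[i + 1L] <- vol[i]
      if (!budding[i]) {
        iv <- NULL
        for (cand in events$budding_intervals)
          if (times[i + 1L] > cand[1] && times[i + 1L] <= cand[2]) iv <- cand
        n_steps <- sum(times > iv[1] & times <= iv[2])
        step_loss <- con[i] * events$transfer_fraction / n_steps
      }
      con[i + 1L] <- con[i] * g - step_loss
    } else {
      vol[i + 1L] <- vol[i] * g
      con[i + 1L] <- con[i] * g
    }
  }

  if (noise_cv > 0) {
    withr::with_seed(as.integer(seed), {
      vol_obs <- vol * exp(rnorm(nt, 0, noise_cv))
      con_obs <- con * exp(rnorm(nt, 0, noise_cv))
    })
  } else {
    vol_obs <- vol; con_obs <- con
  }

  tibble::new_tibble(
    tibble::tibble(time_min = times, volume_um3 = vol_obs,
                   content_au = con_obs, budding = budding),
    class = "growth_trace",
    mitosis_times = events$mitosis_times,
    budding_intervals = events$budding_intervals,
    td = td, dt = dt)
}

#' Fit exponential growth to a trace
#'
#' Ordinary least squares of `log2(volume)` on time over the non-budding
#' timepoints; the doubling time is the reciprocal of the slope. Budding
#' intervals are excluded because the mother volume is frozen there.
#'
#' @param trace A `growth_trace` tibble (or any data frame with
#'   `time_min`, `volume_um3` and optionally `budding` columns).
#' @return A `growth_fit` object: `doubling_time` (min),
#'   `doubling_time_se`, `r_squared`, `n_points`, `growth_detected`.
#'   When the fitted slope is not positive, `growth_detected` is `FALSE`
#'   and `doubling_time` is `NA`.
#' @examples
#' tr <- generate_growth_trace(td = 169, v0 = 10, duration = 338)
#' fit_exponential_growth(tr)$doubling_time
#' @export
fit_exponential_growth <- function(trace) {
  budding <- if ("budding" %in% names(trace)) trace$budding else FALSE
  keep <- !budding & trace$volume_um3 > 0
  t_use <- trace$time_min[keep]
  v_use <- trace$volume_um3[keep]
  if (length(t_use) < 4L)
    abort("need at least 4 non-budding timepoints to fit growth.")
  fit <- lm(log2(v_use) ~ t_use)
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  slope <- coef(fit)[["t_use"]]
  slope_se <- sm$coefficients["t_use", "Std. Error"]
  if (!is.finite(slope) || slope <= 1e-10) {
    res <- list(doubling_time = NA_real_, doubling_time_se = NA_real_,
                r_squared = sm$r.squared, n_points = length(t_use),
                growth_detected = FALSE, model = fit)
  } else {
    res <- list(doubling_time = 1 / slope,
                # delta method: se(1/b) = se(b) / b^2
                doubling_time_se = slope_se / slope^2,
                r_squared = sm$r.squared, n_points = length(t_use),
                growth_detected = TRUE, model = fit)
  }
  structure(res, class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$growth_detected)
    cat(sprintf("<growth_fit> doubling time %.1f +/- %.1f min (R^2 = %.3f, n = %d)\n",
                x$doubling_time, x$doubling_time_se, x$r_squared, x$n_points))
  else
    cat(sprintf("<growth_fit> no growth detected (n = %d)\n", x$n_points))
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(term = "doubling_time",
                 estimate = x$doubling_time,
                 std.error = x$doubling_time_se)
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(doubling_time = x$doubling_time,
                 doubling_time_se = x$doubling_time_se,
                 r.squared = x$r_squared,
                 n_points = x$n_points,
                 growth_detected = x$growth_detected)
}
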