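## Field-potential feature extraction: fEPSP slope, fiber-volley amplitude,
## I/O curves, paired-pulse ratios, normalized LTP profiles.

ephys_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ephys_error")))
}

## Sliding least-squares slope over windows of k samples: a linear filter
## with centered weights (t - tbar) / sum((t - tbar)^2). Returns the slope of
## the window *starting* at each index (NA where the window runs off the end).
sliding_ls_slope <- function(v, dt, k) {
  tw <- (seq_len(k) - 1) * dt
  w <- (tw - mean(tw)) / sum((tw - mean(tw))^2)
  n <- length(v)
  out <- rep(NA_real_, n)
  if (n >= k) {
    ## convolution: slope[j] = sum_i w[i] * v[j + i - 1]
    cs <- stats::filter(v, rev(w), sides = 1)
    out[seq_len(n - k + 1)] <- cs[k:n]
  }
  out
}

#' Extract fEPSP slope and fiber-volley amplitude from one sweep
#'
#' The fEPSP slope is the least-squares slope of voltage over the first 1 ms
#' of the descending domain — the segment running from the local maximum that
#' precedes the fEPSP trough down to the trough. It is located as the 1 ms
#' window with the most negative least-squares slope among windows ending at
#' or before the trough, which for the usual convex descent coincides with
#' the window anchored at the local maximum while staying robust to sample
#' noise. The fiber-volley amplitude is the peak-to-baseline magnitude within
#' \code{fv_window_ms}.
#'
#' @param sweep a \code{sweep} object.
#' @param fv_window_ms fiber-volley search window, ms after stimulus onset.
#' @param fepsp_search_window_ms fEPSP search window, ms after stimulus onset.
#' @param slope_win_ms regression window length (the conventional 1 ms).
#' @return list of class \code{sweep_features}: \code{fv_amplitude_mV},
#'   \code{fepsp_slope_mV_per_ms} (signed), \code{slope_window} (start, end
#'   ms).
#' @export
extract_sweep_features <- function(sweep, fv_window_ms = c(0.5, 2),
                                   fepsp_search_window_ms = c(2, 12),
                                   slope_win_ms = 1.0) {
  stopifnot(inherits(sweep, "sweep"))
  t <- sweep$time_ms; v <- sweep$voltage_mV
  dt <- t[2] - t[1]
  onset <- sweep$stim_onset_ms
  if (fepsp_search_window_ms[1] <= 0 ||
      onset + fepsp_search_window_ms[2] > max(t) + dt / 2) {
    ephys_error("fEPSP search window must lie within the trace after stimulus onset",
                "bad_window")
  }
  baseline <- mean(v[t < onset])

  ## fiber volley
  in_fv <- t >= onset + fv_window_ms[1] & t <= onset + fv_window_ms[2]
  fv_amp <- if (any(in_fv)) max(abs(v[in_fv] - baseline)) else NA_real_

  ## fEPSP descending domain
  in_w <- which(t >= onset + fepsp_search_window_ms[1] &
                t <= onset + fepsp_search_window_ms[2])
  vw <- v[in_w]
  if (max(vw) - min(vw) < 1e-9) {
    ephys_error("flat trace: no fEPSP response detected", "no_response")
  }
  trough <- in_w[which.min(vw)]

  ## local maximum before the trough on a lightly smoothed trace, to bound
  ## the descent and validate its duration (trough and walk-back both taken
  ## on the smoothed trace so sample noise cannot truncate the segment)
  ksm <- max(1L, round(0.3 / dt))
  vs <- as.numeric(stats::filter(v, rep(1 / ksm, ksm), sides = 2))
  vs[is.na(vs)] <- v[is.na(vs)]
  s_trough <- in_w[which.min(vs[in_w])]
  pre <- in_w[1]:s_trough
  vmax <- max(vs[pre])
  tol <- 0.05 * (vmax - vs[s_trough])
  onset_idx <- max(pre[vs[pre] >= vmax - tol])
  descent_ms <- t[s_trough] - t[onset_idx]
  if (descent_ms < slope_win_ms - dt / 2) {
    ephys_error(sprintf("descending segment too short: %.3f ms < %.3f ms",
                        descent_ms, slope_win_ms), "short_descent")
  }

  k <- round(slope_win_ms / dt) + 1L
  slopes <- sliding_ls_slope(v, dt, k)
  ## candidate starts: inside the search window, window ends by the trough
  starts <- in_w[in_w + k - 1L <= trough]
  if (length(starts) == 0) starts <- max(in_w[1], trough - k + 1L)
  s0 <- starts[which.min(slopes[starts])]
  structure(
    list(fv_amplitude_mV = fv_amp,
         fepsp_slope_mV_per_ms = slopes[s0],
         slope_window = c(t[s0], t[s0] + slope_win_ms),
         descent_ms = descent_ms),
    class = "sweep_features"
  )
}

#' @export
print.sweep_features <- function(x, ...) {
  cat(sprintf("fEPSP slope %.4f mV/ms (window %.2f-%.2f ms), fiber volley %.4f mV\n",
              x$fepsp_slope_mV_per_ms, x$slope_window[1], x$slope_window[2],
              x$fv_amplitude_mV))
  invisible(x)
}

#' Build an input-output curve from per-sweep features
#'
#' Points are (fiber-volley amplitude, |fEPSP slope|) sorted by amplitude,
#' with an ordinary least-squares line.
#'
#' @param features list of \code{sweep_features}.
#' @return object of class \code{io_curve} with \code{points} (data.frame)
#'   and \code{fit} (slope, intercept, r2); \code{coef} and \code{predict}
#'   methods apply to the fitted line.
#' @export
build_io_curve <- function(features) {
  if (length(features) < 3) ephys_error("need >= 3 sweeps for an I/O curve", "too_few_points")
  pts <- data.frame(
    fv_amplitude = vapply(features, `[[`, numeric(1), "fv_amplitude_mV"),
    slope_mag = abs(vapply(features, `[[`, numeric(1), "fepsp_slope_mV_per_ms"))
  )
  pts <- pts[order(pts$fv_amplitude), , drop = FALSE]
  fit <- lm(slope_mag ~ fv_amplitude, data = pts)
  structure(
    list(points = pts,
         fit = list(slope = unname(coef(fit)[2]),
                    intercept = unname(coef(fit)[1]),
                    r2 = suppressWarnings(summary(fit)$r.squared)),
         lm = fit),
    class = "io_curve"
  )
}

#' @export
print.io_curve <- function(x, ...) {
  cat(sprintf("I/O curve: %d points, slope %.4f, intercept %.4f, R^2 %.4f\n",
              nrow(x$points), x$fit$slope, x$fit$intercept, x$fit$r2))
  invisible(x)
}

#' @export
coef.io_curve <- function(object, ...) {
  c(intercept = object$fit$intercept, slope = object$fit$slope)
}

#' @export
predict.io_curve <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$points
  object$fit$intercept + object$fit$slope * newdata$fv_amplitude
}

#' Select the test stimulus level from an I/O series
#'
#' Returns the smallest stimulus level whose fEPSP amplitude falls within
#' \code{[frac_lo, frac_hi]} of the maximum amplitude; if no level lands in
#' the band, the level closest to the band midpoint (0.55 of maximum by
#' default) is returned with \code{flagged = TRUE}.
#'
#' @param io_sweeps data.frame with columns \code{stim_level} and
#'   \code{amplitude} (any consistent amplitude measure).
#' @export
select_test_stimulus <- function(io_sweeps, frac_lo = 0.50, frac_hi = 0.60) {
  amp <- io_sweeps$amplitude
  if (length(amp) == 0 || all(!is.finite(amp)) || max(amp, na.rm = TRUE) <= 0) {
    ephys_error("no measurable responses in I/O sweeps", "no_response")
  }
  mx <- max(amp, na.rm = TRUE)
  inside <- which(amp >= frac_lo * mx & amp <= frac_hi * mx)
  if (length(inside) > 0) {
    pick <- inside[which.min(io_sweeps$stim_level[inside])]
    flagged <- FALSE
  } else {
    mid <- (frac_lo + frac_hi) / 2
    pick <- which.min(abs(amp - mid * mx))
    flagged <- TRUE
  }
  if (length(amp) == 1) flagged <- TRUE
  list(stim_level = io_sweeps$stim_level[pick], flagged = flagged)
}

#' Paired-pulse facilitation profile
#'
#' Ratio of the second to the first fEPSP slope magnitude at each inter-pulse
#' interval, reported in ascending interval order.
#'
#' @param pairs list of \code{list(sweep1, sweep2, interval_ms)}.
#' @param ... passed to \code{\link{extract_sweep_features}}.
#' @return data.frame of class \code{ppf_profile}: interval_ms, ratio.
#' @export
ppf_profile <- function(pairs, ...) {
  rows <- lapply(pairs, function(p) {
    f1 <- extract_sweep_features(p$sweep1, ...)
    f2 <- extract_sweep_features(p$sweep2, ...)
    s1 <- abs(f1$fepsp_slope_mV_per_ms)
    if (s1 == 0) ephys_error(sprintf("undefined PPF ratio at %g ms: first slope is zero",
                                     p$interval_ms), "zero_first_slope")
    data.frame(interval_ms = p$interval_ms,
               ratio = abs(f2$fepsp_slope_mV_per_ms) / s1)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$interval_ms), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ppf_profile", "data.frame")
  out
}

#' Normalized long-term potentiation profile
#'
#' Per-minute mean |fEPSP slope| divided by the grand mean of the baseline
#' minutes, in percent; baseline minutes therefore average to 100 by
#' construction. \code{last5_mean} summarizes the final five post-TBS
#' minutes.
#'
#' @param session an \code{ephys_session} (sweeps + minute labels, TBS at
#'   minute 0).
#' @param ... passed to \code{\link{extract_sweep_features}}.
#' @return object of class \code{ltp_profile}: data.frame (minute, pct) plus
#'   attribute \code{last5_mean}.
#' @export
ltp_profile <- function(session, ...) {
  stopifnot(inherits(session, "ephys_session"))
  minutes <- session$minute
  if (sum(unique(minutes) < 0) < 1 || sum(unique(minutes) > 0) < 5) {
    ephys_error("need >= 1 baseline minute and >= 5 post-TBS minutes", "too_few_minutes")
  }
  slopes <- vapply(session$sweeps, function(s)
    abs(extract_sweep_features(s, ...)$fepsp_slope_mV_per_ms), numeric(1))
  per_min <- tapply(slopes, minutes, mean)
  base_mean <- mean(slopes[minutes < 0])
  if (base_mean == 0) ephys_error("zero baseline mean slope", "zero_baseline")
  minute <- as.numeric(names(per_min))
  pct <- 100 * as.numeric(per_min) / base_mean
  ## renormalize so baseline *minutes* average exactly to 100 (equal-weight
  ## minutes, as plotted, rather than equal-weight sweeps)
  pct <- pct * 100 / mean(pct[minute < 0])
  post <- sort(minute[minute > 0])
  last5 <- utils::tail(post, 5)
  out <- data.frame(minute = minute, pct = pct)
  out <- out[order(out$minute), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, last5_mean = mean(pct[minute %in% last5]),
            class = c("ltp_profile", "data.frame"))
}

#' @export
print.ltp_profile <- function(x, ...) {
  cat(sprintf("LTP profile: %d minutes, last-5-min mean %.1f%% of baseline\n",
              nrow(x), attr(x, "last5_mean")))
  invisible(x)
}
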