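#' Ensemble time-averaged mean-squared displacement
#'
#' For every lag that is an integer multiple of the frame interval up to
#' `max_lag`, pools all displacement pairs of all particles (time average
#' within tracks, then across the ensemble, weighted by pair count) and
#' reports the half-sum convention
#' `MSD(dt) = 0.5 * (<dx^2> + <dy^2>)`.
#' Gaps within a track contribute no pairs at the affected lags. Lags
#' supported by fewer than `min_pairs` displacement pairs are dropped.
#'
#' @param tracks a [track_table()]
#' @param max_lag largest lag time, seconds (>= 2 frame intervals)
#' @param min_pairs minimum displacement pairs per reported lag
#' @return object of class `msd_curve`: data.frame with columns `lag`
#'   (s), `msd` (um^2), `n_pairs`, `msd_over_dt` (um^2/s)
#' @export
compute_msd <- function(tracks, max_lag, min_pairs = 50L) {
  stop_if_not(inherits(tracks, "track_table"), "tracks must be a track_table")
  dt <- attr(tracks, "frame_interval")
  stop_if_not(max_lag >= 2 * dt, "max_lag must be >= 2 frame intervals")
  kmax <- floor(max_lag / dt + 1e-9)
  sumsq <- numeric(kmax)
  npair <- numeric(kmax)
  for (p in split(tracks[, c("frame", "x", "y")], tracks$particle)) {
    f <- p$frame
    span <- f[length(f)] - f[1]
    if (span < 1) next
    # index positions on the full frame grid; gaps stay NA
    xs <- rep(NA_real_, span + 1); ys <- xs
    idx <- f - f[1] + 1
    xs[idx] <- p$x; ys[idx] <- p$y
    n <- length(xs)
    for (k in seq_len(min(kmax, n - 1))) {
      dx <- xs[(1 + k):n] - xs[1:(n - k)]
      dy <- ys[(1 + k):n] - ys[1:(n - k)]
      ok <- !is.na(dx)
      if (!any(ok)) next
      sumsq[k] <- sumsq[k] + 0.5 * sum(dx[ok]^2 + dy[ok]^2)
      npair[k] <- npair[k] + sum(ok)
    }
  }
  keep <- npair >= min_pairs
  stop_if_not(any(keep),
              sprintf("no lag has >= %d displacement pairs", min_pairs))
  lag <- (seq_len(kmax) * dt)[keep]
  msd <- (sumsq / pmax(npair, 1))[keep]
  out <- data.frame(lag = lag, msd = msd, n_pairs = npair[keep],
                    msd_over_dt = msd / lag)
  structure(out, class = c("msd_curve", "data.frame"),
            frame_interval = dt)
}

#' Assemble an MSD curve from precomputed values
#'
#' Useful for regime detection on curves obtained elsewhere (or on closed
#' forms in validation harnesses).
#'
#' @param lag strictly increasing positive lag times, seconds
#' @param msd non-negative MSD values, um^2
#' @param n_pairs displacement-pair counts per lag
#' @return an `msd_curve`
#' @export
as_msd_curve <- function(lag, msd, n_pairs = rep(1L, length(lag))) {
  stop_if_not(all(diff(lag) > 0) && all(lag > 0),
              "lags must be strictly increasing and positive")
  stop_if_not(all(msd >= 0), "msd must be >= 0")
  dt <- lag[1]
  structure(data.frame(lag = lag, msd = msd, n_pairs = n_pairs,
                       msd_over_dt = msd / lag),
            class = c("msd_curve", "data.frame"), frame_interval = dt)
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("msd_curve: %d lags in [%g, %g] s\n",
              nrow(x), min(x$lag), max(x$lag)))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, scaled = FALSE, ...) {
  if (scaled) {
    graphics::plot(x$lag, x$msd_over_dt, log = "xy", xlab = "lag time (s)",
                   ylab = expression(MSD / Delta * t ~ (mu * m^2 / s)), ...)
  } else {
    graphics::plot(x$lag, x$msd, log = "xy", xlab = "lag time (s)",
                   ylab = expression(MSD ~ (mu * m^2)), ...)
  }
  invisible(x)
}

#' Detect the end of the initial power-law regime
#'
#' Expanding-window criterion: regress log MSD on log lag over windows
#' that start at the smallest lag and grow lag-by-lag; the boundary is the
#' largest window end for which R-squared exceeds `r2_threshold`. A curve
#' that never fails the criterion is a single power law and the final lag
#' is returned; if even the minimal window fails, the minimal-window lag
#' is returned with attribute `passed = FALSE`.
#'
#' @param curve an [compute_msd()] result
#' @param r2_threshold R-squared threshold for log-log linearity
#' @param min_window smallest window length in lags (R-squared on fewer
#'   points is uninformative)
#' @return boundary lag time in seconds, with attribute `passed`
#' @export
detect_t1 <- function(curve, r2_threshold = 0.99, min_window = 5L) {
  stop_if_not(inherits(curve, "msd_curve"), "curve must be an msd_curve")
  n <- nrow(curve)
  stop_if_not(n >= min_window,
              sprintf("need >= %d lags for the expanding-window criterion", min_window))
  r2 <- vapply(min_window:n, function(w)
    loglog_r2(curve$lag[1:w], curve$msd[1:w]), numeric(1))
  pass <- which(r2 > r2_threshold)
  if (length(pass) == 0) {
    return(structure(curve$lag[min_window], passed = FALSE))
  }
  structure(curve$lag[min_window - 1L + max(pass)], passed = TRUE)
}

#' Detect the onset of the late superdiffusive regime
#'
#' The boundary is the first strict local minimum of MSD/dt (smoothed by
#' a centered moving average on the lag-ordered curve) at a lag greater
#' than `after`. A candidate minimum only counts when it is preceded by a
#' drop and followed by a rise both exceeding `min_prominence` on the log
#' scale (about 10% by default), so statistical ripple on a flat or
#' monotone curve is not mistaken for a transport crossover. A curve with
#' no qualifying minimum is monophasic and `NA` is returned; a curve that
#' rises from the very first lag with no dip (pure superdiffusion)
#' returns the first lag flagged `degenerate`. Ties break toward the
#' smaller lag.
#'
#' @param curve an [compute_msd()] result spanning >= 10 lags
#' @param smooth_window centered moving-average window (points)
#' @param after only minima at lags strictly greater than this count
#'   (seconds); typically the detected regime-1 boundary
#' @param min_prominence required drop/rise around a minimum, in log
#'   units of MSD/dt
#' @return lag time in seconds or `NA` (monophasic); attribute
#'   `degenerate` marks the no-subdiffusive-regime case
#' @export
detect_t2 <- function(curve, smooth_window = 5L, after = 0,
                      min_prominence = 0.1) {
  stop_if_not(inherits(curve, "msd_curve"), "curve must be an msd_curve")
  n <- nrow(curve)
  stop_if_not(n >= 10, "need >= 10 lags to detect a late-regime onset")
  y <- moving_average(log(curve$msd_over_dt), smooth_window)
  for (i in 2:(n - 1)) {
    if (curve$lag[i] <= after) next
    if (y[i] < y[i - 1] && y[i] < y[i + 1]) {
      drop_before <- max(y[1:(i - 1)]) - y[i]
      rise_after <- max(y[(i + 1):n]) - y[i]
      if (min(drop_before, rise_after) > min_prominence) {
        return(structure(curve$lag[i], degenerate = FALSE))
      }
    }
  }
  # rises overall with no dip: superdiffusive from the very first lag
  drawdown <- max(cummax(y) - y)
  if (y[n] - y[1] > min_prominence && drawdown < min_prominence) {
    return(structure(curve$lag[1], degenerate = TRUE))
  }
  structure(NA_real_, degenerate = FALSE)
}

#' Fit anomalous-scaling exponents per transport regime
#'
#' Unweighted least squares of log MSD on log lag over the short
#' (`lag <= t1`), long (`t2 <= lag <= fit_cap`) and intermediate
#' (`t1 <= lag <= t2`) windows; boundary lags belong to both adjacent
#' regimes. The lag grid is subsampled to at most `per_decade` log-spaced
#' points per decade before fitting so dense long-lag points do not
#' dominate. A regime with fewer than 3 lags (intermediate:
#' `min_intermediate`) is reported absent rather than extrapolated.
#'
#' @param curve an [compute_msd()] result
#' @param t1 end of the initial regime (s), e.g. from [detect_t1()]
#' @param t2 onset of the late regime (s), e.g. from [detect_t2()];
#'   `NA` means no late regime
#' @param fit_cap largest lag used in any fit (s); defaults to the last
#'   lag. Long-lag points beyond the cap are noise-dominated in
#'   low-statistics data.
#' @param min_intermediate minimum lags for an intermediate-regime fit
#' @param per_decade subsampling density for fitting
#' @return object of class `regime_result`: list with `t1`, `t2`,
#'   `alpha1`, `alpha12`, `alpha2` ([fit_power_law()] objects or `NULL`)
#'   and `has_intermediate`
#' @export
fit_regimes <- function(curve, t1, t2 = NA, fit_cap = NULL,
                        min_intermediate = 5L, per_decade = 30L) {
  stop_if_not(inherits(curve, "msd_curve"), "curve must be an msd_curve")
  fit_cap <- fit_cap %||% max(curve$lag)
  sub <- curve[log_subsample(curve$lag, per_decade), , drop = FALSE]
  sub <- sub[sub$lag <= fit_cap, , drop = FALSE]
  fit_window <- function(lo, hi, min_n = 3L) {
    w <- sub$lag >= lo & sub$lag <= hi
    if (sum(w) < min_n) return(NULL)
    fit_power_law(sub$lag[w], sub$msd[w])
  }
  alpha1 <- fit_window(0, t1)
  alpha2 <- if (is.na(t2)) NULL else fit_window(t2, fit_cap)
  alpha12 <- if (!is.na(t2) && t2 > t1)
    fit_window(t1, t2, min_n = min_intermediate) else NULL
  structure(list(t1 = as.numeric(t1), t2 = as.numeric(t2),
                 alpha1 = alpha1, alpha12 = alpha12, alpha2 = alpha2,
                 has_intermediate = !is.null(alpha12)),
            class = "regime_result")
}

#' @export
print.regime_result <- function(x, ...) {
  fmt <- function(f) if (is.null(f)) "absent"
    else sprintf("%.3f +/- %.3f (R2 %.3f)", f$exponent, f$stderr, f$r_squared)
  cat("transport regimes:\n")
  cat(sprintf("  t1 = %s s, t2 = %s s\n",
              format(x$t1, digits = 3), format(x$t2, digits = 3)))
  cat("  alpha1  =", fmt(x$alpha1), "\n")
  cat("  alpha12 =", fmt(x$alpha12), "\n")
  cat("  alpha2  =", fmt(x$alpha2), "\n")
  invisible(x)
}

#' Write an MSD curve as CSV
#'
#' Columns `lag_s`, `msd_um2`, `n_pairs` -- the plain-text exchange format
#' of the real-space pipeline.
#'
#' @param curve an [compute_msd()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_msd <- function(curve, path) {
  utils::write.csv(data.frame(lag_s = curve$lag, msd_um2 = curve$msd,
                              n_pairs = curve$n_pairs),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
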