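#' Build a van Hove distribution from raw displacements
#'
#' Histograms single-axis displacements at a fixed lag on uniform bins
#' centered symmetrically about zero and normalizes to unit area (a
#' probability density in 1/um). The support covers the
#' `support_quantile` quantile of |displacement|.
#'
#' @param d displacements, um
#' @param lag lag time the displacements belong to, seconds
#' @param bin_width histogram bin width, um (default 0.05, about the
#'   localization-precision scale)
#' @param axis label: `"pooled"`, `"x"` or `"y"`
#' @param support_quantile quantile of |d| the support must cover
#' @return object of class `van_hove`: data.frame with `bin_center`
#'   (um), `density` (1/um), `counts`; attributes `lag`, `axis`,
#'   `bin_width`, `n_displacements`
#' @export
van_hove_from_displacements <- function(d, lag, bin_width = 0.05,
                                        axis = "pooled",
                                        support_quantile = 0.999) {
  d <- d[is.finite(d)]
  stop_if_not(length(d) >= 2, "need at least 2 displacements")
  stop_if_not(bin_width > 0, "bin_width must be > 0")
  m <- max(stats::quantile(abs(d), support_quantile), 2 * bin_width)
  nb <- ceiling(m / bin_width) + 1L
  edges <- (seq(-nb, nb) + 0.5) * bin_width   # one bin centered on zero
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  idx <- findInterval(d, edges)
  inside <- idx >= 1 & idx <= length(centers)
  counts <- tabulate(idx[inside], nbins = length(centers))
  n <- length(d)
  density <- counts / (n * bin_width)
  structure(data.frame(bin_center = centers, density = density,
                       counts = counts),
            class = c("van_hove", "data.frame"),
            lag = lag, axis = axis, bin_width = bin_width,
            n_displacements = n)
}

#' Displacements of a track table at one lag
#' @keywords internal
lag_displacements <- function(tracks, lag, axis = c("pooled", "x", "y")) {
  axis <- match.arg(axis)
  dt <- attr(tracks, "frame_interval")
  k <- lag / dt
  stop_if_not(abs(k - round(k)) < 1e-6,
              sprintf("lag %g s is not an integer multiple of the frame interval %g s", lag, dt))
  k <- as.integer(round(k))
  stop_if_not(k >= 1, "lag must be at least one frame interval")
  dx <- c(); dy <- c()
  for (p in split(tracks[, c("frame", "x", "y")], tracks$particle)) {
    f <- p$frame
    span <- f[length(f)] - f[1]
    if (span < k) next
    xs <- rep(NA_real_, span + 1); ys <- xs
    idx <- f - f[1] + 1
    xs[idx] <- p$x; ys[idx] <- p$y
    n <- length(xs)
    ddx <- xs[(1 + k):n] - xs[1:(n - k)]
    ddy <- ys[(1 + k):n] - ys[1:(n - k)]
    ok <- !is.na(ddx)
    dx <- c(dx, ddx[ok]); dy <- c(dy, ddy[ok])
  }
  switch(axis, pooled = c(dx, dy), x = dx, y = dy)
}

#' Compute a van Hove displacement distribution from tracks
#'
#' Gathers all displacement pairs of all particles at the requested lag.
#' The pooled axis concatenates x- and y-displacements; `"x"`/`"y"`
#' resolve the distribution per axis (for directional-anisotropy checks).
#'
#' @param tracks a [track_table()]
#' @param lag lag time, seconds (integer multiple of the frame interval)
#' @param bin_width histogram bin width, um
#' @param axis `"pooled"` (default), `"x"` or `"y"`
#' @param min_displacements failure threshold
#' @return a [van_hove_from_displacements()] object
#' @export
compute_van_hove <- function(tracks, lag, bin_width = 0.05,
                             axis = c("pooled", "x", "y"),
                             min_displacements = 100L) {
  axis <- match.arg(axis)
  d <- lag_displacements(tracks, lag, axis)
  stop_if_not(length(d) >= min_displacements,
              sprintf("only %d displacements at lag %g s (need >= %d)",
                      length(d), lag, min_displacements))
  van_hove_from_displacements(d, lag = lag, bin_width = bin_width, axis = axis)
}

#' @export
print.van_hove <- function(x, ...) {
  cat(sprintf("van_hove: lag %g s, axis %s, %d bins of %g um, n = %d\n",
              attr(x, "lag"), attr(x, "axis"), nrow(x), attr(x, "bin_width"),
              attr(x, "n_displacements")))
  invisible(x)
}

#' @export
plot.van_hove <- function(x, log = "y", ...) {
  pos <- x$density > 0
  graphics::plot(x$bin_center[pos], x$density[pos], log = log,
                 xlab = expression(Delta * d ~ (mu * m)),
                 ylab = expression(G(Delta * d) ~ (mu * m^-1)), ...)
  invisible(x)
}

#' Mode, edge half-widths and asymmetry of a van Hove distribution
#'
#' The mode `d_peak` is located by parabolic interpolation around the
#' maximal bin: a least-squares quadratic over a window that grows from
#' the minimal 3 points until the density drop across it exceeds five
#' times the Poisson noise scale of a bin, so flat-topped distributions
#' (many bins across the peak, finite counts) do not inherit the noise of
#' the argmax bin. For noise-free input the window stays at 3 points and
#' the estimate is the classical 3-point parabola. Half-maximum crossings
#' on each side are located by linear interpolation between bins. The
#' leading edge is the side sharing the sign of `d_peak` (displacements
#' of the same sign as the mode and greater in magnitude); the other side
#' trails. When the mode is within one bin of zero, leading defaults to
#' the positive side and the result is flagged `symmetric`. The asymmetry
#' statistic is the fractional excess of the trailing half-width:
#' `asym = (HWHM_trailing - HWHM_leading) / HWHM_leading`.
#'
#' @param dist a [van_hove_from_displacements()] object
#' @return object of class `edge_stats`: list with `d_peak`,
#'   `hwhm_leading`, `hwhm_trailing`, `asym`, `fwhm`, `symmetric`
#' @export
fwhm_and_edges <- function(dist) {
  stop_if_not(inherits(dist, "van_hove"), "dist must be a van_hove")
  y <- dist$density; xc <- dist$bin_center
  bw <- attr(dist, "bin_width")
  nbin <- length(y)
  im <- which.max(y)
  stop_if_not(im > 1 && im < nbin,
              "mode at histogram boundary; support under-resolved")
  # density noise scale of one bin under Poisson counting; 0 for
  # analytic (count-free) input
  n <- attr(dist, "n_displacements")
  noise <- if (is.na(n) || all(is.na(dist$counts))) 0 else
    sqrt(y[im] / (n * bw))
  # grow the fit window until real curvature dominates the noise
  m_cap <- min(im - 1L, nbin - im)
  m <- 1L
  while (m < m_cap && noise > 0 &&
         (y[im] - y[im - m] < 5 * noise || y[im] - y[im + m] < 5 * noise)) {
    m <- m + 1L
  }
  win <- (im - m):(im + m)
  u <- xc[win] - xc[im]
  qf <- stats::lm.fit(cbind(1, u, u^2), y[win])$coefficients
  cc <- qf[3]
  off_um <- if (is.finite(cc) && cc < 0) -qf[2] / (2 * cc) else 0
  off_um <- max(-m * bw / 2, min(m * bw / 2, off_um))
  d_peak <- xc[im] + off_um
  peak_h <- unname(qf[1] + qf[2] * off_um + cc * off_um^2)
  if (!is.finite(peak_h) || peak_h <= 0) peak_h <- y[im]
  half <- peak_h / 2
  cross_right <- {
    j <- which(y < half & seq_along(y) > im)
    stop_if_not(length(j) > 0, "half maximum not crossed on the right")
    j <- j[1]
    xc[j - 1] + (xc[j] - xc[j - 1]) * (y[j - 1] - half) / (y[j - 1] - y[j])
  }
  cross_left <- {
    j <- which(y < half & seq_along(y) < im)
    stop_if_not(length(j) > 0, "half maximum not crossed on the left")
    j <- j[length(j)]
    xc[j] + (xc[j + 1] - xc[j]) * (half - y[j]) / (y[j + 1] - y[j])
  }
  hw_right <- cross_right - d_peak
  hw_left <- d_peak - cross_left
  symmetric <- abs(d_peak) <= bw
  lead_positive <- if (symmetric) TRUE else d_peak > 0
  hw_lead <- if (lead_positive) hw_right else hw_left
  hw_trail <- if (lead_positive) hw_left else hw_right
  structure(list(d_peak = d_peak,
                 hwhm_leading = hw_lead, hwhm_trailing = hw_trail,
                 asym = (hw_trail - hw_lead) / hw_lead,
                 fwhm = hw_left + hw_right,
                 symmetric = symmetric),
            class = "edge_stats")
}

#' @export
print.edge_stats <- function(x, ...) {
  cat(sprintf("edge_stats: d_peak %.4g um, FWHM %.4g um, HWHM(+lead) %.4g, HWHM(-trail) %.4g, asym %.3f%s\n",
              x$d_peak, x$fwhm, x$hwhm_leading, x$hwhm_trailing, x$asym,
              if (x$symmetric) " [symmetric]" else ""))
  invisible(x)
}

#' Anomalous exponents from the lag dependence of the van Hove width
#'
#' For Gaussian-like transport the squared full width at half maximum
#' scales as the MSD, so regressing log FWHM^2 on log lag gives the
#' anomalous exponent directly. Fits are split into a short- and a
#' long-lag regime at `split_at` (both-inclusive at the boundary);
#' `split_at = NULL` fits a single regime.
#'
#' @param lags lag times, seconds
#' @param fwhm full widths at half maximum, um (same length)
#' @param split_at regime boundary in seconds, or `NULL`
#' @return list with [fit_power_law()] objects `alpha1` (short regime,
#'   exponent of FWHM^2 vs lag), `alpha2` (long), or a single `alpha`;
#'   underpopulated regimes (< 3 lags) are `NULL`
#' @export
fit_fwhm_scaling <- function(lags, fwhm, split_at = 1.0) {
  stop_if_not(length(lags) == length(fwhm), "lags and fwhm lengths differ")
  fit_or_null <- function(sel) {
    if (sum(sel) < 3) return(NULL)
    fit_power_law(lags[sel], fwhm[sel]^2)
  }
  if (is.null(split_at)) {
    return(list(alpha = fit_or_null(rep(TRUE, length(lags)))))
  }
  list(alpha1 = fit_or_null(lags <= split_at),
       alpha2 = fit_or_null(lags >= split_at))
}

#' Fit a Gaussian-plus-exponential mixture to a van Hove distribution
#'
#' Nonlinear least squares of the density against
#' `A exp(-(d - c)^2 / (2 sigma^2)) + B exp(-|d - c| / lambda)`, both
#' terms sharing the center `c` (the distribution mode by default; zero
#' for symmetric data is recovered automatically). One-sided fits use
#' only bins on the leading or trailing side of the mode but keep the
#' full functional form, mirroring the fractional-amplitude readout
#' `a = A/(A+B)`, `b = B/(A+B)`. Multiple starting values of `lambda`
#' and `sigma` guard against the local minimum where the Gaussian term
#' absorbs the exponential.
#'
#' @param dist a [van_hove_from_displacements()] object
#' @param side `"both"`, `"leading"` or `"trailing"`
#' @param center fixed common center; default the interpolated mode
#' @return object of class `gauss_exp_fit`: list with `A`, `sigma`, `B`,
#'   `lam`, `a`, `b`, `side`, `center`, `goodness` (residual norm)
#' @export
fit_gauss_exp <- function(dist, side = c("both", "leading", "trailing"),
                          center = NULL) {
  side <- match.arg(side)
  stop_if_not(inherits(dist, "van_hove"), "dist must be a van_hove")
  es <- fwhm_and_edges(dist)
  center <- center %||% es$d_peak
  x <- dist$bin_center; y <- dist$density
  if (side != "both") {
    lead_positive <- if (es$symmetric) TRUE else es$d_peak > 0
    want_positive <- (side == "leading") == lead_positive
    sel <- if (want_positive) x >= center else x <= center
    x <- x[sel]; y <- y[sel]
  }
  stop_if_not(length(x) >= 8, "too few bins on the requested side")
  u <- abs(x - center)
  w <- sqrt(sum(y * u^2) / sum(y))     # crude width scale for starts
  peak <- max(y)
  # direct Levenberg-Marquardt on the residuals: tolerates the pure-limit
  # boundary (B = 0 leaves lambda unidentifiable) that breaks nls-object
  # construction
  model_resid <- function(p) {
    p[1] * exp(-u^2 / (2 * p[2]^2)) + p[3] * exp(-u / p[4]) - y
  }
  starts <- expand.grid(sig0 = w * c(0.5, 1), lam0 = w * c(0.3, 1, 3))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(0.7 * peak, starts$sig0[s], 0.3 * peak, starts$lam0[s]),
        lower = c(0, 1e-4, 0, 1e-4),
        upper = rep(Inf, 4),
        fn = model_resid,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  stop_if_not(!is.null(best),
              sprintf("mixture fit failed to converge from %d starts", nrow(starts)))
  A <- best$par[1]; B <- best$par[3]
  structure(list(A = A, sigma = best$par[2],
                 B = B, lam = best$par[4],
                 a = A / (A + B), b = B / (A + B),
                 side = side, center = center,
                 goodness = sqrt(best$rss)),
            class = "gauss_exp_fit")
}

#' @export
print.gauss_exp_fit <- function(x, ...) {
  cat(sprintf("gauss+exp fit (%s side): a = %.3f, b = %.3f | sigma %.4g um, lambda %.4g um, center %.3g um\n",
              x$side, x$a, x$b, x$sigma, x$lam, x$center))
  invisible(x)
}

#' Per-lag van Hove metric table
#'
#' Runs [compute_van_hove()], [fwhm_and_edges()] and one-sided
#' [fit_gauss_exp()] over a set of lags and tabulates the width,
#' asymmetry and mixture-amplitude metrics. Lags with insufficient
#' statistics are skipped with a message.
#'
#' @param tracks a [track_table()]
#' @param lags lag times, seconds; the default spans two decades
#' @param bin_width histogram bin width, um
#' @param axis `"pooled"`, `"x"` or `"y"`
#' @return data.frame with one row per lag: `lag_s`, `axis`,
#'   `d_peak_um`, `fwhm_um`, `hwhm_plus_um` (leading),
#'   `hwhm_minus_um` (trailing), `asym`, `a_lead`, `b_lead`, `a_trail`,
#'   `b_trail`
#' @export
van_hove_metrics <- function(tracks,
                             lags = c(0.1, 0.2, 0.3, 0.5, 1, 2, 3, 5, 10, 15),
                             bin_width = 0.05, axis = "pooled") {
  rows <- lapply(lags, function(lg) {
    tryCatch({
      vh <- compute_van_hove(tracks, lg, bin_width = bin_width, axis = axis)
      es <- fwhm_and_edges(vh)
      fl <- tryCatch(fit_gauss_exp(vh, "leading"), error = function(e) NULL)
      ft <- tryCatch(fit_gauss_exp(vh, "trailing"), error = function(e) NULL)
      data.frame(lag_s = lg, axis = axis, d_peak_um = es$d_peak,
                 fwhm_um = es$fwhm, hwhm_plus_um = es$hwhm_leading,
                 hwhm_minus_um = es$hwhm_trailing, asym = es$asym,
                 a_lead = if (is.null(fl)) NA_real_ else fl$a,
                 b_lead = if (is.null(fl)) NA_real_ else fl$b,
                 a_trail = if (is.null(ft)) NA_real_ else ft$a,
                 b_trail = if (is.null(ft)) NA_real_ else ft$b)
    }, error = function(e) {
      message(sprintf("van_hove_metrics: lag %g s skipped (%s)", lg,
                      conditionMessage(e)))
      NULL
    })
  })
  out <- do.call(rbind, rows)
  stop_if_not(!is.null(out) && nrow(out) > 0, "no lag produced a distribution")
  out
}
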