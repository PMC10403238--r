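#' Radially averaged image structure function
#'
#' For each of about `n_lags` log-spaced frame lags, averages the squared
#' modulus of the 2-D Fourier transform of frame differences over the
#' available frame pairs (deterministically strided to at most
#' `max_pairs` pairs per lag), then averages over radial wave-vector
#' annuli one FFT bin wide. Wave vectors are physical
#' (`q = 2 pi k / (N * pixel_size)`, 1/um); the zero-frequency bin is
#' excluded and annulus centers are the mean |q| of the contributing FFT
#' pixels. The per-pixel normalization is `|FFT(diff)|^2 / (W * H)`, so
#' before radial averaging the total over the q-plane equals the summed
#' squared difference image (Parseval).
#'
#' @param stack an [image_stack()]
#' @param max_lag largest lag, seconds (default: half the stack duration)
#' @param n_lags approximate number of log-spaced lags
#' @param max_pairs frame-pair cap per lag (evenly strided, deterministic)
#' @return object of class `ddm_matrix`: list with `q` (1/um), `lags`
#'   (s), `D` (matrix, q x lag), `n_pairs` (frame pairs per lag), `n_px`
#'   (FFT pixels per q annulus), `pixel_size`, `frame_interval`
#' @export
image_structure_function <- function(stack, max_lag = NULL, n_lags = 40L,
                                     max_pairs = 300L) {
  stop_if_not(inherits(stack, "image_stack"), "stack must be an image_stack")
  d <- dim(stack$frames)
  H <- d[1]; W <- d[2]; nf <- d[3]
  dt <- stack$frame_interval
  duration <- (nf - 1) * dt
  max_lag <- max_lag %||% (duration / 2)
  stop_if_not(max_lag < duration, "max_lag must be smaller than the stack duration")
  kmax <- max(2L, floor(max_lag / dt))
  ks <- unique(round(10^seq(0, log10(kmax), length.out = n_lags)))
  ks <- ks[ks >= 1 & ks <= kmax]

  # cache the FFT of every needed frame; differences are linear in the FFT
  F <- vector("list", nf)
  for (t in seq_len(nf)) F[[t]] <- stats::fft(stack$frames[, , t])

  # physical wave-vector magnitude per FFT pixel and annulus assignment
  fr <- c(0:(H %/% 2), -((H - H %/% 2 - 1):1)) / H       # cycles/px, rows
  fc <- c(0:(W %/% 2), -((W - W %/% 2 - 1):1)) / W       # cycles/px, cols
  qr <- 2 * pi * fr / stack$pixel_size
  qc <- 2 * pi * fc / stack$pixel_size
  qmag <- sqrt(outer(qr^2, qc^2, `+`))
  dq <- 2 * pi / (min(W, H) * stack$pixel_size)           # one FFT bin
  bin <- round(qmag / dq)
  bin[1, 1] <- -1                                         # drop zero frequency
  nbin <- as.integer(max(bin))
  binv <- as.integer(as.vector(bin))
  counts <- tabulate(binv[binv > 0], nbins = nbin)
  q_centers <- vapply(seq_len(nbin), function(b) 0, numeric(1))
  sums_q <- tapply(as.vector(qmag)[binv > 0], binv[binv > 0], sum)
  q_centers[as.integer(names(sums_q))] <- sums_q / counts[as.integer(names(sums_q))]

  D <- matrix(0, nbin, length(ks))
  n_pairs <- integer(length(ks))
  norm <- W * H
  for (j in seq_along(ks)) {
    k <- ks[j]
    starts <- seq(1L, nf - k)
    if (length(starts) > max_pairs) {
      starts <- unique(round(seq(1L, nf - k, length.out = max_pairs)))
    }
    acc <- numeric(H * W)
    for (s in starts) {
      acc <- acc + Mod(F[[s + k]] - F[[s]])^2
    }
    pw <- acc / (length(starts) * norm)
    sums <- tapply(pw[binv > 0], binv[binv > 0], sum)
    row <- numeric(nbin)
    row[as.integer(names(sums))] <- sums / counts[as.integer(names(sums))]
    D[, j] <- row
    n_pairs[j] <- length(starts)
  }
  keep <- counts > 0 & q_centers > 0
  structure(list(q = q_centers[keep], lags = ks * dt,
                 D = D[keep, , drop = FALSE], n_pairs = n_pairs,
                 n_px = counts[keep],
                 pixel_size = stack$pixel_size, frame_interval = dt),
            class = "ddm_matrix")
}

#' @export
print.ddm_matrix <- function(x, ...) {
  cat(sprintf("ddm_matrix: %d q bins in [%.3g, %.3g] 1/um, %d lags in [%g, %g] s\n",
              length(x$q), min(x$q), max(x$q), length(x$lags),
              min(x$lags), max(x$lags)))
  invisible(x)
}

#' @export
plot.ddm_matrix <- function(x, q_show = NULL, ...) {
  q_show <- q_show %||% stats::quantile(x$q, c(0.1, 0.3, 0.5))
  idx <- vapply(q_show, function(qq) which.min(abs(x$q - qq)), 1L)
  graphics::matplot(x$lags, t(x$D[idx, , drop = FALSE]), log = "xy",
                    type = "b", pch = 1, xlab = "lag time (s)",
                    ylab = expression(D(q, Delta * t)), ...)
  graphics::legend("bottomright", legend = sprintf("q = %.2f", x$q[idx]),
                   col = seq_along(idx), lty = seq_along(idx), bty = "n")
  invisible(x)
}

#' Per-q stretched-exponential fits of the image structure function
#'
#' Fits `D(q, dt) = A(q) * (1 - exp(-(dt/tau(q))^gamma(q))) + B(q)` for
#' every q bin by bounded nonlinear least squares, out to `lag_cap`
#' (longer lags are noise-dominated in low-statistics data). Starting
#' values: `B0 = min D`, `A0 = max D - B0`, `tau0` from the lag where D
#' first reaches `B0 + A0 (1 - 1/e)`, `gamma0 = 1`; amplitudes are bound
#' non-negative and gamma to `gamma_bounds`. Non-converged q bins are
#' flagged and excluded downstream.
#'
#' @param m a [image_structure_function()] result
#' @param lag_cap largest lag used in the fits, seconds
#' @param gamma_bounds allowed stretching-exponent interval
#' @return object of class `stretched_exp_fit`: data.frame with `q`,
#'   `A`, `B`, `tau`, `gamma`, `converged`, `rss`
#' @export
fit_ddm_matrix <- function(m, lag_cap = 100, gamma_bounds = c(0.2, 3)) {
  stop_if_not(inherits(m, "ddm_matrix"), "m must be a ddm_matrix")
  use <- m$lags <= lag_cap
  stop_if_not(sum(use) >= 6, "need >= 6 lags below lag_cap")
  lt <- m$lags[use]
  rows <- lapply(seq_along(m$q), function(i) {
    d <- m$D[i, use]
    B0 <- max(min(d), 1e-12)
    A0 <- max(max(d) - B0, 1e-12)
    thr <- B0 + A0 * (1 - exp(-1))
    tau0 <- if (any(d >= thr)) lt[which(d >= thr)[1]] else stats::median(lt)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        d ~ B + A * (1 - exp(-(lt / tau)^g)),
        start = list(A = A0, B = B0, tau = tau0, g = 1),
        lower = c(A = 0, B = 0, tau = 1e-8, g = gamma_bounds[1]),
        upper = c(A = Inf, B = Inf, tau = Inf, g = gamma_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(q = m$q[i], A = NA_real_, B = NA_real_,
                        tau = NA_real_, gamma = NA_real_,
                        converged = FALSE, rss = NA_real_))
    }
    cf <- stats::coef(fit)
    data.frame(q = m$q[i], A = unname(cf["A"]), B = unname(cf["B"]),
               tau = unname(cf["tau"]), gamma = unname(cf["g"]),
               converged = TRUE, rss = sum(stats::resid(fit)^2))
  })
  out <- do.call(rbind, rows)
  n_failed <- sum(!out$converged)
  if (n_failed > 0) {
    message(sprintf("fit_ddm_matrix: %d of %d q bins did not converge",
                    n_failed, nrow(out)))
  }
  structure(out, class = c("stretched_exp_fit", "data.frame"),
            lag_cap = lag_cap, gamma_bounds = gamma_bounds)
}

#' Power-law scaling of the density-fluctuation decay time
#'
#' Regresses log tau on log q over converged q bins inside `q_range` to
#' obtain `tau(q) ~ q^-beta` and the implied anomalous exponent
#' `alpha_ddm = 2 / beta` (beta = 2 diffusive, 1 ballistic). Two guard
#' diagnostics are attached: a low-q plateau flag (local slope magnitude
#' of the 3 smallest converged q bins below 0.5, symptomatic of the
#' finite image size) and a high-q uptick flag (tau increasing with q at
#' the top of the band, symptomatic of the optical resolution limit).
#'
#' @param fit a [fit_ddm_matrix()] result
#' @param q_range fitted wave-vector band, 1/um
#' @return object of class `scaling_result`: list with `beta`,
#'   `beta_se`, `beta_ci95`, `alpha_ddm`, `prefactor`, `q_fit_range`,
#'   `n_q`, `low_q_plateau`, `high_q_uptick`
#' @export
fit_tau_powerlaw <- function(fit, q_range = c(1, 4)) {
  stop_if_not(inherits(fit, "stretched_exp_fit"),
              "fit must be a stretched_exp_fit")
  ok <- fit$converged & is.finite(fit$tau) & fit$tau > 0
  inr <- ok & fit$q >= q_range[1] & fit$q <= q_range[2]
  stop_if_not(sum(inr) >= 4,
              sprintf("only %d converged q points in [%g, %g] 1/um (need >= 4)",
                      sum(inr), q_range[1], q_range[2]))
  pl <- fit_power_law(fit$q[inr], fit$tau[inr])
  beta <- -pl$exponent
  # low-q plateau: local slope over the 3 smallest converged q bins
  low <- which(ok)[seq_len(min(3, sum(ok)))]
  low_flag <- FALSE
  if (length(low) == 3) {
    sl <- stats::coef(stats::lm(log(fit$tau[low]) ~ log(fit$q[low])))[2]
    low_flag <- abs(sl) < 0.5
  }
  # high-q uptick: tau rising with q at the top of the fitted band
  top <- which(inr)
  top <- top[fit$q[top] >= q_range[2] * 0.75]
  up_flag <- FALSE
  if (length(top) >= 3) {
    sl <- stats::coef(stats::lm(log(fit$tau[top]) ~ log(fit$q[top])))[2]
    up_flag <- sl > 0
  }
  structure(list(beta = beta, beta_se = pl$stderr,
                 beta_ci95 = beta + c(-1, 1) * 1.96 * pl$stderr,
                 alpha_ddm = 2 / beta, prefactor = pl$prefactor,
                 q_fit_range = q_range, n_q = sum(inr),
                 low_q_plateau = low_flag, high_q_uptick = up_flag),
            class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf("tau(q) ~ q^-beta: beta = %.3f +/- %.3f (alpha_ddm = %.3f), %d q in [%g, %g] 1/um\n",
              x$beta, x$beta_se, x$alpha_ddm, x$n_q,
              x$q_fit_range[1], x$q_fit_range[2]))
  if (x$low_q_plateau) cat("  flag: low-q plateau (finite field of view)\n")
  if (x$high_q_uptick) cat("  flag: high-q uptick (resolution limit)\n")
  invisible(x)
}

#' q-averaged stretching exponent
#'
#' Mean and standard error of gamma(q) over converged q bins inside
#' `q_range`, with a q-insensitivity diagnostic (slope of gamma vs q and
#' its 95% interval); interpretation of beta assumes gamma is flat in q.
#'
#' @param fit a [fit_ddm_matrix()] result
#' @param q_range wave-vector band, 1/um
#' @return list with `mean`, `stderr`, `n`, `slope`, `slope_ci95`
#' @export
average_gamma <- function(fit, q_range = c(1, 4)) {
  stop_if_not(inherits(fit, "stretched_exp_fit"),
              "fit must be a stretched_exp_fit")
  sel <- fit$converged & fit$q >= q_range[1] & fit$q <= q_range[2] &
    is.finite(fit$gamma)
  stop_if_not(sum(sel) >= 3, "need >= 3 converged q points in range")
  g <- fit$gamma[sel]; q <- fit$q[sel]
  n <- length(g)
  se <- stats::sd(g) / sqrt(n)
  lmfit <- stats::lm(g ~ q)
  # exactly constant gamma(q) (noiseless synthetic input) is legitimate
  sl <- suppressWarnings(summary(lmfit))$coefficients[2, 1:2]
  list(mean = mean(g), stderr = se, n = n,
       slope = unname(sl[1]),
       slope_ci95 = unname(sl[1] + c(-1, 1) * 1.96 * sl[2]))
}

#' Write a DDM matrix as long-form CSV
#'
#' Columns `q_um_inv`, `lag_s`, `D` -- the plain-text exchange format of
#' the reciprocal-space pipeline.
#'
#' @param m a [image_structure_function()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ddm_matrix <- function(m, path) {
  long <- data.frame(q_um_inv = rep(m$q, times = length(m$lags)),
                     lag_s = rep(m$lags, each = length(m$q)),
                     D = as.vector(m$D))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
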