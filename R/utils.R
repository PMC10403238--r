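#' @keywords internal
"_PACKAGE"

## shared numeric helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Subsample indices to at most `per_decade` log-spaced points per decade
#'
#' Long-lag MSD points are dense on a linear grid and highly correlated;
#' regime fits use a log-uniform subsample so no decade dominates the
#' regression.
#'
#' @param x positive numeric vector (e.g. lag times), strictly increasing
#' @param per_decade maximum points kept per decade of `x`
#' @return integer indices into `x`, always including the first and last
#' @keywords internal
log_subsample <- function(x, per_decade = 30) {
  stopifnot(all(x > 0), !is.unsorted(x))
  n <- length(x)
  if (n <= 2) return(seq_len(n))
  span <- log10(x[n] / x[1])
  n_target <- max(2, ceiling(span * per_decade) + 1)
  if (n_target >= n) return(seq_len(n))
  grid <- 10^seq(log10(x[1]), log10(x[n]), length.out = n_target)
  idx <- unique(vapply(grid, function(g) which.min(abs(log(x) - log(g))), 1L))
  sort(unique(c(1L, idx, n)))
}

#' Centered moving average with shrinking edge windows
#' @param y numeric vector
#' @param window odd window size; 1 returns `y` unchanged
#' @keywords internal
moving_average <- function(y, window = 5L) {
  window <- as.integer(window)
  stopifnot(window >= 1L)
  if (window == 1L) return(y)
  half <- window %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(y[lo:hi])
  }, numeric(1))
}

#' Unweighted power-law fit in log-log space
#'
#' Fits `y = prefactor * x^exponent` by ordinary least squares on
#' (log x, log y). Non-positive `y` values are dropped (counted in the
#' result) because they carry no information on a log scale.
#'
#' @param x,y positive numerics of equal length
#' @return object of class `power_law_fit`: list with `exponent`,
#'   `prefactor`, `stderr` (of the exponent), `r_squared`,
#'   `range` (range of `x` used) and `n` points used
#' @export
fit_power_law <- function(x, y) {
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  stop_if_not(length(x) >= 3, "power-law fit needs at least 3 positive points")
  fit <- stats::lm(log(y) ~ log(x))
  # summary.lm warns on essentially perfect fits; exact power laws are a
  # legitimate input here (closed-form validation curves)
  sm <- suppressWarnings(summary(fit))
  structure(list(
    exponent  = unname(stats::coef(fit)[2]),
    prefactor = exp(unname(stats::coef(fit)[1])),
    stderr    = unname(sm$coefficients[2, 2]),
    r_squared = sm$r.squared,
    range     = range(x),
    n         = length(x)
  ), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power law: y ~ %.4g * x^%.3f  (se %.3f, R2 %.4f, n %d, x in [%.3g, %.3g])\n",
              x$prefactor, x$exponent, x$stderr, x$r_squared, x$n,
              x$range[1], x$range[2]))
  invisible(x)
}

## R-squared of log-log regression on a lag window, used by detect_t1
loglog_r2 <- function(lag, msd) {
  lx <- log(lag); ly <- log(msd)
  suppressWarnings(summary(stats::lm(ly ~ lx)))$r.squared
}
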