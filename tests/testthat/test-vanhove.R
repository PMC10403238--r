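# build a van_hove object from an analytic density evaluated on a bin grid
analytic_van_hove <- function(f, bin_width = 0.05, support = 6) {
  nb <- ceiling(support / bin_width)
  centers <- seq(-nb, nb) * bin_width
  structure(data.frame(bin_center = centers, density = f(centers),
                       counts = NA_integer_),
            class = c("van_hove", "data.frame"),
            lag = 1, axis = "pooled", bin_width = bin_width,
            n_displacements = NA_integer_)
}

test_that("histograms are unit-area densities with mass at zero for static input", {
  df <- data.frame(particle = rep(1:5, each = 30), frame = rep(0:29, 5),
                   x = rep(1:5, each = 30), y = rep(2, 150))
  tr <- track_table(df, frame_interval = 0.1)
  vh <- compute_van_hove(tr, 0.5, bin_width = 0.05)
  expect_equal(sum(vh$density * attr(vh, "bin_width")), 1, tolerance = 1e-6)
  expect_equal(vh$density[abs(vh$bin_center) < 0.025],
               1 / attr(vh, "bin_width"))
  expect_true(all(vh$density[abs(vh$bin_center) >= 0.025] == 0))

  # normalization holds on generic samples too
  set.seed(2)
  vh2 <- van_hove_from_displacements(rnorm(5e4), lag = 1, bin_width = 0.05)
  expect_equal(sum(vh2$density * 0.05), 1, tolerance = 1e-3)  # 0.1% tail clip
})

test_that("Gaussian sample density matches the sampling distribution bin-wise", {
  set.seed(3)
  n <- 1e5
  d <- rnorm(n, 0, 1)
  vh <- van_hove_from_displacements(d, lag = 1, bin_width = 0.05)
  p <- pnorm(vh$bin_center + 0.025) - pnorm(vh$bin_center - 0.025)
  mc_sd <- sqrt(p * (1 - p) / n) / 0.05
  dev <- abs(vh$density - p / 0.05)
  expect_lt(max((dev / pmax(mc_sd, 1e-9))[p > 1e-5]), 5)
})

test_that("closed-form widths: Gaussian FWHM = 2 sqrt(2 ln 2) sigma, exponential FWHM = 2 lambda ln 2", {
  g <- analytic_van_hove(function(x) dnorm(x, 0, 1))
  eg <- fwhm_and_edges(g)
  expect_equal(eg$fwhm, 2 * sqrt(2 * log(2)), tolerance = 0.025)
  expect_lt(abs(eg$asym), 1e-6)
  expect_true(eg$symmetric)

  ex <- analytic_van_hove(function(x) exp(-abs(x) / 1.2) / 2.4)
  ee <- fwhm_and_edges(ex)
  expect_equal(ee$fwhm, 2 * 1.2 * log(2), tolerance = 0.05)
})

test_that("asymmetric construction: edge half-widths follow the mode-sign convention", {
  # mode at -0.5; Gaussian half (sigma 1) above it, exponential half
  # (lambda 1.2) below. Leading edge = same sign as the mode (negative)
  # = the exponential side, HWHM 1.2*ln2; trailing = Gaussian side,
  # HWHM sqrt(2 ln 2).
  # fine bins: the parabolic mode estimate is only half-bin accurate at
  # a kinked peak, and the edge widths are measured from the mode
  f <- function(x) ifelse(x >= -0.5, exp(-(x + 0.5)^2 / 2),
                          exp(-abs(x + 0.5) / 1.2))
  es <- fwhm_and_edges(analytic_van_hove(f, bin_width = 0.01))
  expect_equal(es$d_peak, -0.5, tolerance = 0.05)
  expect_false(es$symmetric)
  expect_equal(es$hwhm_leading, 1.2 * log(2), tolerance = 0.05)
  expect_equal(es$hwhm_trailing, sqrt(2 * log(2)), tolerance = 0.05)
  expect_equal(es$asym, (sqrt(2 * log(2)) - 1.2 * log(2)) / (1.2 * log(2)),
               tolerance = 0.05)
  expect_equal(es$fwhm, es$hwhm_leading + es$hwhm_trailing, tolerance = 1e-9)
})

test_that("mirroring displacements swaps leading and trailing edges", {
  set.seed(4)
  d <- c(rnorm(4e4, -0.4, 0.5), -0.4 - rexp(2e4, 1))  # left-skewed
  vh <- van_hove_from_displacements(d, lag = 1)
  vm <- van_hove_from_displacements(-d, lag = 1)
  a <- fwhm_and_edges(vh); b <- fwhm_and_edges(vm)
  expect_equal(b$d_peak, -a$d_peak, tolerance = 1e-9)
  expect_equal(b$hwhm_leading, a$hwhm_leading, tolerance = 1e-9)
  expect_equal(b$hwhm_trailing, a$hwhm_trailing, tolerance = 1e-9)
  expect_equal(b$asym, (a$hwhm_trailing - a$hwhm_leading) / a$hwhm_leading,
               tolerance = 1e-9)

  # exactly symmetric input gives zero asymmetry
  s <- analytic_van_hove(function(x) dnorm(x, 0, 0.8))
  expect_lt(abs(fwhm_and_edges(s)$asym), 1e-6)
})

test_that("width scaling recovers diffusive and ballistic exponents", {
  set.seed(5)
  lags <- c(0.1, 0.2, 0.3, 0.5, 1, 2, 3, 5, 10, 15)
  # bin width scaled to the expected spread so the binning geometry (and
  # the finite-n bias of the argmax peak) is identical at every lag
  gauss_fw <- function(sig_of_lag) vapply(lags, function(lg) {
    s <- sig_of_lag(lg)
    d <- rnorm(2e4, 0, s)
    fwhm_and_edges(van_hove_from_displacements(d, lg, bin_width = s / 10))$fwhm
  }, numeric(1))

  fw_diff <- gauss_fw(function(lg) sqrt(0.2 * lg))     # sigma^2 ~ lag
  sc <- fit_fwhm_scaling(lags, fw_diff, split_at = 1)
  expect_equal(sc$alpha1$exponent, 1, tolerance = 0.1)
  expect_equal(sc$alpha2$exponent, 1, tolerance = 0.1)

  fw_ball <- gauss_fw(function(lg) 0.3 * lg)           # sigma ~ lag
  sc2 <- fit_fwhm_scaling(lags, fw_ball, split_at = NULL)
  expect_equal(sc2$alpha$exponent, 2, tolerance = 0.1)
})

test_that("width scaling recovers the fBm exponent from trajectories", {
  tr <- fbm_tracks(0.5)
  lags <- c(0.2, 0.5, 1, 2, 5, 10)
  fw <- vapply(lags, function(lg)
    fwhm_and_edges(compute_van_hove(tr, lg, bin_width = 0.02))$fwhm,
    numeric(1))
  sc <- fit_fwhm_scaling(lags, fw, split_at = NULL)
  expect_equal(sc$alpha$exponent, 0.5, tolerance = 0.1)
})

test_that("mixture fit collapses to the correct single component in the pure limits", {
  set.seed(6)
  dg <- rnorm(1e5, 0, 0.4)
  fg <- fit_gauss_exp(van_hove_from_displacements(dg, 1, bin_width = 0.02))
  expect_lt(fg$b, 0.05)
  expect_equal(fg$sigma, 0.4, tolerance = 0.05 * 0.4)

  de <- sample(c(-1, 1), 1e5, replace = TRUE) * rexp(1e5, 1 / 0.6)
  fe <- fit_gauss_exp(van_hove_from_displacements(de, 1, bin_width = 0.02))
  expect_lt(fe$a, 0.05)
  expect_equal(fe$lam, 0.6, tolerance = 0.05 * 0.6)
})

test_that("mixture amplitude fractions are identifiable at a = 0.7", {
  # amplitudes A, B with A/(A+B) = 0.7; component masses follow from
  # the term integrals: Gaussian A*sigma*sqrt(2*pi), exponential 2*B*lambda
  set.seed(7)
  n <- 1e5; A <- 0.7; B <- 0.3; sig <- 0.3; lam <- 0.6
  p_gauss <- A * sig * sqrt(2 * pi) / (A * sig * sqrt(2 * pi) + 2 * B * lam)
  from_g <- rbinom(n, 1, p_gauss) == 1
  d <- ifelse(from_g, rnorm(n, 0, sig),
              sample(c(-1, 1), n, replace = TRUE) * rexp(n, 1 / lam))
  vh <- van_hove_from_displacements(d, 1, bin_width = 0.02)
  for (side in c("leading", "trailing")) {
    fit <- fit_gauss_exp(vh, side)
    expect_lt(abs(fit$a - 0.7), 0.05)
    expect_lt(abs(fit$b - 0.3), 0.05)
  }
})

test_that("metric table covers the requested lags and flags skipped ones", {
  tr <- brownian_tracks()
  mt <- van_hove_metrics(tr, lags = c(0.1, 1, 5), bin_width = 0.05)
  expect_equal(mt$lag_s, c(0.1, 1, 5))
  expect_true(all(is.finite(mt$fwhm_um)))
  expect_true(all(abs(mt$asym) < 0.25))
})
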