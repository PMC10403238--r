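test_that("identical configurations give bit-identical trajectories and images", {
  cfg <- sim_config(5, 40, seed = 9)
  mm <- motion_model("fbm", alpha = 0.6, generalized_coefficient = 0.05)
  t1 <- gen_fbm_tracks(cfg, mm)
  t2 <- gen_fbm_tracks(cfg, mm)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  spec <- image_render_spec(noise_model = "poisson")
  s1 <- render_image_stack(t1, spec, cfg)
  s2 <- render_image_stack(t2, spec, cfg)
  expect_identical(s1$frames, s2$frames)
})

test_that("fBm increments reproduce the exact fGn covariance", {
  for (alpha in c(0.4, 1.3)) {
    cfg <- sim_config(60, 201, frame_interval = 1, seed = 21)
    tr <- gen_fbm_tracks(cfg, motion_model("fbm", alpha = alpha,
                                           generalized_coefficient = 1))
    inc <- do.call(cbind, lapply(split(tr$x, tr$particle), diff))
    n <- length(inc)  # 12000 increments
    for (k in 0:3) {
      emp <- mean(inc[1:(nrow(inc) - k), ] * inc[(1 + k):nrow(inc), ])
      theo <- sptddm:::fgn_acf(k, alpha)
      expect_lt(abs(emp - theo), 4 / sqrt(n))
    }
  }
})

test_that("degenerate fBm limits: zero coefficient is static, Brownian increments uncorrelated", {
  cfg <- sim_config(3, 30, seed = 1)
  tr0 <- gen_fbm_tracks(cfg, motion_model("brownian", generalized_coefficient = 0))
  expect_true(all(tapply(tr0$x, tr0$particle, function(v) all(v == v[1]))))
  expect_error(gen_fbm_tracks(cfg, motion_model("fbm", alpha = 2)), "0, 2")

  cfgB <- sim_config(200, 1000, seed = 8)
  trB <- gen_fbm_tracks(cfgB, motion_model("brownian", generalized_coefficient = 0.2))
  inc <- do.call(cbind, lapply(split(trB$x, trB$particle), diff))
  n <- length(inc)
  rho <- stats::cor(as.vector(inc[-nrow(inc), ]), as.vector(inc[-1, ]))
  expect_lt(abs(rho), 3 / sqrt(n))
})

test_that("ballistic tracks obey the half-sum closed form MSD = 0.5 v^2 dt^2", {
  cfg <- sim_config(5, 50, seed = 2)
  tr <- gen_ballistic_tracks(cfg, motion_model("ballistic", velocity_mean = 1,
                                               velocity_sd = 0,
                                               generalized_coefficient = 0))
  cv <- compute_msd(tr, max_lag = 3, min_pairs = 1)
  expect_equal(cv$msd[cv$lag == 2], 2, tolerance = 1e-12)
  expect_equal(cv$msd, 0.5 * cv$lag^2, tolerance = 1e-12)
})

test_that("zero-velocity ballistic model with jitter reduces to Brownian motion", {
  cfg <- sim_config(150, 1000, seed = 3)
  tr <- gen_ballistic_tracks(cfg, motion_model("ballistic", velocity_mean = 0,
                                               generalized_coefficient = 0.2))
  f <- msd_exponent(compute_msd(tr, max_lag = 10))
  expect_equal(f$exponent, 1, tolerance = 0.05)
})

test_that("without drift, pooled x and y displacements are indistinguishable", {
  cfg <- sim_config(100, 102, seed = 4)
  tr <- gen_fbm_tracks(cfg, motion_model("brownian", generalized_coefficient = 0.2))
  dx <- sptddm:::lag_displacements(tr, 0.1, "x")
  dy <- sptddm:::lag_displacements(tr, 0.1, "y")
  expect_gte(length(dx), 1e4)
  expect_gt(suppressWarnings(stats::ks.test(dx, dy))$p.value, 0.01)
})

test_that("hop-free caged motion plateaus at 2*cage_size^2 and stays Gaussian", {
  cfg <- sim_config(150, 400, seed = 5)
  mm <- motion_model("caged_hopping", cage_size = 0.2,
                     generalized_coefficient = 0.5, hop_rate = 0)
  tr <- gen_caged_hopping_tracks(cfg, mm)
  cv <- compute_msd(tr, max_lag = 20)
  plateau <- mean(cv$msd[cv$lag >= 5])
  expect_equal(plateau, 2 * 0.2^2, tolerance = 0.1)
  vh <- compute_van_hove(tr, lag = 5, bin_width = 0.02)
  fit <- fit_gauss_exp(vh)
  expect_lt(fit$b, 0.05)
})

test_that("cage hopping produces excess exponential tail mass", {
  cfg <- sim_config(150, 400, seed = 6)
  mm <- motion_model("caged_hopping", cage_size = 0.2,
                     generalized_coefficient = 0.5,
                     hop_rate = 0.2, hop_length = 0.5)
  tr <- gen_caged_hopping_tracks(cfg, mm)
  vh <- compute_van_hove(tr, lag = 5, bin_width = 0.02)
  fit <- fit_gauss_exp(vh)
  expect_gt(fit$b, 0.1)
})

test_that("multimode ground truth records the analytic crossover machinery", {
  tr <- multimode_tracks()
  gt <- attr(tr, "ground_truth")
  # speed chosen so the two MSD terms are equal exactly at the crossover
  expect_equal(gt$K * 5^gt$alpha1, 0.5 * gt$speed^2 * 5^2, tolerance = 1e-12)
  expect_equal(gt$expected_t2, (1 - 0.35)^(1 / 1.65) * 5, tolerance = 1e-12)
  expect_warning(
    gen_multimode_tracks(sim_config(2, 20, seed = 1),
                         motion_model("multimode", alpha = 0.4,
                                      generalized_coefficient = 0.02,
                                      crossover_time = 50)),
    "outside simulated lag range")
})

test_that("multimode without a ballistic term is pure subdiffusion", {
  cfg <- sim_config(150, 1000, seed = 7)
  tr <- gen_multimode_tracks(cfg, motion_model("multimode", alpha = 0.4,
                                               generalized_coefficient = 0.05,
                                               crossover_time = NULL))
  cv <- compute_msd(tr, max_lag = 30)
  t2 <- detect_t2(cv)
  expect_true(is.na(t2))
  expect_equal(msd_exponent(cv)$exponent, 0.4, tolerance = 0.05)
})

test_that("unidirectional drift skews per-axis van Hove modes with growing lag", {
  cfg <- sim_config(150, 400, seed = 12)
  mm <- motion_model("multimode", alpha = 0.35, generalized_coefficient = 0.01,
                     crossover_time = 3, drift_direction = -pi / 2,
                     drift_direction_sd = 0)
  tr <- gen_multimode_tracks(cfg, mm)
  peaks <- vapply(c(2, 10), function(lg) {
    fwhm_and_edges(compute_van_hove(tr, lg, axis = "y"))$d_peak
  }, numeric(1))
  expect_lt(peaks[1], 0)
  expect_lt(peaks[2], peaks[1])  # magnitude grows with lag, toward -y
})

test_that("static particles render to identical frames with zero structure function", {
  df <- data.frame(particle = rep(1:3, each = 20), frame = rep(0:19, 3),
                   x = rep(c(5, 12, 20), each = 20),
                   y = rep(c(6, 15, 22), each = 20))
  tr <- track_table(df, frame_interval = 0.1, pixel_size = 0.2)
  cfg <- sim_config(3, 20, frame_interval = 0.1, pixel_size = 0.2,
                    field_of_view = c(128, 128), seed = 1)
  st <- render_image_stack(tr, image_render_spec(noise_model = "none"), cfg)
  expect_true(all(st$frames[, , 1] == st$frames[, , 5]))
  m <- image_structure_function(st, max_lag = 0.5, n_lags = 5)
  expect_true(all(m$D == 0))
  expect_error(render_image_stack(tr[0, ], image_render_spec(), cfg), "empty")
})

test_that("track CSV round trip calibrates pixels to micrometers and filters short tracks", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "tracks.csv")
  df <- data.frame(frame = c(0:9, 0:2), particle = c(rep(1, 10), rep(2, 3)),
                   x = c(rep(100, 10), rep(50, 3)),
                   y = c(rep(40, 10), rep(20, 3)))
  utils::write.csv(df, p, row.names = FALSE)
  expect_message(
    tr <- read_tracks(p, pixel_size = 0.194, frame_interval = 0.1,
                      min_track_length = 5),
    "excluded 1 track")
  expect_equal(attr(tr, "n_excluded"), 1)
  expect_equal(unique(tr$x), 19.4)
  expect_equal(length(unique(tr$particle)), 1)

  # full write/read cycle preserves calibrated positions
  tr2 <- gen_fbm_tracks(sim_config(3, 15, seed = 2),
                        motion_model("brownian", generalized_coefficient = 0.1))
  p2 <- file.path(dir, "t2.csv")
  write_tracks(tr2, p2)
  back <- read_tracks(p2, pixel_size = 0.194, frame_interval = 0.1,
                      min_track_length = 5)
  expect_equal(back$x, tr2$x, tolerance = 1e-8)

  expect_error(read_tracks(file.path(dir, "missing.csv"), 0.2, 0.1), "no such file")
  bad <- file.path(dir, "bad.csv")
  utils::write.csv(df[, c("frame", "x", "y")], bad, row.names = FALSE)
  expect_error(read_tracks(bad, 0.2, 0.1), "missing columns")
})

test_that("image stacks round-trip through 16-bit TIFF with metadata sidecar", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(4, 6, frame_interval = 0.2, pixel_size = 0.3,
                    field_of_view = c(32, 32), seed = 3)
  tr <- gen_fbm_tracks(cfg, motion_model("brownian", generalized_coefficient = 0.05))
  st <- render_image_stack(tr, image_render_spec(noise_model = "gaussian",
                                                 noise_scale = 5), cfg)
  p <- file.path(dir, "stack.tif")
  write_image_stack(st, p)
  back <- read_image_stack(p)
  expect_equal(back$pixel_size, 0.3)
  expect_equal(back$frame_interval, 0.2)
  expect_equal(back$frames, st$frames)

  gt <- file.path(dir, "gt.txt")
  write_ground_truth(tr, gt)
  kv <- sptddm:::read_keyvalue(gt)
  expect_equal(as.numeric(kv$K), 0.05)
})
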