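# Shared synthetic fixtures, generated once per test session and memoized:
# the heavy ensembles are used by several files (unit, property and
# acceptance tests) and regenerating them per block would dominate runtime.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 200 Brownian tracks x 2000 frames, D = 0.1 um^2/s (K = 2D = 0.2)
brownian_tracks <- function() fixture("brownian_tracks", {
  gen_fbm_tracks(sim_config(200, 2000, seed = 42),
                 motion_model("brownian", generalized_coefficient = 0.2))
})

fbm_tracks <- function(alpha) {
  name <- paste0("fbm_", alpha * 100)
  fixture(name, {
    gen_fbm_tracks(sim_config(200, 2000, seed = 43L + as.integer(alpha * 100)),
                   motion_model("fbm", alpha = alpha,
                                generalized_coefficient = 0.05))
  })
}

# multimode: alpha1 = 0.35, K = 0.02, analytic crossover at 5 s
multimode_tracks <- function() fixture("multimode_tracks", {
  gen_multimode_tracks(sim_config(200, 1500, seed = 45),
                       motion_model("multimode", alpha = 0.35,
                                    generalized_coefficient = 0.02,
                                    crossover_time = 5))
})

# analytic multimode MSD: K t^a + 0.5 v^2 t^2 (the generator's closed form)
multimode_analytic_msd <- function(tracks, lag) {
  gt <- attr(tracks, "ground_truth")
  gt$K * lag^gt$alpha1 + 0.5 * gt$speed^2 * lag^2
}

# rendered Brownian stack at the reference imaging geometry:
# 150 particles, 800 frames, 256x256 px, 0.2 um/px, 10 fps, D = 0.2
brownian_stack_bundle <- function() fixture("brownian_stack_bundle", {
  cfg <- sim_config(150, 800, frame_interval = 0.1, pixel_size = 0.2,
                    field_of_view = c(256, 256), seed = 101)
  tracks <- gen_fbm_tracks(cfg, motion_model("brownian",
                                             generalized_coefficient = 0.4))
  stack <- render_image_stack(tracks, image_render_spec(), cfg)
  m <- image_structure_function(stack, n_lags = 40)
  fits <- suppressMessages(fit_ddm_matrix(m))
  list(cfg = cfg, tracks = tracks, stack = stack, matrix = m, fits = fits,
       D = 0.2)
})

# rendered ballistic stack, same geometry, speeds uniform in 0.05-0.15 um/s
ballistic_stack_bundle <- function() fixture("ballistic_stack_bundle", {
  cfg <- sim_config(150, 800, frame_interval = 0.1, pixel_size = 0.2,
                    field_of_view = c(256, 256), seed = 102)
  tracks <- gen_ballistic_tracks(cfg, motion_model("ballistic",
                                                   velocity_min = 0.05,
                                                   velocity_max = 0.15,
                                                   generalized_coefficient = 0))
  stack <- render_image_stack(tracks, image_render_spec(), cfg)
  m <- image_structure_function(stack, n_lags = 40)
  fits <- suppressMessages(fit_ddm_matrix(m))
  list(cfg = cfg, tracks = tracks, stack = stack, matrix = m, fits = fits)
})

# small rendered Brownian stack for ISF-shape checks (cheap)
small_brownian_stack <- function() fixture("small_brownian_stack", {
  cfg <- sim_config(100, 400, frame_interval = 0.1, pixel_size = 0.2,
                    field_of_view = c(128, 128), seed = 11)
  tracks <- gen_fbm_tracks(cfg, motion_model("brownian",
                                             generalized_coefficient = 0.4))
  stack <- render_image_stack(tracks, image_render_spec(), cfg)
  m <- image_structure_function(stack, n_lags = 30)
  fits <- suppressMessages(fit_ddm_matrix(m))
  list(cfg = cfg, tracks = tracks, stack = stack, matrix = m, fits = fits,
       D = 0.2)
})

# overall power-law exponent of an MSD curve on the log-subsampled grid
msd_exponent <- function(curve) {
  idx <- sptddm:::log_subsample(curve$lag)
  fit_power_law(curve$lag[idx], curve$msd[idx])
}
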