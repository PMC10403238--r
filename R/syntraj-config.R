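#' Simulation configuration for synthetic trajectories and image stacks
#'
#' Acquisition-style settings shared by all generators. Defaults emulate a
#' light-sheet SPT experiment: 10 frames per second and a pixel scale of
#' 0.194 um/px.
#'
#' @param n_particles number of particles (>= 1)
#' @param n_frames number of frames (>= 2)
#' @param frame_interval time between frames, seconds
#' @param pixel_size pixel scale, micrometers per pixel
#' @param field_of_view integer vector `c(width_px, height_px)`
#' @param seed integer seed; identical configurations give bit-identical
#'   output
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_particles, n_frames, frame_interval = 0.1,
                       pixel_size = 0.194, field_of_view = c(256L, 256L),
                       seed = 1L) {
  stop_if_not(n_particles >= 1, "n_particles must be >= 1")
  stop_if_not(n_frames >= 2, "n_frames must be >= 2")
  stop_if_not(frame_interval > 0, "frame_interval must be > 0")
  stop_if_not(pixel_size > 0, "pixel_size must be > 0")
  stop_if_not(length(field_of_view) == 2 && all(field_of_view >= 8),
              "field_of_view must be c(width_px, height_px), each >= 8")
  structure(list(
    n_particles = as.integer(n_particles),
    n_frames = as.integer(n_frames),
    frame_interval = frame_interval,
    pixel_size = pixel_size,
    field_of_view = as.integer(field_of_view),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Motion model for synthetic trajectories
#'
#' Bundles the transport parameters consumed by the trajectory generators.
#' Only the fields relevant to `kind` are used.
#'
#' Conventions: `generalized_coefficient` K is the prefactor of the
#' half-sum MSD convention, MSD(dt) = 0.5*(<dx^2> + <dy^2>) = K * dt^alpha,
#' so for normal diffusion with diffusivity D (per-axis <dx^2> = 2 D dt),
#' K = 2 D. Directions are drawn around `drift_direction` (radians,
#' default -pi/2, i.e. the -y axis) with circular spread
#' `drift_direction_sd`; `Inf` (the default) means isotropic.
#'
#' @param kind one of `"brownian"`, `"fbm"`, `"ballistic"`,
#'   `"caged_hopping"`, `"multimode"`
#' @param alpha target MSD exponent, in (0, 2]; `"brownian"` forces 1
#' @param generalized_coefficient K, um^2 / s^alpha (see Conventions)
#' @param velocity_mean,velocity_sd per-particle speed distribution
#'   (truncated normal at 0), um/s
#' @param velocity_min,velocity_max optional; when both given, speeds are
#'   drawn uniformly in `[velocity_min, velocity_max]` instead
#' @param drift_direction mean direction of motion, radians
#' @param drift_direction_sd circular (wrapped-normal) spread of the
#'   per-particle direction, radians; `Inf` = isotropic
#' @param cage_size stationary standard deviation of the confined
#'   (Ornstein-Uhlenbeck) component, um
#' @param hop_rate Poisson rate of cage-center hops, 1/s
#' @param hop_length mean (exponential) hop length, um
#' @param crossover_time for `"multimode"`: lag time at which the analytic
#'   ballistic MSD term equals the subdiffusive term, seconds
#' @return object of class `motion_model`
#' @export
motion_model <- function(kind = c("brownian", "fbm", "ballistic",
                                  "caged_hopping", "multimode"),
                         alpha = 1, generalized_coefficient = 0.1,
                         velocity_mean = 0, velocity_sd = 0,
                         velocity_min = NULL, velocity_max = NULL,
                         drift_direction = -pi / 2, drift_direction_sd = Inf,
                         cage_size = 0.1, hop_rate = 0, hop_length = 0,
                         crossover_time = NULL) {
  kind <- match.arg(kind)
  if (kind == "brownian") alpha <- 1
  stop_if_not(alpha > 0 && alpha <= 2, "alpha must be in (0, 2]")
  stop_if_not(generalized_coefficient >= 0,
              "generalized_coefficient must be >= 0")
  stop_if_not(velocity_sd >= 0, "velocity_sd must be >= 0")
  stop_if_not(hop_rate >= 0, "hop_rate must be >= 0")
  stop_if_not(hop_length >= 0, "hop_length must be >= 0")
  stop_if_not(cage_size >= 0, "cage_size must be >= 0")
  if (!is.null(velocity_min) || !is.null(velocity_max)) {
    stop_if_not(!is.null(velocity_min) && !is.null(velocity_max) &&
                  velocity_min >= 0 && velocity_max >= velocity_min,
                "velocity_min/velocity_max must satisfy 0 <= min <= max")
  }
  structure(list(
    kind = kind, alpha = alpha,
    generalized_coefficient = generalized_coefficient,
    velocity_mean = velocity_mean, velocity_sd = velocity_sd,
    velocity_min = velocity_min, velocity_max = velocity_max,
    drift_direction = drift_direction,
    drift_direction_sd = drift_direction_sd,
    cage_size = cage_size, hop_rate = hop_rate, hop_length = hop_length,
    crossover_time = crossover_time
  ), class = "motion_model")
}

#' Rendering specification for synthetic image stacks
#'
#' Each particle is rendered as a symmetric Gaussian of width `psf_sigma`
#' (an effective point-spread function for a ~1 um emitter) on a uniform
#' background; noise defaults to Poisson counting statistics on
#' signal + background, as for an sCMOS camera.
#'
#' @param psf_sigma Gaussian width, um
#' @param peak_intensity peak counts added per particle
#' @param background_level uniform background counts
#' @param noise_model `"none"`, `"gaussian"` or `"poisson"`
#' @param noise_scale sd of additive Gaussian noise (counts); ignored
#'   otherwise
#' @return object of class `image_render_spec`
#' @export
image_render_spec <- function(psf_sigma = 0.5, peak_intensity = 3000,
                              background_level = 100,
                              noise_model = c("poisson", "gaussian", "none"),
                              noise_scale = 0) {
  noise_model <- match.arg(noise_model)
  stop_if_not(psf_sigma > 0, "psf_sigma must be > 0")
  stop_if_not(peak_intensity >= 0 && background_level >= 0,
              "intensities must be >= 0")
  stop_if_not(noise_scale >= 0, "noise_scale must be >= 0")
  structure(list(psf_sigma = psf_sigma, peak_intensity = peak_intensity,
                 background_level = background_level,
                 noise_model = noise_model, noise_scale = noise_scale),
            class = "image_render_spec")
}
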