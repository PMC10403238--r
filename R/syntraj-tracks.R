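## Synthetic trajectory generators.
##
## All generators seed the RNG from cfg$seed, so identical configurations
## give bit-identical output, and attach the known transport parameters as
## the `ground_truth` attribute for downstream validation.

## Exact fractional Gaussian noise by circulant embedding (Davies-Harte).
## Returns n unit-variance increments whose covariance is the fGn
## autocovariance 0.5*(|k+1|^a - 2|k|^a + |k-1|^a); eigenvalues of the
## embedding circulant are non-negative for alpha in (0, 2).
fgn_acf <- function(k, alpha) {
  0.5 * (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha)
}

fgn_sim <- function(n, alpha) {
  if (n == 1) return(stats::rnorm(1))
  m <- 2L * n
  g <- fgn_acf(0:n, alpha)
  lam <- Re(stats::fft(c(g, rev(g[2:n]))))
  stop_if_not(all(lam > -1e-8 * max(lam)),
              "circulant embedding failed (negative eigenvalue)")
  lam[lam < 0] <- 0
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  z[1] <- complex(real = Re(z[1]) * sqrt(2))
  z[n + 1] <- complex(real = Re(z[n + 1]) * sqrt(2))
  z[(n + 2):m] <- Conj(z[seq(n, 2, by = -1)])
  Re(stats::fft(sqrt(lam / (2 * m)) * z))[1:n]
}

## per-particle direction draws: wrapped normal around the drift axis,
## isotropic when the spread is infinite
draw_directions <- function(n, model) {
  if (!is.finite(model$drift_direction_sd)) {
    stats::runif(n, 0, 2 * pi)
  } else {
    model$drift_direction + stats::rnorm(n, 0, model$drift_direction_sd)
  }
}

## per-particle speed draws: uniform when bounds given, else normal
## truncated at zero (exact at sd = 0)
draw_speeds <- function(n, model) {
  if (!is.null(model$velocity_min)) {
    return(stats::runif(n, model$velocity_min, model$velocity_max))
  }
  if (model$velocity_sd == 0) return(rep(model$velocity_mean, n))
  v <- stats::rnorm(n, model$velocity_mean, model$velocity_sd)
  bad <- v < 0
  while (any(bad)) {
    v[bad] <- stats::rnorm(sum(bad), model$velocity_mean, model$velocity_sd)
    bad <- v < 0
  }
  v
}

initial_positions <- function(cfg) {
  w <- cfg$field_of_view[1] * cfg$pixel_size
  h <- cfg$field_of_view[2] * cfg$pixel_size
  list(x = stats::runif(cfg$n_particles, 0.1 * w, 0.9 * w),
       y = stats::runif(cfg$n_particles, 0.1 * h, 0.9 * h))
}

## X, Y: n_frames x n_particles position matrices in micrometers
assemble_tracks <- function(cfg, X, Y, ground_truth, source) {
  nf <- cfg$n_frames; np <- cfg$n_particles
  track_table(
    data.frame(particle = rep(seq_len(np), each = nf),
               frame = rep.int(0:(nf - 1), np),
               x = as.vector(X), y = as.vector(Y)),
    frame_interval = cfg$frame_interval, pixel_size = cfg$pixel_size,
    source = source, ground_truth = ground_truth)
}

## zero-mean fBm displacement matrices with per-axis displacement variance
## K * (k*dt)^alpha (so the half-sum MSD equals K * dt^alpha)
fbm_component <- function(cfg, model) {
  nf <- cfg$n_frames; np <- cfg$n_particles
  sd_step <- sqrt(model$generalized_coefficient) * cfg$frame_interval^(model$alpha / 2)
  axis_paths <- function() {
    if (sd_step == 0) return(matrix(0, nf, np))
    inc <- vapply(seq_len(np), function(i) fgn_sim(nf - 1L, model$alpha) * sd_step,
                  numeric(nf - 1L))
    rbind(0, apply(matrix(inc, nf - 1L, np), 2, cumsum))
  }
  list(x = axis_paths(), y = axis_paths())
}

#' Generate fractional Brownian motion trajectories
#'
#' Per-axis increments are stationary Gaussian with the exact fractional
#' Gaussian noise covariance (circulant-embedding synthesis), so the
#' ensemble half-sum MSD equals `generalized_coefficient * dt^alpha` with
#' no discretization bias. Axes are independent; `"brownian"` is the
#' `alpha = 1` special case.
#'
#' @param cfg a [sim_config()]
#' @param model a [motion_model()] with `kind` `"brownian"` or `"fbm"` and
#'   `alpha` in (0, 2)
#' @return a [track_table()] with `ground_truth` attribute
#'   `list(kind, alpha, K)`
#' @export
gen_fbm_tracks <- function(cfg, model) {
  stop_if_not(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  stop_if_not(model$kind %in% c("brownian", "fbm"),
              "model$kind must be 'brownian' or 'fbm'")
  stop_if_not(model$alpha > 0 && model$alpha < 2,
              "alpha must be in (0, 2) for fBm generation")
  set.seed(cfg$seed)
  p0 <- initial_positions(cfg)
  comp <- fbm_component(cfg, model)
  X <- sweep(comp$x, 2, p0$x, `+`)
  Y <- sweep(comp$y, 2, p0$y, `+`)
  assemble_tracks(cfg, X, Y,
                  ground_truth = list(kind = model$kind, alpha = model$alpha,
                                      K = model$generalized_coefficient),
                  source = "syn:fbm")
}

#' Generate ballistic trajectories with quenched per-particle velocities
#'
#' Each particle receives a constant velocity: magnitude from a truncated
#' normal (or uniform bounds, see [motion_model()]), direction from a
#' wrapped-normal spread around the drift axis (isotropic by default).
#' Optional Brownian jitter with MSD prefactor `generalized_coefficient`
#' is superimposed. A single particle at speed v has half-sum MSD
#' `0.5 * v^2 * dt^2`.
#'
#' @inheritParams gen_fbm_tracks
#' @return a [track_table()]; `ground_truth` records speeds and the
#'   mean-square speed
#' @export
gen_ballistic_tracks <- function(cfg, model) {
  stop_if_not(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  set.seed(cfg$seed)
  p0 <- initial_positions(cfg)
  v <- draw_speeds(cfg$n_particles, model)
  th <- draw_directions(cfg$n_particles, model)
  tgrid <- (0:(cfg$n_frames - 1)) * cfg$frame_interval
  X <- outer(tgrid, v * cos(th)) ; X <- sweep(X, 2, p0$x, `+`)
  Y <- outer(tgrid, v * sin(th)) ; Y <- sweep(Y, 2, p0$y, `+`)
  if (model$generalized_coefficient > 0) {
    jit <- fbm_component(cfg, motion_model("brownian",
             generalized_coefficient = model$generalized_coefficient))
    X <- X + jit$x; Y <- Y + jit$y
  }
  assemble_tracks(cfg, X, Y,
                  ground_truth = list(kind = "ballistic", speeds = v,
                                      mean_sq_speed = mean(v^2),
                                      K_jitter = model$generalized_coefficient),
                  source = "syn:ballistic")
}

#' Generate caged trajectories with Poisson-timed hopping
#'
#' Per-axis Ornstein-Uhlenbeck confinement of stationary standard
#' deviation `cage_size` about a cage center; the center jumps at Poisson
#' times (`hop_rate`) by exponential lengths (mean `hop_length`) in
#' uniform random directions. The short-time MSD prefactor inside the cage
#' is `generalized_coefficient`, fixing the relaxation time
#' `tau_r = 2 * cage_size^2 / K`; the hop-free MSD plateaus at
#' `2 * cage_size^2` (half-sum convention).
#'
#' @inheritParams gen_fbm_tracks
#' @return a [track_table()]
#' @export
gen_caged_hopping_tracks <- function(cfg, model) {
  stop_if_not(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  stop_if_not(model$cage_size > 0, "cage_size must be > 0")
  stop_if_not(model$generalized_coefficient > 0,
              "generalized_coefficient (short-time MSD prefactor) must be > 0")
  set.seed(cfg$seed)
  nf <- cfg$n_frames; np <- cfg$n_particles; dt <- cfg$frame_interval
  sig <- model$cage_size
  tau_r <- 2 * sig^2 / model$generalized_coefficient
  rho <- exp(-dt / tau_r)
  innov_sd <- sig * sqrt(1 - rho^2)
  p0 <- initial_positions(cfg)
  total_t <- (nf - 1) * dt
  X <- matrix(0, nf, np); Y <- matrix(0, nf, np)
  for (i in seq_len(np)) {
    cx <- rep(p0$x[i], nf); cy <- rep(p0$y[i], nf)
    if (model$hop_rate > 0) {
      n_hops <- stats::rpois(1, model$hop_rate * total_t)
      if (n_hops > 0) {
        at <- sort(stats::runif(n_hops, 0, total_t))
        len <- stats::rexp(n_hops, rate = 1 / model$hop_length)
        dir <- stats::runif(n_hops, 0, 2 * pi)
        for (h in seq_len(n_hops)) {
          k0 <- min(nf, floor(at[h] / dt) + 2L)  # first frame after the hop
          cx[k0:nf] <- cx[k0:nf] + len[h] * cos(dir[h])
          cy[k0:nf] <- cy[k0:nf] + len[h] * sin(dir[h])
        }
      }
    }
    ou <- function() {
      u <- numeric(nf)
      u[1] <- stats::rnorm(1, 0, sig)
      eps <- stats::rnorm(nf - 1, 0, innov_sd)
      for (k in 2:nf) u[k] <- rho * u[k - 1] + eps[k - 1]
      u
    }
    X[, i] <- cx + ou(); Y[, i] <- cy + ou()
  }
  assemble_tracks(cfg, X, Y,
                  ground_truth = list(kind = "caged_hopping",
                                      cage_size = sig, tau_r = tau_r,
                                      hop_rate = model$hop_rate,
                                      hop_length = model$hop_length,
                                      plateau = 2 * sig^2),
                  source = "syn:caged")
}

#' Generate multi-mode trajectories: subdiffusion crossing over to advection
#'
#' Sum of an fBm component (exponent `alpha`, prefactor
#' `generalized_coefficient` K) and a constant-velocity ballistic
#' component whose common speed is set so that the analytic ballistic MSD
#' term `0.5 * v^2 * dt^2` equals the subdiffusive term `K * dt^alpha`
#' exactly at `crossover_time`. Directions follow the drift model. With
#' `crossover_time = NULL` the ballistic amplitude is zero (pure
#' subdiffusion).
#'
#' The analytic local minimum of MSD/dt -- what the long-lag regime
#' detector estimates -- sits at
#' `(1 - alpha)^(1/(2 - alpha)) * crossover_time` and is recorded in the
#' ground truth as `expected_t2`.
#'
#' @inheritParams gen_fbm_tracks
#' @return a [track_table()] with ground-truth exponents
#'   (`alpha1 = alpha`, `alpha2 = 2`), the speed, and `expected_t2`
#' @export
gen_multimode_tracks <- function(cfg, model) {
  stop_if_not(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  stop_if_not(model$kind == "multimode", "model$kind must be 'multimode'")
  stop_if_not(model$alpha > 0 && model$alpha < 1,
              "multimode needs a subdiffusive short-time alpha in (0, 1)")
  set.seed(cfg$seed)
  tc <- model$crossover_time
  K <- model$generalized_coefficient
  if (!is.null(tc)) {
    max_lag <- (cfg$n_frames - 1) * cfg$frame_interval
    if (tc < cfg$frame_interval || tc > max_lag) {
      warning(sprintf("crossover_time %g s outside simulated lag range [%g, %g] s",
                      tc, cfg$frame_interval, max_lag))
    }
    v <- sqrt(2 * K) * tc^((model$alpha - 2) / 2)
  } else {
    v <- 0
  }
  p0 <- initial_positions(cfg)
  th <- draw_directions(cfg$n_particles, model)
  sub <- fbm_component(cfg, model)
  tgrid <- (0:(cfg$n_frames - 1)) * cfg$frame_interval
  X <- sweep(sub$x + outer(tgrid, v * cos(th)), 2, p0$x, `+`)
  Y <- sweep(sub$y + outer(tgrid, v * sin(th)), 2, p0$y, `+`)
  gt <- list(kind = "multimode", alpha1 = model$alpha, alpha2 = 2,
             K = K, speed = v, crossover_time = tc,
             expected_t2 = if (is.null(tc)) NULL else
               (1 - model$alpha)^(1 / (2 - model$alpha)) * tc)
  assemble_tracks(cfg, X, Y, ground_truth = gt, source = "syn:multimode")
}
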