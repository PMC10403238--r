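#' Detectability timescale of advective motion
#'
#' The lag time beyond which network-driven advection moves a particle
#' farther than the minimum resolvable displacement:
#' `dt_a = resolution / speed`. With a 100 nm localization scale and
#' network speeds of roughly 2-85 nm/s this spans about 1-50 s, the
#' window in which crossovers out of subdiffusion become visible.
#'
#' @param resolution minimum resolvable displacement, nm
#' @param speed advection (network) speed, nm/s
#' @return timescale in seconds
#' @export
compute_detectability_timescale <- function(resolution = 100, speed) {
  stop_if_not(all(resolution > 0), "resolution must be > 0")
  stop_if_not(all(speed > 0), "speed must be > 0")
  resolution / speed
}

#' Condition metadata
#'
#' Composition labels carried through to the summary table: the molar
#' actin fraction of an actin-microtubule composite, the myosin:actin
#' ratio, and the total protein molarity.
#'
#' @param label condition name
#' @param phi_A molar actin fraction in [0, 1]
#' @param myosin_ratio myosin:actin molar ratio
#' @param total_molar combined molarity, uM
#' @param notes free text
#' @return object of class `condition_meta`
#' @export
condition_meta <- function(label, phi_A = NA_real_, myosin_ratio = NA_real_,
                           total_molar = NA_real_, notes = "") {
  if (!is.na(phi_A)) {
    stop_if_not(phi_A >= 0 && phi_A <= 1, "phi_A must be in [0, 1]")
  }
  structure(list(label = label, phi_A = phi_A, myosin_ratio = myosin_ratio,
                 total_molar = total_molar, notes = notes),
            class = "condition_meta")
}

fit_field <- function(f, what = c("exponent", "stderr")) {
  what <- match.arg(what)
  if (is.null(f)) NA_real_ else f[[what]]
}

## one condition -> one summary row; failing stages yield NA, never abort
analyze_condition <- function(cond, params) {
  label <- cond$label %||% "condition"
  phi_A <- cond$phi_A %||% NA_real_
  notes <- character(0)
  row <- data.frame(label = label, phi_A = phi_A,
                    t1 = NA_real_, t2 = NA_real_,
                    alpha_msd_1 = NA_real_, alpha_msd_1_se = NA_real_,
                    alpha_msd_12 = NA_real_, alpha_msd_12_se = NA_real_,
                    alpha_msd_2 = NA_real_, alpha_msd_2_se = NA_real_,
                    alpha_vh_1 = NA_real_, alpha_vh_1_se = NA_real_,
                    alpha_vh_2 = NA_real_, alpha_vh_2_se = NA_real_,
                    beta = NA_real_, beta_se = NA_real_,
                    alpha_ddm = NA_real_,
                    gamma_mean = NA_real_, gamma_se = NA_real_,
                    stringsAsFactors = FALSE)
  details <- list()

  tracks <- cond$tracks
  if (is.character(tracks)) {
    tracks <- read_tracks(tracks, pixel_size = cond$pixel_size,
                          frame_interval = cond$frame_interval,
                          min_track_length = params$min_track_length %||% 10L)
  }
  if (!is.null(tracks)) {
    spt <- tryCatch({
      curve <- compute_msd(tracks, max_lag = params$msd$max_lag %||% 40,
                           min_pairs = params$msd$min_pairs %||% 50L)
      t1 <- detect_t1(curve, r2_threshold = params$msd$r2_threshold %||% 0.99)
      t2 <- detect_t2(curve, smooth_window = params$msd$smooth_window %||% 5L,
                      after = t1)
      reg <- fit_regimes(curve, t1 = t1, t2 = t2,
                         fit_cap = params$msd$fit_cap %||% NULL)
      list(curve = curve, regimes = reg)
    }, error = function(e) {
      notes <<- c(notes, paste("msd:", conditionMessage(e))); NULL
    })
    if (!is.null(spt)) {
      reg <- spt$regimes
      row$t1 <- reg$t1; row$t2 <- reg$t2
      row$alpha_msd_1 <- fit_field(reg$alpha1); row$alpha_msd_1_se <- fit_field(reg$alpha1, "stderr")
      row$alpha_msd_12 <- fit_field(reg$alpha12); row$alpha_msd_12_se <- fit_field(reg$alpha12, "stderr")
      row$alpha_msd_2 <- fit_field(reg$alpha2); row$alpha_msd_2_se <- fit_field(reg$alpha2, "stderr")
      details$msd <- spt
    }
    vh <- tryCatch({
      lags <- params$vanhove$lags %||% c(0.1, 0.2, 0.3, 0.5, 1, 2, 3, 5, 10, 15)
      dur <- diff(range(tracks$frame)) * attr(tracks, "frame_interval")
      lags <- lags[lags <= dur / 2]
      mt <- van_hove_metrics(tracks, lags = lags,
                             bin_width = params$vanhove$bin_width %||% 0.05)
      sc <- fit_fwhm_scaling(mt$lag_s, mt$fwhm_um,
                             split_at = params$vanhove$split_at %||% 1.0)
      list(metrics = mt, scaling = sc)
    }, error = function(e) {
      notes <<- c(notes, paste("vanhove:", conditionMessage(e))); NULL
    })
    if (!is.null(vh)) {
      row$alpha_vh_1 <- fit_field(vh$scaling$alpha1); row$alpha_vh_1_se <- fit_field(vh$scaling$alpha1, "stderr")
      row$alpha_vh_2 <- fit_field(vh$scaling$alpha2); row$alpha_vh_2_se <- fit_field(vh$scaling$alpha2, "stderr")
      details$vanhove <- vh
    }
  }

  stack <- cond$stack
  if (is.character(stack)) stack <- read_image_stack(stack)
  if (!is.null(stack)) {
    ddm <- tryCatch({
      m <- image_structure_function(stack,
                                    max_lag = params$ddm$max_lag %||% NULL,
                                    n_lags = params$ddm$n_lags %||% 40L)
      fits <- fit_ddm_matrix(m, lag_cap = params$ddm$lag_cap %||% 100,
                             gamma_bounds = params$ddm$gamma_bounds %||% c(0.2, 3))
      qr <- params$ddm$q_fit %||% c(1, 4)
      sc <- fit_tau_powerlaw(fits, q_range = qr)
      gm <- average_gamma(fits, q_range = qr)
      list(matrix = m, fits = fits, scaling = sc, gamma = gm)
    }, error = function(e) {
      notes <<- c(notes, paste("ddm:", conditionMessage(e))); NULL
    })
    if (!is.null(ddm)) {
      row$beta <- ddm$scaling$beta; row$beta_se <- ddm$scaling$beta_se
      row$alpha_ddm <- ddm$scaling$alpha_ddm
      row$gamma_mean <- ddm$gamma$mean; row$gamma_se <- ddm$gamma$stderr
      details$ddm <- ddm
    }
  }
  if (is.null(tracks) && is.null(stack)) {
    notes <- c(notes, "no tracks and no stack supplied")
  }
  list(row = row, details = details, notes = notes)
}

#' Run the full cross-method transport analysis
#'
#' Orchestrates the real-space (MSD regimes, van Hove widths) and
#' reciprocal-space (DDM scaling) pipelines over one or more conditions
#' and joins the results into a single summary table of transport
#' metrics. Conditions with only tracks or only an image stack produce
#' partial rows: missing metrics are `NA`, never silently dropped; a
#' failing stage is recorded in the `notes` attribute and the remaining
#' stages still run.
#'
#' @param config list with element `conditions`: a list of condition
#'   lists, each holding `label`, optional `phi_A`, and `tracks` (a
#'   [track_table()] or CSV path plus `pixel_size`/`frame_interval`)
#'   and/or `stack` (an [image_stack()] or TIFF path with metadata
#'   sidecar). Optional element `params` with sub-lists `msd`
#'   (`max_lag`, `min_pairs`, `r2_threshold`, `smooth_window`,
#'   `fit_cap`), `vanhove` (`lags`, `bin_width`, `split_at`) and `ddm`
#'   (`max_lag`, `n_lags`, `lag_cap`, `q_fit`, `gamma_bounds`).
#' @return object of class `transport_summary`: data.frame with one row
#'   per condition (alpha estimates from the three methods with standard
#'   errors, regime boundaries `t1`/`t2`, `beta`, `gamma_mean`);
#'   attributes `details` (per-condition intermediate objects) and
#'   `notes`
#' @export
run_full_analysis <- function(config) {
  stop_if_not(is.list(config) && !is.null(config$conditions) &&
                length(config$conditions) > 0,
              "config$conditions must be a non-empty list")
  params <- config$params %||% list()
  res <- lapply(config$conditions, analyze_condition, params = params)
  out <- do.call(rbind, lapply(res, `[[`, "row"))
  rownames(out) <- NULL
  structure(out, class = c("transport_summary", "data.frame"),
            details = lapply(res, `[[`, "details"),
            notes = lapply(res, `[[`, "notes"))
}

#' @export
print.transport_summary <- function(x, ...) {
  cat("transport summary (NA = metric not available for that condition):\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, 3))
  print(df)
  notes <- attr(x, "notes")
  has <- vapply(notes, length, 1L) > 0
  if (any(has)) {
    cat("notes:\n")
    for (i in which(has)) {
      cat(sprintf("  [%s] %s\n", df$label[i], paste(notes[[i]], collapse = "; ")))
    }
  }
  invisible(x)
}

#' Write a transport summary as CSV
#'
#' @param summary a [run_full_analysis()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
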