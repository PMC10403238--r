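#' Construct an image stack
#'
#' @param frames 3-D numeric array of intensities, dimensions
#'   `c(rows, cols, time)`
#' @param pixel_size um/px
#' @param frame_interval seconds between frames
#' @return object of class `image_stack`
#' @export
image_stack <- function(frames, pixel_size, frame_interval) {
  stop_if_not(length(dim(frames)) == 3 && dim(frames)[3] >= 2,
              "frames must be a rows x cols x time array with >= 2 frames")
  stop_if_not(all(is.finite(frames)), "intensities must be finite")
  stop_if_not(pixel_size > 0 && frame_interval > 0,
              "pixel_size and frame_interval must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %d x %d px (%.3g um/px, %g s/frame)\n",
              d[3], d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Render trajectories into a synthetic microscopy image stack
#'
#' Each frame is `background_level` plus, for every particle inside the
#' field of view at that frame, a symmetric Gaussian of width `psf_sigma`
#' and height `peak_intensity` centered on the particle position, plus
#' noise per `noise_model`. Pixel (0,0) is the top-left corner; positions
#' in micrometers map to pixels through `cfg$pixel_size`. Particles
#' outside the field of view are simply not rendered (they stay in the
#' track table). Output counts are rounded and clipped to the 16-bit
#' range.
#'
#' The render uses its own RNG stream seeded from `cfg$seed + 1` so that
#' noise does not perturb the trajectory stream.
#'
#' @param tracks a [track_table()] with positions in micrometers
#' @param spec an [image_render_spec()]
#' @param cfg the [sim_config()] providing field of view, pixel size and
#'   seed
#' @return an [image_stack()]
#' @export
render_image_stack <- function(tracks, spec = image_render_spec(), cfg) {
  stop_if_not(inherits(tracks, "track_table"), "tracks must be a track_table")
  stop_if_not(nrow(tracks) > 0, "empty track table")
  stop_if_not(inherits(spec, "image_render_spec"),
              "spec must be an image_render_spec")
  set.seed(cfg$seed + 1L)
  W <- cfg$field_of_view[1]; H <- cfg$field_of_view[2]
  px <- cfg$pixel_size
  sig_px <- spec$psf_sigma / px
  halfw <- max(2L, ceiling(4 * sig_px))
  frames_idx <- sort(unique(tracks$frame))
  nf <- length(frames_idx)
  stop_if_not(nf >= 2, "need >= 2 distinct frames to render")
  out <- array(0, dim = c(H, W, nf))
  by_frame <- split(tracks[, c("x", "y")], tracks$frame)
  for (t in seq_len(nf)) {
    img <- matrix(spec$background_level, H, W)
    pos <- by_frame[[as.character(frames_idx[t])]]
    if (!is.null(pos) && nrow(pos) > 0) {
      cc <- pos$x / px; rr <- pos$y / px   # 0-based pixel coordinates
      for (i in seq_len(nrow(pos))) {
        if (cc[i] < 0 || cc[i] >= W || rr[i] < 0 || rr[i] >= H) next
        c0 <- max(1L, floor(cc[i]) - halfw + 1L)
        c1 <- min(W, floor(cc[i]) + halfw + 1L)
        r0 <- max(1L, floor(rr[i]) - halfw + 1L)
        r1 <- min(H, floor(rr[i]) + halfw + 1L)
        gr <- exp(-((r0:r1) - 1 - rr[i])^2 / (2 * sig_px^2))
        gc <- exp(-((c0:c1) - 1 - cc[i])^2 / (2 * sig_px^2))
        img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
          spec$peak_intensity * (gr %o% gc)
      }
    }
    img <- switch(spec$noise_model,
      none = img,
      gaussian = img + stats::rnorm(length(img), 0, spec$noise_scale),
      poisson = matrix(stats::rpois(length(img), lambda = img), H, W))
    out[, , t] <- pmin(pmax(round(img), 0), 65535)
  }
  image_stack(out, pixel_size = px, frame_interval = attr(tracks, "frame_interval"))
}

#' Write an image stack as multi-page 16-bit TIFF with a metadata sidecar
#'
#' The sidecar (`<path>.meta.txt`) is a plain key-value text file holding
#' `pixel_size_um_per_px` and `frame_interval_s`, so a stack can be
#' re-read without external bookkeeping.
#'
#' @param stack an [image_stack()]
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_image_stack <- function(stack, path) {
  nf <- dim(stack$frames)[3]
  pages <- lapply(seq_len(nf), function(t) stack$frames[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- c(sprintf("pixel_size_um_per_px: %.10g", stack$pixel_size),
            sprintf("frame_interval_s: %.10g", stack$frame_interval))
  writeLines(meta, paste0(path, ".meta.txt"))
  invisible(path)
}

#' Read a multi-page TIFF image stack
#'
#' @param path TIFF path; metadata is taken from `<path>.meta.txt` when
#'   present, else from the `pixel_size`/`frame_interval` arguments
#' @param pixel_size,frame_interval used when no sidecar exists
#' @return an [image_stack()]
#' @export
read_image_stack <- function(path, pixel_size = NULL, frame_interval = NULL) {
  stop_if_not(file.exists(path), paste("no such file:", path))
  meta_path <- paste0(path, ".meta.txt")
  if (file.exists(meta_path)) {
    kv <- read_keyvalue(meta_path)
    pixel_size <- as.numeric(kv[["pixel_size_um_per_px"]])
    frame_interval <- as.numeric(kv[["frame_interval_s"]])
  }
  stop_if_not(!is.null(pixel_size) && !is.null(frame_interval),
              "pixel_size and frame_interval required (no metadata sidecar)")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]]
  image_stack(frames, pixel_size = pixel_size, frame_interval = frame_interval)
}

## plain "key: value" text files (metadata and ground-truth sidecars)
read_keyvalue <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  parts <- regmatches(ln, regexpr(":", ln), invert = TRUE)
  stats::setNames(lapply(parts, function(p) trimws(p[2])),
                  vapply(parts, function(p) trimws(p[1]), ""))
}

#' Write a ground-truth sidecar for a synthetic track table
#'
#' Records the generator's known parameters as `key: value` text for test
#' harnesses and provenance.
#'
#' @param tracks a [track_table()] carrying a `ground_truth` attribute
#' @param path output text path
#' @return `path`, invisibly
#' @export
write_ground_truth <- function(tracks, path) {
  gt <- attr(tracks, "ground_truth")
  stop_if_not(!is.null(gt), "track table has no ground_truth attribute")
  flat <- vapply(gt, function(v) paste(format(v, digits = 10), collapse = ","), "")
  writeLines(paste0(names(flat), ": ", flat), path)
  invisible(path)
}
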