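#' Construct a calibrated track table
#'
#' The common currency of the real-space analysis: per-particle position
#' time series in micrometers, with the frame interval attached.
#'
#' @param df data.frame with columns `particle`, `frame` (0-based integer),
#'   `x`, `y` (micrometers)
#' @param frame_interval seconds between consecutive frames
#' @param pixel_size pixel scale the positions were calibrated with
#'   (um/px), or `NA` if positions were native micrometers
#' @param source free-text label
#' @param ground_truth optional list of known simulation parameters,
#'   carried along for validation harnesses
#' @return object of class `track_table` (a data.frame)
#' @export
track_table <- function(df, frame_interval, pixel_size = NA_real_,
                        source = "", ground_truth = NULL) {
  need <- c("particle", "frame", "x", "y")
  stop_if_not(all(need %in% names(df)),
              paste("track table needs columns:", paste(need, collapse = ", ")))
  stop_if_not(frame_interval > 0, "frame_interval must be > 0")
  stop_if_not(all(is.finite(df$x)) && all(is.finite(df$y)),
              "positions must be finite")
  df <- df[order(df$particle, df$frame), need, drop = FALSE]
  dup <- stats::ave(df$frame, df$particle, FUN = function(f) {
    c(FALSE, diff(f) <= 0)
  })
  stop_if_not(!any(dup > 0), "frames must be strictly increasing within a particle")
  len <- table(df$particle)
  stop_if_not(any(len >= 2), "need at least one particle with >= 2 observations")
  rownames(df) <- NULL
  structure(df, class = c("track_table", "data.frame"),
            frame_interval = frame_interval, pixel_size = pixel_size,
            source = source, ground_truth = ground_truth)
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("track_table: %d particles, %d rows, frame interval %g s%s\n",
              length(unique(x$particle)), nrow(x), attr(x, "frame_interval"),
              if (nzchar(attr(x, "source") %||% "")) paste0(" [", attr(x, "source"), "]") else ""))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Read a trajectory CSV into a calibrated track table
#'
#' Consumes the `frame,particle,x,y` CSV dialect produced by standard
#' tracking software (positions in pixels, 0-based frame index), converts
#' positions to micrometers and drops short tracks.
#'
#' @param path CSV file with columns `frame`, `particle`, `x`, `y`
#' @param pixel_size um/px applied to `x` and `y`
#' @param frame_interval seconds per frame
#' @param min_track_length particles observed in fewer frames are dropped
#'   (the number excluded is reported via `message()` and attached as
#'   attribute `n_excluded`)
#' @return a [track_table()]
#' @export
read_tracks <- function(path, pixel_size, frame_interval,
                        min_track_length = 10L) {
  stop_if_not(file.exists(path), paste("no such file:", path))
  stop_if_not(pixel_size > 0, "pixel_size must be > 0")
  df <- utils::read.csv(path)
  stop_if_not(nrow(df) > 0, paste("empty track file:", path))
  need <- c("frame", "particle", "x", "y")
  miss <- setdiff(need, names(df))
  stop_if_not(length(miss) == 0,
              paste("missing columns:", paste(miss, collapse = ", ")))
  for (cn in c("frame", "x", "y")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    stop_if_not(!anyNA(v), paste("non-numeric entries in column", cn))
    df[[cn]] <- v
  }
  len <- table(df$particle)
  keep <- names(len)[len >= min_track_length]
  n_excluded <- length(len) - length(keep)
  if (n_excluded > 0) {
    message(sprintf("read_tracks: excluded %d track(s) shorter than %d frames",
                    n_excluded, min_track_length))
  }
  df <- df[df$particle %in% keep, , drop = FALSE]
  stop_if_not(nrow(df) > 0, "no tracks left after length filtering")
  df$x <- df$x * pixel_size
  df$y <- df$y * pixel_size
  tt <- track_table(df, frame_interval = frame_interval,
                    pixel_size = pixel_size, source = path)
  attr(tt, "n_excluded") <- n_excluded
  tt
}

#' Write a track table as a tracking-software-style CSV
#'
#' Positions are written in pixels (divided by the `pixel_size` used at
#' generation, argument `pixel_size` otherwise) with 0-based frame
#' indices, matching the format [read_tracks()] consumes.
#'
#' @param tracks a [track_table()]
#' @param path output CSV path
#' @param pixel_size um/px used to convert back to pixels; defaults to the
#'   table's own calibration
#' @return `path`, invisibly
#' @export
write_tracks <- function(tracks, path, pixel_size = NULL) {
  px <- pixel_size %||% attr(tracks, "pixel_size")
  stop_if_not(is.finite(px) && px > 0,
              "pixel_size unknown; supply it explicitly")
  out <- data.frame(frame = as.integer(tracks$frame),
                    particle = tracks$particle,
                    x = tracks$x / px, y = tracks$y / px)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
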