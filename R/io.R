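# TIFF / CSV / JSON plumbing. Calibration always travels in config or
# sidecar JSON, never inferred from TIFF tags alone.

#' Read a multi-page grayscale TIFF as an array
#'
#' @param path TIFF file.
#' @return nrow x ncol x n_frames numeric array in [0, 1].
#' @export
read_timelapse <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p
  })
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Write an array as a multi-page grayscale TIFF
#'
#' Intensities are clipped to [0, 1] and written at the requested bit
#' depth.
#'
#' @param video nrow x ncol x n_frames array.
#' @param path output file.
#' @param bits 8 or 16.
#' @return the path, invisibly.
#' @export
write_timelapse <- function(video, path, bits = 16) {
  if (length(dim(video)) == 2) video <- array(video, c(dim(video), 1))
  frames <- lapply(seq_len(dim(video)[3]), function(k)
    pmin(pmax(video[, , k], 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = bits)
  invisible(path)
}

#' Write a ground-truth sidecar JSON
#'
#' Stores truth tracks (frame, x, y in px), fiber chains (um) and the
#' calibration block next to a rendered TIFF.
#'
#' @param path output JSON file.
#' @param tracks optional list of track data.frames (um).
#' @param chains optional list of chain matrices (um).
#' @param pixel_size_um,frame_interval_min calibration.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(path, tracks = NULL, chains = NULL,
                             pixel_size_um = NA, frame_interval_min = NA) {
  truth <- list(calibration = list(pixel_size_um = pixel_size_um,
                                   frame_interval_min = frame_interval_min))
  if (!is.null(tracks))
    truth$tracks <- lapply(tracks, function(tr)
      cbind(tr$frame, tr$x / pixel_size_um, tr$y / pixel_size_um))
  if (!is.null(chains))
    truth$chains <- lapply(chains, function(ch) unclass(ch[, 1:2]))
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write a detections table
#'
#' @param detections data.frame from [segment_video()].
#' @param path CSV file.
#' @return the path, invisibly.
#' @export
write_detections_csv <- function(detections, path) {
  write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' Write a track set as a long CSV (cell_id, frame, x_um, y_um)
#'
#' @param trackset a \code{track_set}.
#' @param path CSV file.
#' @return the path, invisibly.
#' @export
write_tracks_csv <- function(trackset, path) {
  df <- do.call(rbind, lapply(trackset$tracks, function(tr)
    data.frame(cell_id = tr$cell_id, frame = tr$frame,
               x_um = tr$x, y_um = tr$y)))
  if (is.null(df))
    df <- data.frame(cell_id = integer(), frame = integer(),
                     x_um = numeric(), y_um = numeric())
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a track set written by [write_tracks_csv()]
#'
#' @param path CSV file.
#' @param pixel_size,frame_interval calibration to attach.
#' @return a \code{track_set}.
#' @export
read_tracks_csv <- function(path, pixel_size = 1.3, frame_interval = 15) {
  df <- read.csv(path)
  ids <- sort(unique(df$cell_id))
  tracks <- lapply(ids, function(id) {
    tr <- df[df$cell_id == id, ]
    tr <- tr[order(tr$frame), ]
    data.frame(cell_id = id, frame = tr$frame, x = tr$x_um, y = tr$y_um)
  })
  structure(list(tracks = tracks,
                 n_frames = if (nrow(df)) max(df$frame) + 1L else 0L),
            class = "track_set",
            pixel_size = pixel_size, frame_interval = frame_interval)
}
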