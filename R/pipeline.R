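#' Run the cell-migration pipeline end to end
#'
#' Segmentation (CLAHE + Chan-Vese graph cut + labeling), gated
#' nearest-neighbour tracking and migration statistics on one time-lapse,
#' with a manifest of the configuration and per-stage timings so runs are
#' reproducible.
#'
#' @param video array, \code{synthetic_video}, or path to a TIFF.
#' @param pixel_size um per px.
#' @param frame_interval minutes per frame.
#' @param params a [chan_vese_params()].
#' @param gate_um association gate, um.
#' @param min_area minimum detection area, px^2.
#' @param min_track_len minimum track length, frames.
#' @param clahe apply CLAHE before segmentation.
#' @param out_dir optional directory; when given, detections and tracks CSV
#'   and a summary JSON are written there.
#' @return list with \code{detections}, \code{trackset}, \code{stats}
#'   (from [migration_summary()]) and \code{manifest}.
#' @export
run_cell_pipeline <- function(video, pixel_size = 1.3, frame_interval = 15,
                              params = chan_vese_params(),
                              gate_um = 40, min_area = 20,
                              min_track_len = 2, clahe = TRUE,
                              out_dir = NULL) {
  if (is.character(video)) video <- read_timelapse(video)
  if (inherits(video, "synthetic_video")) video <- video$video
  manifest <- list(config = list(pixel_size = pixel_size,
                                 frame_interval = frame_interval,
                                 gate_um = gate_um, min_area = min_area,
                                 min_track_len = min_track_len,
                                 clahe = clahe,
                                 chan_vese = unclass(params)),
                   package_version =
                     as.character(utils::packageVersion("scaffoldtrack")))
  t0 <- proc.time()[3]
  detections <- segment_video(video, params = params, clahe = clahe,
                              min_area = min_area)
  t1 <- proc.time()[3]
  trackset <- build_tracks(detections, gate_um = gate_um,
                           min_track_len = min_track_len,
                           pixel_size = pixel_size,
                           frame_interval = frame_interval,
                           n_frames = dim(video)[3])
  t2 <- proc.time()[3]
  stats <- if (length(trackset$tracks)) migration_summary(trackset) else NULL
  manifest$timings_s <- c(segment = unname(t1 - t0),
                          track = unname(t2 - t1))
  manifest$counts <- list(
    detections = nrow(detections),
    tracks = length(trackset$tracks))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_detections_csv(detections, file.path(out_dir, "detections.csv"))
    write_tracks_csv(trackset, file.path(out_dir, "tracks.csv"))
    jsonlite::write_json(
      list(manifest = manifest,
           summary = if (is.null(stats)) NULL else stats$summary),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  list(detections = detections, trackset = trackset, stats = stats,
       manifest = manifest)
}

#' Write the canonical synthetic test battery
#'
#' Generates one artifact per acquisition modality under \code{dir}: a
#' cell time-lapse TIFF with its ground-truth JSON sidecar, a fiber image,
#' an SEM-like two-phase texture and a diffusion series. All randomness
#' derives from \code{seed}; rerunning with the same seed reproduces every
#' file.
#'
#' @param dir output directory (must be empty or absent unless
#'   \code{overwrite}).
#' @param seed integer seed.
#' @param overwrite allow writing into a non-empty directory.
#' @return invisible character vector of the files written.
#' @export
make_fixtures <- function(dir, seed = 0, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("output directory is not empty; use overwrite = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  files <- character()
  # cell video
  model <- motility_model("persistent_rw", step_speed = 4.37,
                          persistence = 0.5, n_frames = 48)
  tracks <- lapply(seq_len(5), function(i)
    sample_track(model, origin = runif(2, 30, 130),
                 bounds = c(5, 160, 5, 160)))
  sv <- render_video(tracks, shape = c(128, 128), pixel_size = 1.3,
                     noise_sigma = 0.02, seed = seed + 1)
  p <- file.path(dir, "cells.tif")
  write_timelapse(sv$video, p)
  write_truth_json(file.path(dir, "cells_truth.json"), tracks = tracks,
                   pixel_size_um = 1.3, frame_interval_min = 15)
  files <- c(files, p)
  # fiber image
  chains <- lapply(seq_len(8), function(i)
    sample_fiber_chain(10, 30, 0.5, origin = runif(2, 5, 35)))
  sf <- render_fiber_image(chains, width = 0.6, shape = c(200, 200),
                           pixel_size = 0.2, noise_sigma = 0.02,
                           seed = seed + 2)
  p <- file.path(dir, "fibers.tif")
  write_timelapse(sf$image, p)
  write_truth_json(file.path(dir, "fibers_truth.json"), chains = chains,
                   pixel_size_um = 0.2)
  files <- c(files, p)
  # SEM-like texture: dilated random fiber lattice
  sem_chains <- lapply(seq_len(12), function(i) {
    th <- runif(1, 0, pi)
    o <- runif(2, 0, 50)
    rbind(o, o + 60 * c(cos(th), sin(th)))
  })
  sem <- render_fiber_image(sem_chains, width = 3, shape = c(200, 200),
                            pixel_size = 0.5, noise_sigma = 0.03,
                            seed = seed + 3)
  p <- file.path(dir, "sem.tif")
  write_timelapse(sem$image, p)
  files <- c(files, p)
  # diffusion series
  ds <- render_diffusion_series(D = 100, length_um = 400, pixel_size = 2,
                                dt_s = 5, n_frames = 120, n_rows = 8,
                                noise_sigma = 0.01, seed = seed + 4)
  p <- file.path(dir, "diffusion.tif")
  write_timelapse(ds$video, p)
  files <- c(files, p)
  invisible(files)
}
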