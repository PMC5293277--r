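#' Gated one-to-one nearest-neighbour association between two frames
#'
#' Candidate pairs within \code{gate_radius} are sorted by ascending
#' distance (globally, over all pairs) and accepted greedily, each
#' detection matching at most once. Exact-distance ties are broken by the
#' lowest (frame-t index, frame-t1 index) lexicographic pair, which makes
#' the result deterministic and invariant to detection ordering.
#'
#' @param det_t,det_t1 data.frames with columns \code{x}, \code{y}
#'   (same units as \code{gate_radius}).
#' @param gate_radius maximum association distance (> 0).
#' @return list with \code{matches} (data.frame i, j, dist — row indices
#'   into det_t and det_t1), \code{deaths} (unmatched rows of det_t) and
#'   \code{births} (unmatched rows of det_t1).
#' @export
associate_detections <- function(det_t, det_t1, gate_radius) {
  if (gate_radius <= 0) stop("'gate_radius' must be > 0")
  n0 <- nrow(det_t); n1 <- nrow(det_t1)
  if (n0 == 0 || n1 == 0) {
    return(list(matches = data.frame(i = integer(), j = integer(),
                                     dist = numeric()),
                deaths = seq_len(n0), births = seq_len(n1)))
  }
  dmat <- sqrt(outer(det_t$x, det_t1$x, "-")^2 +
               outer(det_t$y, det_t1$y, "-")^2)
  cand <- which(dmat <= gate_radius, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(list(matches = data.frame(i = integer(), j = integer(),
                                     dist = numeric()),
                deaths = seq_len(n0), births = seq_len(n1)))
  }
  d <- dmat[cand]
  ord <- order(d, cand[, 1], cand[, 2])
  used0 <- logical(n0); used1 <- logical(n1)
  mi <- integer(); mj <- integer(); md <- numeric()
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used0[i] && !used1[j]) {
      used0[i] <- TRUE; used1[j] <- TRUE
      mi <- c(mi, i); mj <- c(mj, j); md <- c(md, d[k])
    }
  }
  list(matches = data.frame(i = mi, j = mj, dist = md),
       deaths = which(!used0), births = which(!used1))
}

#' Build cell tracks from per-frame detections
#'
#' Chains frame-to-frame gated nearest-neighbour matches into tracks.
#' There is no gap closing: a missed detection terminates the track and a
#' later reappearance starts a new one. Tracks shorter than
#' \code{min_track_len} frames are discarded.
#'
#' @param detections data.frame with columns \code{frame} (0-based,
#'   consecutive), \code{x_px}, \code{y_px} as from [segment_video()].
#' @param gate_um association gate in um.
#' @param min_track_len minimum surviving track length, frames.
#' @param pixel_size um per px.
#' @param frame_interval minutes between frames.
#' @param n_frames total frames in the video; inferred from the detections
#'   when \code{NULL}.
#' @return an object of class \code{track_set}: list of track data.frames
#'   (\code{cell_id}, \code{frame}, \code{x}, \code{y} in um) with
#'   calibration attributes.
#' @export
build_tracks <- function(detections, gate_um = 40, min_track_len = 2,
                         pixel_size = 1.3, frame_interval = 15,
                         n_frames = NULL) {
  n_frames <- n_frames %||%
    (if (nrow(detections)) max(detections$frame) + 1L else 0L)
  if (!is.null(n_frames) && n_frames < 2 && nrow(detections))
    stop("need at least 2 frames to track")
  dets <- detections
  dets$x <- dets$x_px * pixel_size
  dets$y <- dets$y_px * pixel_size
  by_frame <- lapply(0:(max(0L, n_frames - 1L)), function(f)
    dets[dets$frame == f, , drop = FALSE])
  open <- list()    # active tracks: list(points = data.frame)
  done <- list()
  prev <- by_frame[[1]]
  if (nrow(prev)) {
    open <- lapply(seq_len(nrow(prev)), function(i)
      data.frame(frame = prev$frame[i], x = prev$x[i], y = prev$y[i]))
  }
  for (t in seq_len(length(by_frame) - 1L)) {
    cur <- by_frame[[t + 1L]]
    last_pts <- if (length(open)) {
      do.call(rbind, lapply(open, function(tr) tr[nrow(tr), c("x", "y")]))
    } else data.frame(x = numeric(), y = numeric())
    asc <- associate_detections(last_pts, cur[, c("x", "y"), drop = FALSE],
                                gate_radius = gate_um)
    new_open <- list()
    if (nrow(asc$matches)) {
      for (k in seq_len(nrow(asc$matches))) {
        i <- asc$matches$i[k]; j <- asc$matches$j[k]
        new_open[[length(new_open) + 1L]] <-
          rbind(open[[i]], data.frame(frame = cur$frame[j], x = cur$x[j],
                                      y = cur$y[j]))
      }
    }
    for (i in asc$deaths) done[[length(done) + 1L]] <- open[[i]]
    for (j in asc$births)
      new_open[[length(new_open) + 1L]] <-
        data.frame(frame = cur$frame[j], x = cur$x[j], y = cur$y[j])
    open <- new_open
  }
  done <- c(done, open)
  done <- Filter(function(tr) nrow(tr) >= min_track_len, done)
  # deterministic ordering: by first frame, then x, then y of first point
  if (length(done)) {
    key <- vapply(done, function(tr)
      tr$frame[1] * 1e12 + tr$x[1] * 1e4 + tr$y[1] * 1e-4, numeric(1))
    done <- done[order(key)]
    for (i in seq_along(done)) {
      done[[i]]$cell_id <- i
      done[[i]] <- done[[i]][, c("cell_id", "frame", "x", "y")]
    }
  }
  structure(list(tracks = done, n_frames = n_frames),
            class = "track_set",
            pixel_size = pixel_size, frame_interval = frame_interval)
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d tracks over %d frames\n",
              length(x$tracks), x$n_frames))
  invisible(x)
}
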