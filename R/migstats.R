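#' Accumulated distance of one track
#'
#' Sum of Euclidean distances between successive calibrated positions, in
#' um. A single-point track accumulates no path and returns 0 with a
#' warning.
#'
#' @param track data.frame with columns \code{x}, \code{y} in um.
#' @return accumulated path length, um.
#' @export
accumulated_distance <- function(track) {
  if (nrow(track) < 2) {
    warning("single-point track: accumulated distance is 0")
    return(0)
  }
  sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
}

#' Mean accumulated distance (MAD) of a track set
#'
#' Arithmetic mean over tracks of the accumulated path length. When
#' \code{replica} labels are supplied, a replica-pondered mean is also
#' returned: the unweighted mean of the per-replica mean values, matching
#' the convention of averaging the mean of each experimental replica.
#'
#' @param trackset a \code{track_set} or a list of track data.frames.
#' @param replica optional vector of replica labels, one per track.
#' @return list with \code{pooled} (mean over all tracks),
#'   \code{replica_pondered} (NA when no replica labels), and \code{per_track}.
#' @export
mean_accumulated_distance <- function(trackset, replica = NULL) {
  tracks <- if (inherits(trackset, "track_set")) trackset$tracks else trackset
  if (!length(tracks)) stop("empty track set: MAD undefined")
  d <- vapply(tracks, accumulated_distance, numeric(1))
  pondered <- NA_real_
  if (!is.null(replica)) {
    if (length(replica) != length(d))
      stop("one replica label per track required")
    pondered <- mean(tapply(d, replica, mean))
  }
  list(pooled = mean(d), replica_pondered = pondered, per_track = d)
}

#' Average speed of one track
#'
#' Accumulated distance divided by the elapsed time
#' (\code{n_steps * frame_interval / 60} hours), in um/hr.
#'
#' @param track data.frame with \code{x}, \code{y} in um.
#' @param frame_interval minutes per frame; taken from the track-set
#'   calibration by the wrappers.
#' @return speed in um/hr.
#' @export
average_speed <- function(track, frame_interval = 15) {
  if (nrow(track) < 2) return(0)
  dur_hr <- (nrow(track) - 1) * frame_interval / 60
  accumulated_distance(track) / dur_hr
}

# per-step velocity vectors, um/hr
track_velocities <- function(track, frame_interval = 15) {
  dt_hr <- frame_interval / 60
  cbind(diff(track$x), diff(track$y)) / dt_hr
}

#' Primary migration direction of a track (SVD)
#'
#' The principal axis of the per-step velocity vectors: the right singular
#' vector of the (n_steps x 2) velocity matrix associated with the largest
#' singular value, with its sign fixed so that the mean velocity projects
#' non-negatively onto it.
#'
#' @param track data.frame with \code{x}, \code{y} in um.
#' @param frame_interval minutes per frame.
#' @return unit length-2 vector.
#' @export
primary_direction <- function(track, frame_interval = 15) {
  V <- track_velocities(track, frame_interval)
  if (nrow(V) < 2 || all(V == 0))
    stop("primary direction needs >= 2 non-zero velocities")
  s <- svd(V)
  v1 <- s$v[, 1]
  if (sum(colMeans(V) * v1) < 0) v1 <- -v1
  v1 / sqrt(sum(v1^2))
}

#' Orientation-resolved speed profile (polarity) of a track set
#'
#' Each track's velocities are rotated so its primary direction (from
#' [primary_direction()]) maps to 0 degrees, then pooled over tracks. The
#' profile is the mean speed magnitude per orientation bin. The anisotropy
#' index is the ratio of the mean speed within +/- 22.5 degrees of the
#' primary axis (0 and 180 degrees) to the mean speed within +/- 22.5
#' degrees of the orthogonal axis (90 and 270 degrees). A flat profile
#' indicates an isotropic (or persistent) random walk; a peaked one an
#' anisotropic walk.
#'
#' @param trackset a \code{track_set} or list of track data.frames (um).
#' @param n_bins number of orientation bins (even, >= 4).
#' @param frame_interval minutes per frame (taken from the track-set
#'   attribute when available).
#' @param cap ceiling applied when the orthogonal sector is empty.
#' @return class \code{polarity_profile}: list with \code{profile}
#'   (data.frame bin_deg, mean_speed, n), \code{anisotropy_index},
#'   \code{capped} flag and the pooled rotated velocities.
#' @export
polarity_profile <- function(trackset, n_bins = 16, frame_interval = NULL,
                             cap = 100) {
  if (n_bins < 4 || n_bins %% 2 != 0)
    stop("'n_bins' must be even and >= 4")
  tracks <- if (inherits(trackset, "track_set")) trackset$tracks else trackset
  frame_interval <- frame_interval %||%
    (attr(trackset, "frame_interval") %||% 15)
  pooled <- list()
  for (tr in tracks) {
    V <- track_velocities(tr, frame_interval)
    if (nrow(V) < 2 || all(V == 0)) next
    p <- primary_direction(tr, frame_interval)
    ang <- atan2(p[2], p[1])
    R <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2, 2)
    pooled[[length(pooled) + 1L]] <- V %*% t(R)
  }
  if (!length(pooled)) stop("no velocities to pool")
  V <- do.call(rbind, pooled)
  spd <- sqrt(rowSums(V^2))
  keep <- spd > 0
  V <- V[keep, , drop = FALSE]; spd <- spd[keep]
  theta <- atan2(V[, 2], V[, 1]) %% (2 * pi)
  # bins centred on 0, width 2*pi/n_bins
  width <- 2 * pi / n_bins
  bin <- (floor((theta + width / 2) / width) %% n_bins) + 1L
  mean_speed <- rep(NA_real_, n_bins)
  agg <- tapply(spd, bin, mean)
  mean_speed[as.integer(names(agg))] <- agg
  counts <- rep(0L, n_bins)
  tab <- table(bin)
  counts[as.integer(names(tab))] <- as.integer(tab)
  profile <- data.frame(bin_deg = (seq_len(n_bins) - 1L) * 360 / n_bins,
                        mean_speed = mean_speed, n = counts)
  dev0 <- pmin(abs(theta), abs(theta - pi), abs(theta - 2 * pi))
  dev90 <- pmin(abs(theta - pi / 2), abs(theta - 3 * pi / 2))
  primary <- dev0 <= pi / 8
  orth <- dev90 <= pi / 8
  capped <- FALSE
  if (!any(orth) || mean(spd[orth]) == 0) {
    idx <- cap; capped <- TRUE
  } else {
    idx <- mean(spd[primary]) / mean(spd[orth])
    if (idx > cap) { idx <- cap; capped <- TRUE }
  }
  structure(list(profile = profile, anisotropy_index = idx,
                 capped = capped, velocities = V),
            class = "polarity_profile")
}

#' Per-experiment migration summary
#'
#' Computes the standard migration read-outs for a track set: per-track
#' accumulated distance and average speed, the mean accumulated distance
#' (pooled and, when replica labels are given, replica-pondered), and the
#' observation duration.
#'
#' @param trackset a \code{track_set}.
#' @param replica optional replica labels, one per track.
#' @return list with \code{per_track} (data.frame cell_id,
#'   accumulated_distance_um, average_speed_um_hr, n_points) and
#'   \code{summary} (MAD conventions, mean speed, n_tracks, duration_hr).
#' @export
migration_summary <- function(trackset, replica = NULL) {
  stopifnot(inherits(trackset, "track_set"))
  fi <- attr(trackset, "frame_interval") %||% 15
  tracks <- trackset$tracks
  if (!length(tracks)) stop("empty track set")
  dist <- vapply(tracks, accumulated_distance, numeric(1))
  spd <- vapply(tracks, average_speed, numeric(1), frame_interval = fi)
  ids <- vapply(tracks, function(tr) tr$cell_id[1], numeric(1))
  mad <- mean_accumulated_distance(trackset, replica)
  dur <- (trackset$n_frames - 1) * fi / 60
  list(per_track = data.frame(cell_id = ids,
                              accumulated_distance_um = dist,
                              average_speed_um_hr = spd,
                              n_points = vapply(tracks, nrow, 1L)),
       summary = list(mad_um = mad$pooled,
                      mad_replica_pondered_um = mad$replica_pondered,
                      mean_speed_um_hr = mean(spd),
                      n_tracks = length(tracks),
                      duration_hr = dur))
}
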