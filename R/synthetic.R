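#' Motility model for synthetic cell tracks
#'
#' Defines the random-walk family a synthetic cell follows. Three families
#' are supported: \code{"isotropic_rw"} (independent uniform step directions),
#' \code{"persistent_rw"} (directionally correlated steps: the expected cosine
#' of the turning angle between consecutive steps equals \code{persistence}),
#' and \code{"anisotropic_rw"} (uniform directions whose component along
#' \code{anisotropy_axis} is scaled by \code{anisotropy_ratio}, then
#' renormalized so the expected step length is unchanged).
#'
#' @param kind one of \code{"isotropic_rw"}, \code{"persistent_rw"},
#'   \code{"anisotropic_rw"}.
#' @param step_speed cell speed in um/hr; the expected per-frame displacement
#'   is \code{step_speed * frame_interval / 60} um.
#' @param persistence directional correlation between consecutive steps, in
#'   [0, 1]. 0 reproduces the isotropic walk; 1 gives a straight line.
#' @param anisotropy_axis unit 2-vector of the preferred axis.
#' @param anisotropy_ratio ratio (>= 1) of the step-scale along the primary
#'   axis versus the orthogonal axis; 1 reproduces isotropic statistics.
#' @param frame_interval frame interval in minutes.
#' @param n_frames number of frames (>= 2).
#' @param seed optional integer seed used by [sample_track()].
#' @return an object of class \code{motility_model}.
#' @export
motility_model <- function(kind = c("isotropic_rw", "persistent_rw",
                                    "anisotropic_rw"),
                           step_speed, persistence = 0,
                           anisotropy_axis = c(1, 0), anisotropy_ratio = 1,
                           frame_interval = 15, n_frames = 49, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot_scalar(step_speed, "step_speed")
  if (step_speed < 0) stop("'step_speed' must be >= 0")
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  if (n_frames < 2) stop("'n_frames' must be >= 2")
  if (persistence < 0 || persistence > 1)
    stop("'persistence' must lie in [0, 1]")
  if (abs(sqrt(sum(anisotropy_axis^2)) - 1) > 1e-8)
    stop("'anisotropy_axis' must be a unit vector")
  if (anisotropy_ratio < 1) stop("'anisotropy_ratio' must be >= 1")
  if (kind == "isotropic_rw" && persistence != 0)
    stop("isotropic_rw requires persistence = 0")
  structure(list(kind = kind, step_speed = step_speed,
                 persistence = persistence,
                 anisotropy_axis = anisotropy_axis,
                 anisotropy_ratio = anisotropy_ratio,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), seed = seed),
            class = "motility_model")
}

# mean |(r ux, uy)| over a uniformly distributed unit direction u;
# used to renormalize anisotropic steps to the nominal expected length
aniso_mean_scale <- function(r) {
  if (r == 1) return(1)
  (2 / pi) * integrate(function(phi) sqrt(r^2 * cos(phi)^2 + sin(phi)^2),
                       0, pi / 2)$value
}

#' Sample one synthetic cell track
#'
#' Draws a random-walk trajectory from a [motility_model()]. Positions are in
#' um; the first position is \code{origin}. When \code{bounds} is given the
#' walk reflects at the walls so the track never leaves the field of view.
#'
#' @param model a [motility_model()].
#' @param origin numeric length-2 start position (um).
#' @param bounds optional \code{c(xmin, xmax, ymin, ymax)} reflecting walls
#'   (um).
#' @return a \code{data.frame} with columns \code{frame} (0-based), \code{x},
#'   \code{y} (um), carrying the calibration as attributes.
#' @export
sample_track <- function(model, origin = c(0, 0), bounds = NULL) {
  stopifnot(inherits(model, "motility_model"))
  if (!is.null(model$seed)) set.seed(model$seed)
  n <- model$n_frames
  step_len <- model$step_speed * model$frame_interval / 60
  steps <- matrix(0, n - 1L, 2L)
  if (step_len > 0) {
    if (model$kind == "isotropic_rw") {
      th <- runif(n - 1L, 0, 2 * pi)
      steps <- step_len * cbind(cos(th), sin(th))
    } else if (model$kind == "persistent_rw") {
      p <- model$persistence
      if (p >= 1) {
        th <- rep(runif(1, 0, 2 * pi), n - 1L)
      } else if (p <= 0) {
        th <- runif(n - 1L, 0, 2 * pi)
      } else {
        # wrapped-normal turning angles: E[cos(dtheta)] = exp(-s^2/2) = p
        sigma <- sqrt(-2 * log(p))
        th <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 2L, 0, sigma)))
      }
      steps <- step_len * cbind(cos(th), sin(th))
    } else { # anisotropic_rw
      r <- model$anisotropy_ratio
      a <- model$anisotropy_axis
      th <- runif(n - 1L, 0, 2 * pi)
      u <- cbind(cos(th), sin(th))
      along <- u %*% a          # component along the axis
      perp <- u - along %*% t(a)
      u2 <- r * as.vector(along) * matrix(a, n - 1L, 2, byrow = TRUE) + perp
      steps <- (step_len / aniso_mean_scale(r)) * u2
    }
  }
  cum <- apply(steps, 2, cumsum)
  if (n == 2L) cum <- matrix(cum, 1L, 2L)
  pos <- rbind(origin, sweep(cum, 2, origin, "+"))
  if (!is.null(bounds)) {
    pos[, 1] <- reflect_coord(pos[, 1], bounds[1], bounds[2])
    pos[, 2] <- reflect_coord(pos[, 2], bounds[3], bounds[4])
  }
  out <- data.frame(frame = 0:(n - 1L), x = pos[, 1], y = pos[, 2])
  attr(out, "pixel_size") <- NA_real_
  attr(out, "frame_interval") <- model$frame_interval
  class(out) <- c("cell_track", "data.frame")
  out
}

#' Sample well-separated cell origins
#'
#' Rejection-samples \code{n} uniform positions inside \code{bounds} (um)
#' with a minimum pairwise spacing, emulating the dilute seeding of cells
#' in the hydrogel chamber (cells embedded in suspension do not start in
#' contact).
#'
#' @param n number of cells.
#' @param bounds \code{c(xmin, xmax, ymin, ymax)} in um.
#' @param min_spacing minimum pairwise distance, um.
#' @param max_tries rejection budget per point.
#' @return n x 2 matrix of origins (um).
#' @export
sample_origins <- function(n, bounds, min_spacing, max_tries = 2000) {
  pts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (k in seq_len(max_tries)) {
      p <- c(runif(1, bounds[1], bounds[2]), runif(1, bounds[3], bounds[4]))
      if (i == 1 ||
          min(sqrt((pts[seq_len(i - 1), 1] - p[1])^2 +
                   (pts[seq_len(i - 1), 2] - p[2])^2)) >= min_spacing) {
        pts[i, ] <- p; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place origins at the requested spacing")
  }
  pts
}

# fold a coordinate into [lo, hi] by successive reflections
reflect_coord <- function(x, lo, hi) {
  w <- hi - lo
  if (w <= 0) stop("invalid bounds")
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  y + lo
}

#' Render a fluorescence time-lapse video from ground-truth tracks
#'
#' Each cell is rendered as an isotropic Gaussian blob (diffraction-blur
#' proxy) of standard deviation \code{psf_sigma} pixels and peak amplitude
#' \code{cell_level} above \code{background_level}, with additive Gaussian
#' read noise. Positions are converted from um to pixels with
#' \code{pixel_size}; pixel (0, 0) is the centre of the top-left pixel,
#' x = column, y = row.
#'
#' @param tracks list of track data.frames (um) as from [sample_track()].
#' @param shape \code{c(nrow, ncol)} image size in px.
#' @param pixel_size um per px.
#' @param psf_sigma blob standard deviation, px.
#' @param background_level,cell_level background intensity and peak cell
#'   amplitude above background (arbitrary units; \code{cell_level > 0}).
#' @param noise_sigma additive Gaussian noise sd.
#' @param seed integer seed for the noise stream.
#' @return an object of class \code{synthetic_video}: list with \code{video}
#'   (nrow x ncol x n_frames array), \code{tracks} (truth, um),
#'   \code{overlap_warning} (TRUE when two truth positions came closer than
#'   1 px) and the rendering parameters.
#' @export
render_video <- function(tracks, shape = c(128, 128), pixel_size = 1.3,
                         psf_sigma = 2, background_level = 0.1,
                         cell_level = 0.5, noise_sigma = 0.02, seed = NULL) {
  if (cell_level <= 0) stop("'cell_level' must exceed the background")
  if (!is.null(seed)) set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  n_frames <- max(vapply(tracks, nrow, 1L))
  vid <- array(background_level, dim = c(nr, nc, n_frames))
  overlap <- FALSE
  hw <- ceiling(4 * psf_sigma)
  for (t in seq_len(n_frames)) {
    P <- t(vapply(tracks, function(tr) {
      if (t <= nrow(tr)) c(tr$x[t], tr$y[t]) / pixel_size else c(NA, NA)
    }, numeric(2)))
    P <- P[stats::complete.cases(P), , drop = FALSE]
    if (nrow(P) > 1) {
      dmin <- min(stats::dist(P))
      if (dmin < 1) overlap <- TRUE
    }
    for (k in seq_len(nrow(P))) {
      cx <- P[k, 1]; cy <- P[k, 2]   # x = col, y = row (0-based)
      rows <- max(0, floor(cy - hw)):min(nr - 1, ceiling(cy + hw))
      cols <- max(0, floor(cx - hw)):min(nc - 1, ceiling(cx + hw))
      if (!length(rows) || !length(cols)) next
      blob <- outer(exp(-(rows - cy)^2 / (2 * psf_sigma^2)),
                    exp(-(cols - cx)^2 / (2 * psf_sigma^2)))
      vid[rows + 1, cols + 1, t] <- vid[rows + 1, cols + 1, t] +
        cell_level * blob
    }
    if (noise_sigma > 0)
      vid[, , t] <- vid[, , t] + rnorm(nr * nc, 0, noise_sigma)
  }
  if (overlap)
    warning("truth positions closer than 1 px; detections may merge")
  structure(list(video = vid, tracks = tracks, pixel_size = pixel_size,
                 psf_sigma = psf_sigma, background_level = background_level,
                 cell_level = cell_level, noise_sigma = noise_sigma,
                 overlap_warning = overlap),
            class = "synthetic_video")
}

#' Canonical synthetic migration video
#'
#' Composes the track sampler and the video renderer under the standard
#' study conditions: persistent random walkers at serum-stimulated speed
#' (4.37 um/hr), 15-min frames over 12 h, 1.3 um/px at 5x magnification,
#' Gaussian blobs of 2 px sd with 25:1 peak-to-noise contrast. The field
#' of view scales with the cell count at constant seeding density and
#' origins keep a minimum spacing, emulating dilute single-cell embedding.
#'
#' @param n_cells number of cells.
#' @param seed integer seed driving origins, walks and noise.
#' @param step_speed um/hr.
#' @param persistence directional correlation of the walk.
#' @param n_frames frames (48 = 12 h at 15 min).
#' @param kind random-walk family.
#' @param min_spacing minimum origin spacing, um.
#' @param noise_sigma additive noise sd.
#' @return a \code{synthetic_video} (see [render_video()]) whose
#'   \code{tracks} element holds the ground truth in um.
#' @export
synthetic_migration_video <- function(n_cells, seed, step_speed = 4.37,
                                      persistence = 0.5, n_frames = 48,
                                      kind = "persistent_rw",
                                      min_spacing = 45, noise_sigma = 0.02) {
  set.seed(seed)
  ps <- 1.3
  side_um <- max(180, ceiling(sqrt(n_cells) * 65))
  shape <- rep(ceiling(side_um / ps), 2L)
  fov <- (shape - 1) * ps
  model <- motility_model(kind, step_speed = step_speed,
                          persistence = if (kind == "persistent_rw")
                            persistence else 0,
                          n_frames = n_frames)
  orig <- sample_origins(n_cells, c(25, fov[2] - 25, 25, fov[1] - 25),
                         min_spacing = min_spacing)
  tracks <- lapply(seq_len(n_cells), function(i)
    sample_track(model, origin = orig[i, ],
                 bounds = c(5, fov[2] - 5, 5, fov[1] - 5)))
  render_video(tracks, shape = shape, pixel_size = ps, psf_sigma = 2,
               noise_sigma = noise_sigma, seed = seed + 10000L)
}

#' Sample a worm-like-chain fiber centreline
#'
#' Generates a 2D discrete worm-like chain: the tangent angle evolves by
#' independent Gaussian increments of variance \code{step / persistence_length}
#' so that the tangent correlation decays as
#' \code{E[cos(theta(s) - theta(0))] = exp(-s / (2 * Lp))} (2D convention).
#'
#' @param persistence_length Lp in um; \code{Inf} gives a straight segment.
#' @param contour_length total arc length in um.
#' @param step sampling step along the chain in um.
#' @param seed optional integer seed.
#' @param origin start point (um).
#' @param init_angle starting tangent angle (radians); uniform if \code{NULL}.
#' @return a numeric matrix of chain points (um), one row per point, with
#'   attributes \code{step} and \code{persistence_length}.
#' @export
sample_fiber_chain <- function(persistence_length, contour_length,
                               step = 0.5, seed = NULL, origin = c(0, 0),
                               init_angle = NULL) {
  if (contour_length <= 0 || step <= 0)
    stop("'contour_length' and 'step' must be > 0")
  if (!is.infinite(persistence_length) && persistence_length <= 0)
    stop("'persistence_length' must be > 0 (or Inf)")
  if (!is.null(seed)) set.seed(seed)
  n_seg <- round(contour_length / step)
  th0 <- if (is.null(init_angle)) runif(1, 0, 2 * pi) else init_angle
  if (is.infinite(persistence_length)) {
    th <- rep(th0, n_seg)
  } else {
    th <- cumsum(c(th0, rnorm(n_seg - 1L, 0,
                              sqrt(step / persistence_length))))
  }
  cum <- apply(step * cbind(cos(th), sin(th)), 2, cumsum)
  if (n_seg == 1L) cum <- matrix(cum, 1L, 2L)
  pts <- rbind(origin, sweep(cum, 2, origin, "+"))
  dimnames(pts) <- NULL
  attr(pts, "step") <- step
  attr(pts, "persistence_length") <- persistence_length
  pts
}

#' Render a fiber image from ground-truth chains
#'
#' Rasterizes centreline chains (um) onto a pixel grid, dilates them to the
#' requested fiber width (the binary truth mask), then produces a grayscale
#' channel by Gaussian blur plus additive noise.
#'
#' @param chains list of chain point matrices (um).
#' @param width fiber width in um; must be at least 1 px after calibration.
#' @param shape \code{c(nrow, ncol)} in px.
#' @param pixel_size um per px.
#' @param blur_sigma blur of the grayscale channel, px.
#' @param noise_sigma additive Gaussian noise sd.
#' @param seed integer seed for the noise stream.
#' @return class \code{synthetic_fibers}: list with \code{mask} (logical
#'   truth), \code{image} (grayscale), \code{chains}, and parameters.
#' @export
render_fiber_image <- function(chains, width, shape = c(256, 256),
                               pixel_size = 0.2, blur_sigma = 1,
                               noise_sigma = 0, seed = NULL) {
  w_px <- width / pixel_size
  if (w_px < 1) stop("fiber width below 1 px is unresolvable")
  if (!is.null(seed)) set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  mask <- matrix(0L, nr, nc)
  for (ch in chains) {
    dense <- densify_chain(ch, 0.4 * pixel_size)
    col <- round(dense[, 1] / pixel_size) + 1L
    row <- round(dense[, 2] / pixel_size) + 1L
    keep <- row >= 1 & row <= nr & col >= 1 & col <= nc
    mask[cbind(row[keep], col[keep])] <- 1L
  }
  if (w_px > 1) {
    brush_size <- 2 * floor(w_px / 2) + 1
    if (brush_size >= 3)
      mask <- EBImage::dilate(mask, EBImage::makeBrush(brush_size, "disc"))
    mask <- (mask > 0) + 0L
  }
  img <- EBImage::gblur(mask * 1.0, sigma = blur_sigma)
  img <- as.matrix(img)
  if (noise_sigma > 0) img <- img + rnorm(nr * nc, 0, noise_sigma)
  structure(list(mask = mask > 0, image = img, chains = chains,
                 width = width, pixel_size = pixel_size,
                 noise_sigma = noise_sigma),
            class = "synthetic_fibers")
}

# resample a polyline so successive points are <= ds apart
densify_chain <- function(pts, ds) {
  out <- list(pts[1, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / ds))
    tt <- seq_len(k) / k
    out[[i + 1L]] <- cbind(a[1] + tt * (b[1] - a[1]),
                           a[2] + tt * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' Render a 1D diffusion time-lapse with its analytic solution
#'
#' Emulates dextran loading into a half-infinite hydrogel: intensity at
#' distance x from the source boundary and time t follows
#' \code{C(x, t) = (C0 / 2) * erfc(x / (2 * sqrt(D * t)))}. The x axis runs
#' along image columns.
#'
#' @param D diffusivity, um^2/s (> 0).
#' @param C0 source concentration (the plateau at the boundary is C0/2).
#' @param length_um imaged depth along x.
#' @param pixel_size um per px.
#' @param dt_s frame interval in seconds.
#' @param n_frames number of frames (frame 0 is at t = 0, pre-loading).
#' @param n_rows image height in px.
#' @param noise_sigma additive Gaussian noise sd.
#' @param seed integer seed.
#' @return class \code{synthetic_diffusion}: list with \code{video},
#'   \code{times_s}, \code{x_um} (per column), \code{analytic} (noise-free
#'   intensity matrix, columns = frames), and parameters.
#' @export
render_diffusion_series <- function(D, C0 = 1, length_um = 400,
                                    pixel_size = 2, dt_s = 5,
                                    n_frames = 200, n_rows = 16,
                                    noise_sigma = 0, seed = NULL) {
  if (D <= 0) stop("'D' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  nc <- round(length_um / pixel_size)
  x <- (seq_len(nc) - 1) * pixel_size
  times <- (seq_len(n_frames) - 1) * dt_s
  analytic <- vapply(times, function(t) {
    if (t <= 0) c(C0 / 2, rep(0, nc - 1)) else
      (C0 / 2) * pracma::erfc(x / (2 * sqrt(D * t)))
  }, numeric(nc))
  vid <- array(0, dim = c(n_rows, nc, n_frames))
  for (k in seq_len(n_frames)) {
    fr <- matrix(analytic[, k], n_rows, nc, byrow = TRUE)
    if (noise_sigma > 0) fr <- fr + rnorm(n_rows * nc, 0, noise_sigma)
    vid[, , k] <- fr
  }
  structure(list(video = vid, times_s = times, x_um = x,
                 analytic = analytic, D = D, C0 = C0,
                 pixel_size = pixel_size, dt_s = dt_s,
                 noise_sigma = noise_sigma),
            class = "synthetic_diffusion")
}
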