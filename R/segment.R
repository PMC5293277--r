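#' Contrast-limited adaptive histogram equalization
#'
#' Thin wrapper around \code{EBImage::clahe} operating on a plain numeric
#' matrix. The output is rescaled to span [0, 1]. A constant input carries
#' no contrast to equalize and is returned unchanged with attribute
#' \code{flat = TRUE}.
#'
#' @param frame numeric matrix (any range; internally rescaled to [0, 1]).
#' @param tile tile size in px (>= 8); the tile grid is
#'   \code{round(dim / tile)} in each direction.
#' @param clip_limit clip limit as a fraction of the tile histogram
#'   (0 < clip_limit <= 1).
#' @return numeric matrix in [0, 1], same size as the input.
#' @export
clahe_enhance <- function(frame, tile = 64, clip_limit = 0.01) {
  if (tile < 8) stop("'tile' must be >= 8 px")
  if (clip_limit <= 0 || clip_limit > 1)
    stop("'clip_limit' must lie in (0, 1]")
  if (diff(range(frame)) == 0) {
    attr(frame, "flat") <- TRUE
    return(frame)
  }
  # EBImage's x axis is the first array dimension (our rows); pad both
  # dimensions to a multiple of their tile count by edge replication,
  # then crop back
  nr <- nrow(frame); nc <- ncol(frame)
  nx <- max(2L, round(nr / tile))
  ny <- max(2L, round(nc / tile))
  nr_pad <- ceiling(nr / nx) * nx
  nc_pad <- ceiling(nc / ny) * ny
  m <- rescale01(frame)
  if (nr_pad > nr) m <- rbind(m, m[rep(nr, nr_pad - nr), , drop = FALSE])
  if (nc_pad > nc) m <- cbind(m, m[, rep(nc, nc_pad - nc), drop = FALSE])
  out <- EBImage::clahe(EBImage::Image(m), nx = nx, ny = ny, bins = 256L,
                        limit = max(1, clip_limit * 256))
  out <- rescale01(as.matrix(out)[seq_len(nr), seq_len(nc)])
  attr(out, "flat") <- FALSE
  out
}

#' Parameters of the Chan-Vese segmentation energy
#'
#' The two-phase piecewise-constant energy minimized by
#' [chan_vese_graphcut()] is
#' \deqn{E(S) = \lambda_1 \sum_{p \in S} (I_p - c_1)^2 +
#'   \lambda_2 \sum_{p \notin S} (I_p - c_2)^2 + \mu \, Per(S)}
#' with the boundary length \eqn{Per(S)} approximated by the 8-neighbourhood
#' cut metric (weights \eqn{\pi/8} for axial and \eqn{\pi/(8\sqrt 2)} for
#' diagonal pixel pairs, the standard Euclidean-length correction).
#'
#' @param lambda1,lambda2 region-fit weights (>= 0, not both zero).
#' @param mu boundary-length weight (>= 0).
#' @param c1,c2 foreground/background mean intensities. When \code{NULL}
#'   they are estimated by alternating mean-update and cut, initialized from
#'   an Otsu split of the frame histogram.
#' @param max_outer_iters maximum mean-update iterations in free-means mode.
#' @param tol convergence tolerance on the means (intensity units).
#' @return a list of class \code{chan_vese_params}.
#' @export
chan_vese_params <- function(lambda1 = 1, lambda2 = 1, mu = 0.1,
                             c1 = NULL, c2 = NULL, max_outer_iters = 20L,
                             tol = 1e-4) {
  if (lambda1 < 0 || lambda2 < 0 || mu < 0)
    stop("weights must be >= 0")
  if (lambda1 + lambda2 <= 0) stop("lambda1 + lambda2 must be > 0")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, mu = mu,
                 c1 = c1, c2 = c2,
                 max_outer_iters = as.integer(max_outer_iters), tol = tol),
            class = "chan_vese_params")
}

# 8-neighbourhood lattice edges for an nr x nc grid; cached per size.
# Returns 0-based from/to indices and the cut-metric weight of each pair.
lattice_cache <- new.env(parent = emptyenv())
lattice_edges <- function(nr, nc) {
  key <- paste(nr, nc)
  if (!is.null(lattice_cache[[key]])) return(lattice_cache[[key]])
  idx <- matrix(seq_len(nr * nc) - 1L, nr, nc)
  eh <- cbind(as.vector(idx[, -nc, drop = FALSE]),
              as.vector(idx[, -1, drop = FALSE]))
  ev <- cbind(as.vector(idx[-nr, , drop = FALSE]),
              as.vector(idx[-1, , drop = FALSE]))
  d1 <- cbind(as.vector(idx[-nr, -nc, drop = FALSE]),
              as.vector(idx[-1, -1, drop = FALSE]))
  d2 <- cbind(as.vector(idx[-1, -nc, drop = FALSE]),
              as.vector(idx[-nr, -1, drop = FALSE]))
  el <- rbind(eh, ev, d1, d2)
  w <- c(rep(pi / 8, nrow(eh) + nrow(ev)),
         rep(pi / (8 * sqrt(2)), nrow(d1) + nrow(d2)))
  out <- list(from = el[, 1], to = el[, 2], w = w)
  lattice_cache[[key]] <- out
  out
}

#' Chan-Vese segmentation solved exactly by graph min-cut
#'
#' For fixed region means \code{(c1, c2)} the returned mask is a global
#' minimizer of the energy described in [chan_vese_params()]: the energy is
#' submodular, so the s-t minimum cut on the pixel lattice solves it
#' exactly. With free means the function alternates mean updates and cuts
#' until the means move less than \code{tol} or \code{max_outer_iters} is
#' reached (attribute \code{converged} reports which).
#'
#' @param frame numeric matrix of intensities.
#' @param params a [chan_vese_params()] object.
#' @return logical matrix (TRUE = foreground), with attributes
#'   \code{c1}, \code{c2}, \code{converged}.
#' @export
chan_vese_graphcut <- function(frame, params = chan_vese_params()) {
  stopifnot(inherits(params, "chan_vese_params"))
  nr <- nrow(frame); nc <- ncol(frame)
  v <- as.vector(frame)
  free_means <- is.null(params$c1) || is.null(params$c2)
  if (free_means && diff(range(v)) == 0) {
    # degenerate tie: resolve to all-background
    mask <- matrix(FALSE, nr, nc)
    attr(mask, "c1") <- v[1]; attr(mask, "c2") <- v[1]
    attr(mask, "converged") <- TRUE
    return(mask)
  }
  lat <- lattice_edges(nr, nc)
  cut_once <- function(c1, c2) {
    cap_src <- params$lambda2 * (v - c2)^2   # paid when pixel is background
    cap_snk <- params$lambda1 * (v - c1)^2   # paid when pixel is foreground
    fg <- lattice_mincut(nr * nc, lat$from, lat$to, params$mu * lat$w,
                         cap_src, cap_snk)
    matrix(fg == 1L, nr, nc)
  }
  if (!free_means) {
    mask <- cut_once(params$c1, params$c2)
    attr(mask, "c1") <- params$c1; attr(mask, "c2") <- params$c2
    attr(mask, "converged") <- TRUE
    return(mask)
  }
  thr <- otsu_threshold(v)
  hi <- v > thr
  if (!any(hi) || all(hi)) hi <- v > mean(v)
  c1 <- mean(v[hi]); c2 <- mean(v[!hi])
  converged <- FALSE
  mask <- NULL; prev_mask <- NULL
  for (it in seq_len(params$max_outer_iters)) {
    mask <- cut_once(c1, c2)
    c1_new <- if (any(mask)) mean(v[mask]) else c1
    c2_new <- if (!all(mask)) mean(v[!mask]) else c2
    stable <- !is.null(prev_mask) && identical(mask, prev_mask)
    if (stable || abs(c1_new - c1) + abs(c2_new - c2) < params$tol) {
      c1 <- c1_new; c2 <- c2_new
      converged <- TRUE
      break
    }
    prev_mask <- mask
    c1 <- c1_new; c2 <- c2_new
  }
  if (!converged)
    warning("Chan-Vese means did not converge; returning last mask")
  attr(mask, "c1") <- c1; attr(mask, "c2") <- c2
  attr(mask, "converged") <- converged
  mask
}

#' Chan-Vese energy of a given mask
#'
#' Evaluates the same discrete energy that [chan_vese_graphcut()] minimizes,
#' for any candidate mask; used to verify cut optimality against exhaustive
#' enumeration on small images.
#'
#' @param frame numeric matrix.
#' @param mask logical matrix (TRUE = foreground).
#' @param params a [chan_vese_params()] with fixed \code{c1}, \code{c2}.
#' @return the scalar energy.
#' @export
chan_vese_energy <- function(frame, mask, params) {
  if (is.null(params$c1) || is.null(params$c2))
    stop("energy evaluation needs fixed c1, c2")
  v <- as.vector(frame); m <- as.vector(mask)
  lat <- lattice_edges(nrow(frame), ncol(frame))
  data_term <- params$lambda1 * sum((v[m] - params$c1)^2) +
    params$lambda2 * sum((v[!m] - params$c2)^2)
  cut <- m[lat$from + 1L] != m[lat$to + 1L]
  data_term + params$mu * sum(lat$w[cut])
}

# 8-connected labeling of a logical mask via graph components
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (!length(fg)) return(labels)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  pair_if <- function(a, b) {
    keep <- mask[a] & mask[b]
    cbind(a[keep], b[keep])
  }
  eh <- pair_if(as.vector(idx[, -nc, drop = FALSE]),
                as.vector(idx[, -1, drop = FALSE]))
  ev <- pair_if(as.vector(idx[-nr, , drop = FALSE]),
                as.vector(idx[-1, , drop = FALSE]))
  d1 <- pair_if(as.vector(idx[-nr, -nc, drop = FALSE]),
                as.vector(idx[-1, -1, drop = FALSE]))
  d2 <- pair_if(as.vector(idx[-1, -nc, drop = FALSE]),
                as.vector(idx[-nr, -1, drop = FALSE]))
  el <- rbind(eh, ev, d1, d2)
  vmap <- integer(nr * nc)
  vmap[fg] <- seq_along(fg)
  g <- igraph::graph_from_edgelist(cbind(vmap[el[, 1]], vmap[el[, 2]]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # relabel components consecutively in scan order of their first pixel
  first <- tapply(fg, comp, min)
  ord <- rank(first)
  labels[fg] <- as.integer(ord[comp])
  labels
}

#' Label segmented cells and extract detections
#'
#' 8-connected component labeling of a binary mask; components smaller than
#' \code{min_area} are removed and the rest relabeled consecutively in scan
#' order. Centroids are unweighted pixel means in the 0-based (x = column,
#' y = row) convention.
#'
#' @param mask logical matrix (TRUE = cell).
#' @param min_area minimum component area in px^2.
#' @return a list of class \code{labeled_frame}: \code{labels} (integer
#'   matrix, 0 = background) and \code{detections}
#'   (data.frame label, x_px, y_px, area_px2).
#' @export
label_cells <- function(mask, min_area = 20) {
  labels <- label8(mask)
  if (max(labels) == 0L) {
    return(structure(list(labels = labels,
                          detections = data.frame(label = integer(),
                                                  x_px = numeric(),
                                                  y_px = numeric(),
                                                  area_px2 = numeric())),
                     class = "labeled_frame"))
  }
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  labels[labels > 0] <- remap[labels[labels > 0]]
  dets <- if (length(keep)) {
    pix <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[labels > 0]
    data.frame(label = seq_along(keep),
               x_px = as.vector(tapply(pix[, 2] - 1, lab, mean)),
               y_px = as.vector(tapply(pix[, 1] - 1, lab, mean)),
               area_px2 = as.vector(tapply(lab, lab, length)))
  } else {
    data.frame(label = integer(), x_px = numeric(), y_px = numeric(),
               area_px2 = numeric())
  }
  structure(list(labels = labels, detections = dets),
            class = "labeled_frame")
}

#' Cell-count change between the first and last frame of a video
#'
#' Survival proxy for treatment experiments: non-viable fluorescent cells
#' lose their signal and disappear from the segmentation, so the signed
#' difference \code{count(last) - count(first)} close to zero indicates
#' preserved viability.
#'
#' @param first,last \code{labeled_frame} objects (or plain detection
#'   counts).
#' @return signed integer count difference, last minus first.
#' @export
count_survival <- function(first, last) {
  n_of <- function(x) {
    if (inherits(x, "labeled_frame")) nrow(x$detections)
    else as.integer(x)
  }
  n_of(last) - n_of(first)
}

#' Segment a whole video
#'
#' Convenience wrapper: CLAHE enhancement then Chan-Vese graph-cut
#' segmentation and labeling, frame by frame.
#'
#' @param video nrow x ncol x n_frames array.
#' @param params a [chan_vese_params()].
#' @param clahe logical, apply CLAHE first.
#' @param tile,clip_limit CLAHE settings, see [clahe_enhance()].
#' @param min_area minimum detection area, px^2.
#' @param means \code{"video"} estimates free region means on the first
#'   frame and reuses them for the rest of the video (imaging conditions
#'   are constant within one acquisition); \code{"per_frame"} re-estimates
#'   on every frame. Ignored when \code{params} fixes \code{c1}, \code{c2}.
#' @return data.frame of detections (frame 0-based, label, x_px, y_px,
#'   area_px2).
#' @export
segment_video <- function(video, params = chan_vese_params(),
                          clahe = TRUE, tile = 64, clip_limit = 0.01,
                          min_area = 20, means = c("video", "per_frame")) {
  means <- match.arg(means)
  n_frames <- dim(video)[3]
  out <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    fr <- video[, , t]
    if (clahe) fr <- clahe_enhance(fr, tile = tile, clip_limit = clip_limit)
    mask <- chan_vese_graphcut(fr, params)
    if (means == "video" && t == 1L &&
        (is.null(params$c1) || is.null(params$c2))) {
      params$c1 <- attr(mask, "c1")
      params$c2 <- attr(mask, "c2")
    }
    lf <- label_cells(mask, min_area = min_area)
    d <- lf$detections
    if (nrow(d)) d$frame <- t - 1L
    out[[t]] <- d
  }
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res))
    res <- data.frame(label = integer(), x_px = numeric(), y_px = numeric(),
                      area_px2 = numeric(), frame = integer())
  res[, c("frame", "label", "x_px", "y_px", "area_px2")]
}
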