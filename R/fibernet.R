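#' Steerable ridge enhancement of fiber-like structures
#'
#' Second-order Gaussian-derivative steerable filter: the image is smoothed
#' at the requested scale and the response at each pixel is the
#' orientation-maximized negative second directional derivative, i.e. the
#' negated smallest eigenvalue of the Hessian (scale-normalized by
#' sigma^2). Bright ridges of width comparable to the scale give strong
#' positive responses; the maximization over orientation is closed-form, so
#' the response is rotation-invariant up to pixel discretization.
#'
#' @param img numeric matrix, or a 3D array treated slice-wise.
#' @param scale_um filter scale (approximately the fiber radius), um.
#' @param pixel_size um per px; \code{scale_um / pixel_size} must be >= 1.
#' @return ridge-response matrix (or array), same size as the input.
#' @export
enhance_fibers <- function(img, scale_um, pixel_size = 1) {
  sigma <- scale_um / pixel_size
  if (sigma < 1) stop("filter scale below 1 px")
  if (length(dim(img)) == 3) {
    out <- img
    for (k in seq_len(dim(img)[3]))
      out[, , k] <- enhance_fibers(img[, , k], scale_um, pixel_size)
    return(out)
  }
  hw <- ceiling(4 * sigma)
  x <- (-hw):hw
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -x / sigma^2 * g
  g2 <- (x^2 / sigma^4 - 1 / sigma^2) * g
  conv_sep <- function(m, kr, kc) {
    k2 <- outer(kr, kc)
    as.matrix(EBImage::filter2(m, k2, boundary = "replicate"))
  }
  gxx <- conv_sep(img, g, g2)   # second derivative along columns (x)
  gyy <- conv_sep(img, g2, g)
  gxy <- conv_sep(img, g1, g1)
  tr <- gxx + gyy
  dd <- sqrt(((gxx - gyy) / 2)^2 + gxy^2)
  lam_min <- tr / 2 - dd
  sigma^2 * (-lam_min)
}

#' Local Otsu binarization
#'
#' Computes an Otsu threshold per image tile of size \code{window} and
#' bilinearly interpolates the thresholds between tile centres, making the
#' binarization robust to slow illumination gradients. Tiles with no real
#' bimodal structure default to background: an Otsu split of pure noise
#' separates the class means by about 1.6 standard deviations, so a tile is
#' only accepted when its class-mean separation exceeds
#' \code{min_bimodality} times the pooled within-class standard deviation.
#'
#' @param img numeric matrix (or 3D array, slice-wise); internally rescaled
#'   to [0, 1].
#' @param window tile size, px (odd, >= 15).
#' @param min_bimodality minimum ratio of class-mean separation to pooled
#'   within-class sd for a tile to produce foreground.
#' @return logical mask (TRUE = fiber phase).
#' @export
local_otsu_binarize <- function(img, window = 31, min_bimodality = 4) {
  if (window %% 2 == 0 || window < 15)
    stop("'window' must be odd and >= 15 px")
  if (length(dim(img)) == 3) {
    out <- array(FALSE, dim = dim(img))
    for (k in seq_len(dim(img)[3]))
      out[, , k] <- local_otsu_binarize(img[, , k], window, min_bimodality)
    return(out)
  }
  v <- rescale01(img)
  nr <- nrow(v); nc <- ncol(v)
  tr <- max(1L, ceiling(nr / window)); tc <- max(1L, ceiling(nc / window))
  r_edges <- round(seq(0, nr, length.out = tr + 1L))
  c_edges <- round(seq(0, nc, length.out = tc + 1L))
  thr <- matrix(NA_real_, tr, tc)
  valid <- matrix(FALSE, tr, tc)
  for (i in seq_len(tr)) for (j in seq_len(tc)) {
    tile <- v[(r_edges[i] + 1):r_edges[i + 1],
              (c_edges[j] + 1):c_edges[j + 1]]
    th <- otsu_threshold(tile)
    lo <- tile[tile <= th]; hi <- tile[tile > th]
    if (length(lo) > 1 && length(hi) > 1) {
      s_within <- sqrt((sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
                         (length(tile) - 2))
      if (mean(hi) - mean(lo) >= min_bimodality * max(s_within, 1e-12) ||
          s_within == 0) {
        thr[i, j] <- th
        valid[i, j] <- TRUE
      }
    }
  }
  if (!any(valid)) return(matrix(FALSE, nr, nc))
  # fill invalid tiles from the nearest valid tile, then interpolate
  if (any(!valid)) {
    vidx <- which(valid, arr.ind = TRUE)
    for (p in which(!valid)) {
      i <- (p - 1) %% tr + 1; j <- (p - 1) %/% tr + 1
      d2 <- (vidx[, 1] - i)^2 + (vidx[, 2] - j)^2
      nn <- vidx[which.min(d2), , drop = FALSE]
      thr[i, j] <- thr[nn[1], nn[2]]
    }
  }
  rc <- (r_edges[-1] + r_edges[-(tr + 1)]) / 2
  cc <- (c_edges[-1] + c_edges[-(tc + 1)]) / 2
  thr_map <- bilinear_grid(thr, rc, cc, nr, nc)
  mask <- v > thr_map
  # tiles without bimodal structure stay background
  for (i in seq_len(tr)) for (j in seq_len(tc)) {
    if (!valid[i, j])
      mask[(r_edges[i] + 1):r_edges[i + 1],
           (c_edges[j] + 1):c_edges[j + 1]] <- FALSE
  }
  mask
}

# bilinear interpolation of tile-centre values onto the full pixel grid
# (constant extrapolation beyond the outer tile centres)
bilinear_grid <- function(z, rc, cc, nr, nc) {
  interp1 <- function(centers, n) {
    pos <- seq_len(n) - 0.5
    if (length(centers) == 1L)
      return(list(i0 = rep(1L, n), i1 = rep(1L, n), w = rep(0, n)))
    i1 <- findInterval(pos, centers, all.inside = TRUE)
    i2 <- i1 + 1L
    w <- (pos - centers[i1]) / (centers[i2] - centers[i1])
    w <- pmin(1, pmax(0, w))
    list(i0 = i1, i1 = i2, w = w)
  }
  ri <- interp1(rc, nr); ci <- interp1(cc, nc)
  z00 <- z[cbind(rep(ri$i0, nc), rep(ci$i0, each = nr))]
  z10 <- z[cbind(rep(ri$i1, nc), rep(ci$i0, each = nr))]
  z01 <- z[cbind(rep(ri$i0, nc), rep(ci$i1, each = nr))]
  z11 <- z[cbind(rep(ri$i1, nc), rep(ci$i1, each = nr))]
  wr <- rep(ri$w, nc); wc <- rep(ci$w, each = nr)
  matrix((1 - wr) * (1 - wc) * z00 + wr * (1 - wc) * z10 +
           (1 - wr) * wc * z01 + wr * wc * z11, nr, nc)
}

#' FIRE-style fiber extraction from a binary mask
#'
#' Skeleton-form fiber extraction: the fiber phase is reduced to a
#' 1-px-wide skeleton (nucleated on the ridges of its Euclidean distance
#' map by homotopic thinning in distance order), chains are split at
#' junction points (>= 3 skeleton neighbours), short spurs are pruned, and
#' chains shorter than \code{min_fiber_len} are discarded. Optionally,
#' chains meeting at a junction with near-collinear end tangents (within
#' \code{reconnect_angle} degrees) are rejoined, since reported fiber
#' lengths depend on that policy.
#'
#' @param mask logical matrix (TRUE = fiber phase).
#' @param pixel_size um per px.
#' @param min_fiber_len minimum chain length, um.
#' @param reconnect logical: rejoin collinear chains across junctions.
#' @param reconnect_angle collinearity tolerance, degrees.
#' @return class \code{fiber_network}: list with \code{chains} (matrices of
#'   x, y in um), \code{n_junctions}, \code{skeleton}, \code{mask},
#'   \code{pixel_size}.
#' @export
fire_extract <- function(mask, pixel_size = 1, min_fiber_len = 1,
                         reconnect = FALSE, reconnect_angle = 30) {
  if (!any(mask)) {
    return(structure(list(chains = list(), n_junctions = 0L,
                          skeleton = mask & FALSE, mask = mask,
                          pixel_size = pixel_size),
                     class = "fiber_network"))
  }
  edt <- as.matrix(EBImage::distmap((mask > 0) + 0L))
  skel <- medial_axis_thin(mask, edt)
  skel <- prune_spurs(skel, min_len = 3, edt = edt)
  sc <- skeleton_chains(skel)
  chains <- sc$chains
  # drop intra-cluster junction debris (tiny chains joining adjacent
  # junction pixels) before any reconnection
  if (nrow(sc$junctions)) {
    jset <- paste(sc$junctions[, 1], sc$junctions[, 2])
    chains <- Filter(function(ch) {
      !(nrow(ch) <= 3 &&
          all(paste(ch[c(1, nrow(ch)), 1], ch[c(1, nrow(ch)), 2]) %in% jset))
    }, chains)
  }
  if (reconnect && length(chains) > 1)
    chains <- reconnect_chains(chains, reconnect_angle)
  # (row, col) px -> (x, y) um, 0-based pixel centres
  chains_um <- lapply(chains, function(ch)
    cbind(x = (ch[, 2] - 1) * pixel_size, y = (ch[, 1] - 1) * pixel_size))
  keep <- vapply(chains_um, function(ch)
    nrow(ch) >= 2 && polyline_length(ch) >= min_fiber_len, logical(1))
  kept_px <- chains[keep]
  # a junction is a cluster of >= 3-neighbour skeleton pixels where at
  # least 3 retained chains terminate (clusters touched only by pruned
  # debris are end artifacts, not junctions)
  n_junc <- 0L
  if (nrow(sc$junctions)) {
    jm <- matrix(0L, nrow(skel), ncol(skel))
    jm[sc$junctions] <- 1L
    jl <- label8(jm > 0)
    ends <- do.call(rbind, lapply(kept_px, function(ch)
      ch[c(1, nrow(ch)), , drop = FALSE]))
    if (!is.null(ends)) {
      touch <- integer(max(jl))
      for (k in seq_len(nrow(ends))) {
        r <- ends[k, 1]; c <- ends[k, 2]
        rs <- max(1, r - 1):min(nrow(jl), r + 1)
        cs <- max(1, c - 1):min(ncol(jl), c + 1)
        lab <- setdiff(unique(as.vector(jl[rs, cs])), 0L)
        touch[lab] <- touch[lab] + 1L
      }
      n_junc <- sum(touch >= 3L)
    }
  }
  structure(list(chains = chains_um[keep],
                 n_junctions = n_junc,
                 skeleton = skel, mask = mask > 0,
                 pixel_size = pixel_size),
            class = "fiber_network")
}

polyline_length <- function(pts)
  sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))

# end tangent of a pixel chain (unit vector pointing outward at `which` end)
end_tangent <- function(ch, which_end, span = 5) {
  n <- nrow(ch)
  k <- min(span, n - 1)
  v <- if (which_end == 1) ch[1, ] - ch[1 + k, ] else ch[n, ] - ch[n - k, ]
  v / sqrt(sum(v^2))
}

# greedy rejoining of chains whose ends meet (within 2 px) with
# anti-collinear tangents inside the angle tolerance
reconnect_chains <- function(chains, tol_deg) {
  merged <- TRUE
  while (merged && length(chains) > 1) {
    merged <- FALSE
    n <- length(chains)
    best <- NULL; best_ang <- tol_deg
    for (a in seq_len(n - 1)) for (b in (a + 1):n) for (ea in 1:2)
      for (eb in 1:2) {
        pa <- if (ea == 1) chains[[a]][1, ] else
          chains[[a]][nrow(chains[[a]]), ]
        pb <- if (eb == 1) chains[[b]][1, ] else
          chains[[b]][nrow(chains[[b]]), ]
        if (sqrt(sum((pa - pb)^2)) > 3) next
        ta <- end_tangent(chains[[a]], ea)
        tb <- end_tangent(chains[[b]], eb)
        ang <- acos(pmin(1, pmax(-1, -sum(ta * tb)))) * 180 / pi
        if (!is.na(ang) && ang < best_ang) {
          best <- c(a, b, ea, eb); best_ang <- ang
        }
      }
    if (!is.null(best)) {
      a <- best[1]; b <- best[2]
      ca <- chains[[a]]; cb <- chains[[b]]
      if (best[3] == 1) ca <- ca[nrow(ca):1, , drop = FALSE]
      if (best[4] == 2) cb <- cb[nrow(cb):1, , drop = FALSE]
      chains[[a]] <- rbind(ca, cb)
      chains[[b]] <- NULL
      merged <- TRUE
    }
  }
  chains
}

#' Fiber length
#'
#' Aggregated Euclidean distance between successive chain points, um.
#'
#' @param chain matrix of chain points (um), as in a \code{fiber_network}.
#' @return length in um.
#' @export
fiber_length <- function(chain) polyline_length(chain)

#' Fiber persistence length
#'
#' Tangent-correlation estimator: for arc separations s up to
#' \code{fit_range}, the mean tangent-angle cosine
#' \eqn{C(s) = \langle\cos(\theta(u+s) - \theta(u))\rangle} is fit by least
#' squares to the 2D worm-like-chain decay \eqn{\exp(-s / (2 L_p))}, the
#' same convention the synthetic chain generator uses.
#'
#' @param chain matrix of chain points (um).
#' @param fit_range maximum arc separation used in the fit, um
#'   (default: min(chain length, 10)).
#' @param cap value returned for effectively straight chains (flagged via
#'   attribute \code{infinite}).
#' @return persistence length Lp in um; attributes \code{infinite} and
#'   \code{unreliable} flag degenerate fits.
#' @export
fiber_persistence <- function(chain, fit_range = NULL, cap = 1e4) {
  seg <- cbind(diff(chain[, 1]), diff(chain[, 2]))
  ds <- sqrt(rowSums(seg^2))
  keep <- ds > 0
  seg <- seg[keep, , drop = FALSE]; ds <- ds[keep]
  if (nrow(seg) < 3) stop("chain too short for a persistence fit")
  total <- sum(ds)
  fit_range <- fit_range %||% min(total, 10)
  theta <- atan2(seg[, 2], seg[, 1])
  s_mid <- cumsum(ds) - ds / 2
  n <- length(theta)
  step <- mean(ds)
  kmax <- max(1L, min(n - 1L, floor(fit_range / step)))
  svals <- numeric(kmax); cvals <- numeric(kmax)
  for (k in seq_len(kmax)) {
    dth <- theta[(1 + k):n] - theta[1:(n - k)]
    svals[k] <- mean(s_mid[(1 + k):n] - s_mid[1:(n - k)])
    cvals[k] <- mean(cos(dth))
  }
  if (all(cvals <= 0)) {
    out <- NA_real_
    attr(out, "unreliable") <- TRUE
    return(out)
  }
  if (all(cvals > 0.999)) {
    out <- cap
    attr(out, "infinite") <- TRUE
    return(out)
  }
  obj <- function(loglp) {
    lp <- 10^loglp
    sum((cvals - exp(-svals / (2 * lp)))^2)
  }
  opt <- optimize(obj, interval = c(-2, 6))
  lp <- 10^opt$minimum
  if (lp >= cap) {
    out <- cap
    attr(out, "infinite") <- TRUE
    return(out)
  }
  out <- lp
  attr(out, "infinite") <- FALSE
  attr(out, "unreliable") <- FALSE
  out
}

#' Pore-size distribution by the covering radius transform
#'
#' The liquid (background) phase is reduced to its medial axis; the
#' covering radius at a medial-axis point p is the radius of the largest
#' inscribed disk that covers p, i.e. the largest distance-map value r
#' among medial-axis centres c with |p - c| <= r. Inside an open pore this
#' assigns the pore's inscribed radius to (almost) all of its medial axis,
#' so the modal covering diameter reads off the typical pore size. Radii
#' are clipped by the image border (a 1-px virtual fiber frame) and points
#' whose limiting disk touches the border are flagged.
#'
#' @param mask logical matrix (TRUE = fiber phase).
#' @param pixel_size um per px.
#' @return class \code{pore_distribution}: list with \code{radius_um},
#'   \code{border_limited} (per-point flag), and a \code{summary} with
#'   mean/median/modal pore diameter (2 x radius) in um.
#' @export
pore_sizes <- function(mask, pixel_size = 1) {
  bg <- !(mask > 0)
  if (!any(bg)) {
    return(structure(list(radius_um = numeric(),
                          border_limited = logical(),
                          summary = list(mean_diameter_um = NA_real_,
                                         median_diameter_um = NA_real_,
                                         modal_diameter_um = NA_real_)),
                     class = "pore_distribution"))
  }
  nr <- nrow(mask); nc <- ncol(mask)
  # pad with a virtual fiber frame so border pores are distance-limited
  padded <- matrix(0L, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- bg + 0L
  edt <- as.matrix(EBImage::distmap(padded))[2:(nr + 1), 2:(nc + 1)]
  skel <- medial_axis_thin(bg, edt)
  skel <- prune_spurs(skel, min_len = 3)
  pts <- which(skel)
  radii_px <- covering_radii(pts, edt[pts], nr)
  rr <- (pts - 1) %% nr + 1; cc <- (pts - 1) %/% nr + 1
  border_dist <- pmin(rr, nr + 1 - rr, cc, nc + 1 - cc)
  structure(list(radius_um = radii_px * pixel_size,
                 border_limited = radii_px >= border_dist - 0.5,
                 summary = list(
                   mean_diameter_um = mean(2 * radii_px) * pixel_size,
                   median_diameter_um = median(2 * radii_px) * pixel_size,
                   modal_diameter_um = modal_value(round(2 * radii_px)) *
                     pixel_size)),
            class = "pore_distribution")
}

# Covering radius transform over the medial axis: process candidate
# centres in descending distance-map order; each point takes the radius of
# the first (largest) disk that covers it.
covering_radii <- function(pts, r_local, nr) {
  x <- (pts - 1) %/% nr; y <- (pts - 1) %% nr
  out <- rep(NA_real_, length(pts))
  ord <- order(r_local, decreasing = TRUE)
  unass <- rep(TRUE, length(pts))
  for (k in ord) {
    if (!any(unass)) break
    r <- r_local[k]
    idx <- which(unass)
    d2 <- (x[idx] - x[k])^2 + (y[idx] - y[k])^2
    hit <- idx[d2 <= r^2]
    if (length(hit)) {
      out[hit] <- r
      unass[hit] <- FALSE
    }
  }
  out[is.na(out)] <- r_local[is.na(out)]
  out
}

modal_value <- function(x) {
  if (!length(x)) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

#' Quantify a confocal reflection stack slice-wise
#'
#' Full fiber pipeline on a 2D image or 3D stack, slice by slice: steerable
#' ridge enhancement, local Otsu binarization, FIRE-style chain extraction,
#' per-fiber length and persistence, and covering-radius pore sizing.
#' Slice-wise operation reflects the strong z-anisotropy of confocal
#' reflection stacks.
#'
#' @param stack matrix or 3D array of intensities.
#' @param pixel_size um per px (lateral).
#' @param scale_um steerable filter scale.
#' @param window local-Otsu window, px.
#' @param min_fiber_len minimum fiber length, um.
#' @param reconnect rejoin collinear chains across junctions.
#' @return list with \code{fibers} (data.frame slice, chain_id, length_um,
#'   persistence_um), \code{pores} (radius_um over slices), and
#'   \code{summary} (median fiber length/persistence, pore diameter
#'   statistics).
#' @export
analyze_fiber_stack <- function(stack, pixel_size, scale_um = 0.3,
                                window = 31, min_fiber_len = 1,
                                reconnect = FALSE) {
  if (length(dim(stack)) == 2) stack <- array(stack, c(dim(stack), 1))
  n_slices <- dim(stack)[3]
  fibs <- list(); pores <- list()
  for (k in seq_len(n_slices)) {
    enh <- enhance_fibers(stack[, , k], scale_um, pixel_size)
    m <- local_otsu_binarize(enh, window = window)
    net <- fire_extract(m, pixel_size, min_fiber_len, reconnect = reconnect)
    if (length(net$chains)) {
      lens <- vapply(net$chains, fiber_length, numeric(1))
      pers <- vapply(net$chains, function(ch) {
        if (nrow(ch) < 4) return(NA_real_)
        as.numeric(fiber_persistence(ch))
      }, numeric(1))
      fibs[[k]] <- data.frame(slice = k, chain_id = seq_along(lens),
                              length_um = lens, persistence_um = pers)
    }
    pd <- pore_sizes(m, pixel_size)
    pores[[k]] <- pd$radius_um
  }
  fibers <- if (length(fibs)) do.call(rbind, fibs) else
    data.frame(slice = integer(), chain_id = integer(),
               length_um = numeric(), persistence_um = numeric())
  radii <- unlist(pores)
  list(fibers = fibers,
       pores = data.frame(radius_um = radii),
       summary = list(
         median_fiber_length_um = median(fibers$length_um),
         median_persistence_um = median(fibers$persistence_um,
                                        na.rm = TRUE),
         mean_pore_diameter_um = mean(2 * radii),
         median_pore_diameter_um = median(2 * radii)))
}
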