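# Binary skeleton machinery shared by the fiber-network and SEM modules:
# Zhang-Suen axial thinning, distance-ordered homotopic thinning (medial
# axis), skeleton length, spur pruning and chain decomposition.

# neighbor ring P2..P9 (N, NE, E, SE, S, SW, W, NW) as a list of matrices
ring8 <- function(m) {
  list(shift_mat(m, 1, 0), shift_mat(m, 1, -1), shift_mat(m, 0, -1),
       shift_mat(m, -1, -1), shift_mat(m, -1, 0), shift_mat(m, -1, 1),
       shift_mat(m, 0, 1), shift_mat(m, 1, 1))
}

ring_stats <- function(nb) {
  B <- Reduce(`+`, nb)
  A <- 0
  for (i in 1:8) {
    j <- if (i == 8) 1 else i + 1
    A <- A + (nb[[i]] == 0 & nb[[j]] == 1)
  }
  list(A = A, B = B)
}

#' Zhang-Suen axial thinning
#'
#' Iterative two-subiteration thinning of a binary mask down to a
#' 1-px-wide, 8-connected skeleton.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical skeleton matrix.
#' @export
zhang_suen_thin <- function(mask) {
  m <- (mask > 0) + 0L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- ring8(m)
      rs <- ring_stats(nb)
      P2 <- nb[[1]]; P4 <- nb[[3]]; P6 <- nb[[5]]; P8 <- nb[[7]]
      if (sub == 1) {
        cond <- m == 1 & rs$B >= 2 & rs$B <= 6 & rs$A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- m == 1 & rs$B >= 2 & rs$B <= 6 & rs$A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m > 0
}

# Homotopic thinning with pixels removed in ascending order of the
# Euclidean distance transform: a discrete medial axis whose branches stay
# centred on the distance-map ridges.
#' Distance-ordered medial-axis thinning
#'
#' Sequentially removes simple, non-endpoint boundary pixels in ascending
#' order of the Euclidean distance transform while preserving the centres
#' of maximal disks (pixels whose inscribed disk is not contained in any
#' neighbour's), yielding a medial axis centred on the ridges of the
#' distance map. A final Zhang-Suen pass reduces residual 2-px plateaus to
#' unit width.
#'
#' @param mask logical or 0/1 matrix.
#' @param edt optional precomputed distance map of \code{mask}.
#' @return logical skeleton matrix.
#' @export
medial_axis_thin <- function(mask, edt = NULL) {
  m <- (mask > 0) + 0L
  if (!any(m > 0)) return(m > 0)
  if (is.null(edt)) edt <- as.matrix(EBImage::distmap(m))
  nr <- nrow(m); nc <- ncol(m)
  # centre-of-maximal-disk anchors: the disk at p is contained in the disk
  # at a neighbour q iff edt(q) >= edt(p) + |p - q|
  contained <- matrix(FALSE, nr, nc)
  dists <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
  nb_edt <- ring8(edt)
  for (k in 1:8)
    contained <- contained | (nb_edt[[k]] >= edt + dists[k] - 1e-9)
  anchor <- m == 1 & !contained
  repeat {
    nb <- ring8(m)
    rs <- ring_stats(nb)
    cand <- which(m == 1 & !anchor & rs$A == 1 & rs$B >= 2 & rs$B <= 6)
    if (!length(cand)) break
    cand <- cand[order(edt[cand], cand)]
    removed <- FALSE
    for (p in cand) {
      r <- (p - 1) %% nr + 1
      c <- (p - 1) %/% nr + 1
      # recompute ring from the current mask (sequential correctness)
      ringv <- integer(8)
      rr <- r + c(-1, -1, 0, 1, 1, 1, 0, -1)
      cc <- c + c(0, 1, 1, 1, 0, -1, -1, -1)
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      ringv[ok] <- m[cbind(rr[ok], cc[ok])]
      B <- sum(ringv)
      A <- sum(ringv == 0 & ringv[c(2:8, 1)] == 1)
      if (A == 1 && B >= 2 && B <= 6) {
        m[p] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  # reduce residual 2-px plateaus (even-width ridges keep both rows of
  # equal-distance anchors) to unit width
  zhang_suen_thin(m)
}

#' Skeleton length
#'
#' Sum over skeleton-graph edges: 1 per 4-neighbour step and sqrt(2) per
#' diagonal step. A diagonal pair is only counted when it is not shortcut
#' by a shared 4-neighbour skeleton pixel (which would double-count the
#' corner).
#'
#' @param skel logical skeleton matrix.
#' @param pixel_size um per px (1 gives length in px).
#' @return total centreline length.
#' @export
skeleton_length <- function(skel, pixel_size = 1) {
  s <- (skel > 0) + 0L
  E <- shift_mat(s, 0, -1); S <- shift_mat(s, -1, 0)
  SE <- shift_mat(s, -1, -1); NE <- shift_mat(s, 1, -1)
  N <- shift_mat(s, 1, 0)
  n_axial <- sum(s & E) + sum(s & S)
  # diagonal counted unless shortcut by a shared 4-neighbour
  d_se <- s == 1 & SE == 1 & !(S == 1 | E == 1)
  d_ne <- s == 1 & NE == 1 & !(N == 1 | E == 1)
  (n_axial + sqrt(2) * (sum(d_se) + sum(d_ne))) * pixel_size
}

# Degree of each pixel in the reduced skeleton graph: axial adjacencies
# always count; a diagonal adjacency only counts when it is not shortcut
# by a shared axial skeleton pixel (otherwise staircase pixels read as
# spurious junctions).
skeleton_degree <- function(skel) {
  s <- (skel > 0) + 0L
  nb <- ring8(s)   # N, NE, E, SE, S, SW, W, NW
  N <- nb[[1]]; NE <- nb[[2]]; E <- nb[[3]]; SE <- nb[[4]]
  S <- nb[[5]]; SW <- nb[[6]]; W <- nb[[7]]; NW <- nb[[8]]
  deg <- N + E + S + W +
    NE * (1 - pmax(N, E)) + SE * (1 - pmax(S, E)) +
    SW * (1 - pmax(S, W)) + NW * (1 - pmax(N, W))
  deg[!skel] <- 0L
  deg
}

# Decompose a skeleton into chains between nodes (endpoints and junction
# pixels). Returns list(chains = list of n x 2 matrices of (row, col),
# junctions = matrix of junction pixel coords, n_junction_clusters).
skeleton_chains <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  deg <- skeleton_degree(skel)
  nodes <- skel & deg != 2
  visited <- new.env(parent = emptyenv(), size = 1024L)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  at <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- logical(length(r))
    out[ok] <- skel[(c[ok] - 1) * nr + r[ok]]
    out
  }
  # reduced adjacency: diagonal neighbours only when not shortcut by a
  # shared axial skeleton pixel (matches skeleton_degree)
  nbrs <- function(p) {
    r <- (p - 1) %% nr + 1; c <- (p - 1) %/% nr + 1
    dr <- c(-1, 0, 1, 0, -1, -1, 1, 1)
    dc <- c(0, 1, 0, -1, 1, -1, 1, -1)
    pres <- at(r + dr, c + dc)
    if (pres[5]) pres[5] <- !(pres[1] || pres[2])  # NE vs N, E
    if (pres[6]) pres[6] <- !(pres[1] || pres[4])  # NW vs N, W
    if (pres[7]) pres[7] <- !(pres[3] || pres[2])  # SE vs S, E
    if (pres[8]) pres[8] <- !(pres[3] || pres[4])  # SW vs S, W
    (c + dc[pres] - 1) * nr + (r + dr[pres])
  }
  chains <- list()
  trace_from <- function(p, q) {
    path <- c(p, q)
    prev <- p; cur <- q
    while (!nodes[cur]) {
      nx <- setdiff(nbrs(cur), prev)
      # at a corner a deg-2 path pixel can see the previous pixel's
      # diagonal partner; prefer the unvisited continuation
      if (length(nx) == 0L) break
      if (length(nx) > 1L) nx <- nx[!nx %in% path][1]
      if (is.na(nx)) break
      visited[[ekey(cur, nx)]] <- TRUE
      path <- c(path, nx)
      prev <- cur; cur <- nx
    }
    path
  }
  node_idx <- which(nodes)
  for (p in node_idx) {
    for (q in nbrs(p)) {
      k <- ekey(p, q)
      if (is.null(visited[[k]])) {
        visited[[k]] <- TRUE
        chains[[length(chains) + 1L]] <- trace_from(p, q)
      }
    }
  }
  # leftover cycles with no nodes
  in_chain <- new.env(parent = emptyenv())
  for (ch in chains) for (p in ch) in_chain[[as.character(p)]] <- TRUE
  left <- which(skel & deg == 2)
  left <- left[vapply(left, function(p)
    is.null(in_chain[[as.character(p)]]), logical(1))]
  while (length(left)) {
    p <- left[1]
    q <- nbrs(p)[1]
    visited[[ekey(p, q)]] <- TRUE
    path <- trace_from(p, q)
    chains[[length(chains) + 1L]] <- path
    left <- setdiff(left, path)
  }
  junc <- which(skel & deg >= 3)
  n_clusters <- if (length(junc)) {
    jm <- matrix(FALSE, nr, nc); jm[junc] <- TRUE
    max(label8(jm))
  } else 0L
  to_rc <- function(p) cbind((p - 1) %% nr + 1, (p - 1) %/% nr + 1)
  list(chains = lapply(chains, to_rc),
       junctions = to_rc(junc),
       n_junction_clusters = n_clusters)
}

# Remove terminal branches shorter than min_len px that end at a junction.
# When `edt` is given the threshold adapts to the local fiber radius
# (corner branches of a blunt fiber end are about 0.7 x width long).
prune_spurs <- function(skel, min_len = 3, edt = NULL) {
  repeat {
    sc <- skeleton_chains(skel)
    deg <- skeleton_degree(skel)
    removed <- FALSE
    for (ch in sc$chains) {
      ends <- ch[c(1, nrow(ch)), , drop = FALSE]
      d <- deg[ends]
      thr <- min_len
      if (!is.null(edt)) {
        j_end <- if (d[1] >= 3) 1 else if (d[2] >= 3) 2 else NA
        if (!is.na(j_end))
          thr <- max(min_len, 1.6 * edt[ends[j_end, , drop = FALSE]])
      }
      is_spur <- (nrow(ch) - 1) < thr &&
        ((d[1] <= 1 && d[2] >= 3) || (d[2] <= 1 && d[1] >= 3))
      if (is_spur) {
        # drop all chain pixels except the junction-side endpoint
        keep_end <- if (d[1] >= 3) 1 else nrow(ch)
        drop <- setdiff(seq_len(nrow(ch)), keep_end)
        skel[ch[drop, , drop = FALSE]] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}
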