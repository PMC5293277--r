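#' Two-phase binarization by statistical region merging
#'
#' Statistical region merging (sorted-edge, predicate-based union-find over
#' 4-neighbour pixel pairs) partitions the micrograph into
#' piecewise-constant regions; the regions are then split into two classes
#' by thresholding the per-pixel region means at their Otsu threshold.
#' Fibers are the bright (white) class, pores the dark (black) class.
#'
#' @param img numeric matrix; internally rescaled to 0..255.
#' @param Q merging granularity (higher Q = finer regions).
#' @return logical mask (TRUE = fiber), with attributes \code{n_regions}
#'   and \code{degenerate} (TRUE when SRM produced a single region, in
#'   which case the whole image is one class).
#' @export
srm_binarize <- function(img, Q = 32) {
  v <- rescale01(img) * 255
  res <- srm_regions(v, Q, 256)
  if (res$n_regions == 1L) {
    mask <- matrix(FALSE, nrow(img), ncol(img))
    attr(mask, "n_regions") <- 1L
    attr(mask, "degenerate") <- TRUE
    return(mask)
  }
  thr <- otsu_threshold(as.vector(res$mean))
  mask <- res$mean > thr
  attr(mask, "n_regions") <- res$n_regions
  attr(mask, "degenerate") <- FALSE
  mask
}

#' Percentage of porosity
#'
#' 100 times the fraction of pixels in the pore (black) phase.
#'
#' @param mask logical matrix (TRUE = fiber, FALSE = pore).
#' @return porosity in percent.
#' @export
porosity <- function(mask) 100 * sum(!mask) / length(mask)

#' Pore count and mean pore area
#'
#' Pores are 8-connected components of the pore phase; border-touching
#' pores are counted. The mean area is the total pore pixel count divided
#' by the number of pores.
#'
#' @param mask logical matrix (TRUE = fiber).
#' @param um_per_px optional calibration; when given, mean area is also
#'   reported in um^2.
#' @return list with \code{n_pores}, \code{mean_pore_area_px2},
#'   \code{mean_pore_area_um2} (NA without calibration) and \code{flag}
#'   ("no_pores" when the pore phase is empty).
#' @export
pore_stats <- function(mask, um_per_px = NA) {
  pores <- !mask
  if (!any(pores)) {
    return(list(n_pores = 0L, mean_pore_area_px2 = 0,
                mean_pore_area_um2 = 0, flag = "no_pores"))
  }
  lab <- label8(pores)
  n <- max(lab)
  mean_area <- sum(pores) / n
  list(n_pores = n, mean_pore_area_px2 = mean_area,
       mean_pore_area_um2 = if (is.na(um_per_px)) NA_real_ else
         mean_area * um_per_px^2,
       flag = NA_character_)
}

#' Mean fiber diameter by the dual-centreline method
#'
#' Two centrelines of the fiber phase are measured: L1 from Zhang-Suen
#' axial thinning and L2 from the medial axis traced on the exact Euclidean
#' distance transform (a Voronoi-equivalent construction). The uncorrected
#' diameter is \code{area / mean(L1, L2)}. The intersection correction
#' removes junction clusters before the division: junction pixels
#' (skeleton points with >= 3 neighbours) are dilated by the local
#' distance-map radius, the covered fiber area is subtracted from the
#' numerator, and the length contributed by the junction cluster pixels
#' themselves from the denominator. The crossing fibers' centrelines that
#' traverse the zone stay in the denominator: both fibers genuinely run
#' through it, and removing their in-zone length would re-attribute the
#' (singly counted) overlap area to half the centreline. Fiber crossings
#' otherwise inflate the estimate.
#'
#' @param mask logical matrix (TRUE = fiber).
#' @param um_per_px calibration (1 reports px).
#' @param intersection_correction apply the junction correction.
#' @return mean fiber diameter (um, or px when \code{um_per_px = 1}), with
#'   attributes \code{uncorrected}, \code{L1}, \code{L2} (px units).
#' @export
mean_fiber_diameter <- function(mask, um_per_px = 1,
                                intersection_correction = TRUE) {
  if (!any(mask)) stop("fiber phase is empty")
  m <- mask > 0
  sk1 <- zhang_suen_thin(m)
  edt <- as.matrix(EBImage::distmap(m + 0L))
  sk2 <- prune_spurs(medial_axis_thin(m, edt), min_len = 3)
  if (!any(sk1) || !any(sk2)) stop("empty skeleton")
  L1 <- skeleton_length(sk1)
  L2 <- skeleton_length(sk2)
  area <- sum(m)
  d0 <- area / mean(c(L1, L2))
  if (!intersection_correction) {
    out <- d0 * um_per_px
    attr(out, "uncorrected") <- d0 * um_per_px
    attr(out, "L1") <- L1; attr(out, "L2") <- L2
    return(out)
  }
  # junction clusters on the axial skeleton, dilated by the local radius
  deg <- skeleton_degree(sk1)
  junc <- which(sk1 & deg >= 3)
  d <- d0
  if (length(junc)) {
    nr <- nrow(m); nc <- ncol(m)
    zone <- matrix(FALSE, nr, nc)
    jr <- (junc - 1) %% nr + 1; jc <- (junc - 1) %/% nr + 1
    for (k in seq_along(junc)) {
      rad <- max(1, edt[junc[k]])
      rs <- max(1, jr[k] - ceiling(rad)):min(nr, jr[k] + ceiling(rad))
      cs <- max(1, jc[k] - ceiling(rad)):min(nc, jc[k] + ceiling(rad))
      sub <- outer((rs - jr[k])^2, (cs - jc[k])^2, "+") <= rad^2
      zone[rs, cs] <- zone[rs, cs] | sub
    }
    a_excl <- sum(m & zone)
    # length of the junction clusters themselves, per centreline
    jm1 <- matrix(FALSE, nr, nc); jm1[junc] <- TRUE
    deg2 <- skeleton_degree(sk2)
    jm2 <- sk2 & deg2 >= 3
    l1_excl <- skeleton_length(jm1) + sum(jm1)
    l2_excl <- skeleton_length(jm2) + sum(jm2)
    denom <- mean(c(L1 - l1_excl, L2 - l2_excl))
    if (denom > 0 && area > a_excl)
      d <- (area - a_excl) / denom
  }
  out <- d * um_per_px
  attr(out, "uncorrected") <- d0 * um_per_px
  attr(out, "L1") <- L1; attr(out, "L2") <- L2
  out
}

#' SEM morphometry of one micrograph
#'
#' Binarizes a scanning electron micrograph by statistical region merging
#' and reports the standard dehydrated-gel morphometry panel: porosity
#' percentage, pore count, mean pore area and mean fiber diameter with
#' intersection correction. Values characterize the dehydrated,
#' sputter-coated specimen, not the hydrated matrix.
#'
#' @param img numeric matrix (grayscale micrograph), or a logical mask to
#'   skip binarization.
#' @param um_per_px calibration from the SEM scale bar.
#' @param Q SRM granularity.
#' @return class \code{sem_morphology}: list with \code{porosity_pct},
#'   \code{n_pores}, \code{mean_pore_area_px2}, \code{mean_pore_area_um2},
#'   \code{mean_fiber_diameter_px}, \code{mean_fiber_diameter_um},
#'   \code{mask}.
#' @export
sem_morphology <- function(img, um_per_px = 1, Q = 32) {
  mask <- if (is.logical(img)) img else srm_binarize(img, Q = Q)
  ps <- pore_stats(mask, um_per_px)
  fd <- if (any(mask)) mean_fiber_diameter(mask, um_per_px = 1) else NA_real_
  structure(list(porosity_pct = porosity(mask),
                 n_pores = ps$n_pores,
                 mean_pore_area_px2 = ps$mean_pore_area_px2,
                 mean_pore_area_um2 = ps$mean_pore_area_um2,
                 mean_fiber_diameter_px = as.numeric(fd),
                 mean_fiber_diameter_um = as.numeric(fd) * um_per_px,
                 mask = mask),
            class = "sem_morphology")
}
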