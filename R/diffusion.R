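#' Normalized intensity curves at rectangular ROIs
#'
#' Measures the mean intensity inside each ROI per frame and normalizes it
#' so the pre-loading baseline maps to 0 and the source-channel plateau to
#' 1: \code{(I - I_baseline) / (I_plateau - I_baseline)}. The plateau is
#' the mean of the source ROI over the last 5\% of frames; when no ROI is
#' designated as source, the ROI with the highest final intensity is used.
#'
#' @param video nrow x ncol x n_frames array.
#' @param rois data.frame with columns \code{label}, \code{x}, \code{y},
#'   \code{w}, \code{h} (0-based px, x = column).
#' @param dt_s frame interval, seconds.
#' @param baseline_frames number of initial frames defining the baseline
#'   (>= 1).
#' @param source_label label of the source-channel ROI (optional).
#' @return class \code{roi_curves}: data.frame with \code{roi},
#'   \code{t_min}, \code{I_raw}, \code{I_norm}.
#' @export
roi_curves <- function(video, rois, dt_s = 5, baseline_frames = 1,
                       source_label = NULL) {
  if (baseline_frames < 1) stop("'baseline_frames' must be >= 1")
  nr <- dim(video)[1]; nc <- dim(video)[2]; nt <- dim(video)[3]
  raw <- sapply(seq_len(nrow(rois)), function(i) {
    r0 <- rois$y[i] + 1; c0 <- rois$x[i] + 1
    r1 <- r0 + rois$h[i] - 1; c1 <- c0 + rois$w[i] - 1
    if (r0 < 1 || c0 < 1 || r1 > nr || c1 > nc)
      stop(sprintf("ROI '%s' outside image bounds", rois$label[i]))
    apply(video[r0:r1, c0:c1, , drop = FALSE], 3, mean)
  })
  raw <- matrix(raw, nrow = nt)
  colnames(raw) <- rois$label
  tail_n <- max(1L, round(0.05 * nt))
  plateau_by_roi <- colMeans(raw[(nt - tail_n + 1):nt, , drop = FALSE])
  src <- if (!is.null(source_label)) {
    which(rois$label == source_label)[1]
  } else which.max(plateau_by_roi)
  base <- colMeans(raw[seq_len(baseline_frames), , drop = FALSE])
  plateau <- plateau_by_roi[src]
  if (abs(plateau - base[src]) < .Machine$double.eps^0.5)
    stop("zero dynamic range: source plateau equals the baseline")
  t_min <- (seq_len(nt) - 1) * dt_s / 60
  out <- do.call(rbind, lapply(seq_len(ncol(raw)), function(i)
    data.frame(roi = rois$label[i], t_min = t_min, I_raw = raw[, i],
               I_norm = (raw[, i] - base[i]) / (plateau - base[i]))))
  class(out) <- c("roi_curves", "data.frame")
  out
}

#' Half-rise time of a normalized intensity curve
#'
#' First linearly interpolated crossing of 0.5 by the normalized curve. A
#' curve that never reaches 0.5 within the record is right-censored: the
#' record length is returned with attribute \code{censored = TRUE}.
#'
#' @param curve data.frame with \code{t_min} and \code{I_norm} (one ROI).
#' @return half-rise time in minutes (attribute \code{censored}).
#' @export
half_rise_time <- function(curve) {
  t <- curve$t_min; y <- curve$I_norm
  above <- which(y >= 0.5)
  if (!length(above)) {
    out <- max(t)
    attr(out, "censored") <- TRUE
    return(out)
  }
  k <- above[1]
  out <- if (k == 1) t[1] else {
    t[k - 1] + (0.5 - y[k - 1]) / (y[k] - y[k - 1]) * (t[k] - t[k - 1])
  }
  attr(out, "censored") <- FALSE
  out
}

#' Effective diffusivity from an intensity curve
#'
#' Least-squares fit of the half-infinite one-dimensional diffusion
#' solution \code{I(t) = A * erfc(x / (2 * sqrt(D * t)))} to a normalized
#' ROI curve at known distance \code{x_um} from the source boundary.
#' Start values come from the analytic half-rise inversion
#' \code{D0 = x^2 / (4 * t_half * erfcinv(0.5)^2)}.
#'
#' @param curve data.frame with \code{t_min} and \code{I_norm}.
#' @param x_um ROI distance from the source boundary, um (> 0).
#' @param resid_threshold RMS residual above which the fit is flagged
#'   unreliable.
#' @return list with \code{D_um2_s}, \code{A}, \code{rms_resid},
#'   \code{reliable}.
#' @export
fit_effective_D <- function(curve, x_um, resid_threshold = 0.05) {
  if (x_um <= .Machine$double.eps)
    stop("degenerate fit: no spatial lag (x = 0)")
  t_s <- curve$t_min * 60
  y <- curve$I_norm
  keep <- t_s > 0
  t_s <- t_s[keep]; y <- y[keep]
  if (length(t_s) < 10) stop("need >= 10 time points")
  hr <- half_rise_time(curve)
  z <- pracma::erfcinv(0.5)
  d0 <- x_um^2 / (4 * max(hr * 60, min(diff(t_s))) * z^2)
  df <- data.frame(t = t_s, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ A * pracma::erfc(x_um / (2 * sqrt(D * t))),
    data = df, start = list(A = max(max(y), 0.5), D = d0),
    lower = c(1e-6, 1e-9), control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  rms <- sqrt(mean(stats::residuals(fit)^2))
  list(D_um2_s = unname(cf["D"]), A = unname(cf["A"]),
       rms_resid = rms, reliable = rms <= resid_threshold)
}
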