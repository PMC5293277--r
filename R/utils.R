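# shared internal helpers

# Otsu threshold of a numeric vector: maximizes between-class variance over
# a histogram with `levels` bins. Returns a threshold value; the upper class
# is x > threshold.
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = levels)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[levels]; mt <- m[levels]
  w1 <- w[-levels]; m1 <- m[-levels]
  valid <- w1 > 0 & w1 < n
  bcv <- rep(-Inf, levels - 1L)
  bcv[valid] <- (mt * w1[valid] - n * m1[valid])^2 /
    (w1[valid] * (n - w1[valid]))
  breaks[which.max(bcv) + 1L]
}

# rescale to [0, 1]; constant input maps to 0
rescale01 <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) return(x * 0)
  (x - rng[1]) / diff(rng)
}

# index shift of a matrix filling with `fill`; (dr, dc) moves content
# down/right for positive values
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
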