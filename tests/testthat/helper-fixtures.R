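# fixtures and independent oracles shared across the suite

ribbon_mask <- function(nr = 40, nc = 120, row0 = 18, w = 5, col0 = 11,
                        len = 100) {
  m <- matrix(FALSE, nr, nc)
  m[row0:(row0 + w - 1), col0:(col0 + len - 1)] <- TRUE
  m
}

cross_mask <- function(n = 101, w = 5, margin = 6) {
  m <- matrix(FALSE, n, n)
  mid <- (n - w + 1) %/% 2 + 1
  m[mid:(mid + w - 1), margin:(n - margin)] <- TRUE
  m[margin:(n - margin), mid:(mid + w - 1)] <- TRUE
  m
}

# orthogonal fiber grid aligned so every background cell is a full
# (d - w) x (d - w) square (no margin corridors)
grid_fiber_mask <- function(d, w, cells = 4) {
  n <- cells * d + w
  m <- matrix(FALSE, n, n)
  for (k in seq(1, cells * d + 1, d)) {
    m[k:(k + w - 1), ] <- TRUE
    m[, k:(k + w - 1)] <- TRUE
  }
  m
}

# exhaustive Chan-Vese minimum over every mask of a small image; energies
# evaluated with the package's own (public) energy so both routes share
# the discretization, but the minimization here is brute force
brute_min_cv_energy <- function(img, params) {
  n <- length(img)
  stopifnot(n <= 16)
  best <- Inf
  for (k in 0:(2^n - 1)) {
    mask <- matrix(bitwAnd(k, 2^(seq_len(n) - 1)) > 0, nrow(img))
    best <- min(best, chan_vese_energy(img, mask, params))
  }
  best
}

# minimum-total-distance one-to-one assignment by enumeration
brute_best_assignment <- function(dmat) {
  n <- nrow(dmat)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cost <- sum(dmat[cbind(seq_len(n), p)])
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  list(assignment = best, cost = best_cost)
}
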