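# smooth, rotation-symmetric fiber: Gaussian cross-section profile so the
# fixture itself carries no axis-aligned aliasing
smooth_fiber <- function(angle, n = 101, sigma = 1.5, half_len = 40) {
  c0 <- (n + 1) / 2
  i <- matrix(seq_len(n), n, n)
  j <- matrix(seq_len(n), n, n, byrow = TRUE)
  dperp <- (i - c0) * cos(angle) + (j - c0) * sin(angle)
  dal <- -(i - c0) * sin(angle) + (j - c0) * cos(angle)
  exp(-dperp^2 / (2 * sigma^2)) * (abs(dal) <= half_len)
}

test_that("steerable ridge response is strong, centred and steerable", {
  img <- smooth_fiber(0)
  r <- enhance_fibers(img, 1.5, 1)
  # response at the centreline dominates flat background
  expect_gt(max(r), 5 * max(abs(r[1:20, 1:20])))
  # per-column argmax tracks the centreline within 1 px
  mid_cols <- 31:71
  rows <- apply(r[, mid_cols], 2, which.max)
  expect_true(all(abs(rows - 51) <= 1))
  # rotation invariance across 0/45/90 degrees
  resp <- vapply(c(0, pi / 4, pi / 2), function(a)
    max(enhance_fibers(smooth_fiber(a), 1.5, 1)), numeric(1))
  expect_lt((max(resp) - min(resp)) / mean(resp), 0.02)
  # blank input: flat response
  expect_lt(diff(range(enhance_fibers(matrix(0.3, 50, 50), 2, 1))), 1e-9)
  expect_error(enhance_fibers(img, 0.5, 1))
})

test_that("local Otsu survives gradients where global Otsu breaks", {
  set.seed(5)
  n <- 128
  truth <- matrix(FALSE, n, n)
  for (k in seq(10, 120, 25)) truth[k:(k + 2), ] <- TRUE
  grad <- matrix(rep(seq(0, 0.8, length.out = n), each = n), n, n)
  img <- grad + 0.3 * truth + matrix(rnorm(n * n, 0, 0.01), n)
  gm <- img > scaffoldtrack:::otsu_threshold(img)
  lm <- local_otsu_binarize(img, window = 31)
  expect_lt(sum(gm & truth) / sum(truth), 0.9)   # global breaks the fibers
  expect_gte(sum(lm & truth) / sum(truth), 0.99)

  # exact recovery of a clean two-level scene
  two <- matrix(0.2, 64, 64); two[20:40, 10:50] <- 0.8
  expect_identical(unname(local_otsu_binarize(two, 31)),
                   unname(two > 0.5))

  # noise-only image stays (almost) empty
  blank <- matrix(rnorm(128 * 128, 0.2, 0.05), 128)
  expect_lte(mean(local_otsu_binarize(blank, 31)), 0.01)
  expect_error(local_otsu_binarize(two, 30))
})

test_that("FIRE extraction resolves ribbons, crossings and gaps", {
  net <- fire_extract(ribbon_mask(), pixel_size = 1, min_fiber_len = 5)
  expect_length(net$chains, 1)
  ch <- net$chains[[1]]
  # endpoints within 3 px of the ribbon ends (cols 10..109, 0-based)
  expect_lt(abs(ch[1, 1] - 10), 3.5)
  expect_lt(abs(ch[nrow(ch), 1] - 109), 3.5)
  expect_true(all(net$mask[net$skeleton]))  # skeleton stays inside mask

  # crossing ribbons: split policy yields 4 chains at 1 junction,
  # reconnection policy 2 chains
  cm <- cross_mask()
  net <- fire_extract(cm, 1, min_fiber_len = 5)
  expect_length(net$chains, 4)
  expect_equal(net$n_junctions, 1)
  net2 <- fire_extract(cm, 1, min_fiber_len = 5, reconnect = TRUE)
  expect_length(net2$chains, 2)

  # disjoint parallel ribbons never bridge
  m <- matrix(FALSE, 60, 120)
  m[10:14, 11:110] <- TRUE
  m[40:44, 11:110] <- TRUE
  net <- fire_extract(m, 1, min_fiber_len = 5)
  expect_length(net$chains, 2)
  rows <- vapply(net$chains, function(ch) mean(ch[, 2]), numeric(1))
  expect_equal(sort(rows), c(11, 41), tolerance = 1)

  expect_length(fire_extract(matrix(FALSE, 10, 10), 1)$chains, 0)
})

test_that("fiber length aggregates calibrated gaps", {
  expect_equal(fiber_length(cbind(c(0, 3), c(0, 4))), 5)
  # digitized 45-degree chain of 11 pixel-adjacent points at 0.099 um/px
  ch <- cbind(0:10, 0:10) * 0.099
  expect_equal(fiber_length(ch), 10 * sqrt(2) * 0.099, tolerance = 1e-12)
  # closed square loop: perimeter
  sq <- cbind(c(0, 4, 4, 0, 0), c(0, 0, 4, 4, 0))
  expect_equal(fiber_length(sq), 16)
})

test_that("persistence estimation matches oracle fits and flags limits", {
  straight <- cbind(seq(0, 30, 0.5), 0)
  lp <- fiber_persistence(straight)
  expect_true(attr(lp, "infinite"))

  # circular arc: C(s) = cos(s / R); assert against an independent
  # brute-force grid minimizer of the same least-squares objective
  R <- 8
  th <- seq(0, 2.5, by = 0.5 / R)
  arc <- cbind(R * cos(th), R * sin(th))
  lp <- as.numeric(fiber_persistence(arc, fit_range = 6))
  svals <- seq(0.5, 6, 0.5)
  cvals <- cos(svals / R)
  grid <- 10^seq(-2, 6, length.out = 20001)
  sse <- vapply(grid, function(g)
    sum((cvals - exp(-svals / (2 * g)))^2), numeric(1))
  oracle <- grid[which.min(sse)]
  expect_equal(lp, oracle, tolerance = 0.05)

  # generator round trip at Lp = 10 um
  set.seed(22)
  est <- replicate(200, {
    ch <- sample_fiber_chain(10, 40, 0.5)
    as.numeric(fiber_persistence(ch, fit_range = 10))
  })
  expect_gte(median(est), 10 * 0.5)
  expect_lte(median(est), 10 * 2)
})

test_that("covering-radius pore sizing matches analytic geometry", {
  # lone disk pore: max covering radius = disk radius
  mk <- matrix(TRUE, 80, 80)
  xy <- as.matrix(expand.grid(1:80, 1:80))
  mk[xy[(xy[, 1] - 40)^2 + (xy[, 2] - 40)^2 <= 15^2, ]] <- FALSE
  pd <- pore_sizes(mk, 1)
  expect_equal(max(pd$radius_um), 15, tolerance = 1)

  # orthogonal grid: modal covering diameter = spacing - width
  pd <- pore_sizes(grid_fiber_mask(30, 6), 1)
  expect_equal(pd$summary$modal_diameter_um, 24, tolerance = 2)

  # full background: border-limited to half the short side
  pd <- pore_sizes(matrix(FALSE, 60, 80), 1)
  expect_equal(max(pd$radius_um), 30, tolerance = 1)
  expect_true(any(pd$border_limited))

  # all-fiber mask: empty distribution
  pd <- pore_sizes(matrix(TRUE, 30, 30), 1)
  expect_length(pd$radius_um, 0)

  # adding fibers never increases the maximum covering radius
  m <- matrix(FALSE, 100, 100); m[45:50, ] <- TRUE
  r1 <- max(pore_sizes(m, 1)$radius_um)
  m[, 45:50] <- TRUE
  r2 <- max(pore_sizes(m, 1)$radius_um)
  expect_lte(r2, r1)
})

test_that("recovered total fiber length tracks the ground truth", {
  set.seed(31)
  chains <- lapply(1:6, function(i)
    sample_fiber_chain(20, 35, 0.5, origin = runif(2, 8, 40)))
  sf <- render_fiber_image(chains, width = 1.0, shape = c(256, 256),
                           pixel_size = 0.2, blur_sigma = 1,
                           noise_sigma = 0.03, seed = 32)
  enh <- enhance_fibers(sf$image, 0.4, 0.2)
  mk <- local_otsu_binarize(enh, window = 31)
  net <- fire_extract(mk, 0.2, min_fiber_len = 2, reconnect = TRUE)
  tot_est <- sum(vapply(net$chains, fiber_length, numeric(1)))
  tot_truth <- sum(vapply(chains, function(ch)
    sum(sqrt(rowSums(diff(ch)^2))), numeric(1)))
  expect_equal(tot_est, tot_truth, tolerance = 0.10)
})

test_that("pore radii scale linearly with the pixel size", {
  m <- grid_fiber_mask(24, 4)
  p1 <- pore_sizes(m, 1)$summary$modal_diameter_um
  p2 <- pore_sizes(m, 0.099)$summary$modal_diameter_um
  expect_equal(p2, p1 * 0.099, tolerance = 1e-12)
})
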