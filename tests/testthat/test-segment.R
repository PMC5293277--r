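test_that("CLAHE handles flat, two-level and low-contrast inputs", {
  flat <- matrix(0.4, 64, 64)
  out <- clahe_enhance(flat, tile = 16)
  expect_true(attr(out, "flat"))
  expect_equal(as.vector(out), as.vector(flat))

  set.seed(61)
  two <- matrix(sample(c(0.2, 0.6), 128 * 128, TRUE), 128)
  out <- clahe_enhance(two, tile = 32)
  expect_length(unique(as.vector(out)), 2)
  expect_true(all(out[two == 0.6] > max(out[two == 0.2])))

  blob <- matrix(0.5, 128, 128)
  xs <- 54:74
  blob[xs, xs] <- blob[xs, xs] +
    outer(exp(-(xs - 64)^2 / 18), exp(-(xs - 64)^2 / 18)) * 5 / 255
  out <- clahe_enhance(blob, tile = 32, clip_limit = 0.01)
  expect_gte(diff(range(out)) / (5 / 255), 10)

  expect_error(clahe_enhance(blob, tile = 4))
  expect_error(clahe_enhance(blob, clip_limit = 0))
})

test_that("graph cut equals the exhaustive Chan-Vese minimum on 3x3 grids", {
  # spot-check a deterministic sample here; the full enumeration over the
  # whole {0,1,2}^9 grid runs in the acceptance suite
  p <- chan_vese_params(lambda1 = 1, lambda2 = 1, mu = 0.5,
                        c1 = 2, c2 = 0)
  set.seed(70)
  for (i in 1:25) {
    img <- matrix(sample(0:2, 9, TRUE), 3, 3)
    m <- chan_vese_graphcut(img, p)
    expect_equal(chan_vese_energy(img, m, p), brute_min_cv_energy(img, p),
                 tolerance = 1e-9)
  }
})

test_that("two-value images split exactly with mu = 0", {
  img <- matrix(20, 8, 8)
  img[3:5, 2:7] <- 200
  p <- chan_vese_params(c1 = 200, c2 = 20, mu = 0)
  m <- chan_vese_graphcut(img, p)
  expect_identical(matrix(as.logical(m), 8), unname(img == 200))
})

test_that("degenerate constant frames resolve to all-background", {
  m <- chan_vese_graphcut(matrix(1, 6, 6), chan_vese_params())
  expect_false(any(m))
  expect_true(attr(m, "converged"))
})

test_that("segmentation is invariant to intensity shifts of image + means", {
  set.seed(62)
  img <- matrix(runif(100), 10, 10)
  m1 <- chan_vese_graphcut(img, chan_vese_params(c1 = .8, c2 = .2, mu = .3))
  m2 <- chan_vese_graphcut(img + 1,
                           chan_vese_params(c1 = 1.8, c2 = 1.2, mu = .3))
  expect_identical(matrix(as.logical(m1), 10), matrix(as.logical(m2), 10))
})

test_that("stronger boundary weight never lengthens the boundary", {
  set.seed(63)
  img <- matrix(runif(144), 12, 12)
  blen <- function(m)
    sum(m != rbind(m[-1, ], FALSE)) + sum(m != cbind(m[, -1], FALSE))
  bl <- vapply(c(0, 0.05, 0.2, 0.5, 1), function(mu) {
    blen(chan_vese_graphcut(img, chan_vese_params(c1 = .8, c2 = .2,
                                                  mu = mu)))
  }, numeric(1))
  expect_true(all(diff(bl) <= 0))
})

test_that("labeling uses 8-connectivity and honours min_area", {
  empty <- label_cells(matrix(FALSE, 10, 10))
  expect_equal(nrow(empty$detections), 0)

  m <- matrix(FALSE, 20, 20)
  m[3:7, 3:7] <- TRUE
  m[12:16, 12:16] <- TRUE
  lf <- label_cells(m, min_area = 5)
  expect_equal(nrow(lf$detections), 2)
  expect_equal(lf$detections$x_px, c(4, 13))  # 0-based centroids
  expect_equal(lf$detections$y_px, c(4, 13))
  expect_equal(lf$detections$area_px2, c(25, 25))

  # diagonal 1-px bridge joins the squares under 8-connectivity
  m[8, 8] <- TRUE; m[9, 9] <- TRUE; m[10, 10] <- TRUE; m[11, 11] <- TRUE
  lf <- label_cells(m, min_area = 5)
  expect_equal(nrow(lf$detections), 1)

  lf <- label_cells(m, min_area = 100)
  expect_equal(nrow(lf$detections), 0)
})

test_that("survival delta is last minus first", {
  a <- label_cells(matrix(FALSE, 5, 5))
  expect_equal(count_survival(a, a), 0)
  expect_equal(count_survival(10, 9), -1)
  expect_equal(count_survival(9, 10), 1)
  m1 <- matrix(FALSE, 30, 30); m1[2:4, 2:4] <- TRUE; m1[10:12, 10:12] <- TRUE
  m2 <- matrix(FALSE, 30, 30); m2[2:4, 2:4] <- TRUE
  expect_equal(count_survival(label_cells(m1, 4), label_cells(m2, 4)), -1)
})
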