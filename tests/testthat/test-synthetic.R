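test_that("zero-speed and fully persistent walks are degenerate limits", {
  m0 <- motility_model("isotropic_rw", step_speed = 0, n_frames = 10,
                       seed = 1)
  tr <- sample_track(m0, origin = c(3, 4))
  expect_equal(nrow(tr), 10)
  expect_true(all(tr$x == 3) && all(tr$y == 4))

  m1 <- motility_model("persistent_rw", step_speed = 4, persistence = 1,
                       n_frames = 20, seed = 2)
  tr <- sample_track(m1)
  steps <- cbind(diff(tr$x), diff(tr$y))
  expect_equal(accumulated_distance(tr), 19 * 4 * 15 / 60, tolerance = 1e-10)
  # collinear: all steps identical
  expect_lt(max(abs(sweep(steps, 2, steps[1, ]))), 1e-10)
})

test_that("isotropic walk matches law-of-large-numbers expectations", {
  m <- motility_model("isotropic_rw", step_speed = 4, frame_interval = 15,
                      n_frames = 10001, seed = 7)
  tr <- sample_track(m)
  steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  expect_equal(mean(steps), 1, tolerance = 0.01)  # 4 um/hr * 0.25 hr
  drift <- sqrt(tail(tr$x, 1)^2 + tail(tr$y, 1)^2) / length(steps)
  expect_lt(drift, 0.05)
})

test_that("model invariants are enforced and ratio 1 reduces to isotropic", {
  expect_error(motility_model("isotropic_rw", 4, persistence = 0.5))
  expect_error(motility_model("anisotropic_rw", 4,
                              anisotropy_axis = c(1, 1)))
  expect_error(motility_model("anisotropic_rw", 4, anisotropy_ratio = 0.5))
  m <- motility_model("anisotropic_rw", step_speed = 4,
                      anisotropy_ratio = 1, n_frames = 5001, seed = 3)
  tr <- sample_track(m)
  steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  expect_equal(mean(steps), 1, tolerance = 0.02)
  expect_equal(sd(steps), 0, tolerance = 1e-9)  # isotropic: fixed length
})

test_that("fixed seeds reproduce tracks and videos bit-exactly", {
  m <- motility_model("persistent_rw", 4.37, persistence = 0.5,
                      n_frames = 20, seed = 11)
  expect_identical(sample_track(m), sample_track(m))
  tr <- list(sample_track(m, origin = c(30, 30)))
  v1 <- render_video(tr, shape = c(64, 64), seed = 5)
  v2 <- render_video(tr, shape = c(64, 64), seed = 5)
  expect_identical(v1$video, v2$video)
})

test_that("rendered blobs sit at truth positions and add linearly", {
  tr1 <- list(data.frame(frame = 0:4, x = rep(26, 5), y = rep(39, 5)))
  v <- render_video(tr1, shape = c(64, 64), pixel_size = 1.3,
                    noise_sigma = 0, seed = 1)
  for (t in 1:5) {
    peak <- which(v$video[, , t] == max(v$video[, , t]), arr.ind = TRUE)
    expect_equal(unname(peak[1, ]), c(31, 21))  # (row, col) = y,x px + 1
  }
  tr2 <- list(tr1[[1]], data.frame(frame = 0:4, x = rep(52, 5),
                                   y = rep(13, 5)))
  v2 <- render_video(tr2, shape = c(64, 64), pixel_size = 1.3,
                     noise_sigma = 0, seed = 1)
  int1 <- sum(v$video[, , 1] - v$background_level)
  int2 <- sum(v2$video[, , 1] - v2$background_level)
  expect_equal(int2, 2 * int1, tolerance = 0.01)
})

test_that("close truth positions raise the overlap warning", {
  tr <- list(data.frame(frame = 0:1, x = c(26, 26), y = c(26, 26)),
             data.frame(frame = 0:1, x = c(26.5, 26.5), y = c(26, 26)))
  expect_warning(render_video(tr, shape = c(48, 48), pixel_size = 1,
                              noise_sigma = 0), "closer than 1 px")
})

test_that("worm-like chains have the prescribed tangent decorrelation", {
  # E[cos(theta(s) - theta(0))] = exp(-s / (2 Lp)); Lp = 10, s = 20
  set.seed(21)
  v <- replicate(2000, {
    ch <- sample_fiber_chain(10, 20.5, 0.5)
    seg <- diff(ch)
    th <- atan2(seg[, 2], seg[, 1])
    cos(th[41] - th[1])
  })
  expect_equal(mean(v), exp(-1), tolerance = 0.03 / exp(-1))

  ch <- sample_fiber_chain(Inf, 50, 0.5, init_angle = 0)
  expect_equal(nrow(ch), 101)
  gaps <- sqrt(rowSums(diff(ch)^2))
  expect_equal(unname(gaps), rep(0.5, 100), tolerance = 1e-12)
  expect_equal(unname(ch[101, ]), c(50, 0), tolerance = 1e-9)
  expect_error(sample_fiber_chain(-5, 10))
  expect_error(sample_fiber_chain(10, 0))
})

test_that("fiber rasterization produces consistent truth masks", {
  ch <- list(cbind(seq(2, 21.8, 0.2), rep(8, 100)))
  sf <- render_fiber_image(ch, width = 1, shape = c(80, 120),
                           pixel_size = 0.2, noise_sigma = 0)
  expect_true(all(sf$mask[41, 11:110]))      # centreline row covered
  area <- sum(sf$mask)
  expect_lt(abs(area - 100 * 5), 2 * 5^2)    # 100 px x 5 px wide + caps
  # noise-free render thresholded at half contrast recovers the mask up
  # to a 1-px boundary band
  half <- sf$image > 0.5 * max(sf$image)
  core <- sf$mask & !EBImage::dilate(!sf$mask + 0,
                                     EBImage::makeBrush(3, "box")) > 0
  expect_true(all(half[core]))
  expect_error(render_fiber_image(ch, width = 0.1, pixel_size = 0.2))
  blank <- render_fiber_image(list(), width = 1, shape = c(40, 40),
                              pixel_size = 0.2)
  expect_equal(sum(blank$mask), 0)
})

test_that("diffusion series follows the erfc solution", {
  ds <- render_diffusion_series(D = 100, C0 = 1, length_um = 300,
                                pixel_size = 2, dt_s = 5, n_frames = 50,
                                n_rows = 4)
  # x = 0 column sits at C0/2 for every t > 0
  expect_equal(unname(ds$video[1, 1, 2:50]), rep(0.5, 49),
               tolerance = 1e-12)
  # t -> infinity limit approaches C0/2 everywhere
  far <- render_diffusion_series(D = 100, C0 = 1, length_um = 100,
                                 pixel_size = 2, dt_s = 1e9, n_frames = 2,
                                 n_rows = 2)
  expect_true(all(abs(far$video[, , 2] - 0.5) < 1e-3))
  expect_error(render_diffusion_series(D = -1))
})

test_that("origin sampler enforces the minimum spacing", {
  set.seed(9)
  pts <- sample_origins(20, c(0, 200, 0, 200), min_spacing = 30)
  expect_gte(min(dist(pts)), 30)
  expect_error(sample_origins(100, c(0, 50, 0, 50), min_spacing = 30))
})
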