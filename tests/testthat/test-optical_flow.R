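test_that("gradients reproduce analytic and brute-force stencils", {
  m <- matrix(runif(81), 9, 9)
  g0 <- spatial_temporal_gradients(m, m)
  expect_true(all(g0$It == 0))

  ramp <- matrix(rep(1:9, each = 9), 9, 9)  # I(x) = x: value = column index
  gr <- spatial_temporal_gradients(ramp, ramp)
  expect_equal(gr$Ix[, 2:8], matrix(1, 9, 7))
  expect_true(all(gr$It == 0))

  set.seed(7)
  a <- matrix(runif(81), 9, 9); b <- matrix(runif(81), 9, 9)
  g <- spatial_temporal_gradients(a, b)
  avg <- (a + b) / 2
  for (i in 1:9) for (j in 1:9) {
    jm <- max(1, j - 1); jp <- min(9, j + 1)
    im <- max(1, i - 1); ip <- min(9, i + 1)
    expect_equal(g$Ix[i, j], (avg[i, jp] - avg[i, jm]) / 2)
    expect_equal(g$Iy[i, j], (avg[ip, j] - avg[im, j]) / 2)
    expect_equal(g$It[i, j], b[i, j] - a[i, j])
  }
  expect_error(spatial_temporal_gradients(a, matrix(0, 3, 3)), "identical")
})

test_that("degenerate structure tensors are flagged invalid, not solved", {
  z <- matrix(0, 11, 11)
  s <- solve_lk_pixel(z, z, z, c(6, 6))
  expect_false(s$valid)
  expect_identical(c(s$vx, s$vy), c(0, 0))

  # aperture problem: gradient only along x -> rank-1 tensor
  ap <- solve_lk_pixel(matrix(1, 11, 11), z, matrix(-0.5, 11, 11), c(6, 6),
                       flow_params(window_radius = 2, eigenvalue_min = 1e-12))
  expect_false(ap$valid)
  expect_identical(c(ap$vx, ap$vy), c(0, 0))
})

test_that("the pixel solve matches an independent least-squares minimizer", {
  set.seed(42)
  for (kernel in c("gaussian", "uniform")) {
    p <- flow_params(window_radius = 2, weight_kernel = kernel,
                     eigenvalue_min = 1e-9, smoothing_sigma = 0)
    for (rep in 1:25) {
      Ix <- matrix(rnorm(25), 5, 5); Iy <- matrix(rnorm(25), 5, 5)
      It <- matrix(rnorm(25), 5, 5)
      s <- solve_lk_pixel(Ix, Iy, It, c(3, 3), p)
      expect_true(s$valid)
      o <- lk_oracle_lm(Ix, Iy, It, p)
      expect_lt(max(abs(c(s$vx, s$vy) - o)), 1e-8)
    }
  }
})

test_that("dense flow agrees with the per-pixel reference solve", {
  set.seed(3)
  a <- matrix(runif(900), 30, 30) * 0.5
  b <- pmax(a + matrix(rnorm(900, 0, 0.02), 30, 30), 0)
  # normalize so the dense path's internal rescaling is a no-op
  peak <- max(a, b); a <- a / peak; b <- b / peak
  p <- flow_params(window_radius = 3, smoothing_sigma = 0)
  fl <- compute_flow(a, b, p)
  g <- spatial_temporal_gradients(a, b, 0)
  for (px in list(c(7, 9), c(15, 15), c(2, 28), c(30, 1))) {
    s <- solve_lk_pixel(g$Ix, g$Iy, g$It, px, p)
    expect_equal(fl$vx[px[1], px[2]], s$vx, tolerance = 1e-10)
    expect_equal(fl$vy[px[1], px[2]], s$vy, tolerance = 1e-10)
    expect_identical(fl$valid[px[1], px[2]], s$valid)
  }
})

test_that("identical and featureless frame pairs give null flow", {
  set.seed(11)
  a <- matrix(runif(400), 20, 20)
  fl <- compute_flow(a, a)
  expect_true(all(fl$vx == 0) && all(fl$vy == 0))
  expect_true(any(fl$valid))  # texture exists, flow is solvable and zero
  fu <- compute_flow(matrix(1, 20, 20), matrix(1, 20, 20))
  expect_false(any(fu$valid))
})

test_that("a known 1 px shift is recovered and negates with frame order", {
  a <- blob_frame(20, 20); b <- blob_frame(20, 21)
  p <- flow_params(smoothing_sigma = 0)
  fl <- compute_flow(a, b, p)
  expect_lt(abs(median(fl$vx[fl$valid]) - 1), 0.25)
  expect_lt(abs(median(fl$vy[fl$valid])), 0.25)
  rev <- compute_flow(b, a, p)
  expect_lt(abs(median(fl$vx[fl$valid]) + median(rev$vx[rev$valid])), 0.1)
  expect_lt(abs(median(fl$vy[fl$valid]) + median(rev$vy[rev$valid])), 0.1)
})

test_that("translating both frames translates the valid-flow pattern", {
  a <- blob_frame(15, 14, sigma = 2, m = 32, n = 32)
  b <- blob_frame(15, 15, sigma = 2, m = 32, n = 32)
  p <- flow_params(window_radius = 3, smoothing_sigma = 0)
  f1 <- compute_flow(a, b, p)
  f2 <- compute_flow(shift_mat(a, 4, 6), shift_mat(b, 4, 6), p)
  core <- 12:20  # interior rows/cols of the blob, away from both borders
  expect_equal(f2$valid[core + 4, core + 6], f1$valid[core, core])
  expect_equal(f2$vx[core + 4, core + 6], f1$vx[core, core], tolerance = 1e-8)
  expect_equal(f2$vy[core + 4, core + 6], f1$vy[core, core], tolerance = 1e-8)
})

test_that("a flow series decomposes into independent pair solves", {
  set.seed(15)
  frames <- array(runif(4 * 16 * 16), c(4, 16, 16))
  st <- image_stack(frames)
  p <- flow_params(window_radius = 2, smoothing_sigma = 0)
  series <- compute_flow_series(st, p)
  expect_length(series, 3)
  for (k in 1:3)
    expect_equal(series[[k]],
                 compute_flow(frames[k, , ], frames[k + 1, , ], p))
  static <- image_stack(aperm(array(frames[1, , ], c(16, 16, 5)), c(3, 1, 2)))
  sser <- compute_flow_series(static, p)
  expect_length(sser, 4)
  expect_true(all(vapply(sser, function(f) all(f$vx == 0) && all(f$vy == 0), TRUE)))
  expect_error(compute_flow_series(image_stack(array(1, c(2, 4, 4)))[["frames"]]),
               "image_stack")
})
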