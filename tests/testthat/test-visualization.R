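test_that("diverging encoding maps delta linearly with exact endpoints", {
  d <- seq(0, pi, length.out = 101)
  expect_equal(diverging_position(d), d / pi)
  ctr <- c(6, 6)
  # three hand-built pixels with delta 0, pi and pi/2
  vx <- matrix(0, 11, 11); vy <- matrix(0, 11, 11)
  valid <- matrix(FALSE, 11, 11)
  vx[6, 3] <- 1;  valid[6, 3] <- TRUE    # toward center: delta 0
  vx[6, 9] <- 1;  valid[6, 9] <- TRUE    # away from center: delta pi
  vx[3, 6] <- 1;  valid[3, 6] <- TRUE    # tangential: delta pi/2
  dm <- direction_map(make_flow(vx, vy, valid), ctr)
  img <- render_diverging(dm, render_config())
  expect_equal(img[6, 3, ], c(1, 0, 0))        # red extreme
  expect_equal(img[6, 9, ], c(0, 0, 1))        # blue extreme
  expect_equal(img[3, 6, ], c(1, 1, 1))        # neutral midpoint
  # excluded pixels take the background color
  expect_equal(img[1, 1, ], c(0, 0, 0))
})

test_that("HSV rendering encodes angle as hue and magnitude as saturation", {
  vx <- matrix(0, 5, 5); vy <- matrix(0, 5, 5)
  valid <- matrix(TRUE, 5, 5)
  vx[2, 2] <- 0.5            # angle 0
  vx[2, 4] <- -0.5           # angle pi: opposite direction
  fl <- make_flow(vx, vy, valid)
  cfg <- render_config(colormap = "hsv", magnitude_ceiling = 1)
  img <- render_hsv(fl, cfg)
  # zero-magnitude valid pixel is achromatic
  expect_equal(img[1, 1, ], c(1, 1, 1))
  # equal magnitude, opposite direction: same saturation, hues 180 apart
  h1 <- grDevices::rgb2hsv(matrix(img[2, 2, ] * 255, 3, 1),
                           maxColorValue = 255)
  h2 <- grDevices::rgb2hsv(matrix(img[2, 4, ] * 255, 3, 1),
                           maxColorValue = 255)
  expect_equal(h1[2], h2[2])
  expect_equal(abs(h1[1] - h2[1]), 0.5, tolerance = 1e-9)
})

test_that("the HSV encoding round-trips angle and clipped magnitude", {
  set.seed(44)
  vx <- matrix(rnorm(400), 20, 20); vy <- matrix(rnorm(400), 20, 20)
  fl <- make_flow(vx, vy)
  cfg <- render_config(colormap = "hsv", magnitude_ceiling = 2)
  img <- render_hsv(fl, cfg)
  dec <- decode_hsv(img, fl$valid, cfg)
  ang <- atan2(vy, vx)[fl$valid]
  mag <- pmin(sqrt(vx^2 + vy^2)[fl$valid], 2)
  dwrap <- abs(dec$angle - ang)
  dwrap <- pmin(dwrap, 2 * pi - dwrap)
  expect_lt(max(dwrap), 1e-6)
  expect_lt(max(abs(dec$magnitude - mag)), 1e-6)
})

test_that("HSV and diverging renders background the same pixel set", {
  set.seed(45)
  vx <- matrix(rnorm(100), 10, 10); vy <- matrix(rnorm(100), 10, 10)
  valid <- matrix(runif(100) > 0.4, 10, 10)
  fl <- make_flow(vx, vy, valid)
  ctr <- c(5.4, 5.6)  # off-grid: no pixel sits exactly at the center
  dm <- direction_map(fl, ctr, magnitude_min = 0)
  cfg <- render_config(background_color = "black")
  hsv_img <- render_hsv(fl, render_config(colormap = "hsv"))
  div_img <- render_diverging(dm, cfg)
  is_bg <- function(img) img[, , 1] == 0 & img[, , 2] == 0 & img[, , 3] == 0
  # hue 0 with positive saturation can never be pure black (value = 1)
  expect_identical(is_bg(hsv_img), is_bg(div_img))
  expect_identical(is_bg(hsv_img), !valid)
})

test_that("summary panels render to a non-empty file with gaps for NA", {
  ctr <- c(6, 6)
  dm <- direction_map(radial_flow(11, 11, ctr, -1), ctr)
  zero <- make_flow(matrix(0, 11, 11), matrix(0, 11, 11),
                    valid = matrix(FALSE, 11, 11))
  s <- summarize_series(list(dm, direction_map(zero, ctr), dm))
  expect_true(is.na(s$prop_inward[2]))
  f <- file.path(tempdir(), "panels.png")
  render_summary_panels(s, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_error(render_summary_panels(s[0, ], f), "empty")
})
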