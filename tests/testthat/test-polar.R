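test_that("the R = 0 row equals the interpolated center value", {
  set.seed(31)
  img <- matrix(runif(41 * 41), 41, 41)
  ctr <- c(21.3, 20.6)
  p <- to_polar(img, ctr, n_r = 10, n_theta = 16, r_max = 12)
  ctr_val <- vesicleflow:::sample_bilinear(img, ctr[1], ctr[2])
  expect_equal(p$values[1, ], rep(ctr_val, 16))
  pn <- to_polar(img, ctr, n_r = 10, n_theta = 16, r_max = 12,
                 interpolation = "nearest")
  expect_equal(pn$values[1, ], rep(img[21, 21], 16))
})

test_that("a centered disk maps to a radial step for every angle", {
  n <- 51; ctr <- c(26, 26); rho <- 15
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  disk <- 1 * (((rows - ctr[1])^2 + (cols - ctr[2])^2) <= rho^2)
  p <- to_polar(disk, ctr, n_r = 25, n_theta = 36, r_max = 24)
  inner <- p$r < rho - 1; outer <- p$r > rho + 1
  expect_true(all(p$values[inner, ] == 1))
  expect_true(all(p$values[outer, ] == 0))
})

test_that("radially symmetric images give theta-constant polar rows", {
  n <- 61; ctr <- c(31, 31)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  img <- exp(-((rows - ctr[1])^2 + (cols - ctr[2])^2) / 800)
  p <- to_polar(img, ctr, n_r = 25, n_theta = 48, r_max = 24,
                interpolation = "bilinear")
  spread <- apply(p$values, 1, function(v) diff(range(v)))
  expect_true(all(spread <= 1e-3))
})

test_that("rotating the input by 90 degrees cyclically shifts theta", {
  set.seed(37)
  n <- 31; ctr <- c(16, 16)
  img <- matrix(runif(n * n), n, n)
  # +90-degree rotation about the center in the y-down frame:
  # pixel (i, j) -> (j, 2c - i)
  rot <- img
  for (i in 1:n) for (j in 1:n) rot[j, 2 * 16 - i] <- img[i, j]
  n_theta <- 16
  p1 <- to_polar(img, ctr, n_r = 12, n_theta = n_theta, r_max = 13,
                 interpolation = "nearest")
  p2 <- to_polar(rot, ctr, n_r = 12, n_theta = n_theta, r_max = 13,
                 interpolation = "nearest")
  shift <- n_theta / 4
  expect_identical(p2$values[, ((seq_len(n_theta) - 1 + shift) %% n_theta) + 1],
                   p1$values)
})

test_that("categorical label planes resample without interpolation", {
  ctr <- c(11, 11)
  dm <- direction_map(radial_flow(21, 21, ctr, -1), ctr)
  pol <- to_polar_labels(dm, n_r = 8, n_theta = 24, r_max = 9)
  vals <- pol$label$values[!is.na(pol$label$values)]
  expect_true(all(vals %in% c("Inward", "Excluded")))
  expect_true("Inward" %in% vals)
  # labels split by the vertical diameter map to the matching theta bins
  lab <- matrix(1, 21, 21); lab[, 1:10] <- 2   # 1 right of center, 2 left
  pl <- to_polar(lab, ctr, n_r = 6, n_theta = 8, r_max = 9,
                 interpolation = "nearest")
  right <- pl$theta < pi / 2 | pl$theta > 3 * pi / 2   # +x half
  expect_true(all(pl$values[-1, right] == 1))
  left <- pl$theta > pi / 2 & pl$theta < 3 * pi / 2
  expect_true(all(pl$values[-1, left] == 2))
  # excluded stays excluded
  zero <- make_flow(matrix(0, 21, 21), matrix(0, 21, 21),
                    valid = matrix(FALSE, 21, 21))
  pz <- to_polar_labels(direction_map(zero, ctr), n_r = 6, n_theta = 8,
                        r_max = 9)
  expect_true(all(pz$label$values[!is.na(pz$label$values)] == "Excluded"))
})

test_that("degenerate polar requests are rejected", {
  img <- matrix(1, 10, 10)
  expect_error(to_polar(img, c(50, 5), r_max = 3), "outside")
  expect_error(to_polar(img, c(5, 5), n_r = 1, n_theta = 8, r_max = 3),
               "grid too small")
})
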