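test_that("the to-center angle follows the y-down atan2 convention", {
  ctr <- c(10, 10)
  expect_equal(to_center_angle(c(10, 9), ctr), 0)          # center to the +x side
  expect_equal(to_center_angle(c(9, 10), ctr), pi / 2)     # center below (y-down)
  expect_equal(to_center_angle(c(10, 11), ctr), pi)
  expect_equal(to_center_angle(c(11, 10), ctr), -pi / 2)
  expect_true(is.na(to_center_angle(c(10, 10), ctr)))
  set.seed(2)
  for (rep in 1:20) {
    p <- runif(2, 1, 50); c2 <- runif(2, 1, 50)
    expect_equal(to_center_angle(p, c2), atan2(c2[1] - p[1], c2[2] - p[2]))
  }
})

test_that("angle differences wrap onto [0, pi]", {
  expect_equal(angle_difference(1.2, 1.2), 0)
  expect_equal(angle_difference(3 * pi / 4, -3 * pi / 4), pi / 2)
  set.seed(6)
  a <- runif(200, -pi, pi); b <- runif(200, -pi, pi)
  d <- angle_difference(a, b)
  expect_true(all(d >= 0 & d <= pi))
  brute <- sapply(seq_along(a), function(i)
    min(abs(a[i] - b[i] + 2 * pi * (-1:1))))
  expect_equal(d, brute, tolerance = 1e-12)
})

test_that("the inward/outward rule uses the closed interval at pi/2", {
  expect_identical(classify_direction(0, 1), "Inward")
  expect_identical(classify_direction(pi, 1), "Outward")
  expect_identical(classify_direction(pi / 2, 1), "Inward")
  expect_identical(classify_direction(pi / 2 + 1e-6, 1), "Outward")
  expect_identical(classify_direction(0.3, 0.05, magnitude_min = 0.1),
                   "Excluded")
  # exhaustive grid over the admissible delta range
  grid <- seq(0, pi, length.out = 2001)
  lab <- classify_direction(grid, rep(1, 2001))
  expect_identical(lab, ifelse(grid <= pi / 2, "Inward", "Outward"))
  # optional tangential exclusion band
  expect_identical(classify_direction(pi / 2, 1, tangential_band = 0.1),
                   "Excluded")
})

test_that("radial and tangential flow fields classify as the rule dictates", {
  ctr <- c(11, 11)
  dm_in <- direction_map(radial_flow(21, 21, ctr, sign = -1), ctr)
  inc <- dm_in$label != "Excluded"
  expect_true(all(dm_in$label[inc] == "Inward"))
  expect_true(all(dm_in$delta[inc] < 1e-9))

  dm_out <- direction_map(radial_flow(21, 21, ctr, sign = +1), ctr)
  inc <- dm_out$label != "Excluded"
  expect_true(all(dm_out$label[inc] == "Outward"))
  expect_true(all(abs(dm_out$delta[inc] - pi) < 1e-9))

  # tangential motion sits exactly on the closed boundary -> Inward
  dm_t <- direction_map(tangential_flow(21, 21, ctr), ctr)
  inc <- dm_t$label != "Excluded"
  expect_true(all(abs(dm_t$delta[inc] - pi / 2) < 1e-9))
  expect_true(all(dm_t$label[inc] == "Inward"))
})

test_that("rigid 90-degree rotation about the center preserves every label", {
  set.seed(14)
  n <- 21; ctr <- c(11, 11)
  vx <- matrix(rnorm(n * n), n, n); vy <- matrix(rnorm(n * n), n, n)
  fl <- make_flow(vx, vy)
  dm <- direction_map(fl, ctr, magnitude_min = 0)
  # rotate grid by +90 degrees about the center (x->y in the y-down frame):
  # pixel (i,j) moves to (j, 2c-i); vectors rotate (vx,vy) -> (-vy,vx)
  rot_idx <- function(M) {
    out <- M
    for (i in 1:n) for (j in 1:n) out[j, 2 * ctr[2] - i] <- M[i, j]
    out
  }
  fl_rot <- make_flow(rot_idx(-vy), rot_idx(vx))
  dm_rot <- direction_map(fl_rot, ctr, magnitude_min = 0)
  for (i in 1:n) for (j in 1:n) {
    ii <- j; jj <- 2 * ctr[2] - i
    expect_equal(dm_rot$delta[ii, jj], dm$delta[i, j], tolerance = 1e-9)
    expect_identical(dm_rot$label[ii, jj], dm$label[i, j])
  }
})

test_that("negating the flow swaps labels except exactly at pi/2", {
  set.seed(19)
  n <- 15; ctr <- c(8, 8)
  vx <- matrix(rnorm(n * n), n, n); vy <- matrix(rnorm(n * n), n, n)
  dm <- direction_map(make_flow(vx, vy), ctr, magnitude_min = 0)
  dm_neg <- direction_map(make_flow(-vx, -vy), ctr, magnitude_min = 0)
  inc <- dm$label != "Excluded"
  at_boundary <- abs(dm$delta - pi / 2) < 1e-12
  swap <- c(Inward = "Outward", Outward = "Inward")
  expect_true(all(dm_neg$label[inc & !at_boundary] ==
                  swap[dm$label[inc & !at_boundary]]))
  expect_true(all(dm_neg$label[inc & at_boundary] == "Inward"))
})

test_that("frame summaries are exact recounts", {
  ctr <- c(6, 6)
  dm <- direction_map(radial_flow(11, 11, ctr, -1), ctr)
  s <- summarize_series(list(dm, dm))
  expect_equal(nrow(s), 2)
  expect_equal(s$n_vectors, s$n_inward + s$n_outward)
  expect_equal(s$prop_inward + s$prop_outward, c(1, 1))
  expect_equal(s$n_inward[1], sum(dm$label == "Inward"))
  expect_equal(s$total_magnitude[1],
               sum(dm$magnitude[dm$label != "Excluded"]))
  # all-excluded frame: undefined, not zero
  zero <- make_flow(matrix(0, 5, 5), matrix(0, 5, 5),
                    valid = matrix(FALSE, 5, 5))
  s0 <- summarize_series(list(direction_map(zero, c(3, 3))))
  expect_equal(s0$n_vectors, 0)
  expect_true(is.na(s0$prop_inward) && is.na(s0$prop_outward))
  # random maps vs brute recount
  set.seed(23)
  fl <- make_flow(matrix(rnorm(121), 11, 11), matrix(rnorm(121), 11, 11))
  dm2 <- direction_map(fl, c(6.3, 5.7))
  s2 <- summarize_series(list(dm2))
  expect_equal(s2$n_inward, sum(dm2$label == "Inward"))
  expect_equal(s2$n_outward, sum(dm2$label == "Outward"))
  expect_equal(s2$mean_magnitude,
               mean(dm2$magnitude[dm2$label != "Excluded"]))
})

test_that("center displacement flips labels as hand geometry predicts", {
  # single vector at pixel (9, 13), center at (9, 9): flow (+1, 0) points
  # away from the center -> Outward; with the center displaced to (9, 16)
  # the same flow points toward it -> Inward (label flip)
  vx <- matrix(0, 17, 17); vy <- matrix(0, 17, 17)
  valid <- matrix(FALSE, 17, 17)
  vx[9, 13] <- 1; valid[9, 13] <- TRUE
  fl <- make_flow(vx, vy, valid)
  d_true <- direction_map(fl, c(9, 9))
  expect_identical(d_true$label[9, 13], "Outward")
  d_disp <- direction_map(fl, c(9, 16))
  expect_identical(d_disp$label[9, 13], "Inward")

  sens <- center_error_sensitivity(list(fl), c(9, 9), offsets = c(0, 7),
                                   n_angles = 4)
  expect_equal(sens$by_offset$flip_percent[sens$by_offset$offset == 0], 0)
  # offset-7 centers: (9,16) flips the label; (16,9), (9,2), (2,9) do not
  row7 <- sens$per_angle[sens$per_angle$offset == 7, ]
  expect_equal(sort(row7$flip_percent), c(0, 0, 0, 100))
})

test_that("flip percentage grows with center offset on radial scenes", {
  sim <- simulate_vesicle_movie(scene_config(seed = 2, n_frames = 6))
  flows <- compute_flow_series(sim$stack)
  sens <- center_error_sensitivity(flows, sim$truth$cell_center,
                                   offsets = c(0, 1, 2, 5, 10))
  fp <- sens$by_offset$flip_percent
  expect_equal(fp[1], 0)
  expect_false(is.unsorted(fp))
})
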