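# Shared fixtures: tiny deterministic scenes and independent oracles.

# isotropic Gaussian blob frame on an r x c grid
blob_frame <- function(ci, cj, sigma = 2, m = 40, n = 40, amp = 1) {
  amp * outer(seq_len(m), seq_len(n),
              function(i, j) exp(-((i - ci)^2 + (j - cj)^2) / (2 * sigma^2)))
}

# independent weighted least-squares solve of the flow constraint over a
# full window via QR (lm), as the brute-force minimizer oracle
lk_oracle_lm <- function(Ix, Iy, It, params) {
  r <- params$window_radius
  w1 <- if (params$weight_kernel == "uniform") rep(1, 2 * r + 1) else
    exp(-seq(-r, r)^2 / (2 * params$weight_sigma^2))
  W2 <- outer(w1^2, w1^2)
  fit <- stats::lm(as.vector(-It) ~ 0 + as.vector(Ix) + as.vector(Iy),
                   weights = as.vector(W2))
  unname(stats::coef(fit))
}

# circularly shift a matrix by (dr, dc)
shift_mat <- function(x, dr, dc) {
  m <- nrow(x); n <- ncol(x)
  x[((seq_len(m) - 1 - dr) %% m) + 1, ((seq_len(n) - 1 - dc) %% n) + 1]
}

# hand-built flow_field from component matrices
make_flow <- function(vx, vy, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(vx), ncol(vx))
  vx[!valid] <- 0; vy[!valid] <- 0
  structure(list(vx = vx, vy = vy, valid = valid, params = flow_params()),
            class = "flow_field")
}

# purely radial flow field about `center`: +1 points outward, -1 inward
radial_flow <- function(m, n, center, sign = -1) {
  rows <- matrix(seq_len(m), m, n)
  cols <- matrix(seq_len(n), m, n, byrow = TRUE)
  dy <- rows - center[1]; dx <- cols - center[2]
  r <- sqrt(dx^2 + dy^2); r[r == 0] <- 1
  make_flow(sign * dx / r, sign * dy / r)
}

# tangential (rotational) flow about `center`
tangential_flow <- function(m, n, center) {
  rows <- matrix(seq_len(m), m, n)
  cols <- matrix(seq_len(n), m, n, byrow = TRUE)
  dy <- rows - center[1]; dx <- cols - center[2]
  r <- sqrt(dx^2 + dy^2); r[r == 0] <- 1
  make_flow(-dy / r, dx / r)
}

# fraction of included pixels near ground-truth vesicles of one motion
# class that carry the matching label, for frame pair k
label_recovery <- function(sim, map, k, gt_label, radius) {
  truth <- sim$truth
  lab_gt <- ground_truth_direction(truth, k)
  m <- nrow(map$label); n <- ncol(map$label)
  rows <- matrix(seq_len(m), m, n)
  cols <- matrix(seq_len(n), m, n, byrow = TRUE)
  hit <- 0L; tot <- 0L
  for (v in which(lab_gt == gt_label)) {
    pr <- truth$positions[k, v, 1]; pc <- truth$positions[k, v, 2]
    near <- (rows - pr)^2 + (cols - pc)^2 <= radius^2
    inc <- near & map$label != "Excluded"
    tot <- tot + sum(inc)
    hit <- hit + sum(map$label[inc] == gt_label)
  }
  c(hit = hit, tot = tot)
}
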