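# Internal numerical helpers shared across modules.

# Reflect (symmetric) padding of a matrix by `r` pixels on every side.
pad_reflect <- function(x, r) {
  m <- nrow(x); n <- ncol(x)
  if (r == 0) return(x)
  ri <- c(rev(seq_len(min(r, m))), seq_len(m), m + 1 - rev(seq_len(min(r, m))))
  # for r > m, recycle the reflection (images are always larger in practice)
  ri <- pmin(pmax(ri, 1L), m)
  ci <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - rev(seq_len(min(r, n))))
  ci <- pmin(pmax(ci, 1L), n)
  x[ri, ci, drop = FALSE]
}

# Separable 2-D correlation of matrix `x` with outer(k, k).
# pad = "zero" truncates the window at the image border (sums over the
# intersection only); pad = "reflect" mirrors the image.
conv_sep <- function(x, k, pad = c("zero", "reflect")) {
  pad <- match.arg(pad)
  r <- (length(k) - 1L) %/% 2L
  if (r == 0) return(x * k[1])
  m <- nrow(x); n <- ncol(x)
  if (pad == "reflect") {
    xp <- pad_reflect(x, r)
  } else {
    xp <- matrix(0, m + 2 * r, n + 2 * r)
    xp[r + seq_len(m), r + seq_len(n)] <- x
  }
  # convolve along rows (dimension 1)
  tmp <- matrix(0, m, n + 2 * r)
  for (s in seq_along(k))
    tmp <- tmp + k[s] * xp[(s - 1L) + seq_len(m), , drop = FALSE]
  out <- matrix(0, m, n)
  for (s in seq_along(k))
    out <- out + k[s] * tmp[, (s - 1L) + seq_len(n), drop = FALSE]
  out
}

# 1-D Gaussian kernel sampled at integer offsets, truncated at 4 sigma,
# normalized to unit sum.
gaussian_kernel_1d <- function(sigma, radius = ceiling(4 * sigma)) {
  if (sigma <= 0) return(1)
  u <- seq(-radius, radius)
  k <- exp(-u^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian smoothing with reflect padding; sigma = 0 is the identity.
smooth_gaussian <- function(x, sigma) {
  if (sigma <= 0) return(x)
  conv_sep(x, gaussian_kernel_1d(sigma), pad = "reflect")
}

# Central-difference spatial derivatives with reflect padding.
# ddx: derivative along columns (x); ddy: along rows (y, image-down).
central_diff_x <- function(x) {
  n <- ncol(x)
  left  <- x[, c(1L, seq_len(n - 1L)), drop = FALSE]
  right <- x[, c(seq_len(n - 1L) + 1L, n), drop = FALSE]
  (right - left) / 2
}
central_diff_y <- function(x) {
  m <- nrow(x)
  up   <- x[c(1L, seq_len(m - 1L)), , drop = FALSE]
  down <- x[c(seq_len(m - 1L) + 1L, m), , drop = FALSE]
  (down - up) / 2
}

# Bilinear sampling of matrix `img` at continuous (row, col) positions.
# Positions outside [1, m] x [1, n] return NA.
sample_bilinear <- function(img, row, col) {
  m <- nrow(img); n <- ncol(img)
  out <- rep(NA_real_, length(row))
  ok <- row >= 1 & row <= m & col >= 1 & col <= n & is.finite(row) & is.finite(col)
  if (!any(ok)) return(out)
  r <- row[ok]; c <- col[ok]
  r0 <- pmin(floor(r), m - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(c), n - 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- img[cbind(r0, c0)];     i01 <- img[cbind(r0, c0 + 1L)]
  i10 <- img[cbind(r0 + 1L, c0)]; i11 <- img[cbind(r0 + 1L, c0 + 1L)]
  out[ok] <- (1 - fr) * ((1 - fc) * i00 + fc * i01) +
             fr       * ((1 - fc) * i10 + fc * i11)
  out
}

# Nearest-neighbour sampling; outside positions return NA.
sample_nearest <- function(img, row, col) {
  m <- nrow(img); n <- ncol(img)
  out <- rep(NA_real_, length(row))
  ri <- round(row); ci <- round(col)
  ok <- ri >= 1 & ri <= m & ci >= 1 & ci <= n & is.finite(ri) & is.finite(ci)
  out[ok] <- img[cbind(ri[ok], ci[ok])]
  out
}
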