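# Internal numeric primitives shared by all registration methods:
# image sampling at continuous coordinates, separable Gaussian smoothing with
# replicate padding, and Gaussian resolution pyramids. Boundary policy is part
# of the algorithms' contract, so these are kept in-package.

# Sample a matrix at continuous (row, col) coordinates (1-based, pixel
# centers). Out-of-bounds samples are filled with `fill` and flagged FALSE in
# the returned `inside` vector. method: "nearest", "linear", or "cubic"
# (Keys cubic convolution, a = -1/2; interpolates exactly at grid nodes).
.interp2 <- function(img, y, x, method = "cubic", fill = 0) {
  H <- nrow(img); W <- ncol(img)
  out <- rep(fill, length(y))
  if (method == "nearest") {
    yi <- round(y); xi <- round(x)
    inside <- yi >= 1 & yi <= H & xi >= 1 & xi <= W
    out[inside] <- img[cbind(yi[inside], xi[inside])]
    return(list(values = out, inside = inside))
  }
  if (method == "linear") {
    inside <- y >= 1 & y <= H & x >= 1 & x <= W
    ys <- y[inside]; xs <- x[inside]
    y0 <- pmin(floor(ys), H - 1); x0 <- pmin(floor(xs), W - 1)
    fy <- ys - y0; fx <- xs - x0
    v <- img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
      img[cbind(y0 + 1, x0)] * fy * (1 - fx) +
      img[cbind(y0, x0 + 1)] * (1 - fy) * fx +
      img[cbind(y0 + 1, x0 + 1)] * fy * fx
    out[inside] <- v
    return(list(values = out, inside = inside))
  }
  if (method != "cubic") stop("unknown interpolation method: ", method)
  inside <- y >= 1 & y <= H & x >= 1 & x <= W
  ys <- y[inside]; xs <- x[inside]
  if (!length(ys)) return(list(values = out, inside = inside))
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  wy <- .keysWeights(fy)  # 4 columns for offsets -1, 0, 1, 2
  wx <- .keysWeights(fx)
  # replicate-clamp the 4x4 neighborhood at borders
  acc <- numeric(length(ys))
  for (a in 0:3) {
    ya <- pmin(pmax(y0 + a - 1, 1), H)
    rowacc <- numeric(length(ys))
    for (b in 0:3) {
      xb <- pmin(pmax(x0 + b - 1, 1), W)
      rowacc <- rowacc + wx[, b + 1] * img[cbind(ya, xb)]
    }
    acc <- acc + wy[, a + 1] * rowacc
  }
  out[inside] <- acc
  list(values = out, inside = inside)
}

# Keys cubic convolution weights (a = -1/2) for fractional offset f in [0,1);
# returns a length(f) x 4 matrix for neighbor offsets -1, 0, +1, +2.
.keysWeights <- function(f) {
  a <- -0.5
  w <- function(s) {
    s <- abs(s)
    ifelse(s <= 1, (a + 2) * s^3 - (a + 3) * s^2 + 1,
           ifelse(s < 2, a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a, 0))
  }
  cbind(w(f + 1), w(f), w(1 - f), w(2 - f))
}

# 1D convolution of each column of `m` with kernel `k` (odd length),
# replicate padding.
.convCols <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  H <- nrow(m)
  idx <- c(rep(1L, r), seq_len(H), rep(H, r))
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, H, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[j:(j + H - 1L), , drop = FALSE]
  }
  out
}

# Separable convolution with row kernel ky (applied down columns) and column
# kernel kx (applied across rows), replicate padding.
.convSep <- function(m, ky, kx = ky) {
  t(.convCols(t(.convCols(m, ky)), kx))
}

.gaussKernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

.gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  .convSep(m, .gaussKernel(sigma))
}

# One pyramid reduction: Gaussian antialiasing (sigma ~ 1 for factor 2) then
# decimation by 2.
.pyrDown <- function(m) {
  s <- .gaussSmooth(m, 1)
  s[seq(1, nrow(m), by = 2), seq(1, ncol(m), by = 2), drop = FALSE]
}

# Build a coarse-to-fine list of matrices; levels limited so the coarsest
# level keeps at least `minSide` pixels per side.
.pyramid <- function(m, levels, minSide = 16L) {
  pyr <- list(m)
  while (length(pyr) < levels &&
         all(dim(pyr[[length(pyr)]]) >= 2L * minSide)) {
    pyr[[length(pyr) + 1L]] <- .pyrDown(pyr[[length(pyr)]])
  }
  rev(pyr)  # coarse first
}

# Upsample a field component from shape dim(from) to `shape` by bilinear
# interpolation of the coarse grid (used between pyramid levels).
.upsampleTo <- function(m, shape) {
  Hs <- nrow(m); Ws <- ncol(m)
  H <- shape[1]; W <- shape[2]
  # map fine pixel centers into coarse coordinates (decimation kept odd rows)
  yy <- (seq_len(H) - 1) / 2 + 1
  xx <- (seq_len(W) - 1) / 2 + 1
  yy <- pmin(yy, Hs); xx <- pmin(xx, Ws)
  g <- expand.grid(y = yy, x = xx)
  v <- .interp2(m, g$y, g$x, method = "linear")$values
  matrix(v, H, W)
}

# Central differences in the interior, one-sided at the borders.
# Returns list(dy, dx): derivatives along rows / columns.
.gradients <- function(m) {
  H <- nrow(m); W <- ncol(m)
  dy <- matrix(0, H, W); dx <- matrix(0, H, W)
  if (H >= 3) dy[2:(H - 1), ] <- (m[3:H, ] - m[1:(H - 2), ]) / 2
  if (H >= 2) {
    dy[1, ] <- m[2, ] - m[1, ]
    dy[H, ] <- m[H, ] - m[H - 1, ]
  }
  if (W >= 3) dx[, 2:(W - 1)] <- (m[, 3:W] - m[, 1:(W - 2)]) / 2
  if (W >= 2) {
    dx[, 1] <- m[, 2] - m[, 1]
    dx[, W] <- m[, W] - m[, W - 1]
  }
  list(dy = dy, dx = dx)
}

.asImage <- function(x) {
  if (is(x, "FUSImage")) x else FUSImage(as.matrix(x))
}
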