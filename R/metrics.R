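# Evaluation suite: shifted-NCC profile with peak and FWHM, multi-scale
# SSIM, Haar-wavelet perceptual similarity, Otsu-binarized Dice overlap, and
# Jacobian-determinant / folding analysis of deformation fields.

.mat <- function(x) if (is(x, "FUSImage")) intensities(x) else as.matrix(x)

## ---- shifted NCC profile ---------------------------------------------------

# FFT-based cross-correlation of two equally sized matrices, returning the
# full (2H-1) x (2W-1) grid of sums over the overlap region for every
# integer shift (no zero-padding bias: means and variances are computed per
# overlap via the companion sums of squares and counts).
.xcorrSums <- function(a, b) {
  H <- nrow(a); W <- ncol(a)
  P <- 2 * H; Q <- 2 * W
  pad <- function(m) {
    out <- matrix(0, P, Q); out[1:H, 1:W] <- m; out
  }
  Fa <- fft(pad(a)); Fa2 <- fft(pad(a^2)); F1a <- fft(pad(matrix(1, H, W)))
  Fb <- fft(pad(b)); Fb2 <- fft(pad(b^2))
  cc <- function(X, Y) Re(fft(X * Conj(Y), inverse = TRUE)) / (P * Q)
  # correlate(a, b)[shift] = sum_k a(k + shift) b(k)
  wrap <- function(m) {
    # reorder circular lags into shifts -(H-1)..(H-1), -(W-1)..(W-1)
    m[c((P - H + 2):P, 1:H), c((Q - W + 2):Q, 1:W)]
  }
  list(
    sab = wrap(cc(Fa, Fb)),
    sa = wrap(cc(Fa, F1a)), sb = wrap(cc(F1a, Fb)),
    sa2 = wrap(cc(Fa2, F1a)), sb2 = wrap(cc(F1a, Fb2)),
    n = wrap(cc(F1a, F1a))
  )
}

#' Normalized cross-correlation profile over all integer shifts
#'
#' Computes the zero-mean normalized cross-correlation between two images at
#' every integer shift, normalizing over the overlap region of each shift
#' (so a shifted copy attains an exact peak at its true offset). The peak
#' location reads out residual misalignment and the full width at half
#' maximum of the per-axis profiles through the peak measures the sharpness
#' of the correlation.
#'
#' @param moving,fixed \linkS4class{FUSImage}s (or matrices) of equal shape;
#'   neither constant.
#' @param minOverlap minimum overlap fraction of the full pixel count for a
#'   shift to be evaluated (smaller overlaps give meaningless correlations
#'   and are set to NA).
#' @return An \linkS4class{NCCProfile}; shift (0, 0) is the matrix center.
#' @export
nccShiftProfile <- function(moving, fixed, minOverlap = 0.1) {
  a <- .mat(moving); b <- .mat(fixed)
  if (!identical(dim(a), dim(b))) stop("image shapes differ")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("degenerate input: constant image")
  }
  spacing <- if (is(fixed, "FUSImage")) fixed@spacing else c(1, 1)
  H <- nrow(a); W <- ncol(a)
  s <- .xcorrSums(a, b)
  n <- pmax(round(s$n), 1)
  cov <- s$sab / n - (s$sa / n) * (s$sb / n)
  va <- pmax(s$sa2 / n - (s$sa / n)^2, 0)
  vb <- pmax(s$sb2 / n - (s$sb / n)^2, 0)
  ncc <- cov / sqrt(va * vb)
  ncc[round(s$n) < minOverlap * H * W | va <= 1e-12 | vb <= 1e-12] <- NA
  ncc <- pmin(pmax(ncc, -1), 1)
  pk <- unname(which(ncc == max(ncc, na.rm = TRUE), arr.ind = TRUE)[1, ])
  peakShift <- c(dy = unname(pk[1]) - H, dx = unname(pk[2]) - W)
  fw <- c(
    y = .fwhm(ncc[, pk[2]], pk[1]) * spacing[1],
    x = .fwhm(ncc[pk[1], ], pk[2]) * spacing[2]
  )
  new("NCCProfile", matrix = ncc, peakValue = max(ncc, na.rm = TRUE),
      peakShift = peakShift, fwhm = fw)
}

# Full width at half maximum of a 1D profile around index `peak`, by linear
# interpolation between samples; NA when no crossing exists on either side.
.fwhm <- function(p, peak) {
  half <- p[peak] / 2
  left <- NA_real_; right <- NA_real_
  i <- peak
  while (i > 1) {
    if (!is.na(p[i - 1]) && p[i - 1] <= half) {
      left <- (i - 1) + (half - p[i - 1]) / (p[i] - p[i - 1])
      break
    }
    i <- i - 1
  }
  i <- peak
  n <- length(p)
  while (i < n) {
    if (!is.na(p[i + 1]) && p[i + 1] <= half) {
      right <- i + (p[i] - half) / (p[i] - p[i + 1])
      break
    }
    i <- i + 1
  }
  right - left
}

## ---- SSIM family -----------------------------------------------------------

# Single-scale SSIM component maps over valid (fully supported) windows.
# Gaussian 11 x 11 window, sigma 1.5; population-weighted moments.
.ssimComponents <- function(a, b, K1 = 0.01, K2 = 0.03, L = 1,
                            windowSize = 11L, sigma = 1.5) {
  r <- (windowSize - 1L) / 2L
  k <- .gaussKernel(sigma, r)
  H <- nrow(a); W <- ncol(a)
  if (H < windowSize || W < windowSize) {
    stop(sprintf("image too small for SSIM window: need >= %d per side",
                 windowSize))
  }
  valid <- function(m) m[(r + 1):(H - r), (r + 1):(W - r), drop = FALSE]
  mu_a <- valid(.convSep(a, k)); mu_b <- valid(.convSep(b, k))
  va <- valid(.convSep(a^2, k)) - mu_a^2
  vb <- valid(.convSep(b^2, k)) - mu_b^2
  vab <- valid(.convSep(a * b, k)) - mu_a * mu_b
  va <- pmax(va, 0); vb <- pmax(vb, 0)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2; C3 <- C2 / 2
  list(
    l = (2 * mu_a * mu_b + C1) / (mu_a^2 + mu_b^2 + C1),
    c = (2 * sqrt(va) * sqrt(vb) + C2) / (va + vb + C2),
    s = (vab + C3) / (sqrt(va) * sqrt(vb) + C3)
  )
}

#' Multi-scale structural similarity (MS-SSIM)
#'
#' Product form across scales: the luminance term enters only at the
#' coarsest scale (exponent \code{weights[scales]}), contrast and structure
#' at every scale (exponents \code{weights[j]}). Scales are generated by
#' 2 x 2 mean downsampling. Negative contrast/structure values are clamped
#' to zero before exponentiation so the index stays in [0, 1].
#'
#' @param a,b \linkS4class{FUSImage}s or matrices of equal shape.
#' @param scales number of scales; NULL (default) uses the most the image
#'   supports, up to 5.
#' @param weights per-scale exponents (default the standard five-scale
#'   weights 0.0448, 0.2856, 0.3001, 0.2363, 0.1333).
#' @return MS-SSIM value in [0, 1].
#' @export
msSSIM <- function(a, b, scales = NULL,
                   weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)) {
  a <- .mat(a); b <- .mat(b)
  if (!identical(dim(a), dim(b))) stop("image shapes differ")
  maxScales <- floor(log2(min(dim(a)) / 11)) + 1
  if (is.null(scales)) scales <- max(1, min(5, maxScales))
  stopifnot(length(weights) >= scales)
  if (scales > maxScales) {
    stop(sprintf(
      "image too small for %d scales: need >= %d pixels per side", scales,
      2^(scales - 1) * 11))
  }
  val <- 1
  for (j in seq_len(scales)) {
    comp <- .ssimComponents(a, b)
    if (j < scales) {
      cs <- max(mean(comp$c * comp$s), 0)
      val <- val * cs^weights[j]
      a <- .meanPool2(a); b <- .meanPool2(b)
    } else {
      # coarsest scale: full luminance x contrast x structure map
      lcs <- max(mean(comp$l * comp$c * comp$s), 0)
      val <- val * lcs^weights[j]
    }
  }
  val
}

#' Plain single-scale SSIM
#'
#' Mean of the pointwise luminance x contrast x structure product over valid
#' 11 x 11 Gaussian windows; \code{msSSIM} with one scale and unit exponent
#' reduces to this.
#'
#' @param a,b images of equal shape.
#' @return SSIM value.
#' @export
ssim <- function(a, b) {
  comp <- .ssimComponents(.mat(a), .mat(b))
  mean(comp$l * comp$c * comp$s)
}

.meanPool2 <- function(m) {
  H <- 2 * (nrow(m) %/% 2); W <- 2 * (ncol(m) %/% 2)
  m <- m[1:H, 1:W, drop = FALSE]
  (m[seq(1, H, 2), seq(1, W, 2)] + m[seq(2, H, 2), seq(1, W, 2)] +
     m[seq(1, H, 2), seq(2, W, 2)] + m[seq(2, H, 2), seq(2, W, 2)]) / 4
}

## ---- HaarPSI ---------------------------------------------------------------

# 2D convolution, 'same' size, zero padding (kernels here are small Haar
# filters; orientation follows the usual correlation convention).
.conv2same <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  kh <- nrow(k); kw <- ncol(k)
  ph <- kh %/% 2; pw <- kw %/% 2
  padded <- matrix(0, H + kh - 1, W + kw - 1)
  padded[(ph + 1):(ph + H), (pw + 1):(pw + W)] <- m
  out <- matrix(0, H, W)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      out <- out + k[i, j] * padded[i:(i + H - 1), j:(j + W - 1)]
    }
  }
  out
}

# Haar high-frequency analysis kernel of level j (2^j x 2^j), oriented for
# horizontal (k = 1: vertical edges) or vertical (k = 2) structure.
.haarKernel <- function(level, orientation) {
  n <- 2^level
  hi <- c(rep(1, n / 2), rep(-1, n / 2)) / n  # 1D high-pass
  lo <- rep(1, n) / n                         # 1D low-pass
  if (orientation == 1) outer(lo, hi) else outer(hi, lo)
}

#' Haar wavelet-based perceptual similarity index (HaarPSI)
#'
#' Local similarities of the magnitudes of first- and second-level Haar
#' wavelet coefficients, passed through a logistic function, are aggregated
#' with weights given by third-level low-frequency coefficient magnitudes;
#' the aggregate is mapped back through the inverse logistic and squared.
#' Images are rescaled internally to [0, 255] and mean-pooled by 2, matching
#' the method's published parameterization (C = 30, alpha = 4.2).
#'
#' @param a,b images of equal shape, min side >= 8 pixels.
#' @param cConst stability constant C (default 30 on the [0, 255] scale).
#' @param alpha logistic steepness (default 4.2).
#' @return HaarPSI value in [0, 1]; 1 for identical images.
#' @export
haarPSI <- function(a, b, cConst = 30, alpha = 4.2) {
  a <- .mat(a); b <- .mat(b)
  if (!identical(dim(a), dim(b))) stop("image shapes differ")
  if (min(dim(a)) < 8) stop("images must be at least 8 x 8")
  a <- a * 255; b <- b * 255
  a <- .meanPool2(a); b <- .meanPool2(b)
  logistic <- function(x) 1 / (1 + exp(-alpha * x))
  coefA <- list(); coefB <- list()
  for (orient in 1:2) {
    for (lev in 1:3) {
      coefA[[paste(orient, lev)]] <- .conv2same(a, .haarKernel(lev, orient))
      coefB[[paste(orient, lev)]] <- .conv2same(b, .haarKernel(lev, orient))
    }
  }
  num <- 0; den <- 0
  for (orient in 1:2) {
    sim <- 0
    for (lev in 1:2) {
      ca <- abs(coefA[[paste(orient, lev)]])
      cb <- abs(coefB[[paste(orient, lev)]])
      sim <- sim + (2 * ca * cb + cConst) / (ca^2 + cb^2 + cConst)
    }
    hs <- logistic(sim / 2)
    w <- pmax(abs(coefA[[paste(orient, 3)]]), abs(coefB[[paste(orient, 3)]]))
    num <- num + sum(hs * w)
    den <- den + sum(w)
  }
  (log((num / den) / (1 - num / den)) / alpha)^2
}

## ---- Otsu / Dice -----------------------------------------------------------

#' Otsu's global threshold
#'
#' Histogram threshold over \code{bins} levels minimizing total within-class
#' intensity variance (equivalently maximizing between-class variance).
#'
#' @param image a \linkS4class{FUSImage} or matrix; must be non-constant.
#' @param bins number of histogram bins (default 256).
#' @return The threshold value (upper edge of the background class).
#' @export
otsuThreshold <- function(image, bins = 256) {
  x <- as.vector(.mat(image))
  rng <- range(x)
  if (rng[1] == rng[2]) stop("degenerate input: constant image")
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- tabulate(
    pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1), bins),
    nbins = bins)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  total <- w[bins]; muT <- mu[bins]
  w0 <- w[-bins]; mu0 <- mu[-bins]
  w1 <- total - w0
  between <- ifelse(w0 > 0 & w1 > 0,
                    (muT * w0 - mu0 * total)^2 / (w0 * w1), -Inf)
  k <- which.max(between)
  edges[k + 1]
}

#' Dice similarity coefficient of Otsu-binarized images
#'
#' Each image is independently binarized at its own Otsu threshold
#' (foreground = intensity above threshold), then
#' DSC = 2 |A and B| / (|A| + |B|).
#'
#' @param a,b images of equal shape.
#' @param bins histogram bins for the thresholds.
#' @return DSC in [0, 1]; 0 (with a warning) when both foregrounds are
#'   empty.
#' @export
diceCoefficient <- function(a, b, bins = 256) {
  ma <- .mat(a); mb <- .mat(b)
  if (!identical(dim(ma), dim(mb))) stop("image shapes differ")
  fa <- ma > otsuThreshold(ma, bins)
  fb <- mb > otsuThreshold(mb, bins)
  .diceMasks(fa, fb)
}

# Dice of two logical masks.
.diceMasks <- function(fa, fb) {
  denom <- sum(fa) + sum(fb)
  if (denom == 0) {
    warning("both foregrounds empty; Dice defined as 0")
    return(0)
  }
  2 * sum(fa & fb) / denom
}

## ---- Jacobian analysis -----------------------------------------------------

#' Jacobian determinant and folding analysis of a deformation field
#'
#' Differentiates the total mapping phi = identity + d (central differences
#' in the interior, one-sided at borders) and reports the per-pixel
#' determinant, its mean, and the folding rate: the percentage of pixels
#' with determinant <= 0, i.e. local topology violations.
#'
#' @param field a \linkS4class{DeformationField}.
#' @return A \linkS4class{JacobianMap}.
#' @export
#' @examples
#' jacobianAnalysis(identityField(c(16, 16)))  # det 1, folding 0
jacobianAnalysis <- function(field) {
  stopifnot(is(field, "DeformationField"))
  gx <- .gradients(field@dx)  # d(dx)/dy, d(dx)/dx
  gy <- .gradients(field@dy)
  # phi_x = x + dx, phi_y = y + dy
  dphix_dx <- 1 + gx$dx; dphix_dy <- gx$dy
  dphiy_dx <- gy$dx; dphiy_dy <- 1 + gy$dy
  det <- dphix_dx * dphiy_dy - dphix_dy * dphiy_dx
  new("JacobianMap", det = det, meanJacobian = mean(det),
      foldingRate = 100 * mean(det <= 0))
}

## ---- aggregate report ------------------------------------------------------

#' Evaluate one registration with the full metric suite
#'
#' Computes NCC profile peak, MS-SSIM, HaarPSI and Dice for both the
#' pre-registration pair (moving vs fixed) and the post-registration pair
#' (registered vs fixed), plus Jacobian analysis when a deformation field is
#' supplied (non-rigid case).
#'
#' @param moving,registered,fixed images of equal shape.
#' @param field optional \linkS4class{DeformationField} of the recovered
#'   transform.
#' @param scales MS-SSIM scale count, reduced automatically for small
#'   images.
#' @return A \linkS4class{MetricReport}.
#' @export
evaluateRegistration <- function(moving, registered, fixed, field = NULL,
                                 scales = NULL) {
  if (is.null(scales)) {
    scales <- max(1, min(5, floor(log2(min(dim(.mat(fixed))) / 11)) + 1))
  }
  one <- function(x) {
    prof <- nccShiftProfile(x, fixed)
    c(nccPeak = prof@peakValue,
      ncc = nccGlobal(x, fixed),
      msSSIM = msSSIM(x, fixed, scales = scales),
      haarPSI = haarPSI(x, fixed),
      dice = diceCoefficient(x, fixed))
  }
  jac <- if (!is.null(field)) jacobianAnalysis(field) else NULL
  new("MetricReport", pre = one(moving), post = one(registered),
      jacobian = jac)
}
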