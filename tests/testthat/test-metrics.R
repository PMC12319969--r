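# Evaluation metrics: NCC profile, MS-SSIM, HaarPSI, Otsu/Dice, Jacobian.

test_that("similarity metrics are exactly 1 for identical images", {
  m <- intensities(fixturePhantom())
  expect_equal(msSSIM(m, m), 1, tolerance = 1e-9)
  expect_equal(haarPSI(m, m), 1, tolerance = 1e-9)
  expect_equal(diceCoefficient(m, m), 1, tolerance = 1e-9)
  prof <- nccShiftProfile(m, m)
  expect_equal(prof@peakValue, 1, tolerance = 1e-9)
  expect_equal(unname(prof@peakShift), c(0, 0))
})

test_that("MS-SSIM and HaarPSI are symmetric and bounded", {
  set.seed(5)
  a <- matrix(runif(64 * 80), 64, 80)
  b <- pmin(pmax(a + matrix(rnorm(64 * 80, 0, 0.2), 64, 80), 0), 1)
  expect_equal(msSSIM(a, b, scales = 2, weights = c(0.5, 0.5)),
               msSSIM(b, a, scales = 2, weights = c(0.5, 0.5)),
               tolerance = 1e-12)
  expect_equal(haarPSI(a, b), haarPSI(b, a), tolerance = 1e-12)
  for (s in 1:25) {
    set.seed(s)
    x <- matrix(runif(256), 16, 16); y <- matrix(runif(256), 16, 16)
    h <- haarPSI(x, y)
    expect_gte(h, 0); expect_lte(h, 1)
  }
  expect_error(msSSIM(matrix(runif(64), 8, 8),
                      matrix(runif(64), 8, 8), scales = 3),
               "per side")
})

test_that("single-scale MS-SSIM equals a direct windowed SSIM", {
  set.seed(6)
  a <- matrix(runif(40 * 44), 40, 44)
  b <- pmin(pmax(a + matrix(rnorm(40 * 44, 0, 0.1), 40, 44), 0), 1)
  # independent oracle: explicit window extraction, Gaussian weights
  direct <- local({
    g <- dnorm(-5:5, 0, 1.5)
    k <- outer(g, g); k <- k / sum(k)
    C1 <- 0.01^2; C2 <- 0.03^2; C3 <- C2 / 2
    vals <- c()
    for (i in 6:(nrow(a) - 5)) {
      for (j in 6:(ncol(a) - 5)) {
        wa <- a[(i - 5):(i + 5), (j - 5):(j + 5)]
        wb <- b[(i - 5):(i + 5), (j - 5):(j + 5)]
        mua <- sum(k * wa); mub <- sum(k * wb)
        va <- sum(k * (wa - mua)^2); vb <- sum(k * (wb - mub)^2)
        vab <- sum(k * (wa - mua) * (wb - mub))
        vals <- c(vals,
                  ((2 * mua * mub + C1) / (mua^2 + mub^2 + C1)) *
                    ((2 * sqrt(va) * sqrt(vb) + C2) / (va + vb + C2)) *
                    ((vab + C3) / (sqrt(va) * sqrt(vb) + C3)))
      }
    }
    mean(vals)
  })
  expect_equal(msSSIM(a, b, scales = 1, weights = 1), direct,
               tolerance = 1e-9)
})

test_that("HaarPSI equals an independent straight-line evaluation", {
  set.seed(7)
  a <- matrix(runif(256), 16, 16)
  b <- pmin(pmax(a + matrix(rnorm(256, 0, 0.15), 16, 16), 0), 1)
  oracle <- local({
    # naive reimplementation: explicit loops, no shared helpers
    conv2 <- function(m, k) {
      H <- nrow(m); W <- ncol(m); kh <- nrow(k); kw <- ncol(k)
      ph <- kh %/% 2; pw <- kw %/% 2
      out <- matrix(0, H, W)
      for (i in 1:H) for (j in 1:W) {
        s <- 0
        for (u in 1:kh) for (v in 1:kw) {
          ii <- i + u - 1 - ph; jj <- j + v - 1 - pw
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
            s <- s + k[u, v] * m[ii, jj]
          }
        }
        out[i, j] <- s
      }
      out
    }
    haarK <- function(level, orient) {
      n <- 2^level
      hi <- c(rep(1, n / 2), rep(-1, n / 2)) / n
      lo <- rep(1, n) / n
      if (orient == 1) outer(lo, hi) else outer(hi, lo)
    }
    pool2 <- function(m) {
      H <- 2 * (nrow(m) %/% 2); W <- 2 * (ncol(m) %/% 2)
      out <- matrix(0, H / 2, W / 2)
      for (i in seq(1, H, 2)) for (j in seq(1, W, 2)) {
        out[(i + 1) / 2, (j + 1) / 2] <-
          mean(m[i:(i + 1), j:(j + 1)])
      }
      out
    }
    A <- pool2(a * 255); B <- pool2(b * 255)
    C <- 30; alpha <- 4.2
    num <- 0; den <- 0
    for (orient in 1:2) {
      s1a <- abs(conv2(A, haarK(1, orient)))
      s1b <- abs(conv2(B, haarK(1, orient)))
      s2a <- abs(conv2(A, haarK(2, orient)))
      s2b <- abs(conv2(B, haarK(2, orient)))
      sim <- ((2 * s1a * s1b + C) / (s1a^2 + s1b^2 + C) +
                (2 * s2a * s2b + C) / (s2a^2 + s2b^2 + C)) / 2
      hs <- 1 / (1 + exp(-alpha * sim))
      w <- pmax(abs(conv2(A, haarK(3, orient))),
                abs(conv2(B, haarK(3, orient))))
      num <- num + sum(hs * w); den <- den + sum(w)
    }
    (log((num / den) / (1 - num / den)) / alpha)^2
  })
  expect_equal(haarPSI(a, b), oracle, tolerance = 1e-9)
})

test_that("Otsu thresholding equals exhaustive search", {
  # two-value image: threshold strictly between the modes
  tv <- matrix(rep(c(0.1, 0.9), each = 32), 8, 8)
  thr <- otsuThreshold(tv, bins = 64)
  expect_gt(thr, 0.1); expect_lt(thr, 0.9)
  fg <- tv > thr
  expect_equal(var(tv[fg]), 0); expect_equal(var(tv[!fg]), 0)
  # arbitrary image: exhaustive within-class-variance minimization
  set.seed(8)
  x <- matrix(runif(400)^2, 20, 20)
  bins <- 64
  brute <- local({
    v <- as.vector(x); rng <- range(v)
    edges <- seq(rng[1], rng[2], length.out = bins + 1)
    best <- Inf; bt <- NA
    for (k in 2:bins) {
      g1 <- v[v <= edges[k]]; g2 <- v[v > edges[k]]
      if (!length(g1) || !length(g2)) next
      wcv <- length(g1) * mean((g1 - mean(g1))^2) +
        length(g2) * mean((g2 - mean(g2))^2)
      if (wcv < best) { best <- wcv; bt <- edges[k] }
    }
    bt
  })
  expect_equal(otsuThreshold(x, bins), brute, tolerance = 1e-12)
  expect_error(otsuThreshold(matrix(0.4, 5, 5)), "degenerate")
})

test_that("Dice matches direct set counting", {
  a <- matrix(0, 4, 4); a[, 1:2] <- 1
  b <- matrix(0, 4, 4); b[, 2:3] <- 1
  expect_equal(diceCoefficient(a, b), 0.5)
  d <- matrix(0, 4, 4); d[, 4] <- 1
  expect_equal(diceCoefficient(a, d), 0)
  expect_warning(v <- fusireg:::.diceMasks(matrix(FALSE, 2, 2),
                                           matrix(FALSE, 2, 2)), "empty")
  expect_equal(v, 0)
})

test_that("Jacobian analysis matches analytic determinants", {
  shape <- c(20, 24)
  # identity: det 1 everywhere, no folding
  j0 <- jacobianAnalysis(identityField(shape))
  expect_equal(range(j0@det), c(1, 1))
  expect_equal(j0@meanJacobian, 1)
  expect_equal(j0@foldingRate, 0)
  # uniform 1.1x scaling: phi = 1.1 x => d = 0.1 x; det = 1.21
  xs <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ys <- matrix(seq_len(shape[1]), shape[1], shape[2])
  fs <- DeformationField(dx = 0.1 * xs, dy = 0.1 * ys)
  expect_equal(range(jacobianAnalysis(fs)@det), c(1.21, 1.21),
               tolerance = 1e-9)
  # reflection phi_x = -x: det = -1 everywhere, folding 100%
  fr <- DeformationField(dx = -2 * xs, dy = 0 * ys)
  jr <- jacobianAnalysis(fr)
  expect_equal(range(jr@det), c(-1, -1), tolerance = 1e-9)
  expect_equal(jr@foldingRate, 100)
  # mean det equals the report mean exactly
  f <- generateTruthDeformation("smooth", 3, shape, seed = 4)@field
  jm <- jacobianAnalysis(f)
  expect_equal(jm@meanJacobian, mean(jm@det), tolerance = 1e-12)
})

test_that("NCC profile localizes constructed shifts and peak widths", {
  m <- intensities(fixturePhantom())
  H <- nrow(m); W <- ncol(m)
  shifted <- matrix(0, H, W)
  shifted[4:H, 1:(W - 2)] <- m[1:(H - 3), 3:W]
  prof <- nccShiftProfile(shifted, m)
  expect_equal(unname(prof@peakShift), c(3, -2))
  expect_gte(prof@peakValue, 0.99)
  # profile center equals global NCC of the pair
  expect_equal(prof@matrix[H, W], nccGlobal(shifted, m), tolerance = 1e-9)
  # Gaussian blob: FWHM of the autocorrelation is 4 sigma sqrt(ln 2)
  sigma <- 6
  g <- outer(dnorm(1:128, 64, sigma), dnorm(1:128, 64, sigma))
  pg <- nccShiftProfile(FUSImage(g, spacing = c(0.1, 0.1)),
                        FUSImage(g, spacing = c(0.1, 0.1)),
                        minOverlap = 0.2)
  theory <- 4 * sigma * sqrt(log(2)) * 0.1
  expect_equal(unname(pg@fwhm["x"]), theory, tolerance = 0.05)
  expect_equal(unname(pg@fwhm["y"]), theory, tolerance = 0.05)
  expect_error(nccShiftProfile(m, matrix(1, H, W)), "degenerate")
})

test_that("evaluateRegistration aggregates pre and post metrics", {
  img <- fixtureSmallPhantom()
  m <- intensities(img)
  set.seed(9)
  mov <- m + matrix(rnorm(length(m), 0, 0.05), nrow(m), ncol(m))
  rep <- evaluateRegistration(mov, m, m, field = identityField(dim(m)))
  expect_equal(unname(rep@post["msSSIM"]), 1, tolerance = 1e-9)
  expect_equal(unname(rep@post["dice"]), 1, tolerance = 1e-9)
  expect_equal(rep@jacobian@meanJacobian, 1)
  expect_equal(rep@jacobian@foldingRate, 0)
  expect_true(all(rep@post >= rep@pre - 1e-9))
})
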