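# Non-rigid registration: demons, B-spline FFD, TV-regularized, piecewise
# rigid, and the combined driver.

test_that("the demons force equals its pointwise definition", {
  m <- intensities(fixtureSmallPhantom())
  set.seed(1)
  s <- m + matrix(rnorm(length(m), 0, 0.05), nrow(m), ncol(m))
  f <- demonsForce(m, s)
  # independent oracle: direct elementwise evaluation with explicit
  # central/one-sided differences
  H <- nrow(s); W <- ncol(s)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    gx[i, j] <- if (j == 1) s[i, 2] - s[i, 1] else if (j == W)
      s[i, W] - s[i, W - 1] else (s[i, j + 1] - s[i, j - 1]) / 2
    gy[i, j] <- if (i == 1) s[2, j] - s[1, j] else if (i == H)
      s[H, j] - s[H - 1, j] else (s[i + 1, j] - s[i - 1, j]) / 2
  }
  dd <- m - s
  den <- gx^2 + gy^2 + dd^2
  ex <- ifelse(den == 0, 0, dd * gx / den)
  ey <- ifelse(den == 0, 0, dd * gy / den)
  expect_equal(dispX(f), ex, tolerance = 1e-12)
  expect_equal(dispY(f), ey, tolerance = 1e-12)
  # m = s: zero force; zero gradient with m != s: zero force
  z <- demonsForce(s, s)
  expect_equal(max(abs(dispX(z))), 0)
  flat <- matrix(0.3, 4, 4); other <- matrix(0.8, 4, 4)
  expect_equal(max(abs(dispX(demonsForce(other, flat)))), 0)
  # single-pixel check of the printed example: m - s = 1, grad = (1, 0)
  sfix <- matrix(0.5, 5, 5); sfix[3, 4] <- 1.5; sfix[3, 2] <- -0.5
  mv <- sfix; mv[3, 3] <- sfix[3, 3] + 1
  expect_equal(dispX(demonsForce(mv, sfix))[3, 3], 1 * 1 / (1 + 1))
})

test_that("demons recovers a smooth deformation and self-registers", {
  # self-registration: near-zero field
  m <- intensities(fixtureSmallPhantom())
  f0 <- registerDemons(m, m, nonRigidConfig("demons",
                                            iterationsPerLevel = 20))
  expect_lte(max(sqrt(dispX(f0)^2 + dispY(f0)^2)), 0.1)
  # recovery: residual endpoint error under half the initial displacement
  pair <- makePair(3, seed = 11)
  g <- registerDemons(pair$moving, pair$fixed, nonRigidConfig("demons"))
  expect_all_finite(g)
  expect_lt(residualEPE(pair$truth, g), 0.5 * pair$preEPE)
})

test_that("diffeomorphic demons folds no more than plain demons", {
  pair <- makePair(8, seed = 21)
  plain <- registerDemons(pair$moving, pair$fixed,
                          nonRigidConfig("demons"))
  diffeo <- registerDemons(pair$moving, pair$fixed,
                           nonRigidConfig("demons", diffeomorphic = TRUE))
  expect_lte(jacobianAnalysis(diffeo)@foldingRate,
             jacobianAnalysis(plain)@foldingRate + 1e-12)
})

test_that("B-spline registration recovers a lattice-generated field", {
  img <- fixturePhantom()
  m <- intensities(img)
  shape <- dim(m)
  # inverse crime: truth drawn from a lattice at the registration spacing
  g <- bsplineGrid(shape, spacing = 8)
  set.seed(31)
  g@coefDx[] <- rnorm(length(g@coefDx), 0, 1.2)
  g@coefDy[] <- rnorm(length(g@coefDy), 0, 1.2)
  truthField <- bsplineToField(g, shape)
  truth <- new("TruthDeformation", kind = "smooth", rigid = NULL,
               field = truthField,
               maxDisplacement = max(sqrt(dispX(truthField)^2 +
                                            dispY(truthField)^2)))
  mov <- intensities(warpImage(img, truthField))
  rec <- registerBspline(mov, m, nonRigidConfig("bspline", seed = 3))
  expect_lte(residualEPE(truth, rec), 0.5)
  # self-registration
  f0 <- registerBspline(m, m, nonRigidConfig("bspline", seed = 3,
                                             iterationsPerLevel = 30))
  expect_lte(max(sqrt(dispX(f0)^2 + dispY(f0)^2)), 0.2)
})

test_that("a large bending weight smooths the recovered lattice", {
  pair <- makePair(3, seed = 41)
  free <- registerBspline(pair$moving, pair$fixed,
                          nonRigidConfig("bspline", seed = 5))
  stiff <- registerBspline(pair$moving, pair$fixed,
                           nonRigidConfig("bspline", seed = 5,
                                          bendingWeight = 100))
  gradNorm <- function(f) {
    g <- fusireg:::.forwardDiffs(f)
    sum(sqrt(g$xx^2 + g$xy^2 + g$yx^2 + g$yy^2))
  }
  expect_lt(gradNorm(stiff), gradNorm(free))
})

test_that("TV energy matches direct finite-difference evaluation", {
  shape <- c(12, 15)
  expect_equal(tvEnergy(identityField(shape), 1), 0)
  const <- DeformationField(matrix(2.5, shape[1], shape[2]),
                            matrix(-1, shape[1], shape[2]))
  expect_equal(tvEnergy(const, 3), 0)
  # unit-slope ramp in x for dx, dy = 0: each forward-difference site
  # contributes exactly 1
  xs <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ramp <- DeformationField(dx = xs * 1.0,
                           dy = matrix(0, shape[1], shape[2]))
  expect_equal(tvEnergy(ramp, 1), shape[1] * (shape[2] - 1))
  # random field: brute-force double loop over sites
  set.seed(2)
  f <- DeformationField(matrix(rnorm(prod(shape)), shape[1]),
                        matrix(rnorm(prod(shape)), shape[1]))
  brute <- local({
    tot <- 0
    for (i in seq_len(shape[1])) {
      for (j in seq_len(shape[2])) {
        gxx <- if (j < shape[2]) f@dx[i, j + 1] - f@dx[i, j] else 0
        gxy <- if (i < shape[1]) f@dx[i + 1, j] - f@dx[i, j] else 0
        gyx <- if (j < shape[2]) f@dy[i, j + 1] - f@dy[i, j] else 0
        gyy <- if (i < shape[1]) f@dy[i + 1, j] - f@dy[i, j] else 0
        tot <- tot + sqrt(gxx^2 + gxy^2 + gyx^2 + gyy^2)
      }
    }
    tot
  })
  expect_equal(tvEnergy(f, 0.7), 0.7 * brute, tolerance = 1e-12)
})

test_that("TV registration self-registers and respects a huge weight", {
  m <- intensities(fixtureSmallPhantom())
  f0 <- registerTV(m, m, nonRigidConfig("tv"))
  expect_lte(max(sqrt(dispX(f0)^2 + dispY(f0)^2)), 0.2)
  # 1000x the default weight forces a near-constant field
  pair <- makePair(3, seed = 51)
  big <- suppressWarnings(
    registerTV(pair$moving, pair$fixed,
               nonRigidConfig("tv", tvWeight = 500)))
  dev <- max(abs(c(dispX(big) - mean(dispX(big)),
                   dispY(big) - mean(dispY(big)))))
  expect_lte(dev, 0.5)
})

test_that("TV registration improves alignment on moderate deformations", {
  pair <- makePair(3, seed = 61)
  g <- suppressWarnings(
    registerTV(pair$moving, pair$fixed, nonRigidConfig("tv")))
  expect_lt(residualEPE(pair$truth, g), 0.5 * pair$preEPE)
  post <- warpImage(FUSImage(pair$moving), g)
  expect_gt(diceCoefficient(post, pair$fixed),
            diceCoefficient(pair$moving, pair$fixed))
})

test_that("piecewise-rigid registration recovers translations", {
  img <- fixturePhantom()
  m <- intensities(img)
  shape <- dim(m)
  cfg <- nonRigidConfig("piecewise")
  # self-registration: sub-pixel precision bound
  f0 <- registerPiecewiseRigid(m, m, cfg)
  expect_lte(max(abs(c(dispX(f0), dispY(f0)))), 1 / cfg$upsampleFactor)
  # global translation (4.25, -2.5): constant recovery over the region
  # where the content exists on both sides (a patch margin is lost where
  # it translated out of the field of view)
  ft <- DeformationField(matrix(-4.25, shape[1], shape[2]),
                         matrix(2.5, shape[1], shape[2]))
  mov <- intensities(warpImage(img, ft))
  g <- registerPiecewiseRigid(mov, m, cfg)
  inner <- list(rows = 1:shape[1], cols = 1:(shape[2] - cfg$patchSize))
  expect_lte(max(abs(dispX(g)[inner$rows, inner$cols] - 4.25)), 0.5)
  expect_lte(max(abs(dispY(g)[inner$rows, inner$cols] + 2.5)), 0.5)
  # opposed half-shifts with a smooth blend
  xs <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  blend <- max(shape[2] / 10, 4)
  truthDx <- 3 * tanh(((shape[2] + 1) / 2 - xs) / blend)
  movp <- intensities(warpImage(img, DeformationField(-truthDx,
                                                      truthDx * 0)))
  gp <- registerPiecewiseRigid(movp, m, cfg)
  outside <- abs(xs - (shape[2] + 1) / 2) > 2.5 * blend
  expect_lte(max(abs(dispX(gp) - truthDx)[outside]), 1)
  expect_error(registerPiecewiseRigid(m, m,
                                      nonRigidConfig("piecewise",
                                                     patchSize = 200)),
               "smaller")
})

test_that("combined registration composes its two stages", {
  img <- fixturePhantom()
  m <- intensities(img)
  shape <- dim(m)
  ctr <- c((shape[1] + 1) / 2, (shape[2] + 1) / 2)
  pT <- RigidParams(theta = 3 * pi / 180, tx = 4, ty = -2, center = ctr)
  rigidField <- rigidToField(invertRigid(pT), shape)
  # zero non-rigid iterations: exactly the rigid field
  mov <- intensities(warpImage(img, rigidField))
  f0 <- registerCombined(mov, m, rigidRegConfig("blockmatch", seed = 1),
                         nonRigidConfig("demons", iterationsPerLevel = 0))
  onlyRigid <- rigidToField(attr(f0, "rigid"), shape)
  expect_equal(dispX(f0), dispX(onlyRigid), tolerance = 1e-12)
  expect_equal(dispY(f0), dispY(onlyRigid), tolerance = 1e-12)
  # rigid + smooth truth: combined NCC at least the rigid-only NCC
  smoothT <- generateTruthDeformation("smooth", 3, shape, seed = 71)
  total <- composeFields(rigidField, smoothT@field)
  movc <- intensities(warpImage(img, total))
  fc <- suppressWarnings(
    registerCombined(movc, m, rigidRegConfig("blockmatch", seed = 1),
                     nonRigidConfig("demons")))
  wR <- warpImage(FUSImage(movc),
                  rigidToField(attr(fc, "rigid"), shape))
  wC <- warpImage(FUSImage(movc), fc)
  expect_gte(nccGlobal(wC, m), nccGlobal(wR, m))
  # self-registration: near-identity composed field
  fs <- registerCombined(m, m, rigidRegConfig("blockmatch", seed = 1),
                         nonRigidConfig("demons", iterationsPerLevel = 5))
  expect_lte(max(sqrt(dispX(fs)^2 + dispY(fs)^2)), 0.5)
})
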