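# Transform model: rigid fields, B-spline lattices, warping, composition.

test_that("rigid fields follow the backward convention", {
  # identity
  f0 <- rigidToField(RigidParams(), c(10, 12))
  expect_equal(max(abs(dispX(f0))), 0)
  expect_equal(max(abs(dispY(f0))), 0)
  # pure translation: constant field with negated components
  ft <- rigidToField(RigidParams(tx = 2, ty = 1), c(10, 12))
  expect_equal(unique(as.vector(dispX(ft))), -2)
  expect_equal(unique(as.vector(dispY(ft))), -1)
  # quarter turn about the center: analytic rotation of pixel coordinates
  p <- RigidParams(theta = pi / 2, center = c(5, 5))
  fr <- rigidToField(p, c(9, 9))
  for (px in list(c(5, 9), c(1, 5), c(3, 7))) {
    q <- c(px[2], px[1]) - c(5, 5)            # (x, y) offset from center
    backward <- c(q[1] * cos(pi / 2) + q[2] * sin(pi / 2),
                  -q[1] * sin(pi / 2) + q[2] * cos(pi / 2))
    expect_equal(dispX(fr)[px[1], px[2]], backward[1] - q[1],
                 tolerance = 1e-12)
    expect_equal(dispY(fr)[px[1], px[2]], backward[2] - q[2],
                 tolerance = 1e-12)
  }
})

test_that("rigid fields are exactly area-preserving", {
  p <- RigidParams(theta = 0.3, tx = 2.5, ty = -1.25, center = c(8, 9))
  j <- jacobianAnalysis(rigidToField(p, c(20, 24)))
  expect_lt(max(abs(j@det - 1)), 1e-6)
  expect_equal(j@foldingRate, 0)
})

test_that("B-spline lattice evaluation satisfies spline identities", {
  shape <- c(24, 30)
  g <- bsplineGrid(shape, spacing = 6)
  # all-zero control displacements
  f <- bsplineToField(g, shape)
  expect_equal(max(abs(dispX(f))), 0)
  # partition of unity: constant control displacements give a constant field
  g@coefDx[] <- 1.7
  g@coefDy[] <- -0.4
  f <- bsplineToField(g, shape)
  expect_equal(range(dispX(f)), c(1.7, 1.7), tolerance = 1e-12)
  expect_equal(range(dispY(f)), c(-0.4, -0.4), tolerance = 1e-12)
  # single nonzero control point reproduces the tensor cubic kernel
  g2 <- bsplineGrid(shape, spacing = 6)
  g2@coefDx[4, 5] <- 2
  f2 <- bsplineToField(g2, shape)
  b3 <- function(s) {  # cardinal cubic B-spline, support (-2, 2)
    s <- abs(s)
    ifelse(s < 1, (4 - 6 * s^2 + 3 * s^3) / 6,
           ifelse(s < 2, (2 - s)^3 / 6, 0))
  }
  for (px in list(c(10, 16), c(12, 20), c(14, 13))) {
    uy <- (px[1] - g2@origin[1]) / g2@spacing + 1
    ux <- (px[2] - g2@origin[2]) / g2@spacing + 1
    expect_equal(dispX(f2)[px[1], px[2]], 2 * b3(uy - 4) * b3(ux - 5),
                 tolerance = 1e-12)
  }
})

test_that("B-spline field evaluation is linear in the control points", {
  shape <- c(20, 20)
  g1 <- bsplineGrid(shape, 5); g2 <- bsplineGrid(shape, 5)
  set.seed(1)
  g1@coefDx[] <- rnorm(length(g1@coefDx))
  g2@coefDx[] <- rnorm(length(g2@coefDx))
  gs <- g1; gs@coefDx <- g1@coefDx + 2 * g2@coefDx
  f <- bsplineToField(gs, shape)
  fsum <- dispX(bsplineToField(g1, shape)) +
    2 * dispX(bsplineToField(g2, shape))
  expect_equal(dispX(f), fsum, tolerance = 1e-12)
})

test_that("warping with the identity field is the exact identity", {
  img <- fixtureSmallPhantom()
  z <- identityField(dim(img))
  for (ip in c("cubic", "linear", "nearest")) {
    expect_identical(intensities(warpImage(img, z, ip)), intensities(img))
  }
})

test_that("integer translation relocates an impulse exactly", {
  imp <- matrix(0, 16, 16); imp[8, 6] <- 1
  f <- rigidToField(RigidParams(tx = 3, ty = 2), c(16, 16))
  w <- intensities(warpImage(FUSImage(imp), f, "nearest"))
  expect_equal(which(w == 1, arr.ind = TRUE)[1, ],
               c(row = 10, col = 9))
  # out-of-bounds pixels are zero-filled and flagged in the mask
  wimg <- warpImage(FUSImage(imp), f)
  expect_true(all(intensities(wimg)[, 1:3] == 0))
  expect_true(all(!validMask(wimg)[, 1:3]))
})

test_that("warp of a composition approximates sequential warps", {
  img <- fixtureSmallPhantom()
  m <- fusireg:::.gaussSmooth(intensities(img), 2)  # smooth test image
  shape <- dim(m)
  f1 <- generateTruthDeformation("smooth", 2, shape, seed = 3)@field
  f2 <- generateTruthDeformation("smooth", 2, shape, seed = 4)@field
  seq2 <- warpImage(warpImage(FUSImage(m), f1), f2)
  once <- warpImage(FUSImage(m), composeFields(f1, f2))
  interior <- intensities(seq2)[5:(shape[1] - 5), 5:(shape[2] - 5)] -
    intensities(once)[5:(shape[1] - 5), 5:(shape[2] - 5)]
  expect_lt(max(abs(interior)), 1e-2)
})

test_that("field composition has the expected algebra", {
  shape <- c(20, 24)
  z <- identityField(shape)
  f <- generateTruthDeformation("smooth", 2, shape, seed = 5)@field
  expect_equal(dispX(composeFields(z, f)), dispX(f), tolerance = 1e-12)
  expect_equal(dispX(composeFields(f, z)), dispX(f), tolerance = 1e-12)
  # constant translations add
  t1 <- rigidToField(RigidParams(tx = 1.5), shape)
  t2 <- rigidToField(RigidParams(tx = -0.5, ty = 2), shape)
  fc <- composeFields(t1, t2)
  expect_equal(unique(as.vector(dispX(fc))), -1, tolerance = 1e-12)
  expect_equal(unique(as.vector(dispY(fc))), -2, tolerance = 1e-12)
  # rigid-rigid composition matches the analytic composed transform
  p1 <- RigidParams(theta = 0.2, tx = 2, ty = -1, center = c(10, 10))
  p2 <- RigidParams(theta = -0.1, tx = -1.5, ty = 2.5, center = c(12, 8))
  shape2 <- c(30, 30)
  numeric <- composeFields(rigidToField(p1, shape2),
                           rigidToField(p2, shape2))
  analytic <- rigidToField(composeRigid(p1, p2), shape2)
  i <- 5:25  # composition samples the outer field inside the grid only
  expect_equal(dispX(numeric)[i, i], dispX(analytic)[i, i],
               tolerance = 1e-9)
  expect_equal(dispY(numeric)[i, i], dispY(analytic)[i, i],
               tolerance = 1e-9)
})

test_that("rigid inversion and angle wrapping behave", {
  p <- RigidParams(theta = 0.4, tx = 3, ty = -2, center = c(7, 9))
  pid <- composeRigid(p, invertRigid(p))
  expect_equal(pid@theta, 0, tolerance = 1e-12)
  expect_equal(c(pid@tx, pid@ty), c(0, 0), tolerance = 1e-12)
  expect_equal(RigidParams(theta = 3 * pi)@theta, pi, tolerance = 1e-12)
})

test_that("deformation fields survive a serialization round trip", {
  f <- generateTruthDeformation("smooth", 3, c(20, 22), seed = 9)@field
  path <- tempfile(fileext = ".nii")
  writeField(f, path)
  g <- readField(path)
  expect_equal(dispX(g), dispX(f), tolerance = 1e-6)
  expect_equal(dispY(g), dispY(f), tolerance = 1e-6)
})
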