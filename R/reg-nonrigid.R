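# Non-rigid registration: demons (additive and diffeomorphic), cubic
# B-spline free-form deformation driven by adaptive stochastic gradient
# descent, total-variation-regularized local-correlation registration via an
# inexact ADMM, piecewise-rigid patch registration, and the two-step
# rigid + non-rigid driver.

#' Configuration for non-rigid registration
#'
#' @param method "demons", "bspline", "tv" or "piecewise".
#' @param pyramidLevels resolution levels (coarse-to-fine).
#' @param iterationsPerLevel iteration budget per level (0 returns the
#'   identity field, useful for staging tests).
#' @param demonsSigma Gaussian regularization sd in pixels (> 0).
#' @param diffeomorphic demons only: accumulate the update as a velocity
#'   exponentiated by scaling and squaring.
#' @param gridSpacing B-spline control-point spacing in pixels (>= 2).
#' @param bendingWeight weight of the bending-energy penalty on the control
#'   lattice (>= 0).
#' @param tvWeight total-variation weight upsilon (>= 0).
#' @param lccPatch local-correlation window size in pixels (odd, >= 3).
#' @param samplesPerIter random coordinates sampled per ASGD iteration.
#' @param patchSize piecewise-rigid patch side in pixels.
#' @param patchOverlap fractional patch overlap in [0, 1).
#' @param upsampleFactor sub-pixel precision denominator for patch shifts.
#' @param searchRadius patch-translation search radius in pixels.
#' @param seed integer RNG seed (ASGD sampling).
#' @return A classed list of settings.
#' @export
nonRigidConfig <- function(method = c("demons", "bspline", "tv", "piecewise"),
                           pyramidLevels = 3, iterationsPerLevel = 50,
                           demonsSigma = 1.5, diffeomorphic = FALSE,
                           gridSpacing = 8, bendingWeight = 0,
                           tvWeight = 0.5, lccPatch = 5,
                           samplesPerIter = 2000, patchSize = 32,
                           patchOverlap = 0.5, upsampleFactor = 10,
                           searchRadius = 8, seed = 1) {
  method <- match.arg(method)
  stopifnot(demonsSigma > 0, gridSpacing >= 2, lccPatch >= 3,
            lccPatch %% 2 == 1, patchOverlap >= 0, patchOverlap < 1,
            bendingWeight >= 0, tvWeight >= 0, iterationsPerLevel >= 0)
  structure(list(method = method, pyramidLevels = pyramidLevels,
                 iterationsPerLevel = iterationsPerLevel,
                 demonsSigma = demonsSigma, diffeomorphic = diffeomorphic,
                 gridSpacing = gridSpacing, bendingWeight = bendingWeight,
                 tvWeight = tvWeight, lccPatch = lccPatch,
                 samplesPerIter = samplesPerIter, patchSize = patchSize,
                 patchOverlap = patchOverlap,
                 upsampleFactor = upsampleFactor,
                 searchRadius = searchRadius, seed = seed),
            class = "nonRigidConfig")
}

#' Demons force field
#'
#' The per-pixel displacement of one demons iteration,
#' \eqn{d = (m - s) \nabla s / ((\nabla s)^2 + (m - s)^2)}, with s the
#' fixed (reference) image, m the moving image, and the gradient of s taken
#' by central differences; pixels with a vanishing denominator get zero
#' displacement. As written this is the force that pushes the moving image
#' toward the reference; the demons iteration subtracts it from the
#' backward displacement field.
#'
#' @param moving,fixed images of equal shape.
#' @return A \linkS4class{DeformationField} holding the force.
#' @export
demonsForce <- function(moving, fixed) {
  m <- .mat(moving); s <- .mat(fixed)
  if (!identical(dim(m), dim(s))) stop("image shapes differ")
  g <- .gradients(s)
  diff <- m - s
  denom <- g$dx^2 + g$dy^2 + diff^2
  fx <- ifelse(denom == 0, 0, diff * g$dx / denom)
  fy <- ifelse(denom == 0, 0, diff * g$dy / denom)
  DeformationField(dx = fx, dy = fy)
}

# Upsample a coarse-level field to `shape`, doubling displacement values
# (coarse pixels are twice as large).
.upsampleField <- function(field, shape) {
  DeformationField(dx = 2 * .upsampleTo(field@dx, shape),
                   dy = 2 * .upsampleTo(field@dy, shape))
}

#' Demons registration
#'
#' Iterates the demons force on the currently warped moving image,
#' accumulates the displacement, and regularizes the field by Gaussian
#' smoothing after every iteration, coarse-to-fine over a Gaussian pyramid.
#' In diffeomorphic mode the (smoothed) update is treated as a stationary
#' velocity and exponentiated by scaling and squaring before being composed
#' onto the field, which suppresses folding at large deformations. A
#' divergence guard stops a level early and restores the best field seen
#' when the mean squared intensity difference increases for five
#' consecutive iterations.
#'
#' @param moving,fixed images of equal shape.
#' @param config a \code{\link{nonRigidConfig}} (method "demons").
#' @return A backward \linkS4class{DeformationField}.
#' @export
registerDemons <- function(moving, fixed,
                           config = nonRigidConfig("demons")) {
  m <- .mat(moving); f <- .mat(fixed)
  if (!identical(dim(m), dim(f))) stop("image shapes differ")
  pyrM <- .pyramid(m, config$pyramidLevels)
  pyrF <- .pyramid(f, config$pyramidLevels)
  field <- identityField(dim(pyrM[[1]]))
  for (lv in seq_along(pyrM)) {
    mL <- pyrM[[lv]]; fL <- pyrF[[lv]]
    if (lv > 1) field <- .upsampleField(field, dim(mL))
    field <- .demonsLevel(mL, fL, field, config)
  }
  field
}

.demonsLevel <- function(m, f, field, config) {
  bestField <- field
  bestMse <- Inf
  prevMse <- Inf
  rises <- 0L
  for (it in seq_len(config$iterationsPerLevel)) {
    w <- intensities(warpImage(FUSImage(m), field, "cubic"))
    mse <- mean((w - f)^2)
    if (mse < bestMse) {
      bestMse <- mse; bestField <- field
    }
    # divergence guard: five strictly consecutive MSE increases
    if (mse > prevMse) {
      rises <- rises + 1L
      if (rises >= 5L) {
        warning("demons diverging; returning best field so far")
        return(bestField)
      }
    } else {
      rises <- 0L
    }
    prevMse <- mse
    force <- demonsForce(w, f)
    # update toward the reference = negative of the printed force;
    # fluid-like smoothing of the update suppresses speckle-driven noise
    ux <- .gaussSmooth(-force@dx, 1)
    uy <- .gaussSmooth(-force@dy, 1)
    if (config$diffeomorphic) {
      step <- .expField(ux, uy, 6L)
      field <- composeFields(field, step)
    } else {
      field <- DeformationField(field@dx + ux, field@dy + uy)
    }
    field <- DeformationField(.gaussSmooth(field@dx, config$demonsSigma),
                              .gaussSmooth(field@dy, config$demonsSigma))
  }
  field
}

#' B-spline free-form deformation registration by ASGD
#'
#' Optimizes the control-point displacements of a cubic B-spline lattice to
#' maximize the normalized cross-correlation between the warped moving
#' image and the fixed image (minus an optional bending-energy penalty on
#' the lattice). Each iteration draws \code{samplesPerIter} random
#' continuous coordinates (random-coordinate sampling), evaluates the NCC
#' gradient with respect to the control points through the analytic
#' B-spline tensor weights and the moving-image gradient, and takes an
#' adaptive step \eqn{\mu_{k+1} = \mu_k - a_k g(\mu_k)} with decaying gain
#' \eqn{a_k = a / (k + A)^{0.602}} on the direction-normalized gradient.
#' Runs in two stages: a lattice at twice the requested spacing for the
#' gross deformation, then the requested spacing.
#'
#' @param moving,fixed images of equal shape.
#' @param config a \code{\link{nonRigidConfig}} (method "bspline").
#' @return A backward \linkS4class{DeformationField}.
#' @export
registerBspline <- function(moving, fixed,
                            config = nonRigidConfig("bspline")) {
  m <- .mat(moving); f <- .mat(fixed)
  if (!identical(dim(m), dim(f))) stop("image shapes differ")
  shape <- dim(m)
  if (config$gridSpacing * 4 > min(shape)) {
    stop("control grid coarser than the image can support")
  }
  if (config$iterationsPerLevel == 0) return(identityField(shape))
  spacings <- unique(c(config$gridSpacing * 2, config$gridSpacing))
  grid <- NULL
  .withSeed(config$seed, {
    for (sp in spacings) {
      g <- bsplineGrid(shape, sp)
      if (!is.null(grid)) {
        # seed the finer lattice with the field recovered so far
        f0 <- bsplineToField(grid, shape)
        g <- .fitGridToField(g, f0)
      }
      grid <- .asgdLevel(m, f, g, shape, config)
    }
  })
  bsplineToField(grid, shape)
}

# Least-squares-free lattice seeding: sample the target field at control
# point locations (clamped); cubic smoothing keeps this close enough for a
# warm start.
.fitGridToField <- function(grid, field) {
  Gy <- nrow(grid@coefDx); Gx <- ncol(grid@coefDx)
  ys <- grid@origin[1] + (seq_len(Gy) - 1) * grid@spacing
  xs <- grid@origin[2] + (seq_len(Gx) - 1) * grid@spacing
  ys <- pmin(pmax(ys, 1), nrow(field@dx))
  xs <- pmin(pmax(xs, 1), ncol(field@dx))
  gy <- rep(ys, times = Gx); gx <- rep(xs, each = Gy)
  grid@coefDx <- matrix(.interp2(field@dx, gy, gx, "linear")$values, Gy, Gx)
  grid@coefDy <- matrix(.interp2(field@dy, gy, gx, "linear")$values, Gy, Gx)
  grid
}

.asgdLevel <- function(m, f, grid, shape, config) {
  H <- shape[1]; W <- shape[2]
  mg <- .gradients(m)
  a <- 1.0; A <- 20; alpha <- 0.602
  n <- config$samplesPerIter
  for (k in seq_len(config$iterationsPerLevel)) {
    ys <- runif(n, 1, H); xs <- runif(n, 1, W)
    sup <- .bsplineSupport(grid, ys, xs)
    cx <- as.vector(grid@coefDx); cy <- as.vector(grid@coefDy)
    dx <- rowSums(sup$w * matrix(cx[sup$i], n))
    dy <- rowSums(sup$w * matrix(cy[sup$i], n))
    py <- ys + dy; px <- xs + dx
    wv <- .interp2(m, py, px, "linear")$values
    fv <- .interp2(f, ys, xs, "linear")$values
    gxv <- .interp2(mg$dx, py, px, "linear")$values
    gyv <- .interp2(mg$dy, py, px, "linear")$values
    mw <- mean(wv); mf <- mean(fv)
    sw <- sqrt(mean((wv - mw)^2)); sf <- sqrt(mean((fv - mf)^2))
    if (sw < 1e-9 || sf < 1e-9) next
    ncc <- mean((wv - mw) * (fv - mf)) / (sw * sf)
    # d NCC / d w_i
    dn <- ((fv - mf) / (sw * sf) - ncc * (wv - mw) / sw^2) / n
    gx <- .scatterAdd(sup, dn * gxv, length(cx))
    gy <- .scatterAdd(sup, dn * gyv, length(cy))
    if (config$bendingWeight > 0) {
      gx <- gx - config$bendingWeight *
        as.vector(.bendingGrad(grid@coefDx))
      gy <- gy - config$bendingWeight *
        as.vector(.bendingGrad(grid@coefDy))
    }
    gmax <- max(abs(c(gx, gy)))
    if (gmax < 1e-12) next
    gain <- a / (k + A)^alpha
    grid@coefDx <- grid@coefDx + matrix(gain * gx / gmax, nrow(grid@coefDx))
    grid@coefDy <- grid@coefDy + matrix(gain * gy / gmax, nrow(grid@coefDy))
  }
  grid
}

# Accumulate per-sample weighted contributions onto the control vector.
.scatterAdd <- function(sup, vals, nCoef) {
  out <- numeric(nCoef)
  contrib <- sup$w * vals
  for (k in seq_len(ncol(sup$i))) {
    acc <- rowsum(contrib[, k], sup$i[, k])
    out[as.integer(rownames(acc))] <- out[as.integer(rownames(acc))] + acc
  }
  out
}

# Gradient of the discrete bending energy sum(Dyy^2 + 2 Dxy^2 + Dxx^2) of a
# control lattice (zero boundary handling).
.bendingGrad <- function(cf) {
  pad <- function(m, di, dj) {
    G <- matrix(0, nrow(cf), ncol(cf))
    si <- seq_len(nrow(cf)) + di; sj <- seq_len(ncol(cf)) + dj
    ok_i <- si >= 1 & si <= nrow(cf); ok_j <- sj >= 1 & sj <= ncol(cf)
    G[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
    G
  }
  dyy <- pad(cf, -1, 0) - 2 * cf + pad(cf, 1, 0)
  dxx <- pad(cf, 0, -1) - 2 * cf + pad(cf, 0, 1)
  dxy <- pad(cf, 1, 1) - pad(cf, 1, -1) - pad(cf, -1, 1) + pad(cf, -1, -1)
  dxy <- dxy / 4
  # adjoint application of each stencil
  g <- (pad(dyy, -1, 0) - 2 * dyy + pad(dyy, 1, 0)) +
    (pad(dxx, 0, -1) - 2 * dxx + pad(dxx, 0, 1)) +
    2 * (pad(dxy, 1, 1) - pad(dxy, 1, -1) - pad(dxy, -1, 1) +
           pad(dxy, -1, -1)) / 4
  2 * g
}

#' Isotropic total-variation energy of a displacement field
#'
#' \eqn{\upsilon \sum_l \sqrt{\sum_{i,j} (\nabla_i d_j[l])^2}}: the 2,1-norm
#' of the displacement gradient matrix, with forward differences (the last
#' row/column difference is taken as zero) scaled by the weight
#' \code{tvWeight}.
#'
#' @param field a \linkS4class{DeformationField}.
#' @param tvWeight the weight upsilon.
#' @return The scalar energy (0 for constant fields).
#' @export
tvEnergy <- function(field, tvWeight = 1) {
  g <- .forwardDiffs(field)
  tvWeight * sum(sqrt(g$xx^2 + g$yx^2 + g$xy^2 + g$yy^2))
}

# Forward differences of both components; zero at the trailing border.
# Naming: g$ab = d(d_a)/d b.
.forwardDiffs <- function(field) {
  fd <- function(m, axis) {
    H <- nrow(m); W <- ncol(m)
    out <- matrix(0, H, W)
    if (axis == "x" && W > 1) out[, 1:(W - 1)] <- m[, 2:W] - m[, 1:(W - 1)]
    if (axis == "y" && H > 1) out[1:(H - 1), ] <- m[2:H, ] - m[1:(H - 1), ]
    out
  }
  list(xx = fd(field@dx, "x"), xy = fd(field@dx, "y"),
       yx = fd(field@dy, "x"), yy = fd(field@dy, "y"))
}

# Adjoint of the forward-difference operator (negative divergence with the
# matching boundary convention).
.forwardDiffAdjoint <- function(gx, axis) {
  H <- nrow(gx); W <- ncol(gx)
  out <- matrix(0, H, W)
  if (axis == "x" && W > 1) {
    out[, 1] <- -gx[, 1]
    if (W > 2) out[, 2:(W - 1)] <- gx[, 1:(W - 2)] - gx[, 2:(W - 1)]
    out[, W] <- gx[, W - 1]
  }
  if (axis == "y" && H > 1) {
    out[1, ] <- -gx[1, ]
    if (H > 2) out[2:(H - 1), ] <- gx[1:(H - 2), ] - gx[2:(H - 1), ]
    out[H, ] <- gx[H - 1, ]
  }
  out
}

# Local-correlation ascent force. Both images are normalized to local
# z-scores over the Gaussian-weighted lccPatch windows (so that matching
# the normalized intensities maximizes the patch-weighted correlation
# coefficient), then a demons-type step on the normalized pair gives a
# well-conditioned, bounded update toward higher local correlation.
.lccForce <- function(w, s, patch) {
  r <- (patch - 1) / 2
  k <- .gaussKernel(patch / 5, r)
  sm <- function(m) .convSep(m, k)
  zsc <- function(x) {
    mu <- sm(x)
    v <- pmax(sm(x * x) - mu^2, 1e-6)
    (x - mu) / sqrt(v)
  }
  f <- demonsForce(zsc(w), zsc(s))
  list(fx = -f@dx, fy = -f@dy)  # toward the reference
}

#' Total-variation-regularized registration (LCC + ADMM)
#'
#' Minimizes the negated local correlation coefficient (Gaussian-weighted
#' windows of \code{lccPatch} pixels) plus the isotropic total-variation
#' energy of the displacement field, by an inexact ADMM: the TV term is
#' split onto an auxiliary gradient variable updated by group soft
#' thresholding, the field subproblem takes first-order steps combining the
#' LCC ascent force with the augmented-Lagrangian coupling, and a scaled
#' dual variable accumulates the constraint residual. Coarse-to-fine.
#'
#' @param moving,fixed images of equal shape.
#' @param config a \code{\link{nonRigidConfig}} (method "tv"); the
#'   iteration budget per level is the number of outer ADMM iterations.
#' @return A backward \linkS4class{DeformationField}.
#' @export
registerTV <- function(moving, fixed, config = nonRigidConfig("tv")) {
  m <- .mat(moving); f <- .mat(fixed)
  if (!identical(dim(m), dim(f))) stop("image shapes differ")
  pyrM <- .pyramid(m, config$pyramidLevels)
  pyrF <- .pyramid(f, config$pyramidLevels)
  field <- identityField(dim(pyrM[[1]]))
  for (lv in seq_along(pyrM)) {
    mL <- pyrM[[lv]]; fL <- pyrF[[lv]]
    if (lv > 1) field <- .upsampleField(field, dim(mL))
    field <- .tvLevel(mL, fL, field, config)
  }
  field
}

.tvLevel <- function(m, f, field, config) {
  rho <- 2
  tau <- 0.1
  innerSteps <- 10L
  changeTol <- 0.005  # mean |update| (px) below which the level has converged
  shape <- dim(m)
  zero <- matrix(0, shape[1], shape[2])
  z <- list(xx = zero, xy = zero, yx = zero, yy = zero)
  u <- z
  r <- (config$lccPatch - 1) / 2
  kern <- .gaussKernel(config$lccPatch / 5, r)
  sm <- function(x) .convSep(x, kern)
  zsc <- function(x) {
    mu <- sm(x); v <- pmax(sm(x * x) - mu^2, 1e-6); (x - mu) / sqrt(v)
  }
  zf <- zsc(f)
  # step-size balance: as the TV weight grows the data step must shrink so
  # the regularized stationary point (a near-constant field in the limit)
  # is actually reachable within the iteration budget
  forceScale <- 1 / (1 + config$tvWeight / 10)
  # force support: exclude a thin frame at the image border and any pixel
  # whose warped sample left the field of view (fill-0 edges otherwise
  # drive runaway displacements there)
  bw <- 3L
  border <- matrix(1, shape[1], shape[2])
  border[c(seq_len(bw), shape[1] - seq_len(bw) + 1L), ] <- 0
  border[, c(seq_len(bw), shape[2] - seq_len(bw) + 1L)] <- 0
  converged <- FALSE
  for (it in seq_len(config$iterationsPerLevel)) {
    wo <- warpImage(FUSImage(m), field, "cubic")
    w <- intensities(wo)
    zw <- zsc(w)
    # data step: demons-type force on the locally normalized pair
    # (bounded ascent on the patch-weighted local correlation)
    force <- demonsForce(zw, zf)
    msk <- border * (validMask(wo) > 0)
    fx <- .gaussSmooth(-force@dx * msk, 1) * forceScale
    fy <- .gaussSmooth(-force@dy * msk, 1) * forceScale
    dHalf <- DeformationField(field@dx + fx, field@dy + fy)
    # z-update: group soft-thresholding of D(d) + u
    g <- .forwardDiffs(dHalf)
    v <- list(xx = g$xx + u$xx, xy = g$xy + u$xy,
              yx = g$yx + u$yx, yy = g$yy + u$yy)
    norm <- sqrt(v$xx^2 + v$xy^2 + v$yx^2 + v$yy^2)
    shrink <- pmax(0, 1 - (config$tvWeight / rho) / pmax(norm, 1e-12))
    z <- lapply(v, function(c) c * shrink)
    # d-update: proximal steps toward dHalf under the split constraint
    d <- dHalf
    for (inner in seq_len(innerSteps)) {
      g <- .forwardDiffs(d)
      rx <- .forwardDiffAdjoint(g$xx - z$xx + u$xx, "x") +
        .forwardDiffAdjoint(g$xy - z$xy + u$xy, "y")
      ry <- .forwardDiffAdjoint(g$yx - z$yx + u$yx, "x") +
        .forwardDiffAdjoint(g$yy - z$yy + u$yy, "y")
      d <- DeformationField(
        dx = d@dx - tau * ((d@dx - dHalf@dx) + rho * rx),
        dy = d@dy - tau * ((d@dy - dHalf@dy) + rho * ry)
      )
    }
    change <- mean(sqrt((d@dx - field@dx)^2 + (d@dy - field@dy)^2))
    field <- d
    # dual ascent on the constraint residual
    g <- .forwardDiffs(field)
    u <- list(xx = u$xx + g$xx - z$xx, xy = u$xy + g$xy - z$xy,
              yx = u$yx + g$yx - z$yx, yy = u$yy + g$yy - z$yy)
    if (change < changeTol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && config$iterationsPerLevel > 0) {
    warning("TV registration stopped at the iteration budget; ",
            "returning the current estimate")
  }
  field
}

#' Piecewise-rigid patch registration
#'
#' Splits the field of view into overlapping square patches, estimates a
#' sub-pixel rigid translation per patch by normalized cross-correlation
#' (quadratic peak refinement at 1/\code{upsampleFactor} precision), imputes
#' textureless patches from their neighbors, and interpolates the patch
#' shifts bilinearly into a smooth dense motion field.
#'
#' @param moving,fixed images of equal shape; \code{patchSize} must be
#'   smaller than both sides.
#' @param config a \code{\link{nonRigidConfig}} (method "piecewise").
#' @return A backward \linkS4class{DeformationField}.
#' @export
registerPiecewiseRigid <- function(moving, fixed,
                                   config = nonRigidConfig("piecewise")) {
  m <- .mat(moving); f <- .mat(fixed)
  if (!identical(dim(m), dim(f))) stop("image shapes differ")
  H <- nrow(m); W <- ncol(m)
  bs <- config$patchSize
  if (bs >= min(H, W)) stop("patchSize must be smaller than the image")
  step <- max(2L, round(bs * (1 - config$patchOverlap)))
  shifts <- .blockShifts(m, f, bs, step, config$searchRadius,
                         upsample = config$upsampleFactor)
  ys <- sort(unique(shifts$cy)); xs <- sort(unique(shifts$cx))
  ny <- length(ys); nx <- length(xs)
  # .blockShifts enumerates x fastest within each row of patches
  dyG <- matrix(shifts$dy, ny, nx, byrow = TRUE)
  dxG <- matrix(shifts$dx, ny, nx, byrow = TRUE)
  pkG <- matrix(shifts$peak, ny, nx, byrow = TRUE)
  # low-confidence patches (flat texture, field-of-view edges) are imputed
  # from their valid neighbors
  bad <- !is.finite(dyG) | !is.finite(pkG) | pkG < 0.7
  if (all(bad)) {
    dyG[] <- 0; dxG[] <- 0
  } else if (any(bad)) {
    dyG <- .imputeGrid(dyG, bad)
    dxG <- .imputeGrid(dxG, bad)
  }
  # bilinear interpolation of the patch-center grid to the full field,
  # constant beyond the outer centers
  gy <- pmin(pmax((seq_len(H) - ys[1]) /
                    ifelse(ny > 1, diff(ys)[1], 1) + 1, 1), ny)
  gx <- pmin(pmax((seq_len(W) - xs[1]) /
                    ifelse(nx > 1, diff(xs)[1], 1) + 1, 1), nx)
  pts <- expand.grid(y = gy, x = gx)
  dy <- matrix(.interp2(dyG, pts$y, pts$x, "linear")$values, H, W)
  dx <- matrix(.interp2(dxG, pts$y, pts$x, "linear")$values, H, W)
  DeformationField(dx = dx, dy = dy)
}

# Replace flagged entries of a small grid by the mean of their valid
# 4-neighbors, sweeping until all are filled (fallback: global valid mean).
.imputeGrid <- function(g, bad) {
  ny <- nrow(g); nx <- ncol(g)
  g[bad] <- NA_real_
  while (any(is.na(g))) {
    filled <- FALSE
    for (i in seq_len(ny)) {
      for (j in seq_len(nx)) {
        if (!is.na(g[i, j])) next
        nb <- c(if (i > 1) g[i - 1, j], if (i < ny) g[i + 1, j],
                if (j > 1) g[i, j - 1], if (j < nx) g[i, j + 1])
        nb <- nb[!is.na(nb)]
        if (length(nb)) {
          g[i, j] <- mean(nb)
          filled <- TRUE
        }
      }
    }
    if (!filled) {
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      break
    }
  }
  g
}

#' Two-step combined registration
#'
#' Runs rigid registration first, warps the moving image with the rigid
#' field, runs the configured non-rigid method on the rigid-aligned image,
#' and returns the composition of the two backward fields. With a non-rigid
#' iteration budget of zero the result equals the rigid field exactly.
#'
#' @param moving,fixed images of equal shape.
#' @param rigidConfig a \code{\link{rigidRegConfig}}.
#' @param nonrigidConfig a \code{\link{nonRigidConfig}}.
#' @return A backward \linkS4class{DeformationField}; the rigid stage's
#'   \linkS4class{RigidParams} are attached as attribute \code{"rigid"}.
#' @export
registerCombined <- function(moving, fixed,
                             rigidConfig = rigidRegConfig(),
                             nonrigidConfig = nonRigidConfig("demons")) {
  m <- .mat(moving); f <- .mat(fixed)
  p <- registerRigid(m, f, rigidConfig)
  fieldR <- rigidToField(p, dim(m))
  warped <- warpImage(FUSImage(m), fieldR)
  fieldN <- registerNonRigid(intensities(warped), f, nonrigidConfig)
  total <- composeFields(fieldR, fieldN)
  attr(total, "rigid") <- p
  total
}

#' Dispatch a non-rigid method by configuration
#'
#' @param moving,fixed images of equal shape.
#' @param config a \code{\link{nonRigidConfig}}; its \code{method} selects
#'   the algorithm.
#' @return A backward \linkS4class{DeformationField}.
#' @export
registerNonRigid <- function(moving, fixed, config) {
  if (config$iterationsPerLevel == 0 && config$method != "piecewise") {
    return(identityField(dim(.mat(moving))))
  }
  switch(config$method,
    demons = registerDemons(moving, fixed, config),
    bspline = registerBspline(moving, fixed, config),
    tv = registerTV(moving, fixed, config),
    piecewise = registerPiecewiseRigid(moving, fixed, config),
    stop("unknown non-rigid method: ", config$method))
}
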