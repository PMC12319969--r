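# Intensity-based rigid (Euler) registration with three optimizer/metric
# pairings: a (1+1) evolution strategy on mutual information, a cyclic
# one-dimensional golden-section search on the correlation ratio, and block
# matching with NCC followed by a trimmed-least-squares rigid fit. All run
# coarse-to-fine on a Gaussian pyramid.

#' Configuration for rigid registration
#'
#' @param optimizer "es11" ((1+1) evolution strategy), "cyclic1d"
#'   (per-parameter golden-section search), or "blockmatch".
#' @param metric "mutual_information", "correlation_ratio" or "ncc"; the
#'   default pairs the metric the optimizer was described with
#'   (es11 + MI, cyclic1d + CR, blockmatch + NCC).
#' @param pyramidLevels number of resolution levels (>= 1).
#' @param maxIterations iteration budget per level.
#' @param histogramBins bins for MI / CR (>= 8).
#' @param blockSize block side in pixels for blockmatch.
#' @param searchRadius block-match search radius in pixels.
#' @param trimFraction fraction of worst block correspondences discarded per
#'   trimmed-least-squares pass, in (0, 1).
#' @param seed integer RNG seed (es11 mutations).
#' @return A classed list of settings.
#' @export
rigidRegConfig <- function(optimizer = c("es11", "cyclic1d", "blockmatch"),
                           metric = NULL, pyramidLevels = 3,
                           maxIterations = 120, histogramBins = 32,
                           blockSize = 12, searchRadius = 8,
                           trimFraction = 0.5, seed = 1) {
  optimizer <- match.arg(optimizer)
  if (is.null(metric)) {
    metric <- switch(optimizer, es11 = "mutual_information",
                     cyclic1d = "correlation_ratio", blockmatch = "ncc")
  }
  metric <- match.arg(metric, c("mutual_information", "correlation_ratio",
                                "ncc"))
  stopifnot(pyramidLevels >= 1, histogramBins >= 8,
            trimFraction > 0, trimFraction < 1)
  structure(list(optimizer = optimizer, metric = metric,
                 pyramidLevels = pyramidLevels,
                 maxIterations = maxIterations,
                 histogramBins = histogramBins, blockSize = blockSize,
                 searchRadius = searchRadius, trimFraction = trimFraction,
                 seed = seed),
            class = "rigidRegConfig")
}

# Similarity of moving warped by params against fixed (higher is better).
.rigidSimilarity <- function(moving, fixed, params, metric, bins) {
  w <- warpImage(FUSImage(moving), rigidToField(params, dim(moving)),
                 interpolation = "linear")
  wm <- intensities(w)
  if (stats::sd(wm) == 0) return(-Inf)
  switch(metric,
    mutual_information = mutualInformation(wm, fixed, bins = bins),
    correlation_ratio = correlationRatio(fixed, wm, bins = bins),
    ncc = tryCatch(nccGlobal(wm, fixed), error = function(e) -Inf))
}

#' Rigid registration of a moving image to a fixed image
#'
#' Finds the Euler transform (rotation about the image center plus
#' translation) maximizing the configured similarity, coarse-to-fine over a
#' Gaussian pyramid. The per-evaluation best-so-far cost trace is attached
#' as attribute \code{"trace"} (monotone non-increasing; cost is the negated
#' similarity). If the similarity is undefined at the initial overlap the
#' identity is returned with \code{converged = FALSE}.
#'
#' @param moving,fixed \linkS4class{FUSImage}s or matrices of equal shape.
#' @param config a \code{\link{rigidRegConfig}}.
#' @return A \linkS4class{RigidParams} with the rotation centered on the
#'   image center.
#' @export
registerRigid <- function(moving, fixed, config = rigidRegConfig()) {
  m <- .mat(moving); f <- .mat(fixed)
  if (!identical(dim(m), dim(f))) stop("image shapes differ")
  center <- c((nrow(m) + 1) / 2, (ncol(m) + 1) / 2)
  init <- .rigidSimilarity(m, f, RigidParams(center = center),
                           config$metric, config$histogramBins)
  if (!is.finite(init)) {
    warning("similarity undefined at initialization; returning identity")
    p <- RigidParams(center = center, converged = FALSE)
    attr(p, "trace") <- numeric()
    return(p)
  }
  pyrM <- .pyramid(m, config$pyramidLevels)
  pyrF <- .pyramid(f, config$pyramidLevels)
  theta <- 0; tx <- 0; ty <- 0
  trace <- numeric()
  .withSeed(config$seed, {
    for (lv in seq_along(pyrM)) {
      scl <- nrow(pyrM[[lv]]) / nrow(m)  # coarse-level pixels are larger
      mL <- pyrM[[lv]]; fL <- pyrF[[lv]]
      cL <- c((nrow(mL) + 1) / 2, (ncol(mL) + 1) / 2)
      simL <- function(v) {
        .rigidSimilarity(mL, fL,
                         RigidParams(theta = wrapAngle(v[1]), tx = v[2],
                                     ty = v[3], center = cL),
                         config$metric, config$histogramBins)
      }
      v <- c(theta, tx * scl, ty * scl)
      res <- switch(config$optimizer,
        es11 = .optimES11(simL, v, config$maxIterations),
        cyclic1d = .optimCyclic(simL, v, config$maxIterations,
                                radius = config$searchRadius),
        blockmatch = .optimBlockmatch(mL, fL, cL, v, config))
      v <- res$par
      trace <- c(trace, if (length(trace))
        pmin(res$trace, min(trace)) else res$trace)
      theta <- v[1]; tx <- v[2] / scl; ty <- v[3] / scl
    }
  })
  out <- RigidParams(theta = theta, tx = tx, ty = ty, center = center)
  attr(out, "trace") <- cummin(trace)
  out
}

# (1+1) evolution strategy: Gaussian mutation of (theta, tx, ty); the
# offspring replaces the parent when its fitness is better or equal; step
# size adapted by the 1/5-success rule. Initial sigma: 2 px / ~2 deg.
.optimES11 <- function(fn, v, maxIter) {
  sigma <- c(2 * pi / 180 * 2, 2, 2)
  best <- fn(v)
  trace <- -best
  success <- 0L
  for (k in seq_len(maxIter)) {
    cand <- v + rnorm(3) * sigma
    fc <- fn(cand)
    if (fc >= best) {
      v <- cand; best <- fc; success <- success + 1L
    }
    if (k %% 10 == 0) {
      rate <- success / 10
      sigma <- sigma * if (rate > 0.2) 1.3 else 0.75
      success <- 0L
    }
    trace <- c(trace, -best)
  }
  list(par = v, trace = trace)
}

# Cyclic one-dimensional optimization: golden-section search (stats::
# optimize) on each parameter in turn, cycling until the relative cost
# change over a full cycle drops below 1e-6.
.optimCyclic <- function(fn, v, maxIter, radius = 8) {
  widths <- c(10 * pi / 180, radius, radius)
  best <- fn(v)
  trace <- -best
  for (cycle in seq_len(max(1, maxIter %/% 3))) {
    prev <- best
    for (j in 1:3) {
      g <- function(t) {
        vv <- v; vv[j] <- t; -fn(vv)
      }
      opt <- stats::optimize(g, lower = v[j] - widths[j],
                             upper = v[j] + widths[j], tol = 1e-4)
      if (-opt$objective >= best) {
        v[j] <- opt$minimum; best <- -opt$objective
      }
      trace <- c(trace, -best)
    }
    widths <- widths * 0.7  # contract the bracket around the optimum
    if (abs(best - prev) <= 1e-6 * max(1, abs(prev))) break
  }
  list(par = v, trace = trace)
}

# Block matching: per-block integer + subpixel translation by FFT NCC, then
# a rigid (Procrustes) fit to the block-center correspondences with
# iterative trimming of the worst residuals.
.optimBlockmatch <- function(mL, fL, center, v, config) {
  bs <- config$blockSize
  H <- nrow(mL); W <- ncol(mL)
  step <- max(2L, bs %/% 2L)
  shifts <- .blockShifts(mL, fL, bs, step, config$searchRadius,
                         upsample = 10)
  good <- is.finite(shifts$dx) & is.finite(shifts$dy) & shifts$peak > 0.3
  if (sum(good) < 3) {
    return(list(par = v, trace = -.safeSim(mL, fL, v, center, config)))
  }
  # fixed-grid block centers map to moving positions center + shift
  px <- shifts$cx[good]; py <- shifts$cy[good]
  qx <- px + shifts$dx[good]; qy <- py + shifts$dy[good]
  keep <- seq_along(px)
  for (it in 1:5) {
    fit <- .rigidProcrustes(px[keep], py[keep], qx[keep], qy[keep], center)
    res <- sqrt((fit$pred$x - qx[keep])^2 + (fit$pred$y - qy[keep])^2)
    ord <- order(res)
    nkeep <- max(3L, ceiling(length(keep) * (1 - config$trimFraction)))
    keep <- keep[ord[seq_len(nkeep)]]
  }
  fit <- .rigidProcrustes(px[keep], py[keep], qx[keep], qy[keep], center)
  par <- c(fit$theta, fit$tx, fit$ty)
  list(par = par, trace = -.safeSim(mL, fL, par, center, config))
}

.safeSim <- function(mL, fL, v, center, config) {
  s <- .rigidSimilarity(mL, fL,
                        RigidParams(theta = wrapAngle(v[1]), tx = v[2],
                                    ty = v[3], center = center),
                        config$metric, config$histogramBins)
  if (is.finite(s)) s else -1
}

# Closed-form 2D rigid fit. Block matching observes, for fixed-grid block
# centers p, the matching moving positions q = p + shift; under the backward
# convention q = T^{-1}(p) = A (p - c - t) + c with A = [[cos t, sin t],
# [-sin t, cos t]] for forward angle theta. Procrustes on the centered
# point sets gives A, then the translation from the centroids.
.rigidProcrustes <- function(px, py, qx, qy, center) {
  cX <- center[2]; cY <- center[1]
  mpx <- mean(px); mpy <- mean(py)
  mqx <- mean(qx); mqy <- mean(qy)
  ax <- px - mpx; ay <- py - mpy
  bx <- qx - mqx; by <- qy - mqy
  phi <- atan2(sum(ax * by - ay * bx), sum(ax * bx + ay * by))
  theta <- -phi  # A equals the standard rotation by -theta
  ct <- cos(theta); st <- sin(theta)
  # centroid relation: qbar - c = A (pbar - c - t)
  tx <- (mpx - cX) - (ct * (mqx - cX) - st * (mqy - cY))
  ty <- (mpy - cY) - (st * (mqx - cX) + ct * (mqy - cY))
  ux <- px - cX - tx; uy <- py - cY - ty
  pred <- list(x = ct * ux + st * uy + cX,
               y = -st * ux + ct * uy + cY)
  list(theta = theta, tx = tx, ty = ty, pred = pred)
}

# Sub-pixel translation estimates for overlapping blocks via FFT NCC with
# local upsampled-DFT refinement. Returns block centers (fixed grid) and
# the shift (moving position - fixed position) per block.
.blockShifts <- function(mov, fix, bs, step, radius, upsample = 10) {
  H <- nrow(mov); W <- ncol(mov)
  ys <- seq(1, max(1, H - bs + 1), by = step)
  xs <- seq(1, max(1, W - bs + 1), by = step)
  n <- length(ys) * length(xs)
  cy <- numeric(n); cx <- numeric(n)
  dy <- rep(NA_real_, n); dx <- rep(NA_real_, n); pk <- rep(NA_real_, n)
  k <- 0L
  for (y0 in ys) {
    for (x0 in xs) {
      k <- k + 1L
      yy <- y0:min(y0 + bs - 1, H); xx <- x0:min(x0 + bs - 1, W)
      cy[k] <- mean(yy); cx[k] <- mean(xx)
      fpatch <- fix[yy, xx, drop = FALSE]
      # search window in the moving image around the block
      wy <- max(1, y0 - radius):min(H, min(y0 + bs - 1, H) + radius)
      wx <- max(1, x0 - radius):min(W, min(x0 + bs - 1, W) + radius)
      mwin <- mov[wy, wx, drop = FALSE]
      if (stats::sd(fpatch) < 1e-8 || stats::sd(mwin) < 1e-8) next
      sh <- .subpixelShift(fpatch, mwin, upsample)
      if (is.null(sh)) next
      # sh gives the offset of the best-matching patch inside the window
      dy[k] <- (wy[1] + sh$y - 1) - y0
      dx[k] <- (wx[1] + sh$x - 1) - x0
      pk[k] <- sh$peak
    }
  }
  # impute textureless blocks from the mean of estimated neighbors
  bad <- !is.finite(dx)
  if (any(bad) && any(!bad)) {
    dy[bad] <- mean(dy[!bad]); dx[bad] <- mean(dx[!bad])
    pk[bad] <- 0
  }
  list(cy = cy, cx = cx, dy = dy, dx = dx, peak = pk)
}

# Normalized cross-correlation of a template against every position of a
# larger window (direct evaluation; windows here are small), refined to
# sub-pixel precision by a per-axis search over interpolated fractional
# shifts on a 1/upsample grid.
.subpixelShift <- function(template, window, upsample = 10) {
  th <- nrow(template); tw <- ncol(template)
  wh <- nrow(window); ww <- ncol(window)
  ny <- wh - th + 1; nx <- ww - tw + 1
  if (ny < 1 || nx < 1) return(NULL)
  tz <- template - mean(template)
  tden <- sqrt(sum(tz^2))
  if (tden < 1e-10) return(NULL)
  cc <- matrix(-Inf, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      p <- window[i:(i + th - 1), j:(j + tw - 1)]
      pz <- p - mean(p)
      pden <- sqrt(sum(pz^2))
      if (pden < 1e-10) next
      cc[i, j] <- sum(tz * pz) / (tden * pden)
    }
  }
  ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  py <- ij[1]; px <- ij[2]
  # fractional refinement: evaluate interpolated NCC on a 1/upsample grid
  # around the integer peak, one axis at a time
  yy0 <- rep(seq_len(th), tw); xx0 <- rep(seq_len(tw), each = th)
  nccAt <- function(fy, fx) {
    v <- .interp2(window, yy0 + (py - 1) + fy, xx0 + (px - 1) + fx,
                  method = "linear")
    if (!all(v$inside)) return(-Inf)
    pz <- v$values - mean(v$values)
    pden <- sqrt(sum(pz^2))
    if (pden < 1e-10) return(-Inf)
    sum(tz * pz) / (tden * pden)
  }
  fr <- seq(-1, 1, by = 1 / upsample)
  vy <- vapply(fr, function(f) nccAt(f, 0), 0)
  fy <- fr[which.max(vy)]
  vx <- vapply(fr, function(f) nccAt(fy, f), 0)
  fx <- fr[which.max(vx)]
  list(y = py + fy, x = px + fx, peak = max(vx))
}
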