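# Synthetic vascular phantoms. The generator emulates what a 2D sagittal
# power-Doppler vascular map looks like to a registration algorithm: bright
# curvilinear vessels with Gaussian cross-sections over a multiplicative
# speckle background, at the acquisition geometry of a typical mouse fUSI
# session (12.8 mm width x 10 mm depth at 0.1 mm isotropic pixels, i.e.
# 100 x 128). Cross-subject cohorts add a smooth diffeomorphic warp, a rigid
# pose difference and vessel-intensity jitter to a shared template; time
# series add small per-frame noise and, optionally, a multiplicative
# regional activation.

#' Specification of a synthetic vascular phantom
#'
#' @slot gridHeight,gridWidth phantom shape in pixels (default 100 x 128,
#'   i.e. 10 mm depth x 12.8 mm width at 0.1 mm pixels).
#' @slot pixelSpacing isotropic pixel spacing in mm.
#' @slot nVessels number of vessel centerlines.
#' @slot vesselWidthRange vessel full width range in pixels.
#' @slot vesselIntensityRange peak vessel intensity range in (0, 1].
#' @slot backgroundLevel mean tissue background intensity.
#' @slot speckleSigma log-sd of the multiplicative speckle texture.
#' @slot frameNoiseSigma sd of additive per-frame acquisition noise.
#' @slot seed integer RNG seed; same spec + seed is bit-identical.
#' @export
setClass("PhantomSpec",
  representation(
    gridHeight = "numeric", gridWidth = "numeric", pixelSpacing = "numeric",
    nVessels = "numeric", vesselWidthRange = "numeric",
    vesselIntensityRange = "numeric", backgroundLevel = "numeric",
    speckleSigma = "numeric", frameNoiseSigma = "numeric", seed = "numeric"
  ),
  prototype(
    gridHeight = 100, gridWidth = 128, pixelSpacing = 0.1,
    nVessels = 12, vesselWidthRange = c(1.5, 4),
    vesselIntensityRange = c(0.45, 1), backgroundLevel = 0.15,
    speckleSigma = 0.25, frameNoiseSigma = 0.003, seed = 1
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@gridHeight < 1 || object@gridWidth < 1) {
    msg <- c(msg, "grid dimensions must be positive")
  }
  if (object@nVessels < 0) msg <- c(msg, "nVessels must be >= 0")
  if (object@pixelSpacing <= 0) msg <- c(msg, "pixelSpacing must be > 0")
  if (any(object@vesselIntensityRange <= 0) ||
      any(object@vesselIntensityRange > 1)) {
    msg <- c(msg, "vesselIntensityRange must lie in (0, 1]")
  }
  if (object@backgroundLevel < 0 || object@backgroundLevel > 1) {
    msg <- c(msg, "backgroundLevel must lie in [0, 1]")
  }
  if (object@speckleSigma < 0 || object@frameNoiseSigma < 0) {
    msg <- c(msg, "noise parameters must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Create a phantom specification
#'
#' @param gridHeight,gridWidth phantom shape in pixels.
#' @param pixelSpacing isotropic pixel spacing in mm.
#' @param nVessels number of vessels.
#' @param vesselWidthRange full-width range of vessels in pixels.
#' @param vesselIntensityRange peak intensity range in (0, 1].
#' @param backgroundLevel mean background intensity.
#' @param speckleSigma log-sd of multiplicative speckle.
#' @param frameNoiseSigma sd of per-frame additive noise.
#' @param seed integer RNG seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(gridHeight = 100, gridWidth = 128, pixelSpacing = 0.1,
                        nVessels = 12, vesselWidthRange = c(1.5, 4),
                        vesselIntensityRange = c(0.45, 1),
                        backgroundLevel = 0.15, speckleSigma = 0.25,
                        frameNoiseSigma = 0.003, seed = 1) {
  new("PhantomSpec",
      gridHeight = gridHeight, gridWidth = gridWidth,
      pixelSpacing = pixelSpacing, nVessels = nVessels,
      vesselWidthRange = vesselWidthRange,
      vesselIntensityRange = vesselIntensityRange,
      backgroundLevel = backgroundLevel, speckleSigma = speckleSigma,
      frameNoiseSigma = frameNoiseSigma, seed = seed)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so generators are pure functions of (spec, seed).
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# One smooth random-walk centerline: control points from a persistent
# directed walk, resampled densely with cubic splines.
.vesselCenterline <- function(H, W) {
  nCtrl <- 8L
  start <- c(runif(1, 0.1 * H, 0.9 * H), runif(1, 0.05 * W, 0.3 * W))
  heading <- runif(1, -pi / 4, pi / 4)
  step <- W / (nCtrl - 1) * runif(1, 0.6, 0.9)
  pts <- matrix(0, nCtrl, 2)
  pts[1, ] <- start
  for (i in 2:nCtrl) {
    heading <- heading + rnorm(1, 0, 0.35)
    pts[i, ] <- pts[i - 1, ] + step * c(sin(heading) * 0.6, cos(heading))
  }
  tt <- seq_len(nCtrl)
  dense <- seq(1, nCtrl, length.out = max(64L, 4L * ceiling(step * nCtrl)))
  cbind(stats::spline(tt, pts[, 1], xout = dense)$y,
        stats::spline(tt, pts[, 2], xout = dense)$y)
}

# Render a centerline with a Gaussian cross-section onto a canvas (max
# blending so self-overlap does not over-brighten).
.renderVessel <- function(canvas, centerline, width, peak) {
  H <- nrow(canvas); W <- ncol(canvas)
  sigma <- width / 2.355  # FWHM -> sd
  r <- ceiling(3 * sigma)
  for (k in seq_len(nrow(centerline))) {
    cyk <- centerline[k, 1]; cxk <- centerline[k, 2]
    y0 <- max(1, floor(cyk - r)); y1 <- min(H, ceiling(cyk + r))
    x0 <- max(1, floor(cxk - r)); x1 <- min(W, ceiling(cxk + r))
    if (y0 > y1 || x0 > x1) next
    yy <- y0:y1; xx <- x0:x1
    g <- peak * exp(-(outer((yy - cyk)^2, (xx - cxk)^2, "+")) /
                      (2 * sigma^2))
    canvas[yy, xx] <- pmax(canvas[yy, xx], g)
  }
  canvas
}

#' Generate a synthetic vascular phantom image
#'
#' Draws \code{nVessels} smooth random-walk centerlines with Gaussian
#' cross-sections over a multiplicative log-normal speckle background and
#' clips to [0, 1]. The generated centerlines are recorded in the image
#' metadata (\code{metadata(img)$centerlines}) as provenance.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{FUSImage} in [0, 1], deterministic given the seed.
#' @export
#' @examples
#' img <- generateVascularPhantom(phantomSpec(seed = 7))
#' img
generateVascularPhantom <- function(spec) {
  validObject(spec)
  H <- as.integer(spec@gridHeight); W <- as.integer(spec@gridWidth)
  .withSeed(spec@seed, {
    if (spec@speckleSigma > 0) {
      z <- .gaussSmooth(matrix(rnorm(H * W), H, W), 1)
      z <- z / stats::sd(z)  # keep log-sd at the requested value
      bg <- spec@backgroundLevel *
        exp(spec@speckleSigma * z - spec@speckleSigma^2 / 2)
    } else {
      bg <- matrix(spec@backgroundLevel, H, W)
    }
    vessels <- matrix(0, H, W)
    centerlines <- list()
    n <- as.integer(spec@nVessels)
    if (n > 0) {
      for (v in seq_len(n)) {
        cl <- .vesselCenterline(H, W)
        width <- runif(1, spec@vesselWidthRange[1], spec@vesselWidthRange[2])
        peak <- runif(1, spec@vesselIntensityRange[1],
                      spec@vesselIntensityRange[2])
        vessels <- .renderVessel(vessels, cl, width, peak)
        centerlines[[v]] <- cl
      }
    }
    img <- pmin(pmax(bg + vessels, 0), 1)
    FUSImage(img, spacing = rep(spec@pixelSpacing, 2),
             metadata = list(spec = spec, seed = spec@seed,
                             centerlines = centerlines))
  })
}

#' Ground-truth deformation for recovery experiments
#'
#' @slot kind one of "rigid", "smooth", "piecewise".
#' @slot rigid the \linkS4class{RigidParams} (rigid kind) or NULL.
#' @slot field the dense \linkS4class{DeformationField} of the deformation.
#' @slot maxDisplacement upper bound on the displacement magnitude (pixels).
#' @export
setClass("TruthDeformation",
  representation(kind = "character", rigid = "ANY", field = "ANY",
                 maxDisplacement = "numeric")
)

setMethod("show", "TruthDeformation", function(object) {
  cat(sprintf("TruthDeformation kind = %s, max |d| <= %g px\n",
              object@kind, object@maxDisplacement))
})

#' Generate a ground-truth deformation with a known bound
#'
#' Smooth deformations are built from low-frequency Gaussian random fields
#' rescaled to the requested peak displacement and verified (and if needed
#' further rescaled) to be diffeomorphic: det of the Jacobian of
#' identity + d strictly positive at every pixel. Rigid deformations sample
#' an angle and translation uniformly within bounds implied by
#' \code{maxDisplacement}; piecewise deformations shift the left and right
#' halves in opposite directions with a smooth tanh blend.
#'
#' @param kind one of "rigid", "smooth", "piecewise".
#' @param maxDisplacement peak displacement magnitude in pixels (>= 0).
#' @param shape grid shape c(H, W).
#' @param seed integer RNG seed.
#' @return A \linkS4class{TruthDeformation} whose \code{field} slot always
#'   holds the dense field.
#' @export
generateTruthDeformation <- function(kind = c("smooth", "rigid", "piecewise"),
                                     maxDisplacement, shape, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(maxDisplacement >= 0, length(shape) == 2)
  H <- shape[1]; W <- shape[2]
  .withSeed(seed, {
    if (maxDisplacement == 0) {
      return(new("TruthDeformation", kind = kind, rigid = NULL,
                 field = identityField(shape), maxDisplacement = 0))
    }
    if (kind == "rigid") {
      rmax <- sqrt((H / 2)^2 + (W / 2)^2)
      theta <- runif(1, -1, 1) * 0.5 * maxDisplacement / rmax
      tx <- runif(1, -1, 1) * 0.35 * maxDisplacement
      ty <- runif(1, -1, 1) * 0.35 * maxDisplacement
      p <- RigidParams(theta = theta, tx = tx, ty = ty,
                       center = c((H + 1) / 2, (W + 1) / 2))
      return(new("TruthDeformation", kind = "rigid", rigid = p,
                 field = rigidToField(p, shape),
                 maxDisplacement = maxDisplacement))
    }
    if (kind == "smooth") {
      sigma <- max(min(H, W) / 8, 3)
      dx <- .gaussSmooth(matrix(rnorm(H * W), H, W), sigma)
      dy <- .gaussSmooth(matrix(rnorm(H * W), H, W), sigma)
      # scale so displacements fill the budget over most of the grid (a
      # cross-subject deformation moves large regions, not one spot), then
      # clamp magnitudes smoothly below the stated maximum
      mag <- sqrt(dx^2 + dy^2)
      scl <- maxDisplacement / stats::quantile(mag, 0.98)
      dx <- dx * scl; dy <- dy * scl
      mag <- sqrt(dx^2 + dy^2)
      fac <- ifelse(mag > 0,
                    maxDisplacement * tanh(mag / maxDisplacement) / mag, 1)
      dx <- dx * fac; dy <- dy * fac
      repeat {
        f <- DeformationField(dx, dy)
        if (min(jacobianAnalysis(f)@det) > 0.05) break
        dx <- dx * 0.8; dy <- dy * 0.8
      }
      return(new("TruthDeformation", kind = "smooth", rigid = NULL,
                 field = f, maxDisplacement = maxDisplacement))
    }
    # piecewise: opposite horizontal shifts of the two halves, tanh blend
    xs <- matrix(seq_len(W), H, W, byrow = TRUE)
    blend <- max(W / 10, 4)
    dx <- maxDisplacement * tanh(((W + 1) / 2 - xs) / blend)
    f <- DeformationField(dx = dx, dy = matrix(0, H, W))
    new("TruthDeformation", kind = "piecewise", rigid = NULL, field = f,
        maxDisplacement = maxDisplacement)
  })
}

#' Generate a noisy frame series from a base image
#'
#' Frames are the base image plus independent Gaussian per-frame noise; an
#' optional activation multiplies pixels inside a rectangular region by
#' \code{1 + amplitude} from \code{onset} onward (percent-change injection).
#' Intensities are not clipped so injected amplitudes are exact.
#'
#' @param base a \linkS4class{FUSImage}.
#' @param nFrames number of frames (>= 2).
#' @param frameNoiseSigma additive noise sd (default keeps frame-to-frame
#'   NCC at or above 0.999, emulating the near-perfect temporal stability of
#'   anesthetized acquisitions).
#' @param activation NULL, or \code{list(rows =, cols =, amplitude =,
#'   onset =)} with \code{rows}/\code{cols} index ranges inside the grid.
#' @param seed integer RNG seed.
#' @return A \linkS4class{FUSISeries}; the activation mask (if any) is kept
#'   in the series metadata.
#' @export
generateSeries <- function(base, nFrames, frameNoiseSigma = 0.003,
                           activation = NULL, seed = 1) {
  base <- .asImage(base)
  stopifnot(nFrames >= 2, frameNoiseSigma >= 0)
  m <- intensities(base)
  H <- nrow(m); W <- ncol(m)
  region <- NULL
  if (!is.null(activation)) {
    if (min(activation$rows) < 1 || max(activation$rows) > H ||
        min(activation$cols) < 1 || max(activation$cols) > W) {
      stop("activation region outside grid")
    }
    region <- matrix(FALSE, H, W)
    region[activation$rows, activation$cols] <- TRUE
  }
  .withSeed(seed, {
    frames <- array(0, dim = c(H, W, nFrames))
    for (t in seq_len(nFrames)) {
      ft <- m
      if (!is.null(region) && t >= activation$onset) {
        ft[region] <- ft[region] * (1 + activation$amplitude)
      }
      if (frameNoiseSigma > 0) {
        ft <- ft + matrix(rnorm(H * W, 0, frameNoiseSigma), H, W)
      }
      frames[, , t] <- ft
    }
    FUSISeries(frames, spacing = base@spacing,
               metadata = list(activationRegion = region,
                               activation = activation, seed = seed))
  })
}

#' Generate a cohort of subjects from a shared template
#'
#' Cross-subject anatomical variability is modeled as a smooth diffeomorphic
#' warp of a shared vascular template plus a per-subject rigid pose
#' difference and independent vessel-intensity jitter, mimicking the setting
#' of registering images from different animals to common references.
#'
#' @param spec template \linkS4class{PhantomSpec}.
#' @param nSubjects number of subjects.
#' @param maxDisplacement peak non-rigid inter-subject displacement (pixels).
#' @param rigidMax peak rigid-pose displacement (pixels).
#' @param intensityJitter sd of the per-subject multiplicative gain.
#' @param seed integer RNG seed.
#' @return list with \code{template} (FUSImage), \code{subjects} (list of
#'   FUSImage) and \code{truth} (list of \linkS4class{TruthDeformation},
#'   the total field applied to the template for each subject).
#' @export
generateCohort <- function(spec, nSubjects, maxDisplacement = 4,
                           rigidMax = 3, intensityJitter = 0.05, seed = 1) {
  template <- generateVascularPhantom(spec)
  shape <- dim(template)
  .withSeed(seed, {
    seeds <- sample.int(1e6, 2 * nSubjects + 1)
    subjects <- vector("list", nSubjects)
    truth <- vector("list", nSubjects)
    for (i in seq_len(nSubjects)) {
      smoothT <- generateTruthDeformation("smooth", maxDisplacement, shape,
                                          seed = seeds[2 * i - 1])
      rigidT <- generateTruthDeformation("rigid", rigidMax, shape,
                                         seed = seeds[2 * i])
      total <- composeFields(smoothT@field, rigidT@field)
      gain <- exp(rnorm(1, 0, intensityJitter))
      warped <- warpImage(template, total)
      img <- pmin(pmax(intensities(warped) * gain, 0), 1)
      subjects[[i]] <- FUSImage(img, spacing = template@spacing,
                                mask = warped@mask,
                                metadata = list(subject = i))
      truth[[i]] <- new("TruthDeformation", kind = "smooth", rigid = NULL,
                        field = total,
                        maxDisplacement = maxDisplacement + rigidMax)
    }
    list(template = template, subjects = subjects, truth = truth)
  })
}
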