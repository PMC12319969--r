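#' @import methods
#' @importFrom stats fft optimize pt p.adjust quantile rnorm runif sd var
#'   setNames median qnorm pnorm
#' @importFrom utils head tail
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' A single 2D grayscale image with physical pixel spacing
#'
#' The basic unit of registration: one power-Doppler-like vascular frame.
#' Intensities are dimensionless, nominally in [0, 1]; pixel coordinates are
#' 1-based (row, col) at pixel centers, with row = depth (y) and
#' col = width (x). Physical units enter only through \code{spacing}
#' (millimetres per pixel, as \code{c(dy, dx)}).
#'
#' @slot intensities numeric matrix (H x W) of pixel values, all finite.
#' @slot spacing numeric length-2, \code{c(dy, dx)} in mm, both > 0.
#' @slot mask optional logical-valued matrix of the same shape marking valid
#'   pixels (e.g. inside the field of view after warping); \code{NULL} means
#'   all valid.
#' @slot metadata free-form list (provenance, vessel centerlines, scales).
#' @export
setClass("FUSImage",
  representation(
    intensities = "matrix",
    spacing = "numeric",
    mask = "matrixOrNULL",
    metadata = "list"
  ),
  prototype(spacing = c(0.1, 0.1), mask = NULL, metadata = list())
)

setValidity("FUSImage", function(object) {
  msg <- character()
  if (!is.numeric(object@intensities)) {
    msg <- c(msg, "intensities must be a numeric matrix")
  } else if (!all(is.finite(object@intensities))) {
    msg <- c(msg, "intensities must be finite")
  }
  if (length(object@spacing) != 2 || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) {
    msg <- c(msg, "spacing must be two positive numbers (dy, dx) in mm")
  }
  if (!is.null(object@mask) &&
      !identical(dim(object@mask), dim(object@intensities))) {
    msg <- c(msg, "mask must have the same shape as intensities")
  }
  if (length(msg)) msg else TRUE
})

#' An ordered stack of frames sharing shape and spacing
#'
#' @slot frames numeric array H x W x T.
#' @slot spacing numeric c(dy, dx) in mm.
#' @slot frameRate acquisition rate in Hz (default 1).
#' @slot metadata free-form list.
#' @export
setClass("FUSISeries",
  representation(
    frames = "array",
    spacing = "numeric",
    frameRate = "numeric",
    metadata = "list"
  ),
  prototype(spacing = c(0.1, 0.1), frameRate = 1, metadata = list())
)

setValidity("FUSISeries", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3 || dim(object@frames)[3] < 1) {
    msg <- c(msg, "frames must be an H x W x T array with T >= 1")
  }
  if (!all(is.finite(object@frames))) msg <- c(msg, "frames must be finite")
  if (length(object@spacing) != 2 || any(object@spacing <= 0)) {
    msg <- c(msg, "spacing must be two positive numbers")
  }
  if (length(object@frameRate) != 1 || object@frameRate <= 0) {
    msg <- c(msg, "frameRate must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})

#' Rigid (Euler) transform parameters
#'
#' Rotation by \code{theta} radians about \code{center} followed by a
#' translation of \code{(tx, ty)} pixels (x = columns, y = rows).
#' \code{theta} is wrapped to (-pi, pi].
#'
#' @slot theta rotation angle in radians.
#' @slot tx,ty translation in pixels along columns / rows.
#' @slot center rotation center as c(row, col), 1-based pixel coordinates.
#' @slot converged FALSE when an optimizer reported failure and returned the
#'   identity.
#' @export
setClass("RigidParams",
  representation(
    theta = "numeric", tx = "numeric", ty = "numeric",
    center = "numeric", converged = "logical"
  ),
  prototype(theta = 0, tx = 0, ty = 0, center = c(1, 1), converged = TRUE)
)

setValidity("RigidParams", function(object) {
  ok <- all(is.finite(c(object@theta, object@tx, object@ty, object@center))) &&
    length(object@center) == 2
  if (!ok) return("theta, tx, ty and center (row, col) must be finite")
  if (object@theta <= -pi - 1e-12 || object@theta > pi + 1e-12) {
    return("theta must be wrapped to (-pi, pi]")
  }
  TRUE
})

#' Dense backward-mapping displacement field
#'
#' For every fixed-grid pixel x the warped image samples the moving image at
#' x + d(x) (pull-back convention); \code{dx} holds column displacements and
#' \code{dy} row displacements, both in pixels.
#'
#' @slot dx,dy numeric H x W matrices, finite, equal shape.
#' @export
setClass("DeformationField",
  representation(dx = "matrix", dy = "matrix")
)

setValidity("DeformationField", function(object) {
  if (!identical(dim(object@dx), dim(object@dy))) {
    return("dx and dy must have identical shape")
  }
  if (!all(is.finite(object@dx)) || !all(is.finite(object@dy))) {
    return("displacements must be finite")
  }
  TRUE
})

#' Cubic B-spline control lattice for free-form deformation
#'
#' @slot coefDx,coefDy control-point displacements (Gy x Gx, pixels).
#' @slot spacing control-point spacing in pixels (scalar, >= 1).
#' @slot origin position (row, col) of control point (1,1) in pixel
#'   coordinates; the lattice extends one spacing beyond each image border so
#'   cubic support covers the full grid.
#' @export
setClass("BSplineGrid",
  representation(
    coefDx = "matrix", coefDy = "matrix",
    spacing = "numeric", origin = "numeric"
  )
)

setValidity("BSplineGrid", function(object) {
  if (!identical(dim(object@coefDx), dim(object@coefDy))) {
    return("coefDx and coefDy must have identical shape")
  }
  if (any(dim(object@coefDx) < 4)) {
    return("control lattice must be at least 4 x 4 for cubic support")
  }
  if (object@spacing < 1) return("control spacing must be >= 1 pixel")
  TRUE
})

#' Shifted normalized cross-correlation profile
#'
#' @slot matrix (2H-1) x (2W-1) NCC values per integer shift; shifts with an
#'   overlap below the minimum-overlap fraction are NA.
#' @slot peakValue maximum of the matrix.
#' @slot peakShift c(dy, dx) in pixels at the peak.
#' @slot fwhm c(y, x) full widths at half maximum in mm (NA when no
#'   half-maximum crossing exists).
#' @export
setClass("NCCProfile",
  representation(
    matrix = "matrix", peakValue = "numeric",
    peakShift = "numeric", fwhm = "numeric"
  )
)

#' Jacobian-determinant map of a deformation
#'
#' Determinant of the Jacobian of the total mapping phi = identity + d at
#' every pixel; 1 means no local area change, values <= 0 mark folding.
#'
#' @slot det H x W determinant grid.
#' @slot meanJacobian mean of \code{det}.
#' @slot foldingRate percent of pixels with det <= 0, in [0, 100].
#' @export
setClass("JacobianMap",
  representation(det = "matrix", meanJacobian = "numeric",
                 foldingRate = "numeric")
)

setValidity("JacobianMap", function(object) {
  if (abs(object@meanJacobian - mean(object@det)) > 1e-12) {
    return("meanJacobian must equal mean(det)")
  }
  fr <- 100 * mean(object@det <= 0)
  if (abs(object@foldingRate - fr) > 1e-9) {
    return("foldingRate inconsistent with det grid")
  }
  TRUE
})

#' Similarity and distortion measurements for one registration
#'
#' @slot pre named numeric of pre-registration metrics (moving vs fixed).
#' @slot post named numeric of post-registration metrics (registered vs
#'   fixed).
#' @slot jacobian JacobianMap for the recovered field, or NULL for rigid
#'   registrations.
#' @export
setClass("MetricReport",
  representation(pre = "numeric", post = "numeric", jacobian = "ANY"),
  prototype(jacobian = NULL)
)

#' Pixelwise statistical parametric map
#'
#' @slot pValues,qValues H x W grids of raw and FDR-adjusted p-values.
#' @slot significant logical-valued matrix, q < alpha.
#' @slot retained logical-valued matrix, top fraction of significant pixels
#'   by |z|.
#' @slot zScores H x W z-scores of percent signal change.
#' @slot settings list recording windows, alpha, top fraction and test used.
#' @export
setClass("SPMMap",
  representation(
    pValues = "matrix", qValues = "matrix",
    significant = "matrix", retained = "matrix",
    zScores = "matrix", settings = "list"
  )
)

#' Result of a genetic-algorithm or grid-search optimization
#'
#' @slot bestParams named list of the selected parameter values.
#' @slot bestFitness fitness at \code{bestParams} (lower is better).
#' @slot history best-so-far fitness per generation (non-increasing).
#' @slot stopReason one of "stall", "max_generations", "tolerance",
#'   "exhaustive".
#' @export
setClass("GAResult",
  representation(
    bestParams = "list", bestFitness = "numeric",
    history = "numeric", stopReason = "character"
  )
)

## ---- constructors ----------------------------------------------------------

#' Construct a FUSImage
#'
#' @param intensities numeric matrix of pixel values.
#' @param spacing pixel spacing c(dy, dx) in mm.
#' @param mask optional validity matrix.
#' @param metadata optional provenance list.
#' @return A \linkS4class{FUSImage}.
#' @export
#' @examples
#' img <- FUSImage(matrix(runif(12), 3, 4))
#' dim(img)
FUSImage <- function(intensities, spacing = c(0.1, 0.1), mask = NULL,
                     metadata = list()) {
  new("FUSImage", intensities = intensities, spacing = as.numeric(spacing),
      mask = mask, metadata = metadata)
}

#' Construct a FUSISeries from an array or list of frames
#'
#' @param frames H x W x T array, or list of equally shaped matrices /
#'   FUSImage objects.
#' @param spacing pixel spacing c(dy, dx) in mm.
#' @param frameRate frames per second.
#' @param metadata optional provenance list.
#' @return A \linkS4class{FUSISeries}.
#' @export
FUSISeries <- function(frames, spacing = c(0.1, 0.1), frameRate = 1,
                       metadata = list()) {
  if (is.list(frames)) {
    mats <- lapply(frames, function(f) {
      if (is(f, "FUSImage")) intensities(f) else f
    })
    frames <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  }
  new("FUSISeries", frames = frames, spacing = as.numeric(spacing),
      frameRate = frameRate, metadata = metadata)
}

#' Construct rigid (Euler) transform parameters
#'
#' @param theta rotation in radians (wrapped to (-pi, pi]).
#' @param tx,ty translation in pixels (columns, rows).
#' @param center rotation center c(row, col); defaults to c(0, 0) meaning
#'   "fill in the image center" when converted to a field.
#' @param converged optimizer success flag.
#' @return A \linkS4class{RigidParams}.
#' @export
RigidParams <- function(theta = 0, tx = 0, ty = 0, center = c(1, 1),
                        converged = TRUE) {
  theta <- wrapAngle(theta)
  new("RigidParams", theta = theta, tx = tx, ty = ty,
      center = as.numeric(center), converged = converged)
}

#' Construct a dense backward displacement field
#'
#' @param dx,dy column / row displacement matrices in pixels.
#' @return A \linkS4class{DeformationField}.
#' @export
DeformationField <- function(dx, dy) new("DeformationField", dx = dx, dy = dy)

wrapAngle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  ifelse(w <= -pi, pi, w)
}

## ---- accessors and show ----------------------------------------------------

#' @describeIn FUSImage pixel intensity matrix
#' @param object,x a FUSImage
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname FUSImage-class
#' @export
setMethod("intensities", "FUSImage", function(object) object@intensities)

#' Physical pixel spacing accessor
#' @param object a FUSImage or FUSISeries
#' @return numeric c(dy, dx) in mm.
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @rdname pixelSpacing
#' @export
setMethod("pixelSpacing", "FUSImage", function(object) object@spacing)
#' @rdname pixelSpacing
#' @export
setMethod("pixelSpacing", "FUSISeries", function(object) object@spacing)

#' Validity mask accessor
#' @param object a FUSImage
#' @return logical matrix of valid pixels (all TRUE when no mask is set).
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname validMask
#' @export
setMethod("validMask", "FUSImage", function(object) {
  if (is.null(object@mask)) {
    matrix(TRUE, nrow(object@intensities), ncol(object@intensities))
  } else {
    object@mask > 0
  }
})

#' @export
setMethod("dim", "FUSImage", function(x) dim(x@intensities))
#' @export
setMethod("dim", "DeformationField", function(x) dim(x@dx))

#' Number of frames in a series
#' @param object a FUSISeries
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname nFrames
#' @export
setMethod("nFrames", "FUSISeries", function(object) dim(object@frames)[3])

#' Extract one frame of a series as a FUSImage
#' @param object a FUSISeries
#' @param i frame index
#' @export
setGeneric("getFrame", function(object, i) standardGeneric("getFrame"))
#' @rdname getFrame
#' @export
setMethod("getFrame", "FUSISeries", function(object, i) {
  stopifnot(i >= 1, i <= nFrames(object))
  FUSImage(object@frames[, , i], spacing = object@spacing)
})

#' Displacement component accessors
#' @param object a DeformationField
#' @return numeric matrix of per-pixel displacements in pixels.
#' @export
setGeneric("dispX", function(object) standardGeneric("dispX"))
#' @rdname dispX
#' @export
setMethod("dispX", "DeformationField", function(object) object@dx)
#' @rdname dispX
#' @export
setGeneric("dispY", function(object) standardGeneric("dispY"))
#' @rdname dispX
#' @export
setMethod("dispY", "DeformationField", function(object) object@dy)

setMethod("show", "FUSImage", function(object) {
  d <- dim(object@intensities)
  cat(sprintf(
    "FUSImage %d x %d px (%.3g x %.3g mm), range [%.3g, %.3g]%s\n",
    d[1], d[2], d[1] * object@spacing[1], d[2] * object@spacing[2],
    min(object@intensities), max(object@intensities),
    if (is.null(object@mask)) "" else ", masked"
  ))
})

setMethod("show", "FUSISeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FUSISeries %d frames of %d x %d px at %g Hz\n",
              d[3], d[1], d[2], object@frameRate))
})

setMethod("show", "RigidParams", function(object) {
  cat(sprintf(
    "RigidParams: theta = %.4f rad (%.3f deg), t = (%.3f, %.3f) px, center = (%.1f, %.1f)%s\n",
    object@theta, object@theta * 180 / pi, object@tx, object@ty,
    object@center[1], object@center[2],
    if (object@converged) "" else " [registration failed; identity]"
  ))
})

setMethod("show", "DeformationField", function(object) {
  mag <- sqrt(object@dx^2 + object@dy^2)
  cat(sprintf("DeformationField %d x %d px, |d| max %.3f, mean %.3f px\n",
              nrow(object@dx), ncol(object@dx), max(mag), mean(mag)))
})

setMethod("show", "JacobianMap", function(object) {
  cat(sprintf("JacobianMap: mean det %.4f, folding %.2f%%\n",
              object@meanJacobian, object@foldingRate))
})

setMethod("show", "NCCProfile", function(object) {
  cat(sprintf(
    "NCCProfile: peak %.4f at shift (dy = %g, dx = %g) px, FWHM (y, x) = (%.3g, %.3g) mm\n",
    object@peakValue, object@peakShift[1], object@peakShift[2],
    object@fwhm[1], object@fwhm[2]
  ))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n  pre:  ",
      paste(sprintf("%s=%.4f", names(object@pre), object@pre), collapse = " "),
      "\n  post: ",
      paste(sprintf("%s=%.4f", names(object@post), object@post),
            collapse = " "), "\n")
  if (!is.null(object@jacobian)) {
    cat("  ")
    show(object@jacobian)
  }
})

setMethod("show", "SPMMap", function(object) {
  cat(sprintf(
    "SPMMap: %d significant px (q < %g), %d retained (top %g%% by |z|)\n",
    sum(object@significant > 0), object@settings$alpha,
    sum(object@retained > 0), 100 * object@settings$topFraction
  ))
})

setMethod("show", "GAResult", function(object) {
  cat(sprintf(
    "GAResult: best fitness %.6g after %d generations (%s)\n  params: %s\n",
    object@bestFitness, length(object@history), object@stopReason,
    paste(sprintf("%s=%s", names(object@bestParams),
                  vapply(object@bestParams, format, "")), collapse = ", ")
  ))
})
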