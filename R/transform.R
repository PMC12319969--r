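# Canonical transform representations and warping. Every displacement field
# in the package uses the backward (pull-back) convention: for a fixed-grid
# pixel x the warped image samples the moving image at x + d(x). This makes
# warping a single interpolation pass on the fixed grid, which is where all
# the optimizers evaluate similarity.

#' Convert rigid parameters to a dense backward displacement field
#'
#' The forward rigid map rotates pixel coordinates by \code{theta} about
#' \code{center} and then translates by \code{(tx, ty)}; the returned field
#' is the backward map of that transform, so that
#' \code{warpImage(img, rigidToField(p, dim(img)))} rotates-then-translates
#' the image content.
#'
#' @param params a \linkS4class{RigidParams}.
#' @param shape target grid shape \code{c(H, W)}.
#' @return A \linkS4class{DeformationField}.
#' @export
#' @examples
#' f <- rigidToField(RigidParams(tx = 2, ty = 1), c(8, 8))
#' unique(as.vector(dispX(f)))  # -2: backward convention
rigidToField <- function(params, shape) {
  stopifnot(is(params, "RigidParams"), length(shape) == 2, all(shape >= 1))
  H <- shape[1]; W <- shape[2]
  cy <- params@center[1]; cx <- params@center[2]
  ct <- cos(params@theta); st <- sin(params@theta)
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  # backward map: T^{-1}(q) = R' (q - c - t) + c
  qx <- xs - cx - params@tx
  qy <- ys - cy - params@ty
  bx <- ct * qx + st * qy + cx
  by <- -st * qx + ct * qy + cy
  DeformationField(dx = bx - xs, dy = by - ys)
}

#' Compose two rigid transforms (apply \code{first}, then \code{second})
#'
#' @param first,second \linkS4class{RigidParams} applied in that order.
#' @return A \linkS4class{RigidParams} with the center of \code{first}.
#' @export
composeRigid <- function(first, second) {
  c1 <- first@center; c2 <- second@center
  ct <- cos(second@theta); st <- sin(second@theta)
  # T(p) = R2 R1 (p - c1) + R2 (c1 + t1 - c2) + c2 + t2
  vx <- c1[2] + first@tx - c2[2]
  vy <- c1[1] + first@ty - c2[1]
  RigidParams(
    theta = first@theta + second@theta,
    tx = ct * vx - st * vy + c2[2] + second@tx - c1[2],
    ty = st * vx + ct * vy + c2[1] + second@ty - c1[1],
    center = c1
  )
}

#' Invert a rigid transform
#'
#' @param params a \linkS4class{RigidParams}.
#' @return The inverse transform, sharing the same center.
#' @export
invertRigid <- function(params) {
  ct <- cos(params@theta); st <- sin(params@theta)
  RigidParams(
    theta = -params@theta,
    tx = -(ct * params@tx + st * params@ty),
    ty = -(-st * params@tx + ct * params@ty),
    center = params@center
  )
}

#' Build a cubic B-spline control lattice covering an image grid
#'
#' The lattice extends one control spacing beyond each border so that every
#' pixel has full 4 x 4 cubic support; control displacements start at zero.
#'
#' @param shape image shape \code{c(H, W)}.
#' @param spacing control-point spacing in pixels (>= 2).
#' @return A \linkS4class{BSplineGrid}.
#' @export
bsplineGrid <- function(shape, spacing = 8) {
  stopifnot(length(shape) == 2, spacing >= 1)
  Gy <- floor((shape[1] - 1) / spacing) + 4L
  Gx <- floor((shape[2] - 1) / spacing) + 4L
  new("BSplineGrid",
      coefDx = matrix(0, Gy, Gx), coefDy = matrix(0, Gy, Gx),
      spacing = spacing, origin = c(1 - spacing, 1 - spacing))
}

# Uniform cubic B-spline basis values for fractional position t in [0, 1);
# returns length(t) x 4 weights for control offsets -1, 0, +1, +2.
.bsplineBasis <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

# For continuous pixel coordinates (y, x), the 16 control indices and tensor
# weights of the cubic lattice. Returns list(i = n x 16 linear control index,
# w = n x 16 weight).
.bsplineSupport <- function(grid, y, x) {
  Gy <- nrow(grid@coefDx); Gx <- ncol(grid@coefDx)
  uy <- (y - grid@origin[1]) / grid@spacing + 1
  ux <- (x - grid@origin[2]) / grid@spacing + 1
  iy <- floor(uy); ix <- floor(ux)
  if (any(iy < 2 | iy + 2 > Gy | ix < 2 | ix + 2 > Gx)) {
    stop("insufficient control-point support for the requested coordinates")
  }
  by <- .bsplineBasis(uy - iy)
  bx <- .bsplineBasis(ux - ix)
  n <- length(y)
  idx <- matrix(0L, n, 16L)
  w <- matrix(0, n, 16L)
  k <- 1L
  for (a in 0:3) {
    ia <- iy + a - 1
    for (b in 0:3) {
      ib <- ix + b - 1
      idx[, k] <- as.integer(ia + (ib - 1) * Gy)
      w[, k] <- by[, a + 1] * bx[, b + 1]
      k <- k + 1L
    }
  }
  list(i = idx, w = w)
}

#' Evaluate a B-spline control lattice as a dense displacement field
#'
#' Tensor-product cubic B-spline interpolation of the control displacements
#' at every pixel of the target grid.
#'
#' @param grid a \linkS4class{BSplineGrid}.
#' @param shape target image shape \code{c(H, W)}.
#' @return A \linkS4class{DeformationField}.
#' @export
bsplineToField <- function(grid, shape) {
  stopifnot(is(grid, "BSplineGrid"), length(shape) == 2)
  H <- shape[1]; W <- shape[2]
  ys <- rep(seq_len(H), W)
  xs <- rep(seq_len(W), each = H)
  sup <- .bsplineSupport(grid, ys, xs)
  cx <- as.vector(grid@coefDx); cy <- as.vector(grid@coefDy)
  dx <- rowSums(sup$w * matrix(cx[sup$i], nrow(sup$i)))
  dy <- rowSums(sup$w * matrix(cy[sup$i], nrow(sup$i)))
  DeformationField(dx = matrix(dx, H, W), dy = matrix(dy, H, W))
}

#' Warp an image with a backward displacement field
#'
#' For each output pixel x the moving image is sampled at x + d(x). Samples
#' falling outside the moving grid are filled with 0 and flagged invalid in
#' the output mask.
#'
#' @param image a \linkS4class{FUSImage} (or plain matrix).
#' @param field a \linkS4class{DeformationField} of the same shape.
#' @param interpolation one of "cubic" (default; cubic convolution, exact at
#'   grid nodes), "linear", "nearest".
#' @return A warped \linkS4class{FUSImage} with a validity mask.
#' @export
#' @examples
#' img <- FUSImage(matrix(runif(64), 8, 8))
#' zero <- DeformationField(matrix(0, 8, 8), matrix(0, 8, 8))
#' identical(intensities(warpImage(img, zero)), intensities(img))
warpImage <- function(image, field,
                      interpolation = c("cubic", "linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  image <- .asImage(image)
  m <- intensities(image)
  if (!identical(dim(m), dim(field))) {
    stop("image and field shapes differ")
  }
  H <- nrow(m); W <- ncol(m)
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  res <- .interp2(m, as.vector(ys + field@dy), as.vector(xs + field@dx),
                  method = interpolation, fill = 0)
  out <- matrix(res$values, H, W)
  msk <- matrix(res$inside, H, W)
  if (!is.null(image@mask)) {
    mres <- .interp2(image@mask + 0, as.vector(ys + field@dy),
                     as.vector(xs + field@dx), method = "nearest", fill = 0)
    msk <- msk & matrix(mres$values > 0, H, W)
  }
  FUSImage(out, spacing = image@spacing, mask = msk * 1,
           metadata = image@metadata)
}

#' Compose two backward displacement fields
#'
#' \code{composeFields(fOuter, fInner)} returns the field of the warp
#' pipeline \code{warpImage(warpImage(I, fOuter), fInner)}:
#' \code{d(x) = dInner(x) + dOuter(x + dInner(x))}, with the outer field
#' sampled by linear interpolation (border-clamped).
#'
#' @param fOuter,fInner \linkS4class{DeformationField}s of equal shape.
#' @return A \linkS4class{DeformationField}.
#' @export
composeFields <- function(fOuter, fInner) {
  if (!identical(dim(fOuter), dim(fInner))) stop("field shapes differ")
  H <- nrow(fOuter@dx); W <- ncol(fOuter@dx)
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  yq <- pmin(pmax(as.vector(ys + fInner@dy), 1), H)
  xq <- pmin(pmax(as.vector(xs + fInner@dx), 1), W)
  ox <- matrix(.interp2(fOuter@dx, yq, xq, method = "linear")$values, H, W)
  oy <- matrix(.interp2(fOuter@dy, yq, xq, method = "linear")$values, H, W)
  DeformationField(dx = fInner@dx + ox, dy = fInner@dy + oy)
}

#' An all-zero (identity) displacement field
#'
#' @param shape grid shape \code{c(H, W)}.
#' @return A \linkS4class{DeformationField} of zeros.
#' @export
identityField <- function(shape) {
  DeformationField(matrix(0, shape[1], shape[2]),
                   matrix(0, shape[1], shape[2]))
}

# Scaling-and-squaring exponentiation of a stationary velocity field:
# exp(v) approximated by (id + v / 2^n) composed with itself n times.
.expField <- function(vx, vy, nSquarings = 6L) {
  f <- DeformationField(vx / 2^nSquarings, vy / 2^nSquarings)
  for (i in seq_len(nSquarings)) f <- composeFields(f, f)
  f
}

#' Serialize / restore a deformation field
#'
#' Fields are written as a 2-component NIfTI vector image (dx then dy along
#' the last dimension) with a JSON sidecar recording shape and the
#' displacement convention string \code{"backward"}.
#'
#' @param field a \linkS4class{DeformationField}.
#' @param path output path (".nii" or ".nii.gz").
#' @return \code{writeField}: the path, invisibly. \code{readField}: the
#'   restored \linkS4class{DeformationField}.
#' @export
writeField <- function(field, path) {
  arr <- array(c(field@dx, field@dy), dim = c(dim(field@dx), 2L))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  hdr <- list(shape = dim(field@dx), convention = "backward",
              components = c("dx", "dy"))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeField
#' @param path path previously written by \code{writeField}.
#' @export
readField <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(hdr$convention, "backward")) {
    stop("unsupported displacement convention: ", hdr$convention)
  }
  DeformationField(dx = arr[, , 1], dy = arr[, , 2])
}
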