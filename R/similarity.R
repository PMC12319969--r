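# Scalar similarity measures optimized by the rigid registration methods.
# All three are invariant to affine intensity rescaling of either input.

#' Global normalized cross-correlation
#'
#' \eqn{(1/K) \sum_k (a_k - \mu_a)(b_k - \mu_b) / (\sigma_a \sigma_b)} with
#' population standard deviations; in [-1, 1].
#'
#' @param a,b \linkS4class{FUSImage}s or matrices of equal shape, neither
#'   constant.
#' @param mask optional logical matrix restricting the computation.
#' @return NCC value.
#' @export
#' @examples
#' m <- matrix(runif(64), 8, 8)
#' nccGlobal(m, m)  # 1
nccGlobal <- function(a, b, mask = NULL) {
  x <- .mat(a); y <- .mat(b)
  if (!identical(dim(x), dim(y))) stop("image shapes differ")
  if (!is.null(mask)) {
    x <- x[mask]; y <- y[mask]
  }
  K <- length(x)
  mx <- mean(x); my <- mean(y)
  sx <- sqrt(mean((x - mx)^2)); sy <- sqrt(mean((y - my)^2))
  if (sx == 0 || sy == 0) stop("degenerate input: constant image")
  sum((x - mx) * (y - my)) / (K * sx * sy)
}

#' Correlation ratio eta(B | A)
#'
#' Measures how well image \code{b} is explained as a function of the
#' intensity of image \code{a}: \eqn{1 - (1/(N \sigma^2)) \sum_i N_i
#' \sigma_i^2}, where the sum runs over iso-intensity sets of \code{a}
#' (after binning into \code{bins} levels), \eqn{\sigma_i^2} is the
#' variance of \code{b} within set i, and \eqn{\sigma^2} the total variance
#' of \code{b}. Directional: not symmetric in its arguments.
#'
#' @param a image whose intensity levels define the iso-sets.
#' @param b image whose conditional variance is measured; non-constant.
#' @param bins number of intensity bins applied to \code{a}.
#' @return eta in [0, 1]; 1 when b is a deterministic function of a's bins.
#' @export
correlationRatio <- function(a, b, bins = 64) {
  x <- as.vector(.mat(a)); y <- as.vector(.mat(b))
  if (length(x) != length(y)) stop("image shapes differ")
  vy <- mean((y - mean(y))^2)
  if (vy == 0) stop("degenerate input: constant image b")
  lev <- .binIndices(x, bins)
  # sum of N_i * sigma_i^2 = within-set sums of squared deviations
  sy <- vapply(split(y, lev), function(v) sum((v - mean(v))^2), 0)
  eta <- 1 - sum(sy) / (length(y) * vy)
  min(max(eta, 0), 1)
}

# Uniform binning of intensities into 1..bins (constant input -> bin 1).
.binIndices <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  idx <- floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  pmin(idx, bins)
}

#' Mutual information of the joint intensity histogram
#'
#' Shannon mutual information (in bits) of the joint histogram of the two
#' images after uniform binning; simple binning, no Parzen windowing.
#'
#' @param a,b images of equal shape.
#' @param bins histogram bins per image (default 64).
#' @return MI >= 0 in bits; equals the histogram entropy of \code{a} when
#'   \code{b = a}.
#' @export
mutualInformation <- function(a, b, bins = 64) {
  x <- as.vector(.mat(a)); y <- as.vector(.mat(b))
  if (length(x) != length(y)) stop("image shapes differ")
  ix <- .binIndices(x, bins); iy <- .binIndices(y, bins)
  tab <- table(factor(ix, levels = 1:bins), factor(iy, levels = 1:bins))
  p <- as.matrix(tab) / length(x)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / (px[row(p)[nz]] * py[col(p)[nz]])))
}
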