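# Pixelwise statistical parametric mapping of percent signal change between
# a baseline and a post window, with Benjamini-Hochberg FDR control and
# top-fraction retention by effect magnitude.

#' SPM analysis settings
#'
#' @param baselineWindow,postWindow frame index vectors (disjoint, each with
#'   at least 2 frames).
#' @param alpha FDR level on the adjusted p-values (default 0.001).
#' @param topFraction fraction of significant pixels retained, ranked by
#'   |z| (default 0.30).
#' @param test "welch_t" (default) or "ranksum".
#' @return A classed list of settings.
#' @export
spmConfig <- function(baselineWindow, postWindow, alpha = 0.001,
                      topFraction = 0.30, test = c("welch_t", "ranksum")) {
  test <- match.arg(test)
  baselineWindow <- as.integer(baselineWindow)
  postWindow <- as.integer(postWindow)
  stopifnot(length(baselineWindow) >= 2, length(postWindow) >= 2,
            length(intersect(baselineWindow, postWindow)) == 0,
            alpha > 0, alpha < 1, topFraction > 0, topFraction <= 1)
  structure(list(baselineWindow = baselineWindow, postWindow = postWindow,
                 alpha = alpha, topFraction = topFraction, test = test),
            class = "spmConfig")
}

#' Percent signal change from a baseline window
#'
#' Per pixel: \eqn{100 (I_t - \bar{I}_{base}) / \bar{I}_{base}} for every
#' frame t. Pixels whose baseline mean is at or below \code{eps} are
#' flagged invalid (NA in every frame).
#'
#' @param series a \linkS4class{FUSISeries}.
#' @param baselineWindow frame indices of the baseline (>= 2 frames).
#' @param eps positivity floor for the baseline mean.
#' @return A \linkS4class{FUSISeries} of percent-change frames; the
#'   validity grid is stored in the metadata as \code{validBaseline}.
#' @export
percentChange <- function(series, baselineWindow, eps = 1e-6) {
  stopifnot(is(series, "FUSISeries"), length(baselineWindow) >= 2,
            max(baselineWindow) <= nFrames(series))
  base <- apply(series@frames[, , baselineWindow, drop = FALSE], c(1, 2),
                mean)
  valid <- base > eps
  if (!any(valid)) stop("all pixels have a degenerate baseline")
  H <- dim(series@frames)[1]; W <- dim(series@frames)[2]
  Tn <- nFrames(series)
  pc <- array(NA_real_, dim = c(H, W, Tn))
  for (t in seq_len(Tn)) {
    f <- 100 * (series@frames[, , t] - base) / base
    f[!valid] <- NA_real_
    pc[, , t] <- f
  }
  md <- series@metadata
  md$validBaseline <- valid
  new("FUSISeries", frames = .naSafeArray(pc), spacing = series@spacing,
      frameRate = series@frameRate, metadata = md)
}

# FUSISeries validity requires finite frames; carry NA pixels as a
# sentinel and the valid mask in metadata.
.naSafeArray <- function(a) {
  a[!is.finite(a)] <- 0
  a
}

#' Pixelwise statistical parametric map
#'
#' Converts the series to percent change from the baseline window, then per
#' pixel runs a two-sample test (Welch t by default, rank-sum optional)
#' between the baseline-window and post-window percent-change samples.
#' Raw p-values are adjusted by Benjamini-Hochberg; \code{significant} is
#' q < alpha; \code{retained} keeps the top \code{topFraction} of
#' significant pixels ranked by |z| (ties by p-value, then row-major
#' index), with cardinality \code{round(topFraction * n significant)}.
#' The z-score per pixel is the baseline-referenced effect size:
#' (mean post percent change - mean baseline percent change) / sd of the
#' baseline percent change. Degenerate pixels (invalid baseline or zero
#' variance in both windows) get p = 1 and z = 0.
#'
#' @param series a \linkS4class{FUSISeries} of raw intensities.
#' @param config an \code{\link{spmConfig}}.
#' @return An \linkS4class{SPMMap}.
#' @export
spmMap <- function(series, config) {
  stopifnot(is(series, "FUSISeries"), inherits(config, "spmConfig"))
  if (max(config$baselineWindow, config$postWindow) > nFrames(series)) {
    stop("analysis windows exceed the series length")
  }
  pc <- percentChange(series, config$baselineWindow)
  valid <- pc@metadata$validBaseline
  H <- dim(series@frames)[1]; W <- dim(series@frames)[2]
  bl <- pc@frames[, , config$baselineWindow, drop = FALSE]
  po <- pc@frames[, , config$postWindow, drop = FALSE]
  n1 <- dim(bl)[3]; n2 <- dim(po)[3]
  m1 <- apply(bl, c(1, 2), mean); m2 <- apply(po, c(1, 2), mean)
  v1 <- apply(bl, c(1, 2), var); v2 <- apply(po, c(1, 2), var)
  z <- matrix(0, H, W)
  sdb <- sqrt(v1)
  ok <- valid & sdb > 0
  z[ok] <- (m2[ok] - m1[ok]) / sdb[ok]
  if (config$test == "welch_t") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  } else {
    p <- matrix(1, H, W)
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        if (!valid[i, j]) next
        p[i, j] <- .ranksumP(bl[i, j, ], po[i, j, ])
      }
    }
  }
  p[!is.finite(p)] <- 1  # degenerate variance
  p[!valid] <- 1
  q <- matrix(p.adjust(as.vector(p), method = "BH"), H, W)
  significant <- q < config$alpha
  retained <- matrix(FALSE, H, W)
  nSig <- sum(significant)
  nKeep <- round(config$topFraction * nSig)
  if (nKeep > 0) {
    sigIdx <- which(significant)
    ord <- order(-abs(z[sigIdx]), p[sigIdx], sigIdx)
    retained[sigIdx[ord[seq_len(nKeep)]]] <- TRUE
  }
  new("SPMMap", pValues = p, qValues = q,
      significant = significant + 0, retained = retained + 0, zScores = z,
      settings = list(alpha = config$alpha,
                      topFraction = config$topFraction, test = config$test,
                      baselineWindow = config$baselineWindow,
                      postWindow = config$postWindow))
}

# Normal-approximation two-sided rank-sum (Wilcoxon) p-value with tie
# correction.
.ranksumP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tieAdj <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  s2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tieAdj)
  if (s2 <= 0) return(1)
  zstat <- (U - mu) / sqrt(s2)
  2 * pnorm(abs(zstat), lower.tail = FALSE)
}
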