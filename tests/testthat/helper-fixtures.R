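# Shared fixtures, built once per test run. Small grids keep the suite fast
# while preserving the vascular structure the algorithms rely on.

fixturePhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generateVascularPhantom(phantomSpec(seed = 5))
    }
    cache
  }
})

fixtureSmallPhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generateVascularPhantom(
        phantomSpec(seed = 11, gridHeight = 64, gridWidth = 80))
    }
    cache
  }
})

# A moving/fixed pair under a known smooth deformation, with independent
# acquisition noise on both sides (the moving image is a different
# acquisition in any real setting).
makePair <- function(maxDisplacement = 3, seed = 1, base = fixturePhantom(),
                     noise = 0.003) {
  m <- intensities(base)
  shape <- dim(m)
  td <- generateTruthDeformation("smooth", maxDisplacement, shape,
                                 seed = seed)
  mov <- intensities(warpImage(base, td@field))
  set.seed(seed + 10000)
  mov <- mov + matrix(rnorm(length(mov), 0, noise), shape[1], shape[2])
  fix <- m + matrix(rnorm(length(m), 0, noise), shape[1], shape[2])
  list(moving = mov, fixed = fix, truth = td,
       preEPE = mean(sqrt(dispX(td@field)^2 + dispY(td@field)^2)))
}

# Mean endpoint error of a recovered field against the truth it should
# invert: warp(moving, g) aligns to fixed iff compose(truth, g) is near the
# identity, so the residual composition measures the recovery error.
residualEPE <- function(truth, recovered) {
  res <- composeFields(truth@field, recovered)
  mean(sqrt(dispX(res)^2 + dispY(res)^2))
}

expect_all_finite <- function(field) {
  expect_true(all(is.finite(dispX(field))) && all(is.finite(dispY(field))))
}
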