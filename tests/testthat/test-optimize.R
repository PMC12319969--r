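# Fitness function, GA, grid search, rotational cross-validation.

test_that("the registration fitness equals its defining double sum", {
  m <- intensities(fixtureSmallPhantom())
  # perfect alignment to two identical references: exactly -2n
  regs <- list(m, m, m)
  refs <- list(m, m)
  expect_equal(gaFitness(regs, refs), -6, tolerance = 1e-12)
  expect_equal(gaFitness(list(), refs), 0)
  # random images: brute-force double loop
  set.seed(1)
  imgs <- replicate(3, matrix(runif(100), 10, 10), simplify = FALSE)
  refs2 <- replicate(2, matrix(runif(100), 10, 10), simplify = FALSE)
  brute <- -sum(vapply(refs2, function(r) {
    sum(vapply(imgs, function(i) nccGlobal(i, r), 0))
  }, 0))
  expect_equal(gaFitness(imgs, refs2), brute, tolerance = 1e-12)
  # constant images are skipped with a warning
  expect_warning(v <- gaFitness(c(imgs, list(matrix(1, 10, 10))), refs2),
                 "skipped")
  expect_equal(v, brute, tolerance = 1e-12)
})

test_that("the GA finds a 1-D optimum and obeys the stall rule", {
  space <- paramSpace(x = list(kind = "continuous", bounds = c(0, 1)))
  res <- runGA(function(p) (p$x - 0.3)^2, space, gaConfig(seed = 7))
  expect_lte(abs(res@bestParams$x - 0.3), 0.02)
  # constant fitness: stall stop after exactly the stall-window length
  resc <- runGA(function(p) 1, space, gaConfig(seed = 3))
  expect_equal(resc@stopReason, "stall")
  expect_equal(length(resc@history) - 1, 50)
})

test_that("GA best-so-far history is non-increasing for any seed", {
  space <- paramSpace(x = list(kind = "continuous", bounds = c(-2, 2)),
                      y = list(kind = "integer", bounds = c(1, 5)))
  for (seed in 1:20) {
    res <- runGA(function(p) sin(5 * p$x) + p$y * 0.1, space,
                 gaConfig(population = 8, maxGenerations = 30,
                          seed = seed))
    expect_true(all(diff(res@history) <= 1e-12))
  }
})

test_that("a failing fitness callback demotes the candidate", {
  space <- paramSpace(x = list(kind = "continuous", bounds = c(0, 1)))
  res <- runGA(function(p) {
    if (p$x > 0.8) stop("boom")
    p$x
  }, space, gaConfig(population = 10, maxGenerations = 20, seed = 5))
  expect_lte(res@bestParams$x, 0.8)
})

test_that("grid search enumerates the full Cartesian product", {
  calls <- new.env(); calls$n <- 0L
  space <- paramSpace(a = list(kind = "integer", bounds = c(1, 2)),
                      b = list(kind = "categorical",
                               choices = list("u", "v", "w")))
  res <- runGridSearch(function(p) {
    calls$n <- calls$n + 1L
    (p$a - 2)^2 + (p$b != "v")
  }, space)
  expect_equal(calls$n, 6L)
  expect_equal(res@bestParams$a, 2)
  expect_equal(res@bestParams$b, "v")
  expect_equal(res@bestFitness, 0)
  # seeded random fitness table: equals an exhaustive loop oracle
  set.seed(11)
  tab <- matrix(runif(6), 2, 3)
  res2 <- runGridSearch(function(p) {
    tab[p$a, match(p$b, c("u", "v", "w"))]
  }, space)
  oracle <- which(tab == min(tab), arr.ind = TRUE)
  expect_equal(res2@bestParams$a, unname(oracle[1, 1]))
  expect_equal(res2@bestParams$b, c("u", "v", "w")[oracle[1, 2]])
  # combinatorial guard
  big <- paramSpace(a = list(kind = "integer", bounds = c(1, 1000)),
                    b = list(kind = "integer", bounds = c(1, 1000)))
  expect_error(runGridSearch(function(p) 0, big), "budget")
})

test_that("GA with a grid-covering seed and no mutation matches grid search", {
  space <- paramSpace(a = list(kind = "integer", bounds = c(1, 3)),
                      b = list(kind = "integer", bounds = c(1, 2)))
  fit <- function(p) (p$a - 2)^2 + (p$b - 2)^2
  grid <- expand.grid(a = 1:3, b = 1:2)
  init <- lapply(seq_len(nrow(grid)), function(r) {
    list(a = grid$a[r], b = grid$b[r])
  })
  ga <- runGA(fit, space,
              gaConfig(population = 6, maxGenerations = 2,
                       mutationRate = 0, seed = 1),
              initialPopulation = init)
  gs <- runGridSearch(fit, space)
  expect_equal(ga@bestFitness, gs@bestFitness)
  expect_equal(ga@bestParams[order(names(ga@bestParams))],
               gs@bestParams[order(names(gs@bestParams))])
})

test_that("rotational CV uses each reference as validation exactly once", {
  img <- generateVascularPhantom(phantomSpec(seed = 2, gridHeight = 40,
                                             gridWidth = 48))
  m <- intensities(img)
  refs <- lapply(1:3, function(i) {
    set.seed(i)
    FUSImage(pmin(pmax(m + matrix(rnorm(length(m), 0, 0.01), nrow(m)),
                       0), 1))
  })
  movs <- lapply(4:5, function(i) {
    set.seed(i)
    FUSImage(fusireg:::.gaussSmooth(m, 2) +
               matrix(rnorm(length(m), 0, 0.01), nrow(m)))
  })
  # toy method with one parameter controlling residual blur
  regFn <- function(mv, fx, params) {
    FUSImage(fusireg:::.gaussSmooth(intensities(mv), params$blur))
  }
  space <- paramSpace(blur = list(kind = "continuous",
                                  choices = list(0.01, 0.5, 1, 2)))
  cv <- rotationalCV(refs, movs, regFn, space, strategy = "grid")
  expect_setequal(vapply(cv$folds, function(f) f$validation, 0), 1:3)
  for (f in cv$folds) {
    expect_setequal(c(f$validation, f$training), 1:3)
  }
  # brute-force fold evaluation picks the same winner
  bruteScores <- vapply(cv$folds, function(f) f$validationFitness, 0)
  expect_equal(cv$validationFitness, min(bruteScores))
  expect_identical(cv$params, cv$folds[[which.min(bruteScores)]]$params)
  # identical result on repetition (determinism)
  cv2 <- rotationalCV(refs, movs, regFn, space, strategy = "grid")
  expect_identical(cv$params, cv2$params)
})
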