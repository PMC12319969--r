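# Hyperparameter optimization of registration methods: the negated-NCC-sum
# fitness, a real-coded genetic algorithm with the stall / tolerance /
# max-generation stopping rules, exhaustive grid search, and the rotational
# cross-validation protocol over reference images.

#' Registration fitness: negated sum of NCC values
#'
#' \eqn{-\sum_j \sum_i NCC(I_i, ref_j)} over every registered image and
#' every reference; lower is better, and a perfect alignment of n images to
#' N identical references gives exactly -n N. Constant images (undefined
#' NCC) are skipped with a warning.
#'
#' @param registered list of registered \linkS4class{FUSImage}s/matrices.
#' @param references list of reference images of the same shape.
#' @return The scalar fitness (0 for an empty image list).
#' @export
gaFitness <- function(registered, references) {
  total <- 0
  skipped <- 0L
  for (ref in references) {
    for (img in registered) {
      v <- tryCatch(nccGlobal(img, ref), error = function(e) NA_real_)
      if (is.na(v)) skipped <- skipped + 1L else total <- total + v
    }
  }
  if (skipped > 0) {
    warning(sprintf("%d constant-image NCC terms skipped", skipped))
  }
  -total
}

#' Define a parameter search space
#'
#' @param ... named entries, each \code{list(kind =, ...)} with kind
#'   "continuous" (\code{bounds = c(lo, hi)}), "integer"
#'   (\code{bounds = c(lo, hi)}) or "categorical" (\code{choices}).
#' @return A classed list usable by \code{\link{runGA}},
#'   \code{\link{runGridSearch}} and \code{\link{rotationalCV}}.
#' @export
#' @examples
#' paramSpace(sigma = list(kind = "continuous", bounds = c(0.5, 4)),
#'            levels = list(kind = "integer", bounds = c(1, 4)))
paramSpace <- function(...) {
  entries <- list(...)
  stopifnot(length(entries) > 0, !is.null(names(entries)),
            all(nzchar(names(entries))))
  for (nm in names(entries)) {
    e <- entries[[nm]]
    kind <- match.arg(e$kind, c("continuous", "integer", "categorical"))
    if (kind == "categorical") {
      if (!length(e$choices)) stop("empty choices for ", nm)
    } else if (is.null(e$choices)) {
      if (length(e$bounds) != 2 || any(!is.finite(e$bounds))) {
        stop("bounds (or explicit choices) required for ", nm)
      }
    }
    entries[[nm]]$kind <- kind
  }
  structure(entries, class = "paramSpace")
}

#' Genetic-algorithm settings
#'
#' Defaults follow the standard stopping rules: maximum generations of 100
#' times the number of variables, function tolerance 1e-6, and a stall
#' limit of 50 generations (stop when the average relative change of the
#' best fitness across the stall window is at or below the tolerance).
#'
#' @param population individuals per generation (>= 2).
#' @param maxGenerations cap on generations; default 100 x n variables
#'   (resolved inside \code{\link{runGA}} when NULL).
#' @param functionTolerance stall tolerance on relative fitness change.
#' @param maxStallGenerations stall window length.
#' @param mutationRate per-gene mutation probability; NULL (default) means
#'   1 / (number of genes). Zero disables mutation.
#' @param seed integer RNG seed.
#' @return A classed list of settings.
#' @export
gaConfig <- function(population = 20, maxGenerations = NULL,
                     functionTolerance = 1e-6, maxStallGenerations = 50,
                     mutationRate = NULL, seed = 1) {
  stopifnot(population >= 2, functionTolerance > 0,
            maxStallGenerations >= 1)
  structure(list(population = population, maxGenerations = maxGenerations,
                 functionTolerance = functionTolerance,
                 maxStallGenerations = maxStallGenerations,
                 mutationRate = mutationRate, seed = seed),
            class = "gaConfig")
}

.sampleGene <- function(entry) {
  if (entry$kind != "categorical" && !is.null(entry$choices)) {
    return(sample(entry$choices, 1)[[1]])
  }
  switch(entry$kind,
    continuous = runif(1, entry$bounds[1], entry$bounds[2]),
    integer = sample(seq(entry$bounds[1], entry$bounds[2]), 1),
    categorical = sample(entry$choices, 1)[[1]])
}

.mutateGene <- function(entry, value) {
  if (entry$kind != "categorical" && !is.null(entry$choices)) {
    return(sample(entry$choices, 1)[[1]])
  }
  switch(entry$kind,
    continuous = {
      s <- (entry$bounds[2] - entry$bounds[1]) / 10
      min(max(value + rnorm(1, 0, s), entry$bounds[1]), entry$bounds[2])
    },
    integer = {
      s <- max(1, round((entry$bounds[2] - entry$bounds[1]) / 10))
      min(max(value + sample(c(-s, s), 1), entry$bounds[1]),
          entry$bounds[2])
    },
    categorical = sample(entry$choices, 1)[[1]])
}

#' Run a genetic algorithm over a parameter space
#'
#' Real-coded GA: tournament selection (size 3), uniform crossover
#' (probability 0.8), per-gene mutation at rate 1/(number of genes) with
#' Gaussian perturbation for numeric genes and resampling for categorical
#' ones, one elite individual carried over. Fitness is minimized. Stops on
#' the stall rule (no relative improvement above the tolerance for
#' \code{maxStallGenerations} consecutive generations), or at the
#' generation cap. A failing fitness callback assigns the candidate the
#' worst finite fitness seen so far.
#'
#' @param evaluate function(named list of parameter values) -> scalar
#'   fitness, lower better.
#' @param space a \code{\link{paramSpace}}.
#' @param config a \code{\link{gaConfig}}.
#' @param initialPopulation optional list of named parameter lists seeding
#'   the first generation (padded by random sampling if shorter than the
#'   population size).
#' @return A \linkS4class{GAResult}; \code{history} is the best-so-far
#'   fitness per generation (non-increasing).
#' @export
runGA <- function(evaluate, space, config = gaConfig(),
                  initialPopulation = NULL) {
  stopifnot(inherits(space, "paramSpace"), length(space) > 0)
  nGenes <- length(space)
  maxGen <- if (is.null(config$maxGenerations)) 100L * nGenes else
    config$maxGenerations
  pmut <- if (is.null(config$mutationRate)) 1 / nGenes else
    config$mutationRate
  safeEval <- function(ind, worst) {
    v <- tryCatch(evaluate(ind), error = function(e) NA_real_)
    if (!is.finite(v)) worst else v
  }
  .withSeed(config$seed, {
    pop <- replicate(config$population,
                     lapply(space, .sampleGene), simplify = FALSE)
    if (!is.null(initialPopulation)) {
      n0 <- min(length(initialPopulation), config$population)
      pop[seq_len(n0)] <- initialPopulation[seq_len(n0)]
    }
    fit <- vapply(pop, function(ind) {
      v <- tryCatch(evaluate(ind), error = function(e) NA_real_)
      if (is.finite(v)) v else Inf
    }, 0)
    if (all(!is.finite(fit))) stop("all initial fitness evaluations failed")
    fit[!is.finite(fit)] <- max(fit[is.finite(fit)])
    history <- min(fit)
    stall <- 0L
    stopReason <- "max_generations"
    for (gen in seq_len(maxGen)) {
      newPop <- vector("list", config$population)
      elite <- which.min(fit)
      newPop[[1]] <- pop[[elite]]
      for (i in 2:config$population) {
        p1 <- pop[[.tournament(fit, 3)]]
        p2 <- pop[[.tournament(fit, 3)]]
        child <- p1
        if (runif(1) < 0.8) {
          take2 <- runif(nGenes) < 0.5
          child[take2] <- p2[take2]
        }
        for (g in seq_len(nGenes)) {
          if (runif(1) < pmut) {
            child[[g]] <- .mutateGene(space[[g]], child[[g]])
          }
        }
        newPop[[i]] <- child
      }
      pop <- newPop
      worst <- max(fit[is.finite(fit)])
      fit <- vapply(pop, safeEval, 0, worst = worst)
      best <- min(min(fit), history[length(history)])
      prev <- history[length(history)]
      history <- c(history, best)
      rel <- abs(prev - best) / max(abs(prev), 1)
      if (rel <= config$functionTolerance) {
        stall <- stall + 1L
      } else {
        stall <- 0L
      }
      if (stall >= config$maxStallGenerations) {
        stopReason <- "stall"
        break
      }
    }
    bestIdx <- which.min(fit)
    new("GAResult", bestParams = pop[[bestIdx]],
        bestFitness = history[length(history)], history = history,
        stopReason = stopReason)
  })
}

.tournament <- function(fit, k) {
  idx <- sample.int(length(fit), k, replace = TRUE)
  idx[which.min(fit[idx])]
}

#' Exhaustive grid search over an enumerable parameter space
#'
#' Evaluates the full Cartesian product of the entries (integer ranges and
#' categorical choices; continuous entries must provide explicit
#' \code{choices}); ties are broken by first-in-enumeration order.
#'
#' @param evaluate fitness callback as in \code{\link{runGA}}.
#' @param space a \code{\link{paramSpace}} with enumerable entries.
#' @param maxPoints guard on the grid size (default 1e5).
#' @return A \linkS4class{GAResult} with \code{stopReason = "exhaustive"}
#'   and \code{history} the best-so-far trace over the enumeration.
#' @export
runGridSearch <- function(evaluate, space, maxPoints = 1e5) {
  stopifnot(inherits(space, "paramSpace"))
  choices <- lapply(space, function(e) {
    switch(e$kind,
      categorical = e$choices,
      integer = as.list(seq(e$bounds[1], e$bounds[2])),
      continuous = {
        if (is.null(e$choices)) {
          stop("continuous entries need explicit choices for grid search")
        }
        as.list(e$choices)
      })
  })
  sizes <- vapply(choices, length, 0L)
  if (prod(sizes) > maxPoints) {
    stop(sprintf("grid of %g points exceeds the budget of %g",
                 prod(sizes), maxPoints))
  }
  idxGrid <- do.call(expand.grid, lapply(sizes, seq_len))
  best <- Inf; bestParams <- NULL
  history <- numeric(nrow(idxGrid))
  for (r in seq_len(nrow(idxGrid))) {
    params <- setNames(
      lapply(seq_along(space),
             function(j) choices[[j]][[idxGrid[r, j]]]),
      names(space))
    v <- tryCatch(evaluate(params), error = function(e) Inf)
    if (is.finite(v) && v < best) {
      best <- v; bestParams <- params
    }
    history[r] <- best
  }
  if (is.null(bestParams)) stop("all grid evaluations failed")
  new("GAResult", bestParams = bestParams, bestFitness = best,
      history = history, stopReason = "exhaustive")
}

#' Rotational cross-validation over reference images
#'
#' With k references (default and canonical case k = 3), forms k folds in
#' which each reference serves as the validation set exactly once and the
#' remaining k - 1 are the training references. Per fold, the optimizer
#' minimizes the registration fitness (\code{\link{gaFitness}}) of the
#' moving set against the training references; the fold's selected
#' parameters are then scored on the held-out reference, and the parameter
#' set with the best (lowest) validation fitness is returned (ties broken
#' by fold order).
#'
#' @param references list of reference images.
#' @param moving list of moving images.
#' @param registerWith function(moving image, fixed image, named parameter
#'   list) returning the registered image; defines the method under
#'   optimization.
#' @param space a \code{\link{paramSpace}}.
#' @param strategy "grid" (default) or "ga".
#' @param config a \code{\link{gaConfig}} (GA strategy only).
#' @return list with \code{params} (selected values), \code{folds}
#'   (per-fold training/validation indices, selected params, validation
#'   fitness) and \code{validationFitness} of the winner.
#' @export
rotationalCV <- function(references, moving, registerWith, space,
                         strategy = c("grid", "ga"), config = gaConfig()) {
  strategy <- match.arg(strategy)
  k <- length(references)
  stopifnot(k >= 2)
  folds <- vector("list", k)
  for (v in seq_len(k)) {
    trainIdx <- setdiff(seq_len(k), v)
    fitnessOn <- function(refIdx) {
      force(refIdx)
      # register every moving image to each reference in the set and sum
      # the per-reference negated NCC totals (N = length(refIdx) terms)
      function(params) {
        sum(vapply(refIdx, function(j) {
          reg <- lapply(moving, function(mv) {
            registerWith(mv, references[[j]], params)
          })
          gaFitness(reg, references[j])
        }, 0))
      }
    }
    trainEval <- fitnessOn(trainIdx)
    res <- if (strategy == "grid") {
      runGridSearch(trainEval, space)
    } else {
      runGA(trainEval, space, config)
    }
    valFitness <- fitnessOn(v)(res@bestParams)
    folds[[v]] <- list(validation = v, training = trainIdx,
                       params = res@bestParams,
                       validationFitness = valFitness)
  }
  scores <- vapply(folds, function(f) f$validationFitness, 0)
  win <- which.min(scores)
  list(params = folds[[win]]$params, folds = folds,
       validationFitness = scores[win])
}
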