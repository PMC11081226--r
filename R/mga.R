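# Matrix-structured genetic algorithm (MGA): the population lives on an
# R x C grid. Each generation the best individual of every row is marked
# (first occurrence on ties) and copied onto that row's main-diagonal slot;
# every other cell is recombined with its row's diagonal individual and
# mutated. Diagonal slots are never crossed or mutated, so the global best
# survives every generation and best-so-far fitness is monotone.

#' Define a minimization problem for the MGA engine
#'
#' @param objective function mapping a decision vector to a finite real
#'   (minimized).
#' @param dims number of decision variables.
#' @param lower,upper bounds of the feasible box (continuous mode); recycled
#'   to length `dims`. Ignored in binary mode.
#' @param type `"continuous"` (real vector in the box) or `"binary"`
#'   (0/1 chromosome).
#' @param ops optional list of custom operators overriding the defaults:
#'   `init(n, d)` returning an n x d gene matrix, `crossover(a, b)` and
#'   `mutate(x, rate)` returning gene vectors.
#' @return An object of class `OptimizationProblem`.
#' @export
optimizationProblem <- function(objective, dims, lower = 0, upper = 1,
                                type = c("continuous", "binary"),
                                ops = NULL) {
  type <- match.arg(type)
  stopifnot(is.function(objective), dims >= 1)
  lower <- rep_len(lower, dims); upper <- rep_len(upper, dims)
  if (type == "continuous" && any(lower >= upper)) {
    stop("infeasible bounds: lower must be < upper", call. = FALSE)
  }
  structure(list(objective = objective, dims = as.integer(dims),
                 lower = lower, upper = upper, type = type, ops = ops),
            class = "OptimizationProblem")
}

#' Standard benchmark objectives
#'
#' Closed-form minimization benchmarks with known global minimum 0:
#' sphere (at the origin, box \[-5.12, 5.12\]), Rastrigin (origin, same box)
#' and Rosenbrock (at (1, ..., 1), box \[-2.048, 2.048\]).
#'
#' @param name `"sphere"`, `"rastrigin"` or `"rosenbrock"`.
#' @param dims dimensionality, 1 to 30.
#' @return An [optimizationProblem()].
#' @examples
#' p <- benchmarkProblem("sphere", 2)
#' p$objective(c(0, 0)) # 0
#' @export
benchmarkProblem <- function(name = c("sphere", "rastrigin", "rosenbrock"),
                             dims = 2L) {
  name <- match.arg(name)
  assertScalarNumber(dims, "dims", lower = 1, upper = 30)
  dims <- as.integer(dims)
  switch(name,
    sphere = optimizationProblem(function(x) sum(x^2), dims, -5.12, 5.12),
    rastrigin = optimizationProblem(
      function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
      dims, -5.12, 5.12),
    rosenbrock = {
      if (dims < 2L) stop("rosenbrock needs dims >= 2", call. = FALSE)
      optimizationProblem(function(x) {
        sum(100 * (x[-1] - x[-length(x)]^2)^2 + (1 - x[-length(x)])^2)
      }, dims, -2.048, 2.048)
    })
}

#' MGA configuration
#'
#' @param rows,cols grid shape (default 5 x 5, a population of 25). A
#'   non-square grid disables the diagonal-dominance step (row-best cells
#'   take the diagonal's role) with a warning at run time.
#' @param generations number of evolution steps.
#' @param crossoverRate per-cell probability of recombining with the row's
#'   diagonal individual.
#' @param mutationRate per-gene mutation probability.
#' @param seed integer RNG seed (NULL = ambient stream).
#' @param tolerance optional absolute fitness tolerance; evolution stops
#'   early once best fitness <= tolerance.
#' @return An object of class `GAConfig`.
#' @export
mgaConfig <- function(rows = 5L, cols = 5L, generations = 100L,
                      crossoverRate = 0.9, mutationRate = 0.1,
                      seed = NULL, tolerance = NULL) {
  assertScalarNumber(rows, "rows", lower = 1)
  assertScalarNumber(cols, "cols", lower = 1)
  if (rows * cols < 2) stop("population must have at least 2 cells",
                            call. = FALSE)
  assertScalarNumber(generations, "generations", lower = 0)
  assertScalarNumber(crossoverRate, "crossoverRate", 0, 1)
  assertScalarNumber(mutationRate, "mutationRate", 0, 1)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 generations = as.integer(generations),
                 crossoverRate = crossoverRate, mutationRate = mutationRate,
                 seed = seed, tolerance = tolerance),
            class = "GAConfig")
}

cellIndex <- function(i, j, cols) (i - 1L) * cols + j

defaultInit <- function(problem, n) {
  if (!is.null(problem$ops$init)) return(problem$ops$init(n, problem$dims))
  d <- problem$dims
  if (problem$type == "binary") {
    matrix(as.numeric(stats::runif(n * d) < 0.5), n, d)
  } else {
    matrix(stats::runif(n * d, rep(problem$lower, each = n),
                        rep(problem$upper, each = n)), n, d)
  }
}

defaultCrossover <- function(problem, a, b) {
  if (!is.null(problem$ops$crossover)) return(problem$ops$crossover(a, b))
  if (problem$type == "binary") {
    pick <- stats::runif(length(a)) < 0.5
    ifelse(pick, a, b)
  } else {
    alpha <- stats::runif(1)
    alpha * a + (1 - alpha) * b
  }
}

defaultMutate <- function(problem, x, rate) {
  if (!is.null(problem$ops$mutate)) return(problem$ops$mutate(x, rate))
  hit <- stats::runif(length(x)) < rate
  if (!any(hit)) return(x)
  if (problem$type == "binary") {
    x[hit] <- 1 - x[hit]
  } else {
    sd <- 0.1 * (problem$upper - problem$lower)
    x[hit] <- x[hit] + stats::rnorm(sum(hit), 0, sd[hit])
    x <- pmin(pmax(x, problem$lower), problem$upper)
  }
  x
}

## Column index of each row's best cell, first occurrence on ties.
computeRowBest <- function(fitness) {
  apply(fitness, 1L, function(f) which(f == min(f))[1L])
}

#' Initialize a matrix population
#'
#' Fills the grid uniformly at random within the bounds (continuous) or with
#' Bernoulli(0.5) bits (binary), evaluates every cell, and marks the row
#' bests. Uses the ambient RNG stream; seed via [mgaMinimize()] or
#' [withr-style seeding][set.seed].
#'
#' @param problem an [optimizationProblem()].
#' @param cfg an [mgaConfig()].
#' @return A `MatrixPopulation`: list with `genes` ((rows*cols) x dims
#'   matrix, cell (i, j) in row `(i-1)*cols + j`), `fitness` (rows x cols),
#'   `rowBest` (length-rows column indices) and `generation`.
#' @export
mgaInit <- function(problem, cfg) {
  n <- cfg$rows * cfg$cols
  genes <- defaultInit(problem, n)
  fit <- matrix(apply(genes, 1L, problem$objective),
                cfg$rows, cfg$cols, byrow = TRUE)
  if (any(!is.finite(fit))) {
    stop("objective returned a non-finite value on the feasible region",
         call. = FALSE)
  }
  structure(list(genes = genes, fitness = fit,
                 rowBest = computeRowBest(fit), generation = 0L),
            class = "MatrixPopulation")
}

#' One MGA generation
#'
#' Recomputes row bests, copies each row's best individual onto the row's
#' main-diagonal slot (square grids only), recombines every non-diagonal
#' cell with its row's diagonal individual at `crossoverRate`, mutates each
#' offspring gene at `mutationRate`, and re-evaluates changed cells.
#' Diagonal slots pass through untouched (elitism), so the global best
#' fitness never increases.
#'
#' @param pop a `MatrixPopulation` from [mgaInit()] or a previous step.
#' @param problem an [optimizationProblem()].
#' @param cfg an [mgaConfig()].
#' @return The next-generation `MatrixPopulation`.
#' @export
mgaStep <- function(pop, problem, cfg) {
  R <- cfg$rows; C <- cfg$cols
  square <- R == C
  if (!square && is.null(pop$warned)) {
    warning("non-square grid: diagonal dominance disabled, row-best cells ",
            "take the diagonal's role", call. = FALSE)
  }
  genes <- pop$genes; fit <- pop$fitness
  rowBest <- computeRowBest(fit)
  ## diagonal dominance: the row best claims the diagonal slot
  eliteCol <- integer(R)
  for (i in seq_len(R)) {
    if (square) {
      src <- cellIndex(i, rowBest[i], C)
      dst <- cellIndex(i, i, C)
      genes[dst, ] <- genes[src, ]
      fit[i, i] <- fit[i, rowBest[i]]
      eliteCol[i] <- i
    } else {
      eliteCol[i] <- rowBest[i]
    }
  }
  newGenes <- genes; newFit <- fit
  for (i in seq_len(R)) {
    partner <- genes[cellIndex(i, eliteCol[i], C), ]
    for (j in seq_len(C)) {
      if (j == eliteCol[i]) next
      idx <- cellIndex(i, j, C)
      child <- genes[idx, ]
      if (stats::runif(1) < cfg$crossoverRate) {
        child <- defaultCrossover(problem, child, partner)
      }
      child <- defaultMutate(problem, child, cfg$mutationRate)
      if (!identical(child, genes[idx, ])) {
        newGenes[idx, ] <- child
        newFit[i, j] <- problem$objective(child)
      }
    }
  }
  structure(list(genes = newGenes, fitness = newFit,
                 rowBest = computeRowBest(newFit),
                 generation = pop$generation + 1L,
                 warned = if (!square) TRUE else NULL),
            class = "MatrixPopulation")
}

## Global best cell of a population.
populationBest <- function(pop) {
  k <- which.min(pop$fitness)          # column-major over rows x cols
  i <- (k - 1L) %% nrow(pop$fitness) + 1L
  j <- (k - 1L) %/% nrow(pop$fitness) + 1L
  idx <- cellIndex(i, j, ncol(pop$fitness))
  list(x = pop$genes[idx, ], f = pop$fitness[i, j])
}

#' Minimize an objective with the matrix-structured GA
#'
#' Runs [mgaInit()] plus `cfg$generations` steps (stopping early when the
#' optional fitness tolerance is reached) and returns the best individual
#' found, its fitness, and the per-generation best-fitness history (which is
#' non-increasing by elitism).
#'
#' @param problem an [optimizationProblem()] or [benchmarkProblem()].
#' @param cfg an [mgaConfig()]; `cfg$seed` makes the run deterministic.
#' @return A list with `bestX`, `bestF`, `history` (length generations + 1
#'   when the tolerance is never met) and the final `population`.
#' @examples
#' res <- mgaMinimize(benchmarkProblem("sphere", 2),
#'                    mgaConfig(generations = 50, seed = 1))
#' res$bestF
#' @export
mgaMinimize <- function(problem, cfg = mgaConfig()) {
  withSeed(cfg$seed, {
    pop <- mgaInit(problem, cfg)
    best <- populationBest(pop)
    history <- best$f
    for (g in seq_len(cfg$generations)) {
      if (!is.null(cfg$tolerance) && best$f <= cfg$tolerance) break
      pop <- mgaStep(pop, problem, cfg)
      cand <- populationBest(pop)
      if (cand$f < best$f) best <- cand
      history <- c(history, best$f)
    }
    list(bestX = best$x, bestF = best$f, history = history, population = pop)
  })
}
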