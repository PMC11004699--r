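.benchmarkTable <- list(
  F1 = list(lower = -100, upper = 100, stochastic = FALSE),
  F2 = list(lower = -100, upper = 100, stochastic = FALSE),
  F3 = list(lower = -30,  upper = 30,  stochastic = FALSE),
  F4 = list(lower = -128, upper = 128, stochastic = TRUE),
  F5 = list(lower = -128, upper = 128, stochastic = FALSE))

#' Names of the built-in benchmark functions
#'
#' @return Character vector \code{c("F1", ..., "F5")}.
#' @export
benchmarkNames <- function() names(.benchmarkTable)

#' Search bounds of a built-in benchmark
#'
#' @param name one of \code{benchmarkNames()}.
#' @param dimension problem dimension n.
#' @return A \linkS4class{BoxBounds} with the function's published range
#'   replicated over \code{dimension} coordinates.
#' @examples
#' benchmarkBounds("F1", 30)   # [-100, 100]^30
#' @export
benchmarkBounds <- function(name, dimension) {
  spec <- .benchmarkTable[[match.arg(name, benchmarkNames())]]
  boxBounds(spec$lower, spec$upper, dimension = dimension)
}

#' Evaluate a built-in benchmark function
#'
#' The five classic test functions of the validation suite, all with
#' minimum value 0:
#' \itemize{
#'   \item F1 (sphere): \eqn{\sum_i x_i^2}, minimizer at the origin.
#'   \item F2 (shifted quadratic): \eqn{\sum_i (x_i + 0.5)^2}, minimizer at
#'     \eqn{-0.5 \cdot \mathbf{1}}; with \code{f2Step = TRUE} the classic
#'     step variant \eqn{\sum_i \lfloor x_i + 0.5 \rfloor^2} is used
#'     instead (minimum 0 on the plateau around the origin).
#'   \item F3: \eqn{\sum_i |x_i| + \prod_i |x_i|}, minimizer at the origin.
#'   \item F4 (noisy quartic): \eqn{\sum_i i\, x_i^4 + \mathrm{unif}[0,1)};
#'     stochastic — the additive noise draws from the current RNG, so its
#'     printed minimum 0 is an infimum.
#'   \item F5 (Rosenbrock): \eqn{\sum_{i=1}^{n-1} [100 (x_{i+1} - x_i^2)^2
#'     + (x_i - 1)^2]}, minimizer at \eqn{\mathbf{1}}.
#' }
#'
#' @param name one of \code{benchmarkNames()}.
#' @param x numeric vector inside the function's bounds.
#' @param f2Step logical; use the floor-step variant of F2.
#' @param checkBounds logical; error when \code{x} leaves the published
#'   range (the optimizer clamps its agents, so this is a user guard).
#' @return The scalar function value.
#' @examples
#' evaluateBenchmark("F1", c(1, 2, 3))        # 14
#' evaluateBenchmark("F5", rep(1, 10))        # 0
#' @export
evaluateBenchmark <- function(name, x, f2Step = FALSE, checkBounds = TRUE) {
  name <- match.arg(name, benchmarkNames())
  spec <- .benchmarkTable[[name]]
  if (!is.numeric(x) || length(x) < 1L) stop("x must be a numeric vector")
  if (checkBounds && (any(x < spec$lower) || any(x > spec$upper)))
    stop(sprintf("x lies outside the %s range [%g, %g]", name,
                 spec$lower, spec$upper))
  n <- length(x)
  switch(name,
    F1 = sum(x^2),
    F2 = if (f2Step) sum(floor(x + 0.5)^2) else sum((x + 0.5)^2),
    F3 = sum(abs(x)) + prod(abs(x)),
    F4 = sum(seq_len(n) * x^4) + stats::runif(1),
    F5 = if (n < 2L) stop("F5 needs dimension >= 2") else
      sum(100 * (x[-1] - x[-n]^2)^2 + (x[-n] - 1)^2))
}

#' Objective closure for a benchmark
#'
#' @param name one of \code{benchmarkNames()}.
#' @param f2Step logical; floor-step variant of F2.
#' @return A function of \code{x} suitable for \code{\link{goaOptimize}}
#'   (bounds checking off, since the optimizer clamps to the box).
#' @export
benchmarkObjective <- function(name, f2Step = FALSE) {
  name <- match.arg(name, benchmarkNames())
  function(x) evaluateBenchmark(name, x, f2Step = f2Step, checkBounds = FALSE)
}

#' Repeated optimizer trials on one benchmark
#'
#' Runs one optimizer configuration \code{nRuns} times on a benchmark
#' function with seeds \code{seedBase + 0, ..., seedBase + nRuns - 1} and
#' summarizes the final best fitnesses by their mean (AVE) and standard
#' deviation (STD), the repeated-trial protocol of the validation study
#' (35 runs, population 50, 100 iterations).
#'
#' @param functionName one of \code{benchmarkNames()}, or a function of
#'   \code{x} for a custom objective (then \code{bounds} is required).
#' @param control a \linkS4class{GoaControl}; its seed slot is overridden
#'   per run.
#' @param nRuns number of repeated runs (>= 2).
#' @param dimension problem dimension (default 30).
#' @param seedBase first seed of the run sequence.
#' @param bounds optional \linkS4class{BoxBounds} for a custom objective.
#' @param optimizerName label stored in the summary; defaults to the
#'   control's variant.
#' @return A \linkS4class{TrialSummary}.
#' @examples
#' runTrials("F1", goaControl(populationSize = 10, maxIterations = 10),
#'           nRuns = 3, dimension = 2, seedBase = 1)
#' @export
runTrials <- function(functionName, control, nRuns = 35, dimension = 30,
                      seedBase = 1L, bounds = NULL, optimizerName = NULL) {
  stopifnot(is(control, "GoaControl"))
  if (nRuns < 2L) stop("nRuns must be at least 2")
  if (is.function(functionName)) {
    if (is.null(bounds)) stop("custom objectives need explicit bounds")
    objective <- functionName
    fname <- "custom"
  } else {
    fname <- match.arg(functionName, benchmarkNames())
    objective <- benchmarkObjective(fname)
    if (is.null(bounds)) bounds <- benchmarkBounds(fname, dimension)
  }
  if (is.null(optimizerName)) {
    optimizerName <- if (control@useChaos && control@useQobl) "agoa"
                     else if (!control@useChaos && !control@useQobl) "goa"
                     else "goa-partial"
  }
  bests <- vapply(seq_len(nRuns) - 1L, function(off) {
    ctl <- control
    ctl@seed <- as.integer(seedBase + off)
    bestFitness(goaOptimize(objective, bounds, ctl))
  }, numeric(1))
  new("TrialSummary", optimizer = optimizerName, functionName = fname,
      nRuns = as.integer(nRuns), meanBest = mean(bests),
      stdBest = stats::sd(bests), perRunBests = bests)
}

#' Tabulate trial summaries
#'
#' Collects \linkS4class{TrialSummary} objects into a comparison table
#' keyed by (function, optimizer) with AVE and STD columns, ordered by
#' function then optimizer. Duplicate keys are an error.
#'
#' @param summaries a list of \linkS4class{TrialSummary} objects (a single
#'   summary is accepted).
#' @return A \code{data.frame} with columns \code{functionName},
#'   \code{optimizer}, \code{nRuns}, \code{ave}, \code{std}.
#' @export
summarizeTrials <- function(summaries) {
  if (is(summaries, "TrialSummary")) summaries <- list(summaries)
  if (length(summaries) == 0L) stop("no summaries supplied")
  stopifnot(all(vapply(summaries, is, logical(1), "TrialSummary")))
  tab <- do.call(rbind, lapply(summaries, function(s)
    data.frame(functionName = s@functionName, optimizer = s@optimizer,
               nRuns = s@nRuns, ave = s@meanBest, std = s@stdBest,
               stringsAsFactors = FALSE)))
  key <- paste(tab$functionName, tab$optimizer, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate (function, optimizer) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  tab[order(tab$functionName, tab$optimizer), , drop = FALSE]
}
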