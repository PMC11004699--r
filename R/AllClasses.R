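#' @import methods
NULL

#' Rectangular search domain
#'
#' A box-constrained search domain: componentwise lower and upper limits for a
#' D-dimensional continuous decision vector. Every optimizer in this package
#' keeps its agents inside such a box by clamping after each position update.
#'
#' @slot lower numeric vector of lower limits, one per dimension.
#' @slot upper numeric vector of upper limits, same length as \code{lower}.
#' @aliases BoxBounds
#' @exportClass BoxBounds
setClass("BoxBounds", representation(lower = "numeric", upper = "numeric"))

setValidity("BoxBounds", function(object) {
  if (length(object@lower) != length(object@upper))
    return("lower and upper must have the same length")
  if (length(object@lower) < 1L)
    return("bounds must have at least one dimension")
  if (any(!is.finite(object@lower)) || any(!is.finite(object@upper)))
    return("bounds must be finite")
  if (any(object@lower >= object@upper))
    return("each lower bound must be strictly below its upper bound")
  TRUE
})

#' Construct a BoxBounds object
#'
#' @param lower numeric vector of lower limits (recycled against \code{upper}
#'   if scalar).
#' @param upper numeric vector of upper limits.
#' @param dimension optional dimension used to recycle scalar limits, e.g.
#'   \code{boxBounds(-100, 100, dimension = 30)}.
#' @return A \linkS4class{BoxBounds} object.
#' @examples
#' boxBounds(-5, 5, dimension = 2)
#' @export
boxBounds <- function(lower, upper, dimension = NULL) {
  if (!is.null(dimension)) {
    if (length(lower) == 1L) lower <- rep(lower, dimension)
    if (length(upper) == 1L) upper <- rep(upper, dimension)
  } else if (length(lower) == 1L && length(upper) > 1L) {
    lower <- rep(lower, length(upper))
  } else if (length(upper) == 1L && length(lower) > 1L) {
    upper <- rep(upper, length(lower))
  }
  new("BoxBounds", lower = as.numeric(lower), upper = as.numeric(upper))
}

#' Grasshopper optimizer settings
#'
#' Settings shared by the baseline grasshopper optimization algorithm (GOA)
#' and its amended variant (AGOA). The comfort-zone coefficient decays
#' linearly from \code{cMax} to \code{cMin} over \code{maxIterations}
#' iterations; the social-force kernel is
#' \eqn{s(d) = f e^{-d/l} - e^{-d}} with attraction intensity \code{f}
#' and length scale \code{l}. Gravity and wind drifts are kept as optional
#' terms with zero defaults, since the working position update omits them.
#'
#' @slot populationSize integer, number of grasshopper agents (N).
#' @slot maxIterations integer, number of iterations (L).
#' @slot cMax,cMin comfort-zone coefficient schedule endpoints.
#' @slot attractionIntensity social-force attraction intensity f.
#' @slot attractionLengthScale social-force attraction length scale l.
#' @slot gravityConstant gravity drift magnitude g (default 0).
#' @slot windStrength wind drift magnitude u (default 0).
#' @slot useChaos logical; drive the r1/r2/r3 streams by the singer map.
#' @slot useQobl logical; apply quasi-opposition-based learning per agent.
#' @slot seed integer seed for the run's random number generator.
#' @aliases GoaControl
#' @exportClass GoaControl
setClass("GoaControl", representation(
  populationSize = "integer", maxIterations = "integer",
  cMax = "numeric", cMin = "numeric",
  attractionIntensity = "numeric", attractionLengthScale = "numeric",
  gravityConstant = "numeric", windStrength = "numeric",
  useChaos = "logical", useQobl = "logical", seed = "integer"))

setValidity("GoaControl", function(object) {
  if (object@populationSize < 2L) return("populationSize must be >= 2")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (!(object@cMin > 0 && object@cMin < object@cMax))
    return("need 0 < cMin < cMax")
  if (object@attractionLengthScale <= 0)
    return("attractionLengthScale must be positive")
  TRUE
})

#' Construct grasshopper optimizer settings
#'
#' @param populationSize number of agents N (default 50, the benchmark
#'   protocol value).
#' @param maxIterations number of iterations L (default 100, likewise).
#' @param cMax,cMin endpoints of the linearly decaying comfort coefficient;
#'   defaults 1 and 0.01.
#' @param attractionIntensity,attractionLengthScale social-force kernel
#'   parameters f and l; defaults 0.5 and 1.5, the customary GOA values.
#' @param gravityConstant,windStrength optional gravity/wind drift magnitudes,
#'   both 0 by default.
#' @param useChaos,useQobl the two AGOA amendments; both \code{FALSE} gives
#'   baseline GOA, both \code{TRUE} gives AGOA.
#' @param seed integer seed; every run with the same control is reproducible.
#' @return A \linkS4class{GoaControl} object.
#' @examples
#' goaControl(populationSize = 20, maxIterations = 50, seed = 1)
#' agoaControl(seed = 1)
#' @export
goaControl <- function(populationSize = 50, maxIterations = 100,
                       cMax = 1, cMin = 0.01,
                       attractionIntensity = 0.5, attractionLengthScale = 1.5,
                       gravityConstant = 0, windStrength = 0,
                       useChaos = FALSE, useQobl = FALSE, seed = 1L) {
  new("GoaControl",
      populationSize = as.integer(populationSize),
      maxIterations = as.integer(maxIterations),
      cMax = as.numeric(cMax), cMin = as.numeric(cMin),
      attractionIntensity = as.numeric(attractionIntensity),
      attractionLengthScale = as.numeric(attractionLengthScale),
      gravityConstant = as.numeric(gravityConstant),
      windStrength = as.numeric(windStrength),
      useChaos = isTRUE(useChaos), useQobl = isTRUE(useQobl),
      seed = as.integer(seed))
}

#' @rdname goaControl
#' @param ... arguments passed on to \code{goaControl}.
#' @export
agoaControl <- function(...) goaControl(..., useChaos = TRUE, useQobl = TRUE)

#' Result of a grasshopper optimizer run
#'
#' @slot bestPosition best decision vector found.
#' @slot bestFitness its objective value (minimization).
#' @slot convergenceHistory best-so-far fitness after each iteration,
#'   length \code{maxIterations + 1} (entry 1 is the initial population's
#'   best); non-increasing by construction.
#' @slot evaluationsUsed total objective evaluations spent, counting
#'   quasi-opposite candidate evaluations.
#' @slot optimizer label, \code{"goa"} or \code{"agoa"} (or \code{"goa+"}
#'   variants when only one amendment is on).
#' @aliases GoaResult
#' @exportClass GoaResult
setClass("GoaResult", representation(
  bestPosition = "numeric", bestFitness = "numeric",
  convergenceHistory = "numeric", evaluationsUsed = "integer",
  optimizer = "character"))

setValidity("GoaResult", function(object) {
  h <- object@convergenceHistory
  if (any(diff(h) > 0)) return("convergenceHistory must be non-increasing")
  if (length(h) && object@bestFitness != h[length(h)])
    return("bestFitness must equal the last history entry")
  TRUE
})

#' Repeated-trial summary for one optimizer on one benchmark
#'
#' Holds the per-run final best fitnesses of repeated independent optimizer
#' runs together with their mean (AVE) and standard deviation (STD), the two
#' quantities the benchmark validation protocol reports.
#'
#' @slot optimizer,functionName identifying labels.
#' @slot nRuns number of repeated runs.
#' @slot meanBest,stdBest mean and sd of \code{perRunBests}.
#' @slot perRunBests final best fitness of each run.
#' @aliases TrialSummary
#' @exportClass TrialSummary
setClass("TrialSummary", representation(
  optimizer = "character", functionName = "character", nRuns = "integer",
  meanBest = "numeric", stdBest = "numeric", perRunBests = "numeric"))

setValidity("TrialSummary", function(object) {
  if (object@nRuns != length(object@perRunBests))
    return("nRuns must match length(perRunBests)")
  if (abs(object@meanBest - mean(object@perRunBests)) > 1e-9 *
      max(1, abs(object@meanBest)))
    return("meanBest is not the mean of perRunBests")
  TRUE
})

#' Extreme learning machine model
#'
#' A single-hidden-layer feedforward network: fixed (random or
#' optimizer-chosen) hidden-layer input weights and biases, a nonlinear
#' hidden activation, and output weights solved in closed form as the
#' minimum-norm least-squares solution \eqn{\beta = H^\dagger T} of
#' \eqn{H \beta = T}, where \eqn{H} is the hidden-layer output matrix and
#' \eqn{T} the one-hot target matrix.
#'
#' @slot inputWeights L_h x d matrix of hidden-layer input weights.
#' @slot biases length-L_h hidden bias vector.
#' @slot activation hidden activation name ("sigmoid", "tanh", "relu",
#'   "linear").
#' @slot outputWeights L_h x k output weight matrix (linear output layer).
#' @slot classLevels the k class labels, in score-column order.
#' @aliases ELMModel
#' @exportClass ELMModel
setClass("ELMModel", representation(
  inputWeights = "matrix", biases = "numeric", activation = "character",
  outputWeights = "matrix", classLevels = "character"))

setValidity("ELMModel", function(object) {
  Lh <- nrow(object@inputWeights)
  if (length(object@biases) != Lh)
    return("biases length must equal nrow(inputWeights)")
  if (nrow(object@outputWeights) != Lh)
    return("outputWeights rows must equal the hidden node count")
  if (ncol(object@outputWeights) != length(object@classLevels))
    return("outputWeights columns must match classLevels")
  if (any(!is.finite(object@inputWeights)) || any(!is.finite(object@biases)))
    return("weights and biases must be finite")
  TRUE
})

#' Binary confusion counts
#'
#' True/false positive and negative counts from which all eight report
#' metrics derive.
#'
#' @slot tp,tn,fp,fn nonnegative integer counts.
#' @aliases ConfusionCounts
#' @exportClass ConfusionCounts
setClass("ConfusionCounts", representation(
  tp = "integer", tn = "integer", fp = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  counts <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(counts < 0L)) return("counts must be nonnegative")
  if (sum(counts) < 1L) return("at least one observation is required")
  TRUE
})

#' Convolutional feature stack
#'
#' The AlexNet-shaped convolution/pooling stack used as a fixed feature
#' extractor: five convolution layers (each followed by per-channel batch
#' normalization and ReLU) interleaved with three 3x3 stride-2 max-pooling
#' layers, flattened to a 9216-length feature vector. Shape consistency of
#' the whole chain is checked at construction time.
#'
#' @slot layers list of layer descriptors (type, kernel, stride, pad,
#'   filters).
#' @slot shapes list of output shapes, one per layer, starting from the
#'   input shape.
#' @slot outputLength flattened feature length (9216 for the default stack).
#' @aliases ConvStack
#' @exportClass ConvStack
setClass("ConvStack", representation(
  layers = "list", shapes = "list", outputLength = "integer"))
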