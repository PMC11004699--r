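#' Accessors for optimizer results and models
#'
#' Small accessor generics so user code never reaches into slots:
#' \code{bestFitness} / \code{bestPosition} / \code{convergenceHistory} /
#' \code{evaluationsUsed} for \linkS4class{GoaResult},
#' \code{hiddenWeights} / \code{hiddenBiases} / \code{outputWeights} /
#' \code{classLevels} for \linkS4class{ELMModel}, and
#' \code{perRunBests} for \linkS4class{TrialSummary}.
#'
#' @param object the object to access.
#' @return The corresponding component.
#' @name accessors
#' @examples
#' res <- goaOptimize(function(x) sum(x^2), boxBounds(-5, 5, dimension = 2),
#'                    goaControl(populationSize = 10, maxIterations = 20))
#' bestFitness(res)
#' length(convergenceHistory(res))
NULL

#' @rdname accessors
#' @export
setGeneric("bestFitness", function(object) standardGeneric("bestFitness"))
#' @rdname accessors
#' @export
setGeneric("bestPosition", function(object) standardGeneric("bestPosition"))
#' @rdname accessors
#' @export
setGeneric("convergenceHistory",
           function(object) standardGeneric("convergenceHistory"))
#' @rdname accessors
#' @export
setGeneric("evaluationsUsed",
           function(object) standardGeneric("evaluationsUsed"))
#' @rdname accessors
#' @export
setGeneric("hiddenWeights", function(object) standardGeneric("hiddenWeights"))
#' @rdname accessors
#' @export
setGeneric("hiddenBiases", function(object) standardGeneric("hiddenBiases"))
#' @rdname accessors
#' @export
setGeneric("outputWeights", function(object) standardGeneric("outputWeights"))
#' @rdname accessors
#' @export
setGeneric("classLevels", function(object) standardGeneric("classLevels"))
#' @rdname accessors
#' @export
setGeneric("perRunBests", function(object) standardGeneric("perRunBests"))

#' @rdname accessors
setMethod("bestFitness", "GoaResult", function(object) object@bestFitness)
#' @rdname accessors
setMethod("bestPosition", "GoaResult", function(object) object@bestPosition)
#' @rdname accessors
setMethod("convergenceHistory", "GoaResult",
          function(object) object@convergenceHistory)
#' @rdname accessors
setMethod("evaluationsUsed", "GoaResult",
          function(object) object@evaluationsUsed)
#' @rdname accessors
setMethod("hiddenWeights", "ELMModel", function(object) object@inputWeights)
#' @rdname accessors
setMethod("hiddenBiases", "ELMModel", function(object) object@biases)
#' @rdname accessors
setMethod("outputWeights", "ELMModel", function(object) object@outputWeights)
#' @rdname accessors
setMethod("classLevels", "ELMModel", function(object) object@classLevels)
#' @rdname accessors
setMethod("perRunBests", "TrialSummary", function(object) object@perRunBests)

setMethod("show", "BoxBounds", function(object) {
  d <- length(object@lower)
  cat(sprintf("BoxBounds: %d dimension%s\n", d, if (d > 1) "s" else ""))
  if (d <= 6) {
    cat("  lower:", paste(signif(object@lower, 4), collapse = " "), "\n")
    cat("  upper:", paste(signif(object@upper, 4), collapse = " "), "\n")
  } else {
    cat(sprintf("  lower in [%g, %g], upper in [%g, %g]\n",
                min(object@lower), max(object@lower),
                min(object@upper), max(object@upper)))
  }
})

setMethod("show", "GoaControl", function(object) {
  variant <- if (object@useChaos && object@useQobl) "AGOA"
             else if (!object@useChaos && !object@useQobl) "GOA"
             else "GOA (partial amendments)"
  cat(sprintf("GoaControl [%s]: N=%d, L=%d, c in [%g, %g], f=%g, l=%g, seed=%d\n",
              variant, object@populationSize, object@maxIterations,
              object@cMin, object@cMax, object@attractionIntensity,
              object@attractionLengthScale, object@seed))
  cat(sprintf("  chaos streams: %s, quasi-opposition: %s\n",
              object@useChaos, object@useQobl))
})

setMethod("show", "GoaResult", function(object) {
  cat(sprintf("GoaResult [%s]\n", object@optimizer))
  cat(sprintf("  best fitness: %.6g after %d evaluations\n",
              object@bestFitness, object@evaluationsUsed))
  cat(sprintf("  dimensions: %d, iterations recorded: %d\n",
              length(object@bestPosition),
              length(object@convergenceHistory) - 1L))
})

setMethod("show", "TrialSummary", function(object) {
  cat(sprintf("TrialSummary: %s on %s, %d runs\n", object@optimizer,
              object@functionName, object@nRuns))
  cat(sprintf("  AVE = %.6g, STD = %.6g\n", object@meanBest, object@stdBest))
})

setMethod("show", "ELMModel", function(object) {
  cat(sprintf("ELMModel: %d inputs -> %d hidden (%s) -> %d outputs (linear)\n",
              ncol(object@inputWeights), nrow(object@inputWeights),
              object@activation, ncol(object@outputWeights)))
  cat("  classes:", paste(object@classLevels, collapse = ", "), "\n")
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts\n")
  cat(sprintf("  TP=%d FN=%d\n  FP=%d TN=%d\n",
              object@tp, object@fn, object@fp, object@tn))
})

setMethod("show", "ConvStack", function(object) {
  cat("ConvStack feature extractor\n")
  shp <- vapply(object@shapes, function(s) paste(s, collapse = "x"), "")
  cat("  ", paste(shp, collapse = " -> "), "\n", sep = "")
  cat(sprintf("  flattened feature length: %d\n", object@outputLength))
})
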