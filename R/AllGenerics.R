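# Generics and simple accessors.

#' @rdname DrugLibrary-class
#' @param object,x a \code{DrugLibrary}.
#' @export
setGeneric("drugIds", function(object) standardGeneric("drugIds"))

#' @rdname DrugLibrary-class
#' @export
setGeneric("fingerprints", function(object) standardGeneric("fingerprints"))

#' @rdname DrugLibrary-class
#' @export
setGeneric("mechanisms", function(object) standardGeneric("mechanisms"))

#' @rdname DrugFeatureMatrix-class
#' @param object a \code{DrugFeatureMatrix}.
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' @rdname PredictiveDistribution-class
#' @param object the object to query.
#' @export
setGeneric("predictedMean", function(object) standardGeneric("predictedMean"))

#' @rdname PredictiveDistribution-class
#' @export
setGeneric("predictedSd", function(object) standardGeneric("predictedSd"))

#' @rdname PredictiveDistribution-class
#' @export
setGeneric("candidatePairs", function(object) standardGeneric("candidatePairs"))

#' @rdname SynergyEnsemble-class
#' @param object a \code{SynergyEnsemble}.
#' @export
setGeneric("members", function(object) standardGeneric("members"))

#' @rdname SMOTrajectory-class
#' @param object a \code{SMOTrajectory}.
#' @export
setGeneric("trajectoryRounds", function(object) standardGeneric("trajectoryRounds"))

#' @rdname SMOTrajectory-class
#' @export
setGeneric("queriedPairs", function(object) standardGeneric("queriedPairs"))

#' @rdname NoiseEstimate-class
#' @param object a \code{NoiseEstimate}.
#' @export
setGeneric("noiseLevel", function(object) standardGeneric("noiseLevel"))

setMethod("drugIds", "DrugLibrary", function(object) object@ids)
setMethod("fingerprints", "DrugLibrary", function(object) object@fingerprints)
setMethod("mechanisms", "DrugLibrary", function(object) object@mechanism)
setMethod("featureMatrix", "DrugFeatureMatrix", function(object) object@features)
setMethod("predictedMean", "PredictiveDistribution", function(object) object@mu)
setMethod("predictedSd", "PredictiveDistribution", function(object) object@sigma)
setMethod("candidatePairs", "PredictiveDistribution", function(object) object@pairs)
setMethod("members", "SynergyEnsemble", function(object) object@members)
setMethod("trajectoryRounds", "SMOTrajectory", function(object) object@rounds)
setMethod("noiseLevel", "NoiseEstimate", function(object) object@etaBar)

#' @rdname SMOTrajectory-class
#' @export
setMethod("queriedPairs", "SMOTrajectory", function(object) {
  out <- lapply(object@rounds, function(r) {
    if (nrow(r$queried) == 0) return(NULL)
    cbind(round = r$round, r$queried)
  })
  do.call(rbind, out)
})

#' @rdname DrugLibrary-class
#' @export
setMethod("length", "DrugLibrary", function(x) length(x@ids))

#' @rdname SynergyEnsemble-class
#' @export
setMethod("length", "SynergyEnsemble", function(x) length(x@members))

setMethod("show", "DoseResponseBlock", function(object) {
  d <- dim(object@inhibition)
  cat("DoseResponseBlock:", object@drugA, "x", object@drugB,
      "on", object@cellLine, "\n")
  cat("  grid:", d[2], "x", d[3], "doses,", d[1], "replicate(s)\n")
})

setMethod("show", "DrugLibrary", function(object) {
  cat("DrugLibrary with", length(object@ids), "drugs,",
      ncol(object@fingerprints), "fingerprint bits\n")
})

setMethod("show", "SynergyModel", function(object) {
  cat("SynergyModel (permutation-invariant bilinear regressor)\n")
  cat("  input dim:", object@inputDim,
      "| embedding:", object@config@drugEmbeddingDim,
      "| bilinear slices:", object@config@bilinearDim, "\n")
  cat("  cell conditioning:", if (object@cellDim > 0) "FiLM" else "none",
      "| trained:", object@trained, "\n")
})

setMethod("show", "SynergyEnsemble", function(object) {
  cat("SynergyEnsemble of", length(object@members), "models\n")
})

setMethod("show", "PredictiveDistribution", function(object) {
  cat("PredictiveDistribution (", object@method, ") over ",
      nrow(object@pairs), " candidates\n", sep = "")
})

setMethod("show", "SMOTrajectory", function(object) {
  cat("SMOTrajectory:", length(object@rounds), "round(s), pool of",
      nrow(object@pool), "candidates\n")
})

setMethod("show", "NoiseEstimate", function(object) {
  cat("NoiseEstimate: eta_bar =", format(object@etaBar, digits = 4),
      "over", object@nTriplets, "replicated triplets\n")
})
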