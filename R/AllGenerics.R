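#' Accessors for ppiFusion classes
#'
#' Small accessor generics so user code never reaches into slots:
#' `nodeIds()` returns the ordered identifier vector of any node-indexed
#' object, `edges()` the canonical two-column edge matrix of a network,
#' `kernelValues()` / `scoreValues()` the underlying numeric matrix of a
#' kernel or score object, `kernelName()` a kernel's label, and
#' `trainNetwork()`, `validationEdges()`, `testEdges()` the parts of a
#' [NetworkSplit-class].
#'
#' @param x the object.
#' @return `nodeIds`: character vector; `edges`, `validationEdges`,
#'   `testEdges`: two-column character matrix; `kernelValues`,
#'   `scoreValues`: numeric matrix with identifier dimnames;
#'   `kernelName`: single string; `trainNetwork`: a
#'   [ProteinNetwork-class]; `numNodes`, `numEdges`: integer counts.
#' @name accessors
#' @aliases nodeIds edges kernelValues kernelName scoreValues trainNetwork
#'   validationEdges testEdges numNodes numEdges
#' @examples
#' net <- proteinNetwork(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' nodeIds(net)
#' numEdges(net)
NULL

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname accessors
#' @export
setGeneric("kernelValues", function(x) standardGeneric("kernelValues"))

#' @rdname accessors
#' @export
setGeneric("kernelName", function(x) standardGeneric("kernelName"))

#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname accessors
#' @export
setGeneric("trainNetwork", function(x) standardGeneric("trainNetwork"))

#' @rdname accessors
#' @export
setGeneric("validationEdges", function(x) standardGeneric("validationEdges"))

#' @rdname accessors
#' @export
setGeneric("testEdges", function(x) standardGeneric("testEdges"))

## ---- ProteinNetwork ---------------------------------------------------

#' @rdname accessors
#' @export
setMethod("nodeIds", "ProteinNetwork", function(x) x@nodeIds)

#' @rdname accessors
#' @export
setMethod("edges", "ProteinNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("numNodes", "ProteinNetwork", function(x) length(x@nodeIds))

#' @rdname accessors
#' @export
setMethod("numEdges", "ProteinNetwork", function(x) nrow(x@edges))

setMethod("show", "ProteinNetwork", function(object) {
  cat("ProteinNetwork with", length(object@nodeIds), "proteins and",
      nrow(object@edges), "interactions\n")
  if (length(object@nodeIds)) {
    cat("  nodes:", paste(head(object@nodeIds, 4L), collapse = ", "),
        if (length(object@nodeIds) > 4L) "..." else "", "\n")
  }
})

## ---- NetworkSplit -----------------------------------------------------

#' @rdname accessors
#' @export
setMethod("trainNetwork", "NetworkSplit", function(x) x@trainNetwork)

#' @rdname accessors
#' @export
setMethod("validationEdges", "NetworkSplit", function(x) x@validationEdges)

#' @rdname accessors
#' @export
setMethod("testEdges", "NetworkSplit", function(x) x@testEdges)

#' @rdname accessors
#' @export
setMethod("nodeIds", "NetworkSplit", function(x) x@trainNetwork@nodeIds)

setMethod("show", "NetworkSplit", function(object) {
  cat("NetworkSplit (seed ", object@seed, ")\n", sep = "")
  cat("  G_tn:", length(object@trainNetwork@nodeIds), "nodes,",
      nrow(object@trainNetwork@edges), "edges (spanning tree +",
      object@nExtra, "extra)\n")
  cat("  G_vn:", nrow(object@validationEdges), "validation edges\n")
  cat("  G_tt:", nrow(object@testEdges), "test edges\n")
})

## ---- KernelMatrix -----------------------------------------------------

#' @rdname accessors
#' @export
setMethod("nodeIds", "KernelMatrix", function(x) x@nodeIds)

#' @rdname accessors
#' @export
setMethod("kernelValues", "KernelMatrix", function(x) {
  v <- x@values
  dimnames(v) <- list(x@nodeIds, x@nodeIds)
  v
})

#' @rdname accessors
#' @export
setMethod("kernelName", "KernelMatrix", function(x) x@name)

setMethod("show", "KernelMatrix", function(object) {
  v <- object@values
  cat("KernelMatrix \"", object@name, "\": ", length(object@nodeIds), " x ",
      length(object@nodeIds), sep = "")
  if (length(v)) {
    cat(", range [", format(min(v), digits = 4), ", ",
        format(max(v), digits = 4), "]", sep = "")
  }
  cat("\n")
})

## ---- KernelSet --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("nodeIds", "KernelSet", function(x) x@kernels[[1L]]@nodeIds)

#' Number of kernels and member access for a KernelSet
#'
#' @param x a [KernelSet-class].
#' @param i kernel position (or name) to extract.
#' @return `length()`: the number of member kernels; `[[`: the
#'   [KernelMatrix-class] at position `i`; `kernelNames()`: the member
#'   labels in list order.
#' @aliases [[,KernelSet-method length,KernelSet-method
#' @name KernelSet-utils
#' @export
setMethod("length", "KernelSet", function(x) length(x@kernels))

#' @rdname KernelSet-utils
#' @export
setMethod("[[", "KernelSet", function(x, i) {
  if (is.character(i)) i <- match(i, kernelNames(x))
  x@kernels[[i]]
})

#' @rdname KernelSet-utils
#' @export
kernelNames <- function(x) {
  stopifnot(is(x, "KernelSet"))
  vapply(x@kernels, function(k) k@name, character(1))
}

setMethod("show", "KernelSet", function(object) {
  cat("KernelSet of", length(object@kernels), "kernels on",
      length(nodeIds(object)), "proteins\n")
  cat("  order:", paste(kernelNames(object), collapse = ", "), "\n")
})

## ---- InferenceScores --------------------------------------------------

#' @rdname accessors
#' @export
setMethod("nodeIds", "InferenceScores", function(x) x@nodeIds)

#' @rdname accessors
#' @export
setMethod("scoreValues", "InferenceScores", function(x) {
  v <- x@values
  dimnames(v) <- list(x@nodeIds, x@nodeIds)
  v
})

setMethod("show", "InferenceScores", function(object) {
  cat("InferenceScores over", length(object@nodeIds),
      "proteins (alpha =", format(object@alpha, digits = 4), ")\n")
})

## ---- Particle ---------------------------------------------------------

#' @rdname accessors
#' @export
setGeneric("particleWeights", function(x) standardGeneric("particleWeights"))

#' @rdname accessors
#' @export
setMethod("particleWeights", "Particle", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("particleFitnessValue",
           function(x) standardGeneric("particleFitnessValue"))

#' @rdname accessors
#' @export
setMethod("particleFitnessValue", "Particle", function(x) x@fitness)

setMethod("show", "Particle", function(object) {
  cat("Particle: weights (", paste(format(object@weights, digits = 3),
      collapse = ", "), "), fitness ",
      if (is.na(object@fitness)) "unevaluated" else
        format(object@fitness, digits = 4), "\n", sep = "")
})

setMethod("show", "SamplerConfig", function(object) {
  cat("SamplerConfig: ", object@populationSize, " particles, <= ",
      object@maxGenerations, " generations, F = ", object@deScaleFactor,
      ", CR = ", object@crossoverRate, ", T0 = ",
      object@initialTemperature, ", cooling = ", object@coolingRate,
      ", lambda = ", object@fitnessBlend, ", seed = ", object@seed,
      "\n", sep = "")
})

setMethod("show", "BenchmarkScenario", function(object) {
  cat("BenchmarkScenario (seed ", object@seed, ")\n", sep = "")
  cat("  gold:", length(object@gold@nodeIds), "nodes,",
      nrow(object@gold@edges), "edges\n")
  cat("  kernels:", paste(sprintf("%s[%s]", names(object@truth),
      substr(object@truth, 1L, 1L)), collapse = ", "), "\n")
})

setMethod("show", "ROCResult", function(object) {
  cat("ROCResult: AUC ", format(object@auc, digits = 4), " (",
      object@nPos, " positives vs ", object@nNeg, " negatives)\n", sep = "")
})
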