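#' ProteinNetwork: an undirected protein-protein interaction graph
#'
#' Holds an undirected, unweighted interaction graph \eqn{G = (V, E)} over a
#' fixed, lexicographically ordered set of protein identifiers. Edges are
#' stored canonically (smaller identifier first, rows deduplicated and
#' sorted) so that the adjacency matrix and every kernel aligned to the
#' network share one unambiguous node order.
#'
#' @slot nodeIds character vector of unique protein identifiers, sorted in
#'   C collation; this order is shared by all matrices derived from the
#'   network.
#' @slot edges two-column character matrix of unordered interaction pairs
#'   in canonical form; no self-pairs, no duplicates.
#'
#' @seealso [proteinNetwork()], [readEdgeList()], [adjacencyMatrix()]
#' @export
setClass("ProteinNetwork",
  representation(nodeIds = "character", edges = "matrix"))

setValidity("ProteinNetwork", function(object) {
  ids <- object@nodeIds
  e <- object@edges
  if (anyDuplicated(ids)) return("duplicate node identifiers")
  if (!identical(ids, .csort(ids))) return("nodeIds must be sorted (C collation)")
  if (ncol(e) != 2L) return("edges must have two columns")
  if (nrow(e) > 0L) {
    if (!is.character(e)) return("edges must be a character matrix")
    if (!all(e %in% ids)) return("edge endpoint not in nodeIds")
    if (any(e[, 1L] == e[, 2L])) return("self-pair present")
    if (!identical(unname(e), .canonical_edges(e))) {
      return("edges not in canonical form")
    }
  }
  TRUE
})

#' NetworkSplit: training network plus held-out validation and test edges
#'
#' The supervised split of a gold-standard network: a connected training
#' network \eqn{G_{tn}} spanning every node (a random spanning tree
#' augmented with a few extra edges), and two disjoint held-out edge sets,
#' the validation set \eqn{G_{vn}} (overfitting guard during weight
#' optimisation) and the test set \eqn{G_{tt}} (final evaluation).
#'
#' @slot trainNetwork [ProteinNetwork-class] \eqn{G_{tn}}, connected and
#'   spanning all nodes of the source network.
#' @slot validationEdges canonical edge matrix \eqn{E_{vn}}.
#' @slot testEdges canonical edge matrix \eqn{E_{tt}}.
#' @slot nExtra integer, number of non-tree edges added to the spanning tree.
#' @slot seed integer seed that produced the split.
#'
#' @seealso [splitNetwork()]
#' @export
setClass("NetworkSplit",
  representation(trainNetwork = "ProteinNetwork",
                 validationEdges = "matrix",
                 testEdges = "matrix",
                 nExtra = "integer",
                 seed = "integer"))

setValidity("NetworkSplit", function(object) {
  ids <- object@trainNetwork@nodeIds
  n <- length(ids)
  ktn <- .edge_keys(object@trainNetwork@edges, ids)
  kvn <- tryCatch(.edge_keys(object@validationEdges, ids),
                  error = function(e) return(NULL))
  ktt <- tryCatch(.edge_keys(object@testEdges, ids),
                  error = function(e) return(NULL))
  if (is.null(kvn) || is.null(ktt)) return("held-out edge endpoint not in node set")
  if (length(intersect(ktn, kvn)) || length(intersect(ktn, ktt)) ||
      length(intersect(kvn, ktt))) {
    return("train, validation and test edge sets must be pairwise disjoint")
  }
  if (nrow(object@trainNetwork@edges) != n - 1L + object@nExtra) {
    return("train edge count must equal |V| - 1 + nExtra")
  }
  if (!igraph::is_connected(.as_igraph(object@trainNetwork))) {
    return("training network must be connected")
  }
  TRUE
})

#' KernelMatrix: a symmetric nonnegative similarity matrix over proteins
#'
#' A kernel in the loose, practical sense used throughout the package: a
#' symmetric matrix of pairwise similarities over an ordered protein set,
#' with finite nonnegative entries (normalised into \[0, 1\] by the
#' constructors) and zero diagonal. Positive semi-definiteness is
#' monitored (see [minEigenvalue()]) but not enforced: min-max scaling and
#' diagonal zeroing can break exact PSD, and the regularized Laplacian
#' \eqn{(I + \alpha L)^{-1}} stays well-defined for any nonnegative matrix.
#'
#' @slot nodeIds ordered protein identifiers (row/column order).
#' @slot values symmetric numeric matrix, finite, nonnegative.
#' @slot name short label, e.g. `"G_tn"`, `"jaccard"`, `"pfam"`.
#'
#' @seealso [jaccardKernel()], [sharedNeighborKernel()],
#'   [loadKernelMatrix()], [normalizeKernel()]
#' @export
setClass("KernelMatrix",
  representation(nodeIds = "character", values = "matrix", name = "character"))

setValidity("KernelMatrix", function(object) {
  v <- object@values
  n <- length(object@nodeIds)
  if (nrow(v) != n || ncol(v) != n) return("matrix dimension != |nodeIds|")
  if (n > 0L) {
    if (!is.numeric(v)) return("values must be numeric")
    if (any(!is.finite(v))) return("non-finite kernel entry")
    if (any(v < 0)) return("negative kernel entry")
    if (max(abs(v - t(v))) > 0) return("kernel not exactly symmetric")
  }
  if (length(object@name) != 1L) return("name must be a single string")
  TRUE
})

#' KernelSet: an ordered collection of kernels on one node order
#'
#' The operand list of the kernel fusion \eqn{K_{fusion} = W_0 G_{tn} +
#' \sum_i W_i K_i}: by convention the first member is the training-network
#' adjacency and weight \eqn{W_i} refers to position \eqn{i} (0-based in
#' the formula, 1-based in R). All members share one node order.
#'
#' @slot kernels list of [KernelMatrix-class] objects with identical
#'   `nodeIds`; the list order is fixed and meaningful.
#'
#' @seealso [kernelSet()], [fuseKernels()]
#' @export
setClass("KernelSet", representation(kernels = "list"))

setValidity("KernelSet", function(object) {
  ks <- object@kernels
  if (length(ks) < 1L) return("a KernelSet needs at least one kernel")
  if (!all(vapply(ks, is, logical(1), class2 = "KernelMatrix"))) {
    return("all members must be KernelMatrix objects")
  }
  ids <- ks[[1L]]@nodeIds
  same <- vapply(ks, function(k) identical(k@nodeIds, ids), logical(1))
  if (!all(same)) return("all kernels must share one node order")
  TRUE
})

#' InferenceScores: regularized-Laplacian pair scores
#'
#' The output of the regularized Laplacian kernel \eqn{RL = (I + \alpha
#' L)^{-1}} applied to a (fused) kernel matrix. Entry \eqn{(i, j)} is read
#' as the propensity of an interaction between proteins \eqn{i} and
#' \eqn{j}; the diagonal is ignored by all consumers.
#'
#' @slot nodeIds ordered protein identifiers.
#' @slot values symmetric numeric score matrix.
#' @slot alpha the diffusion parameter actually used.
#'
#' @seealso [regularizedLaplacian()], [inferScores()]
#' @export
setClass("InferenceScores",
  representation(nodeIds = "character", values = "matrix", alpha = "numeric"))

setValidity("InferenceScores", function(object) {
  v <- object@values
  n <- length(object@nodeIds)
  if (nrow(v) != n || ncol(v) != n) return("matrix dimension != |nodeIds|")
  if (any(!is.finite(v))) return("non-finite score")
  if (n > 0L && max(abs(v - t(v))) > 0) return("scores not symmetric")
  if (length(object@alpha) != 1L ||
      (!is.na(object@alpha) && object@alpha < 0)) {
    return("alpha must be a single nonnegative number (NA if unknown)")
  }
  TRUE
})

#' Particle: one candidate weight vector in the sampler population
#'
#' @slot weights numeric vector, one weight per kernel in the
#'   [KernelSet-class] (\eqn{W_0} for \eqn{G_{tn}} first); each inside the
#'   box \[0, 1\].
#' @slot fitness blended AUC fitness in \[0, 1\], or `NA_real_` while
#'   unevaluated.
#'
#' @seealso [initializePopulation()], [particleFitness()]
#' @export
setClass("Particle",
  representation(weights = "numeric", fitness = "numeric"))

setValidity("Particle", function(object) {
  if (any(object@weights < 0) || any(object@weights > 1)) {
    return("weights must lie in [0, 1]")
  }
  if (length(object@fitness) != 1L) return("fitness must be length 1")
  if (!is.na(object@fitness) &&
      (object@fitness < 0 || object@fitness > 1)) {
    return("fitness must be in [0, 1] or NA")
  }
  TRUE
})

#' SamplerConfig: tuning parameters of the weight sampler
#'
#' Configuration of the population sampler that learns kernel weights:
#' differential-evolution proposals (DE/rand/1/bin) accepted under a
#' Boltzmann rule with a geometric annealing schedule
#' \eqn{T_k = T_0 \cdot cooling^k}.
#'
#' @slot populationSize particles per generation (default 150).
#' @slot maxGenerations hard cap on generations (default 50).
#' @slot deScaleFactor DE differential weight F (default 0.8).
#' @slot crossoverRate DE binomial crossover rate CR in \[0, 1\]
#'   (default 0.9).
#' @slot initialTemperature T0 of the annealing schedule (default 0.1).
#' @slot coolingRate geometric cooling factor in (0, 1) (default 0.9).
#' @slot convergenceWindow generations of sub-tolerance improvement that
#'   trigger early stopping (default 3).
#' @slot convergenceTol minimum best-fitness improvement counted as
#'   progress (default 1e-4).
#' @slot fitnessBlend lambda in \[0, 1\]: weight of the validation AUC in
#'   the fitness `lambda * AUC_vn + (1 - lambda) * AUC_tn` (default 0.5).
#' @slot negativeSampleRatio negatives drawn per positive for the fitness
#'   context (default 10).
#' @slot seed master seed; fans out to initialization, proposals,
#'   acceptance draws and negative sampling.
#'
#' @seealso [samplerConfig()], [optimizeWeights()]
#' @export
setClass("SamplerConfig",
  representation(populationSize = "integer", maxGenerations = "integer",
                 deScaleFactor = "numeric", crossoverRate = "numeric",
                 initialTemperature = "numeric", coolingRate = "numeric",
                 convergenceWindow = "integer", convergenceTol = "numeric",
                 fitnessBlend = "numeric", negativeSampleRatio = "integer",
                 seed = "integer"))

setValidity("SamplerConfig", function(object) {
  if (object@populationSize < 4L) return("populationSize must be >= 4")
  if (object@maxGenerations < 1L) return("maxGenerations must be >= 1")
  if (object@deScaleFactor < 0) return("deScaleFactor must be >= 0")
  if (object@crossoverRate < 0 || object@crossoverRate > 1) {
    return("crossoverRate must be in [0, 1]")
  }
  if (object@initialTemperature <= 0) return("initialTemperature must be > 0")
  if (object@coolingRate <= 0 || object@coolingRate >= 1) {
    return("coolingRate must be in (0, 1)")
  }
  if (object@convergenceWindow < 1L) return("convergenceWindow must be >= 1")
  if (object@convergenceTol < 0) return("convergenceTol must be >= 0")
  if (object@fitnessBlend < 0 || object@fitnessBlend > 1) {
    return("fitnessBlend must be in [0, 1]")
  }
  if (object@negativeSampleRatio < 1L) return("negativeSampleRatio must be >= 1")
  TRUE
})

#' BenchmarkScenario: a seeded synthetic gold standard with planted kernels
#'
#' Bundles everything an end-to-end run needs: a synthetic gold-standard
#' network, its train/validation/test split, a [KernelSet-class] whose
#' first member is the training adjacency followed by planted informative
#' kernels (correlated with the full network, held-out edges included) and
#' pure-noise kernels, plus the truth labels saying which is which.
#'
#' @slot gold [ProteinNetwork-class] gold-standard network.
#' @slot split [NetworkSplit-class] derived from `gold`.
#' @slot kernels [KernelSet-class] aligned to the gold node order.
#' @slot truth named character vector mapping kernel names to one of
#'   `"train"`, `"informative"`, `"noise"`.
#' @slot seed master seed of the scenario.
#'
#' @seealso [generateBenchmark()]
#' @export
setClass("BenchmarkScenario",
  representation(gold = "ProteinNetwork", split = "NetworkSplit",
                 kernels = "KernelSet", truth = "character",
                 seed = "integer"))

setValidity("BenchmarkScenario", function(object) {
  ids <- object@gold@nodeIds
  if (!identical(object@kernels@kernels[[1L]]@nodeIds, ids)) {
    return("kernels must share the gold node order")
  }
  kn <- vapply(object@kernels@kernels, function(k) k@name, character(1))
  if (!identical(.csort(names(object@truth)), .csort(kn))) {
    return("truth labels must name every kernel")
  }
  if (!all(object@truth %in% c("train", "informative", "noise"))) {
    return("truth labels must be train/informative/noise")
  }
  TRUE
})

#' ROCResult: a ROC curve with its AUC
#'
#' @slot points two-column numeric matrix of (false positive rate, true
#'   positive rate) pairs, tie-grouped, from (0, 0) to (1, 1).
#' @slot auc area under the curve (Mann-Whitney statistic, midrank ties).
#' @slot nPos,nNeg class sizes behind the curve.
#'
#' @seealso [rocAuc()]
#' @export
setClass("ROCResult",
  representation(points = "matrix", auc = "numeric",
                 nPos = "integer", nNeg = "integer"))

setValidity("ROCResult", function(object) {
  p <- object@points
  if (ncol(p) != 2L) return("points must have two columns (fpr, tpr)")
  if (any(diff(p[, 1L]) < 0) || any(diff(p[, 2L]) < 0)) {
    return("ROC points must be monotone non-decreasing")
  }
  if (object@auc < 0 || object@auc > 1) return("auc must be in [0, 1]")
  TRUE
})
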