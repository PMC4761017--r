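#' Generate a connected preferential-attachment network
#'
#' A scale-free-ish interaction network mimicking PPI degree
#' heterogeneity: start from a clique on the first `attachment` nodes,
#' then attach each new node to `attachment` distinct existing nodes
#' chosen with probability proportional to current degree. The
#' construction is connected by design and its edge count is exactly
#' \eqn{\binom{m}{2} + (n - m) m} for `attachment` \eqn{m}.
#'
#' @param nNodes number of proteins; must satisfy
#'   `nNodes >= attachment + 1 >= 2`.
#' @param attachment edges added per new node.
#' @param seed integer RNG seed.
#' @return a [ProteinNetwork-class] with zero-padded identifiers
#'   (`"P0001"`, ...) whose lexicographic order matches creation order.
#' @export
generateNetwork <- function(nNodes, attachment, seed) {
  if (attachment + 1L > nNodes || attachment < 1L) {
    stop("need nNodes >= attachment + 1 >= 2")
  }
  width <- nchar(as.character(nNodes))
  ids <- sprintf(paste0("P%0", width, "d"), seq_len(nNodes))
  m <- as.integer(attachment)
  .with_seed(seed, {
    deg <- integer(nNodes)
    eFrom <- integer(0)
    eTo <- integer(0)
    if (m >= 2L) {
      cl <- .all_pairs(m)
      eFrom <- cl[, 1L]
      eTo <- cl[, 2L]
      deg[seq_len(m)] <- m - 1L
    }
    for (t in seq.int(m + 1L, nNodes)) {
      existing <- seq_len(t - 1L)
      prob <- deg[existing]
      targets <- if (all(prob == 0)) {
        .sample_from(existing, m)
      } else if (length(existing) == m) {
        existing
      } else {
        .sample_from(existing, m, prob = prob)
      }
      eFrom <- c(eFrom, targets)
      eTo <- c(eTo, rep.int(t, m))
      deg[targets] <- deg[targets] + 1L
      deg[t] <- m
    }
    proteinNetwork(ids, cbind(ids[eFrom], ids[eTo]))
  })
}

#' Generate a planted informative kernel
#'
#' A feature kernel correlated with the structure of the *full* gold
#' network — including its held-out edges — which is what makes real
#' genomic kernels (domain profiles, co-expression) worth weighting up.
#' The base signal is the common-neighbour count \eqn{c_{ij}} on the gold
#' network, passed through the saturating similarity \eqn{c / (c + 1)}
#' (bounded in \[0, 1\), robust to the heavy-tailed counts around hubs);
#' it is then mixed elementwise with symmetric uniform noise at
#' `noiseLevel` and rescaled by the maximum, diagonal zeroed.
#'
#' @param gold the gold-standard [ProteinNetwork-class].
#' @param noiseLevel mixing fraction in \[0, 1\]: 0 = pure signal, 1 =
#'   pure noise.
#' @param seed integer RNG seed.
#' @param name kernel label (default `"informative"`).
#' @return a [KernelMatrix-class] with entries in \[0, 1\].
#' @export
generateInformativeKernel <- function(gold, noiseLevel, seed,
                                      name = "informative") {
  stopifnot(is(gold, "ProteinNetwork"),
            noiseLevel >= 0, noiseLevel <= 1)
  a <- adjacencyMatrix(gold)@values
  cn <- a %*% a
  diag(cn) <- 0
  cn <- cn / (cn + 1)
  .with_seed(seed, {
    n <- nrow(cn)
    u <- matrix(0, n, n)
    up <- upper.tri(u)
    u[up] <- runif(sum(up))
    u <- u + t(u)
    v <- (1 - noiseLevel) * cn + noiseLevel * u
    diag(v) <- 0
    if (max(v) > 0) v <- v / max(v)
    new("KernelMatrix", nodeIds = gold@nodeIds, values = v, name = name)
  })
}

#' Generate a pure-noise kernel
#'
#' A symmetric uniform-noise matrix, min-max normalised with zero
#' diagonal, independent of any network — the planted "irrelevant data
#' source" whose learned weight should end up near zero.
#'
#' @param nodeIdsVec ordered protein identifiers.
#' @param seed integer RNG seed.
#' @param name kernel label (default `"noise"`).
#' @return a [KernelMatrix-class].
#' @export
generateNoiseKernel <- function(nodeIdsVec, seed, name = "noise") {
  n <- length(nodeIdsVec)
  .with_seed(seed, {
    u <- matrix(0, n, n)
    up <- upper.tri(u)
    u[up] <- runif(sum(up))
    u <- u + t(u)
    k <- new("KernelMatrix", nodeIds = as.character(nodeIdsVec),
             values = u, name = name)
    normalizeKernel(k)
  })
}

#' Generate a complete seeded benchmark scenario
#'
#' Composes a gold-standard preferential-attachment network, its
#' train/validation/test split, and a [KernelSet-class] holding the
#' training adjacency first, then `nInformative` planted informative
#' kernels and `nNoise` pure-noise kernels, with truth labels recording
#' which is which. All sub-seeds are derived from `seed`, so the whole
#' scenario is reproducible from one integer.
#'
#' The defaults define the package's standard benchmark conditions: 200
#' proteins, attachment 5 (mean degree near the ~9 of the yeast
#' interactome), one informative kernel at noise level 0.3, two noise
#' kernels, and a split of spanning tree + 20 extra training edges, 30
#' validation edges, 150 test edges.
#'
#' @param nNodes,attachment gold network shape.
#' @param nInformative,nNoise,noiseLevel planted kernel layout.
#' @param nExtra,nValidation,nTest split sizes.
#' @param seed master seed.
#' @return a [BenchmarkScenario-class].
#' @export
generateBenchmark <- function(nNodes = 200L, attachment = 5L,
                              nInformative = 1L, nNoise = 2L,
                              noiseLevel = 0.3,
                              nExtra = 20L, nValidation = 30L,
                              nTest = 150L, seed = 1L) {
  gold <- generateNetwork(nNodes, attachment, seed = .child_seed(seed, 1L))
  split <- splitNetwork(gold, nExtra, nValidation, nTest,
                        seed = .child_seed(seed, 2L))
  kernels <- list(adjacencyMatrix(split@trainNetwork, name = "G_tn"))
  truth <- c(G_tn = "train")
  for (i in seq_len(nInformative)) {
    nm <- if (nInformative == 1L) "informative" else paste0("informative_", i)
    kernels <- c(kernels, generateInformativeKernel(
      gold, noiseLevel, seed = .child_seed(seed, 10L + i), name = nm))
    truth[nm] <- "informative"
  }
  for (i in seq_len(nNoise)) {
    nm <- if (nNoise == 1L) "noise" else paste0("noise_", i)
    kernels <- c(kernels, generateNoiseKernel(
      gold@nodeIds, seed = .child_seed(seed, 100L + i), name = nm))
    truth[nm] <- "noise"
  }
  scen <- new("BenchmarkScenario", gold = gold, split = split,
              kernels = kernelSet(kernels), truth = truth,
              seed = as.integer(seed))
  validObject(scen)
  scen
}

#' Serialise / load a benchmark scenario as plain-text files
#'
#' Writes `edges.tsv` (gold edge list), `split.json`, one labelled dense
#' matrix file per kernel (`kernel_<name>.tsv`), and `truth.json` into a
#' directory; `readScenario()` reconstructs the scenario from them.
#'
#' @param scenario a [BenchmarkScenario-class].
#' @param dir output directory (created if needed).
#' @return `writeScenario`: `dir` invisibly; `readScenario`: a
#'   [BenchmarkScenario-class].
#' @export
writeScenario <- function(scenario, dir) {
  stopifnot(is(scenario, "BenchmarkScenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeEdgeList(scenario@gold, file.path(dir, "edges.tsv"))
  writeSplit(scenario@split, file.path(dir, "split.json"))
  for (k in scenario@kernels@kernels) {
    writeKernelMatrix(k, file.path(dir, paste0("kernel_", k@name, ".tsv")))
  }
  jsonlite::write_json(list(truth = as.list(scenario@truth),
                            order = kernelNames(scenario@kernels),
                            seed = scenario@seed),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeScenario
#' @export
readScenario <- function(dir) {
  gold <- readEdgeList(file.path(dir, "edges.tsv"))
  split <- readSplit(file.path(dir, "split.json"))
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  kernels <- lapply(meta$order, function(nm) {
    loadKernelMatrix(file.path(dir, paste0("kernel_", nm, ".tsv")),
                     gold@nodeIds, name = nm)
  })
  scen <- new("BenchmarkScenario", gold = gold, split = split,
              kernels = kernelSet(kernels),
              truth = unlist(meta$truth), seed = as.integer(meta$seed))
  validObject(scen)
  scen
}
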