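#' Build a sampler configuration
#'
#' Constructor for [SamplerConfig-class] with the package defaults: 150
#' particles, DE/rand/1/bin proposals with F = 0.8 and CR = 0.9, Boltzmann
#' acceptance annealed as \eqn{T_k = 0.1 \cdot 0.9^k}, fitness
#' \eqn{\lambda \cdot AUC_{vn} + (1 - \lambda) \cdot AUC_{tn}} with
#' \eqn{\lambda = 0.5}, and early stopping once the best fitness improves
#' by less than `convergenceTol` over `convergenceWindow` consecutive
#' generations.
#'
#' @param populationSize,maxGenerations,deScaleFactor,crossoverRate
#'   sampler knobs; see [SamplerConfig-class].
#' @param initialTemperature,coolingRate annealing schedule.
#' @param convergenceWindow,convergenceTol plateau detector.
#' @param fitnessBlend lambda of the blended AUC objective.
#' @param negativeSampleRatio negatives per positive in the fitness
#'   context.
#' @param seed master seed; every random draw of a run fans out from it.
#' @return a validated [SamplerConfig-class].
#' @export
samplerConfig <- function(populationSize = 150L, maxGenerations = 50L,
                          deScaleFactor = 0.8, crossoverRate = 0.9,
                          initialTemperature = 0.1, coolingRate = 0.9,
                          convergenceWindow = 3L, convergenceTol = 1e-4,
                          fitnessBlend = 0.5, negativeSampleRatio = 10L,
                          seed = 1L) {
  cfg <- new("SamplerConfig",
    populationSize = as.integer(populationSize),
    maxGenerations = as.integer(maxGenerations),
    deScaleFactor = as.numeric(deScaleFactor),
    crossoverRate = as.numeric(crossoverRate),
    initialTemperature = as.numeric(initialTemperature),
    coolingRate = as.numeric(coolingRate),
    convergenceWindow = as.integer(convergenceWindow),
    convergenceTol = as.numeric(convergenceTol),
    fitnessBlend = as.numeric(fitnessBlend),
    negativeSampleRatio = as.integer(negativeSampleRatio),
    seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Initialise the particle population
#'
#' Draws `populationSize` particles whose `nKernels + 1` weights (one for
#' \eqn{G_{tn}}, one per feature kernel) are i.i.d. uniform on \[0, 1\];
#' fitness starts unevaluated. Deterministic given the configuration
#' seed. The RNG draws happen on the current stream, so
#' [optimizeWeights()] can fan one master seed across all of its
#' randomness; call it directly for a standalone, seeded population.
#'
#' @param cfg a [SamplerConfig-class].
#' @param nKernels number of feature kernels (particle length is
#'   `nKernels + 1`; 0 is allowed for a training-network-only set).
#' @param seeded if `TRUE` (default), seed the RNG from `cfg` first.
#' @return list of [Particle-class] objects.
#' @export
initializePopulation <- function(cfg, nKernels, seeded = TRUE) {
  stopifnot(is(cfg, "SamplerConfig"), nKernels >= 0L)
  draw <- function() {
    lapply(seq_len(cfg@populationSize), function(i) {
      new("Particle", weights = runif(nKernels + 1L), fitness = NA_real_)
    })
  }
  if (seeded) .with_seed(cfg@seed, draw()) else draw()
}

#' Build the fixed evaluation context for particle fitness
#'
#' Everything a fitness evaluation needs, constructed once per run so
#' every particle is judged against the same data: the kernel matrices,
#' the positive pair indices of \eqn{G_{tn}} and \eqn{G_{vn}}, and one
#' shared negative sample of size `negativeSampleRatio * (|E_tn| +
#' |E_vn|)` drawn without replacement from the non-edges of the full gold
#' network (all pairs outside the gold edge set). The final evaluation
#' ([candidateUniverse()]) uses the complete negative universe instead;
#' the subsample only keeps the optimisation loop affordable.
#'
#' Draws from the current RNG stream (seed it, or let [optimizeWeights()]
#' do so).
#'
#' @param ks a [KernelSet-class] (first member: training adjacency).
#' @param split a [NetworkSplit-class] on the same node order.
#' @param gold the full gold-standard [ProteinNetwork-class]; its edges
#'   are excluded from the negative sample.
#' @param cfg a [SamplerConfig-class].
#' @param alphaFraction diffusion fraction passed through to the scorer.
#' @return an opaque list consumed by [particleFitness()].
#' @export
fitnessContext <- function(ks, split, gold, cfg, alphaFraction = 0.5) {
  stopifnot(is(ks, "KernelSet"), is(split, "NetworkSplit"),
            is(gold, "ProteinNetwork"), is(cfg, "SamplerConfig"))
  ids <- nodeIds(ks)
  if (!identical(ids, nodeIds(split))) {
    stop("kernel set and split disagree on node order")
  }
  n <- length(ids)
  posTn <- .edge_index(split@trainNetwork@edges, ids)
  if (nrow(split@validationEdges) == 0L) {
    stop("empty validation set: the overfitting guard needs G_vn edges")
  }
  posVn <- .edge_index(split@validationEdges, ids)
  goldKeys <- .edge_keys(gold@edges, ids)
  allPairs <- .all_pairs(n)
  allKeys <- .pair_key(allPairs[, 1L], allPairs[, 2L], n)
  nonEdges <- allPairs[!(allKeys %in% goldKeys), , drop = FALSE]
  nNeg <- min(nrow(nonEdges),
              cfg@negativeSampleRatio * (nrow(posTn) + nrow(posVn)))
  if (nNeg < 1L) stop("no negative pairs available")
  negIdx <- nonEdges[sample(nrow(nonEdges), nNeg), , drop = FALSE]
  list(mats = lapply(ks@kernels, function(k) k@values),
       n = n, posTn = posTn, posVn = posVn, neg = negIdx,
       alphaFraction = alphaFraction, lambda = cfg@fitnessBlend)
}

## fitness + its two AUC components; the sampler's hot path
.eval_particle <- function(w, ctx) {
  v <- .fuse_values(ctx$mats, w)
  if (max(v) == 0) {
    ## zero fusion: identity RL, every pair tied => both AUCs are 1/2
    return(c(fitness = 0.5, aucTn = 0.5, aucVn = 0.5))
  }
  L <- .laplacian(v)
  rho <- max(abs(eigen(L, symmetric = TRUE, only.values = TRUE)$values))
  A <- (ctx$alphaFraction / rho) * L
  diag(A) <- diag(A) + 1
  rl <- chol2inv(chol(A))
  negS <- rl[ctx$neg]
  aucTn <- .fast_auc(rl[ctx$posTn], negS)
  aucVn <- .fast_auc(rl[ctx$posVn], negS)
  c(fitness = ctx$lambda * aucVn + (1 - ctx$lambda) * aucTn,
    aucTn = aucTn, aucVn = aucVn)
}

#' Fitness of a weight vector
#'
#' The blended ranking quality \eqn{\lambda \cdot AUC_{vn} + (1 -
#' \lambda) \cdot AUC_{tn}}, where both AUCs score the regularized
#' Laplacian of the fusion under `w` against the context's shared
#' negative sample — \eqn{G_{tn}} edges as positives for the first,
#' \eqn{G_{vn}} edges for the second.
#'
#' @param w numeric weight vector (length = number of kernels).
#' @param ctx a context from [fitnessContext()].
#' @return fitness in \[0, 1\], with attributes `aucTn` and `aucVn`.
#' @export
particleFitness <- function(w, ctx) {
  if (length(w) != length(ctx$mats)) {
    stop("weight vector length ", length(w), " != number of kernels ",
         length(ctx$mats))
  }
  r <- .eval_particle(as.numeric(w), ctx)
  structure(unname(r["fitness"]), aucTn = unname(r["aucTn"]),
            aucVn = unname(r["aucVn"]))
}

#' Differential-evolution proposal (DE/rand/1/bin)
#'
#' Picks three distinct population members \eqn{r_1, r_2, r_3} different
#' from the base particle, forms the donor \eqn{w_{r_1} + F (w_{r_2} -
#' w_{r_3})}, applies binomial crossover against the base at rate CR with
#' one coordinate always taken from the donor, and clips the result to
#' the \[0, 1\] weight box. Consumes the current RNG stream.
#'
#' @param baseIndex index of the base particle in `popWeights`.
#' @param popWeights numeric matrix, one row per particle.
#' @param cfg a [SamplerConfig-class] (F and CR are used).
#' @return proposed weight vector.
#' @export
proposeCandidate <- function(baseIndex, popWeights, cfg) {
  np <- nrow(popWeights)
  if (np < 4L) stop("DE proposal needs a population of at least 4")
  d <- ncol(popWeights)
  r <- .sample_from(setdiff(seq_len(np), baseIndex), 3L)
  donor <- popWeights[r[1L], ] +
    cfg@deScaleFactor * (popWeights[r[2L], ] - popWeights[r[3L], ])
  cand <- popWeights[baseIndex, ]
  jrand <- sample.int(d, 1L)
  cross <- runif(d) < cfg@crossoverRate
  cross[jrand] <- TRUE
  cand[cross] <- donor[cross]
  pmin(pmax(cand, 0), 1)
}

#' Boltzmann acceptance under simulated annealing
#'
#' Accepts a candidate with probability \eqn{\min(1, \exp((f_{new} -
#' f_{old}) / T))}: improvements always pass, deteriorations pass with a
#' temperature-controlled probability that vanishes as the schedule
#' cools. Consumes one uniform draw from the current RNG stream.
#'
#' @param fitnessNew,fitnessOld candidate and incumbent fitness.
#' @param temperature current temperature, must be positive.
#' @return logical: accept the candidate?
#' @export
boltzmannAccept <- function(fitnessNew, fitnessOld, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  p <- min(1, exp((fitnessNew - fitnessOld) / temperature))
  runif(1L) < p
}

#' Advance the population by one generation
#'
#' For every particle except the current best (elitism: the best particle
#' survives each generation unchanged), a DE candidate is proposed,
#' evaluated, and swapped in iff it passes [boltzmannAccept()] at
#' temperature \eqn{T = T_0 \cdot cooling^{generation}}. Consumes the
#' current RNG stream.
#'
#' @param population list of evaluated [Particle-class] objects.
#' @param ctx fitness context from [fitnessContext()].
#' @param cfg a [SamplerConfig-class].
#' @param generationIndex 0-based generation number (sets the
#'   temperature).
#' @return the next population, all fitnesses set.
#' @export
evolveGeneration <- function(population, ctx, cfg, generationIndex) {
  fit <- vapply(population, function(p) p@fitness, numeric(1))
  if (anyNA(fit)) stop("all particles must be evaluated before evolving")
  temp <- cfg@initialTemperature * cfg@coolingRate^generationIndex
  popW <- do.call(rbind, lapply(population, function(p) p@weights))
  elite <- which.max(fit)  # ties: first encountered, for determinism
  for (i in seq_along(population)) {
    if (i == elite) next
    cand <- proposeCandidate(i, popW, cfg)
    r <- .eval_particle(cand, ctx)
    if (boltzmannAccept(r[["fitness"]], fit[i], temp)) {
      population[[i]] <- new("Particle", weights = cand,
                             fitness = r[["fitness"]])
      fit[i] <- r[["fitness"]]
      ## note: popW deliberately keeps the generation-start weights, so
      ## proposals within one generation draw from a fixed pool
    }
  }
  population
}

#' Learn kernel weights by annealed differential-evolution sampling
#'
#' The full optimisation loop: seed the RNG from the configuration, draw
#' the shared negative sample, initialise a uniform population, evaluate
#' it, and run [evolveGeneration()] until `maxGenerations` or until the
#' best fitness has improved by less than `convergenceTol` for
#' `convergenceWindow` consecutive generations. Elitism makes the
#' best-ever fitness non-decreasing; the best-ever particle is returned
#' together with the per-generation history used for convergence plots.
#'
#' @param ks a [KernelSet-class], training adjacency first.
#' @param split a [NetworkSplit-class]; its validation set must be
#'   nonempty.
#' @param cfg a [SamplerConfig-class].
#' @param gold the full gold-standard [ProteinNetwork-class] (negative
#'   sampling excludes its edges).
#' @param alphaFraction diffusion fraction for the scorer (default 0.5).
#' @return list with elements `best` (a [Particle-class]) and `history`
#'   (data frame: generation, bestFitness, meanFitness, aucTn, aucVn of
#'   the generation's best particle).
#' @export
optimizeWeights <- function(ks, split, cfg, gold, alphaFraction = 0.5) {
  stopifnot(is(ks, "KernelSet"), is(split, "NetworkSplit"),
            is(cfg, "SamplerConfig"), is(gold, "ProteinNetwork"))
  .with_seed(cfg@seed, {
    ctx <- fitnessContext(ks, split, gold, cfg, alphaFraction)
    pop <- initializePopulation(cfg, length(ks@kernels) - 1L, seeded = FALSE)
    pop <- lapply(pop, function(p) {
      r <- .eval_particle(p@weights, ctx)
      new("Particle", weights = p@weights, fitness = r[["fitness"]])
    })
    record <- function(gen, pop) {
      fit <- vapply(pop, function(p) p@fitness, numeric(1))
      b <- which.max(fit)
      r <- .eval_particle(pop[[b]]@weights, ctx)
      data.frame(generation = gen, bestFitness = fit[b],
                 meanFitness = mean(fit),
                 aucTn = r[["aucTn"]], aucVn = r[["aucVn"]])
    }
    history <- record(0L, pop)
    bestEver <- pop[[which.max(vapply(pop, function(p) p@fitness,
                                      numeric(1)))]]
    stall <- 0L
    for (gen in seq_len(cfg@maxGenerations)) {
      pop <- evolveGeneration(pop, ctx, cfg, gen - 1L)
      history <- rbind(history, record(gen, pop))
      newBest <- max(vapply(pop, function(p) p@fitness, numeric(1)))
      if (newBest > bestEver@fitness) {
        b <- which.max(vapply(pop, function(p) p@fitness, numeric(1)))
        if (newBest - bestEver@fitness < cfg@convergenceTol) {
          stall <- stall + 1L
        } else {
          stall <- 0L
        }
        bestEver <- pop[[b]]
      } else {
        stall <- stall + 1L
      }
      if (stall >= cfg@convergenceWindow) break
    }
    list(best = bestEver, history = history)
  })
}

#' Write an optimisation history as TSV, and best weights as JSON
#'
#' @param result the list returned by [optimizeWeights()].
#' @param ks the [KernelSet-class] the run used (for kernel names).
#' @param historyPath,weightsPath output paths (either may be `NULL` to
#'   skip).
#' @return invisibly, the paths written.
#' @export
writeOptimizationResult <- function(result, ks, historyPath = NULL,
                                    weightsPath = NULL) {
  if (!is.null(historyPath)) {
    h <- result$history
    names(h) <- c("generation", "best_fitness", "mean_fitness",
                  "auc_tn", "auc_vn")
    utils::write.table(h, historyPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(weightsPath)) {
    w <- as.list(setNames(result$best@weights, kernelNames(ks)))
    jsonlite::write_json(w, weightsPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(historyPath, weightsPath))
}
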