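#' Run the full inference experiment with its controls
#'
#' Executes the complete pipeline on a [BenchmarkScenario-class] (or any
#' equivalent gold/split/kernels triple): learn optimal kernel weights
#' with [optimizeWeights()], score all pairs with the regularized
#' Laplacian of the optimally weighted fusion (OPT-K), and always compute
#' the two controls alongside — the equal-weight fusion (EW-K, every
#' weight 1) and the bare training network (\eqn{G_{tn}}-only, one-hot
#' weight on the adjacency) — so the method's relative claims are one
#' call. Each variant is evaluated by ROC/AUC over the full candidate
#' universe of the test set, and again on the long-range subset
#' (test pairs more than `farawayDistance` hops apart in \eqn{G_{tn}}).
#'
#' @param scenario a [BenchmarkScenario-class], or `NULL` if `gold`,
#'   `split`, `kernels` are given explicitly.
#' @param cfg a [SamplerConfig-class]; its seed drives the whole run.
#' @param alphaFraction diffusion fraction for all scorers (default 0.5).
#' @param farawayDistance strict hop threshold for the long-range regime
#'   (default 3).
#' @param outDir if non-`NULL`, write weights, history, ROC points,
#'   metrics and a config echo there.
#' @param gold,split,kernels explicit inputs overriding `scenario`.
#' @return list with elements `weights` (named optimal weights),
#'   `history` (sampler trace), `auc` (named: `opt_k`, `ew_k`,
#'   `gtn_only`), `aucFaraway` (same names, `NA` if no qualifying test
#'   pair), `nFaraway`, and `alpha` (named vector of diffusion parameters
#'   used).
#' @examples
#' \donttest{
#' scen <- generateBenchmark(nNodes = 80, nExtra = 10, nValidation = 15,
#'                           nTest = 60, seed = 1)
#' cfg <- samplerConfig(populationSize = 30, maxGenerations = 5, seed = 1)
#' res <- runInference(scen, cfg)
#' res$auc
#' }
#' @export
runInference <- function(scenario = NULL, cfg = samplerConfig(),
                         alphaFraction = 0.5, farawayDistance = 3,
                         outDir = NULL, gold = NULL, split = NULL,
                         kernels = NULL) {
  if (!is.null(scenario)) {
    stopifnot(is(scenario, "BenchmarkScenario"))
    gold <- scenario@gold
    split <- scenario@split
    kernels <- scenario@kernels
  }
  stopifnot(is(gold, "ProteinNetwork"), is(split, "NetworkSplit"),
            is(kernels, "KernelSet"))
  nk <- length(kernels@kernels)

  opt <- optimizeWeights(kernels, split, cfg, gold, alphaFraction)
  wOpt <- opt$best@weights
  wEw <- rep(1, nk)
  wGtn <- c(1, rep(0, nk - 1L))

  scoreSets <- list(
    opt_k = inferScores(kernels, wOpt, alphaFraction),
    ew_k = inferScores(kernels, wEw, alphaFraction),
    gtn_only = inferScores(kernels, wGtn, alphaFraction))

  universe <- candidateUniverse(gold, split, split@testEdges)
  rocs <- lapply(scoreSets, function(s) rocAuc(scorePairs(universe, s)))
  auc <- vapply(rocs, function(r) r@auc, numeric(1))

  fw <- farawaySubset(split, minDistanceExclusive = farawayDistance)
  if (nrow(fw) > 0L) {
    fwUniverse <- candidateUniverse(gold, split, fw)
    fwRocs <- lapply(scoreSets, function(s) rocAuc(scorePairs(fwUniverse, s)))
    aucFw <- vapply(fwRocs, function(r) r@auc, numeric(1))
  } else {
    fwRocs <- NULL
    aucFw <- setNames(rep(NA_real_, length(scoreSets)), names(scoreSets))
  }

  res <- list(
    weights = setNames(wOpt, kernelNames(kernels)),
    history = opt$history,
    auc = auc,
    aucFaraway = aucFw,
    nFaraway = nrow(fw),
    alpha = vapply(scoreSets, function(s) s@alpha, numeric(1)))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeOptimizationResult(opt, kernels,
      historyPath = file.path(outDir, "history.tsv"),
      weightsPath = file.path(outDir, "weights.json"))
    for (nm in names(rocs)) {
      writeRocResult(rocs[[nm]],
        pointsPath = file.path(outDir, paste0("roc_", nm, ".tsv")))
    }
    jsonlite::write_json(
      list(schema = "ppiFusion/run-metrics/1",
           auc = as.list(auc), auc_faraway = as.list(aucFw),
           n_faraway = nrow(fw), alpha = as.list(res$alpha),
           weights = as.list(res$weights)),
      file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(schema = "ppiFusion/run-config/1",
           sampler = list(
             population_size = cfg@populationSize,
             max_generations = cfg@maxGenerations,
             de_scale_factor = cfg@deScaleFactor,
             crossover_rate = cfg@crossoverRate,
             initial_temperature = cfg@initialTemperature,
             cooling_rate = cfg@coolingRate,
             convergence_window = cfg@convergenceWindow,
             convergence_tol = cfg@convergenceTol,
             fitness_blend = cfg@fitnessBlend,
             negative_sample_ratio = cfg@negativeSampleRatio,
             seed = cfg@seed),
           alpha_fraction = alphaFraction,
           faraway_distance = farawayDistance),
      file.path(outDir, "config.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Read a run configuration from JSON
#'
#' Parses the JSON written next to every run (`config.json`) — or one
#' authored by hand — into a [SamplerConfig-class] plus the pipeline
#' options, for use by the command-line driver.
#'
#' @param path JSON file path.
#' @return list with elements `cfg` ([SamplerConfig-class]),
#'   `alphaFraction`, `farawayDistance`.
#' @export
readRunConfig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- obj$sampler
  pick <- function(x, default) if (is.null(x)) default else x
  cfg <- samplerConfig(
    populationSize = pick(s$population_size, 150L),
    maxGenerations = pick(s$max_generations, 50L),
    deScaleFactor = pick(s$de_scale_factor, 0.8),
    crossoverRate = pick(s$crossover_rate, 0.9),
    initialTemperature = pick(s$initial_temperature, 0.1),
    coolingRate = pick(s$cooling_rate, 0.9),
    convergenceWindow = pick(s$convergence_window, 3L),
    convergenceTol = pick(s$convergence_tol, 1e-4),
    fitnessBlend = pick(s$fitness_blend, 0.5),
    negativeSampleRatio = pick(s$negative_sample_ratio, 10L),
    seed = pick(s$seed, 1L))
  list(cfg = cfg,
       alphaFraction = pick(obj$alpha_fraction, 0.5),
       farawayDistance = pick(obj$faraway_distance, 3))
}
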