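#' Build the labelled candidate-pair universe
#'
#' The evaluation universe of a link-prediction run: the given held-out
#' edges are the positives, and every unordered node pair with no edge in
#' the *full* gold-standard network is a negative (so genuinely unknown
#' interactions count against the method, as in standard practice).
#' Training and validation pairs are excluded entirely — they are neither
#' positive nor negative — as are self-pairs and gold edges outside
#' `positives`.
#'
#' @param gold the full gold-standard [ProteinNetwork-class].
#' @param split the [NetworkSplit-class] used for training.
#' @param positives canonical edge matrix of positive pairs (typically
#'   [testEdges()] of the split, or a faraway subset of them).
#' @return data frame with columns `node_i`, `node_j`, `label`
#'   (`"positive"`/`"negative"`); scores unset.
#' @seealso [scorePairs()], [rocAuc()]
#' @export
candidateUniverse <- function(gold, split, positives) {
  stopifnot(is(gold, "ProteinNetwork"), is(split, "NetworkSplit"))
  positives <- .canonical_edges(positives)
  if (nrow(positives) == 0L) stop("empty positive set")
  ids <- gold@nodeIds
  n <- length(ids)
  goldKeys <- .edge_keys(gold@edges, ids)
  posKeys <- .edge_keys(positives, ids)
  if (!all(posKeys %in% goldKeys)) {
    stop("positives must be edges of the gold network")
  }
  tnKeys <- .edge_keys(split@trainNetwork@edges, ids)
  if (any(posKeys %in% tnKeys)) {
    stop("leakage: positive pair(s) present in the training network")
  }
  pairs <- .all_pairs(n)
  keys <- .pair_key(pairs[, 1L], pairs[, 2L], n)
  negRows <- !(keys %in% goldKeys)
  neg <- pairs[negRows, , drop = FALSE]
  posIdx <- .edge_index(positives, ids)
  data.frame(
    node_i = ids[c(posIdx[, 1L], neg[, 1L])],
    node_j = ids[c(posIdx[, 2L], neg[, 2L])],
    label = rep(c("positive", "negative"), c(nrow(posIdx), nrow(neg))),
    stringsAsFactors = FALSE)
}

#' Attach inference scores to a pair table
#'
#' @param universe data frame from [candidateUniverse()] (columns
#'   `node_i`, `node_j`).
#' @param scores an [InferenceScores-class] covering all pair endpoints.
#' @return `universe` with a `score` column, sorted by decreasing score.
#' @export
scorePairs <- function(universe, scores) {
  stopifnot(is(scores, "InferenceScores"))
  i <- match(universe$node_i, scores@nodeIds)
  j <- match(universe$node_j, scores@nodeIds)
  if (anyNA(i) || anyNA(j)) stop("pair endpoint missing from scores")
  universe$score <- scores@values[cbind(i, j)]
  universe[order(-universe$score), , drop = FALSE]
}

#' ROC curve and AUC of a labelled ranking
#'
#' AUC is the Mann-Whitney statistic — the probability that a random
#' positive outranks a random negative, ties credited 1/2 (midrank
#' convention). ROC points come from a threshold sweep down the ranked
#' list with tied scores grouped, so the curve passes through (0, 0) and
#' (1, 1) and its trapezoidal area equals the AUC.
#'
#' @param ranking data frame with columns `score` and `label`
#'   (`"positive"`/`"negative"`), e.g. from [scorePairs()].
#' @return a [ROCResult-class].
#' @export
rocAuc <- function(ranking) {
  lab <- ranking$label == "positive"
  s <- ranking$score
  np <- sum(lab)
  nn <- sum(!lab)
  if (np == 0L || nn == 0L) {
    stop("degenerate ranking: need at least one positive and one negative")
  }
  auc <- .fast_auc(s[lab], s[!lab])
  o <- order(-s)
  s <- s[o]
  lab <- lab[o]
  ## group ties: cumulative counts at the last element of each tie block
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(lab)[last]
  fp <- cumsum(!lab)[last]
  points <- rbind(c(0, 0), cbind(fp / nn, tp / np))
  colnames(points) <- c("fpr", "tpr")
  res <- new("ROCResult", points = unname(points), auc = auc,
             nPos = as.integer(np), nNeg = as.integer(nn))
  validObject(res)
  res
}

#' Long-range (faraway) subset of the test edges
#'
#' The regime where plain network-proximity scoring degrades: test pairs
#' whose endpoints are more than `minDistanceExclusive` hops apart in the
#' training network \eqn{G_{tn}} (strict inequality; pairs in different
#' components, i.e. infinite distance, are included).
#'
#' @param split a [NetworkSplit-class]; distances are computed on its
#'   training network.
#' @param testEdges canonical edge matrix (defaults to the split's test
#'   set).
#' @param minDistanceExclusive hop threshold, default 3.
#' @return the qualifying subset of `testEdges` (possibly zero rows).
#' @export
farawaySubset <- function(split, testEdges = NULL, minDistanceExclusive = 3) {
  stopifnot(is(split, "NetworkSplit"))
  if (is.null(testEdges)) testEdges <- split@testEdges
  testEdges <- .canonical_edges(testEdges)
  if (nrow(testEdges) == 0L) return(testEdges)
  d <- pairwiseDistances(split@trainNetwork, testEdges)
  testEdges[d > minDistanceExclusive, , drop = FALSE]
}

#' Write ROC points and summary metrics
#'
#' @param roc a [ROCResult-class].
#' @param pointsPath TSV of (fpr, tpr) points, or `NULL` to skip.
#' @param metricsPath one-line JSON `{auc, n_pos, n_neg}`, or `NULL`.
#' @return invisibly, the paths written.
#' @export
writeRocResult <- function(roc, pointsPath = NULL, metricsPath = NULL) {
  stopifnot(is(roc, "ROCResult"))
  if (!is.null(pointsPath)) {
    df <- data.frame(fpr = roc@points[, 1L], tpr = roc@points[, 2L])
    utils::write.table(df, pointsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(metricsPath)) {
    jsonlite::write_json(list(auc = roc@auc, n_pos = roc@nPos,
                              n_neg = roc@nNeg),
                         metricsPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(pointsPath, metricsPath))
}
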