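#' Weighted kernel fusion
#'
#' The elementwise nonnegative combination
#' \deqn{K_{fusion} = W_0 G_{tn} + \sum_{i \ge 1} W_i K_i}
#' of the training adjacency and the feature kernels, in the fixed order
#' of the [KernelSet-class].
#'
#' @param ks a [KernelSet-class].
#' @param w numeric weight vector, one nonnegative weight per kernel.
#' @return a [KernelMatrix-class] named `"fusion"`.
#' @export
fuseKernels <- function(ks, w) {
  stopifnot(is(ks, "KernelSet"))
  w <- as.numeric(w)
  if (length(w) != length(ks@kernels)) {
    stop("weight vector length ", length(w), " != number of kernels ",
         length(ks@kernels))
  }
  if (any(w < 0)) stop("negative weight: weights live in [0, wMax]")
  v <- .fuse_values(lapply(ks@kernels, function(k) k@values), w)
  new("KernelMatrix", nodeIds = nodeIds(ks), values = v, name = "fusion")
}

## plain-matrix fusion, used in the sampler's hot loop
.fuse_values <- function(mats, w) {
  v <- mats[[1L]] * w[1L]
  for (i in seq_along(mats)[-1L]) {
    if (w[i] != 0) v <- v + mats[[i]] * w[i]
  }
  v
}

#' Spectral radius of the graph Laplacian
#'
#' \eqn{\rho(L)} for \eqn{L = D - M} with \eqn{D} the diagonal of row
#' sums of the (weighted) adjacency `m`; it bounds the admissible
#' diffusion parameter of the regularized Laplacian,
#' \eqn{0 < \alpha < \rho(L)^{-1}}.
#'
#' @param m a [KernelMatrix-class] or plain symmetric matrix.
#' @return largest eigenvalue magnitude of \eqn{L} (0 for a zero matrix).
#' @export
spectralRadius <- function(m) {
  v <- if (is(m, "KernelMatrix")) m@values else as.matrix(m)
  if (max(abs(v - t(v))) > 1e-10 * max(1, max(abs(v)))) {
    stop("matrix must be symmetric")
  }
  if (all(v == 0)) return(0)
  L <- .laplacian(v)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  max(abs(ev))
}

.laplacian <- function(v) {
  L <- -v
  diag(L) <- diag(L) + rowSums(v)
  L
}

#' Regularized Laplacian kernel
#'
#' The graph kernel
#' \deqn{RL = \sum_{k \ge 0} \alpha^k (-L)^k = (I + \alpha L)^{-1}}
#' computed by a direct (Cholesky) solve; \eqn{I + \alpha L} is positive
#' definite for any nonnegative `m` and \eqn{\alpha \ge 0}. The series
#' interpretation requires \eqn{\alpha < \rho(L)^{-1}}; beyond that bound
#' the closed form is still returned with a warning. Entries are read as
#' pairwise interaction propensities.
#'
#' @param m a [KernelMatrix-class] (e.g. a fusion) or plain symmetric
#'   nonnegative matrix.
#' @param alpha diffusion parameter, \eqn{\alpha \ge 0}.
#' @param nodeIds identifiers when `m` is a plain matrix.
#' @return an [InferenceScores-class]; symmetry is enforced by averaging
#'   with the transpose.
#' @examples
#' edge <- proteinNetwork(c("A", "B"), rbind(c("A", "B")))
#' scoreValues(regularizedLaplacian(adjacencyMatrix(edge), 0.25))
#' @export
regularizedLaplacian <- function(m, alpha, nodeIds = NULL) {
  if (is(m, "KernelMatrix")) {
    ids <- m@nodeIds
    v <- m@values
  } else {
    v <- as.matrix(m)
    ids <- if (is.null(nodeIds)) {
      if (!is.null(rownames(v))) rownames(v) else as.character(seq_len(nrow(v)))
    } else nodeIds
  }
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0) {
    stop("alpha must be a single finite number >= 0")
  }
  rho <- spectralRadius(v)
  if (rho > 0 && alpha >= 1 / rho) {
    warning("alpha = ", format(alpha), " >= 1/rho(L) = ", format(1 / rho),
            ": outside the series regime; returning the closed form")
  }
  .rl_scores(v, alpha, ids)
}

## closed-form RL without the rho-based warning; hot path for the sampler
.rl_scores <- function(v, alpha, ids) {
  L <- .laplacian(v)
  A <- alpha * L
  diag(A) <- diag(A) + 1
  rl <- chol2inv(chol(A))
  rl <- (rl + t(rl)) / 2
  new("InferenceScores", nodeIds = ids, values = rl, alpha = alpha)
}

#' Fuse, build the Laplacian, and score in one step
#'
#' Convenience composition: fuse the kernels with weights `w`, derive the
#' diffusion parameter as a fixed fraction of the admissible bound,
#' \eqn{\alpha = alphaFraction / \rho(L(K_{fusion}))}, and return the
#' regularized Laplacian scores. One-hot weight on the first kernel
#' reproduces the bare training-network baseline; all-ones weights give
#' the equal-weight control.
#'
#' @param ks a [KernelSet-class].
#' @param w nonnegative weight vector.
#' @param alphaFraction fraction of \eqn{1/\rho(L)} used for
#'   \eqn{\alpha}, in (0, 1) (default 0.5).
#' @return an [InferenceScores-class] (its `alpha` slot records the value
#'   actually used).
#' @export
inferScores <- function(ks, w, alphaFraction = 0.5) {
  stopifnot(is(ks, "KernelSet"))
  if (alphaFraction <= 0 || alphaFraction >= 1) {
    stop("alphaFraction must lie in (0, 1)")
  }
  fusion <- fuseKernels(ks, w)
  if (max(fusion@values) == 0) {
    stop("empty fusion: all weighted kernels are zero")
  }
  rho <- spectralRadius(fusion@values)
  .rl_scores(fusion@values, alphaFraction / rho, nodeIds(ks))
}

#' Write scores as a ranked-pairs table
#'
#' Emits a tab-separated table `(node_i, node_j, score)` over all
#' unordered pairs, sorted by decreasing score — the ranked list a ROC
#' sweep walks down.
#'
#' @param scores an [InferenceScores-class].
#' @param path output path.
#' @param topN optionally keep only the best `topN` pairs.
#' @return `path`, invisibly.
#' @export
writeRankedPairs <- function(scores, path, topN = NULL) {
  stopifnot(is(scores, "InferenceScores"))
  n <- length(scores@nodeIds)
  pr <- .all_pairs(n)
  s <- scores@values[pr]
  o <- order(-s)
  if (!is.null(topN)) o <- head(o, topN)
  df <- data.frame(node_i = scores@nodeIds[pr[o, 1L]],
                   node_j = scores@nodeIds[pr[o, 2L]],
                   score = s[o])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
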