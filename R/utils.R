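#' @importFrom methods new validObject is slot
#' @importFrom stats runif setNames
#' @importFrom utils head
NULL

## Locale-independent (C-collation) sort; node order must not depend on
## the session locale.
.csort <- function(x) sort(x, method = "radix")

## Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
## RNG state afterwards so library code never clobbers user randomness.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a master seed; stays inside 32-bit range.
.child_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 1009 * as.double(offset)) %% 2147483647L)
}

## ---- edge bookkeeping -------------------------------------------------
## Edges are 2-column character matrices in canonical form: within a row
## the lexicographically (C collation) smaller id comes first; rows are
## deduplicated and sorted. Self-pairs are dropped by .canonical_edges.

.canonical_edges <- function(edges) {
  if (is.null(edges) || length(edges) == 0L) {
    return(matrix(character(0), ncol = 2L))
  }
  edges <- as.matrix(edges)
  storage.mode(edges) <- "character"
  if (ncol(edges) != 2L) stop("edge matrix must have two columns")
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  ## string comparison must be C-collation, not locale
  cmp <- .c_less(edges[, 1L], edges[, 2L])
  a <- ifelse(cmp, edges[, 1L], edges[, 2L])
  b <- ifelse(cmp, edges[, 2L], edges[, 1L])
  m <- cbind(a, b, deparse.level = 0L)
  m <- m[!duplicated(paste(m[, 1L], m[, 2L], sep = "\r")), , drop = FALSE]
  o <- order(m[, 1L], m[, 2L], method = "radix")
  unname(m[o, , drop = FALSE])
}

## elementwise "x < y" under C collation
.c_less <- function(x, y) {
  n <- length(x)
  if (n == 0L) return(logical(0))
  u <- .csort(unique(c(x, y)))
  match(x, u) < match(y, u)
}

## sample `size` elements from vector `x` without the sample(x) length-1
## surprise (sample(5L, 1) draws from 1:5, not from c(5))
.sample_from <- function(x, size, prob = NULL) {
  x[sample.int(length(x), size, prob = prob)]
}

## numeric key for an integer pair (i, j), i != j, order-insensitive
.pair_key <- function(i, j, n) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  (as.double(lo) - 1) * n + as.double(hi)
}

## keys of a canonical character edge matrix under node order `ids`
.edge_keys <- function(edges, ids) {
  if (nrow(edges) == 0L) return(double(0))
  i <- match(edges[, 1L], ids)
  j <- match(edges[, 2L], ids)
  if (anyNA(i) || anyNA(j)) stop("edge endpoint not found in node set")
  .pair_key(i, j, length(ids))
}

## integer index matrix (i, j) for a character edge matrix
.edge_index <- function(edges, ids) {
  i <- match(edges[, 1L], ids)
  j <- match(edges[, 2L], ids)
  if (anyNA(i) || anyNA(j)) stop("edge endpoint not found in node set")
  cbind(i, j)
}

## all unordered pairs (i < j) over 1..n as an integer matrix
.all_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(idx[, "row"], idx[, "col"])
}

## Mann-Whitney AUC with midrank ties: P(score_pos > score_neg) + 0.5 ties
.fast_auc <- function(pos, neg) {
  np <- length(pos)
  nn <- length(neg)
  if (np == 0L || nn == 0L) {
    stop("AUC needs at least one positive and one negative score")
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}
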