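#' Construct a ProteinNetwork
#'
#' Builds a [ProteinNetwork-class] from node identifiers and an edge
#' matrix. Node order is always lexicographic (C collation); self-pairs
#' and duplicate edges are dropped silently (the file reader
#' [readEdgeList()] reports the dropped count).
#'
#' @param nodeIds character vector of protein identifiers; nodes with no
#'   edges are allowed.
#' @param edges two-column character matrix (or data frame) of unordered
#'   pairs; may be `NULL` for an edgeless network.
#' @return a validated [ProteinNetwork-class].
#' @examples
#' proteinNetwork(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' @export
proteinNetwork <- function(nodeIds, edges = NULL) {
  net <- new("ProteinNetwork",
             nodeIds = .csort(unique(as.character(nodeIds))),
             edges = .canonical_edges(edges))
  validObject(net)
  net
}

## igraph view of a network, vertices in nodeIds order
.as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = length(net@nodeIds), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net@nodeIds)
  if (nrow(net@edges) > 0L) {
    g <- igraph::add_edges(g, t(.edge_index(net@edges, net@nodeIds)))
  }
  g
}

#' Read a PPI network from an edge-list file
#'
#' Parses a plain-text edge list (DIP-style): one interaction per line,
#' the first two whitespace- or tab-separated fields being protein
#' identifiers (any further columns are ignored); lines starting with
#' `#` are comments. Duplicate edges and self-loops are collapsed and
#' their count reported via `message()`.
#'
#' @param path path to the edge-list file.
#' @return a [ProteinNetwork-class] with lexicographically sorted nodes.
#' @seealso [writeEdgeList()]
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[ \t]+")
  ok <- lengths(toks) >= 2L
  if (sum(!ok)) {
    message("readEdgeList: skipped ", sum(!ok), " malformed line(s)")
  }
  toks <- toks[ok]
  if (length(toks) == 0L) stop("empty network: no valid edges in ", path)
  raw <- t(vapply(toks, function(t) t[1:2], character(2)))
  canon <- .canonical_edges(raw)
  if (nrow(canon) == 0L) stop("empty network: no valid edges in ", path)
  dropped <- nrow(raw) - nrow(canon)
  if (dropped > 0L) {
    message("readEdgeList: dropped ", dropped,
            " duplicate edge(s)/self-loop(s)")
  }
  proteinNetwork(unique(as.vector(canon)), canon)
}

#' Write a network as a tab-separated edge list
#'
#' Emits one edge per line, tab-separated, in canonical (lexicographically
#' sorted) order; readable back with [readEdgeList()].
#'
#' @param net a [ProteinNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "ProteinNetwork"))
  writeLines(paste(net@edges[, 1L], net@edges[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Largest connected component
#'
#' Returns the induced subgraph on the largest connected component of the
#' network, the usual preprocessing step that turns a raw interaction
#' download into the gold-standard network. Ties in component size are
#' broken in favour of the component containing the lexicographically
#' smallest node identifier.
#'
#' @param net a nonempty [ProteinNetwork-class].
#' @return a [ProteinNetwork-class] restricted to the chosen component.
#' @export
largestConnectedComponent <- function(net) {
  stopifnot(is(net, "ProteinNetwork"))
  if (length(net@nodeIds) == 0L) stop("empty network")
  comp <- igraph::components(.as_igraph(net))
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    ## nodeIds are sorted, so the first node in a tied-size component
    ## decides: pick the component whose smallest member comes first
    firsts <- vapply(best, function(b) min(which(comp$membership == b)),
                     integer(1))
    best <- best[which.min(firsts)]
  }
  keep <- net@nodeIds[comp$membership == best]
  inside <- net@edges[, 1L] %in% keep & net@edges[, 2L] %in% keep
  proteinNetwork(keep, net@edges[inside, , drop = FALSE])
}

#' Adjacency matrix of a network
#'
#' The 0/1 adjacency matrix \eqn{A} in node order, wrapped as a
#' [KernelMatrix-class] so it can head a [KernelSet-class] as the
#' training-network operand of the fusion.
#'
#' @param net a [ProteinNetwork-class].
#' @param name label for the resulting kernel (default `"G_tn"`).
#' @return a [KernelMatrix-class] with zero diagonal.
#' @export
adjacencyMatrix <- function(net, name = "G_tn") {
  stopifnot(is(net, "ProteinNetwork"))
  n <- length(net@nodeIds)
  a <- matrix(0, n, n)
  if (nrow(net@edges) > 0L) {
    idx <- .edge_index(net@edges, net@nodeIds)
    a[idx] <- 1
    a[idx[, c(2L, 1L), drop = FALSE]] <- 1
  }
  new("KernelMatrix", nodeIds = net@nodeIds, values = a, name = name)
}

#' Split a network into training, validation and test parts
#'
#' Divides a connected gold-standard network into the supervised triple
#' \eqn{(G_{tn}, G_{vn}, G_{tt})}. The training network is a uniformly
#' randomised spanning tree — a minimum spanning tree over i.i.d. uniform
#' random edge weights, so each seed yields a different tree — augmented
#' with `nExtra` edges drawn without replacement from the remaining
#' edges. Validation and test edges are then sampled disjointly from what
#' is left. Everything is deterministic given `seed`.
#'
#' @param net a connected [ProteinNetwork-class].
#' @param nExtra extra non-tree edges for \eqn{G_{tn}}.
#' @param nValidation size of the validation edge set \eqn{E_{vn}}.
#' @param nTest size of the test edge set \eqn{E_{tt}}.
#' @param seed integer RNG seed.
#' @return a [NetworkSplit-class].
#' @examples
#' net <- proteinNetwork(c("A", "B", "C"),
#'                       rbind(c("A", "B"), c("B", "C"), c("A", "C")))
#' splitNetwork(net, nExtra = 0, nValidation = 0, nTest = 1, seed = 1)
#' @export
splitNetwork <- function(net, nExtra, nValidation, nTest, seed) {
  stopifnot(is(net, "ProteinNetwork"))
  g <- .as_igraph(net)
  if (!igraph::is_connected(g)) stop("not connected: cannot split")
  n <- length(net@nodeIds)
  m <- nrow(net@edges)
  need <- (n - 1L) + nExtra + nValidation + nTest
  if (need > m) {
    stop("split infeasible: need ", need, " edges but network has ", m,
         " (deficit ", need - m, ")")
  }
  .with_seed(seed, {
    w <- runif(m)
    tree <- igraph::mst(g, weights = w)
    te <- igraph::as_edgelist(tree, names = TRUE)
    treeKeys <- .edge_keys(.canonical_edges(te), net@nodeIds)
    allKeys <- .edge_keys(net@edges, net@nodeIds)
    rest <- which(!(allKeys %in% treeKeys))
    extra <- if (nExtra > 0L) .sample_from(rest, nExtra) else integer(0)
    rest2 <- setdiff(rest, extra)
    val <- if (nValidation > 0L) .sample_from(rest2, nValidation) else integer(0)
    rest3 <- setdiff(rest2, val)
    tst <- if (nTest > 0L) .sample_from(rest3, nTest) else integer(0)
    trainEdges <- .canonical_edges(rbind(
      net@edges[match(treeKeys, allKeys), , drop = FALSE],
      net@edges[extra, , drop = FALSE]))
    split <- new("NetworkSplit",
      trainNetwork = proteinNetwork(net@nodeIds, trainEdges),
      validationEdges = .canonical_edges(net@edges[val, , drop = FALSE]),
      testEdges = .canonical_edges(net@edges[tst, , drop = FALSE]),
      nExtra = as.integer(nExtra), seed = as.integer(seed))
    validObject(split)
    split
  })
}

#' Hop distances between node pairs
#'
#' Breadth-first-search hop counts in an unweighted network for a list of
#' node pairs; pairs in different components get `Inf`.
#'
#' @param net a [ProteinNetwork-class].
#' @param pairs two-column character matrix of node pairs.
#' @return numeric vector of hop counts (0 for identical endpoints,
#'   `Inf` if unreachable), one per row of `pairs`.
#' @export
pairwiseDistances <- function(net, pairs) {
  stopifnot(is(net, "ProteinNetwork"))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  if (!all(pairs %in% net@nodeIds)) {
    bad <- setdiff(unique(as.vector(pairs)), net@nodeIds)
    stop("unknown node id(s): ", paste(head(bad, 3L), collapse = ", "))
  }
  g <- .as_igraph(net)
  src <- unique(pairs[, 1L])
  d <- igraph::distances(g, v = src, to = igraph::V(g), mode = "all")
  rownames(d) <- src
  d[cbind(match(pairs[, 1L], src), match(pairs[, 2L], net@nodeIds))]
}

#' Write / read a split manifest as JSON
#'
#' The manifest holds the three edge sets, the seed and `nExtra`; together
#' with the gold-standard edge list it reproduces a [NetworkSplit-class]
#' without rerunning the sampler.
#'
#' @param split a [NetworkSplit-class].
#' @param path JSON file path.
#' @return `writeSplit`: `path` invisibly. `readSplit`: a
#'   [NetworkSplit-class].
#' @export
writeSplit <- function(split, path) {
  stopifnot(is(split, "NetworkSplit"))
  obj <- list(
    nodes = split@trainNetwork@nodeIds,
    train_edges = unname(split@trainNetwork@edges),
    validation_edges = unname(split@validationEdges),
    test_edges = unname(split@testEdges),
    seed = split@seed,
    n_extra = split@nExtra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSplit
#' @export
readSplit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  .as_edge_matrix <- function(x) {
    if (length(x) == 0L) matrix(character(0), ncol = 2L) else as.matrix(x)
  }
  split <- new("NetworkSplit",
    trainNetwork = proteinNetwork(unlist(obj$nodes),
                                  .as_edge_matrix(obj$train_edges)),
    validationEdges = .canonical_edges(.as_edge_matrix(obj$validation_edges)),
    testEdges = .canonical_edges(.as_edge_matrix(obj$test_edges)),
    nExtra = as.integer(obj$n_extra), seed = as.integer(obj$seed))
  validObject(split)
  split
}
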