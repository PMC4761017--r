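#' Jaccard neighbour-overlap kernel
#'
#' Topological similarity of two proteins in the training network:
#' \eqn{|N(i) \cap N(j)| / |N(i) \cup N(j)|} over neighbour sets, with the
#' 0/0 case defined as 0 and the diagonal zeroed (self-pairs are never
#' prediction candidates).
#'
#' @param net a [ProteinNetwork-class] (typically \eqn{G_{tn}}).
#' @param name kernel label (default `"jaccard"`).
#' @return a [KernelMatrix-class] with entries in \[0, 1\].
#' @export
jaccardKernel <- function(net, name = "jaccard") {
  stopifnot(is(net, "ProteinNetwork"))
  g <- .as_igraph(net)
  s <- igraph::similarity(g, mode = "all", method = "jaccard", loops = FALSE)
  s[!is.finite(s)] <- 0
  diag(s) <- 0
  s <- (s + t(s)) / 2  # guard against last-bit asymmetry
  new("KernelMatrix", nodeIds = net@nodeIds, values = s, name = name)
}

#' Shared-neighbour (degree-sum) kernel
#'
#' Raw entry \eqn{(i, j)} is the total neighbour count
#' \eqn{\deg(i) + \deg(j)}; the diagonal is zeroed and the matrix is then
#' divided by its maximum so entries land in \[0, 1\]. An edgeless network
#' yields the zero matrix.
#'
#' @param net a [ProteinNetwork-class].
#' @param name kernel label (default `"shared_neighbor"`).
#' @return a [KernelMatrix-class].
#' @export
sharedNeighborKernel <- function(net, name = "shared_neighbor") {
  stopifnot(is(net, "ProteinNetwork"))
  n <- length(net@nodeIds)
  deg <- rep(0, n)
  if (nrow(net@edges) > 0L) {
    idx <- .edge_index(net@edges, net@nodeIds)
    deg <- tabulate(c(idx[, 1L], idx[, 2L]), nbins = n)
  }
  v <- outer(deg, deg, `+`)
  diag(v) <- 0
  mx <- max(v)
  if (mx > 0) v <- v / mx
  new("KernelMatrix", nodeIds = net@nodeIds, values = v, name = name)
}

#' Load a precomputed kernel from a labelled dense matrix file
#'
#' Reads the package's genomic-kernel exchange format: tab-separated
#' text whose first line is the N protein identifiers and whose N
#' following lines are an identifier plus N numeric fields. The matrix is
#' permuted into `expectedIds` order; proteins absent from the file get
#' zero rows/columns (reported via `message()`, mirroring name-mapping
#' losses between interaction databases and kernel sources); asymmetry up
#' to `tol` is averaged away, larger asymmetry is an error.
#'
#' @param path file path.
#' @param expectedIds ordered identifiers the kernel must be aligned to.
#' @param name kernel label (default: file base name).
#' @param tol maximum tolerated asymmetry before erroring (default 1e-8).
#' @return a [KernelMatrix-class] in `expectedIds` order.
#' @seealso [writeKernelMatrix()]
#' @export
loadKernelMatrix <- function(path, expectedIds,
                             name = sub("\\.[^.]*$", "", basename(path)),
                             tol = 1e-8) {
  if (!file.exists(path)) stop("cannot read kernel file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
  nf <- length(header)
  if (length(lines) - 1L != nf) {
    stop("kernel file ", path, ": header lists ", nf, " proteins but ",
         length(lines) - 1L, " data rows follow")
  }
  vals <- matrix(NA_real_, nf, nf)
  rowIds <- character(nf)
  for (r in seq_len(nf)) {
    tk <- strsplit(trimws(lines[[r + 1L]]), "[ \t]+")[[1L]]
    if (length(tk) != nf + 1L) {
      stop("kernel file ", path, " line ", r + 1L, ": expected ",
           nf + 1L, " fields, got ", length(tk))
    }
    rowIds[r] <- tk[1L]
    num <- suppressWarnings(as.numeric(tk[-1L]))
    if (anyNA(num)) {
      stop("kernel file ", path, " line ", r + 1L,
           ": malformed numeric field")
    }
    vals[r, ] <- num
  }
  if (!identical(rowIds, header)) {
    vals <- vals[match(header, rowIds), , drop = FALSE]
    if (anyNA(vals)) stop("kernel file ", path, ": row labels != header")
  }
  asym <- max(abs(vals - t(vals)))
  if (asym > tol) {
    stop("kernel file ", path, " not symmetric (max asymmetry ",
         format(asym), " > ", format(tol), ")")
  }
  vals <- (vals + t(vals)) / 2
  missing <- setdiff(expectedIds, header)
  if (length(missing)) {
    message("loadKernelMatrix: ", length(missing),
            " protein(s) missing from ", basename(path),
            "; filled with zero similarity")
  }
  extra <- setdiff(header, expectedIds)
  if (length(extra)) {
    message("loadKernelMatrix: ignoring ", length(extra),
            " protein(s) not in the expected node set")
  }
  n <- length(expectedIds)
  out <- matrix(0, n, n)
  common <- intersect(expectedIds, header)
  out[match(common, expectedIds), match(common, expectedIds)] <-
    vals[match(common, header), match(common, header)]
  new("KernelMatrix", nodeIds = expectedIds, values = out, name = name)
}

#' Write a kernel (or score matrix) in the labelled dense format
#'
#' @param k a [KernelMatrix-class] or [InferenceScores-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeKernelMatrix <- function(k, path) {
  ids <- nodeIds(k)
  v <- k@values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ids, collapse = "\t"), con)
  for (r in seq_along(ids)) {
    writeLines(paste(c(ids[r], format(v[r, ], digits = 17, trim = TRUE,
                                      scientific = FALSE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Min-max normalise a kernel to \[0, 1\]
#'
#' Rescales the off-diagonal entries by \eqn{(x - \min) / (\max - \min)};
#' a constant matrix maps to all zeros; the diagonal is forced to 0.
#'
#' @param k a [KernelMatrix-class] with finite entries.
#' @return a [KernelMatrix-class] with entries in \[0, 1\].
#' @export
normalizeKernel <- function(k) {
  stopifnot(is(k, "KernelMatrix"))
  v <- k@values
  if (any(!is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)[1L, ]
    stop("non-finite kernel entry at (", k@nodeIds[bad[1L]], ", ",
         k@nodeIds[bad[2L]], ")")
  }
  n <- nrow(v)
  off <- v[upper.tri(v) | lower.tri(v)]
  if (length(off)) {
    lo <- min(off)
    hi <- max(off)
    if (hi > lo) {
      v <- (v - lo) / (hi - lo)
    } else {
      v[] <- 0
    }
  }
  diag(v) <- 0
  v <- (v + t(v)) / 2
  new("KernelMatrix", nodeIds = k@nodeIds, values = v, name = k@name)
}

#' Smallest eigenvalue of a kernel
#'
#' Positive semi-definiteness monitor: min-max scaling and diagonal
#' zeroing may push a kernel slightly off PSD, which the regularized
#' Laplacian tolerates; this reports how far.
#'
#' @param k a [KernelMatrix-class].
#' @return the smallest eigenvalue (symmetric eigensolve).
#' @export
minEigenvalue <- function(k) {
  stopifnot(is(k, "KernelMatrix"))
  ev <- eigen(k@values, symmetric = TRUE, only.values = TRUE)$values
  ev[length(ev)]
}

#' Assemble kernels into a KernelSet
#'
#' Collects kernels sharing one node order into a [KernelSet-class]; the
#' first member must be the training-network adjacency (weight \eqn{W_0}
#' refers to it). Each kernel's smallest eigenvalue is reported via
#' `message()` when `checkPSD = TRUE` — monitored, never enforced.
#'
#' @param ... [KernelMatrix-class] objects (or a single list of them).
#' @param checkPSD log each kernel's smallest eigenvalue (default FALSE).
#' @return a [KernelSet-class].
#' @export
kernelSet <- function(..., checkPSD = FALSE) {
  ks <- list(...)
  if (length(ks) == 1L && is.list(ks[[1L]]) && !is(ks[[1L]], "KernelMatrix")) {
    ks <- ks[[1L]]
  }
  out <- new("KernelSet", kernels = ks)
  validObject(out)
  if (checkPSD) {
    for (k in ks) {
      message("kernel ", k@name, ": smallest eigenvalue ",
              format(minEigenvalue(k), digits = 4))
    }
  }
  out
}
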