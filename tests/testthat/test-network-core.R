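test_that("edge-list parsing collapses duplicates, self-loops and comments", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1 P2", "P2 P1", "P2 P2"), f)
  net <- suppressMessages(readEdgeList(f))
  expect_equal(numNodes(net), 2L)
  expect_equal(numEdges(net), 1L)
  expect_message(readEdgeList(f), "dropped 2")

  writeLines(c("A B", "B C", "# comment", "C D"), f)
  net <- readEdgeList(f)
  expect_equal(numNodes(net), 4L)
  expect_equal(numEdges(net), 3L)

  # a third column (e.g. a confidence score) is ignored
  writeLines("A\tB\t0.9", f)
  net <- readEdgeList(f)
  expect_equal(edges(net), rbind(c("A", "B")))
})

test_that("edge-list reader rejects unreadable and empty inputs", {
  expect_error(readEdgeList(file.path(tempdir(), "no-such-file.tsv")),
               "cannot read")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# only comments", "X X"), f)
  expect_error(suppressMessages(readEdgeList(f)), "empty network")
})

test_that("edge list writer round-trips through the reader", {
  net <- random_connected_network(20, 15, seed = 42)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(net, f)
  back <- readEdgeList(f)
  expect_identical(edges(back), edges(net))
  expect_identical(nodeIds(back), nodeIds(net))
})

test_that("largest connected component keeps the biggest part, ties to 'A'", {
  tri <- triangle_network()
  expect_identical(edges(largestConnectedComponent(tri)), edges(tri))

  two <- proteinNetwork(c("A", "B", "C", "D", "E"),
                        rbind(c("A", "B"), c("B", "C"), c("D", "E")))
  lcc <- largestConnectedComponent(two)
  expect_identical(nodeIds(lcc), c("A", "B", "C"))

  tie <- proteinNetwork(c("A", "B", "C", "D"),
                        rbind(c("A", "B"), c("C", "D")))
  expect_identical(nodeIds(largestConnectedComponent(tie)), c("A", "B"))
})

test_that("adjacency matrix is symmetric 0/1 with zero diagonal", {
  e <- proteinNetwork(c("A", "B"), rbind(c("A", "B")))
  expect_equal(unname(kernelValues(adjacencyMatrix(e))),
               matrix(c(0, 1, 1, 0), 2))
  empty <- proteinNetwork(c("A", "B", "C"))
  expect_equal(unname(kernelValues(adjacencyMatrix(empty))), matrix(0, 3, 3))
  p <- path_network()
  expect_equal(unname(kernelValues(adjacencyMatrix(p))),
               matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))
})

test_that("split on a triangle forces the expected sizes and disjointness", {
  s <- splitNetwork(triangle_network(), nExtra = 0, nValidation = 0,
                    nTest = 1, seed = 1)
  expect_equal(numEdges(trainNetwork(s)), 2L)
  expect_equal(nrow(testEdges(s)), 1L)
  expect_false(paste(testEdges(s), collapse = "|") %in%
                 apply(edges(trainNetwork(s)), 1, paste, collapse = "|"))
})

test_that("split errors name infeasibility and disconnectedness", {
  tree <- path_network(c("A", "B", "C", "D"))
  expect_error(splitNetwork(tree, 0, 0, 1, seed = 1), "split infeasible")
  expect_error(splitNetwork(tree, 0, 0, 1, seed = 1), "deficit")
  disc <- proteinNetwork(c("A", "B", "C", "D"),
                         rbind(c("A", "B"), c("C", "D")))
  expect_error(splitNetwork(disc, 0, 0, 0, seed = 1), "not connected")
})

test_that("split is seed-reproducible and seed-sensitive", {
  net <- random_connected_network(25, 30, seed = 7)
  s1 <- splitNetwork(net, 3, 5, 10, seed = 11)
  s2 <- splitNetwork(net, 3, 5, 10, seed = 11)
  expect_identical(edges(trainNetwork(s1)), edges(trainNetwork(s2)))
  expect_identical(testEdges(s1), testEdges(s2))

  # K4 has 16 spanning trees; different seeds must find different ones
  trees <- vapply(1:10, function(s) {
    paste(splitNetwork(k4_network(), 0, 0, 0, seed = s)@trainNetwork@edges,
          collapse = "|")
  }, character(1))
  expect_gt(length(unique(trees)), 1L)
})

test_that("split invariants hold across seeds on random connected graphs", {
  for (s in 1:20) {
    net <- random_connected_network(20, 15, seed = s)
    sp <- splitNetwork(net, 4, 3, 5, seed = s)
    ids <- nodeIds(net)
    ktn <- apply(edges(trainNetwork(sp)), 1, paste, collapse = "|")
    kvn <- apply(validationEdges(sp), 1, paste, collapse = "|")
    ktt <- apply(testEdges(sp), 1, paste, collapse = "|")
    kall <- apply(edges(net), 1, paste, collapse = "|")
    expect_length(intersect(ktn, kvn), 0L)
    expect_length(intersect(ktn, ktt), 0L)
    expect_length(intersect(kvn, ktt), 0L)
    expect_true(all(c(ktn, kvn, ktt) %in% kall))
    expect_identical(nodeIds(trainNetwork(sp)), ids)
    expect_equal(length(ktn), length(ids) - 1L + 4L)
  }
})

test_that("pairwise hop distances match a Floyd-Warshall oracle", {
  p5 <- path_network(c("A", "B", "C", "D", "E"))
  expect_equal(pairwiseDistances(p5, rbind(c("A", "E"))), 4)
  expect_equal(pairwiseDistances(p5, rbind(c("A", "A"))), 0)
  disc <- proteinNetwork(c("A", "B", "C", "D"),
                         rbind(c("A", "B"), c("C", "D")))
  expect_equal(pairwiseDistances(disc, rbind(c("A", "C"))), Inf)
  expect_error(pairwiseDistances(p5, rbind(c("A", "Z"))), "unknown node")

  for (s in 1:3) {
    net <- random_connected_network(30, 10, seed = s)
    ids <- nodeIds(net)
    oracle <- fw_distances(net)
    set.seed(s)
    pairs <- cbind(sample(ids, 40, replace = TRUE),
                   sample(ids, 40, replace = TRUE))
    expect_equal(pairwiseDistances(net, pairs), unname(oracle[pairs]))
  }
})

test_that("split manifest JSON round-trips", {
  net <- random_connected_network(15, 10, seed = 3)
  sp <- splitNetwork(net, 2, 3, 4, seed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  writeSplit(sp, f)
  back <- readSplit(f)
  expect_identical(edges(trainNetwork(back)), edges(trainNetwork(sp)))
  expect_identical(validationEdges(back), validationEdges(sp))
  expect_identical(testEdges(back), testEdges(sp))
  expect_identical(back@seed, sp@seed)
})
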