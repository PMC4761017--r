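test_that("candidate universe enumerates non-edges of the full gold network", {
  # 4 nodes, 4 gold edges, 1 held out as test:
  # negatives = C(4,2) - |E_gold| = 2 (A-C and B-D)
  gold <- proteinNetwork(c("A", "B", "C", "D"),
                         rbind(c("A", "B"), c("B", "C"), c("C", "D"),
                               c("A", "D")))
  sp <- new("NetworkSplit",
            trainNetwork = proteinNetwork(c("A", "B", "C", "D"),
                                          rbind(c("A", "B"), c("B", "C"),
                                                c("C", "D"))),
            validationEdges = matrix(character(0), ncol = 2),
            testEdges = rbind(c("A", "D")),
            nExtra = 0L, seed = 1L)
  u <- candidateUniverse(gold, sp, testEdges(sp))
  expect_equal(sum(u$label == "positive"), 1L)
  expect_setequal(paste(u$node_i[u$label == "negative"],
                        u$node_j[u$label == "negative"]),
                  c("A C", "B D"))

  expect_error(candidateUniverse(gold, sp, rbind(c("A", "B"))), "leakage")
  expect_error(candidateUniverse(gold, sp, matrix(character(0), ncol = 2)),
               "empty positive")
  expect_error(candidateUniverse(gold, sp, rbind(c("A", "C"))),
               "edges of the gold network")
})

test_that("universe size obeys the bookkeeping identity on random graphs", {
  for (s in 1:5) {
    gold <- random_connected_network(12, 14, seed = s)
    sp <- splitNetwork(gold, 2, 3, 4, seed = s)
    u <- candidateUniverse(gold, sp, testEdges(sp))
    n <- numNodes(gold)
    expect_equal(nrow(u), 4L + choose(n, 2) - numEdges(gold))
  }
})

test_that("AUC matches hand-computed values and handles ties at midrank", {
  rk <- function(pos, neg) {
    data.frame(score = c(pos, neg),
               label = rep(c("positive", "negative"),
                           c(length(pos), length(neg))))
  }
  expect_equal(rocAuc(rk(c(2, 3), c(0, 1)))@auc, 1)
  expect_equal(rocAuc(rk(c(1, 1), c(1, 1, 1)))@auc, 0.5)
  expect_equal(rocAuc(rk(c(0.8, 0.4), c(0.6, 0.2)))@auc, 0.75)
  expect_error(rocAuc(rk(numeric(0), 1)), "degenerate")
})

test_that("AUC equals the brute-force comparison oracle and pROC", {
  set.seed(99)
  for (i in 1:30) {
    np <- sample(2:25, 1)
    nn <- sample(2:25, 1)
    pos <- sample(seq(0, 1, by = 0.1), np, replace = TRUE)  # force ties
    neg <- sample(seq(0, 1, by = 0.1), nn, replace = TRUE)
    rk <- data.frame(score = c(pos, neg),
                     label = rep(c("positive", "negative"), c(np, nn)))
    expect_equal(rocAuc(rk)@auc, brute_auc(pos, neg))
  }
  pos <- c(0.9, 0.8, 0.8, 0.3)
  neg <- c(0.8, 0.5, 0.2, 0.2, 0.1)
  rk <- data.frame(score = c(pos, neg),
                   label = rep(c("positive", "negative"), c(4, 5)))
  proc <- suppressMessages(pROC::auc(pROC::roc(
    response = rk$label, predictor = rk$score, levels = c("negative",
    "positive"), direction = "<")))
  expect_equal(rocAuc(rk)@auc, as.numeric(proc))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(7)
  sc <- runif(40)
  rk <- data.frame(score = sc,
                   label = rep(c("positive", "negative"), 20))
  a0 <- rocAuc(rk)@auc
  rk$score <- exp(sc)
  expect_equal(rocAuc(rk)@auc, a0)
  rk$score <- 3 * sc - 11
  expect_equal(rocAuc(rk)@auc, a0)
})

test_that("ROC points run from (0,0) to (1,1) and integrate to the AUC", {
  set.seed(3)
  sc <- sample(seq(0, 1, by = 0.05), 60, replace = TRUE)
  rk <- data.frame(score = sc,
                   label = sample(c("positive", "negative"), 60,
                                  replace = TRUE))
  r <- rocAuc(rk)
  p <- r@points
  expect_equal(p[1, ], c(0, 0))
  expect_equal(p[nrow(p), ], c(1, 1))
  expect_false(is.unsorted(p[, 1]))
  expect_false(is.unsorted(p[, 2]))
  trap <- sum(diff(p[, 1]) * (head(p[, 2], -1) + tail(p[, 2], -1)) / 2)
  expect_equal(trap, r@auc, tolerance = 1e-12)
})

test_that("faraway subset keeps strictly-more-than-threshold pairs", {
  ids <- c("A", "B", "C", "D", "E")
  train <- path_network(ids)
  sp <- new("NetworkSplit", trainNetwork = train,
            validationEdges = matrix(character(0), ncol = 2),
            testEdges = rbind(c("A", "E"), c("A", "D"), c("A", "C")),
            nExtra = 0L, seed = 1L)
  fw <- farawaySubset(sp)
  expect_equal(fw, rbind(c("A", "E")))  # dist 4 in, dist 3 and 2 out
  expect_equal(nrow(farawaySubset(sp, minDistanceExclusive = 1)), 3L)
  expect_equal(nrow(farawaySubset(sp, testEdges = matrix(character(0),
                                                         ncol = 2))), 0L)
})

test_that("scored pairs and ROC files round-trip", {
  gold <- random_connected_network(10, 12, seed = 2)
  sp <- splitNetwork(gold, 2, 2, 3, seed = 2)
  ks <- kernelSet(adjacencyMatrix(trainNetwork(sp)))
  sc <- inferScores(ks, 1)
  u <- scorePairs(candidateUniverse(gold, sp, testEdges(sp)), sc)
  expect_false(is.unsorted(rev(u$score)))
  r <- rocAuc(u)
  pf <- withr::local_tempfile(fileext = ".tsv")
  mf <- withr::local_tempfile(fileext = ".json")
  writeRocResult(r, pf, mf)
  expect_equal(nrow(read.delim(pf)), nrow(r@points))
  m <- jsonlite::read_json(mf)
  expect_equal(m$auc, r@auc)
  expect_equal(m$n_pos, 3L)
})
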