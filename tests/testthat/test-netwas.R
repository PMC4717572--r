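# A separable toy: positives form a clique of weight 1, the rest of the
# network is empty except for faint background so no row is all-zero.
separableNetwork <- function(nGenes = 40, nPos = 8, seed = 5) {
  ids <- sprintf("N%03d", seq_len(nGenes))
  withr::with_seed(seed, {
    W <- matrix(0, nGenes, nGenes, dimnames = list(ids, ids))
    W[seq_len(nPos), seq_len(nPos)] <- 1
    bg <- which(upper.tri(W) & row(W) > nPos)
    pick <- sample(bg, round(0.2 * length(bg)))
    W[pick] <- 0.01
    W[lower.tri(W)] <- 0
    W <- W + t(W)
    W[W > 1] <- 1
    diag(W) <- 0
    tissueNetwork(ids, W)
  })
}

toyScores <- function(ids, sigIds, seed = 2) {
  withr::with_seed(seed, {
    p <- runif(length(ids), 0.02, 1)
    p[match(sigIds, ids)] <- runif(length(sigIds), 0, 0.009)
    data.frame(gene = ids, chr = "chr1", nSnps = 1L, stat = chisqFromP(p),
               p = p, nSims = 1000L, seed = seed, stringsAsFactors = FALSE)
  })
}

test_that("label partition follows the strict threshold", {
  net <- separableNetwork()
  ids <- geneIds(net)
  gs <- toyScores(ids, ids[1:6])
  gs$p[7] <- 0.01  # exactly at threshold -> negative
  labs <- suppressMessages(buildLabels(gs, net, 0.01))
  expect_setequal(labs@positives, ids[1:6])
  expect_true(ids[7] %in% labs@negatives)
  expect_length(labs@unlabeled, 0)

  gs$p[8] <- NA  # unscored gene stays unlabeled
  labs2 <- suppressMessages(buildLabels(gs, net, 0.01))
  expect_identical(labs2@unlabeled, ids[8])

  gsFlat <- gs; gsFlat$p <- 0.5
  expect_error(buildLabels(gsFlat, net, 0.01), "no nominal signal")

  # constructed count is recovered exactly
  gs3 <- toyScores(sprintf("N%03d", 1:40), sprintf("N%03d", 1:10), seed = 9)
  labs3 <- suppressMessages(buildLabels(gs3, net, 0.01))
  expect_length(labs3@positives, sum(gs3$p < 0.01))
})

test_that("separable module is ranked perfectly and reproducibly", {
  net <- separableNetwork()
  ids <- geneIds(net)
  labs <- suppressMessages(
    buildLabels(toyScores(ids, ids[c(1:4)]), net, 0.01))
  run <- netwasSingle(net, labs, seed = 31)
  expect_identical(sort(unname(run$rank)), seq_along(ids))
  gold <- goldStandard(ids[1:8], universe = ids)
  expect_identical(rocAuc(-run$rank, gold), 1)

  run2 <- netwasSingle(net, labs, seed = 31)
  expect_identical(run$decision, run2$decision)
  runs <- netwasIterate(net, labs, 5, seed = 77)
  for (r in runs) expect_identical(rocAuc(-r$rank, gold), 1)
  # iteration 1 equals a direct call with the derived child seed
  direct <- netwasSingle(net, labs, childSeed(77, "netwas", 1))
  expect_identical(runs[[1]]$rank, direct$rank)
})

test_that("relabeling genes permutes the ranking consistently", {
  net <- separableNetwork(nGenes = 30, nPos = 6)
  ids <- geneIds(net)
  labs <- suppressMessages(
    buildLabels(toyScores(ids, ids[1:5], seed = 4), net, 0.01))
  lab <- c(labs@positives, labs@negatives)
  folds <- setNames(rep(1:5, length.out = length(lab)), lab)
  run <- netwasSingle(net, labs, seed = 1, folds = folds)

  perm <- withr::with_seed(8, sample(length(ids)))
  W <- networkWeights(net)[perm, perm]
  netP <- tissueNetwork(ids[perm], W)
  runP <- netwasSingle(netP, labs, seed = 1, folds = folds)
  expect_equal(runP$decision[ids], run$decision[ids], tolerance = 1e-8)
})

test_that("degenerate networks and label sets are rejected", {
  ids <- sprintf("N%03d", 1:20)
  empty <- tissueNetwork(ids, matrix(0, 20, 20))
  labs <- new("LabelSet", threshold = 0.01, positives = ids[1:5],
              negatives = ids[6:20], unlabeled = character(0))
  expect_error(netwasSingle(empty, labs, seed = 1), "degenerate")
  labsTiny <- new("LabelSet", threshold = 0.01, positives = ids[1],
                  negatives = ids[2:5], unlabeled = character(0))
  net <- separableNetwork(nGenes = 20, nPos = 5)
  expect_error(netwasSingle(net, labsTiny, seed = 1), "10 labeled")
})

test_that("summed-rank aggregation matches an explicit loop and breaks ties by id", {
  net <- separableNetwork(nGenes = 25, nPos = 5)
  ids <- geneIds(net)
  labs <- suppressMessages(
    buildLabels(toyScores(ids, ids[1:5], seed = 6), net, 0.01))
  runs <- netwasIterate(net, labs, 10, seed = 3)
  agg <- aggregateRanks(runs)
  expect_identical(attr(agg, "nIterations"), 10L)
  for (g in ids) {
    manual <- sum(vapply(runs, function(r) r$rank[[g]], integer(1)))
    expect_identical(agg$summed_rank[agg$gene == g], manual)
  }
  expect_identical(agg$mean_rank, agg$summed_rank / 10)
  # single run: aggregate order equals the run's own order
  agg1 <- aggregateRanks(runs[1])
  expect_identical(agg1$gene, names(sort(runs[[1]]$rank)))

  # two runs with reversed orders of 4 genes -> all tied, lexicographic
  r1 <- list(rank = setNames(1:4, c("d", "b", "c", "a")))
  r2 <- list(rank = setNames(4:1, c("d", "b", "c", "a")))
  aggT <- aggregateRanks(list(r1, r2))
  expect_identical(aggT$gene, c("a", "b", "c", "d"))
  expect_true(all(aggT$summed_rank == 5))

  r3 <- list(rank = setNames(1:4, c("d", "b", "c", "x")))
  expect_error(aggregateRanks(list(r1, r3)), "symmetric difference")
})

test_that("label permutation preserves the p-value multiset", {
  ids <- sprintf("N%03d", 1:500)
  module <- ids[1:50]
  gs <- toyScores(ids, module, seed = 10)
  nPos <- sum(gs$p < 0.01)
  overlaps <- vapply(1:1000, function(i) {
    perm <- permuteLabels(gs, seed = i)
    expect_identical(sort(perm$p), sort(gs$p))
    sum(perm$gene[perm$p < 0.01] %in% module)
  }, numeric(1))
  expect_identical(sum(permuteLabels(gs, 1)$p < 0.01), nPos)
  # expected overlap with the module follows the hypergeometric mean
  m <- length(module)
  expMean <- nPos * m / length(ids)
  hyperVar <- nPos * (m / 500) * (1 - m / 500) * (500 - nPos) / 499
  expect_lt(abs(mean(overlaps) - expMean),
            3 * sqrt(hyperVar / 1000) + 1e-9)
})

test_that("single-model decision values separate a clean module", {
  net <- separableNetwork(nGenes = 24, nPos = 6)
  ids <- geneIds(net)
  dv <- svmDecisionValues(net, positives = ids[1:4], negatives = ids[9:24])
  # unlabeled module members (5 and 6) score with the labeled ones
  expect_gt(min(dv[1:6]), max(dv[7:24]))
})
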