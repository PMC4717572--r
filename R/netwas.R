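#' Build training labels from gene scores
#'
#' Network genes with a gene-based p-value strictly below `threshold`
#' become positive examples; scored network genes at or above it become
#' negatives; network genes without a score (no assigned SNPs, or absent
#' from the score table) stay unlabeled. An error is raised when no gene is
#' nominally significant: a GWAS without an enrichment of small p-values
#' carries no signal for the classifier to learn from.
#'
#' @param geneScores data.frame from [scoreGenes()] (columns `gene`, `p`).
#' @param network a [TissueNetwork-class].
#' @param threshold nominal significance cutoff in `(0, 1)` (default 0.01).
#' @return a [LabelSet-class].
#' @export
buildLabels <- function(geneScores, network, threshold = 0.01) {
  stopifnot(is.data.frame(geneScores),
            all(c("gene", "p") %in% names(geneScores)),
            is(network, "TissueNetwork"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  ids <- geneIds(network)
  scored <- geneScores[!is.na(geneScores$p) & geneScores$gene %in% ids, ]
  pos <- scored$gene[scored$p < threshold]
  neg <- scored$gene[scored$p >= threshold]
  unl <- setdiff(ids, scored$gene)
  if (length(pos) == 0L)
    stop("no gene has p < ", threshold,
         ": the GWAS shows no nominal signal to train on")
  message(sprintf("labels: %d positives, %d negatives, %d unlabeled",
                  length(pos), length(neg), length(unl)))
  new("LabelSet", threshold = threshold, positives = pos,
      negatives = neg, unlabeled = unl)
}

# Linear-kernel Gram matrix over network rows (feature vectors).
networkGram <- function(network) {
  tcrossprod(networkWeights(network))
}

# Fit a weighted soft-margin linear SVM on a kernel submatrix and return the
# decision values for all genes (positive class = higher). The dual is
# solved by the package's compiled SMO (.smoSvcFit) on the precomputed
# Gram, with per-sample box bounds C * inverse-class-frequency weight.
fitFoldSvm <- function(gram, trainIdx, yTrain, cost, tol) {
  yy <- ifelse(yTrain == "positive", 1L, -1L)
  nTr <- length(yy)
  cw <- ifelse(yy == 1L, nTr / (2 * sum(yy == 1L)),
               nTr / (2 * sum(yy == -1L)))
  fit <- .smoSvcFit(gram[trainIdx, trainIdx, drop = FALSE],
                    as.integer(yy), cost * cw, tol = tol)
  drop(gram[, trainIdx, drop = FALSE] %*% (fit$alpha * yy)) - fit$rho
}

#' Decision values from a single SVM fit on all labeled genes
#'
#' Trains one linear soft-margin SVM (inverse-class-frequency weights) on
#' every labeled gene's network row and returns the decision value of every
#' network gene under that model, oriented so that higher values are more
#' disease-like. This is the plain "train, then apply back to the network"
#' operation; [netwasSingle()] wraps the cross-validated variant that
#' scores labeled genes held-out.
#'
#' @param network a [TissueNetwork-class].
#' @param positives,negatives character vectors of labeled gene ids.
#' @param cost SVM soft-margin cost (default 1).
#' @param tol SMO convergence tolerance (default 1e-6).
#' @param gram optional precomputed [networkGram()] output.
#' @return named numeric vector of decision values over all network genes.
#' @export
svmDecisionValues <- function(network, positives, negatives, cost = 1,
                              tol = 1e-6, gram = NULL) {
  stopifnot(is(network, "TissueNetwork"),
            length(positives) > 0L, length(negatives) > 0L,
            !anyDuplicated(c(positives, negatives)))
  ids <- geneIds(network)
  lab <- c(positives, negatives)
  if (!all(lab %in% ids)) stop("labeled genes missing from the network")
  if (is.null(gram)) gram <- networkGram(network)
  y <- rep(c("positive", "negative"),
           c(length(positives), length(negatives)))
  dv <- fitFoldSvm(gram, match(lab, ids), y, cost, tol)
  setNames(dv, ids)
}

#' One NetWAS run: five-fold cross-validated SVM re-ranking
#'
#' Labeled genes are split into five random folds. For each fold a linear
#' soft-margin SVM (cost `cost`, inverse-class-frequency weights) is trained
#' on the other four folds, using each gene's row of the network weight
#' matrix as its feature vector. Every labeled gene receives the decision
#' value from the one model that did not train on it (held-out scoring);
#' unlabeled genes receive the mean decision value over the five fold
#' models. All network genes are then ranked by descending decision value
#' (rank 1 = most disease-like), ties broken lexicographically by gene id.
#'
#' If a random fold ends up with only one class the folds are redrawn (up to
#' 10 attempts) and finally drawn stratified by class. A network whose
#' weights are all zero is rejected.
#'
#' @param network a [TissueNetwork-class] with >= 10 labeled genes.
#' @param labels a [LabelSet-class].
#' @param seed RNG seed for the fold draw.
#' @param cost SVM soft-margin cost (default 1).
#' @param folds optional precomputed integer fold assignment (values 1..5,
#'   named by labeled gene id) overriding the random draw; intended for
#'   tests.
#' @param gram optional precomputed [networkGram()] output, reused across
#'   iterations.
#' @param tol SMO convergence tolerance (default 1e-6).
#' @return list with `decision` (named numeric, all genes), `rank` (named
#'   integer permutation of `1..n`), `folds`, `seed`.
#' @export
netwasSingle <- function(network, labels, seed, cost = 1, folds = NULL,
                         gram = NULL, tol = 1e-6) {
  stopifnot(is(network, "TissueNetwork"), is(labels, "LabelSet"))
  validObject(labels)
  ids <- geneIds(network)
  lab <- c(labels@positives, labels@negatives)
  if (!all(lab %in% ids)) stop("labeled genes missing from the network")
  if (length(lab) < 10L) stop("need at least 10 labeled genes")
  W <- networkWeights(network)
  if (all(W == 0)) stop("degenerate network: all weights are zero")
  if (is.null(gram)) gram <- networkGram(network)
  y <- setNames(rep(c("positive", "negative"),
                    c(length(labels@positives), length(labels@negatives))),
                lab)
  nLab <- length(lab)

  if (is.null(folds)) {
    folds <- withSeed(as.integer(seed), {
      f <- NULL
      for (try in 1:10) {
        cand <- sample(rep(1:5, length.out = nLab))
        ok <- all(vapply(1:5, function(j)
          length(unique(y[cand == j])) == 2L ||
            sum(cand == j) == 0L, logical(1)))
        if (ok) { f <- cand; break }
      }
      if (is.null(f)) {  # stratified fallback
        f <- integer(nLab)
        for (cls in c("positive", "negative")) {
          i <- which(y == cls)
          f[i] <- sample(rep(1:5, length.out = length(i)))
        }
      }
      f
    })
    names(folds) <- lab
  } else {
    stopifnot(all(lab %in% names(folds)))
    folds <- folds[lab]
  }

  labIdx <- match(lab, ids)
  decision <- setNames(numeric(length(ids)), ids)
  unlabIdx <- which(!(ids %in% lab))
  unlabSum <- numeric(length(unlabIdx))
  for (j in 1:5) {
    trainLab <- lab[folds != j]
    dv <- fitFoldSvm(gram, match(trainLab, ids), y[trainLab], cost, tol)
    held <- lab[folds == j]
    decision[held] <- dv[match(held, ids)]
    unlabSum <- unlabSum + dv[unlabIdx]
  }
  decision[unlabIdx] <- unlabSum / 5
  ord <- order(-decision, ids)
  rank <- setNames(integer(length(ids)), ids)
  rank[ord] <- seq_along(ids)
  list(decision = decision, rank = rank, folds = folds,
       seed = as.integer(seed))
}

#' Repeat NetWAS over many cross-validation draws
#'
#' Runs [netwasSingle()] `nIterations` times; iteration `i` uses the child
#' seed derived from `(seed, "netwas", i)`, so runs are independent given
#' the master seed and any single iteration can be reproduced in isolation.
#' The Gram matrix is computed once and shared.
#'
#' @inheritParams netwasSingle
#' @param nIterations number of cross-validation draws (>= 1).
#' @param verbose log progress every 25 iterations.
#' @return list of [netwasSingle()] results, each with an `iteration` field.
#' @export
netwasIterate <- function(network, labels, nIterations, seed, cost = 1,
                          tol = 1e-6, verbose = FALSE) {
  stopifnot(nIterations >= 1)
  gram <- networkGram(network)
  runs <- vector("list", nIterations)
  for (i in seq_len(nIterations)) {
    runs[[i]] <- tryCatch(
      netwasSingle(network, labels, childSeed(seed, "netwas", i),
                   cost = cost, gram = gram, tol = tol),
      error = function(e) stop("iteration ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    runs[[i]]$iteration <- i
    if (verbose && i %% 25L == 0L)
      message("netwas iteration ", i, "/", nIterations)
  }
  runs
}

#' Aggregate NetWAS runs by summed ranks
#'
#' Sums each gene's rank across runs and orders genes by ascending summed
#' rank (ties broken lexicographically by gene id). Because every run ranks
#' the same gene set, the summed-rank and mean-rank (average-score)
#' orderings are identical; both statistics are reported.
#'
#' @param runs list of [netwasSingle()] results over the same gene universe.
#' @return data.frame with columns `gene`, `summed_rank`, `mean_rank`,
#'   `final_rank`, ordered by `final_rank`; attribute `nIterations`.
#' @export
aggregateRanks <- function(runs) {
  stopifnot(length(runs) >= 1)
  universe <- sort(names(runs[[1]]$rank))
  for (r in runs) {
    u <- sort(names(r$rank))
    if (!identical(u, universe)) {
      dif <- c(setdiff(u, universe), setdiff(universe, u))
      stop("runs rank different gene sets; symmetric difference: ",
           paste(dif, collapse = ", "))
    }
  }
  summed <- Reduce(`+`, lapply(runs, function(r) r$rank[universe]))
  ord <- order(summed, universe)
  out <- data.frame(gene = universe[ord],
                    summed_rank = unname(summed[ord]),
                    mean_rank = unname(summed[ord]) / length(runs),
                    final_rank = seq_along(universe),
                    stringsAsFactors = FALSE)
  attr(out, "nIterations") <- length(runs)
  out
}

#' Permute the gene-to-p-value assignment
#'
#' Returns a copy of the score table in which the p-values (and the
#' associated statistics) of the scored genes are reassigned by a uniform
#' random permutation. The multiset of p-values -- and therefore the number
#' of nominally significant genes at any threshold -- is preserved exactly;
#' only which genes carry them changes. Unscored genes stay unscored.
#'
#' @param geneScores data.frame from [scoreGenes()].
#' @param seed RNG seed.
#' @return permuted copy of `geneScores`.
#' @export
permuteLabels <- function(geneScores, seed) {
  stopifnot(is.data.frame(geneScores), all(c("gene", "p") %in% names(geneScores)))
  scored <- which(!is.na(geneScores$p))
  if (length(scored) < 2L) stop("need at least 2 scored genes to permute")
  perm <- withSeed(as.integer(seed), sample(scored))
  out <- geneScores
  movable <- intersect(c("p", "stat", "nSnps", "nSims"), names(geneScores))
  out[scored, movable] <- geneScores[perm, movable]
  out
}

#' Permuted-label NetWAS null runs
#'
#' For each permutation, the gene-to-p assignment is shuffled
#' ([permuteLabels()]), labels are rebuilt at the same threshold, and a
#' single five-fold NetWAS run is performed. The resulting rankings form
#' the null distribution against which the unpermuted NetWAS is compared.
#'
#' @inheritParams netwasSingle
#' @param geneScores data.frame from [scoreGenes()].
#' @param nPermutations number of permuted runs (>= 1).
#' @param threshold nominal significance cutoff (default 0.01).
#' @param verbose log progress every 25 permutations.
#' @return list of [netwasSingle()] results, each with a `permutation` field.
#' @export
permutedNetwas <- function(network, geneScores, nPermutations, seed,
                           threshold = 0.01, cost = 1, tol = 1e-6,
                           verbose = FALSE) {
  stopifnot(nPermutations >= 1)
  gram <- networkGram(network)
  runs <- vector("list", nPermutations)
  for (i in seq_len(nPermutations)) {
    perm <- permuteLabels(geneScores, childSeed(seed, "permute", i))
    labs <- suppressMessages(buildLabels(perm, network, threshold))
    runs[[i]] <- netwasSingle(network, labs,
                              childSeed(seed, "permuted-netwas", i),
                              cost = cost, gram = gram, tol = tol)
    runs[[i]]$permutation <- i
    if (verbose && i %% 25L == 0L)
      message("permutation ", i, "/", nPermutations)
  }
  runs
}
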