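#' ROC AUC of a gene ranking against a gold standard
#'
#' Computed as the Mann-Whitney U statistic with mid-rank tie correction:
#' the probability that a random positive scores above a random negative,
#' plus half the probability of a tie. Scores are "higher = more
#' disease-like"; use [scoresFromRanking()] to convert a rank-ordered table.
#' Evaluation is restricted to the intersection of the ranked genes and the
#' gold-standard universe; an empty positive or negative set after
#' intersection is an error, never a silent 0.5.
#'
#' @param scores named numeric vector (names = gene ids).
#' @param gold a [GoldStandard-class].
#' @return the AUC in `[0, 1]`.
#' @examples
#' gold <- goldStandard(c("a", "c"), universe = letters[1:4])
#' rocAuc(c(a = 4, b = 3, c = 2, d = 1), gold)
#' @export
rocAuc <- function(scores, gold) {
  stopifnot(is.numeric(scores), !is.null(names(scores)),
            is(gold, "GoldStandard"))
  common <- intersect(names(scores), gold@universe)
  s <- scores[common]
  isPos <- common %in% gold@positives
  nPos <- sum(isPos)
  nNeg <- sum(!isPos)
  if (nPos == 0L || nNeg == 0L)
    stop("need at least one positive and one negative after intersecting ",
         "the ranking with the gold-standard universe (got ", nPos, " / ",
         nNeg, ")")
  r <- rank(s)  # midranks
  (sum(r[isPos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Convert a rank-ordered table into evaluation scores
#'
#' @param ranking either an aggregate data.frame from [aggregateRanks()]
#'   (uses `-summed_rank`) or a gene-score data.frame from [scoreGenes()]
#'   (uses `-p` over scored genes).
#' @return named numeric vector, higher = more disease-like.
#' @export
scoresFromRanking <- function(ranking) {
  stopifnot(is.data.frame(ranking), "gene" %in% names(ranking))
  if ("summed_rank" %in% names(ranking))
    return(setNames(-ranking$summed_rank, ranking$gene))
  if ("p" %in% names(ranking)) {
    scored <- ranking[!is.na(ranking$p), ]
    return(setNames(-scored$p, scored$gene))
  }
  stop("ranking must carry a 'summed_rank' or 'p' column")
}

#' Bootstrap confidence interval for the AUC
#'
#' Genes (with their labels attached) are resampled with replacement
#' `nBoot` times and the AUC recomputed per replicate; replicates in which
#' one class is absent are redrawn and counted. The interval is the
#' percentile interval at `ciLevel`.
#'
#' @param scores named numeric vector, higher = more disease-like.
#' @param gold a [GoldStandard-class].
#' @param nBoot bootstrap replicates (>= 100; default 1000).
#' @param ciLevel confidence level (default 0.95).
#' @param seed RNG seed.
#' @param method label stored in the result (e.g. `"gwas"`, `"netwas"`).
#' @return an [EvalResult-class].
#' @export
bootstrapCi <- function(scores, gold, nBoot = 1000L, ciLevel = 0.95,
                        seed = 1L, method = "ranking") {
  if (nBoot < 100L) stop("nBoot must be >= 100")
  auc <- rocAuc(scores, gold)
  common <- intersect(names(scores), gold@universe)
  s <- unname(scores[common])
  isPos <- common %in% gold@positives
  n <- length(s)
  reps <- numeric(nBoot)
  redrawn <- 0L
  withSeed(as.integer(seed), {
    for (b in seq_len(nBoot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        np <- sum(isPos[idx])
        if (np > 0L && np < n) break
        redrawn <- redrawn + 1L
      }
      r <- rank(s[idx])
      np <- sum(isPos[idx])
      reps[b] <- (sum(r[isPos[idx]]) - np * (np + 1) / 2) / (np * (n - np))
    }
  })
  qs <- quantile(reps, c((1 - ciLevel) / 2, 1 - (1 - ciLevel) / 2),
                 names = FALSE, type = 7)
  if (redrawn > 0L)
    message(redrawn, " one-class bootstrap replicate(s) redrawn")
  new("EvalResult", method = method, auc = auc, ciLow = qs[1], ciHigh = qs[2],
      ciLevel = ciLevel, nBoot = as.integer(nBoot),
      nPos = sum(common %in% gold@positives),
      nNeg = sum(!(common %in% gold@positives)), seed = as.integer(seed),
      nRedrawn = redrawn)
}

#' Permutation-null AUC band
#'
#' Computes the AUC of every permuted-label ranking, then a bootstrap
#' percentile confidence interval for the *mean* permuted AUC. A method
#' whose AUC lies above `bandHigh` outperforms the label-permutation null.
#'
#' @param rankings either a list of named score vectors (or of
#'   [netwasSingle()] runs, whose `rank` entries are used) or a plain
#'   numeric vector of precomputed AUCs; at least 30 are required.
#' @param gold a [GoldStandard-class] (ignored when AUCs are supplied).
#' @param ciLevel band confidence level (default 0.95).
#' @param nBoot bootstrap replicates for the mean (default 1000).
#' @param seed RNG seed.
#' @return list with `meanAuc`, `bandLow`, `bandHigh`, `aucs`, `ciLevel`.
#' @export
permutationBand <- function(rankings, gold = NULL, ciLevel = 0.95,
                            nBoot = 1000L, seed = 1L) {
  aucs <- if (is.numeric(rankings)) {
    as.numeric(rankings)
  } else {
    vapply(rankings, function(r) {
      sc <- if (is.list(r) && !is.null(r$rank)) -r$rank
            else if (is.numeric(r)) r
            else stop("unsupported ranking entry")
      rocAuc(sc, gold)
    }, numeric(1))
  }
  if (length(aucs) < 30L) stop("need at least 30 permuted rankings")
  means <- withSeed(as.integer(seed), {
    vapply(seq_len(nBoot), function(b)
      mean(aucs[sample.int(length(aucs), replace = TRUE)]), numeric(1))
  })
  qs <- quantile(means, c((1 - ciLevel) / 2, 1 - (1 - ciLevel) / 2),
                 names = FALSE, type = 7)
  list(meanAuc = mean(aucs), bandLow = qs[1], bandHigh = qs[2],
       aucs = aucs, ciLevel = ciLevel)
}

#' QQ data and genomic-inflation factor for gene p-values
#'
#' Sorts the observed p-values against uniform expected quantiles
#' `i / (n + 1)` and computes the inflation factor
#' `lambda = median(chisq(p_obs)) / median(chisq(1))`, with the chi-square(1)
#' median obtained by quantile inversion at run time rather than from a
#' hard-coded constant. `lambda > 1` indicates an enrichment of small
#' p-values (the precondition for a fruitful network reprioritization).
#'
#' @param genePs numeric vector of p-values in `(0, 1]`, length >= 20.
#' @return list with `observed` (sorted ascending), `expected`
#'   (`i / (n + 1)`), and `lambda`.
#' @export
qqInflation <- function(genePs) {
  genePs <- genePs[!is.na(genePs)]
  if (length(genePs) < 20L) stop("need at least 20 p-values")
  if (any(genePs <= 0) || any(genePs > 1)) stop("p-values must lie in (0, 1]")
  obs <- sort(genePs)
  n <- length(obs)
  expd <- seq_len(n) / (n + 1)
  chiMedianNull <- qchisq(0.5, df = 1, lower.tail = FALSE)
  lambda <- median(chisqFromP(obs)) / chiMedianNull
  list(observed = obs, expected = expd, lambda = lambda)
}

#' Compare GWAS and NetWAS rankings against the gold standard
#'
#' Both rankings must cover the same evaluation universe (network genes
#' with a gene score), so that AUC differences reflect the ranking method
#' rather than gene coverage. Produces an AUC with bootstrap CI per method,
#' carries the permuted-null band through, and reports the qualitative
#' flags of interest: does the network reprioritization beat the raw GWAS
#' ranking, and do either beat the permutation null.
#'
#' @param gwasScores named score vector for the GWAS (gene-p) ranking.
#' @param netwasScores named score vector for the aggregated NetWAS ranking.
#' @param permutedBand output of [permutationBand()].
#' @param gold a [GoldStandard-class].
#' @param nBoot,ciLevel,seed bootstrap settings for the per-method CIs.
#' @return list with `gwas`, `netwas` ([EvalResult-class]), `permuted`
#'   (the band), and logical flags `netwasAboveGwas`,
#'   `netwasAbovePermutedBand`, `gwasAbovePermutedBand`.
#' @export
compareMethods <- function(gwasScores, netwasScores, permutedBand, gold,
                           nBoot = 1000L, ciLevel = 0.95, seed = 1L) {
  if (!setequal(names(gwasScores), names(netwasScores)))
    stop("GWAS and NetWAS rankings cover different gene universes; ",
         "symmetric difference: ",
         paste(c(setdiff(names(gwasScores), names(netwasScores)),
                 setdiff(names(netwasScores), names(gwasScores))),
               collapse = ", "))
  gwasEval <- bootstrapCi(gwasScores, gold, nBoot, ciLevel,
                          seed = childSeed(seed, "boot-gwas"),
                          method = "gwas")
  netwasEval <- bootstrapCi(netwasScores, gold, nBoot, ciLevel,
                            seed = childSeed(seed, "boot-netwas"),
                            method = "netwas")
  list(gwas = gwasEval, netwas = netwasEval, permuted = permutedBand,
       netwasAboveGwas = netwasEval@auc > gwasEval@auc,
       netwasAbovePermutedBand = netwasEval@auc > permutedBand$bandHigh,
       gwasAbovePermutedBand = gwasEval@auc > permutedBand$bandHigh)
}
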