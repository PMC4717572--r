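#' Synthetic network-reprioritization benchmark
#'
#' Constructs the standard parameter-recovery scenario for the two-phase
#' pipeline directly at the gene level: `nGenes` network genes containing a
#' `moduleSize`-gene disease module. Gene-based p-values are uniform on
#' `(0, 1]` for background genes (so about 1% are nominally significant by
#' chance, keeping the labels realistically noisy), while a fraction
#' `labeledFraction` of the module genes receives p drawn uniformly below
#' the nominal threshold -- the genes a GWAS with moderate power would flag.
#' The gold standard is the full module over the full gene universe.
#'
#' The network emulates a probabilistic functional-interaction network
#' rather than an idealized clique: module gene pairs are connected with
#' probability `moduleEdgeProb` and weight drawn uniformly in
#' `moduleWeightRange`, over a background where any pair is connected with
#' probability `backgroundEdgeDensity` and weight uniform in
#' `(0, backgroundWeightMax)`. The two weight distributions overlap, so
#' module membership is only visible as a statistical elevation of
#' connectivity -- strong enough for the classifier to recover the
#' unlabeled module members, but not so coherent that a label permutation
#' can systematically learn (or anti-learn) the module, which would
#' off-center the permutation null.
#'
#' The interesting property of this construction is that most module genes
#' are *not* nominally significant: a ranking that recovers them must
#' exploit their network connectivity, which is what the SVM
#' reprioritization is for. The raw gene-p ranking sets the baseline AUC.
#'
#' @param nGenes total genes (default 1000).
#' @param moduleSize disease-module size (default 50).
#' @param labeledFraction fraction of module genes given p below
#'   `threshold` (default 0.4).
#' @param threshold nominal significance cutoff (default 0.01).
#' @param moduleEdgeProb probability a module gene pair is connected
#'   (default 0.5).
#' @param moduleWeightRange weight range for module edges
#'   (default `c(0.2, 0.6)`).
#' @param backgroundEdgeDensity background edge probability (default 0.3).
#' @param backgroundWeightMax upper bound of background weights
#'   (default 0.4).
#' @param seed RNG seed.
#' @return list with `network` ([TissueNetwork-class]), `geneScores`
#'   (data.frame as from [scoreGenes()]), `gold` ([GoldStandard-class]),
#'   `module` (character), `threshold`.
#' @export
generateBenchmark <- function(nGenes = 1000L, moduleSize = 50L,
                              labeledFraction = 0.4, threshold = 0.01,
                              moduleEdgeProb = 0.5,
                              moduleWeightRange = c(0.2, 0.6),
                              backgroundEdgeDensity = 0.3,
                              backgroundWeightMax = 0.4, seed = 1L) {
  stopifnot(moduleSize <= nGenes, labeledFraction >= 0, labeledFraction <= 1,
            length(moduleWeightRange) == 2L,
            moduleWeightRange[2] <= 1, backgroundWeightMax <= 1)
  ids <- sprintf("G%05d", seq_len(nGenes))
  withSeed(as.integer(seed), {
    module <- sort(sample(ids, moduleSize))
    p <- runif(nGenes)
    labeled <- sample(module, round(labeledFraction * moduleSize))
    p[match(labeled, ids)] <- runif(length(labeled), 0, threshold * 0.99)

    W <- matrix(0, nGenes, nGenes, dimnames = list(ids, ids))
    up <- which(upper.tri(W))
    has <- runif(length(up)) < backgroundEdgeDensity
    W[up[has]] <- runif(sum(has), 0, backgroundWeightMax)
    W <- W + t(W)
    mi <- match(module, ids)
    sub <- matrix(0, moduleSize, moduleSize)
    upM <- which(upper.tri(sub))
    hasM <- runif(length(upM)) < moduleEdgeProb
    sub[upM[hasM]] <- runif(sum(hasM), moduleWeightRange[1],
                            moduleWeightRange[2])
    sub <- sub + t(sub)
    W[mi, mi] <- sub
    diag(W) <- 0

    geneScores <- data.frame(gene = ids, chr = "chr1",
                             nSnps = 1L, stat = chisqFromP(p), p = p,
                             nSims = NA_integer_, seed = as.integer(seed),
                             stringsAsFactors = FALSE)
    list(network = tissueNetwork(ids, W), geneScores = geneScores,
         gold = goldStandard(module, universe = ids,
                             label = "benchmark-disease-module"),
         module = module, threshold = threshold)
  })
}
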