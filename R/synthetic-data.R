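#' Generate synthetic gene models
#'
#' Lays genes out sequentially along one or more chromosomes (100 genes per
#' chromosome) with at least `2 * windowBp` spacing between non-overlapping
#' genes, so assignment windows of distinct genes never collide. If
#' `overlapClusterSize >= 2`, the first genes form one mutually overlapping
#' cluster: starts staggered by 2 kb with a shared 3' end, emulating gene
#' families such as the protocadherin alpha cluster whose members share a
#' constant region. Every pair of cluster genes overlaps, and the cluster
#' shares a common span that captures any SNP placed inside it.
#'
#' @param config a [SimConfig-class].
#' @return a [GenomicRanges::GRanges] with one range per gene, names set to
#'   gene ids, strand `*`, and a logical metadata column `cluster`.
#' @examples
#' genes <- generateGeneModels(simConfig(nGenes = 20, seed = 1))
#' @export
generateGeneModels <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  nGenes <- config@nGenes
  k <- config@overlapClusterSize
  if (nGenes == 0L)
    return(GenomicRanges::GRanges())
  withSeed(childSeed(config@seed, "genes"), {
    ids <- sprintf("G%05d", seq_len(nGenes))
    lens <- as.integer(round(runif(nGenes, 10000, 40000)))
    extra <- as.integer(round(runif(nGenes, 1000, 20000)))
    chrom <- paste0("chr", (seq_len(nGenes) - 1L) %/% 100L + 1L)
    start <- integer(nGenes)
    end <- integer(nGenes)
    isCluster <- rep(FALSE, nGenes)
    gap <- 2L * config@windowBp + 1L
    i <- 1L
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      cursor <- 100000L
      for (j in idx) {
        if (k >= 2L && j == 1L) {
          # the overlap cluster occupies genes 1..k as one staggered locus
          cl <- seq_len(k)
          start[cl] <- cursor + (cl - 1L) * 2000L
          end[cl] <- cursor + (k - 1L) * 2000L + 30000L
          isCluster[cl] <- TRUE
          cursor <- end[k] + gap + extra[j]
        } else if (!isCluster[j]) {
          start[j] <- cursor
          end[j] <- cursor + lens[j] - 1L
          cursor <- end[j] + gap + extra[j]
        }
      }
    }
    gr <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = start, end = end),
      strand = "*",
      cluster = isCluster)
    names(gr) <- ids
    gr
  })
}

#' Generate a synthetic genotype-phenotype cohort
#'
#' Places `snpsPerGene` SNPs uniformly inside each gene body and draws
#' dosages per gene block from thresholded latent Gaussians: within a block
#' the two haplotype latents have exchangeable correlation `ldRho`, and each
#' is thresholded at the quantile of an allele frequency drawn uniformly in
#' `[0.05, 0.5]`, giving Hardy-Weinberg dosages in `{0, 1, 2}` with tunable
#' LD. The phenotype is a linear combination of four independent standard
#' normal covariates (true coefficients 1.0, -0.5, 0.25, 0.8), plus
#' `effectSize` times the dosage of one tagged SNP per causal gene, plus
#' standard normal noise. Causal genes are sampled with their own child
#' seed, so the truth set is reproducible independently of the cohort draw.
#'
#' @param config a [SimConfig-class]; `snpsPerGene` must be >= 1.
#' @param genes gene models from [generateGeneModels()].
#' @return a [SyntheticCohort-class].
#' @export
generateCohort <- function(config, genes) {
  stopifnot(is(config, "SimConfig"), is(genes, "GRanges"))
  validObject(config)
  if (length(genes) == 0L) stop("genes must be non-empty")
  if (config@snpsPerGene < 1L) stop("snpsPerGene must be >= 1")
  n <- config@nSubjects
  k <- config@snpsPerGene
  ids <- names(genes)

  truth <- withSeed(childSeed(config@seed, "truth"), {
    sort(sample(ids, min(config@nDiseaseGenes, length(ids))))
  })

  withSeed(childSeed(config@seed, "cohort"), {
    nSnp <- length(genes) * k
    snpId <- sprintf("rs%06d", seq_len(nSnp))
    snpChr <- character(nSnp)
    snpBp <- integer(nSnp)
    genotypes <- matrix(0L, n, nSnp, dimnames = list(NULL, snpId))
    rho <- config@ldRho
    for (g in seq_along(genes)) {
      cols <- (g - 1L) * k + seq_len(k)
      snpChr[cols] <- as.character(GenomicRanges::seqnames(genes)[g])
      snpBp[cols] <- sort(as.integer(round(runif(
        k, GenomicRanges::start(genes)[g], GenomicRanges::end(genes)[g]))))
      maf <- runif(k, 0.05, 0.5)
      thr <- qnorm(1 - maf)
      dos <- matrix(0L, n, k)
      for (h in 1:2) {  # two haplotypes per subject
        u <- rnorm(n)
        z <- sqrt(rho) * u + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
        dos <- dos + (z > rep(thr, each = n))
      }
      genotypes[, cols] <- dos
    }
    snpTable <- data.frame(SNP = snpId, CHR = snpChr, BP = snpBp,
                           stringsAsFactors = FALSE)

    covariates <- matrix(rnorm(n * 4L), n, 4L,
                         dimnames = list(NULL, c("age", "sex", "edu", "icv")))
    covBeta <- c(1.0, -0.5, 0.25, 0.8)
    phenotype <- drop(covariates %*% covBeta) + rnorm(n)
    tagged <- character(0)
    if (length(truth) && config@effectSize != 0) {
      for (gid in truth) {
        g <- match(gid, ids)
        cols <- (g - 1L) * k + seq_len(k)
        tag <- snpId[sample(cols, 1L)]
        tagged[gid] <- tag
        phenotype <- phenotype + config@effectSize * genotypes[, tag]
      }
    } else if (length(truth)) {
      # still record a tagged SNP per causal gene (first SNP) for diagnostics
      for (gid in truth) {
        g <- match(gid, ids)
        tagged[gid] <- snpId[(g - 1L) * k + 1L]
      }
    }

    new("SyntheticCohort", genotypes = genotypes, phenotype = phenotype,
        covariates = covariates, snpTable = snpTable, truth = truth,
        taggedSnps = tagged, seed = config@seed)
  })
}

#' Generate a tissue-like functional network with an embedded disease module
#'
#' All pairs of disease-module (truth) genes are connected with weight
#' `moduleEdgeWeight`; every other pair receives an edge with probability
#' `backgroundEdgeDensity` and weight drawn uniformly in
#' `(0, moduleEdgeWeight / 2)`. The result is symmetric with a zero diagonal.
#'
#' @param config a [SimConfig-class].
#' @param genes gene models ([GenomicRanges::GRanges]) or a character vector
#'   of gene ids.
#' @param truth character vector of disease-module gene ids (subset of genes).
#' @return a [TissueNetwork-class].
#' @export
generateNetwork <- function(config, genes, truth) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  ids <- if (is.character(genes)) genes else names(genes)
  if (!all(truth %in% ids)) stop("truth must be a subset of the gene ids")
  n <- length(ids)
  withSeed(childSeed(config@seed, "network"), {
    W <- matrix(0, n, n, dimnames = list(ids, ids))
    up <- upper.tri(W)
    nUp <- sum(up)
    hasEdge <- runif(nUp) < config@backgroundEdgeDensity
    w <- numeric(nUp)
    w[hasEdge] <- runif(sum(hasEdge), 0, config@moduleEdgeWeight / 2)
    W[up] <- w
    W <- W + t(W)
    mi <- match(truth, ids)
    W[mi, mi] <- config@moduleEdgeWeight
    diag(W) <- 0
    tissueNetwork(ids, W)
  })
}

#' Sample a gold standard from the disease module
#'
#' A uniformly sampled subset of the truth genes of size
#' `round(goldFraction * length(truth))` becomes the annotated positive set;
#' all other universe genes are gold negatives. This stands in for a curated
#' disease-gene annotation (e.g. OMIM genes mapped to a disease-ontology
#' term) covering only part of the true disease module.
#'
#' @param truth character vector of disease-module gene ids.
#' @param goldFraction fraction of truth genes annotated, in `[0, 1]`.
#' @param seed RNG seed.
#' @param universe evaluation universe (defaults to `truth`; in a full study
#'   pass all simulated gene ids).
#' @param label identifier stored in the standard.
#' @return a [GoldStandard-class].
#' @export
generateGoldStandard <- function(truth, goldFraction, seed,
                                 universe = truth,
                                 label = "synthetic-disease-module") {
  if (goldFraction < 0 || goldFraction > 1)
    stop("goldFraction must be in [0, 1]")
  nPos <- round(goldFraction * length(truth))
  pos <- withSeed(as.integer(seed), sort(sample(truth, nPos)))
  goldStandard(pos, universe = universe, label = label)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running all generators with one configuration:
#' gene models, cohort, functional network over all genes, and a gold
#' standard sampled from the disease module with the full gene set as the
#' evaluation universe.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `genes`, `cohort`, `network`, `gold`, `config`.
#' @examples
#' study <- simulateStudy(simConfig(nSubjects = 100, nGenes = 30,
#'                                  snpsPerGene = 3, nDiseaseGenes = 5,
#'                                  seed = 11))
#' @export
simulateStudy <- function(config) {
  genes <- generateGeneModels(config)
  cohort <- generateCohort(config, genes)
  network <- generateNetwork(config, genes, cohort@truth)
  gold <- generateGoldStandard(cohort@truth, config@goldFraction,
                               childSeed(config@seed, "gold"),
                               universe = names(genes))
  list(genes = genes, cohort = cohort, network = network, gold = gold,
       config = config)
}
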