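#' @import methods
#' @importFrom stats cor median p.adjust pchisq pnorm pt qchisq qnorm quantile
#'   rbinom rnorm runif sd setNames var ks.test
#' @importFrom utils read.table write.table head
NULL

#' Simulation configuration
#'
#' Holds every knob of the synthetic study: cohort size, gene layout,
#' LD structure, genetic effect size, the disease module embedded in the
#' functional network, and the gold-standard coverage. All downstream
#' generators are deterministic given `seed`; per-component child seeds are
#' derived from it by a fixed labelled scheme (see [childSeed()]), so each
#' component can be regenerated independently.
#'
#' @slot nSubjects number of subjects in the cohort.
#' @slot nGenes number of genes to simulate.
#' @slot snpsPerGene SNPs placed inside each gene body.
#' @slot windowBp SNP-to-gene assignment window in base pairs
#'   (50000 on each side by default).
#' @slot ldRho within-block (within-gene) exchangeable latent correlation,
#'   in `[0, 1)`.
#' @slot nDiseaseGenes number of causal genes; these form the disease module
#'   in the functional network.
#' @slot effectSize per-allele phenotype shift of the tagged causal SNP, in
#'   phenotype standard-deviation units.
#' @slot moduleEdgeWeight edge weight among disease-module genes, in `(0, 1]`.
#' @slot backgroundEdgeDensity probability of a background edge.
#' @slot overlapClusterSize number of mutually overlapping genes forming one
#'   protocadherin-like cluster (0 disables).
#' @slot goldFraction fraction of disease-module genes annotated in the
#'   gold standard.
#' @slot seed master RNG seed, recorded in all outputs.
#' @export
setClass("SimConfig", representation(
  nSubjects = "integer",
  nGenes = "integer",
  snpsPerGene = "integer",
  windowBp = "integer",
  ldRho = "numeric",
  nDiseaseGenes = "integer",
  effectSize = "numeric",
  moduleEdgeWeight = "numeric",
  backgroundEdgeDensity = "numeric",
  overlapClusterSize = "integer",
  goldFraction = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(nSubjects = object@nSubjects, nGenes = object@nGenes,
           snpsPerGene = object@snpsPerGene, windowBp = object@windowBp,
           nDiseaseGenes = object@nDiseaseGenes,
           overlapClusterSize = object@overlapClusterSize)
  bad <- names(cnt)[is.na(cnt) | cnt < 0L]
  if (length(bad))
    msg <- c(msg, paste0("counts must be >= 0: ", paste(bad, collapse = ", ")))
  if (is.na(object@ldRho) || object@ldRho < 0 || object@ldRho >= 1)
    msg <- c(msg, "ldRho must be in [0, 1)")
  for (nm in c("backgroundEdgeDensity", "goldFraction")) {
    v <- slot(object, nm)
    if (is.na(v) || v < 0 || v > 1)
      msg <- c(msg, paste0(nm, " must be in [0, 1]"))
  }
  if (is.na(object@moduleEdgeWeight) || object@moduleEdgeWeight <= 0 ||
      object@moduleEdgeWeight > 1)
    msg <- c(msg, "moduleEdgeWeight must be in (0, 1]")
  if (object@overlapClusterSize > object@nGenes)
    msg <- c(msg, "overlapClusterSize exceeds nGenes")
  if (object@overlapClusterSize == 1L)
    msg <- c(msg, "overlapClusterSize must be 0 or >= 2 (a cluster needs two genes)")
  if (object@nDiseaseGenes > object@nGenes)
    msg <- c(msg, "nDiseaseGenes exceeds nGenes")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param nSubjects,nGenes,snpsPerGene,windowBp,ldRho,nDiseaseGenes,effectSize
#'   see [SimConfig-class].
#' @param moduleEdgeWeight,backgroundEdgeDensity,overlapClusterSize see
#'   [SimConfig-class].
#' @param goldFraction,seed see [SimConfig-class].
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nSubjects = 200, nGenes = 50, seed = 7)
#' @export
simConfig <- function(nSubjects = 500L, nGenes = 200L, snpsPerGene = 10L,
                      windowBp = 50000L, ldRho = 0.5, nDiseaseGenes = 20L,
                      effectSize = 0.5, moduleEdgeWeight = 0.9,
                      backgroundEdgeDensity = 0.05, overlapClusterSize = 0L,
                      goldFraction = 1.0, seed = 1L) {
  new("SimConfig",
      nSubjects = as.integer(nSubjects), nGenes = as.integer(nGenes),
      snpsPerGene = as.integer(snpsPerGene), windowBp = as.integer(windowBp),
      ldRho = as.numeric(ldRho), nDiseaseGenes = as.integer(nDiseaseGenes),
      effectSize = as.numeric(effectSize),
      moduleEdgeWeight = as.numeric(moduleEdgeWeight),
      backgroundEdgeDensity = as.numeric(backgroundEdgeDensity),
      overlapClusterSize = as.integer(overlapClusterSize),
      goldFraction = as.numeric(goldFraction), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSubjects, "subjects,", object@nGenes, "genes x",
      object@snpsPerGene, "SNPs, ldRho =", object@ldRho,
      ", effectSize =", object@effectSize, "\n")
  cat("  disease module:", object@nDiseaseGenes, "genes (edge weight",
      object@moduleEdgeWeight, "), overlap cluster:",
      object@overlapClusterSize, ", seed:", object@seed, "\n")
})

#' Synthetic cohort: genotypes, phenotype, covariates
#'
#' Dosage genotypes in `{0, 1, 2}` with within-gene LD, a continuous
#' (hippocampal-volume-like) phenotype driven by four covariates plus one
#' tagged causal SNP per disease gene, and the causal truth.
#'
#' @slot genotypes subjects x SNPs dosage matrix, entries in `{0, 1, 2}`.
#' @slot phenotype numeric trait per subject.
#' @slot covariates subjects x 4 matrix (age-, sex-, education-, ICV-like).
#' @slot snpTable data.frame with columns `SNP`, `CHR`, `BP` (1-based).
#' @slot truth character vector of causal gene ids.
#' @slot taggedSnps named character vector mapping causal gene -> tagged SNP.
#' @slot seed master seed the cohort was generated from.
#' @export
setClass("SyntheticCohort", representation(
  genotypes = "matrix",
  phenotype = "numeric",
  covariates = "matrix",
  snpTable = "data.frame",
  truth = "character",
  taggedSnps = "character",
  seed = "integer"
))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (!all(object@genotypes %in% c(0, 1, 2)))
    msg <- c(msg, "dosages must be in {0, 1, 2}")
  if (anyNA(object@covariates))
    msg <- c(msg, "covariates must have no missing entries")
  if (nrow(object@genotypes) != length(object@phenotype))
    msg <- c(msg, "genotype rows must match phenotype length")
  if (ncol(object@genotypes) != nrow(object@snpTable))
    msg <- c(msg, "genotype columns must match snpTable rows")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@genotypes), "subjects x",
      ncol(object@genotypes), "SNPs;", length(object@truth),
      "causal genes; seed", object@seed, "\n")
})

#' Weighted tissue-specific functional network
#'
#' Symmetric gene-gene weight matrix with zero diagonal and weights in
#' `[0, 1]`; a gene's feature vector for the NetWAS classifier is its row.
#'
#' @slot geneIds ordered node (gene) identifiers.
#' @slot weights symmetric numeric matrix, `dimnames` equal to `geneIds`.
#' @export
setClass("TissueNetwork", representation(
  geneIds = "character",
  weights = "matrix"
))

setValidity("TissueNetwork", function(object) {
  W <- object@weights
  msg <- character()
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "gene ids must be unique")
  if (nrow(W) != length(object@geneIds) || ncol(W) != length(object@geneIds))
    msg <- c(msg, "weight matrix dimensions must match geneIds")
  else {
    if (!isTRUE(all.equal(W, t(W), tolerance = 1e-12, check.attributes = FALSE)))
      msg <- c(msg, "weight matrix must be symmetric")
    if (any(diag(W) != 0))
      msg <- c(msg, "diagonal must be zero (no self-loops)")
    if (any(W < 0) || any(W > 1))
      msg <- c(msg, "weights must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TissueNetwork
#' @param geneIds character node ids.
#' @param weights symmetric weight matrix in `[0, 1]`, zero diagonal.
#' @return a [TissueNetwork-class].
#' @export
tissueNetwork <- function(geneIds, weights) {
  dimnames(weights) <- list(geneIds, geneIds)
  new("TissueNetwork", geneIds = as.character(geneIds), weights = weights)
}

#' @describeIn TissueNetwork-class node identifiers.
#' @param object,x a `TissueNetwork`.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setMethod("geneIds", "TissueNetwork", function(x) x@geneIds)

#' @describeIn TissueNetwork-class the symmetric weight matrix.
#' @export
setGeneric("networkWeights", function(x) standardGeneric("networkWeights"))

#' @export
setMethod("networkWeights", "TissueNetwork", function(x) x@weights)

setMethod("show", "TissueNetwork", function(object) {
  W <- object@weights
  ne <- sum(W[upper.tri(W)] > 0)
  cat("TissueNetwork:", length(object@geneIds), "genes,", ne,
      "weighted edges (density",
      signif(ne / choose(length(object@geneIds), 2), 3), ")\n")
})

#' Training labels for network reprioritization
#'
#' Scored network genes partitioned by nominal gene-level significance:
#' positives have gene p below the threshold (strict), negatives are the
#' remaining scored genes, and network genes without a gene score stay
#' unlabeled (never used for training, always ranked).
#'
#' @slot threshold nominal p-value cutoff (default 0.01).
#' @slot positives,negatives,unlabeled character vectors of gene ids.
#' @export
setClass("LabelSet", representation(
  threshold = "numeric",
  positives = "character",
  negatives = "character",
  unlabeled = "character"
))

setValidity("LabelSet", function(object) {
  msg <- character()
  if (length(intersect(object@positives, object@negatives)))
    msg <- c(msg, "positives and negatives must be disjoint")
  if (length(object@positives) == 0L)
    msg <- c(msg, "positives must be non-empty for training")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LabelSet", function(object) {
  cat("LabelSet (p <", object@threshold, "):",
      length(object@positives), "positives,",
      length(object@negatives), "negatives,",
      length(object@unlabeled), "unlabeled\n")
})

#' Gold-standard disease gene annotation
#'
#' @slot label free-text identifier of the standard.
#' @slot positives annotated disease gene ids.
#' @slot universe gene ids over which negatives are defined.
#' @export
setClass("GoldStandard", representation(
  label = "character",
  positives = "character",
  universe = "character"
))

setValidity("GoldStandard", function(object) {
  if (!all(object@positives %in% object@universe))
    "positives must be a subset of the universe"
  else TRUE
})

#' Construct a GoldStandard
#' @param positives annotated gene ids.
#' @param universe evaluation universe (defaults to `positives`).
#' @param label free-text identifier.
#' @return a [GoldStandard-class].
#' @export
goldStandard <- function(positives, universe = positives,
                         label = "gold-standard") {
  new("GoldStandard", label = label,
      positives = unique(as.character(positives)),
      universe = unique(as.character(universe)))
}

setMethod("show", "GoldStandard", function(object) {
  cat("GoldStandard '", object@label, "': ", length(object@positives),
      " positives / ", length(object@universe), " universe genes\n", sep = "")
})

#' AUC evaluation result with bootstrap confidence interval
#'
#' @slot method one of `gwas`, `netwas`, `netwas_permuted` (free text allowed).
#' @slot auc area under the ROC curve in `[0, 1]` (midrank tie correction).
#' @slot ciLow,ciHigh percentile bootstrap bounds.
#' @slot ciLevel confidence level (default 0.95).
#' @slot nBoot bootstrap replicates used.
#' @slot nPos,nNeg evaluation counts after universe intersection.
#' @slot seed bootstrap RNG seed.
#' @slot nRedrawn replicates redrawn because one class was absent.
#' @export
setClass("EvalResult", representation(
  method = "character",
  auc = "numeric",
  ciLow = "numeric",
  ciHigh = "numeric",
  ciLevel = "numeric",
  nBoot = "integer",
  nPos = "integer",
  nNeg = "integer",
  seed = "integer",
  nRedrawn = "integer"
))

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult [%s]: AUC = %.4f (%d%% CI %.4f-%.4f, %d bootstraps; %d pos / %d neg)\n",
              object@method, object@auc, round(100 * object@ciLevel),
              object@ciLow, object@ciHigh, object@nBoot,
              object@nPos, object@nNeg))
})

#' Per-gene LD (correlation) matrix
#'
#' Pearson correlation of dosage columns for the SNPs assigned to one gene,
#' made positive semidefinite by eigenvalue clipping and rescaling to a unit
#' diagonal. The repair magnitude (largest absolute eigenvalue adjustment)
#' is retained so heavy repairs are visible.
#'
#' @slot snpIds ordered SNP identifiers.
#' @slot R symmetric correlation matrix with unit diagonal.
#' @slot source `"genotypes"` or `"provided"`.
#' @slot repair largest absolute eigenvalue adjustment applied.
#' @export
setClass("LdMatrix", representation(
  snpIds = "character",
  R = "matrix",
  source = "character",
  repair = "numeric"
))

setValidity("LdMatrix", function(object) {
  msg <- character()
  R <- object@R
  if (nrow(R) != length(object@snpIds) || ncol(R) != length(object@snpIds))
    msg <- c(msg, "R dimensions must match snpIds")
  else {
    if (any(abs(R) > 1 + 1e-8)) msg <- c(msg, "|R_ij| must be <= 1")
    if (max(abs(R - t(R))) > 1e-10) msg <- c(msg, "R must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "LdMatrix", function(object) {
  cat("LdMatrix:", length(object@snpIds), "SNPs, source =", object@source,
      ", PSD repair magnitude =", signif(object@repair, 3), "\n")
})
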