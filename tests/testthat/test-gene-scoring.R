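toyGenes <- function() {
  gr <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2"),
                               IRanges::IRanges(c(1e6, 2e6, 1e6),
                                                c(1.02e6, 2.05e6, 1.01e6)))
  names(gr) <- c("gA", "gB", "gC")
  gr
}

test_that("window boundaries are inclusive at exactly +/- windowBp", {
  genes <- toyGenes()
  snps <- data.frame(SNP = c("in_lo", "out_lo", "in_hi", "out_hi"),
                     CHR = "chr1",
                     BP = c(1e6 - 50000, 1e6 - 50001,
                            1.02e6 + 50000, 1.02e6 + 50001))
  asg <- assignSnps(snps, genes, windowBp = 50000)
  expect_identical(asg$gA, c("in_lo", "in_hi"))
})

test_that("assignment matches the exhaustive interval oracle, multi-mapping kept", {
  cfg <- simConfig(nGenes = 25, overlapClusterSize = 15, snpsPerGene = 2,
                   nDiseaseGenes = 0, seed = 61)
  genes <- generateGeneModels(cfg)
  coh <- generateCohort(simConfig(nSubjects = 50, nGenes = 25,
                                  overlapClusterSize = 15, snpsPerGene = 2,
                                  nDiseaseGenes = 0, seed = 61), genes)
  asg <- assignSnps(coh@snpTable, genes, windowBp = 50000)
  genesDf <- data.frame(gene = names(genes),
                        chrom = as.character(GenomicRanges::seqnames(genes)),
                        start = GenomicRanges::start(genes),
                        end = GenomicRanges::end(genes))
  oracle <- bruteAssign(coh@snpTable, genesDf, windowBp = 50000)
  expect_identical(asg[names(oracle)], oracle, ignore_attr = TRUE)
  # the cluster genes each capture the SNPs of the shared span
  cl <- names(genes)[genes$cluster]
  counts <- lengths(asg[cl])
  expect_true(all(counts >= 2 * 15 / 2))  # far beyond their own 2 SNPs
})

test_that("duplicate SNPs are an error, foreign chromosomes a warning", {
  genes <- toyGenes()
  dup <- data.frame(SNP = c("s1", "s1"), CHR = "chr1", BP = c(1e6, 1.1e6))
  expect_error(assignSnps(dup, genes), "duplicate")
  alien <- data.frame(SNP = c("s1", "s2"), CHR = c("chr1", "chrX"),
                      BP = c(1e6, 5e5))
  expect_warning(asg <- assignSnps(alien, genes), "chrX")
  expect_identical(asg$gA, "s1")
})

test_that("chi-square transform inverts the survival function", {
  expect_identical(chisqFromP(1), 0)
  # independent numerical inversion of the chi-square(1) survival function
  inv <- uniroot(function(x) pchisq(x, 1, lower.tail = FALSE) - 0.05,
                 c(0, 100), tol = 1e-12)$root
  expect_equal(chisqFromP(0.05), inv, tolerance = 1e-10)
  for (p in c(0.5, 0.01, 1e-6))
    expect_equal(pchisq(chisqFromP(p), 1, lower.tail = FALSE), p,
                 tolerance = 1e-12)
  expect_error(chisqFromP(0), "0, 1")
  expect_error(chisqFromP(1.01), "0, 1")
  expect_warning(chisqFromP(1e-310), "clamp")
})

test_that("LD estimation: perfect LD, independence, PSD repair", {
  set.seed(3)
  x <- rbinom(2000, 2, 0.3)
  dup <- cbind(a = x, b = x, c = rbinom(2000, 2, 0.4))
  ld <- ldFromGenotypes(dup)
  expect_equal(ld@R["a", "b"], 1.0, tolerance = 1e-12)
  ind <- sapply(1:6, function(i) rbinom(2000, 2, 0.3))
  colnames(ind) <- paste0("s", 1:6)
  R <- ldFromGenotypes(ind)@R
  expect_lt(max(abs(R[upper.tri(R)])), 0.1)
  expect_error(ldFromGenotypes(dup[1, , drop = FALSE]), "2 subjects")

  # deliberately indefinite matrix becomes PSD with unit diagonal
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_lt(min(eigen(bad)$values), 0)
  fixed <- ldFromMatrix(bad)
  expect_gte(min(eigen(fixed@R)$values), -1e-12)
  expect_equal(unname(diag(fixed@R)), rep(1, 3))
  expect_gt(fixed@repair, 0)
})

test_that("gene p: single SNP recovers the SNP p; order invariance; monotone", {
  snpP <- c(s1 = 0.012)
  ld <- ldFromMatrix(matrix(1, 1, 1, dimnames = list("s1", "s1")))
  res <- geneP("s1", snpP, ld, stages = 1e5, seed = 7)
  se <- sqrt(0.012 * 0.988 / 1e5)
  expect_lt(abs(res$p - 0.012), 3 * se)

  # permuting SNPs (and R with them) leaves the gene p unchanged
  set.seed(11)
  k <- 4
  R <- ldFromMatrix(cor(matrix(rnorm(200 * k), 200, k)))@R
  ids <- paste0("s", 1:k)
  dimnames(R) <- list(ids, ids)
  ps <- setNames(runif(k, 0.001, 0.5), ids)
  r1 <- geneP(ids, ps, ldFromMatrix(R), stages = 1e4, seed = 3)
  perm <- c(3, 1, 4, 2)
  r2 <- geneP(ids[perm], ps, ldFromMatrix(R[perm, perm]), stages = 1e4,
              seed = 3)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
  expect_equal(r1$stat, r2$stat, tolerance = 1e-12)

  # for a fixed null, p is monotone non-increasing in the statistic
  psLow <- setNames(rep(0.5, k), ids)
  psHigh <- setNames(rep(0.01, k), ids)
  pLow <- geneP(ids, psLow, ldFromMatrix(R), stages = 1e4, seed = 3)$p
  pHigh <- geneP(ids, psHigh, ldFromMatrix(R), stages = 1e4, seed = 3)$p
  expect_gte(pLow, pHigh)

  expect_null(geneP(character(0), snpP, ld))
})

test_that("adaptive staging escalates only for small p and stays reproducible", {
  ld1 <- ldFromMatrix(diag(1), "s1")
  big <- geneP("s1", c(s1 = 0.6), ld1, stages = c(1e3, 1e4), seed = 5)
  expect_identical(big$nSims, 1000L)
  small <- geneP("s1", c(s1 = 1e-4), ld1, stages = c(1e3, 1e4), seed = 5)
  expect_identical(small$nSims, 10000L)
  again <- geneP("s1", c(s1 = 1e-4), ld1, stages = c(1e3, 1e4), seed = 5)
  expect_identical(small$p, again$p)
  expect_gt(small$p, 0)  # (r+1)/(n+1) never returns exactly zero
  expect_gte(small$p, 1 / (1 + 10000))
})

test_that("unscored genes are listed, never silently p = 1", {
  genes <- toyGenes()
  snps <- data.frame(SNP = c("s1", "s2"), CHR = "chr1", BP = c(1e6, 1.01e6))
  set.seed(2)
  coh <- new("SyntheticCohort",
             genotypes = matrix(rbinom(200, 2, 0.4), 100, 2,
                                dimnames = list(NULL, c("s1", "s2"))),
             phenotype = rnorm(100),
             covariates = matrix(rnorm(400), 100, 4,
                                 dimnames = list(NULL, letters[1:4])),
             snpTable = snps, truth = character(0),
             taggedSnps = character(0), seed = 2L)
  assoc <- snpAssociation(coh)
  gs <- scoreGenes(assoc, genes, cohort = coh, stages = 500, seed = 3)
  expect_identical(gs$nSnps[gs$gene == "gC"], 0L)
  expect_true(is.na(gs$p[gs$gene == "gC"]))
  expect_false(anyNA(gs$p[gs$gene == "gA"]))
})

test_that("multi-mapping diagnostic isolates gene clusters sharing significant SNPs", {
  asg <- list(gA = c("s1", "s2"), gB = c("s2", "s3"), gC = "s4", gD = "s5")
  ps <- c(s1 = 0.5, s2 = 1e-6, s3 = 0.2, s4 = 1e-7, s5 = 0.9)
  out <- multiMappingDiagnostic(asg, ps, alphaSnp = 1e-3)
  expect_length(out, 1)
  expect_identical(out[[1]]$genes, c("gA", "gB"))
  expect_identical(out[[1]]$snps, "s2")
  # no significant SNP -> empty; singleton components excluded
  expect_length(multiMappingDiagnostic(asg, ps, alphaSnp = 1e-8), 0)
  ps2 <- c(s1 = 0.5, s2 = 0.5, s3 = 0.5, s4 = 1e-7, s5 = 1e-7)
  expect_length(multiMappingDiagnostic(asg, ps2, alphaSnp = 1e-3), 0)
})
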