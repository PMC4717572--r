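test_that("config validation rejects out-of-range knobs", {
  expect_error(simConfig(ldRho = 1), "ldRho")
  expect_error(simConfig(goldFraction = 1.2), "goldFraction")
  expect_error(simConfig(nGenes = 10, overlapClusterSize = 15), "overlapClusterSize")
  expect_error(simConfig(moduleEdgeWeight = 0), "moduleEdgeWeight")
})

test_that("gene layout keeps non-overlapping genes apart and clusters together", {
  cfg <- simConfig(nGenes = 30, overlapClusterSize = 0, seed = 4)
  genes <- generateGeneModels(cfg)
  hits <- GenomicRanges::findOverlaps(genes, genes)
  expect_true(all(S4Vectors::queryHits(hits) == S4Vectors::subjectHits(hits)))

  cfg15 <- simConfig(nGenes = 40, overlapClusterSize = 15, seed = 4)
  g15 <- generateGeneModels(cfg15)
  cl <- g15[g15$cluster]
  expect_length(cl, 15)
  # pairwise overlap, verified exhaustively
  st <- GenomicRanges::start(cl); en <- GenomicRanges::end(cl)
  for (i in 1:14) for (j in (i + 1):15)
    expect_true(st[i] <= en[j] && st[j] <= en[i])
  # every SNP placed inside the shared span is captured by all 15 genes
  shared <- c(max(st), min(en))
  expect_true(shared[1] <= shared[2])
  probe <- data.frame(SNP = paste0("s", 1:5),
                      CHR = as.character(GenomicRanges::seqnames(cl))[1],
                      BP = round(seq(shared[1], shared[2], length.out = 5)))
  genesDf <- data.frame(gene = names(g15),
                        chrom = as.character(GenomicRanges::seqnames(g15)),
                        start = GenomicRanges::start(g15),
                        end = GenomicRanges::end(g15))
  oracle <- bruteAssign(probe, genesDf, windowBp = 50000)
  for (g in names(cl)) expect_identical(oracle[[g]], probe$SNP)

  g1 <- generateGeneModels(simConfig(nGenes = 1, nDiseaseGenes = 0, seed = 2))
  expect_length(g1, 1)
  expect_false(any(g1$cluster))
})

test_that("generators are byte-identical under the same seed", {
  cfg <- simConfig(nSubjects = 60, nGenes = 12, snpsPerGene = 3,
                   nDiseaseGenes = 3, overlapClusterSize = 4, seed = 77)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(a$genes, b$genes)
  expect_identical(a$cohort@genotypes, b$cohort@genotypes)
  expect_identical(a$cohort@phenotype, b$cohort@phenotype)
  expect_identical(networkWeights(a$network), networkWeights(b$network))
  expect_identical(a$gold@positives, b$gold@positives)
})

test_that("dosages are {0,1,2}; ld_rho controls within-block correlation", {
  genes <- generateGeneModels(simConfig(nGenes = 2, nDiseaseGenes = 0,
                                        seed = 8))
  coh0 <- generateCohort(simConfig(nSubjects = 2000, nGenes = 2,
                                   snpsPerGene = 5, ldRho = 0,
                                   nDiseaseGenes = 0, seed = 8), genes)
  expect_true(all(coh0@genotypes %in% 0:2))
  r0 <- cor(coh0@genotypes[, 1:5])
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.1)

  coh9 <- generateCohort(simConfig(nSubjects = 2000, nGenes = 2,
                                   snpsPerGene = 5, ldRho = 0.9,
                                   nDiseaseGenes = 0, seed = 8), genes)
  # thresholding attenuates the latent correlation (more so at extreme
  # MAFs), but high ld_rho must stay clearly separated from the null case
  r9 <- cor(coh9@genotypes[, 1:5])
  expect_gt(min(r9[upper.tri(r9)]), 0.25)
})

test_that("tagged causal SNPs carry the association signal", {
  cfg <- simConfig(nSubjects = 800, nGenes = 50, snpsPerGene = 4,
                   nDiseaseGenes = 10, effectSize = 0.5, seed = 21)
  st <- simulateStudy(cfg)
  assoc <- suppressWarnings(snpAssociation(st$cohort))
  tagP <- assoc$P[match(st$cohort@taggedSnps, assoc$SNP)]
  expect_lt(median(tagP), median(assoc$P))
})

test_that("null cohort p-values are uniform and LD blocks need no PSD repair", {
  cfg <- simConfig(nSubjects = 500, nGenes = 500, snpsPerGene = 10,
                   nDiseaseGenes = 0, effectSize = 0, ldRho = 0.5, seed = 31)
  genes <- generateGeneModels(cfg)
  coh <- generateCohort(cfg, genes)
  assoc <- suppressWarnings(snpAssociation(coh))
  # fraction of p < 0.01 within 3 binomial SEs of 0.01 (5000 SNPs)
  frac <- mean(assoc$P < 0.01)
  se <- sqrt(0.01 * 0.99 / nrow(assoc))
  expect_lt(abs(frac - 0.01), 3 * se)
  # sample correlation of a dosage block is PSD: repair is a near-no-op
  for (g in c(1, 250, 500)) {
    cols <- (g - 1) * 10 + 1:10
    ld <- ldFromGenotypes(coh@genotypes[, cols])
    expect_lt(ld@repair, 1e-6)
  }
})

test_that("network has the promised module / background structure", {
  cfg <- simConfig(nGenes = 100, nDiseaseGenes = 10, moduleEdgeWeight = 0.8,
                   backgroundEdgeDensity = 0.05, seed = 12)
  genes <- generateGeneModels(cfg)
  truth <- names(genes)[11:20]
  net <- generateNetwork(cfg, genes, truth)
  W <- networkWeights(net)
  expect_identical(W, t(W))
  expect_true(all(diag(W) == 0))
  mi <- match(truth, geneIds(net))
  expect_true(all(W[mi, mi][upper.tri(W[mi, mi])] == 0.8))
  # module degree dominates background degree
  deg <- rowSums(W)
  expect_gt(mean(deg[mi]), mean(deg[-mi]))
  # limiting case: no background -> exactly one clique on truth
  cfg0 <- simConfig(nGenes = 100, nDiseaseGenes = 10, moduleEdgeWeight = 1,
                    backgroundEdgeDensity = 0, seed = 12)
  net0 <- generateNetwork(cfg0, genes, truth)
  W0 <- networkWeights(net0)
  expect_true(all(W0[mi, mi][upper.tri(W0[mi, mi])] == 1))
  expect_identical(sum(W0 > 0), 10L * 9L)
})

test_that("gold standard sampling respects the annotated fraction", {
  truth <- sprintf("G%03d", 1:50)
  expect_identical(sort(generateGoldStandard(truth, 1, 3)@positives), truth)
  g0 <- generateGoldStandard(truth, 0, 3)
  expect_length(g0@positives, 0)
  expect_length(generateGoldStandard(truth, 0.5, 3)@positives, 25)
  # degenerate empty positive set must break AUC loudly downstream
  expect_error(rocAuc(setNames(runif(50), truth), g0), "positive")
})
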