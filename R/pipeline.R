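#' Validated end-to-end run configuration
#'
#' Bundles the simulation configuration with every stage parameter of the
#' two-phase pipeline. All numeric fields are validated here, before any
#' stage runs, so an invalid setting fails fast instead of after an
#' expensive simulation.
#'
#' @slot sim a [SimConfig-class].
#' @slot windowBp SNP-to-gene window in bp.
#' @slot threshold nominal significance cutoff in `(0, 1)`.
#' @slot nIterations NetWAS cross-validation draws.
#' @slot nPermutations permuted-label null runs.
#' @slot nBoot bootstrap replicates for AUC CIs.
#' @slot ciLevel confidence level in `(0, 1)`.
#' @slot svmCost SVM soft-margin cost (> 0).
#' @slot mcStages Monte Carlo staging for the gene test.
#' @slot seed master seed.
#' @slot verbose progress logging flag.
#' @export
setClass("RunConfig", representation(
  sim = "SimConfig",
  windowBp = "integer",
  threshold = "numeric",
  nIterations = "integer",
  nPermutations = "integer",
  nBoot = "integer",
  ciLevel = "numeric",
  svmCost = "numeric",
  mcStages = "numeric",
  seed = "integer",
  verbose = "logical"
))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@windowBp < 0L) msg <- c(msg, "windowBp must be >= 0")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must be in (0, 1)")
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
  if (object@nPermutations < 30L)
    msg <- c(msg, "nPermutations must be >= 30 (permutation band)")
  if (object@nBoot < 100L) msg <- c(msg, "nBoot must be >= 100")
  if (object@ciLevel <= 0 || object@ciLevel >= 1)
    msg <- c(msg, "ciLevel must be in (0, 1)")
  if (object@svmCost <= 0) msg <- c(msg, "svmCost must be > 0")
  if (any(object@mcStages < 100)) msg <- c(msg, "mcStages must be >= 100")
  if (length(msg)) msg else TRUE
})

#' Create a run configuration
#' @param sim a [SimConfig-class].
#' @param windowBp,threshold,nIterations,nPermutations see
#'   [RunConfig-class].
#' @param nBoot,ciLevel,svmCost,mcStages,seed,verbose see
#'   [RunConfig-class].
#' @return a validated [RunConfig-class].
#' @export
runConfig <- function(sim = simConfig(), windowBp = 50000L,
                      threshold = 0.01, nIterations = 100L,
                      nPermutations = 100L, nBoot = 1000L, ciLevel = 0.95,
                      svmCost = 1, mcStages = c(1e3, 1e4, 1e5),
                      seed = 1L, verbose = FALSE) {
  new("RunConfig", sim = sim, windowBp = as.integer(windowBp),
      threshold = as.numeric(threshold),
      nIterations = as.integer(nIterations),
      nPermutations = as.integer(nPermutations), nBoot = as.integer(nBoot),
      ciLevel = as.numeric(ciLevel), svmCost = as.numeric(svmCost),
      mcStages = as.numeric(mcStages), seed = as.integer(seed),
      verbose = isTRUE(verbose))
}

configAsList <- function(config) {
  s <- config@sim
  list(sim = list(nSubjects = s@nSubjects, nGenes = s@nGenes,
                  snpsPerGene = s@snpsPerGene, windowBp = s@windowBp,
                  ldRho = s@ldRho, nDiseaseGenes = s@nDiseaseGenes,
                  effectSize = s@effectSize,
                  moduleEdgeWeight = s@moduleEdgeWeight,
                  backgroundEdgeDensity = s@backgroundEdgeDensity,
                  overlapClusterSize = s@overlapClusterSize,
                  goldFraction = s@goldFraction, seed = s@seed),
       windowBp = config@windowBp, threshold = config@threshold,
       nIterations = config@nIterations,
       nPermutations = config@nPermutations, nBoot = config@nBoot,
       ciLevel = config@ciLevel, svmCost = config@svmCost,
       mcStages = config@mcStages, seed = config@seed)
}

#' Run the full two-phase pipeline on a synthetic study
#'
#' Executes, in order: simulation, per-SNP association testing, gene-based
#' scoring, NetWAS iteration and aggregation, the permuted-label null, and
#' AUC evaluation against the gold standard. Every stage writes its
#' checkpointed artifact into `outDir` (association table, gene-score CSV,
#' `combined-results.csv`, evaluation CSV, QQ data), along with the echoed
#' configuration and a manifest recording the package version, seeds, input
#' digests and stage counts. Reruns with an identical configuration produce
#' byte-identical outputs.
#'
#' @param config a [RunConfig-class].
#' @param outDir output directory (created; pre-existing files are
#'   overwritten).
#' @return invisibly, a list with the in-memory stage results (`study`,
#'   `assoc`, `geneScores`, `aggregate`, `report`, `qq`, `paths`).
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  validObject(config@sim)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (config@verbose) message(...)
  paths <- list(
    config = file.path(outDir, "config.json"),
    genes = file.path(outDir, "genes.bed"),
    network = file.path(outDir, "network.tsv"),
    gold = file.path(outDir, "gold-standard.txt"),
    assoc = file.path(outDir, "gwas.qassoc"),
    geneScores = file.path(outDir, "gene-scores.csv"),
    aggregate = file.path(outDir, "combined-results.csv"),
    evaluation = file.path(outDir, "evaluation.csv"),
    qq = file.path(outDir, "qq.csv"),
    manifest = file.path(outDir, "manifest.json"))

  jsonlite::write_json(configAsList(config), paths$config,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  stage <- "simulate"
  result <- tryCatch({
    log("stage: simulate")
    study <- simulateStudy(config@sim)
    writeGeneModels(study$genes, paths$genes)
    writeNetwork(study$network, paths$network)
    writeGoldStandard(study$gold, paths$gold)

    stage <- "gwas"
    log("stage: gwas (", ncol(study$cohort@genotypes), " SNPs)")
    assoc <- suppressWarnings(snpAssociation(study$cohort))
    writeAssocTable(assoc, paths$assoc)

    stage <- "vegas"
    log("stage: gene scoring")
    geneScores <- scoreGenes(assoc, study$genes, cohort = study$cohort,
                             windowBp = config@windowBp,
                             stages = config@mcStages,
                             seed = childSeed(config@seed, "vegas"))
    writeGeneScores(geneScores, paths$geneScores)
    qq <- qqInflation(geneScores$p[!is.na(geneScores$p)])
    write.table(data.frame(observed = fmtNum(qq$observed),
                           expected = fmtNum(qq$expected)),
                paths$qq, sep = ",", quote = FALSE, row.names = FALSE)

    stage <- "netwas"
    log("stage: netwas (", config@nIterations, " iterations)")
    labels <- suppressMessages(
      buildLabels(geneScores, study$network, config@threshold))
    runs <- netwasIterate(study$network, labels, config@nIterations,
                          childSeed(config@seed, "netwas-master"),
                          cost = config@svmCost, verbose = config@verbose)
    aggregate <- aggregateRanks(runs)
    writeAggregate(aggregate, paths$aggregate)

    stage <- "permute"
    log("stage: permuted null (", config@nPermutations, " permutations)")
    permRuns <- permutedNetwas(study$network, geneScores,
                               config@nPermutations,
                               childSeed(config@seed, "permute-master"),
                               threshold = config@threshold,
                               cost = config@svmCost,
                               verbose = config@verbose)

    stage <- "evaluate"
    log("stage: evaluation")
    universe <- intersect(geneIds(study$network),
                          geneScores$gene[!is.na(geneScores$p)])
    gwasScores <- scoresFromRanking(geneScores)[universe]
    netwasScores <- scoresFromRanking(aggregate)[universe]
    permScores <- lapply(permRuns, function(r)
      -r$rank[universe])
    band <- permutationBand(permScores, study$gold,
                            ciLevel = config@ciLevel,
                            nBoot = config@nBoot,
                            seed = childSeed(config@seed, "band"))
    report <- suppressMessages(
      compareMethods(gwasScores, netwasScores, band, study$gold,
                     nBoot = config@nBoot, ciLevel = config@ciLevel,
                     seed = childSeed(config@seed, "evaluate")))
    evalDf <- data.frame(
      method = c("gwas", "netwas", "netwas_permuted_mean"),
      auc = fmtNum(c(report$gwas@auc, report$netwas@auc, band$meanAuc)),
      ci_low = fmtNum(c(report$gwas@ciLow, report$netwas@ciLow,
                        band$bandLow)),
      ci_high = fmtNum(c(report$gwas@ciHigh, report$netwas@ciHigh,
                         band$bandHigh)),
      lambda = c(fmtNum(qq$lambda), "", ""))
    write.table(evalDf, paths$evaluation, sep = ",", quote = FALSE,
                row.names = FALSE)

    manifest <- list(
      package = as.character(utils::packageVersion("netwasr")),
      seed = config@seed,
      counts = list(
        snps = nrow(assoc),
        genesScored = sum(!is.na(geneScores$p)),
        genesUnscored = sum(is.na(geneScores$p)),
        positives = length(labels@positives),
        negatives = length(labels@negatives),
        unlabeled = length(labels@unlabeled)),
      digests = as.list(tools::md5sum(unlist(paths[c(
        "genes", "network", "gold", "assoc", "geneScores",
        "aggregate")]))))
    names(manifest$digests) <- basename(names(manifest$digests))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE)

    list(study = study, assoc = assoc, geneScores = geneScores,
         aggregate = aggregate, report = report, qq = qq, paths = paths)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
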