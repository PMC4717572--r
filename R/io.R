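#' Read a PLINK-style association table
#'
#' Accepts the full `.qassoc`-style dialect (`SNP CHR BP BETA SE P`) as
#' well as the minimal summary-statistics dialect (`SNP CHR BP P`), both
#' tab-separated with a header. p-values in scientific notation are parsed;
#' p outside `(0, 1]`, malformed rows, and duplicate SNP ids are errors.
#'
#' @param path file path.
#' @return data.frame with columns `SNP`, `CHR`, `BP`, `P` and, when
#'   present, `BETA`, `SE`.
#' @export
readAssocTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  need <- c("SNP", "CHR", "BP", "P")
  if (!all(need %in% hdr))
    stop("unrecognized association table header (need SNP, CHR, BP, P): ",
         paste(hdr, collapse = ", "))
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE)
  for (col in intersect(c("BP", "BETA", "SE", "P"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("NA", "")))
    if (length(bad))
      stop("malformed ", col, " value at line ", bad[1] + 1L, ": '",
           df[[col]][bad[1]], "'")
    df[[col]] <- v
  }
  df$BP <- as.integer(df$BP)
  if (anyDuplicated(df$SNP))
    stop("duplicate SNP ids: ",
         paste(unique(df$SNP[duplicated(df$SNP)]), collapse = ", "))
  if (any(is.na(df$P) | df$P <= 0 | df$P > 1)) {
    bad <- which(is.na(df$P) | df$P <= 0 | df$P > 1)[1]
    stop("p-value outside (0, 1] at line ", bad + 1L)
  }
  keep <- intersect(c("SNP", "CHR", "BP", "BETA", "SE", "P"), names(df))
  df[, keep]
}

#' Write a PLINK-style association table
#'
#' Tab-separated `.qassoc` dialect; numeric columns at 12 significant
#' digits for reproducible diffs.
#'
#' @param assoc data.frame from [snpAssociation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAssocTable <- function(assoc, path) {
  out <- assoc
  for (col in intersect(c("BETA", "SE", "P"), names(out)))
    out[[col]] <- fmtNum(out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from a BED file
#'
#' BED is 0-based half-open on disk; ranges are converted to the 1-based
#' inclusive convention used internally (via [rtracklayer::import()], which
#' performs the conversion). The BED name column supplies the gene ids.
#'
#' @param path BED file path (>= 4 columns).
#' @return [GenomicRanges::GRanges] with names set to gene ids.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$name) || anyNA(gr$name))
    stop("BED gene file must carry gene ids in column 4")
  if (anyDuplicated(gr$name)) stop("duplicate gene ids in BED file")
  names(gr) <- gr$name
  gr
}

#' Write gene models to a BED file
#'
#' @param genes [GenomicRanges::GRanges] with names set to gene ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  gr <- genes
  gr$name <- names(genes)
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)["name"]
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a weighted network edge list
#'
#' Three tab-separated columns (`gene_a`, `gene_b`, `weight`), no header
#' required (one is detected and skipped). Edges are symmetrized; repeated
#' edges with conflicting weights are an error, self-loops are dropped with
#' a warning, and weights outside `[0, 1]` are rejected.
#'
#' @param path edge-list path.
#' @param geneIds optional full node universe (isolated genes otherwise
#'   absent from the edge list).
#' @return a [TissueNetwork-class].
#' @export
readNetwork <- function(path, geneIds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  skip <- if (length(first) >= 3L &&
              is.na(suppressWarnings(as.numeric(first[3])))) 1L else 0L
  df <- read.table(path, sep = "\t", skip = skip, col.names =
                     c("gene_a", "gene_b", "weight"),
                   colClasses = c("character", "character", "numeric"))
  if (any(is.na(df$weight))) stop("unparseable weight in network file")
  if (any(df$weight < 0 | df$weight > 1))
    stop("network weights must lie in [0, 1]")
  self <- df$gene_a == df$gene_b
  if (any(self)) {
    warning("dropping ", sum(self), " self-loop(s)")
    df <- df[!self, , drop = FALSE]
  }
  key <- ifelse(df$gene_a < df$gene_b,
                paste(df$gene_a, df$gene_b), paste(df$gene_b, df$gene_a))
  dup <- duplicated(key)
  if (any(dup)) {
    w1 <- df$weight[match(key[dup], key)]
    if (any(abs(w1 - df$weight[dup]) > 1e-12))
      stop("conflicting duplicate edge weights for: ",
           paste(unique(key[dup][abs(w1 - df$weight[dup]) > 1e-12]),
                 collapse = "; "))
    df <- df[!dup, , drop = FALSE]
  }
  ids <- sort(unique(c(df$gene_a, df$gene_b, geneIds)))
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  W[cbind(match(df$gene_a, ids), match(df$gene_b, ids))] <- df$weight
  W[cbind(match(df$gene_b, ids), match(df$gene_a, ids))] <- df$weight
  tissueNetwork(ids, W)
}

#' Write a network as a three-column edge list
#'
#' Upper-triangle edges with nonzero weight, tab-separated with header
#' `gene_a gene_b weight`, weights at 12 significant digits.
#'
#' @param network a [TissueNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path) {
  W <- networkWeights(network)
  ids <- geneIds(network)
  up <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  df <- data.frame(gene_a = ids[up[, 1]], gene_b = ids[up[, 2]],
                   weight = fmtNum(W[up]), stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gold-standard gene list
#'
#' One gene id per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @param universe evaluation universe (defaults to the listed genes).
#' @param label identifier for the standard.
#' @return a [GoldStandard-class].
#' @export
readGoldStandard <- function(path, universe = NULL, label = basename(path)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  goldStandard(lines, universe = if (is.null(universe)) lines else universe,
               label = label)
}

#' Write a gold-standard gene list
#' @param gold a [GoldStandard-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGoldStandard <- function(gold, path) {
  writeLines(c(paste0("# ", gold@label), gold@positives), path)
  invisible(path)
}

#' Write per-gene scores as CSV
#'
#' Columns `gene, chr, nSNPs, Test_Statistic, P, n_sims, seed` (RFC-4180
#' quoting, 12 significant digits), mirroring a VEGAS-style per-gene export.
#'
#' @param geneScores data.frame from [scoreGenes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneScores <- function(geneScores, path) {
  out <- data.frame(gene = geneScores$gene, chr = geneScores$chr,
                    nSNPs = geneScores$nSnps,
                    Test_Statistic = fmtNum(geneScores$stat),
                    P = fmtNum(geneScores$p),
                    n_sims = geneScores$nSims, seed = geneScores$seed)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Read per-gene scores written by [writeGeneScores()]
#' @param path CSV path.
#' @return data.frame with columns `gene`, `chr`, `nSnps`, `stat`, `p`,
#'   `nSims`, `seed`.
#' @export
readGeneScores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(gene = as.character(df$gene), chr = as.character(df$chr),
             nSnps = as.integer(df$nSNPs),
             stat = as.numeric(df$Test_Statistic), p = as.numeric(df$P),
             nSims = as.integer(df$n_sims), seed = as.integer(df$seed),
             stringsAsFactors = FALSE)
}

#' Write the aggregate NetWAS ranking
#'
#' CSV with columns `gene, summed_rank, mean_rank, final_rank`.
#'
#' @param aggregate data.frame from [aggregateRanks()].
#' @param path output path (conventionally `combined-results.csv`).
#' @return `path`, invisibly.
#' @export
writeAggregate <- function(aggregate, path) {
  out <- aggregate
  out$mean_rank <- fmtNum(out$mean_rank)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an aggregate ranking written by [writeAggregate()]
#' @param path CSV path.
#' @return data.frame with columns `gene`, `summed_rank`, `mean_rank`,
#'   `final_rank`.
#' @export
readAggregate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$gene <- as.character(df$gene)
  df
}

#' Write a synthetic cohort to a directory of plain-text tables
#'
#' Layout: `genotypes.tsv` (subjects x SNPs dosage matrix, SNP ids as
#' header), `phenotype.tsv` (columns `phenotype` plus the four covariates),
#' `snps.tsv` (`SNP`, `CHR`, `BP`), `truth.txt` (causal gene ids, tagged
#' SNP appended after a tab).
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(cohort@genotypes, file.path(dir, "genotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- data.frame(phenotype = fmtNum(cohort@phenotype))
  for (j in seq_len(ncol(cohort@covariates)))
    ph[[colnames(cohort@covariates)[j]]] <- fmtNum(cohort@covariates[, j])
  write.table(ph, file.path(dir, "phenotype.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort@snpTable, file.path(dir, "snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tag <- cohort@taggedSnps[cohort@truth]
  writeLines(paste0(cohort@truth, ifelse(is.na(tag), "", paste0("\t", tag))),
             file.path(dir, "truth.txt"))
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#' @param dir directory produced by [writeCohort()].
#' @param seed seed recorded in the reconstructed object (default 0).
#' @return a [SyntheticCohort-class].
#' @export
readCohort <- function(dir, seed = 0L) {
  geno <- as.matrix(read.table(file.path(dir, "genotypes.tsv"),
                               header = TRUE, sep = "\t",
                               check.names = FALSE))
  if (anyNA(geno)) stop("missing genotype values are not supported")
  storage.mode(geno) <- "integer"
  ph <- read.table(file.path(dir, "phenotype.tsv"), header = TRUE,
                   sep = "\t")
  snps <- read.table(file.path(dir, "snps.tsv"), header = TRUE, sep = "\t",
                     colClasses = c("character", "character", "integer"))
  tl <- strsplit(readLines(file.path(dir, "truth.txt")), "\t", fixed = TRUE)
  truth <- vapply(tl, `[`, character(1), 1L)
  tagged <- setNames(vapply(tl, function(x)
    if (length(x) > 1L) x[2] else NA_character_, character(1)), truth)
  tagged <- tagged[!is.na(tagged)]
  new("SyntheticCohort", genotypes = geno,
      phenotype = as.numeric(ph$phenotype),
      covariates = as.matrix(ph[, -1, drop = FALSE]),
      snpTable = snps, truth = truth, taggedSnps = tagged,
      seed = as.integer(seed))
}
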