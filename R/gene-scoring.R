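#' Assign SNPs to genes within a symmetric window
#'
#' A SNP is assigned to a gene when it lies on the same chromosome and its
#' position falls in `[start - windowBp, end + windowBp]` (1-based,
#' boundaries inclusive). One SNP may be assigned to many genes; this
#' multi-mapping is preserved by design and surfaced by
#' [multiMappingDiagnostic()]. Strand is ignored: the window is applied
#' symmetrically on both sides. Implemented with
#' [GenomicRanges::findOverlaps()] on the widened gene ranges.
#'
#' @param snps data.frame with columns `SNP`, `CHR`, `BP` (additional
#'   columns such as `P` are allowed and ignored here).
#' @param genes [GenomicRanges::GRanges] of gene bodies, names = gene ids.
#' @param windowBp window size in bp on each side (default 50000).
#' @return named list, one element per gene, each a character vector of
#'   assigned SNP ids ordered by position (possibly empty); attribute
#'   `windowBp` records the window.
#' @export
assignSnps <- function(snps, genes, windowBp = 50000L) {
  stopifnot(is.data.frame(snps), all(c("SNP", "CHR", "BP") %in% names(snps)),
            is(genes, "GRanges"))
  if (windowBp < 0) stop("windowBp must be >= 0")
  if (anyDuplicated(snps$SNP))
    stop("duplicate SNP ids: ",
         paste(unique(snps$SNP[duplicated(snps$SNP)]), collapse = ", "))
  known <- snps$CHR %in% unique(as.character(GenomicRanges::seqnames(genes)))
  if (!all(known)) {
    warning("skipping ", sum(!known),
            " SNP(s) on chromosome(s) absent from the gene annotation: ",
            paste(unique(snps$CHR[!known]), collapse = ", "))
    snps <- snps[known, , drop = FALSE]
  }
  snpGr <- GenomicRanges::GRanges(snps$CHR,
                                  IRanges::IRanges(snps$BP, snps$BP))
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(
      start = pmax(1L, GenomicRanges::start(genes) - as.integer(windowBp)),
      end = GenomicRanges::end(genes) + as.integer(windowBp)))
  hits <- GenomicRanges::findOverlaps(win, snpGr, ignore.strand = TRUE)
  out <- vector("list", length(genes))
  names(out) <- names(genes)
  for (i in seq_along(out)) out[[i]] <- character(0)
  if (length(hits)) {
    sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    for (q in names(sp)) {
      js <- sp[[q]]
      out[[as.integer(q)]] <- snps$SNP[js[order(snps$BP[js])]]
    }
  }
  attr(out, "windowBp") <- as.integer(windowBp)
  out
}

#' Convert a two-sided p-value into a 1-df chi-square statistic
#'
#' Returns the upper-tail quantile of the chi-square distribution with one
#' degree of freedom at `p`, i.e. the statistic whose survival probability
#' equals `p`. Monotone decreasing in `p`; `p = 1` maps to 0. Two-sided
#' t-based p-values are treated directly as chi-square tail probabilities
#' (the large-sample equivalence used by gene-based combination tests).
#' p-values below `1e-300` are clamped there with a warning to avoid
#' infinite statistics.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return chi-square(1) statistics, same length as `p`.
#' @examples
#' chisqFromP(c(1, 0.05, 1e-6))
#' @export
chisqFromP <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  if (any(p < 1e-300)) {
    warning("p-value(s) below 1e-300 clamped to avoid numerical underflow")
    p <- pmax(p, 1e-300)
  }
  qchisq(p, df = 1, lower.tail = FALSE)
}

# Eigenvalue-clipping PSD repair: clip negative eigenvalues at zero, rebuild,
# rescale to unit diagonal. Returns the repaired matrix with the largest
# absolute eigenvalue adjustment as attribute "repair".
psdRepair <- function(R, tol = 1e-8) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  adj <- max(0, -min(e$values))
  if (min(e$values) < -tol) {
    lam <- pmax(e$values, 0)
    R <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(diag(R))
    d[d == 0] <- 1
    R <- R / outer(d, d)
    R <- (R + t(R)) / 2
    diag(R) <- 1
  }
  attr(R, "repair") <- adj
  R
}

#' Pairwise LD (correlation) matrix from dosage genotypes
#'
#' Pearson correlation of the dosage columns, followed by a positive
#' semidefinite repair (eigenvalue clipping at zero and rescaling to a unit
#' diagonal). The repair magnitude is recorded; for a full-rank sample
#' correlation it is numerically zero.
#'
#' @param dosages subjects x SNPs numeric matrix with column names;
#'   monomorphic columns are dropped with a warning.
#' @return an [LdMatrix-class] with `source = "genotypes"`.
#' @export
ldFromGenotypes <- function(dosages) {
  stopifnot(is.matrix(dosages))
  if (nrow(dosages) < 2L) stop("need at least 2 subjects to estimate LD")
  v <- apply(dosages, 2, var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " monomorphic SNP(s) from LD matrix")
    dosages <- dosages[, v > 0, drop = FALSE]
  }
  if (ncol(dosages) == 0L) stop("no polymorphic SNPs left")
  R <- cor(dosages)
  Rr <- psdRepair(R)
  ld <- new("LdMatrix", snpIds = colnames(dosages), R = unclass(Rr)[, , drop = FALSE],
            source = "genotypes", repair = attr(Rr, "repair"))
  attr(ld@R, "repair") <- NULL
  ld
}

#' Wrap a user-supplied correlation matrix as an LdMatrix
#'
#' Applies the same PSD repair as [ldFromGenotypes()]; use when LD comes
#' from an external reference panel rather than from genotypes.
#'
#' @param R square correlation matrix with SNP ids as dimnames.
#' @param snpIds optional SNP ids (defaults to `rownames(R)`).
#' @return an [LdMatrix-class] with `source = "provided"`.
#' @export
ldFromMatrix <- function(R, snpIds = rownames(R)) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(nrow(R)))
  Rr <- psdRepair(R)
  rep <- attr(Rr, "repair")
  attr(Rr, "repair") <- NULL
  dimnames(Rr) <- list(snpIds, snpIds)
  new("LdMatrix", snpIds = as.character(snpIds), R = Rr,
      source = "provided", repair = rep)
}

#' LD-aware Monte Carlo gene-based p-value
#'
#' The observed gene statistic is the sum of per-SNP chi-square(1)
#' statistics obtained from the SNP p-values. Its null distribution under
#' LD is that of `sum(z^2)` for `z ~ MVN(0, R)`, simulated through the
#' spectral representation `sum(lambda_i * w_i^2)` with `w_i` iid standard
#' normal and `lambda_i` the eigenvalues of the repaired `R` -- identical
#' in distribution to Cholesky sampling, with the advantage that the draw
#' is exactly invariant to SNP ordering (eigenvalues are canonical). The
#' gene p-value is the conservative Monte Carlo estimate
#' `(1 + exceedances) / (1 + nSims)`, which is never exactly zero.
#' Simulation is staged adaptively: the first stage runs `stages[1]` draws
#' and escalates to the next stage whenever the current estimate is below
#' 10 times the stage's resolution (`10 / nSims`), so small p-values get
#' proportionally more simulations up to the configured cap.
#'
#' @param snpIds SNP ids in the gene's assignment, in order.
#' @param snpPs named numeric vector of per-SNP p-values covering `snpIds`.
#' @param ld an [LdMatrix-class] (or plain correlation matrix) over exactly
#'   these SNPs, same order.
#' @param stages increasing integer vector of simulation sizes
#'   (default `c(1e3, 1e4, 1e5)`).
#' @param seed RNG seed for the null draws.
#' @return one-row data.frame: `gene` (NA here; filled by [scoreGenes()]),
#'   `nSnps`, `stat`, `p`, `nSims`, `seed`; or `NULL` for an empty
#'   assignment (the gene is reported unscored, never silently `p = 1`).
#' @export
geneP <- function(snpIds, snpPs, ld, stages = c(1e3, 1e4, 1e5), seed = 1L) {
  if (length(snpIds) == 0L) return(NULL)
  if (is(ld, "LdMatrix")) {
    if (!identical(ld@snpIds, as.character(snpIds)))
      stop("LD matrix SNPs do not match the assignment")
    R <- ld@R
  } else {
    R <- psdRepair(ld)
    attr(R, "repair") <- NULL
  }
  if (!all(snpIds %in% names(snpPs)))
    stop("missing p-values for: ",
         paste(setdiff(snpIds, names(snpPs)), collapse = ", "))
  ps <- unname(snpPs[snpIds])
  stat <- sum(chisqFromP(ps))
  k <- length(ps)
  stages <- sort(as.integer(stages))
  lambda <- pmax(eigen(R, symmetric = TRUE, only.values = TRUE)$values, 0)
  p <- NA_real_
  used <- NA_integer_
  withSeed(as.integer(seed), {
    for (s in seq_along(stages)) {
      nSims <- stages[s]
      exceed <- 0L
      blockMax <- 2e5
      done <- 0
      while (done < nSims) {
        m <- min(blockMax, nSims - done)
        w <- matrix(rnorm(m * k)^2, m, k)
        exceed <- exceed + sum(drop(w %*% lambda) >= stat)
        done <- done + m
      }
      p <- (1 + exceed) / (1 + nSims)
      used <- nSims
      if (p >= 10 / nSims || s == length(stages)) break
    }
  })
  data.frame(gene = NA_character_, nSnps = k, stat = stat, p = p,
             nSims = used, seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

#' Score all genes: Phase I driver
#'
#' Assigns SNPs to genes, estimates per-gene LD from the cohort genotypes,
#' and computes the Monte Carlo gene-based p-value for every gene with at
#' least one assigned SNP. Genes with no assigned SNPs are listed unscored
#' (NA statistic and p) for audit and are excluded from Phase II labels.
#' Per-gene seeds are derived from `seed` and the gene id, so any single
#' gene can be recomputed independently.
#'
#' @param assoc association table (`SNP`, `CHR`, `BP`, `P`, ...) from
#'   [snpAssociation()] or [readAssocTable()].
#' @param genes gene models ([GenomicRanges::GRanges]).
#' @param cohort optional [SyntheticCohort-class] supplying genotypes for LD;
#'   alternatively pass `ldList`, a named list of [LdMatrix-class] objects.
#' @param windowBp assignment window (default 50000).
#' @param stages Monte Carlo staging, see [geneP()].
#' @param seed master seed for the per-gene null simulations.
#' @param ldList optional named list of per-gene LD matrices (used when no
#'   cohort genotypes are available).
#' @return data.frame with columns `gene`, `chr`, `nSnps`, `stat`, `p`,
#'   `nSims`, `seed`, one row per gene.
#' @export
scoreGenes <- function(assoc, genes, cohort = NULL, windowBp = 50000L,
                       stages = c(1e3, 1e4, 1e5), seed = 1L, ldList = NULL) {
  stopifnot(is.data.frame(assoc), "P" %in% names(assoc))
  if (is.null(cohort) && is.null(ldList))
    stop("supply either a cohort (genotype LD) or ldList (provided LD)")
  assignments <- assignSnps(assoc, genes, windowBp)
  snpPs <- setNames(assoc$P, assoc$SNP)
  rows <- vector("list", length(assignments))
  chrs <- as.character(GenomicRanges::seqnames(genes))
  for (i in seq_along(assignments)) {
    gid <- names(assignments)[i]
    snpIds <- assignments[[i]]
    gseed <- childSeed(seed, "geneP", i)
    if (length(snpIds) == 0L) {
      rows[[i]] <- data.frame(gene = gid, chr = chrs[i], nSnps = 0L,
                              stat = NA_real_, p = NA_real_,
                              nSims = NA_integer_, seed = gseed,
                              stringsAsFactors = FALSE)
      next
    }
    ld <- if (!is.null(ldList)) {
      if (is.null(ldList[[gid]])) stop("no LD matrix provided for gene ", gid)
      ldList[[gid]]
    } else {
      suppressWarnings(ldFromGenotypes(
        cohort@genotypes[, snpIds, drop = FALSE]))
    }
    keep <- intersect(snpIds, ld@snpIds)  # monomorphic SNPs may be dropped
    res <- geneP(keep, snpPs, ldFromMatrix(ld@R[keep, keep, drop = FALSE]),
                 stages = stages, seed = gseed)
    res$gene <- gid
    res <- cbind(res[, "gene", drop = FALSE], chr = chrs[i],
                 res[, c("nSnps", "stat", "p", "nSims", "seed")])
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multi-mapping diagnostic: overlapping genes driven by shared SNPs
#'
#' Builds the bipartite map from nominally significant SNPs
#' (`p < alphaSnp`) to the genes they are assigned to and reports every
#' connected component containing two or more genes, together with the
#' shared significant SNPs. This is the machine-readable analogue of
#' spotting a run of top-ranked genes that all belong to one overlapping
#' gene family (e.g. the protocadherin alpha cluster), where the same
#' variants inside the assignment window drive many gene-level scores.
#'
#' @param assignments output of [assignSnps()].
#' @param snpPs named numeric vector of per-SNP p-values.
#' @param alphaSnp SNP significance cutoff in `(0, 1)` (default 0.001).
#' @return list of clusters, each a list with `genes` (character, sorted)
#'   and `snps` (the significant SNPs involved, sorted); empty list if no
#'   SNP is significant or no component has >= 2 genes.
#' @export
multiMappingDiagnostic <- function(assignments, snpPs, alphaSnp = 0.001) {
  if (alphaSnp <= 0 || alphaSnp >= 1) stop("alphaSnp must be in (0, 1)")
  sig <- names(snpPs)[!is.na(snpPs) & snpPs < alphaSnp]
  if (length(sig) == 0L) return(list())
  edges <- character(0)
  for (g in names(assignments)) {
    hits <- intersect(assignments[[g]], sig)
    if (length(hits))
      edges <- c(edges, rbind(paste0("gene:", g), paste0("snp:", hits)))
  }
  if (length(edges) == 0L) return(list())
  gr <- igraph::make_graph(edges, directed = FALSE)
  comp <- igraph::components(gr)
  out <- list()
  for (ci in seq_len(comp$no)) {
    memb <- names(comp$membership)[comp$membership == ci]
    gs <- sort(sub("^gene:", "", memb[startsWith(memb, "gene:")]))
    ss <- sort(sub("^snp:", "", memb[startsWith(memb, "snp:")]))
    if (length(gs) >= 2L)
      out[[length(out) + 1L]] <- list(genes = gs, snps = ss)
  }
  out
}
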