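#' Per-SNP association testing by linear regression with covariates
#'
#' Fits, for every SNP, an ordinary least-squares regression of the
#' phenotype on (intercept, additive dosage, covariates) and reports the
#' two-sided t-test on the dosage coefficient. Computation residualizes the
#' phenotype and every dosage column on the covariate design once
#' (Frisch-Waugh-Lovell), which is numerically identical to the per-SNP full
#' fit but a single pass of dense linear algebra; the residual degrees of
#' freedom are `n - (2 + nCovariates)`. Monomorphic SNPs are reported with
#' `P = 1`, `BETA = 0`, `SE = NA` and a warning.
#'
#' @param cohort a [SyntheticCohort-class] (complete data; missing genotypes
#'   are rejected, not imputed).
#' @return data.frame with columns `SNP`, `CHR`, `BP`, `BETA`, `SE`, `P`
#'   (PLINK `.qassoc`-style), one row per SNP in input order.
#' @examples
#' study <- simulateStudy(simConfig(nSubjects = 150, nGenes = 10,
#'                                  snpsPerGene = 2, nDiseaseGenes = 2,
#'                                  seed = 3))
#' head(snpAssociation(study$cohort))
#' @export
snpAssociation <- function(cohort) {
  stopifnot(is(cohort, "SyntheticCohort"))
  G <- cohort@genotypes
  y <- cohort@phenotype
  C <- cohort@covariates
  n <- length(y)
  nCov <- ncol(C)
  if (anyNA(G) || anyNA(y)) stop("missing genotype or phenotype values are not supported")
  if (n <= nCov + 2L) stop("need more subjects than covariates + 2")
  if (var(y) == 0) stop("phenotype has zero variance")

  X0 <- cbind(`(intercept)` = 1, C)
  qrX <- qr(X0)
  if (qrX$rank < ncol(X0)) {
    dropped <- colnames(X0)[-(qrX$pivot[seq_len(qrX$rank)])]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df <- n - (nCov + 2L)

  # residualize phenotype and all dosage columns on the covariate design
  yR <- qr.resid(qrX, y)
  gR <- qr.resid(qrX, G)
  sxx <- colSums(gR^2)
  mono <- sxx < .Machine$double.eps * n
  sxx[mono] <- NA_real_

  beta <- colSums(gR * yR) / sxx
  rss <- sum(yR^2) - beta^2 * sxx
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / sxx)
  tstat <- beta / se
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) reported with P = 1, BETA = 0")
    beta[mono] <- 0
    se[mono] <- NA_real_
    p[mono] <- 1
  }
  data.frame(SNP = cohort@snpTable$SNP, CHR = cohort@snpTable$CHR,
             BP = cohort@snpTable$BP, BETA = unname(beta), SE = unname(se),
             P = unname(p), stringsAsFactors = FALSE)
}
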