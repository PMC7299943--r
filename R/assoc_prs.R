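#' Pre-adjust phenotypes for covariates
#'
#' Ordinary least-squares regression of the trait on an intercept plus the
#' named covariate columns; the returned trait values are the residuals
#' (mean zero). Binary traits are adjusted identically on the observed 0/1
#' scale, so downstream association and correlation work on the adjusted
#' scale throughout.
#'
#' @param pheno A phenotype tibble (column `trait` plus covariate columns).
#' @param covariate_names Character vector of covariate columns; may be
#'   empty, in which case the trait is simply centred.
#' @return The phenotype tibble with `trait` replaced by residuals; the
#'   trait type attribute is set to `"quantitative"` (residuals are
#'   continuous even for binary inputs).
#' @export
adjust_phenotype <- function(pheno, covariate_names = character(0)) {
  stopifnot(all(c("id", "trait") %in% names(pheno)))
  missing_cov <- setdiff(covariate_names, names(pheno))
  if (length(missing_cov)) {
    stop("covariates not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  x <- cbind(`(Intercept)` = 1,
             as.matrix(pheno[, covariate_names, drop = FALSE]))
  if (!is.numeric(x)) stop("covariates must be numeric", call. = FALSE)
  if (anyNA(x) || anyNA(pheno$trait)) {
    stop("missing values in trait or covariates; apply listwise deletion first",
         call. = FALSE)
  }
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    stop("collinear covariate column(s): ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }
  res <- stats::lm.fit(x, pheno$trait)$residuals
  out <- pheno
  out$trait <- unname(res)
  new_phenotype_tbl(out, "quantitative")
}

#' Per-SNP association scan
#'
#' Simple linear regression of the (pre-adjusted) trait on each SNP dosage
#' with an intercept: `beta = cov(w, y)/var(w)`, Wald standard errors and
#' two-sided p-values from the t distribution with n-2 degrees of freedom.
#' Monomorphic SNPs are emitted with `beta = 0`, `p = 1` and flagged. All
#' SNPs are fitted at once via cross-products.
#'
#' @param genotypes A [geno_matrix()] of the discovery sample.
#' @param adjusted Phenotype tibble (columns `id`, `trait`); ids must cover
#'   the genotype rows used. Missing dosages are mean-imputed per SNP.
#' @return A tibble of class `gwas_result` with columns `snp_id`, `beta`,
#'   `se`, `p`, `n`, `monomorphic`.
#' @export
run_gwas <- function(genotypes, adjusted) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  common <- intersect(genotypes$ids, adjusted$id)
  if (length(common) < 3) stop("need at least 3 overlapping individuals",
                               call. = FALSE)
  y <- adjusted$trait[match(common, adjusted$id)]
  w <- genotypes$dosage[common, , drop = FALSE]
  if (anyNA(w)) {
    miss <- which(is.na(w), arr.ind = TRUE)
    w[miss] <- 2 * genotypes$freqs[miss[, 2]]
  }
  n <- length(y)
  w_mean <- colMeans(w)
  sxx <- colSums(w^2) - n * w_mean^2
  yc <- y - mean(y)
  sxy <- drop(crossprod(w, yc))
  syy <- sum(yc^2)
  mono <- sxx <= 0
  beta <- ifelse(mono, 0, sxy / pmax(sxx, .Machine$double.eps))
  rss <- pmax(syy - beta * sxy, 0)
  sigma2 <- rss / (n - 2)
  se <- ifelse(mono, NA_real_, sqrt(sigma2 / pmax(sxx, .Machine$double.eps)))
  tstat <- beta / se
  p <- ifelse(mono, 1, 2 * stats::pt(-abs(tstat), df = n - 2))
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  out <- tibble::tibble(
    snp_id = genotypes$snp_ids,
    beta = unname(beta), se = unname(se), p = unname(p), n = n,
    monomorphic = unname(mono)
  )
  class(out) <- unique(c("gwas_result", class(out)))
  out
}

#' Polygenic risk scores from GWAS effects
#'
#' Per target individual, the sum of alternate-allele dosages weighted by
#' the estimated SNP effects, over SNPs passing the p-value threshold.
#' Missing dosages contribute their expectation `2p * beta`.
#'
#' @param genotypes A [geno_matrix()] of the target sample; SNP ids are
#'   aligned to the GWAS table by id (alleles are assumed consistent, as
#'   guaranteed by the simulator and PLINK round-trip).
#' @param gwas A [run_gwas()] result.
#' @param p_threshold Include SNPs with `p <= p_threshold` (default 1:
#'   every SNP, the whole-genome approach).
#' @return A tibble of class `prs_result` with columns `id`, `score`,
#'   `n_snps_used`.
#' @export
score_prs <- function(genotypes, gwas, p_threshold = 1.0) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  keep <- gwas$p <= p_threshold & !is.na(gwas$beta)
  if (!any(keep)) stop("no SNPs pass the p-value threshold", call. = FALSE)
  snps <- gwas$snp_id[keep]
  missing_snps <- setdiff(snps, genotypes$snp_ids)
  if (length(missing_snps)) {
    stop("GWAS SNPs absent from target genotypes: ",
         paste(utils::head(missing_snps, 5), collapse = ", "), call. = FALSE)
  }
  cols <- match(snps, genotypes$snp_ids)
  w <- genotypes$dosage[, cols, drop = FALSE]
  if (anyNA(w)) {
    miss <- which(is.na(w), arr.ind = TRUE)
    w[miss] <- 2 * genotypes$freqs[cols][miss[, 2]]
  }
  score <- unname(drop(w %*% gwas$beta[keep]))
  out <- tibble::tibble(id = genotypes$ids, score = score,
                        n_snps_used = length(snps))
  class(out) <- unique(c("prs_result", class(out)))
  out
}
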