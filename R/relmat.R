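#' Relationship matrix container
#'
#' A labelled symmetric matrix of pairwise relationships of kind `"G"`
#' (genomic), `"A"` (pedigree/numerator) or `"H"` (combined single-step).
#'
#' @param values Symmetric numeric matrix with individual ids as dimnames.
#' @param kind One of `"G"`, `"A"`, `"H"`.
#' @return An object of class `rel_matrix`.
#' @export
rel_matrix <- function(values, kind) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  kind <- match.arg(kind, c("G", "A", "H"))
  if (is.null(rownames(values))) {
    stop("relationship matrix needs individual ids as dimnames", call. = FALSE)
  }
  asym <- max(abs(values - t(values)))
  if (asym > 1e-10) {
    stop(sprintf("matrix is not symmetric (max asymmetry %.2e)", asym),
         call. = FALSE)
  }
  values <- (values + t(values)) / 2
  colnames(values) <- rownames(values)
  structure(list(values = values, ids = rownames(values), kind = kind),
            class = "rel_matrix")
}

#' @export
print.rel_matrix <- function(x, ...) {
  d <- diag(x$values)
  cat(sprintf("<rel_matrix kind=%s> %d individuals; diag mean %.3f [%.3f, %.3f]\n",
              x$kind, length(x$ids), mean(d), min(d), max(d)))
  invisible(x)
}

#' @export
dim.rel_matrix <- function(x) dim(x$values)

#' Tidy a relationship matrix into its lower triangle
#'
#' @param x A [rel_matrix()].
#' @param diagonal Include diagonal entries (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with columns `id_i`, `id_j`, `value` (`id_i` index
#'   greater than or equal to `id_j` index: lower triangle).
#' @exportS3Method generics::tidy
tidy.rel_matrix <- function(x, diagonal = TRUE, ...) {
  idx <- which(lower.tri(x$values, diag = diagonal), arr.ind = TRUE)
  tibble::tibble(
    id_i = x$ids[idx[, 1]],
    id_j = x$ids[idx[, 2]],
    value = x$values[idx]
  )
}

#' Genomic relationship matrix (GRM)
#'
#' Computes \eqn{G = WW'/M} over M SNPs. By default each SNP column is
#' standardised, \eqn{w = (d - 2p)/\sqrt{2p(1-p)}} with `p` the stored
#' alternate-allele frequency, so unrelated pairs have expected relationship
#' 0 and the diagonal has expectation 1. With `standardize = FALSE` the raw
#' 0/1/2 coding is used verbatim. Missing dosages are imputed to `2p` before
#' standardisation.
#'
#' @param genotypes A [geno_matrix()].
#' @param standardize Standardise SNP columns (default `TRUE`).
#' @return A [rel_matrix()] of kind `"G"`.
#' @export
compute_grm <- function(genotypes, standardize = TRUE) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  w <- grm_design(genotypes, standardize)
  g <- tcrossprod(w) / ncol(w)
  rel_matrix(g, "G")
}

# Imputed / standardised genotype design matrix used by the GRM and by
# SNP-ridge.
grm_design <- function(genotypes, standardize = TRUE) {
  w <- genotypes$dosage
  p <- genotypes$freqs
  if (standardize) {
    mono <- p <= 0 | p >= 1
    if (any(mono)) {
      stop("monomorphic SNPs cannot be standardised: ",
           paste(utils::head(genotypes$snp_ids[mono], 5), collapse = ", "),
           if (sum(mono) > 5) sprintf(" (and %d more)", sum(mono) - 5) else "",
           call. = FALSE)
    }
  }
  if (anyNA(w)) {
    miss <- which(is.na(w), arr.ind = TRUE)
    w[miss] <- 2 * p[miss[, 2]]
  }
  if (standardize) {
    w <- sweep(w, 2, 2 * p, "-")
    w <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
  }
  w
}

#' Cross-sample genomic relationships
#'
#' Computes only the block of standardised genomic relationships between two
#' id sets (rows x columns), avoiding the full GRM when only
#' discovery-by-target relationships are needed, e.g. for [estimate_me()].
#'
#' @param genotypes A [geno_matrix()].
#' @param ids_row,ids_col Disjoint id vectors.
#' @param standardize As in [compute_grm()].
#' @return A plain numeric matrix with `ids_row` rows and `ids_col` columns.
#' @export
compute_grm_cross <- function(genotypes, ids_row, ids_col, standardize = TRUE) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  w <- grm_design(genotypes, standardize)
  tcrossprod(w[ids_row, , drop = FALSE], w[ids_col, , drop = FALSE]) / ncol(w)
}

#' Numerator relationship matrix from a pedigree (tabular method)
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' recursion: processing individuals with parents before offspring,
#' \eqn{a_{ij} = (a_{j,sire(i)} + a_{j,dam(i)})/2} for `j` already tabulated,
#' and \eqn{a_{ii} = 1 + a_{sire(i),dam(i)}/2}. Unknown parents contribute 0;
#' founders have diagonal 1 and mutual relationship 0.
#'
#' @param pedigree A pedigree tibble (columns `id`, `sire`, `dam`).
#' @return A [rel_matrix()] of kind `"A"` in pedigree row order.
#' @export
compute_a_matrix <- function(pedigree) {
  topo <- validate_pedigree(pedigree)
  n <- nrow(pedigree)
  idx <- stats::setNames(seq_along(topo), topo)
  sire <- stats::setNames(pedigree$sire, pedigree$id)[topo]
  dam <- stats::setNames(pedigree$dam, pedigree$id)[topo]
  a <- matrix(0, n, n, dimnames = list(topo, topo))
  for (i in seq_len(n)) {
    s <- if (is.na(sire[i])) 0L else idx[[sire[i]]]
    d <- if (is.na(dam[i])) 0L else idx[[dam[i]]]
    if (i > 1) {
      j <- seq_len(i - 1L)
      rel <- (if (s > 0) a[j, s] else 0) / 2 + (if (d > 0) a[j, d] else 0) / 2
      a[j, i] <- rel
      a[i, j] <- rel
    }
    a[i, i] <- 1 + (if (s > 0 && d > 0) a[s, d] else 0) / 2
  }
  ord <- match(pedigree$id, topo)
  rel_matrix(a[ord, ord, drop = FALSE], "A")
}

#' Combined pedigree-genomic relationship matrix (single-step H)
#'
#' Merges the numerator matrix A of all individuals with the genomic matrix
#' G of the genotyped subset. With subscript 1 for ungenotyped and 2 for
#' genotyped individuals:
#' \deqn{H_{11} = A_{11} + A_{12}A_{22}^{-1}(G - A_{22})A_{22}^{-1}A_{21}}
#' \deqn{H_{12} = A_{12}A_{22}^{-1}G, \quad H_{22} = G.}
#'
#' @param A A [rel_matrix()] of kind `"A"` over all individuals.
#' @param G A [rel_matrix()] of kind `"G"` over exactly the genotyped ids.
#' @param genotyped_ids Ids of the genotyped individuals (defaults to
#'   `G$ids`).
#' @param blend Optional weight `w` in (0, 1]; when supplied, G is first
#'   blended as `w * G + (1 - w) * A22`. Off by default; useful when `A22`
#'   is singular or G is incompatible with the pedigree.
#' @return A [rel_matrix()] of kind `"H"` in A's id order; the genotyped
#'   block equals G exactly (when `blend` is unused).
#' @export
compute_h_matrix <- function(A, G, genotyped_ids = G$ids, blend = NULL) {
  stopifnot(inherits(A, "rel_matrix"), inherits(G, "rel_matrix"))
  if (!setequal(G$ids, genotyped_ids)) {
    stop("G must cover exactly the genotyped ids", call. = FALSE)
  }
  if (!all(genotyped_ids %in% A$ids)) {
    stop("genotyped ids missing from A: ",
         paste(utils::head(setdiff(genotyped_ids, A$ids), 5), collapse = ", "),
         call. = FALSE)
  }
  ids1 <- setdiff(A$ids, genotyped_ids)
  ids2 <- A$ids[A$ids %in% genotyped_ids]
  g <- G$values[ids2, ids2, drop = FALSE]
  a22 <- A$values[ids2, ids2, drop = FALSE]
  if (!is.null(blend)) {
    stopifnot(is.numeric(blend), blend > 0, blend <= 1)
    g <- blend * g + (1 - blend) * a22
  }
  if (!length(ids1)) {
    return(rel_matrix(g, "H"))
  }
  a11 <- A$values[ids1, ids1, drop = FALSE]
  a12 <- A$values[ids1, ids2, drop = FALSE]
  a22_inv_a21 <- tryCatch(
    solve(a22, t(a12)),
    error = function(e) {
      stop("A22 (genotyped block of A) is singular; consider blending, ",
           "e.g. compute_h_matrix(A, G, blend = 0.99) which uses ",
           "0.99*G + 0.01*A22", call. = FALSE)
    }
  )
  h11 <- a11 + crossprod(a22_inv_a21, (g - a22) %*% a22_inv_a21)
  h12 <- crossprod(a22_inv_a21, g)
  h <- matrix(0, length(A$ids), length(A$ids), dimnames = list(A$ids, A$ids))
  h[ids1, ids1] <- h11
  h[ids1, ids2] <- h12
  h[ids2, ids1] <- t(h12)
  h[ids2, ids2] <- g
  rel_matrix(h, "H")
}

# Degree thresholds on the kinship coefficient: powers-of-two bins around
# the theoretical values 0.25 (1st), 0.125 (2nd), 0.0625 (3rd degree).
.kinship_breaks <- c(third = 2^-4.5, second = 2^-3.5,
                     first = 2^-2.5, mz = 2^-1.5)

#' Classify a kinship coefficient into a relatedness degree
#'
#' Bins are half-open, lower-exclusive and upper-inclusive, centred on the
#' theoretical kinship values: `MZ/dup` above \eqn{2^{-1.5}} (0.3536), first
#' degree in (0.1768, 0.3536], second in (0.0884, 0.1768], third in
#' (0.0442, 0.0884], otherwise `unrelated`.
#'
#' @param phi Numeric vector of kinship coefficients.
#' @return Character vector in `{"MZ/dup", "1", "2", "3", "unrelated"}`.
#' @export
#' @examples
#' classify_degree(c(0.25, 0.125, 0.0625, 0.01))
classify_degree <- function(phi) {
  stopifnot(is.numeric(phi), all(is.finite(phi)))
  out <- rep("unrelated", length(phi))
  out[phi > .kinship_breaks[["third"]]] <- "3"
  out[phi > .kinship_breaks[["second"]]] <- "2"
  out[phi > .kinship_breaks[["first"]]] <- "1"
  out[phi > .kinship_breaks[["mz"]]] <- "MZ/dup"
  out
}

#' Robust pairwise kinship from genotypes
#'
#' Within-sample robust kinship estimator based on identity-by-state counts:
#' \deqn{\hat\phi = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}(i) + N_{Aa}(j)}}
#' where \eqn{N_{Aa,Aa}} counts SNPs heterozygous in both individuals,
#' \eqn{N_{AA,aa}} counts opposite homozygotes and \eqn{N_{Aa}(\cdot)} the
#' heterozygous SNPs of each individual. SNPs missing in either individual
#' are excluded pairwise.
#'
#' @param genotypes A [geno_matrix()].
#' @param id_i,id_j Individual ids.
#' @return A one-row tibble with `id_i`, `id_j`, `phi`, `degree`.
#' @export
estimate_kinship <- function(genotypes, id_i, id_j) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  gi <- genotypes$dosage[id_i, ]
  gj <- genotypes$dosage[id_j, ]
  keep <- !is.na(gi) & !is.na(gj)
  if (sum(keep) < 100) {
    stop("fewer than 100 SNPs with both individuals non-missing", call. = FALSE)
  }
  gi <- gi[keep]; gj <- gj[keep]
  n_het_both <- sum(gi == 1L & gj == 1L)
  n_opp_hom <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  denom <- sum(gi == 1L) + sum(gj == 1L)
  if (denom == 0) {
    stop("kinship undefined: neither individual has heterozygous SNPs",
         call. = FALSE)
  }
  phi <- (n_het_both - 2 * n_opp_hom) / denom
  tibble::tibble(id_i = id_i, id_j = id_j, phi = phi,
                 degree = classify_degree(phi))
}

#' All-pairs robust kinship
#'
#' Vectorised version of [estimate_kinship()] for every unordered pair,
#' computed from heterozygosity/opposite-homozygote count matrices.
#' Missing dosages are treated as non-informative for the counts.
#'
#' @param genotypes A [geno_matrix()].
#' @param min_degree Drop pairs less related than this degree
#'   (`"unrelated"` keeps all pairs).
#' @return A tibble with `id_i`, `id_j`, `phi`, `degree`.
#' @export
estimate_kinship_all <- function(genotypes,
                                 min_degree = c("unrelated", "3", "2", "1")) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  min_degree <- match.arg(min_degree)
  d <- genotypes$dosage
  het <- (!is.na(d) & d == 1L) * 1
  hom0 <- (!is.na(d) & d == 0L) * 1
  hom2 <- (!is.na(d) & d == 2L) * 1
  n_het_both <- tcrossprod(het)
  n_opp_hom <- tcrossprod(hom0, hom2)
  n_opp_hom <- n_opp_hom + t(n_opp_hom)
  n_het <- rowSums(het)
  denom <- outer(n_het, n_het, "+")
  phi <- (n_het_both - 2 * n_opp_hom) / denom
  idx <- which(lower.tri(phi), arr.ind = TRUE)
  out <- tibble::tibble(
    id_i = genotypes$ids[idx[, 1]],
    id_j = genotypes$ids[idx[, 2]],
    phi = phi[idx]
  )
  out <- out[is.finite(out$phi), , drop = FALSE]
  out$degree <- classify_degree(out$phi)
  if (min_degree != "unrelated") {
    keep_levels <- switch(min_degree,
      "3" = c("MZ/dup", "1", "2", "3"),
      "2" = c("MZ/dup", "1", "2"),
      "1" = c("MZ/dup", "1")
    )
    out <- out[out$degree %in% keep_levels, , drop = FALSE]
  }
  out
}

#' True kinship pairs from a pedigree
#'
#' Converts the numerator relationship matrix into pairwise kinship
#' coefficients (\eqn{\phi_{ij} = a_{ij}/2}) with degree labels, e.g. for
#' building study designs from simulation truth instead of estimated
#' kinship.
#'
#' @param pedigree A pedigree tibble.
#' @param min_degree As in [estimate_kinship_all()].
#' @return A tibble with `id_i`, `id_j`, `phi`, `degree`.
#' @export
pedigree_kinship <- function(pedigree,
                             min_degree = c("unrelated", "3", "2", "1")) {
  min_degree <- match.arg(min_degree)
  A <- compute_a_matrix(pedigree)
  out <- tidy(A, diagonal = FALSE)
  out$phi <- out$value / 2
  out$value <- NULL
  out$degree <- classify_degree(out$phi)
  if (min_degree != "unrelated") {
    keep_levels <- switch(min_degree,
      "3" = c("MZ/dup", "1", "2", "3"),
      "2" = c("MZ/dup", "1", "2"),
      "1" = c("MZ/dup", "1")
    )
    out <- out[out$degree %in% keep_levels, , drop = FALSE]
  }
  out
}
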