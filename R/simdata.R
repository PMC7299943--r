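#' Simulation configuration
#'
#' Bundles and validates all parameters of the family-structured simulator.
#' The phenotype model is \eqn{y = g + f + e} on a standardised scale:
#' `h2` is the narrow-sense heritability (variance share of the additive
#' polygenic value `g`), `f2` the variance share of a family effect `f`
#' shared by all members of the same sibship, and the residual takes the
#' remainder `1 - h2 - f2`.
#'
#' @param n_families Number of independent families.
#' @param sibship_size Number of children per mated couple.
#' @param n_generations Pedigree depth, 2 (parents + children) or 3
#'   (additionally each child is mated to a new unrelated founder and has
#'   `sibship_size` children, creating avuncular, grandparental and
#'   first-cousin pairs).
#' @param n_snps Number of independent biallelic SNPs.
#' @param maf_range Length-2 numeric, founder minor-allele-frequency range
#'   (uniform draw per SNP).
#' @param h2 Narrow-sense heritability in `[0, 1]`.
#' @param f2 Family-effect variance fraction in `[0, 1)`; `h2 + f2 <= 1`.
#' @param prevalence Optional case prevalence in (0, 1); when set,
#'   [simulate_phenotypes()] thresholds the liability into a binary trait.
#' @param causal_fraction Fraction of SNPs with non-zero effects in (0, 1].
#' @param seed Master integer seed; per-stage streams are derived from it by
#'   fixed offsets so each stage is reproducible in isolation.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_families = 10, sibship_size = 2, n_snps = 100)
sim_config <- function(n_families,
                       sibship_size = 2,
                       n_generations = 2,
                       n_snps = 1000,
                       maf_range = c(0.1, 0.5),
                       h2 = 0.5,
                       f2 = 0,
                       prevalence = NULL,
                       causal_fraction = 1,
                       seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) {
      stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
    }
  }
  chk(is.numeric(n_families) && length(n_families) == 1 && n_families >= 1,
      "n_families", "must be a single integer >= 1")
  chk(is.numeric(sibship_size) && length(sibship_size) == 1 && sibship_size >= 1,
      "sibship_size", "must be a single integer >= 1")
  chk(n_generations %in% c(2, 3), "n_generations", "must be 2 or 3")
  chk(is.numeric(n_snps) && length(n_snps) == 1 && n_snps >= 1,
      "n_snps", "must be a single integer >= 1")
  chk(is.numeric(maf_range) && length(maf_range) == 2 &&
        maf_range[1] > 0 && maf_range[2] < 1 && maf_range[1] <= maf_range[2],
      "maf_range", "must be (low, high) with 0 < low <= high < 1")
  chk(is.numeric(h2) && length(h2) == 1 && h2 >= 0 && h2 <= 1,
      "h2", "must be in [0, 1]")
  chk(is.numeric(f2) && length(f2) == 1 && f2 >= 0 && f2 < 1,
      "f2", "must be in [0, 1)")
  chk(h2 + f2 <= 1, "f2", "h2 + f2 must not exceed 1")
  if (!is.null(prevalence)) {
    chk(is.numeric(prevalence) && length(prevalence) == 1 &&
          prevalence > 0 && prevalence < 1,
        "prevalence", "must be in (0, 1)")
  }
  chk(is.numeric(causal_fraction) && length(causal_fraction) == 1 &&
        causal_fraction > 0 && causal_fraction <= 1,
      "causal_fraction", "must be in (0, 1]")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
      "seed", "must be a single finite integer")

  structure(
    list(
      n_families = as.integer(n_families),
      sibship_size = as.integer(sibship_size),
      n_generations = as.integer(n_generations),
      n_snps = as.integer(n_snps),
      maf_range = as.numeric(maf_range),
      h2 = as.numeric(h2),
      f2 = as.numeric(f2),
      prevalence = if (is.null(prevalence)) NULL else as.numeric(prevalence),
      causal_fraction = as.numeric(causal_fraction),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  families: %d x sibship %d, %d generations\n",
              x$n_families, x$sibship_size, x$n_generations))
  cat(sprintf("  SNPs: %d, MAF in [%.2f, %.2f], causal fraction %.2f\n",
              x$n_snps, x$maf_range[1], x$maf_range[2], x$causal_fraction))
  cat(sprintf("  h2 = %.2f, f2 = %.2f%s, seed = %d\n", x$h2, x$f2,
              if (is.null(x$prevalence)) "" else
                sprintf(", prevalence = %.2f", x$prevalence),
              x$seed))
  invisible(x)
}

# Fixed per-stage seed offsets derived from the master seed.
stage_seed <- function(config, stage) {
  offset <- c(pedigree = 101L, genotypes = 211L, phenotypes = 307L)[[stage]]
  (config$seed + offset) %% .Machine$integer.max
}

#' Generate a nuclear-family pedigree
#'
#' Builds `n_families` independent families. With two generations each family
#' is a founder couple and its sibship. With three generations every child of
#' the founder couple is mated to a new unrelated founder spouse and has
#' `sibship_size` children, so second-degree (avuncular, grandparental) and
#' third-degree (first-cousin) pairs exist within a family. Spouses are always
#' new unrelated founders; no inbreeding loops are generated.
#'
#' @param config A [sim_config()].
#' @return A tibble of class `pedigree` with columns `id`, `sire`, `dam`
#'   (`NA` for founders), `sex` (`"M"`/`"F"`), `family_id` and `generation`
#'   (1 = founders). Parents always precede their offspring.
#' @export
#' @examples
#' generate_pedigree(sim_config(n_families = 2, sibship_size = 3))
generate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fams <- purrr::map(seq_len(config$n_families), function(f) {
    fid <- sprintf("F%04d", f)
    sexes <- rep(c("M", "F"), length.out = config$sibship_size)
    rows <- list(
      tibble::tibble(
        id = paste0(fid, c("_P1", "_P2")),
        sire = NA_character_, dam = NA_character_,
        sex = c("M", "F"), family_id = fid, generation = 1L
      ),
      tibble::tibble(
        id = sprintf("%s_C%d", fid, seq_len(config$sibship_size)),
        sire = paste0(fid, "_P1"), dam = paste0(fid, "_P2"),
        sex = sexes, family_id = fid, generation = 2L
      )
    )
    if (config$n_generations == 3) {
      for (c_i in seq_len(config$sibship_size)) {
        child <- sprintf("%s_C%d", fid, c_i)
        spouse <- sprintf("%s_S%d", fid, c_i)
        child_sex <- sexes[c_i]
        rows <- c(rows, list(
          tibble::tibble(
            id = spouse, sire = NA_character_, dam = NA_character_,
            sex = if (child_sex == "M") "F" else "M",
            family_id = fid, generation = 1L
          ),
          tibble::tibble(
            id = sprintf("%s_C%d_G%d", fid, c_i, seq_len(config$sibship_size)),
            sire = if (child_sex == "M") child else spouse,
            dam = if (child_sex == "M") spouse else child,
            sex = rep(c("M", "F"), length.out = config$sibship_size),
            family_id = fid, generation = 3L
          )
        ))
      }
    }
    dplyr::bind_rows(rows)
  })
  ped <- dplyr::bind_rows(fams)
  ped <- ped[order(ped$generation, ped$id), , drop = FALSE]
  new_pedigree(ped)
}

new_pedigree <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  validate_pedigree(tbl)
  class(tbl) <- c("pedigree", class(tbl))
  tbl
}

#' Validate a pedigree table
#'
#' Checks id uniqueness, parent existence and acyclicity, and returns the ids
#' in a topological order (parents before offspring).
#'
#' @param ped A data frame with columns `id`, `sire`, `dam` (`NA` = unknown).
#' @return Invisibly, the character vector of ids in topological order.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$id)) {
    stop("pedigree ids are not unique: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "),
         call. = FALSE)
  }
  parents <- c(ped$sire, ped$dam)
  bad <- setdiff(stats::na.omit(parents), ped$id)
  if (length(bad)) {
    stop("unknown parent id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  # Kahn's algorithm on the parent -> offspring graph.
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  indeg <- (!is.na(ped$sire)) + (!is.na(ped$dam))
  children <- vector("list", n)
  for (j in seq_len(n)) {
    for (p in c(ped$sire[j], ped$dam[j])) {
      if (!is.na(p)) children[[idx[[p]]]] <- c(children[[idx[[p]]]], j)
    }
  }
  order_out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    j <- queue[1L]; queue <- queue[-1L]
    order_out <- c(order_out, j)
    for (k in children[[j]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order_out) < n) {
    stop("pedigree contains a cycle (an individual is its own ancestor)",
         call. = FALSE)
  }
  invisible(ped$id[order_out])
}

#' Genotype matrix container
#'
#' Wraps an individuals-by-SNPs matrix of alternate-allele counts
#' \{0, 1, 2\} (`NA` = missing) together with per-SNP alternate-allele
#' frequencies. Frequencies default to the realised frequencies
#' `colMeans(dosage)/2`.
#'
#' @param dosage Integer matrix, rows named by individual id, columns by SNP
#'   id, entries in \{0, 1, 2, NA\}.
#' @param freqs Optional per-SNP alternate-allele frequencies.
#' @return An object of class `geno_matrix` with fields `dosage`, `ids`,
#'   `snp_ids`, `freqs`.
#' @export
geno_matrix <- function(dosage, freqs = NULL) {
  stopifnot(is.matrix(dosage))
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("ind%d", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("snp%05d", seq_len(ncol(dosage)))
  }
  if (is.null(freqs)) freqs <- colMeans(dosage, na.rm = TRUE) / 2
  stopifnot(length(freqs) == ncol(dosage))
  structure(
    list(dosage = dosage, ids = rownames(dosage),
         snp_ids = colnames(dosage), freqs = unname(freqs)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d SNPs", length(x$ids),
              length(x$snp_ids)))
  n_miss <- sum(is.na(x$dosage))
  if (n_miss) cat(sprintf(", %d missing dosages", n_miss))
  cat(sprintf("\n  alt-allele freq: %.3f-%.3f\n",
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by individual ids
#'
#' @param genotypes A [geno_matrix()].
#' @param ids Individual ids to keep, in the requested order.
#' @param recompute_freqs Recompute allele frequencies on the subset
#'   (default keeps the original, full-sample frequencies).
#' @return A `geno_matrix`.
#' @export
subset_genotypes <- function(genotypes, ids, recompute_freqs = FALSE) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  missing_ids <- setdiff(ids, genotypes$ids)
  if (length(missing_ids)) {
    stop("ids not in genotype matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  d <- genotypes$dosage[ids, , drop = FALSE]
  geno_matrix(d, freqs = if (recompute_freqs) NULL else genotypes$freqs)
}

#' Drop SNPs by minor-allele-frequency
#'
#' @param genotypes A [geno_matrix()].
#' @param min_maf Minimum minor-allele frequency to retain a SNP.
#' @return A `geno_matrix` with the surviving SNPs.
#' @export
filter_maf <- function(genotypes, min_maf = 0.01) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  maf <- pmin(genotypes$freqs, 1 - genotypes$freqs)
  keep <- maf >= min_maf
  geno_matrix(genotypes$dosage[, keep, drop = FALSE],
              freqs = genotypes$freqs[keep])
}

#' Simulate genotypes down a pedigree by gene dropping
#'
#' Per-SNP founder alternate-allele frequencies are drawn uniformly from
#' `config$maf_range`; founder dosages are Binomial(2, p). Each non-founder
#' receives, per locus, one allele sampled from each parent (for unlinked
#' loci this is a Bernoulli(dosage/2) draw per parent, exactly equivalent to
#' sampling one of the parent's two alleles). Loci are independent: there is
#' no linkage disequilibrium, so the effective number of segments of an
#' unrelated sample is approximately the SNP count.
#'
#' @param pedigree A [generate_pedigree()] result (or compatible tibble).
#' @param config A [sim_config()]; `n_snps` and `maf_range` are used.
#' @return A [geno_matrix()] with rows in pedigree order.
#' @export
simulate_genotypes <- function(pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  topo <- validate_pedigree(pedigree)
  m <- config$n_snps
  withr::with_seed(stage_seed(config, "genotypes"), {
    p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    dosage <- matrix(NA_integer_, nrow(pedigree), m,
                     dimnames = list(pedigree$id,
                                     sprintf("snp%05d", seq_len(m))))
    is_founder <- is.na(pedigree$sire) & is.na(pedigree$dam)
    founders <- pedigree$id[is_founder]
    dosage[founders, ] <- matrix(
      stats::rbinom(length(founders) * m, 2L, rep(p, each = length(founders))),
      nrow = length(founders)
    )
    sire_of <- stats::setNames(pedigree$sire, pedigree$id)
    dam_of <- stats::setNames(pedigree$dam, pedigree$id)
    for (id in topo) {
      if (id %in% founders) next
      dosage[id, ] <- stats::rbinom(m, 1L, dosage[sire_of[[id]], ] / 2) +
        stats::rbinom(m, 1L, dosage[dam_of[[id]], ] / 2)
    }
    geno_matrix(dosage)
  })
}

#' Simulate phenotypes with additive, family and residual components
#'
#' The polygenic value is \eqn{g_j = \sum_k w_{jk}\beta_k} over a causal SNP
#' subset, with `w` the standardised dosage and
#' \eqn{\beta_k \sim N(0, h^2/M_c)}; `g` is then rescaled so its sample
#' variance equals `h2` exactly, removing Monte-Carlo drift in the realised
#' heritability. The family effect `f` is a single \eqn{N(0, f^2)} draw
#' shared by all members of a `family_id`; the residual is
#' \eqn{N(0, 1 - h^2 - f^2)}. In binary mode the liability is thresholded at
#' its empirical `1 - prevalence` quantile.
#'
#' @param genotypes A [geno_matrix()].
#' @param pedigree Pedigree tibble supplying `family_id` (may cover a
#'   superset of the genotyped ids).
#' @param config A [sim_config()].
#' @return A tibble of class `phenotype_tbl` with columns `id`, `trait`,
#'   `true_g`, `true_f` and, for binary traits, `liability`; the trait type
#'   is stored in attribute `trait_type`.
#' @export
simulate_phenotypes <- function(genotypes, pedigree, config) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(config, "sim_config"))
  if (config$h2 + config$f2 > 1) stop("h2 + f2 must not exceed 1", call. = FALSE)
  ids <- genotypes$ids
  fam <- stats::setNames(pedigree$family_id, pedigree$id)[ids]
  if (anyNA(fam)) stop("all genotyped ids must appear in the pedigree",
                       call. = FALSE)
  n <- length(ids)
  m <- length(genotypes$snp_ids)
  withr::with_seed(stage_seed(config, "phenotypes"), {
    poly <- which(genotypes$freqs > 0 & genotypes$freqs < 1)
    if (!length(poly)) stop("no polymorphic SNPs to act as causal variants",
                            call. = FALSE)
    m_causal <- max(1L, ceiling(config$causal_fraction * length(poly)))
    causal <- sort(sample(poly, m_causal))
    if (config$h2 > 0) {
      p <- genotypes$freqs[causal]
      w <- genotypes$dosage[, causal, drop = FALSE]
      w <- sweep(w, 2, 2 * p, "-")
      w <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
      beta <- stats::rnorm(m_causal, 0, sqrt(config$h2 / m_causal))
      g <- drop(w %*% beta)
      v <- stats::var(g)
      g <- if (v > 0) g * sqrt(config$h2 / v) else g
    } else {
      g <- rep(0, n)
    }
    fam_levels <- unique(fam)
    f_by_fam <- stats::setNames(
      stats::rnorm(length(fam_levels), 0, sqrt(config$f2)), fam_levels)
    f <- unname(f_by_fam[fam])
    e_sd <- sqrt(max(0, 1 - config$h2 - config$f2))
    e <- if (e_sd > 0) stats::rnorm(n, 0, e_sd) else rep(0, n)
    y <- unname(g + f + e)
    out <- tibble::tibble(id = ids, trait = y, true_g = unname(g),
                          true_f = unname(f))
    trait_type <- "quantitative"
    if (!is.null(config$prevalence)) {
      thr <- stats::quantile(y, 1 - config$prevalence, names = FALSE)
      out$liability <- y
      out$trait <- as.numeric(y > thr)
      trait_type <- "binary"
    }
    new_phenotype_tbl(out, trait_type)
  })
}

new_phenotype_tbl <- function(tbl, trait_type = "quantitative") {
  stopifnot(trait_type %in% c("quantitative", "binary"))
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(c("id", "trait") %in% names(tbl)))
  if (trait_type == "binary" && !all(tbl$trait %in% c(0, 1))) {
    stop("binary traits must contain only 0/1 values", call. = FALSE)
  }
  attr(tbl, "trait_type") <- trait_type
  class(tbl) <- unique(c("phenotype_tbl", class(tbl)))
  tbl
}

#' Trait type of a phenotype table
#' @param pheno A phenotype tibble from [simulate_phenotypes()] or
#'   [adjust_phenotype()].
#' @return `"quantitative"` or `"binary"`.
#' @export
trait_type <- function(pheno) {
  attr(pheno, "trait_type") %||% "quantitative"
}

#' Simulate a cohort end to end
#'
#' Convenience wrapper running [generate_pedigree()],
#' [simulate_genotypes()] and [simulate_phenotypes()].
#'
#' @param config A [sim_config()].
#' @return A list with elements `pedigree`, `genotypes`, `phenotypes`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_families = 5, n_snps = 50))
simulate_cohort <- function(config) {
  ped <- generate_pedigree(config)
  geno <- simulate_genotypes(ped, config)
  pheno <- simulate_phenotypes(geno, ped, config)
  list(pedigree = ped, genotypes = geno, phenotypes = pheno)
}
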