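# Shared fixtures and independent oracles for the test suite.

# Hand-built three-generation pedigree containing a first-cousin pair:
# founder couple GP1xGP2 with two children U1, U2; each child mated to an
# unrelated founder spouse; one child per couple (K1, K2 are first cousins).
cousin_pedigree <- function() {
  tibble::tibble(
    id = c("GP1", "GP2", "U1", "U2", "S1", "S2", "K1", "K2"),
    sire = c(NA, NA, "GP1", "GP1", NA, NA, "U1", "S2"),
    dam = c(NA, NA, "GP2", "GP2", NA, NA, "S1", "U2"),
    sex = c("M", "F", "M", "F", "F", "M", "M", "F"),
    family_id = "FAM1",
    generation = c(1L, 1L, 2L, 2L, 1L, 1L, 3L, 3L)
  )
}

# Pedigree with a parent-offspring mating producing an inbred individual.
inbred_pedigree <- function() {
  tibble::tibble(
    id = c("A", "B", "C", "D"),
    sire = c(NA, NA, "A", "A"),
    dam = c(NA, NA, "B", "C"),
    sex = c("M", "F", "F", "F"),
    family_id = "FAM1",
    generation = c(1L, 1L, 2L, 3L)
  )
}

# Independent gene-dropping IBD oracle for expected additive relationships:
# drops distinct founder allele labels down the pedigree `reps` times at a
# single unlinked locus and estimates a_ij = 2 * P(random alleles IBD).
# Completely independent of the tabular recursion in compute_a_matrix().
gene_drop_relationship <- function(ped, reps = 2e5, seed = 99) {
  ids <- ped$id
  n <- length(ids)
  withr::with_seed(seed, {
    al1 <- matrix(0L, reps, n, dimnames = list(NULL, ids))
    al2 <- matrix(0L, reps, n, dimnames = list(NULL, ids))
    next_label <- 1L
    ord <- kinpred::validate_pedigree(ped)
    for (id in ord) {
      row <- ped[ped$id == id, ]
      if (is.na(row$sire)) {
        al1[, id] <- next_label
        al2[, id] <- next_label + 1L
        next_label <- next_label + 2L
      } else {
        pick1 <- stats::runif(reps) < 0.5
        pick2 <- stats::runif(reps) < 0.5
        al1[, id] <- ifelse(pick1, al1[, row$sire], al2[, row$sire])
        al2[, id] <- ifelse(pick2, al1[, row$dam], al2[, row$dam])
      }
    }
    a <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) {
      for (j in i:n) {
        phi <- mean((al1[, i] == al1[, j]) + (al1[, i] == al2[, j]) +
                      (al2[, i] == al1[, j]) + (al2[, i] == al2[, j])) / 4
        a[i, j] <- a[j, i] <- 2 * phi
      }
    }
    # diagonal: phi_ii = (2 + 2*P(al1 == al2))/4 = (1 + F)/2, so a_ii = 1 + F
    a
  })
}

# Large sib-pair genotype fixture shared across files (computed once per
# test run): 60 full-sib pairs at 20,000 independent SNPs.
.fixture_cache <- new.env(parent = emptyenv())

sib_pair_fixture <- function() {
  if (!is.null(.fixture_cache$sibs)) return(.fixture_cache$sibs)
  cfg <- kinpred::sim_config(n_families = 60, sibship_size = 2,
                             n_generations = 2, n_snps = 20000,
                             maf_range = c(0.1, 0.5), h2 = 0.5, seed = 2024)
  ped <- kinpred::generate_pedigree(cfg)
  geno <- kinpred::simulate_genotypes(ped, cfg)
  .fixture_cache$sibs <- list(config = cfg, pedigree = ped, genotypes = geno)
  .fixture_cache$sibs
}

sib_ids <- function(ped) {
  list(first = ped$id[grepl("_C1$", ped$id)],
       second = ped$id[grepl("_C2$", ped$id)])
}
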