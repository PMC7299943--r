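test_that("standardized GRM reproduces hand-computed values", {
  # single SNP, dosages (0,1,2), realised p = 0.5
  d <- matrix(c(0L, 1L, 2L), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  G <- compute_grm(geno_matrix(d))
  expect_equal(diag(G$values), c(a = 2, b = 0, c = 2))
  expect_equal(G$values["a", "c"], -2)

  # identical genotype rows give G_ij = G_ii = G_jj
  d2 <- rbind(x = c(0L, 1L, 2L, 1L), y = c(0L, 1L, 2L, 1L),
              z = c(1L, 0L, 1L, 2L))
  colnames(d2) <- paste0("s", 1:4)
  G2 <- compute_grm(geno_matrix(d2))
  expect_equal(G2$values["x", "y"], G2$values["x", "x"])
  expect_equal(G2$values["x", "x"], G2$values["y", "y"])

  # raw mode uses the 0/1/2 coding verbatim
  G_raw <- compute_grm(geno_matrix(d2), standardize = FALSE)
  expect_equal(G_raw$values["x", "x"], sum(c(0, 1, 2, 1)^2) / 4)
})

test_that("GRM diagonal averages one in a large unrelated sample", {
  cfg <- sim_config(n_families = 300, sibship_size = 1, n_snps = 5000,
                    seed = 41)
  ped <- generate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  founders <- ped$id[is.na(ped$sire)]  # 600 unrelated founders
  G <- compute_grm(subset_genotypes(geno, founders, recompute_freqs = TRUE))
  expect_lt(abs(mean(diag(G$values)) - 1), 0.02)
})

test_that("monomorphic SNPs are refused under standardization", {
  d <- matrix(c(0L, 0L, 0L, 1L, 2L, 1L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("mono", "poly")))
  expect_error(compute_grm(geno_matrix(d)), "mono")
  expect_silent(compute_grm(geno_matrix(d), standardize = FALSE))
})

test_that("missing dosages are imputed to 2p in the GRM", {
  d <- matrix(c(0L, 1L, 2L, NA, 1L, 1L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  g <- geno_matrix(d)
  G <- compute_grm(g)
  d_imp <- d
  d_imp[1, 2] <- 2 * g$freqs[2]  # freq computed on non-missing entries
  w <- sweep(sweep(d_imp, 2, 2 * g$freqs, "-"), 2,
             sqrt(2 * g$freqs * (1 - g$freqs)), "/")
  expect_equal(G$values, tcrossprod(w) / 2, tolerance = 1e-12)
})

test_that("A matrix follows the tabular method on textbook cases", {
  ped <- generate_pedigree(sim_config(n_families = 1, sibship_size = 2))
  A <- compute_a_matrix(ped)
  expect_equal(diag(A$values), rep(1, 4), ignore_attr = TRUE)
  expect_equal(A$values["F0001_P1", "F0001_C1"], 0.5)  # parent-offspring
  expect_equal(A$values["F0001_C1", "F0001_C2"], 0.5)  # full sibs
  expect_equal(A$values["F0001_P1", "F0001_P2"], 0)    # unrelated founders

  # offspring of a parent-offspring mating: F = 0.25, diagonal 1.25
  Ai <- compute_a_matrix(inbred_pedigree())
  expect_equal(Ai$values["D", "D"], 1.25)

  # unknown parent id is an error
  bad <- tibble::tibble(id = "X", sire = "GHOST", dam = NA_character_,
                        sex = "M", family_id = "F", generation = 1L)
  expect_error(compute_a_matrix(bad), "GHOST")
})

test_that("A matrix agrees with the gene-dropping IBD oracle", {
  for (ped in list(cousin_pedigree(), inbred_pedigree(),
                   generate_pedigree(sim_config(n_families = 2,
                                                sibship_size = 3,
                                                n_generations = 3)))) {
    A <- compute_a_matrix(ped)
    a_mc <- gene_drop_relationship(ped, reps = 2e5)
    expect_lt(max(abs(A$values - a_mc[A$ids, A$ids])), 0.01)
  }
  # the hand pedigree contains a first-cousin pair at exactly 1/8
  A <- compute_a_matrix(cousin_pedigree())
  expect_equal(A$values["K1", "K2"], 0.125)
})

test_that("H matrix collapses correctly in its degenerate configurations", {
  cfg <- sim_config(n_families = 10, sibship_size = 2, n_snps = 500, seed = 51)
  co <- simulate_cohort(cfg)
  A <- compute_a_matrix(co$pedigree)
  G <- compute_grm(co$genotypes)

  # everyone genotyped: H = G
  H_all <- compute_h_matrix(A, G)
  expect_lt(max(abs(H_all$values[G$ids, G$ids] - G$values)), 1e-12)

  # G numerically equal to A22: H = A
  kids <- co$pedigree$id[!is.na(co$pedigree$sire)]
  A22 <- rel_matrix(A$values[kids, kids], "G")
  H_a <- compute_h_matrix(A, A22, genotyped_ids = kids)
  expect_lt(max(abs(H_a$values[A$ids, A$ids] - A$values)), 1e-10)

  # id mismatch is an error
  expect_error(compute_h_matrix(A, G, genotyped_ids = c(G$ids, "NOPE")),
               "exactly")
})

test_that("H matrix matches direct block arithmetic on a trio", {
  ped <- generate_pedigree(sim_config(n_families = 1, sibship_size = 1))
  founders <- ped$id[is.na(ped$sire)]
  kid <- setdiff(ped$id, founders)
  A <- compute_a_matrix(ped)
  g <- matrix(c(1.05, -0.1, -0.1, 0.98), 2, 2,
              dimnames = list(founders, founders))
  G <- rel_matrix(g, "G")
  H <- compute_h_matrix(A, G)
  # independent evaluation of the printed blocks
  a12 <- A$values[kid, founders, drop = FALSE]
  a22 <- A$values[founders, founders]
  a22i <- solve(a22)
  h11 <- A$values[kid, kid] + a12 %*% a22i %*% (g - a22) %*% a22i %*% t(a12)
  h12 <- a12 %*% a22i %*% g
  expect_lt(abs(H$values[kid, kid] - h11), 1e-10)
  expect_lt(max(abs(H$values[kid, founders] - h12)), 1e-10)
  expect_lt(max(abs(H$values[founders, founders] - g)), 1e-12)
  expect_equal(H$ids, A$ids)
})

test_that("kinship estimator matches hand-counted examples", {
  # identical genotypes with heterozygous sites: phi = 0.5, MZ/duplicate
  d <- matrix(rep(c(0L, 1L, 2L, 1L), each = 2), 2, 4, byrow = FALSE,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  d_big <- d[, rep(1:4, 50)]
  colnames(d_big) <- paste0("s", seq_len(ncol(d_big)))
  k <- estimate_kinship(geno_matrix(d_big), "a", "b")
  expect_equal(k$phi, 0.5)
  expect_equal(k$degree, "MZ/dup")

  # opposite homozygotes everywhere: undefined kinship
  d2 <- rbind(a = rep(0L, 200), b = rep(2L, 200))
  colnames(d2) <- paste0("s", 1:200)
  expect_error(estimate_kinship(geno_matrix(d2), "a", "b"), "undefined")

  # engineered counts: N_AaAa = 50, N_AAaa = 10, N_Aa(i) = 120, N_Aa(j) = 80
  gi <- c(rep(1L, 50), rep(1L, 70), rep(0L, 30), rep(0L, 10), rep(0L, 40))
  gj <- c(rep(1L, 50), rep(0L, 70), rep(1L, 30), rep(2L, 10), rep(0L, 40))
  d3 <- rbind(i = gi, j = gj)
  colnames(d3) <- paste0("s", seq_along(gi))
  k3 <- estimate_kinship(geno_matrix(d3), "i", "j")
  expect_equal(k3$phi, (50 - 2 * 10) / (120 + 80))
  expect_equal(k3$degree, "2")
})

test_that("kinship estimates recover pedigree degrees in simulation", {
  fx <- sib_pair_fixture()
  sibs <- sib_ids(fx$pedigree)
  # parent-offspring pairs: phi ~ 0.25
  phis <- vapply(seq_len(30), function(i) {
    fam <- sprintf("F%04d", i)
    estimate_kinship(fx$genotypes, paste0(fam, "_P1"), paste0(fam, "_C1"))$phi
  }, numeric(1))
  expect_lt(abs(mean(phis) - 0.25), 0.03)
  # full sibs via the GRM: mean relationship ~ 0.5
  cross <- compute_grm_cross(fx$genotypes, sibs$first, sibs$second)
  expect_lt(abs(mean(diag(cross)) - 0.5), 0.03)
  # the all-pairs scan flags exactly the true first-degree pairs as degree 1
  sub_ids <- fx$pedigree$id[fx$pedigree$family_id %in%
                              sprintf("F%04d", 1:10)]
  all_k <- estimate_kinship_all(subset_genotypes(fx$genotypes, sub_ids),
                                min_degree = "1")
  truth <- pedigree_kinship(fx$pedigree[fx$pedigree$id %in% sub_ids, ],
                            min_degree = "1")
  key <- function(t) sort(paste(pmin(t$id_i, t$id_j), pmax(t$id_i, t$id_j)))
  expect_identical(key(all_k), key(truth))
})

test_that("degree classification uses lower-exclusive, upper-inclusive bins", {
  expect_equal(classify_degree(c(0.25, 0.125, 0.0625, 0.02)),
               c("1", "2", "3", "unrelated"))
  expect_equal(classify_degree(0.0442), "3")    # just above the 3rd cut
  expect_equal(classify_degree(2^-4.5), "unrelated")  # boundary -> lower bin
  expect_equal(classify_degree(2^-1.5), "1")          # boundary -> degree 1
  expect_equal(classify_degree(0.40), "MZ/dup")
})
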