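test_that("single-component REML recovers heritability and handles nulls", {
  cfg <- sim_config(n_families = 600, sibship_size = 1, n_snps = 1500,
                    h2 = 0.5, seed = 201)
  ped <- generate_pedigree(cfg)
  founders <- ped$id[is.na(ped$sire)]  # 1200 unrelated
  geno <- simulate_genotypes(ped, cfg)
  geno_f <- subset_genotypes(geno, founders, recompute_freqs = TRUE)
  G <- compute_grm(geno_f)

  # parameter recovery, averaged over phenotype replicates on a fixed G
  h2_hats <- vapply(1:3, function(r) {
    cfg_r <- sim_config(n_families = 600, sibship_size = 1, n_snps = 1500,
                        h2 = 0.5, seed = 201 + 10 * r)
    ph <- simulate_phenotypes(geno_f, ped, cfg_r)
    reml_single(G, ph)$h2_narrow
  }, numeric(1))
  expect_lt(abs(mean(h2_hats) - 0.5), 0.1)

  # null trait: estimate collapses towards the boundary
  cfg0 <- sim_config(n_families = 600, sibship_size = 1, n_snps = 1500,
                     h2 = 0, seed = 205)
  ph0 <- simulate_phenotypes(geno_f, ped, cfg0)
  expect_lt(reml_single(G, ph0)$h2_narrow, 0.05)

  # shift invariance of the variance components
  ph1 <- simulate_phenotypes(geno_f, ped, cfg)
  f1 <- reml_single(G, ph1)
  ph_shift <- dplyr::mutate(ph1, trait = trait + 5)
  f2 <- reml_single(G, ph_shift)
  expect_equal(f1$sigma_g2, f2$sigma_g2, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("REML rejects degenerate inputs", {
  ids <- sprintf("i%03d", 1:100)
  K_ident <- rel_matrix(diag(100) |> `dimnames<-`(list(ids, ids)), "G")
  y <- tibble::tibble(id = ids, trait = rnorm(100))
  expect_error(reml_single(K_ident, y), "identifiable")

  npd <- diag(100); npd[1, 2] <- npd[2, 1] <- 2
  K_npd <- rel_matrix(`dimnames<-`(npd, list(ids, ids)), "G")
  expect_error(reml_single(K_npd, y), "positive semi-definite")

  expect_error(reml_single(K_npd, y[1:10, ]), "at least 50")
  K_ok <- rel_matrix(`dimnames<-`(crossprod(matrix(rnorm(100 * 100), 100)) /
                                    100, list(ids, ids)), "G")
  expect_error(reml_single(K_ok, dplyr::mutate(y, trait = 1)),
               "zero variance")
  expect_error(reml_two(K_ok, family_block_matrix(
    tibble::tibble(id = ids, family_id = rep(1:20, each = 5))),
    dplyr::mutate(y, trait = 0)), "zero variance")
})

test_that("two-component REML separates genetic and family variance", {
  sim_fit <- function(h2, f2, seed) {
    cfg <- sim_config(n_families = 300, sibship_size = 3, n_snps = 1200,
                      h2 = h2, f2 = f2, seed = seed)
    co <- simulate_cohort(cfg)
    kids <- co$pedigree$id[!is.na(co$pedigree$sire)]  # 900 sibs
    geno_k <- subset_genotypes(co$genotypes, kids, recompute_freqs = TRUE)
    G <- compute_grm(geno_k)
    K2 <- family_block_matrix(co$pedigree, kids)
    reml_two(G, K2, co$phenotypes[co$phenotypes$id %in% kids, ])
  }
  fits <- lapply(1:3, function(r) sim_fit(0.4, 0.2, 300 + r))
  expect_true(all(vapply(fits, function(f) f$converged, logical(1))))
  expect_lt(abs(mean(vapply(fits, function(f) f$sigma_g2, numeric(1))) - 0.4),
            0.12)
  expect_lt(abs(mean(vapply(fits, function(f) f$sigma_f2, numeric(1))) - 0.2),
            0.12)
  expect_lt(abs(mean(vapply(fits, function(f) f$h2_family, numeric(1))) - 0.6),
            0.1)

  # null family variance collapses to the floor
  fit0 <- sim_fit(0.4, 0, 310)
  expect_lt(fit0$sigma_f2, 0.05)
})

test_that("BLUP obeys its closed-form special cases", {
  ids <- sprintf("d%02d", 1:20)
  K <- rel_matrix(`dimnames<-`(diag(20), list(ids, ids)), "G")
  y <- tibble::tibble(id = ids, trait = rnorm(20, 1))
  vc <- variance_components(sigma_g2 = 0.3, sigma_e2 = 0.7)

  # K = I, predicting the discovery records: plain shrinkage towards 0
  pred <- blup_predict(K, y, vc, ids)
  lambda <- 0.7 / 0.3
  mu_hat <- mean(y$trait)  # GLS mean = arithmetic mean under K = I
  expect_equal(pred$ghat, 0.3 / (0.3 + 0.7) * (y$trait - mu_hat),
               tolerance = 1e-10)

  # vanishing genetic variance: everything shrinks to zero
  vc0 <- variance_components(sigma_g2 = 0, sigma_e2 = 1)
  expect_equal(blup_predict(K, y, vc0, ids)$ghat, rep(0, 20))
})

test_that("BLUP matches a dense Henderson mixed-model-equation solve", {
  ids <- c("d1", "d2", "d3", "t1", "t2")
  set.seed(42)
  L <- matrix(rnorm(25), 5)
  K <- crossprod(L) / 5 + diag(0.5, 5)
  dimnames(K) <- list(ids, ids)
  Krel <- rel_matrix(K, "G")
  y <- tibble::tibble(id = c("d1", "d2", "d3"), trait = c(0.3, -1.1, 0.7))
  vc <- variance_components(sigma_g2 = 0.4, sigma_e2 = 0.6)
  pred <- blup_predict(Krel, y, vc, c("t1", "t2"))

  # independent oracle: full Henderson MME over all five genetic effects
  lambda <- vc$sigma_e2 / vc$sigma_g2
  Z <- matrix(0, 3, 5); Z[cbind(1:3, 1:3)] <- 1
  X <- matrix(1, 3, 1)
  lhs <- rbind(
    cbind(crossprod(X), crossprod(X, Z)),
    cbind(crossprod(Z, X), crossprod(Z) + lambda * solve(K))
  )
  rhs <- rbind(crossprod(X, y$trait), crossprod(Z, y$trait))
  sol <- solve(lhs, rhs)
  expect_lt(max(abs(pred$ghat - sol[c(5, 6)])), 1e-8)
})

test_that("GBLUP is identical to SNP-ridge with matched penalty", {
  cfg <- sim_config(n_families = 40, sibship_size = 2, n_snps = 120,
                    h2 = 0.5, seed = 401)
  co <- simulate_cohort(cfg)
  ids <- co$pedigree$id
  disc <- ids[1:120]; targ <- ids[121:160]
  geno <- subset_genotypes(co$genotypes, ids, recompute_freqs = TRUE)
  vc <- variance_components(sigma_g2 = 0.5, sigma_e2 = 0.5)
  yd <- co$phenotypes[co$phenotypes$id %in% disc, ]
  g_blup <- blup_predict(compute_grm(geno), yd, vc, targ)
  g_ridge <- ridge_predict(geno, yd, vc, targ)
  expect_lt(max(abs(g_blup$ghat - g_ridge$ghat)), 1e-6)
})

test_that("HBLUP exploits ungenotyped relatives' phenotypes", {
  # families of six; one child per family is a target, parents and one
  # child are ungenotyped but phenotyped
  accs <- vapply(1:5, function(r) {
    cfg <- sim_config(n_families = 120, sibship_size = 4, n_snps = 800,
                      h2 = 0.6, f2 = 0, seed = 500 + r)
    co <- simulate_cohort(cfg)
    ped <- co$pedigree
    targets <- ped$id[grepl("_C1$", ped$id)]
    geno_disc <- ped$id[grepl("_C2$|_C3$", ped$id)]
    ungeno <- setdiff(ped$id, c(targets, geno_disc))
    adj <- adjust_phenotype(co$phenotypes)
    yd <- adj[adj$id %in% c(geno_disc, ungeno), ]
    geno <- subset_genotypes(co$genotypes, c(geno_disc, targets))
    G <- compute_grm(geno)
    A <- compute_a_matrix(ped)
    H <- compute_h_matrix(A, G)
    vc <- variance_components(sigma_g2 = 0.6, sigma_e2 = 0.4)
    acc_h <- empirical_accuracy(blup_predict(H, yd, vc, targets), adj)
    acc_g <- empirical_accuracy(
      blup_predict(G, yd[yd$id %in% geno_disc, ], vc, targets), adj)
    acc_h - acc_g
  }, numeric(1))
  expect_gt(mean(accs), 0)
})
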