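test_that("pruning removes exactly one member of each violating pair", {
  pairs <- tibble::tibble(id_i = "A", id_j = "B", value = 0.3)
  ids <- c("A", "B", "C")
  kept <- prune_unrelated(pairs, threshold = 0.05, seed = 1, ids = ids)
  expect_length(kept, 2)
  expect_true("C" %in% kept)
  expect_identical(kept,
                   prune_unrelated(pairs, threshold = 0.05, seed = 1,
                                   ids = ids))  # reproducible by seed

  # nothing above the threshold: everyone retained
  low <- tibble::tibble(id_i = "A", id_j = "B", value = 0.01)
  expect_setequal(prune_unrelated(low, seed = 2, ids = ids), ids)

  # empty input, empty output
  expect_length(prune_unrelated(low[0, ], seed = 1), 0)
})

test_that("pruning a chain always ends below the threshold", {
  # A-B and B-C exceed the cut, A-C does not; every removal order is valid
  chain <- tibble::tibble(id_i = c("A", "B"), id_j = c("B", "C"),
                          value = c(0.3, 0.3))
  above <- function(kept) {
    any(apply(chain, 1, function(r)
      r[["id_i"]] %in% kept && r[["id_j"]] %in% kept))
  }
  outcomes <- lapply(1:20, function(s)
    sort(prune_unrelated(chain, seed = s, ids = c("A", "B", "C"))))
  expect_true(all(!vapply(outcomes, above, logical(1))))
  # removing B is possible and retains both A and C
  expect_true(any(vapply(outcomes, identical, logical(1), y = c("A", "C"))))
})

test_that("pruned simulated samples never retain a close pair", {
  cfg <- sim_config(n_families = 40, sibship_size = 2, n_snps = 800, seed = 61)
  co <- simulate_cohort(cfg)
  G <- compute_grm(co$genotypes)
  kept <- prune_unrelated(G, threshold = 0.05, seed = 3)
  gv <- G$values[kept, kept]
  diag(gv) <- 0
  expect_lte(max(gv), 0.05)
})

test_that("the relative graph recovers family components", {
  pairs <- tibble::tibble(
    id_i = c("A", "B", "P", "P", "Q", "X"),
    id_j = c("B", "C", "Q", "R", "R", "Y"),
    degree = c("1", "1", "1", "1", "1", "1")
  )
  comps <- build_family_graph(pairs, "1")
  sizes <- sort(unique(comps$component_size), decreasing = TRUE)
  expect_equal(sort(comps$component_size[match(c("A", "P", "X"), comps$id)]),
               c(2, 3, 3))
  # union-find oracle on the same edges
  parent <- stats::setNames(unique(c(pairs$id_i, pairs$id_j)),
                            unique(c(pairs$id_i, pairs$id_j)))
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_len(nrow(pairs))) {
    parent[[find(pairs$id_i[k])]] <- find(pairs$id_j[k])
  }
  roots <- vapply(names(parent), find, character(1))
  oracle_sizes <- sort(as.integer(table(roots)))
  expect_equal(sort(unique(comps$component)) |> length(),
               length(unique(roots)))
  expect_equal(sort(tapply(comps$id, comps$component, length)) |> as.integer(),
               oracle_sizes)
  # no edges of the requested degree: no components
  expect_equal(nrow(build_family_graph(pairs[0, ], "1")), 0)
})

test_that("greedy subset selection takes whole large components first", {
  mk <- function(sizes) {
    purrr::imap_dfr(sizes, function(s, i) {
      tibble::tibble(id = sprintf("c%d_m%02d", i, seq_len(s)),
                     component = i, component_size = s,
                     n_links = s - 1L)
    })
  }
  comps <- mk(c(6, 4, 2))
  sel <- select_related_subset(comps, 10)
  expect_setequal(sel, comps$id[comps$component_size %in% c(6, 4)])

  comps2 <- mk(c(3, 3))
  sel2 <- select_related_subset(comps2, 4)
  expect_length(sel2, 4)
  expect_equal(sort(table(sub("_.*", "", sel2)), decreasing = TRUE)[[1]], 3)

  expect_error(select_related_subset(comps2, 10), "short by 4")
})

test_that("greedy selection beats random subsets on average kinship", {
  cfg <- sim_config(n_families = 300, sibship_size = 2, n_snps = 100,
                    seed = 71)
  ped <- generate_pedigree(cfg)  # 1200 individuals in sibship components
  pairs <- pedigree_kinship(ped, min_degree = "3")
  comps <- build_family_graph(pairs, "1")
  A <- compute_a_matrix(ped)
  mean_rel <- function(ids) {
    m <- A$values[ids, ids]
    mean(m[lower.tri(m)])
  }
  sel <- select_related_subset(comps, 600)
  sel_rel <- mean_rel(sel)
  rand_rel <- withr::with_seed(8, {
    vapply(1:100, function(i) mean_rel(sample(ped$id, 600)), numeric(1))
  })
  expect_true(all(sel_rel > rand_rel))
})

test_that("substituting relatives preserves size and split fractions", {
  base <- study_design(sprintf("u%03d", 1:80), sprintf("u%03d", 81:100))
  expect_identical(substitute_relatives(base, character(0)), base)

  rel <- sprintf("r%03d", 1:100)
  all_rel <- substitute_relatives(base, rel, seed = 5)
  expect_setequal(all_rel$id, rel)
  expect_equal(sum(all_rel$role == "discovery"), 80)

  some <- substitute_relatives(base, sprintf("r%03d", 1:10), seed = 6)
  expect_equal(nrow(some), 100)
  expect_equal(sum(grepl("^r", some$id)), 10)
  expect_error(substitute_relatives(base, sprintf("r%03d", 1:101)),
               "exceed")
  expect_error(substitute_relatives(base, c("u001", "zz")), "present")
})

test_that("random splits respect the discovery fraction", {
  d <- split_design(sprintf("i%02d", 1:10), 0.8, seed = 2)
  expect_equal(sum(d$role == "discovery"), 8)
  expect_equal(sum(d$role == "target"), 2)
  expect_length(intersect(design_ids(d, "discovery"),
                          design_ids(d, "target")), 0)
  d2 <- split_design(c("a", "b"), 0.5, seed = 3)
  expect_equal(sort(table(d2$role)) |> as.integer(), c(1, 1))
  # deterministic given the seed
  expect_identical(split_design(sprintf("i%02d", 1:10), 0.8, seed = 2)$id,
                   d$id)
})

test_that("TA targets all have a relative in discovery; TB targets have none", {
  cfg <- sim_config(n_families = 100, sibship_size = 2, n_snps = 2000,
                    seed = 81)
  co <- simulate_cohort(cfg)
  ped <- co$pedigree
  sib_pool <- ped$id[!is.na(ped$sire)]          # 200 sibs in 100 pairs
  lone_pool <- ped$id[is.na(ped$sire)]          # founders, no sibs
  pairs <- pedigree_kinship(ped, min_degree = "1")
  sib_pairs <- pairs[pairs$id_i %in% sib_pool & pairs$id_j %in% sib_pool, ]

  ta <- split_design(sib_pool, 0.75, seed = 4, related_targets = TRUE,
                     pairs = sib_pairs)
  disc <- design_ids(ta, "discovery")
  for (t in design_ids(ta, "target")) {
    partners <- c(sib_pairs$id_j[sib_pairs$id_i == t],
                  sib_pairs$id_i[sib_pairs$id_j == t])
    expect_true(any(partners %in% disc))
    # confirm with the genotype-based kinship estimator
    k <- estimate_kinship(co$genotypes, t, partners[partners %in% disc][1])
    expect_equal(k$degree, "1")
  }

  mixed_pool <- c(sib_pool[1:50], lone_pool[1:150])
  tb <- split_design(mixed_pool, 0.8, seed = 5, related_targets = FALSE,
                     pairs = sib_pairs)
  expect_true(all(design_ids(tb, "target") %in% lone_pool))
  expect_error(split_design(sib_pool[1:4], 0.5, seed = 6,
                            related_targets = FALSE, pairs = sib_pairs),
               "unrelated targets")
})

test_that("degree-1 small designs inflate cross-relationship variance", {
  cfg <- sim_config(n_families = 150, sibship_size = 2, n_snps = 2000,
                    seed = 91)
  co <- simulate_cohort(cfg)
  ped <- co$pedigree
  pairs <- pedigree_kinship(ped, min_degree = "1")
  related <- split_design(ped$id[!is.na(ped$sire)], 0.8, seed = 7,
                          related_targets = TRUE, pairs = pairs)
  unrelated <- split_design(ped$id[is.na(ped$sire)], 0.8, seed = 7)
  v <- function(d) {
    cr <- compute_grm_cross(co$genotypes, design_ids(d, "discovery"),
                            design_ids(d, "target"))
    var(as.numeric(cr))
  }
  expect_gt(v(related), v(unrelated))
})
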