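# kinpred

Polygenic risk scores are conventionally built from large samples of
*unrelated* individuals: close relatives are pruned away so that family
effects cannot contaminate SNP-effect estimates. For **prediction**,
however, relatives of the people being predicted are a source of signal,
not a nuisance — a few thousand discovery individuals that include close
relatives of the targets can rival hundreds of thousands of unrelated
ones. kinpred is a simulation and analysis toolkit for studying exactly
this trade-off: it generates family-structured cohorts, builds
relatedness-controlled study designs, computes PRS / GBLUP / ABLUP /
single-step HBLUP predictions, and compares empirical accuracy against
the theory that explains it.

## The core quantities

Phenotypes decompose as `y = g + f + e` (additive polygenic value with
variance `h²`, family effect shared within a sibship with variance `f²`,
residual). Prediction accuracy — the correlation between scores and
adjusted phenotypes in targets — is governed by

    r = h² / sqrt(h² + Me / N)

where `N` is the discovery phenotype count and `Me` is the effective
number of chromosome segments, estimated as the inverse variance of the
genomic relationships between discovery and target samples:

    Me = 1 / var(G_ij)

Close discovery–target relatives inflate `var(G_ij)`, collapse `Me`, and
raise accuracy. The package implements the three relationship matrices
behind the score types — the standardised genomic matrix `G = WW'/M`, the
pedigree numerator matrix `A`, and the single-step `H` matrix that merges
pedigree relationships of ungenotyped individuals with genomic
relationships of genotyped ones — plus REML variance components, a KING-style
robust kinship estimator with degree classification, study-design
construction (unrelated pruning at 0.05, greedy relative-group selection,
relative substitution, related/unrelated target splits), and evaluation
metrics (accuracy reports, cross-trait fold changes, decile
prevalence/odds-ratio analysis).

## Worked example

Simulate 700 nuclear families (2 parents, 2 children) at 2,000
independent SNPs with `h² = 0.5` and a family effect of `f² = 0.2`, then
contrast two designs of identical size (400 discovery, 200 targets): one
whose targets each have a full sib in discovery, one fully unrelated.

```r
library(kinpred)
library(dplyr)

cfg <- sim_config(n_families = 700, sibship_size = 2, n_snps = 2000,
                  h2 = 0.5, f2 = 0.2, seed = 1)
cohort <- simulate_cohort(cfg)
adj <- adjust_phenotype(cohort$phenotypes)

ped <- cohort$pedigree
sib1 <- ped$id[grepl("_C1$", ped$id)]; sib2 <- ped$id[grepl("_C2$", ped$id)]
founders <- ped$id[is.na(ped$sire)]
fam_of <- function(ids) as.integer(sub("F(\\d+).*", "\\1", ids))

targ_rel <- sib1[fam_of(sib1) <= 200]
disc_rel <- c(sib2[fam_of(sib2) <= 200],
              founders[fam_of(founders) > 200 & fam_of(founders) <= 300])
targ_unr <- sib1[fam_of(sib1) > 300 & fam_of(sib1) <= 500]
disc_unr <- founders[fam_of(founders) > 500]

run <- function(disc, targ, label) {
  gwas <- run_gwas(subset_genotypes(cohort$genotypes, disc),
                   adj[adj$id %in% disc, ])
  prs  <- score_prs(subset_genotypes(cohort$genotypes, targ), gwas)
  me   <- estimate_me(compute_grm_cross(cohort$genotypes, disc, targ))
  accuracy_report(prs, adj[adj$id %in% targ, ], me,
                  n_discovery = length(disc), h2_narrow = 0.5,
                  h2_family = 0.7, label = label)
}
bind_rows(run(disc_rel, targ_rel, "with_sibs"),
          run(disc_unr, targ_unr, "unrelated"))
#>      design r_empirical r_theory_narrow r_theory_family   me n_discovery
#> 1 with_sibs       0.488           0.302           0.409  893         400
#> 2 unrelated       0.261           0.213           0.293 1996         400
```

Reading the table: sibs in discovery cut `Me` from ~2,000 (the SNP count,
as expected without linkage disequilibrium) to ~900, and the empirical
accuracy nearly doubles. The related design also *overshoots* its
narrow-`h²` theory (0.49 vs 0.30) because the shared family effect is
predictable from a sib but invisible to narrow-sense theory — using the
family-based heritability (0.41) closes most of the gap.

The same erosion of `Me` can be computed analytically for a single
target: starting from a reference panel whose relationship variance
corresponds to 50,000 segments, adding that target's three first-degree
relatives yields

```r
base <- rep(c(1, -1) * sqrt(1 / 50000), 2500)
analytic_me_with_relatives(base, degree = "1", k = 3)
#>      me  variance n_pairs infinite
#> 1 5889. 0.000170     5003 FALSE
```

— an order-of-magnitude drop from three relatives.

Ready-made experiment recipes (YAML) live under
`system.file("recipes", package = "kinpred")` and run end to end with
`run_recipe()`, writing designs, PLINK1 genotypes, and tidy accuracy
tables; `autoplot()` methods visualise accuracy reports, decile reports
and fold-change summaries.

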