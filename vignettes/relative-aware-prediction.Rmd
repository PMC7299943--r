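---
title: "Relative-aware polygenic prediction: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative-aware polygenic prediction: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kinpred studies a simple question with practical consequences for biobank
analysis: how much predictive power does a polygenic score gain when the
discovery sample contains close relatives of the people being predicted?
This vignette documents the models the package implements, what the
synthetic-data generator does and does not emulate, the numerical choices
inside the estimators, and the design decisions taken where the underlying
methodology leaves room.

## The model

Phenotypes follow a variance-component decomposition on a standardised
scale,

$$y_j = g_j + f_j + e_j,$$

where $g_j$ is an additive polygenic value with variance $h^2$
(narrow-sense heritability), $f_j$ a family effect shared by all members of
the same family with variance $f^2$, and $e_j$ a residual with variance
$1 - h^2 - f^2$. Two heritabilities follow: the narrow-sense
$\sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$, estimable in unrelated samples,
and the family-based
$(\sigma_g^2 + \sigma_f^2) / (\sigma_g^2 + \sigma_f^2 + \sigma_e^2)$,
which is what prediction from relatives can actually exploit.

Prediction uses three relationship matrices:

* **G** (genomic): $G = WW'/M$ over $M$ SNPs. The package standardises
  each SNP column, $w = (d - 2p)/\sqrt{2p(1-p)}$, before forming the
  product, so unrelated pairs centre on 0 and full sibs on 0.5. The raw
  0/1/2 coding is retained behind `standardize = FALSE` for comparison,
  but raw relationships are not on the scale on which conventional
  relatedness cut-offs (e.g. 0.05) or sib values (~0.5) are defined, so the
  standardised form is the default.
* **A** (pedigree): the numerator relationship matrix from the tabular
  recursion, $a_{ij} = (a_{j,s(i)} + a_{j,d(i)})/2$,
  $a_{ii} = 1 + a_{s(i),d(i)}/2$.
* **H** (single-step): the combined matrix that embeds the genomic
  relationships of genotyped individuals inside the pedigree expectations
  of ungenotyped ones,
  $H_{11} = A_{11} + A_{12}A_{22}^{-1}(G - A_{22})A_{22}^{-1}A_{21}$,
  $H_{12} = A_{12}A_{22}^{-1}G$, $H_{22} = G$.

BLUP prediction with any of the three matrices is the same computation
(`blup_predict()`): $\hat g_t = K_{td}(K_{dd} + \lambda I)^{-1}(y_d -
\hat\mu)$ with $\lambda = \sigma_e^2/\sigma_g^2$, which is GBLUP, ABLUP or
HBLUP depending on K. With the standardised G this is algebraically
identical to ridge regression on all SNPs with per-SNP prior variance
$\sigma_g^2/M$; the test suite verifies the identity against an
independent primal-form ridge implementation.

The theoretical accuracy layer uses the classical result that the expected
correlation between phenotype and estimated score is

$$r = \frac{h^2}{\sqrt{h^2 + M_e/N}},$$

with $N$ the discovery phenotype count and $M_e$ the effective number of
chromosome segments, estimated empirically as the inverse of the variance
of discovery-by-target genomic relationships, $M_e = 1/\mathrm{var}(G_{ij})$.
Close relatives between the two samples inflate that variance, shrink
$M_e$, and raise the achievable accuracy — the mechanism the whole package
is built to expose. `analytic_me_with_relatives()` quantifies it in closed
form by appending constant relationships (0.5, 0.25, 0.125 for first-,
second- and third-degree relatives) to a baseline relationship vector.

## What the simulator emulates — and what it does not

`generate_pedigree()` builds independent nuclear families: a founder
couple with a configurable sibship, optionally extended to a third
generation in which every child is mated to a new unrelated founder and
has the same number of children. Two generations give parent–offspring and
full-sib (first-degree) pairs; three generations add avuncular and
grandparental (second-degree) and first-cousin (third-degree) pairs.
Spouses are always new founders, so no inbreeding loops arise unless a
pedigree is constructed by hand.

`simulate_genotypes()` drops alleles down this pedigree at independent
biallelic loci, founder frequencies drawn uniformly from `maf_range`
(default 0.1–0.5). For unlinked loci, drawing each transmitted allele as
Bernoulli(dosage/2) per parent is exactly equivalent to sampling one of
the parent's two alleles, and the implementation uses that shortcut.

`simulate_phenotypes()` draws causal effects
$\beta_k \sim N(0, h^2/M_c)$ on a causal subset, then rescales $g$ so its
sample variance equals $h^2$ exactly. The rescaling removes Monte-Carlo
drift in realised heritability, which would otherwise dominate the
comparison of empirical against theoretical accuracy at desk scale. The
family effect is a single normal draw per `family_id` — the sibship is the
sharing unit, so founder couples share it too, which reads naturally as a
household effect. In binary mode the liability is thresholded at its
empirical $1 - \text{prevalence}$ quantile, so the realised case fraction
matches the requested prevalence up to ties.

Deliberate omissions, and what they imply for interpreting green tests:
there is **no linkage disequilibrium**, so $M_e \approx M$ for unrelated
samples and the closed-form checks are exact in expectation; real genomes
have $M_e$ far below the SNP count. There is no assortative mating, no
genotyping error or imputation noise, no population structure, and no
X chromosome. Consequently, passing tests validate the estimators and the
relative-driven mechanism, not the absolute accuracy values one would
obtain on real biobank data.

Seeding: each simulation stage derives its stream from the master seed by
a fixed offset, so a stage re-run in isolation reproduces its output, and
equal seeds give bit-identical cohorts.

## Parameters that matter

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `h2` | narrow-sense heritability (variance share) | 0.5 | mid-range for the anthropometric traits this mirrors |
| `f2` | family-effect variance share | 0 | 0.1–0.2 reproduces realistic sib correlations $h^2/2 + f^2$ |
| `n_snps` | independent loci | 1000 | also the expected $M_e$ of an unrelated design |
| `maf_range` | founder MAF window | (0.1, 0.5) | common variants; avoids monomorphic drift in small cohorts |
| `causal_fraction` | share of loci with effects | 1 | polygenic limit |
| `prevalence` | binary-mode case fraction | unset | liability threshold model |
| kinship degree cuts | $2^{-1.5}, 2^{-2.5}, 2^{-3.5}, 2^{-4.5}$ | — | upper-inclusive bins centred on 0.25/0.125/0.0625 |
| `threshold` in `prune_unrelated()` | max retained relationship | 0.05 | the conventional unrelatedness cut |

## Numerical choices

* **Single-component REML** diagonalises K once and profiles the REML
  log-likelihood over the heritability ratio with Brent search on
  $[0, 1)$; the edge is checked explicitly and the estimate snaps to the
  boundary when the edge log-likelihood is at least as good, so null
  traits return $\hat h^2 = 0$ rather than a numerical sliver. An exact
  identity K is rejected ($\sigma_g^2, \sigma_e^2$ unidentifiable), as is
  any K with eigenvalues below $-10^{-8}$ (relative).
* **Two-component REML** (additive + family block) runs
  average-information updates from starting values of one third of the
  phenotypic variance per component, with an expectation–maximisation
  fallback whenever the AI step fails or decreases the likelihood;
  variances are floored at $10^{-8} \times \mathrm{var}(y)$, convergence
  is declared below a $10^{-6}$ log-likelihood change, and after 200
  iterations the best point is returned flagged unconverged.
* **H matrix**: a singular genotyped block $A_{22}$ aborts with guidance
  to blend ($0.99\,G + 0.01\,A_{22}$); blending is opt-in via the `blend`
  argument, never silent, because it changes $H_{22}$ away from G.
* **Pruning to unrelatedness** removes one random member of one random
  violating pair at a time — deliberately the biobank procedure, not a
  maximum independent set, to reproduce its statistical behaviour.
* **Greedy related-subset selection** takes whole relative-graph
  components in decreasing size order, ties broken by the smallest member
  id; an overshooting final component is truncated keeping the
  best-connected members first. Both tie-breaks are arbitrary but fixed,
  so designs are reproducible.
* **Decile analysis** uses nested strict upper tails (threshold $d$ keeps
  the top $(10-d)/10$ of targets) and breaks score ties by a seeded
  stable shuffle. Odds ratios with empty control tails are reported as
  flagged infinities rather than numbers.
* **Fold changes** report the plain t-interval on per-trait ratios next
  to a paired t-test on differences; both are printed because the
  ratio-vs-1 and difference-vs-0 tests are not the same test, and a
  zero-variance comparison is flagged degenerate instead of returning
  p = 1.
* **Me estimation** subtracts the mean and divides by the pair count
  (population variance); at the pair counts involved the divisor choice
  moves $M_e$ by well under 0.1%.

## Problem sizes in the tests

The acceptance-style tests exercise the pipeline at sizes chosen to make
Monte-Carlo error comfortably smaller than the tolerances while staying
desk-scale: unrelated theory-versus-empirics at 2,500 discovery + 500
targets with 5,000 SNPs over 20 replicates; the sib-boost contrast at the
same sizes with $f^2 = 0.2$; the single-step comparison at 800 genotyped +
1,200 ungenotyped + 400 targets over 30 replicates; REML recovery at
n = 3,000 (single component) and 20 replicates of 300 sibships of three
(two components). The single-step comparison injects the simulation-truth
variance components into both HBLUP and GBLUP so that the contrast
isolates what the H matrix adds, not REML noise; the recipe pipeline
(`run_recipe()`) re-estimates components by REML, and both modes are
available to users.

## Known limitations

Everything inherited from the simulator's omissions above, plus: binary
traits are analysed by linear regression on the 0/1 scale (matching the
pre-adjustment pipeline convention) rather than a liability-scale GLM;
no clumping/thresholding grids (without LD there is nothing to clump);
no summary-statistic HBLUP — the H-matrix path requires individual-level
phenotypes; and variance-component standard errors are not reported, as
the package's comparisons rest on replicate spread rather than asymptotic
approximations.
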