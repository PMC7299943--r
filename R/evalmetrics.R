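#' Empirical prediction accuracy
#'
#' Pearson correlation between predicted scores (PRS or BLUP) and the
#' covariate-adjusted phenotype, over the id intersection.
#'
#' @param scores Tibble with `id` and a score column (`score` or `ghat`).
#' @param adjusted Phenotype tibble (`id`, `trait`).
#' @return A single correlation in `[-1, 1]`.
#' @export
empirical_accuracy <- function(scores, adjusted) {
  score_col <- intersect(c("score", "ghat"), names(scores))[1]
  if (is.na(score_col)) stop("scores need a `score` or `ghat` column",
                             call. = FALSE)
  common <- intersect(scores$id, adjusted$id)
  if (length(common) < 3) stop("need at least 3 overlapping ids", call. = FALSE)
  s <- scores[[score_col]][match(common, scores$id)]
  y <- adjusted$trait[match(common, adjusted$id)]
  if (stats::sd(s) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant scores or phenotypes", call. = FALSE)
  }
  stats::cor(s, y)
}

#' Fold-change summary across traits
#'
#' Per-trait accuracy ratios between two analyses, their mean with a 95%
#' t-interval, and a two-tailed paired t-test. The confidence interval is a
#' plain t-interval on the ratio scale; the reported `p_value` tests the
#' paired differences `acc_a - acc_b` against zero, and `p_value_ratio`
#' (the ratio-vs-1 test) is emitted alongside for transparency since the
#' two tests are not identical.
#'
#' @param acc_a,acc_b Equal-length (>= 2) numeric vectors of per-trait
#'   accuracies; `acc_b` entries must be positive (denominator).
#' @return A one-row tibble of class `fold_change_summary` with
#'   `mean_fold`, `ci_low`, `ci_high`, `p_value`, `p_value_ratio`,
#'   `n_traits`, `degenerate` (flag set when the paired differences have
#'   zero variance, in which case the p-values are `NA`).
#' @export
fold_change_stats <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b), length(acc_a) >= 2)
  bad <- which(acc_b <= 0)
  if (length(bad)) {
    stop("non-positive denominator accuracy for trait(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  folds <- acc_a / acc_b
  n <- length(folds)
  mean_fold <- mean(folds)
  sd_fold <- stats::sd(folds)
  tcrit <- stats::qt(0.975, df = n - 1)
  ci <- mean_fold + c(-1, 1) * tcrit * sd_fold / sqrt(n)
  diffs <- acc_a - acc_b
  degenerate <- stats::sd(diffs) == 0
  p_diff <- if (degenerate) NA_real_ else {
    stats::t.test(acc_a, acc_b, paired = TRUE)$p.value
  }
  p_ratio <- if (sd_fold == 0) NA_real_ else {
    stats::t.test(folds, mu = 1)$p.value
  }
  out <- tibble::tibble(
    mean_fold = mean_fold, ci_low = ci[1], ci_high = ci[2],
    p_value = p_diff, p_value_ratio = p_ratio,
    n_traits = n, degenerate = degenerate
  )
  class(out) <- unique(c("fold_change_summary", class(out)))
  out
}

#' Decile prevalence and odds-ratio analysis
#'
#' Ranks target individuals by score and, for each decile threshold
#' d = 1..9, takes the individuals strictly above the d-th decile boundary
#' (nested upper tails; d = 9 is the top 10%). Reports the case prevalence
#' in each tail and the tail case/control odds divided by the population
#' odds. Ties at a boundary are resolved by a stable seeded random rank
#' order.
#'
#' @param scores Tibble with `id` and `score` (or `ghat`).
#' @param status Binary phenotype tibble (`id`, `trait` in 0/1).
#' @param population_odds Case/control odds of the reference population
#'   (> 0).
#' @param seed Seed for the tie-breaking shuffle.
#' @return A tibble of class `decile_report` with one row per threshold:
#'   `decile`, `n_above`, `cases_above`, `controls_above`,
#'   `prevalence_above`, `odds_ratio` (`Inf`, flagged, when a tail has no
#'   controls).
#' @export
decile_analysis <- function(scores, status, population_odds, seed = 1L) {
  stopifnot(population_odds > 0)
  score_col <- intersect(c("score", "ghat"), names(scores))[1]
  if (is.na(score_col)) stop("scores need a `score` or `ghat` column",
                             call. = FALSE)
  common <- intersect(scores$id, status$id)
  if (length(common) < 10) stop("need at least 10 targets", call. = FALSE)
  s <- scores[[score_col]][match(common, scores$id)]
  y <- status$trait[match(common, status$id)]
  if (!all(y %in% c(0, 1))) stop("status must be 0/1", call. = FALSE)
  n <- length(s)
  withr::with_seed(seed, {
    shuffle <- sample.int(n)
  })
  rank_s <- integer(n)  # ties broken by the seeded shuffle, stably
  rank_s[shuffle] <- rank(s[shuffle], ties.method = "first")
  purrr::map_dfr(1:9, function(d) {
    cut <- floor(n * d / 10)
    above <- rank_s > cut
    cases <- sum(y[above] == 1)
    controls <- sum(y[above] == 0)
    n_above <- sum(above)
    prev <- cases / n_above
    or <- if (controls == 0) {
      if (cases == 0) NA_real_ else Inf
    } else {
      (cases / controls) / population_odds
    }
    tibble::tibble(decile = d, n_above = n_above, cases_above = cases,
                   controls_above = controls, prevalence_above = prev,
                   odds_ratio = or)
  }) -> out
  class(out) <- unique(c("decile_report", class(out)))
  out
}

#' Full accuracy report for one design
#'
#' Bundles the empirical accuracy of a set of predictions with the
#' theoretical accuracies implied by the estimated Me under narrow-sense
#' and family-based heritability.
#'
#' @param scores Prediction tibble (`id` + `score`/`ghat`) for the targets.
#' @param adjusted Adjusted phenotype tibble covering the targets.
#' @param me A `me_estimate` (see [estimate_me()]).
#' @param n_discovery Discovery phenotype count.
#' @param h2_narrow,h2_family Heritabilities to plug into the theory.
#' @param label Free-text design descriptor.
#' @return A one-row tibble of class `accuracy_report`.
#' @export
accuracy_report <- function(scores, adjusted, me, n_discovery,
                            h2_narrow, h2_family = h2_narrow,
                            label = "design") {
  r_emp <- empirical_accuracy(scores, adjusted)
  out <- tibble::tibble(
    design = label,
    r_empirical = r_emp,
    r_theory_narrow = theoretical_accuracy(h2_narrow, me$me, n_discovery),
    r_theory_family = theoretical_accuracy(h2_family, me$me, n_discovery),
    me = me$me,
    n_discovery = n_discovery
  )
  class(out) <- unique(c("accuracy_report", class(out)))
  out
}
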