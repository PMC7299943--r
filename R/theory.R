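#' Effective number of chromosome segments (Me)
#'
#' Estimates Me as the inverse of the variance of the genomic relationships
#' between the discovery and target samples. The variance is the population
#' variance over all discovery-by-target pairs (mean subtracted, divisor =
#' pair count). With independent standardised loci and unrelated samples,
#' `var(G_ij) = 1/M`, so Me approximates the SNP count; close relatives
#' inflate the variance and shrink Me.
#'
#' @param G A [rel_matrix()] covering both id sets, or a plain numeric
#'   matrix of cross-relationships (rows = discovery, columns = target),
#'   e.g. from [compute_grm_cross()].
#' @param discovery_ids,target_ids Disjoint, non-empty id sets (ignored
#'   when `G` is already a cross-relationship matrix without these ids).
#' @return A tibble of class `me_estimate` with columns `me`, `variance`,
#'   `n_pairs`, `infinite`. When all cross-relationships are equal the
#'   variance is zero and Me is flagged infinite (`me = Inf`,
#'   `infinite = TRUE`).
#' @export
estimate_me <- function(G, discovery_ids = NULL, target_ids = NULL) {
  if (inherits(G, "rel_matrix")) {
    stopifnot(!is.null(discovery_ids), !is.null(target_ids))
    if (length(intersect(discovery_ids, target_ids))) {
      stop("discovery and target ids must be disjoint", call. = FALSE)
    }
    cross <- G$values[discovery_ids, target_ids, drop = FALSE]
  } else {
    stopifnot(is.matrix(G))
    cross <- G
  }
  if (!length(cross)) stop("both id sets must be non-empty", call. = FALSE)
  me_from_relationships(as.numeric(cross))
}

# Population variance (divisor = n) of a cross-relationship vector -> Me.
me_from_relationships <- function(rel) {
  n_pairs <- length(rel)
  v <- mean((rel - mean(rel))^2)
  out <- tibble::tibble(
    me = if (v > 0) 1 / v else Inf,
    variance = v,
    n_pairs = n_pairs,
    infinite = v <= 0
  )
  class(out) <- unique(c("me_estimate", class(out)))
  out
}

#' Theoretical genomic prediction accuracy
#'
#' The expected correlation between phenotype and estimated polygenic
#' score given heritability, the effective number of chromosome segments
#' and the discovery sample size:
#' \deqn{r = \frac{h^2}{\sqrt{h^2 + M_e/N}}.}
#'
#' @param h2 Heritability in `[0, 1]` (narrow-sense or family-based,
#'   depending on which variance the score can capture).
#' @param me Effective number of chromosome segments (> 0), e.g.
#'   `estimate_me(...)$me`.
#' @param n Number of discovery phenotypes (>= 1).
#' @return Numeric accuracy in `[0, h]` (vectorised over the inputs).
#' @export
#' @examples
#' theoretical_accuracy(h2 = 0.5, me = 5000, n = 5000)  # 0.4082
theoretical_accuracy <- function(h2, me, n) {
  stopifnot(all(h2 >= 0 & h2 <= 1), all(me > 0), all(n >= 1))
  h2 / sqrt(h2 + me / n)
}

#' Analytic Me after adding relatives of a single target
#'
#' Appends `k` constant relationships to a target individual's baseline
#' vector of discovery relationships -- 0.5 per first-degree, 0.25 per
#' second-degree, 0.125 per third-degree relative -- and recomputes Me as
#' the inverse variance of the combined vector. Quantifies analytically how
#' fast each relative class erodes Me (first-degree fastest).
#'
#' @param baseline Numeric vector of existing relationships between the
#'   target and the discovery sample.
#' @param degree `"1"`, `"2"` or `"3"`.
#' @param k Number of added relatives (>= 0).
#' @return A `me_estimate` tibble (see [estimate_me()]).
#' @export
#' @examples
#' base <- rep(c(1, -1) * sqrt(1 / 50000), 2500)  # variance exactly 1/50000
#' analytic_me_with_relatives(base, degree = "1", k = 3)
analytic_me_with_relatives <- function(baseline, degree = c("1", "2", "3"),
                                       k = 0L) {
  degree <- match.arg(as.character(degree), c("1", "2", "3"))
  stopifnot(is.numeric(baseline), length(baseline) >= 1, k >= 0)
  added <- rep(c("1" = 0.5, "2" = 0.25, "3" = 0.125)[[degree]], k)
  me_from_relationships(c(baseline, added))
}
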