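#' Single-component REML (GREML) via eigendecomposition
#'
#' Fits \eqn{y = 1\mu + g + e} with \eqn{g \sim N(0, K\sigma_g^2)} by
#' restricted maximum likelihood. The relationship matrix is
#' eigendecomposed once and the REML log-likelihood is profiled over the
#' heritability ratio with a one-dimensional bounded (Brent) search, which
#' is exact and stable at the sample sizes this package targets.
#'
#' @param K A [rel_matrix()] (G, A or H) covering the phenotyped ids.
#' @param y Phenotype tibble (`id`, `trait`), already covariate-adjusted;
#'   only an intercept is fitted.
#' @param tol Convergence/search tolerance on the variance ratio.
#' @return An object of class `vc_fit` (also `vc_single`): list with
#'   `sigma_g2`, `sigma_f2` (0), `sigma_e2`, `h2_narrow`, `h2_family`,
#'   `loglik`, `converged`, `n`.
#' @export
reml_single <- function(K, y, tol = 1e-8) {
  stopifnot(inherits(K, "rel_matrix"))
  ids <- intersect(K$ids, y$id)
  n <- length(ids)
  if (n < 50) stop("need at least 50 phenotyped individuals", call. = FALSE)
  yy <- y$trait[match(ids, y$id)]
  if (stats::sd(yy) == 0) stop("phenotype has zero variance", call. = FALSE)
  k <- K$values[ids, ids]
  if (max(abs(k - diag(n))) < 1e-8) {
    stop(paste("K is the identity matrix: sigma_g2 and sigma_e2 are not",
               "separately identifiable"), call. = FALSE)
  }
  eig <- eigen(k, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values))) {
    stop(sprintf("K is not positive semi-definite (min eigenvalue %.3e)",
                 min(eig$values)), call. = FALSE)
  }
  d <- pmax(eig$values, 0)
  yt <- drop(crossprod(eig$vectors, yy))
  xt <- drop(crossprod(eig$vectors, rep(1, n)))

  # Profiled REML log-likelihood at heritability ratio r = sg2/(sg2+se2).
  nll <- function(r) {
    v <- r * d + (1 - r)
    if (any(v <= 0)) return(1e10)
    xvx <- sum(xt^2 / v)
    mu <- sum(xt * yt / v) / xvx
    res <- yt - xt * mu
    quad <- sum(res^2 / v)
    s2 <- quad / (n - 1)
    0.5 * (sum(log(v)) + log(xvx) + (n - 1) * (log(s2) + 1))
  }
  opt <- stats::optimize(nll, c(0, 1 - 1e-9), tol = tol)
  r <- opt$minimum
  # snap to the boundary when the edge is at least as good
  for (edge in c(0, 1 - 1e-9)) {
    if (nll(edge) <= opt$objective + 1e-9) {
      r <- edge
      opt$objective <- nll(edge)
      break
    }
  }
  v <- r * d + (1 - r)
  xvx <- sum(xt^2 / v)
  mu <- sum(xt * yt / v) / xvx
  s2 <- sum((yt - xt * mu)^2 / v) / (n - 1)
  sg2 <- r * s2
  se2 <- (1 - r) * s2
  new_vc_fit(sigma_g2 = sg2, sigma_f2 = 0, sigma_e2 = se2,
             loglik = -opt$objective, converged = TRUE, n = n,
             mu = mu, kind = K$kind, class2 = "vc_single")
}

#' Two-component REML: additive plus shared-family variance
#'
#' Fits \eqn{y = 1\mu + g + f + e} with \eqn{g \sim N(0, K_1\sigma_g^2)}
#' and \eqn{f \sim N(0, K_2\sigma_f^2)}, \eqn{K_2} the 0/1 same-family
#' block matrix, by average-information REML with expectation-maximisation
#' fallback steps. Starting values are one third of the phenotypic variance
#' per component; non-negativity is enforced by projection to a small
#' positive floor.
#'
#' @param K1 A [rel_matrix()] (typically the GRM).
#' @param K2 A [rel_matrix()] or plain symmetric 0/1 matrix with ids, the
#'   same-family indicator (see [family_block_matrix()]).
#' @param y Phenotype tibble (`id`, `trait`).
#' @param max_iter Maximum REML iterations (default 200).
#' @param tol Log-likelihood convergence tolerance (default 1e-6).
#' @return A `vc_fit` (also `vc_two`) with `sigma_g2`, `sigma_f2`,
#'   `sigma_e2`, heritabilities, `loglik`, `converged`, `n`.
#' @export
reml_two <- function(K1, K2, y, max_iter = 200L, tol = 1e-6) {
  stopifnot(inherits(K1, "rel_matrix"))
  k2_ids <- if (inherits(K2, "rel_matrix")) K2$ids else rownames(K2)
  k2_val <- if (inherits(K2, "rel_matrix")) K2$values else K2
  ids <- Reduce(intersect, list(K1$ids, k2_ids, y$id))
  n <- length(ids)
  if (n < 50) stop("need at least 50 phenotyped individuals", call. = FALSE)
  yy <- y$trait[match(ids, y$id)]
  vp <- stats::var(yy)
  if (vp == 0) stop("phenotype has zero variance", call. = FALSE)
  klist <- list(K1$values[ids, ids], k2_val[ids, ids], diag(n))
  x <- matrix(1, n, 1)
  floor_v <- 1e-8 * vp
  s <- rep(vp / 3, 3)

  loglik_parts <- function(s) {
    v <- s[1] * klist[[1]] + s[2] * klist[[2]]
    diag(v) <- diag(v) + s[3]
    ch <- tryCatch(chol(v), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    vinv <- chol2inv(ch)
    vinv_x <- vinv %*% x
    xvx <- drop(crossprod(x, vinv_x))
    p <- vinv - tcrossprod(vinv_x) / xvx
    py <- drop(p %*% yy)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + log(xvx) + sum(yy * py))
    list(ll = ll, p = p, py = py)
  }

  cur <- loglik_parts(s)
  if (is.null(cur)) stop("initial variance matrix not positive definite",
                         call. = FALSE)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    py <- cur$py
    tvec <- lapply(klist, function(k) drop(k %*% py))
    score <- vapply(seq_len(3), function(i) {
      -0.5 * (sum(cur$p * klist[[i]]) - sum(py * tvec[[i]]))
    }, numeric(1))
    ptv <- lapply(tvec, function(t) drop(cur$p %*% t))
    ai <- matrix(0, 3, 3)
    for (i in 1:3) for (j in i:3) {
      ai[i, j] <- ai[j, i] <- 0.5 * sum(tvec[[i]] * ptv[[j]])
    }
    step <- tryCatch(solve(ai, score), error = function(e) NULL)
    proposal <- if (is.null(step)) NULL else pmax(s + step, floor_v)
    nxt <- if (is.null(proposal)) NULL else loglik_parts(proposal)
    if (is.null(nxt) || nxt$ll < cur$ll - 1e-8) {
      # EM fallback step, guaranteed uphill
      em <- vapply(seq_len(3), function(i) {
        s[i] + (s[i]^2 / n) * (sum(py * tvec[[i]]) - sum(cur$p * klist[[i]]))
      }, numeric(1))
      proposal <- pmax(em, floor_v)
      nxt <- loglik_parts(proposal)
      if (is.null(nxt)) break
    }
    delta <- nxt$ll - cur$ll
    s <- proposal
    cur <- nxt
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }
  new_vc_fit(sigma_g2 = s[1], sigma_f2 = s[2], sigma_e2 = s[3],
             loglik = cur$ll, converged = converged, n = n,
             mu = NA_real_, kind = K1$kind, class2 = "vc_two")
}

new_vc_fit <- function(sigma_g2, sigma_f2, sigma_e2, loglik, converged, n,
                       mu = NA_real_, kind = NA_character_, class2 = NULL) {
  h2_narrow <- if (sigma_g2 + sigma_e2 > 0) {
    sigma_g2 / (sigma_g2 + sigma_e2)
  } else NA_real_
  tot <- sigma_g2 + sigma_f2 + sigma_e2
  h2_family <- if (tot > 0) (sigma_g2 + sigma_f2) / tot else NA_real_
  structure(
    list(sigma_g2 = sigma_g2, sigma_f2 = sigma_f2, sigma_e2 = sigma_e2,
         h2_narrow = h2_narrow, h2_family = h2_family, loglik = loglik,
         converged = converged, n = n, mu = mu, kind = kind),
    class = c(class2, "vc_fit")
  )
}

#' Construct variance components directly
#'
#' Truth-injection constructor: wraps known variance components in the same
#' object returned by [reml_single()]/[reml_two()], e.g. to isolate
#' prediction error from variance-component estimation error in
#' simulations.
#'
#' @param sigma_g2,sigma_f2,sigma_e2 Non-negative variances.
#' @return A `vc_fit`.
#' @export
variance_components <- function(sigma_g2, sigma_f2 = 0, sigma_e2) {
  stopifnot(sigma_g2 >= 0, sigma_f2 >= 0, sigma_e2 >= 0)
  new_vc_fit(sigma_g2, sigma_f2, sigma_e2, loglik = NA_real_,
             converged = NA, n = NA_integer_)
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("<vc_fit> sigma_g2 = %.4f, sigma_f2 = %.4f, sigma_e2 = %.4f\n",
              x$sigma_g2, x$sigma_f2, x$sigma_e2))
  cat(sprintf("  h2 (narrow) = %.3f, h2 (family) = %.3f\n",
              x$h2_narrow, x$h2_family))
  if (!is.na(x$loglik)) {
    cat(sprintf("  REML loglik = %.3f, converged = %s, n = %d\n",
                x$loglik, x$converged, x$n))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vc_fit <- function(x, ...) {
  tibble::tibble(
    component = c("sigma_g2", "sigma_f2", "sigma_e2"),
    estimate = c(x$sigma_g2, x$sigma_f2, x$sigma_e2)
  )
}

#' @exportS3Method generics::glance
glance.vc_fit <- function(x, ...) {
  tibble::tibble(
    h2_narrow = x$h2_narrow, h2_family = x$h2_family,
    loglik = x$loglik, converged = x$converged, n = x$n
  )
}

#' Same-family indicator matrix
#'
#' 0/1 block matrix marking pairs sharing a `family_id`, the covariance
#' structure of the shared-family effect in [reml_two()].
#'
#' @param pedigree Pedigree tibble with `id`, `family_id`.
#' @param ids Optional id subset/order (default: pedigree order).
#' @return A [rel_matrix()]-like plain matrix with dimnames.
#' @export
family_block_matrix <- function(pedigree, ids = NULL) {
  ids <- ids %||% pedigree$id
  fam <- stats::setNames(pedigree$family_id, pedigree$id)[ids]
  m <- outer(fam, fam, "==") * 1
  dimnames(m) <- list(ids, ids)
  m
}

#' BLUP prediction of genetic values (GBLUP / ABLUP / HBLUP)
#'
#' Predicts target genetic values from discovery phenotypes:
#' \deqn{\hat g_t = K_{td}\,(K_{dd} + \lambda I)^{-1}(y_d - \hat\mu)}
#' with \eqn{\lambda = \sigma_e^2/\sigma_g^2} and \eqn{\hat\mu} the GLS
#' mean. The identical contract serves GBLUP (K = G), ABLUP (K = A) and
#' single-step HBLUP (K = H). When the family variance is non-zero the
#' shrinkage uses \eqn{\lambda = \sigma_e^2/(\sigma_g^2 + \sigma_f^2)},
#' treating family and additive components as jointly predictable signal.
#'
#' @param K A [rel_matrix()] spanning discovery and target ids.
#' @param y_discovery Phenotype tibble (`id`, `trait`) of the discovery set.
#' @param vc A `vc_fit` (from REML or [variance_components()]).
#' @param target_ids Ids to predict (must be in `K`).
#' @param stabilize Add `1e-8` to the diagonal before solving (opt-in, for
#'   numerically singular systems).
#' @return A tibble of class `blup_result` with columns `id`, `ghat`.
#' @export
blup_predict <- function(K, y_discovery, vc, target_ids, stabilize = FALSE) {
  stopifnot(inherits(K, "rel_matrix"), inherits(vc, "vc_fit"))
  disc <- intersect(K$ids, y_discovery$id)
  missing_t <- setdiff(target_ids, K$ids)
  if (length(missing_t)) {
    stop("target ids absent from K: ",
         paste(utils::head(missing_t, 5), collapse = ", "), call. = FALSE)
  }
  yd <- y_discovery$trait[match(disc, y_discovery$id)]
  sig2 <- vc$sigma_g2 + vc$sigma_f2
  if (sig2 <= 0) {
    out <- tibble::tibble(id = target_ids, ghat = 0)
    class(out) <- unique(c("blup_result", class(out)))
    return(out)
  }
  lambda <- vc$sigma_e2 / sig2
  kdd <- K$values[disc, disc, drop = FALSE]
  c_mat <- kdd + diag(lambda, length(disc))
  if (stabilize) diag(c_mat) <- diag(c_mat) + 1e-8
  ch <- tryCatch(chol(c_mat), error = function(e) NULL)
  if (is.null(ch)) {
    stop(paste("singular BLUP system; retry with stabilize = TRUE to add a",
               "1e-8 diagonal"), call. = FALSE)
  }
  cinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, length(disc))))
  cinv_y <- backsolve(ch, forwardsolve(t(ch), yd))
  mu <- sum(cinv_y) / sum(cinv_1)
  alpha <- backsolve(ch, forwardsolve(t(ch), yd - mu))
  ktd <- K$values[target_ids, disc, drop = FALSE]
  out <- tibble::tibble(id = target_ids, ghat = unname(drop(ktd %*% alpha)))
  class(out) <- unique(c("blup_result", class(out)))
  out
}

#' SNP-ridge (random-effects marker) prediction
#'
#' Ridge regression of the discovery phenotypes on all standardised SNPs
#' with per-SNP prior variance \eqn{\sigma_g^2/M}, i.e. penalty
#' \eqn{\lambda = M\sigma_e^2/\sigma_g^2}, evaluated at the target
#' genotypes. Algebraically identical to GBLUP with the standardised GRM;
#' retained as an independent route for cross-checking.
#'
#' @param genotypes A [geno_matrix()] spanning discovery and target ids.
#' @param y_discovery Phenotype tibble of the discovery set.
#' @param vc A `vc_fit`.
#' @param target_ids Ids to predict.
#' @return A tibble with `id`, `ghat`.
#' @export
ridge_predict <- function(genotypes, y_discovery, vc, target_ids) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  disc <- intersect(genotypes$ids, y_discovery$id)
  yd <- y_discovery$trait[match(disc, y_discovery$id)]
  w <- grm_design(genotypes)
  wd <- w[disc, , drop = FALSE]
  wt <- w[target_ids, , drop = FALSE]
  m <- ncol(w)
  sig2 <- vc$sigma_g2 + vc$sigma_f2
  if (sig2 <= 0) return(tibble::tibble(id = target_ids, ghat = 0))
  # primal form: per-SNP penalty lambda = M * sigma_e2 / sigma_g2,
  # beta = (Wd'Wd + lambda I)^{-1} Wd'(y - mu), GLS mean via Woodbury
  lambda <- m * vc$sigma_e2 / sig2
  a_mat <- crossprod(wd) + diag(lambda, m)
  vinv_prop <- function(z) z - wd %*% solve(a_mat, crossprod(wd, z))
  ones <- rep(1, length(disc))
  mu <- sum(yd * drop(vinv_prop(ones))) / sum(ones * drop(vinv_prop(ones)))
  beta <- drop(solve(a_mat, crossprod(wd, yd - mu)))
  tibble::tibble(id = target_ids, ghat = drop(wt %*% beta))
}
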