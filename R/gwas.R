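#' Mixed-model genome-wide association scan
#'
#' Variance components are estimated once on the null model by spectral
#' REML ([reml_h2()]), then every SNP is tested by generalized least
#' squares under `V = sigma2_g K + sigma2_e I` (working on the eigenbasis
#' of `K`, so each SNP costs one weighted regression).  Wald p-values are
#' reported together with the genomic-control inflation factor
#' `lambda = median(chi2) / qchisq(0.5, 1)`.
#'
#' @param y Accession-level phenotype (BLUPs of richness, or PCA scores of
#'   abundance BLUPs), named by accession or aligned with `g`.
#' @param g A `genotype_matrix`.
#' @param K A `kinship_matrix` over the same accessions (computed from `g`
#'   if omitted).
#' @return An object of class `gwas_result`: `snps` tibble (`snp_id`,
#'   `chrom`, `pos`, `beta`, `se`, `stat`, `p_value`), `lambda_gc`,
#'   `h2_null`, and the null variance components.  Monomorphic SNPs are
#'   skipped.
#' @export
gwas_scan <- function(y, g, K = NULL) {
  if (is.null(K)) K <- kinship(g)
  acc <- rownames(g$dosages)
  if (!is.null(names(y))) {
    assert_that(all(names(y) %in% acc), "phenotype names not among accessions")
    g_idx <- match(names(y), acc)
  } else {
    assert_that(length(y) == length(acc), "phenotype length must match accessions")
    g_idx <- seq_along(acc)
  }
  X <- g$dosages[g_idx, , drop = FALSE]
  Ksub <- as.matrix(K)[acc[g_idx], acc[g_idx]]
  null <- reml_h2(unname(y), Ksub)
  ev <- eigen(Ksub, symmetric = TRUE)
  w <- null$sigma2_g * pmax(ev$values, 0) + null$sigma2_e
  Ut <- t(ev$vectors)
  uy <- as.vector(Ut %*% unname(y))
  u1 <- as.vector(Ut %*% rep(1, length(y)))
  UX <- Ut %*% X
  # per-SNP GLS with intercept, on the whitened scale
  sw <- 1 / sqrt(w)
  uy_w <- uy * sw
  u1_w <- u1 * sw
  UX_w <- UX * sw
  s11 <- sum(u1_w^2)
  s1y <- sum(u1_w * uy_w)
  sxx <- colSums(UX_w^2)
  sx1 <- as.vector(crossprod(UX_w, u1_w))
  sxy <- as.vector(crossprod(UX_w, uy_w))
  det <- s11 * sxx - sx1^2
  mono <- apply(X, 2, function(col) stats::var(col) < 1e-12) | det < 1e-12
  beta <- (s11 * sxy - sx1 * s1y) / det
  # residual variance per SNP fit (phenotype already V-standardized per
  # the null components, so sigma2 ~ 1; re-estimate for proper Wald SEs)
  n <- length(y)
  yy <- sum(uy_w^2)
  alpha <- (sxx * s1y - sx1 * sxy) / det
  rss <- yy - alpha * s1y - beta * sxy
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 * s11 / det)
  stat <- beta / se
  p <- 2 * stats::pt(-abs(stat), df = n - 2)
  beta[mono] <- NA; se[mono] <- NA; stat[mono] <- NA; p[mono] <- NA
  beta <- unname(beta); se <- unname(se); stat <- unname(stat); p <- unname(p)
  chi2 <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda_gc <- stats::median(chi2, na.rm = TRUE) / stats::qchisq(0.5, 1)
  structure(list(
    snps = dplyr::bind_cols(g$snps,
                            tibble::tibble(beta = beta, se = se, stat = stat,
                                           p_value = p)),
    lambda_gc = lambda_gc,
    h2_null = null$h2,
    sigma2_g = null$sigma2_g,
    sigma2_e = null$sigma2_e,
    n = n
  ), class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  top <- dplyr::slice_min(x$snps, .data$p_value, n = 1, with_ties = FALSE)
  cat(sprintf("<gwas_result> %d SNPs, %d accessions; lambda_GC = %.3f\n",
              nrow(x$snps), x$n, x$lambda_gc))
  cat(sprintf("  top SNP %s, p = %.3g\n", top$snp_id, top$p_value))
  invisible(x)
}

#' @export
tidy.gwas_result <- function(x, ...) x$snps

#' @export
glance.gwas_result <- function(x, ...) {
  ok <- !is.na(x$snps$p_value)
  tibble::tibble(n_snps = nrow(x$snps), n_accessions = x$n,
                 lambda_gc = x$lambda_gc, h2_null = x$h2_null,
                 min_p = if (any(ok)) min(x$snps$p_value[ok]) else NA_real_)
}

#' Genome-wide significance threshold by Cholesky permutation
#'
#' Permutation threshold that respects population structure: the phenotype
#' is whitened with the Cholesky factor of the inverse of the fitted
#' phenotypic covariance `V = sigma2_g K + sigma2_e I` (so the whitened
#' values are exchangeable), permuted, transformed back, and rescanned;
#' the threshold is the empirical `alpha`-quantile of the per-permutation
#' minimum p-values.
#'
#' @param y,g,K As in [gwas_scan()].
#' @param n_perm Number of permutations (>= 20; default 100).
#' @param alpha Genome-wide type-I error rate (default 0.05).
#' @param seed Integer seed.
#' @return List with `threshold` (p-value scale), `alpha`, `min_p`
#'   (vector of permutation minima), `n_perm`.
#' @export
cholesky_perm_threshold <- function(y, g, K = NULL, n_perm = 100,
                                    alpha = 0.05, seed = 1L) {
  assert_that(n_perm >= 20, "need at least 20 permutations for a stable quantile")
  if (is.null(K)) K <- kinship(g)
  if (is.null(names(y))) names(y) <- rownames(g$dosages)
  Ksub <- as.matrix(K)[names(y), names(y)]
  null <- reml_h2(unname(y), Ksub)
  V <- null$sigma2_g * Ksub + null$sigma2_e * diag(length(y))
  L <- t(chol(V))                       # V = L L'
  ystar <- solve(L, unname(y))          # whitened: Cov(ystar) = I
  set.seed(seed)
  min_p <- replicate(n_perm, {
    yp <- as.vector(L %*% ystar[sample.int(length(ystar))])
    names(yp) <- names(y)
    min(gwas_scan(yp, g, K)$snps$p_value, na.rm = TRUE)
  })
  list(threshold = unname(stats::quantile(min_p, alpha, type = 1)),
       alpha = alpha, min_p = min_p, n_perm = n_perm)
}

#' Windowed minimum p-values along the genome
#'
#' Assigns each SNP to a half-open window `[k * w, (k + 1) * w)` on its
#' chromosome (0-based positions `k = floor(pos / w)`) and reports the
#' minimum p-value per non-empty window.
#'
#' @param res A `gwas_result`.
#' @param window_bp Window width in base pairs (default 10000).
#' @return Tibble `chrom`, `window`, `start`, `end`, `min_p`, `n_snps`.
#' @export
window_summary <- function(res, window_bp = 10000) {
  snps <- dplyr::filter(res$snps, !is.na(.data$p_value))
  snps$window <- floor(snps$pos / window_bp)
  out <- dplyr::summarise(
    dplyr::group_by(snps, .data$chrom, .data$window),
    min_p = min(.data$p_value),
    n_snps = dplyr::n(),
    .groups = "drop")
  out$start <- out$window * window_bp
  out$end <- out$start + window_bp
  out[, c("chrom", "window", "start", "end", "min_p", "n_snps")]
}

#' Cross-trait overlap of windowed GWAS results
#'
#' Joins two [window_summary()] tables on chromosome and window id, the
#' substrate for overlap scatterplots of two traits' association signals.
#'
#' @param res1,res2 `gwas_result` objects for the two traits.
#' @param window_bp Window width in base pairs.
#' @return Tibble `chrom`, `window`, `min_p_1`, `min_p_2`.
#' @export
overlap_windows <- function(res1, res2, window_bp = 10000) {
  w1 <- window_summary(res1, window_bp)
  w2 <- window_summary(res2, window_bp)
  out <- dplyr::inner_join(w1[, c("chrom", "window", "min_p")],
                           w2[, c("chrom", "window", "min_p")],
                           by = c("chrom", "window"),
                           suffix = c("_1", "_2"))
  out
}
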