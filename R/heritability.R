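#' Kinship (genomic relationship) matrix
#'
#' Standardized GRM: `K = Z Z' / m`, with `Z` the per-SNP standardized
#' dosage matrix (mean 0, variance 1 across accessions) and `m` the number
#' of SNPs.  Monomorphic SNPs carry no information and are dropped with a
#' warning.  A tiny negative eigenvalue arising numerically is projected
#' away so the result is positive semi-definite.
#'
#' @param g A `genotype_matrix` (already MAF-filtered; see [maf_filter()]).
#' @return A symmetric accessions x accessions matrix of class
#'   `kinship_matrix` with a `method` attribute (`"standardized_grm"`).
#' @export
kinship <- function(g) {
  X <- g$dosages
  v <- apply(X, 2, stats::var)
  if (any(v < 1e-12)) {
    rlang::warn(sprintf("dropping %d monomorphic SNPs from kinship",
                        sum(v < 1e-12)))
    X <- X[, v >= 1e-12, drop = FALSE]
  }
  assert_that(ncol(X) >= 1, "no polymorphic SNPs left")
  Z <- scale(X)
  K <- tcrossprod(Z) / ncol(Z)
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    vals <- pmax(ev$values, 0)
    K <- ev$vectors %*% (vals * t(ev$vectors))
    dimnames(K) <- list(rownames(X), rownames(X))
  }
  structure(K, class = c("kinship_matrix", "matrix"),
            method = "standardized_grm")
}

# REML log-likelihood for y = mu + g + e on the spectral scale.
# lambda: eigenvalues of K; uy, ux: rotated phenotype and intercept;
# ratio = sigma2_g / sigma2_e
reml_loglik <- function(log_ratio, lambda, uy, ux) {
  ratio <- exp(log_ratio)
  w <- ratio * lambda + 1            # V / sigma2_e on the spectral scale
  xtvx <- sum(ux^2 / w)
  beta <- sum(ux * uy / w) / xtvx
  r <- uy - ux * beta
  n <- length(uy)
  rss <- sum(r^2 / w)
  sigma2_e <- rss / (n - 1)
  ll <- -0.5 * ((n - 1) * log(sigma2_e) + sum(log(w)) + log(xtvx) + (n - 1))
  if (!is.finite(ll)) -1e10 else ll  # degenerate fits: keep optimize() sane
}

#' SNP heritability by spectral REML
#'
#' Fits `y = mu + g + e` with `g ~ N(0, sigma2_g K)` and
#' `e ~ N(0, sigma2_e I)` by restricted maximum likelihood.  The kinship
#' matrix is eigendecomposed once and the likelihood profiled down to a
#' one-dimensional search over the variance ratio (optimized on the log
#' scale, tolerance 1e-8), the classic trick for single-kinship mixed
#' models.
#'
#' @param y Accession-level phenotype vector (e.g. richness BLUPs), named by
#'   accession or aligned with `K`.
#' @param K A `kinship_matrix`.
#' @return An object of class `heritability_estimate` with `sigma2_g`,
#'   `sigma2_e`, `h2 = sigma2_g / (sigma2_g + sigma2_e)`, `loglik`,
#'   `boundary` flag, and `method = "REML-spectral"`.
#' @export
reml_h2 <- function(y, K) {
  if (!is.null(names(y)) && !is.null(rownames(K))) {
    assert_that(all(names(y) %in% rownames(K)), "phenotype names not in K")
    K <- K[names(y), names(y)]
  }
  assert_that(length(y) == nrow(K), "phenotype length must match K")
  assert_that(all(is.finite(y)), "phenotype must be finite")
  ev <- eigen(as.matrix(K), symmetric = TRUE)
  assert_that(min(ev$values) > -1e-6, "K is not positive semi-definite")
  lambda <- pmax(ev$values, 0)
  uy <- as.vector(crossprod(ev$vectors, y))
  ux <- as.vector(crossprod(ev$vectors, rep(1, length(y))))
  opt <- stats::optimize(reml_loglik, interval = c(-12, 12), maximum = TRUE,
                         tol = 1e-8, lambda = lambda, uy = uy, ux = ux)
  # compare against the boundaries of the search interval
  ll_lo <- reml_loglik(-12, lambda, uy, ux)
  ll_hi <- reml_loglik(12, lambda, uy, ux)
  cand <- c(opt$maximum, -12, 12)
  lls <- c(opt$objective, ll_lo, ll_hi)
  best <- which.max(lls)
  log_ratio <- cand[best]
  boundary <- best > 1 || abs(log_ratio) > 11.9
  ratio <- exp(log_ratio)
  w <- ratio * lambda + 1
  xtvx <- sum(ux^2 / w)
  beta <- sum(ux * uy / w) / xtvx
  rss <- sum((uy - ux * beta)^2 / w)
  sigma2_e <- rss / (length(y) - 1)
  sigma2_g <- ratio * sigma2_e
  structure(list(
    sigma2_g = sigma2_g, sigma2_e = sigma2_e,
    h2 = sigma2_g / (sigma2_g + sigma2_e),
    loglik = lls[best], boundary = boundary,
    method = "REML-spectral", n = length(y)
  ), class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("<heritability_estimate> h2 = %.3f (sigma2_g = %.3g, sigma2_e = %.3g)%s\n",
              x$h2, x$sigma2_g, x$sigma2_e,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' @export
glance.heritability_estimate <- function(x, ...) {
  tibble::tibble(h2 = x$h2, sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e,
                 loglik = x$loglik, boundary = x$boundary, n = x$n,
                 method = x$method)
}

#' Broad-sense heritability from a fitted richness or abundance GLMM
#'
#' Partition of linear-predictor variance in a Poisson log-link GLMM:
#' `H2 = sigma2_accession / (sigma2_fixed + sum(sigma2_random) +
#' sigma2_dist)`, where `sigma2_fixed` is the variance of the fixed-effect
#' linear predictor (offset excluded), the random-effect variances come from
#' the fit, and the distribution-specific variance on the log scale is the
#' lognormal approximation `log(1 + 1 / lambda_bar)` evaluated at the
#' model's expected rate.  This is the conditional-minus-marginal variance
#' decomposition commonly used for GLMM R-squared, applied to the accession
#' component.
#'
#' @param fit A `richness_blups` object, or a fitted [lme4::glmer()] model
#'   with an `accession_id` random intercept.
#' @return An object of class `broad_sense_estimate` with the components and
#'   `H2`.
#' @export
broad_sense_h2 <- function(fit) {
  model <- if (inherits(fit, "richness_blups")) fit$model else fit
  assert_that(inherits(model, "glmerMod"), "need a fitted Poisson GLMM")
  X <- lme4::getME(model, "X")
  beta <- lme4::fixef(model)
  eta_fixed <- as.vector(X %*% beta)
  sigma2_fixed <- stats::var(eta_fixed)
  vc <- as.data.frame(lme4::VarCorr(model))
  sigma2_acc <- sum(vc$vcov[vc$grp == "accession_id"])
  sigma2_other <- sum(vc$vcov[vc$grp != "accession_id"])
  lambda_bar <- mean(stats::fitted(model))
  sigma2_dist <- log(1 + 1 / lambda_bar)
  total <- sigma2_fixed + sigma2_acc + sigma2_other + sigma2_dist
  structure(list(
    H2 = sigma2_acc / total,
    sigma2_accession = sigma2_acc,
    sigma2_other_random = sigma2_other,
    sigma2_fixed = sigma2_fixed,
    sigma2_dist = sigma2_dist,
    lambda_bar = lambda_bar
  ), class = "broad_sense_estimate")
}

#' @export
print.broad_sense_estimate <- function(x, ...) {
  cat(sprintf("<broad_sense_estimate> H2 = %.3f (accession %.3g / total %.3g)\n",
              x$H2, x$sigma2_accession,
              x$sigma2_accession + x$sigma2_other_random + x$sigma2_fixed +
                x$sigma2_dist))
  invisible(x)
}

#' @export
glance.broad_sense_estimate <- function(x, ...) {
  tibble::tibble(H2 = x$H2, sigma2_accession = x$sigma2_accession,
                 sigma2_other_random = x$sigma2_other_random,
                 sigma2_fixed = x$sigma2_fixed, sigma2_dist = x$sigma2_dist)
}
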