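# independent oracles used by both the module tests and the acceptance suite

# direct maximum likelihood of the Poisson regression by general-purpose
# optimization (no IRLS, no glm)
optim_enrichment <- function(counts, meta) {
  organ <- as.numeric(meta$organ == "root")
  block <- if (length(unique(meta$block)) > 1) {
    as.numeric(meta$block == sort(unique(meta$block))[2])
  } else NULL
  X <- cbind(1, organ, block)
  negll <- function(theta) {
    eta <- as.vector(X %*% theta) + log(meta$total_reads)
    -sum(counts * eta - exp(eta))
  }
  fit <- optim(rep(0, ncol(X)), negll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  exp(fit$par[2])
}

# dense GLS oracle: explicit V inverse, one weighted regression per SNP
dense_gls_oracle <- function(y, X, V) {
  Vi <- solve(V)
  n <- length(y)
  sapply(seq_len(ncol(X)), function(j) {
    D <- cbind(1, X[, j])
    A <- solve(t(D) %*% Vi %*% D)
    b <- A %*% t(D) %*% Vi %*% y
    r <- y - D %*% b
    sigma2 <- as.numeric(t(r) %*% Vi %*% r) / (n - 2)
    se <- sqrt(sigma2 * A[2, 2])
    stat <- b[2] / se
    c(beta = b[2], p = 2 * pt(-abs(stat), n - 2))
  })
}
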