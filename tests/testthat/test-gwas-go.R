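test_that("the spectral GWAS matches a dense GLS oracle on 30 x 50", {
  set.seed(1)
  p <- sim_params(n_accessions = 30, n_snps = 50, n_clusters = 2, fst = 0.2,
                  seed = 71)
  g <- maf_filter(simulate_genotypes(p), 0.05)
  K <- kinship(g)
  ev <- eigen(unclass(K), symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  y <- as.vector(L %*% rnorm(30)) * 0.6 + rnorm(30)
  names(y) <- rownames(g$dosages)
  res <- gwas_scan(y, g, K)
  V <- res$sigma2_g * unclass(K) + res$sigma2_e * diag(30)
  oracle <- dense_gls_oracle(unname(y), g$dosages, V)
  ok <- !is.na(res$snps$p_value)
  expect_equal(res$snps$beta[ok], unname(oracle["beta", ok]),
               tolerance = 1e-8)
  expect_equal(res$snps$p_value[ok], unname(oracle["p", ok]),
               tolerance = 1e-8)
})

test_that("jointly permuting phenotype and kinship leaves the scan unchanged", {
  set.seed(2)
  p <- sim_params(n_accessions = 25, n_snps = 40, seed = 72)
  g <- maf_filter(simulate_genotypes(p), 0.05)
  K <- kinship(g)
  y <- rnorm(25)
  names(y) <- rownames(g$dosages)
  res1 <- gwas_scan(y, g, K)
  perm <- sample(25)
  g2 <- g
  g2$dosages <- g$dosages[perm, ]
  res2 <- gwas_scan(y[rownames(g2$dosages)], g2, K)
  expect_equal(res2$snps$p_value, res1$snps$p_value, tolerance = 1e-6)
})

test_that("a strong causal SNP usually tops the scan under polygenic background", {
  set.seed(3)
  hits <- replicate(15, {
    n <- 150
    dos <- matrix(rbinom(n * 300, 1, rep(runif(300, 0.1, 0.5), each = n)),
                  n, 300, dimnames = list(sprintf("a%03d", 1:n),
                                          sprintf("chr1_%d", 1:300 * 100)))
    g <- maf_filter(mkmicrobiome:::genotype_matrix(dos), 0.05)
    K <- kinship(g)
    causal <- sample(ncol(g$dosages), 1)
    ev <- eigen(unclass(K), symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
    y <- g$dosages[, causal] +
      as.vector(L %*% rnorm(n)) * sqrt(0.3) + rnorm(n, sd = sqrt(0.4))
    names(y) <- rownames(g$dosages)
    res <- gwas_scan(y, g, K)
    which.min(res$snps$p_value) ==
      match(colnames(g$dosages)[causal], res$snps$snp_id)
  })
  expect_gte(mean(hits), 0.8)
})

test_that("the Cholesky permutation threshold behaves like Sidak and respects K = I", {
  set.seed(4)
  n <- 60; m <- 250
  dos <- matrix(rbinom(n * m, 1, rep(runif(m, 0.2, 0.5), each = n)), n, m,
                dimnames = list(sprintf("a%03d", 1:n),
                                sprintf("chr1_%d", 1:m * 37)))
  g <- maf_filter(mkmicrobiome:::genotype_matrix(dos), 0.05)
  K <- kinship(g)
  y <- rnorm(n)
  names(y) <- rownames(g$dosages)
  thr <- cholesky_perm_threshold(y, g, K, n_perm = 60, alpha = 0.05, seed = 5)
  m_eff <- ncol(g$dosages)
  sidak <- 1 - (1 - 0.05)^(1 / m_eff)
  expect_gt(thr$threshold, sidak / 3)
  expect_lt(thr$threshold, sidak * 3)
  expect_equal(length(thr$min_p), 60)

  # with K = I the procedure reduces to a plain phenotype permutation
  KI <- structure(diag(n), dimnames = list(names(y), names(y)),
                  class = c("kinship_matrix", "matrix"))
  thrI <- cholesky_perm_threshold(y, g, KI, n_perm = 60, alpha = 0.05,
                                  seed = 6)
  set.seed(6)
  plain <- replicate(60, {
    yp <- setNames(sample(unname(y)), names(y))
    min(gwas_scan(yp, g, KI)$snps$p_value, na.rm = TRUE)
  })
  # same Monte-Carlo scale (log10 thresholds within an order of magnitude)
  expect_lt(abs(log10(thrI$threshold) -
                  log10(quantile(plain, 0.05, type = 1))), 1)

  expect_error(cholesky_perm_threshold(y, g, K, n_perm = 10), "20")
})

test_that("the threshold tightens as the genome grows", {
  set.seed(7)
  n <- 50
  thr_for <- function(m) {
    dos <- matrix(rbinom(n * m, 1, rep(runif(m, 0.2, 0.5), each = n)), n, m,
                  dimnames = list(sprintf("a%03d", 1:n),
                                  sprintf("chr1_%d", seq_len(m) * 13)))
    g <- maf_filter(mkmicrobiome:::genotype_matrix(dos), 0.05)
    cholesky_perm_threshold(y = setNames(rnorm(n), rownames(g$dosages)),
                            g = g, n_perm = 40, seed = 8)$threshold
  }
  t_small <- thr_for(40)
  t_large <- thr_for(400)
  expect_lt(t_large, t_small)
})

test_that("window summaries match a group-by oracle and the printed arithmetic", {
  set.seed(9)
  snps <- tibble::tibble(
    snp_id = sprintf("s%03d", 1:200),
    chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
    pos = sample.int(2e5, 200),
    beta = rnorm(200), se = 1, stat = rnorm(200),
    p_value = runif(200))
  res <- structure(list(snps = snps, lambda_gc = 1, n = 50),
                   class = "gwas_result")
  ws <- window_summary(res, window_bp = 10000)
  # brute-force group-by oracle
  oracle <- tapply(snps$p_value,
                   paste(snps$chrom, floor(snps$pos / 10000)), min)
  expect_equal(nrow(ws), length(oracle))
  expect_equal(ws$min_p, as.vector(oracle[paste(ws$chrom, ws$window)]))
  expect_true(all(ws$n_snps >= 1))

  # the worked position: 23,179,000 / 10 kb -> window 2317
  one <- res
  one$snps <- tibble::tibble(snp_id = "x", chrom = "chr1", pos = 23179000,
                             beta = 0, se = 1, stat = 0, p_value = 0.5)
  expect_equal(window_summary(one, 10000)$window, 2317)

  # overlap join keeps only windows populated in both scans
  res2 <- res
  res2$snps$p_value <- runif(200)
  ov <- overlap_windows(res, res2, 10000)
  expect_true(all(paste(ov$chrom, ov$window) %in% paste(ws$chrom, ws$window)))
  expect_true(all(c("min_p_1", "min_p_2") %in% names(ov)))
})

test_that("Storey q-values reduce to BH at pi0 = 1 and stay monotone", {
  set.seed(10)
  p <- c(runif(80), rbeta(20, 0.2, 5))
  q_forced <- storey_qvalue(p, pi0 = 1)
  expect_equal(as.numeric(q_forced), p.adjust(p, "BH"), tolerance = 1e-12)
  q <- storey_qvalue(p)
  pi0 <- attr(q, "pi0")
  expect_true(pi0 > 0 && pi0 <= 1)
  expect_true(all(q <= 1))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  # uniform p-values: essentially nothing passes a 10% FDR
  q_null <- storey_qvalue(runif(200))
  expect_lt(mean(q_null < 0.10), 0.02)
})

test_that("GO tail enrichment matches closed-form hypergeometric bookkeeping", {
  # 1000 genes on one chromosome, every gene scored by one SNP;
  # the 10 tail genes all fall in one 20-gene category
  n_genes <- 1000
  genes <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:n_genes),
    chrom = "chr1",
    start = 1:n_genes * 50000,
    end = 1:n_genes * 50000 + 2000)
  set.seed(11)
  pvals <- runif(n_genes, 0.2, 1)
  pvals[1:10] <- 1e-6  # the tail
  snps <- tibble::tibble(
    snp_id = sprintf("snp%04d", 1:n_genes), chrom = "chr1",
    pos = genes$start + 1000, beta = 0, se = 1, stat = 0, p_value = pvals)
  res <- structure(list(snps = snps, lambda_gc = 1, n = 100),
                   class = "gwas_result")
  go_map <- tibble::tibble(
    gene_id = c(sprintf("g%04d", 1:20),          # GO:HIT 20 genes, 10 in tail
                sprintf("g%04d", 101:140),       # GO:COLD 40 genes, none
                "g0999"),                        # GO:TINY < 2 genes, excluded
    go_id = c(rep("GO:HIT", 20), rep("GO:COLD", 40), "GO:TINY"))
  out <- suppressMessages(
    go_tail_enrichment(res, genes, go_map, tail_fraction = 0.01,
                       window_bp = 1500))
  expect_false("GO:TINY" %in% out$go_id)
  hit <- out[out$go_id == "GO:HIT", ]
  expect_equal(hit$observed, 10)
  expect_equal(hit$expected, 10 * 20 / 1000)
  expect_equal(hit$enrichment, 10 / (10 * 20 / 1000))  # = 50
  # exact enumeration of the hypergeometric upper tail
  exact <- sum(dhyper(10:20, 20, 980, 10))
  expect_equal(hit$p_value, exact, tolerance = 1e-12)
  expect_lt(hit$q_value, 0.10)
  expect_true(hit$significant)
  cold <- out[out$go_id == "GO:COLD", ]
  expect_equal(cold$observed, 0)
  expect_gt(cold$p_value, 0.5)
})

test_that("gene scores take the best SNP in the flanked gene body", {
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                          start = c(10000, 50000), end = c(12000, 52000))
  snps <- tibble::tibble(
    snp_id = paste0("s", 1:4), chrom = "chr1",
    pos = c(9500, 11000, 13500, 30000),
    beta = 0, se = 1, stat = 0,
    p_value = c(0.01, 0.20, 0.05, 0.001))
  res <- structure(list(snps = snps, lambda_gc = 1, n = 10),
                   class = "gwas_result")
  sc <- gene_scores(res, genes, window_bp = 2000)
  expect_equal(sc$score[sc$gene_id == "gA"], 0.01)  # s1 inside the flank
  expect_equal(sc$n_snps[sc$gene_id == "gA"], 3)
  expect_false("gB" %in% sc$gene_id)                # no SNP within reach
})
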