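test_that("Pearson r and its t-based p match the direct formulas", {
  set.seed(1)
  counts <- matrix(rpois(10 * 6, 30), 10, 6,
                   dimnames = list(paste0("s", 1:10), paste0("t", 1:6)))
  tab <- count_table(counts, "bacteria")
  cm <- correlation_matrix(tab, top_n = Inf)
  # brute-force covariance formula oracle
  for (i in 1:5) for (j in (i + 1):6) {
    x <- counts[, i]; y <- counts[, j]
    r_direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(cm$r[i, j], r_direct, tolerance = 1e-12)
    t_direct <- r_direct * sqrt(8 / (1 - r_direct^2))
    expect_equal(cm$p[i, j], 2 * pt(-abs(t_direct), 8), tolerance = 1e-12)
  }
  expect_equal(unname(diag(cm$r)), rep(1, 6))
  expect_true(isSymmetric(cm$r))

  # permuting sample order leaves the matrix unchanged
  perm <- sample(10)
  tab2 <- count_table(counts[perm, ], "bacteria")
  cm2 <- correlation_matrix(tab2, top_n = Inf)
  expect_equal(cm2$r, cm$r)
})

test_that("a duplicated taxon correlates perfectly and zero variance is excluded", {
  set.seed(2)
  base <- rpois(12, 50)
  counts <- cbind(t1 = base, t1_copy = base, t2 = rpois(12, 50),
                  t_const = rep(5L, 12))
  rownames(counts) <- paste0("s", 1:12)
  tab <- count_table(counts, "fungi")
  cm <- correlation_matrix(tab, top_n = Inf)
  expect_equal(cm$r["t1", "t1_copy"], 1, tolerance = 1e-12)
  expect_lt(cm$p["t1", "t1_copy"], 1e-12)
  expect_true(all(is.na(cm$r["t_const", c("t1", "t2")])))
  net <- build_network(cm, edge_alpha = 0.01)
  expect_false("t_const" %in% net$nodes$taxon_id)
})

test_that("edges appear exactly where p falls under the threshold", {
  taxa <- paste0("t", 1:4)
  r <- diag(4); r[upper.tri(r)] <- c(0.9, -0.8, 0.1, 0.2, 0.05, 0.7)
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  p <- matrix(0.5, 4, 4)
  p[1, 2] <- p[2, 1] <- 0.001   # t1-t2
  p[1, 3] <- p[3, 1] <- 0.005   # t1-t3
  p[3, 4] <- p[4, 3] <- 0.0001  # t3-t4
  diag(p) <- NA
  dimnames(r) <- dimnames(p) <- list(taxa, taxa)
  cm <- manual_corr(r, p, kingdom = c("bacteria", "bacteria", "fungi", "fungi"))
  net <- build_network(cm, edge_alpha = 0.01)
  expect_equal(nrow(net$edges), 3)
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("t1 t2", "t1 t3", "t3 t4"))
  # sign retained from r
  expect_equal(net$edges$sign[net$edges$from == "t1" & net$edges$to == "t3"],
               "negative")

  # boundary thresholds
  expect_equal(nrow(build_network(cm, edge_alpha = 1e-9)$edges), 0)
  expect_equal(nrow(build_network(cm, edge_alpha = 1.0)$edges), 6)

  # degree sum = 2 x edge count
  cent <- centrality(net)
  expect_equal(sum(cent$degree), 2 * nrow(net$edges))
})

test_that("centrality matches shortest-path enumeration on canonical graphs", {
  # star K_{1,4}: center degree 4, betweenness C(4,2) = 6; leaves 0
  taxa <- c("hub", paste0("leaf", 1:4))
  p <- matrix(0.9, 5, 5, dimnames = list(taxa, taxa))
  p["hub", 2:5] <- p[2:5, "hub"] <- 0.001
  r <- matrix(0.5, 5, 5, dimnames = list(taxa, taxa)); diag(r) <- 1
  diag(p) <- NA
  net <- build_network(manual_corr(r, p, rep("bacteria", 5)), 0.01)
  cent <- centrality(net)
  expect_equal(cent$degree[cent$taxon_id == "hub"], 4L)
  expect_equal(cent$betweenness[cent$taxon_id == "hub"], 6)
  expect_equal(cent$betweenness[cent$taxon_id == "leaf1"], 0)

  # path a-b-c: b lies on the single a-c geodesic
  taxa <- c("a", "b", "c")
  p <- matrix(0.9, 3, 3, dimnames = list(taxa, taxa))
  p["a", "b"] <- p["b", "a"] <- 0.001
  p["b", "c"] <- p["c", "b"] <- 0.001
  diag(p) <- NA
  r <- matrix(0.5, 3, 3, dimnames = list(taxa, taxa))
  net <- build_network(manual_corr(r, p, rep("fungi", 3)), 0.01)
  cent <- centrality(net)
  expect_equal(cent$betweenness[cent$taxon_id == "b"], 1)
  expect_equal(cent$degree[cent$taxon_id == "a"], 1L)

  # isolated node
  p2 <- p; p2["b", "c"] <- p2["c", "b"] <- 0.9
  p2["a", "b"] <- p2["b", "a"] <- 0.9
  net2 <- build_network(manual_corr(r, p2, rep("fungi", 3)), 0.01)
  cent2 <- centrality(net2)
  expect_equal(cent2$degree, rep(0L, 3))
  expect_equal(cent2$betweenness, rep(0, 3))
})

test_that("the kingdom-degree slope is the difference of mean degrees", {
  # fungi densely connected among themselves, bacteria sparse
  set.seed(4)
  n <- 40
  taxa <- c(paste0("b", 1:20), paste0("f", 1:20))
  kingdom <- rep(c("bacteria", "fungi"), each = 20)
  p <- matrix(0.9, n, n, dimnames = list(taxa, taxa))
  fidx <- 21:40
  p[fidx, fidx] <- 0.001
  bidx <- sample(1:20, 6)
  for (k in seq(1, 6, by = 2)) {
    p[bidx[k], bidx[k + 1]] <- p[bidx[k + 1], bidx[k]] <- 0.001
  }
  diag(p) <- NA
  r <- matrix(0.4, n, n, dimnames = list(taxa, taxa)); diag(r) <- 1
  net <- build_network(manual_corr(r, p, kingdom), 0.01)
  res <- kingdom_degree_test(net)
  cent <- centrality(net)
  expect_equal(res$slope,
               mean(cent$degree[cent$kingdom == "fungi"]) -
                 mean(cent$degree[cent$kingdom == "bacteria"]))
  expect_lt(res$p_value, 0.01)

  # single-kingdom network errors
  net1 <- build_network(manual_corr(r[1:20, 1:20], p[1:20, 1:20],
                                    rep("bacteria", 20)), 0.01)
  expect_error(kingdom_degree_test(net1), "both kingdoms")
})

test_that("mean within- and cross-kingdom correlations are row means without self", {
  taxa <- c("b1", "b2", "f1")
  r <- matrix(c(1, 0.5, -0.2,
                0.5, 1, 0.4,
                -0.2, 0.4, 1), 3, dimnames = list(taxa, taxa))
  p <- matrix(0.5, 3, 3, dimnames = list(taxa, taxa)); diag(p) <- NA
  cm <- manual_corr(r, p, c("bacteria", "bacteria", "fungi"))
  mc <- node_mean_correlations(cm)
  expect_equal(mc$mean_r_within[mc$taxon_id == "b1"], 0.5)
  expect_equal(mc$mean_r_cross[mc$taxon_id == "b1"], -0.2)
  expect_equal(mc$mean_r_within[mc$taxon_id == "f1"], NaN)
  expect_equal(mc$mean_r_cross[mc$taxon_id == "f1"], mean(c(-0.2, 0.4)))
})

test_that("depth sensitivity reports retention and degree stability", {
  sim <- small_sim(n_accessions = 12, n_replicates = 3, n_taxa = 15,
                   latent_factors = 3, loadings_scale = 0.8, seed = 6,
                   depth_mean_bacteria = 1200, depth_sd_bacteria = 400)
  res <- suppressMessages(suppressWarnings(
    depth_sensitivity(sim$bacteria, depths = c(250, 400, 800),
                      reference = 400, top_n = 15, seed = 2)))
  expect_equal(nrow(res), 3)
  # retention is monotone non-increasing in depth
  expect_true(all(diff(res$n_samples) <= 0))
  # the reference depth against itself with the same seed stream need not
  # be the identical draw, but a repeated identical depth is rank-stable
  res2 <- suppressMessages(suppressWarnings(
    depth_sensitivity(sim$bacteria, depths = c(400, 400), reference = 400,
                      top_n = 15, seed = 2)))
  expect_true(all(res2$n_samples == res2$n_samples[1]))
})
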