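# small in-code fixtures shared across test files

# a tiny hand-specified table: 2 samples x 3 taxa, row sums 10 and 5
toy_table <- function() {
  counts <- matrix(c(6L, 2L, 2L,
                     1L, 0L, 4L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
  count_table(counts, kingdom = "bacteria",
              lineage = c("k__Bacteria;p__P1;c__C1;o__O1;f__F1;g__G1",
                          "k__Bacteria;p__P1;c__C2;o__O2;f__F2;g__G2",
                          "k__Bacteria;p__P2;c__C3;o__O3;f__F3;g__G3"))
}

# random integer count table with given dimensions
random_table <- function(n_samples, n_taxa, kingdom = "bacteria",
                         lambda = 20, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_taxa, lambda), nrow = n_samples,
                   dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                   sprintf("t%02d", seq_len(n_taxa))))
  storage.mode(counts) <- "integer"
  count_table(counts, kingdom = kingdom)
}

# balanced two-sample metadata for the organ-enrichment worked examples
two_sample_meta <- function(total = 1000L) {
  tibble::tibble(sample_id = c("L", "R"), accession_id = "acc1",
                 organ = c("leaf", "root"), block = "b1", run = "r1",
                 total_reads = as.integer(total))
}

# metadata for a simple replicated design without simulating communities
design_meta <- function(n_accessions, n_replicates, organ = "root",
                        n_blocks = 2, n_runs = 2, seed = 1) {
  set.seed(seed)
  acc <- sprintf("acc%02d", seq_len(n_accessions))
  out <- tidyr::expand_grid(accession_id = acc,
                            replicate = seq_len(n_replicates))
  out$sample_id <- paste0(out$accession_id, "_r", out$replicate)
  out$plant_id <- out$sample_id
  out$organ <- organ
  out$block <- paste0("b", ((out$replicate - 1) %% n_blocks) + 1)
  out$run <- paste0("run", sample(n_runs, nrow(out), replace = TRUE))
  out
}

# quick small simulated experiment for downstream modules
small_sim <- function(n_accessions = 20, n_replicates = 3, n_taxa = 10,
                      h2_bacteria = 0, h2_fungi = 0, organs = "root",
                      n_snps = 200, seed = 1, ...) {
  p <- sim_params(n_accessions = n_accessions, n_replicates = n_replicates,
                  n_snps = n_snps, n_taxa_bacteria = n_taxa,
                  n_taxa_fungi = n_taxa, h2_bacteria = h2_bacteria,
                  h2_fungi = h2_fungi, organs = organs,
                  depth_mean_fungi = 1500, depth_sd_fungi = 700,
                  seed = seed, ...)
  g <- simulate_genotypes(p)
  sim <- simulate_community(g, p)
  sim$genotypes <- g
  sim$params <- p
  sim
}

# construct a correlation_matrix object directly (white-box) for network
# tests that need exact control over p-values
manual_corr <- function(r, p, kingdom) {
  structure(list(r = r, p = p, n_samples = 30,
                 taxa = tibble::tibble(taxon_id = rownames(r),
                                       kingdom = kingdom)),
            class = "correlation_matrix")
}

# a count table whose per-sample richness follows an exact Poisson GLMM:
# richness r_i ~ Poisson(exp(b0 + a_accession)), constant depth
richness_glmm_table <- function(meta, sigma2_acc, b0 = 3, depth = 1000L,
                                seed = 1) {
  set.seed(seed)
  acc <- unique(meta$accession_id)
  a <- setNames(rnorm(length(acc), 0, sqrt(sigma2_acc)), acc)
  r <- rpois(nrow(meta), exp(b0 + a[meta$accession_id]))
  r <- pmax(1L, pmin(r, 80L))
  counts <- matrix(0L, nrow(meta), 81,
                   dimnames = list(meta$sample_id, sprintf("t%02d", 0:80)))
  for (i in seq_len(nrow(meta))) {
    counts[i, 1] <- depth - (r[i] - 1L)
    if (r[i] > 1) counts[i, 1 + seq_len(r[i] - 1L)] <- 1L
  }
  count_table(counts, "bacteria")
}

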