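#' Parameters for the synthetic two-kingdom study
#'
#' Collects every knob of the synthetic-data generator.  The defaults emulate
#' the study design the package targets: 196 inbred accessions with four
#' replicate plants in a randomized block design, leaf and root sampled from
#' each plant, bacterial and fungal communities sequenced separately with
#' heavily dispersed depths (lognormal, moment-matched to mean 2524 / sd 1594
#' reads for bacteria and 562 / 726 for fungi).
#'
#' Per-taxon log-rates are built additively from a baseline, an accession
#' effect (polygenic over causal SNPs, or i.i.d.), an organ effect, block and
#' sequencing-run artifacts, low-rank latent factors inducing cross-taxon
#' correlation, and i.i.d. overdispersion noise.  Accession effects are
#' rescaled so that, on the realized sample, the fraction of linear-predictor
#' variance attributable to accession equals `h2` for each taxon.
#'
#' @param n_accessions,n_replicates Design size (default 196 x 4).
#' @param organs Organs sampled from each plant.
#' @param n_blocks,n_runs Numbers of field blocks and sequencing runs.
#' @param n_snps Number of simulated SNPs.
#' @param n_clusters,fst Optional population structure: ancestral clusters
#'   with Balding-Nichols differentiation `fst` (ignored when
#'   `n_clusters = 1`).
#' @param n_taxa_bacteria,n_taxa_fungi Taxa per kingdom.
#' @param h2_bacteria,h2_fungi Per-taxon target heritability of the
#'   log-abundance linear predictor, scalar or one value per taxon.
#' @param polygenic Draw accession effects as sums over causal SNPs (`TRUE`)
#'   or as i.i.d. accession deviations (`FALSE`).
#' @param n_causal_snps Causal SNPs per taxon when `polygenic`.
#' @param shared_fraction Fraction of each taxon's accession-effect variance
#'   carried by a single kingdom-wide genetic axis (a polygenic score with
#'   taxon-varying loadings), the remainder being taxon-specific.  Host genes
#'   with community-wide effects (root morphology, immunity) motivate a
#'   nonzero default of 0.5; purely taxon-specific architecture is
#'   `shared_fraction = 0`.
#' @param sigma_block,sigma_run,sigma_organ,sigma_noise Log-scale standard
#'   deviations of block artifacts, run artifacts, per-taxon organ effects,
#'   and i.i.d. overdispersion.
#' @param mu_sd Spread of baseline log-abundances across taxa (larger gives
#'   a more uneven, realistic rank-abundance curve).
#' @param latent_factors,loadings_scale Number of per-sample latent factors
#'   and the standard deviation of taxon loadings on them.
#' @param depth_mean_bacteria,depth_sd_bacteria,depth_mean_fungi,depth_sd_fungi
#'   Target mean and standard deviation of per-sample read depths.
#' @param seed Integer seed recorded in every simulated object.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_accessions = 196,
                       n_replicates = 4,
                       organs = c("leaf", "root"),
                       n_blocks = 4,
                       n_runs = 2,
                       n_snps = 1000,
                       n_clusters = 1,
                       fst = 0.1,
                       n_taxa_bacteria = 100,
                       n_taxa_fungi = 100,
                       h2_bacteria = 0,
                       h2_fungi = 0,
                       polygenic = TRUE,
                       n_causal_snps = 10,
                       shared_fraction = 0.5,
                       sigma_block = 0.2,
                       sigma_run = 0.2,
                       sigma_organ = 0.5,
                       sigma_noise = 0.4,
                       mu_sd = 1.5,
                       latent_factors = 2,
                       loadings_scale = 0.3,
                       depth_mean_bacteria = 2524,
                       depth_sd_bacteria = 1594,
                       depth_mean_fungi = 562,
                       depth_sd_fungi = 726,
                       seed = 1L) {
  p <- as.list(environment())
  assert_that(all(c(p$h2_bacteria, p$h2_fungi) >= 0) &&
                all(c(p$h2_bacteria, p$h2_fungi) <= 1),
              "heritabilities must lie in [0, 1]")
  assert_that(all(c(p$sigma_block, p$sigma_run, p$sigma_organ,
                    p$sigma_noise, p$loadings_scale) >= 0),
              "all standard deviations must be >= 0")
  assert_that(p$shared_fraction >= 0 && p$shared_fraction <= 1,
              "shared_fraction must lie in [0, 1]")
  structure(p, class = "sim_params")
}

# lognormal parameters matching a target mean and sd
lognormal_moments <- function(mean, sd) {
  s2 <- log(1 + sd^2 / mean^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate inbred accession genotypes
#'
#' SNP allele frequencies are drawn Uniform(0.05, 0.5); dosages are haploid
#' 0/1 Bernoulli draws.  With `n_clusters > 1`, cluster-specific frequencies
#' follow a Balding-Nichols model with differentiation `fst`, giving the
#' kinship matrix a leading eigenvector that separates the clusters.
#'
#' @param params A [sim_params()] object.
#' @return A `genotype_matrix` with an extra `cluster` attribute giving each
#'   accession's ancestral cluster.
#' @export
simulate_genotypes <- function(params) {
  set.seed(derive_seed(params$seed, 11L))
  n <- params$n_accessions
  m <- params$n_snps
  p0 <- runif(m, 0.05, 0.5)
  cluster <- sort(rep_len(seq_len(params$n_clusters), n))
  if (params$n_clusters > 1) {
    fst <- params$fst
    pk <- sapply(seq_len(params$n_clusters), function(k) {
      rbeta(m, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst)
    })
    dos <- matrix(rbinom(n * m, 1, t(pk[, cluster])), nrow = n, byrow = FALSE)
  } else {
    dos <- matrix(rbinom(n * m, 1, rep(p0, each = n)), nrow = n)
  }
  rownames(dos) <- sprintf("acc%03d", seq_len(n))
  chrom <- rep(1:5, length.out = m)[order(rep(1:5, length.out = m))]
  pos <- unlist(lapply(split(seq_len(m), chrom), function(i) {
    sort(sample.int(3e7, length(i)))
  }))
  colnames(dos) <- paste0("chr", chrom, "_", pos)
  g <- genotype_matrix(dos)
  attr(g, "cluster") <- cluster
  g
}

#' Simulate a replicated two-kingdom microbiome experiment
#'
#' Generates bacterial and fungal count tables plus sample metadata for the
#' full accession x replicate x organ design, with a truth record sufficient
#' to reconstruct every linear predictor exactly.  For each taxon the
#' per-sample log-rate is
#' `eta = mu + a[accession] + o[organ] + b[block] + c[run] + F %*% L + e`,
#' and counts are drawn as Poisson conditioned on the sample's simulated
#' depth (i.e. multinomial over taxa with probabilities proportional to
#' `exp(eta)`), so each sample's counts sum exactly to its depth.
#'
#' @param g A `genotype_matrix` from [simulate_genotypes()] (accessions are
#'   taken from its rows).  May be `NULL` when `params$polygenic = FALSE`.
#' @param params A [sim_params()] object.
#' @return A list with elements `bacteria` and `fungi` ([count_table()]s),
#'   `meta` (metadata tibble; depths per kingdom are attached by
#'   [complete_metadata()]), and `truth` (list of all simulated effects).
#' @export
simulate_community <- function(g, params) {
  set.seed(derive_seed(params$seed, 23L))
  if (params$polygenic) {
    assert_that(!is.null(g), "polygenic simulation needs genotypes")
    accessions <- rownames(g$dosages)
  } else {
    accessions <- sprintf("acc%03d", seq_len(params$n_accessions))
  }
  n_acc <- length(accessions)
  design <- tidyr::expand_grid(
    accession_id = accessions,
    replicate = seq_len(params$n_replicates),
    organ = params$organs
  )
  design$plant_id <- paste0(design$accession_id, "_r", design$replicate)
  design$sample_id <- paste0(design$plant_id, "_", design$organ)
  # randomized block design: replicates spread over blocks; runs assigned
  # to plants at random so run is partially confounded with nothing
  design$block <- paste0("b", ((design$replicate - 1) %% params$n_blocks) + 1)
  plant_run <- setNames(
    paste0("run", sample.int(params$n_runs, n_acc * params$n_replicates,
                             replace = TRUE)),
    unique(design$plant_id))
  design$run <- plant_run[design$plant_id]
  n_samp <- nrow(design)

  one_kingdom <- function(kingdom, n_taxa, h2, depth_mean, depth_sd, sub) {
    set.seed(derive_seed(params$seed, sub))
    h2 <- rep_len(h2, n_taxa)
    mu <- rnorm(n_taxa, 0, params$mu_sd)
    organ_eff <- matrix(rnorm(length(params$organs) * n_taxa, 0,
                              params$sigma_organ),
                        nrow = length(params$organs),
                        dimnames = list(params$organs, NULL))
    if (length(params$organs) > 1) {
      organ_eff <- sweep(organ_eff, 2, colMeans(organ_eff))
    }
    block_eff <- matrix(rnorm(params$n_blocks * n_taxa, 0, params$sigma_block),
                        nrow = params$n_blocks,
                        dimnames = list(paste0("b", seq_len(params$n_blocks)), NULL))
    run_eff <- matrix(rnorm(params$n_runs * n_taxa, 0, params$sigma_run),
                      nrow = params$n_runs,
                      dimnames = list(paste0("run", seq_len(params$n_runs)), NULL))
    Fmat <- matrix(rnorm(n_samp * params$latent_factors), nrow = n_samp)
    L <- matrix(rnorm(n_taxa * params$latent_factors, 0, params$loadings_scale),
                nrow = n_taxa)
    noise <- matrix(rnorm(n_samp * n_taxa, 0, params$sigma_noise), nrow = n_samp)

    # raw accession effects, then empirical rescaling to hit h2 per taxon
    if (params$polygenic) {
      causal <- replicate(n_taxa,
                          sample.int(ncol(g$dosages), params$n_causal_snps),
                          simplify = FALSE)
      own <- sapply(seq_len(n_taxa), function(t) {
        beta <- rnorm(params$n_causal_snps)
        as.vector(g$dosages[, causal[[t]], drop = FALSE] %*% beta)
      })
      # a kingdom-wide polygenic axis: one genetic score, taxon loadings;
      # a uniform (loading-free) axis would cancel under the multinomial
      # closure, so loadings vary across taxa
      shared_snps <- sample.int(ncol(g$dosages), params$n_causal_snps)
      g_shared <- as.vector(scale(
        g$dosages[, shared_snps, drop = FALSE] %*%
          rnorm(params$n_causal_snps)))
      # loadings lean on baseline abundance: the shared axis acts on
      # community evenness (dominance), which moves observed richness at
      # fixed depth as well as composition
      w <- (as.vector(scale(mu)) + rnorm(n_taxa)) / sqrt(2)
      sf <- params$shared_fraction
      a_raw <- sqrt(sf) * outer(g_shared, w) +
        sqrt(1 - sf) * apply(own, 2, function(x) {
          s <- stats::sd(x)
          if (s > 0) (x - mean(x)) / s else x
        })
      causal <- list(per_taxon = causal, shared = shared_snps)
    } else {
      causal <- NULL
      a_raw <- matrix(rnorm(n_acc * n_taxa), nrow = n_acc)
    }
    rownames(a_raw) <- accessions
    idx_acc <- match(design$accession_id, accessions)
    idx_org <- match(design$organ, params$organs)
    idx_blk <- match(design$block, rownames(block_eff))
    idx_run <- match(design$run, rownames(run_eff))

    eta_ng <- matrix(mu, n_samp, n_taxa, byrow = TRUE) +
      organ_eff[idx_org, , drop = FALSE] +
      block_eff[idx_blk, , drop = FALSE] +
      run_eff[idx_run, , drop = FALSE] +
      Fmat %*% t(L) + noise
    a <- a_raw
    for (t in seq_len(n_taxa)) {
      if (h2[t] == 0) {
        a[, t] <- 0
        next
      }
      v_ng <- stats::var(eta_ng[, t])
      if (v_ng < 1e-12 && h2[t] < 1) {
        rlang::abort("target h2 infeasible: no non-genetic variance to balance")
      }
      v_raw <- stats::var(a_raw[idx_acc, t])
      assert_that(v_raw > 0, "degenerate accession effect draw")
      target <- if (h2[t] < 1) h2[t] / (1 - h2[t]) * v_ng else 1
      a[, t] <- a_raw[, t] * sqrt(target / v_raw)
    }
    eta <- eta_ng + a[idx_acc, , drop = FALSE]

    dp <- lognormal_moments(depth_mean, depth_sd)
    depth <- pmax(1L, as.integer(round(rlnorm(n_samp, dp$meanlog, dp$sdlog))))
    counts <- matrix(0L, n_samp, n_taxa)
    for (i in seq_len(n_samp)) {
      pr <- exp(eta[i, ] - max(eta[i, ]))
      counts[i, ] <- as.integer(rmultinom(1, depth[i], pr))
    }
    taxon_id <- sprintf("%s_t%03d", substr(kingdom, 1, 1), seq_len(n_taxa))
    dimnames(counts) <- list(design$sample_id, taxon_id)
    colnames(a) <- taxon_id
    list(
      table = count_table(counts, kingdom = kingdom),
      truth = list(mu = setNames(mu, taxon_id), accession_effects = a,
                   organ_effects = organ_eff, block_effects = block_eff,
                   run_effects = run_eff, latent_scores = Fmat,
                   latent_loadings = L, noise = noise, causal_snps = causal,
                   h2 = setNames(h2, taxon_id), depth = depth, eta = eta)
    )
  }

  bact <- one_kingdom("bacteria", params$n_taxa_bacteria, params$h2_bacteria,
                      params$depth_mean_bacteria, params$depth_sd_bacteria, 31L)
  fung <- one_kingdom("fungi", params$n_taxa_fungi, params$h2_fungi,
                      params$depth_mean_fungi, params$depth_sd_fungi, 37L)
  meta <- tibble::as_tibble(design[, c("sample_id", "accession_id", "plant_id",
                                       "organ", "block", "run")])
  list(
    bacteria = bact$table,
    fungi = fung$table,
    meta = meta,
    truth = list(bacteria = bact$truth, fungi = fung$truth,
                 design = tibble::as_tibble(design), seed = params$seed)
  )
}

#' Reconstruct a simulated linear predictor from the truth record
#'
#' Used in tests to verify that the stored effects regenerate `eta` exactly.
#'
#' @param truth One kingdom's entry of the `truth` element returned by
#'   [simulate_community()].
#' @param design The `design` tibble from the same truth record.
#' @return Samples x taxa matrix of linear predictors.
#' @export
reconstruct_eta <- function(truth, design) {
  idx_acc <- match(design$accession_id, rownames(truth$accession_effects))
  idx_org <- match(design$organ, rownames(truth$organ_effects))
  idx_blk <- match(design$block, rownames(truth$block_effects))
  idx_run <- match(design$run, rownames(truth$run_effects))
  matrix(truth$mu, nrow(design), length(truth$mu), byrow = TRUE) +
    truth$organ_effects[idx_org, , drop = FALSE] +
    truth$block_effects[idx_blk, , drop = FALSE] +
    truth$run_effects[idx_run, , drop = FALSE] +
    truth$latent_scores %*% t(truth$latent_loadings) +
    truth$noise +
    truth$accession_effects[idx_acc, , drop = FALSE]
}
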