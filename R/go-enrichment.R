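#' Storey q-values
#'
#' False discovery rate adjustment with an estimate of the null proportion
#' `pi0`.  `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` is evaluated
#' on a lambda grid (0.05 to 0.95 in steps of 0.05 by default) and smoothed
#' with a cubic spline; the estimate is the smoothed value at the largest
#' lambda, clamped to `(0, 1]`.  q-values are
#' `pi0 * m * p / rank`, monotonized from the largest p downward and capped
#' at 1.  Forcing `pi0 = 1` reproduces Benjamini-Hochberg adjustment
#' exactly.
#'
#' @param p Vector of p-values.
#' @param lambda Grid for the `pi0` estimate.
#' @param pi0 Optional fixed null proportion, bypassing estimation.
#' @return Numeric vector of q-values with a `pi0` attribute.
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must be in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0_l <- sapply(lambda, function(l) mean(p > l, na.rm = TRUE) / (1 - l))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(1, max(pi0, 1 / m))
  }
  ord <- order(p)
  ranked <- p[ord] * m * pi0 / seq_len(m)
  q <- rev(cummin(rev(ranked)))        # monotone non-decreasing in p
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Per-gene association scores from a GWAS scan
#'
#' Gene score = minimum SNP p-value within the gene body extended by
#' `window_bp` on each side.  Genes without any SNP in range are dropped.
#'
#' @param res A `gwas_result`.
#' @param genes Gene annotation tibble (`gene_id`, `chrom`, `start`, `end`;
#'   1-based inclusive; see [read_gene_annotation()]).
#' @param window_bp Flank added to each side of the gene body
#'   (default 10000).
#' @return Tibble `gene_id`, `chrom`, `score` (min p), `n_snps`.
#' @export
gene_scores <- function(res, genes, window_bp = 10000) {
  snps <- dplyr::filter(res$snps, !is.na(.data$p_value))
  out <- purrr::map_dfr(split(genes, genes$chrom), function(gc) {
    sc <- snps[snps$chrom == gc$chrom[1], ]
    if (nrow(sc) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(gc)), function(i) {
      hit <- sc$pos >= gc$start[i] - window_bp & sc$pos <= gc$end[i] + window_bp
      if (!any(hit)) return(NULL)
      tibble::tibble(gene_id = gc$gene_id[i], chrom = gc$chrom[1],
                     score = min(sc$p_value[hit]), n_snps = sum(hit))
    })
  })
  tibble::as_tibble(out)
}

#' GO enrichment in the tail of a GWAS scan
#'
#' Scores every annotated gene by its best local SNP p-value
#' ([gene_scores()]), takes the top `tail_fraction` of genes (smallest
#' scores, ties broken by gene id), and tests each GO category for
#' over-representation in that tail with a hypergeometric test.  The
#' enrichment ratio is observed over expected tail membership; multiple
#' testing is corrected with Storey q-values ([storey_qvalue()]).
#' Categories annotating fewer than 2 scored genes are excluded.
#'
#' @param res A `gwas_result`.
#' @param genes Gene annotation tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param go_map Tibble `gene_id`, `go_id` (see [read_go_map()]).
#' @param tail_fraction Fraction of scored genes forming the tail
#'   (default 0.01).
#' @param window_bp Flank for SNP-to-gene assignment (default 10000).
#' @param fdr_q Highlight threshold stored on the result (default 0.10).
#' @return Tibble `go_id`, `n_genes`, `observed`, `expected`,
#'   `enrichment`, `p_value`, `q_value`, `significant`, sorted by q then p.
#' @export
go_tail_enrichment <- function(res, genes, go_map, tail_fraction = 0.01,
                               window_bp = 10000, fdr_q = 0.10) {
  scores <- gene_scores(res, genes, window_bp)
  assert_that(nrow(scores) > 0, "no genes could be scored")
  n_total <- nrow(scores)
  n_tail <- max(1L, ceiling(tail_fraction * n_total))
  ord <- order(scores$score, scores$gene_id)
  tail_genes <- scores$gene_id[ord[seq_len(n_tail)]]
  go_map <- dplyr::filter(go_map, .data$gene_id %in% scores$gene_id)
  cats <- split(go_map$gene_id, go_map$go_id)
  small <- names(cats)[lengths(cats) < 2]
  if (length(small)) {
    rlang::inform(sprintf("excluding %d GO categories with < 2 scored genes",
                          length(small)))
    cats <- cats[lengths(cats) >= 2]
  }
  assert_that(length(cats) > 0, "no testable GO categories")
  out <- purrr::map_dfr(names(cats), function(go) {
    members <- unique(cats[[go]])
    k <- length(members)
    obs <- sum(members %in% tail_genes)
    expected <- n_tail * k / n_total
    tibble::tibble(
      go_id = go, n_genes = k, observed = obs, expected = expected,
      enrichment = obs / expected,
      p_value = stats::phyper(obs - 1, k, n_total - k, n_tail,
                              lower.tail = FALSE)
    )
  })
  out$q_value <- as.numeric(storey_qvalue(out$p_value))
  out$significant <- out$q_value < fdr_q
  dplyr::arrange(out, .data$q_value, .data$p_value)
}
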