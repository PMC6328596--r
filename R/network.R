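#' Cross-kingdom Pearson correlation matrix
#'
#' Pairwise Pearson correlations among the best-sequenced taxa of each
#' kingdom, computed on a depth-resampled table so sequencing effort cannot
#' drive the correlations.  Two-sided p-values come from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#' Zero-variance taxa have undefined correlations; their pairs are recorded
#' as missing and excluded from any graph built on the matrix.
#'
#' @param table A rarefied [count_table()] (see [rarefy()]).
#' @param top_n Number of best-sequenced taxa to keep per kingdom
#'   (default 100); `Inf` keeps everything.
#' @return An object of class `correlation_matrix`: list with `r`, `p`
#'   (symmetric matrices), `n_samples`, and `taxa` (tibble `taxon_id`,
#'   `kingdom`).
#' @export
correlation_matrix <- function(table, top_n = 100) {
  kept <- purrr::map(split(taxon_ids(table), table$taxa$kingdom), function(ids) {
    sub <- subset_taxa(table, ids)
    if (is.finite(top_n) && top_n < length(ids)) sub <- top_taxa(sub, top_n)
    taxon_ids(sub)
  })
  table <- subset_taxa(table, unlist(kept, use.names = FALSE))
  x <- table$counts
  n <- nrow(x)
  assert_that(n >= 3, "need at least 3 samples for correlation p-values")
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(r) <- 1
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n_samples = n,
                 taxa = table$taxa[, c("taxon_id", "kingdom")]),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d taxa, %d samples\n",
              nrow(x$r), x$n_samples))
  invisible(x)
}

#' Per-node mean correlations within and across kingdoms
#'
#' For each taxon, the mean of its correlation-row entries with taxa of the
#' same kingdom and with taxa of the other kingdom (self excluded).
#'
#' @param c A `correlation_matrix`.
#' @return Tibble `taxon_id`, `kingdom`, `mean_r_within`, `mean_r_cross`.
#' @export
node_mean_correlations <- function(c) {
  same <- outer(c$taxa$kingdom, c$taxa$kingdom, "==")
  diag(same) <- NA
  purrr::map_dfr(seq_len(nrow(c$r)), function(i) {
    tibble::tibble(
      taxon_id = c$taxa$taxon_id[i],
      kingdom = c$taxa$kingdom[i],
      mean_r_within = mean(c$r[i, which(same[i, ])], na.rm = TRUE),
      mean_r_cross = mean(c$r[i, which(!same[i, ])], na.rm = TRUE)
    )
  })
}

#' Build a co-occurrence network from a correlation matrix
#'
#' Draws an (undirected, unweighted) edge between two taxa whenever the
#' correlation p-value is below `edge_alpha`; the correlation sign is kept
#' on the edge for display and summaries.
#'
#' @param c A `correlation_matrix`.
#' @param edge_alpha p-value threshold for edges (default 0.01).
#' @return An object of class `microbiome_network`: list with `graph`
#'   (igraph), `nodes` (tibble `taxon_id`, `kingdom`), `edges` (tibble
#'   `from`, `to`, `r`, `p`, `sign`), and `edge_alpha`.
#' @export
build_network <- function(c, edge_alpha = 0.01) {
  ut <- upper.tri(c$p)
  ok <- ut & !is.na(c$p) & c$p < edge_alpha
  idx <- which(ok, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = rownames(c$r)[idx[, 1]],
    to = colnames(c$r)[idx[, 2]],
    r = c$r[ok],
    p = c$p[ok],
    sign = ifelse(c$r[ok] >= 0, "positive", "negative")
  )
  # drop taxa whose correlations are entirely undefined (zero variance)
  undefined <- rowSums(!is.na(c$r)) <= 1
  nodes <- c$taxa[!undefined, ]
  graph <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                         directed = FALSE,
                                         vertices = nodes$taxon_id)
  structure(list(graph = graph, nodes = nodes, edges = edges,
                 edge_alpha = edge_alpha),
            class = "microbiome_network")
}

#' @export
print.microbiome_network <- function(x, ...) {
  cat(sprintf("<microbiome_network> %d nodes, %d edges (alpha = %g)\n",
              nrow(x$nodes), nrow(x$edges), x$edge_alpha))
  invisible(x)
}

#' @export
tidy.microbiome_network <- function(x, ...) x$edges

#' @export
glance.microbiome_network <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 edge_alpha = x$edge_alpha,
                 prop_positive = mean(x$edges$sign == "positive"))
}

#' Node centrality of a microbiome network
#'
#' Degree (number of incident edges, sign-agnostic) and unnormalized
#' shortest-path betweenness on the unweighted undirected graph.
#'
#' @param net A `microbiome_network`.
#' @return Tibble `taxon_id`, `kingdom`, `degree`, `betweenness`.
#' @export
centrality <- function(net) {
  deg <- igraph::degree(net$graph)
  btw <- igraph::betweenness(net$graph, directed = FALSE, weights = NA,
                             normalized = FALSE)
  tibble::tibble(
    taxon_id = names(deg),
    kingdom = net$nodes$kingdom[match(names(deg), net$nodes$taxon_id)],
    degree = as.integer(deg),
    betweenness = as.numeric(btw)
  )
}

#' Do fungi have more network connections than bacteria?
#'
#' Ordinary least squares of node degree on a kingdom indicator
#' (fungi = 1).  With a binary regressor the slope is exactly the
#' difference of kingdom mean degrees.
#'
#' @param net A `microbiome_network` containing both kingdoms.
#' @return Tibble `slope` (mean fungal minus mean bacterial degree),
#'   `p_value` (two-sided), `n_nodes`.
#' @export
kingdom_degree_test <- function(net) {
  cent <- centrality(net)
  assert_that(length(unique(cent$kingdom)) == 2,
              "kingdom_degree_test needs both kingdoms in the network")
  fit <- stats::lm(degree ~ I(kingdom == "fungi"), data = cent)
  s <- summary(fit)$coefficients
  tibble::tibble(slope = s[2, 1], p_value = s[2, 4], n_nodes = nrow(cent))
}

#' Stability of centrality across rarefaction depths
#'
#' Rebuilds the network at several resampling depths and reports, for each,
#' the Spearman rank correlation of node degree with the reference-depth
#' network (over the taxa present in both).
#'
#' @param table A raw [count_table()].
#' @param depths Integer vector of depths to compare (at least 2).
#' @param reference Reference depth (default 400).
#' @param top_n,edge_alpha Passed to [correlation_matrix()] /
#'   [build_network()].
#' @param seed Seed for the resampling draws.
#' @return Tibble `depth`, `n_samples`, `n_edges`, `degree_rank_cor`.
#' @export
depth_sensitivity <- function(table, depths, reference = 400, top_n = 100,
                              edge_alpha = 0.01, seed = 1L) {
  assert_that(length(depths) >= 2, "need at least 2 depths")
  degree_at <- function(depth, k) {
    rt <- rarefy(table, depth, seed = derive_seed(seed, k))
    if (nrow(rt$counts) < nrow(table$counts) / 2) {
      rlang::warn(sprintf("depth %d excludes more than half of the samples", depth))
    }
    net <- build_network(correlation_matrix(rt, top_n = top_n), edge_alpha)
    list(cent = centrality(net), n = nrow(rt$counts),
         n_edges = nrow(net$edges))
  }
  ref <- degree_at(reference, 0L)
  purrr::map_dfr(seq_along(depths), function(k) {
    cur <- degree_at(depths[k], k)
    joined <- dplyr::inner_join(ref$cent, cur$cent, by = "taxon_id",
                                suffix = c("_ref", ""))
    tibble::tibble(
      depth = depths[k],
      n_samples = cur$n,
      n_edges = cur$n_edges,
      degree_rank_cor = suppressWarnings(
        stats::cor(joined$degree_ref, joined$degree, method = "spearman"))
    )
  })
}
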