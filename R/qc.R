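#' Quality-filter a count table
#'
#' Removes taxa that are (a) unassigned at the kingdom rank of their lineage,
#' (b) assigned to class Chloroplast, (c) assigned to family Mitochondria, or
#' (d) singletons -- taxa observed (count > 0) in at most one sample.  By
#' default singleton status is judged jointly across all samples in the
#' table (leaf and root together); set `per_organ = TRUE` with a metadata
#' tibble to require presence in at least two samples of some single organ.
#'
#' @param table A [count_table()].
#' @param per_organ Judge singletons within each organ separately.
#' @param meta Metadata tibble, required when `per_organ = TRUE`.
#' @return The filtered [count_table()] with a `filter_report` attribute: a
#'   tibble listing each removed taxon and the rule that removed it
#'   (a taxon failing several rules is reported under the first, in the
#'   order unassigned-kingdom, chloroplast, mitochondria, singleton).
#' @export
qc_filter <- function(table, per_organ = FALSE, meta = NULL) {
  tax <- taxonomy(table)
  unassigned <- tax$rank_kingdom == "Unassigned" & !is.na(table$taxa$lineage)
  # taxa with no lineage at all keep their stamped kingdom
  unassigned[is.na(table$taxa$lineage)] <- FALSE
  chloro <- tax$rank_class == "Chloroplast"
  mito   <- tax$rank_family == "Mitochondria"
  if (per_organ) {
    assert_that(!is.null(meta), "per-organ filtering needs `meta`")
    organs <- split(meta$sample_id, meta$organ)
    prev <- sapply(organs, function(s) {
      colSums(table$counts[rownames(table$counts) %in% s, , drop = FALSE] > 0)
    })
    singleton <- apply(prev, 1, max) <= 1
  } else {
    singleton <- colSums(table$counts > 0) <= 1
  }
  rule <- rep(NA_character_, ncol(table$counts))
  rule[singleton]  <- "singleton"
  rule[mito]       <- "mitochondria"
  rule[chloro]     <- "chloroplast"
  rule[unassigned] <- "unassigned_kingdom"
  report <- tibble::tibble(taxon_id = taxon_ids(table), rule = rule)
  report <- dplyr::filter(report, !is.na(.data$rule))
  out <- subset_taxa(table, is.na(rule))
  if (ncol(out$counts) == 0) {
    rlang::warn("qc_filter removed every taxon; the table is empty")
  }
  attr(out, "filter_report") <- report
  out
}

#' @rdname qc_filter
#' @export
filter_report <- function(table) {
  attr(table, "filter_report") %||%
    tibble::tibble(taxon_id = character(), rule = character())
}

#' Select the best-sequenced taxa
#'
#' Ranks taxa by total reads summed over samples (descending) and keeps the
#' top `n`.  Ties are broken lexicographically on `taxon_id` so the
#' selection is deterministic.
#'
#' @param table A [count_table()].
#' @param n Number of taxa to keep.
#' @return A [count_table()] restricted to the selected taxa, in rank order.
#' @export
top_taxa <- function(table, n) {
  assert_that(is.numeric(n) && n >= 1, "`n` must be >= 1")
  if (n > ncol(table$counts)) {
    rlang::warn(sprintf("n = %d exceeds the %d available taxa; returning all",
                        n, ncol(table$counts)))
    n <- ncol(table$counts)
  }
  totals <- taxon_totals(table)
  ord <- order(-totals, taxon_ids(table))
  subset_taxa(table, ord[seq_len(n)])
}

#' Filter SNPs on minor allele frequency
#'
#' @param g A `genotype_matrix` (see [read_genotypes()]).
#' @param min_maf Minimum minor allele frequency to retain (default 0.05).
#' @return The filtered `genotype_matrix`.
#' @export
maf_filter <- function(g, min_maf = 0.05) {
  keep <- g$maf >= min_maf
  structure(list(
    dosages = g$dosages[, keep, drop = FALSE],
    snps    = g$snps[keep, ],
    maf     = g$maf[keep]
  ), class = "genotype_matrix")
}
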