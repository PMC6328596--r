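#' Differential enrichment of one taxon between organs
#'
#' Poisson GLM of a taxon's read counts on organ (root vs leaf), with block
#' and sequencing-run fixed effects where the design has more than one
#' level, and `log(total_reads)` as offset.  The enrichment is the rate
#' ratio `exp(beta_organ)` (root relative to leaf); in the balanced
#' two-sample case with no covariates this equals the ratio of relative
#' abundances `(c_root / N_root) / (c_leaf / N_leaf)` exactly.
#'
#' Taxa entirely absent from one organ sit on the boundary of the parameter
#' space: the enrichment is reported as 0 (absent from root) or `Inf`
#' (absent from leaf) and the Wald p-value is flagged unreliable via
#' `boundary = TRUE`.
#'
#' @param counts Integer vector of reads for one taxon, one entry per sample
#'   (named by sample id, or in `meta` row order).
#' @param meta Metadata tibble including `total_reads` (see
#'   [complete_metadata()]); both organs must be represented.
#' @param p_type `"wald"` (default) or `"lrt"`.
#' @return One-row tibble: `leaf`, `root` (mean per-sample relative
#'   abundances), `leaf_pooled`, `root_pooled` (pooled proportions),
#'   `enrichment`, `p_value`, `preferred_habitat`, `boundary`.
#' @export
fit_enrichment <- function(counts, meta, p_type = c("wald", "lrt")) {
  p_type <- match.arg(p_type)
  assert_that(all(c("leaf", "root") %in% meta$organ),
              "both organs must be present")
  assert_that("total_reads" %in% names(meta),
              "meta needs total_reads; see complete_metadata()")
  if (!is.null(names(counts))) counts <- counts[meta$sample_id]
  dat <- meta
  dat$count <- as.numeric(counts)
  dat$organ <- factor(dat$organ, levels = c("leaf", "root"))
  fixed <- fixed_terms(dat, extra = "organ")
  form <- stats::as.formula(paste(
    "count ~", paste(fixed, collapse = " + "), "+ offset(log(total_reads))"))
  fit <- suppressWarnings(
    stats::glm(form, data = dat, family = stats::poisson(),
               control = list(epsilon = 1e-10, maxit = 100)))
  beta <- stats::coef(fit)["organroot"]
  se <- sqrt(diag(stats::vcov(fit)))["organroot"]
  zero_leaf <- sum(dat$count[dat$organ == "leaf"]) == 0
  zero_root <- sum(dat$count[dat$organ == "root"]) == 0
  boundary <- zero_leaf || zero_root
  enrichment <- if (zero_root) 0 else if (zero_leaf) Inf else exp(unname(beta))
  p <- if (p_type == "wald") {
    2 * stats::pnorm(-abs(unname(beta) / unname(se)))
  } else {
    null_form <- stats::as.formula(paste(
      "count ~", paste(c(setdiff(fixed, "organ"), "1"), collapse = " + "),
      "+ offset(log(total_reads))"))
    fit0 <- suppressWarnings(
      stats::glm(null_form, data = dat, family = stats::poisson(),
                 control = list(epsilon = 1e-10, maxit = 100)))
    stats::pchisq(fit0$deviance - fit$deviance, df = 1, lower.tail = FALSE)
  }
  rel <- dat$count / dat$total_reads
  tibble::tibble(
    leaf = mean(rel[dat$organ == "leaf"]),
    root = mean(rel[dat$organ == "root"]),
    leaf_pooled = sum(dat$count[dat$organ == "leaf"]) /
      sum(dat$total_reads[dat$organ == "leaf"]),
    root_pooled = sum(dat$count[dat$organ == "root"]) /
      sum(dat$total_reads[dat$organ == "root"]),
    enrichment = enrichment,
    p_value = p,
    preferred_habitat = ifelse(enrichment > 1, "root", "leaf"),
    boundary = boundary
  )
}

# sum counts within a lineage rank, per kingdom; "Unassigned" is its own bin
aggregate_rank <- function(table, rank) {
  rank_col <- paste0("rank_", rank)
  tax <- taxonomy(table)
  assert_that(rank_col %in% names(tax),
              sprintf("unknown taxonomic rank '%s'", rank))
  key <- paste(tax$kingdom, tax[[rank_col]], sep = "|")
  groups <- split(seq_len(ncol(table$counts)), key)
  counts <- sapply(groups, function(j) {
    rowSums(table$counts[, j, drop = FALSE])
  })
  kingdom <- sub("\\|.*$", "", colnames(counts))
  name <- sub("^.*\\|", "", colnames(counts))
  colnames(counts) <- paste0(kingdom, ":", name)
  storage.mode(counts) <- "integer"
  list(counts = counts, kingdom = kingdom, name = name)
}

#' Organ-enrichment table at a taxonomic rank
#'
#' Aggregates counts to the requested rank (summing reads within each
#' kingdom-rank group, with `"Unassigned"` as its own category), fits the
#' organ-enrichment GLM for every group, and returns results sorted by total
#' abundance.  `rank = "phylotype"` skips aggregation.
#'
#' @param tables A [count_table()] or a list of them (one per kingdom).
#' @param meta Metadata tibble (`total_reads` attached internally per table).
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, or `"phylotype"`.
#' @param p_type Passed to [fit_enrichment()].
#' @return Tibble with one row per taxon group, columns `taxon`, `kingdom`,
#'   the [fit_enrichment()] columns, and `total_reads`.
#' @export
enrichment_table <- function(tables, meta, rank = "genus",
                             p_type = c("wald", "lrt")) {
  p_type <- match.arg(p_type)
  if (inherits(tables, "count_table")) tables <- list(tables)
  out <- purrr::map_dfr(tables, function(table) {
    m <- complete_metadata(meta, table)
    if (rank == "phylotype") {
      agg <- list(counts = table$counts, kingdom = table$taxa$kingdom,
                  name = taxon_ids(table))
      colnames(agg$counts) <- paste0(agg$kingdom, ":", agg$name)
    } else {
      agg <- aggregate_rank(table, rank)
    }
    counts <- agg$counts[m$sample_id, , drop = FALSE]
    res <- purrr::map_dfr(seq_len(ncol(counts)), function(j) {
      fit_enrichment(counts[, j], m, p_type = p_type)
    })
    dplyr::bind_cols(
      tibble::tibble(taxon = agg$name, kingdom = agg$kingdom,
                     total_reads = colSums(counts)),
      res
    )
  })
  dplyr::arrange(out, dplyr::desc(.data$total_reads))
}
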