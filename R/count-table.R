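#' Build a two-kingdom amplicon count table
#'
#' The central observation object of the package: a samples-by-taxa matrix of
#' non-negative integer read counts, together with the kingdom
#' (`"bacteria"` or `"fungi"`) and a ranked taxonomic lineage for every taxon.
#' Most analysis functions in the package take a `count_table` plus a sample
#' metadata tibble (see [read_metadata()]) and return tibbles.
#'
#' @param counts Integer matrix, samples in rows, taxa in columns.  Must have
#'   unique row and column names.
#' @param kingdom Character vector with one entry per taxon (recycled if
#'   length 1), each `"bacteria"` or `"fungi"`.
#' @param lineage Optional character vector of semicolon-separated ranked
#'   labels per taxon (`k__...;p__...;c__...;o__...;f__...;g__...` dialect).
#'   `"Unassigned"` is allowed at any rank; missing lineages are stored as
#'   `NA`.
#'
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix) and `taxa` (a tibble with columns `taxon_id`, `kingdom`,
#'   `lineage`).
#' @export
count_table <- function(counts, kingdom, lineage = NULL) {
  counts <- as.matrix(counts)
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "`counts` needs sample row names and taxon column names")
  assert_that(!anyDuplicated(rownames(counts)), "duplicate sample ids")
  assert_that(!anyDuplicated(colnames(counts)), "duplicate taxon ids")
  if (!is.numeric(counts) || any(is.na(counts)) ||
      any(counts < 0) || any(counts != round(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)
    rlang::abort(sprintf(
      "counts must be non-negative integers; first offending cell: sample '%s', taxon '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "integer"
  kingdom <- rep_len(as.character(kingdom), ncol(counts))
  assert_that(all(kingdom %in% c("bacteria", "fungi")),
              "kingdom must be 'bacteria' or 'fungi'")
  lineage <- if (is.null(lineage)) NA_character_ else as.character(lineage)
  taxa <- tibble::tibble(
    taxon_id = colnames(counts),
    kingdom  = kingdom,
    lineage  = rep_len(lineage, ncol(counts))
  )
  structure(list(counts = counts, taxa = taxa), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d samples x %d taxa (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(table(x$taxa$kingdom)),
                            as.integer(table(x$taxa$kingdom))),
                    collapse = ", ")))
  cat(sprintf("  total reads: %d; median sample depth: %s\n",
              sum(x$counts), format(stats::median(rowSums(x$counts)))))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Sample and taxon accessors
#'
#' @param table A [count_table()].
#' @return Character vectors of identifiers, or named numeric vectors of
#'   per-sample / per-taxon read totals.
#' @export
sample_ids <- function(table) rownames(table$counts)

#' @rdname sample_ids
#' @export
taxon_ids <- function(table) colnames(table$counts)

#' @rdname sample_ids
#' @export
sample_depths <- function(table) rowSums(table$counts)

#' @rdname sample_ids
#' @export
taxon_totals <- function(table) colSums(table$counts)

# keep a subset of taxa (columns), preserving taxa metadata
subset_taxa <- function(table, keep) {
  counts <- table$counts[, keep, drop = FALSE]
  structure(list(
    counts = counts,
    taxa = table$taxa[match(colnames(counts), table$taxa$taxon_id), ]
  ), class = "count_table")
}

# keep a subset of samples (rows)
subset_samples <- function(table, keep) {
  structure(list(counts = table$counts[keep, , drop = FALSE], taxa = table$taxa),
            class = "count_table")
}

#' Turn a count table into a long tibble
#'
#' One row per (sample, taxon) pair, suitable for dplyr/ggplot2 work.
#'
#' @param x A [count_table()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `taxon_id`, `kingdom`, `count`.
#' @export
tidy.count_table <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x$counts), times = ncol(x$counts)),
    taxon_id  = rep(colnames(x$counts), each = nrow(x$counts)),
    kingdom   = rep(x$taxa$kingdom, each = nrow(x$counts)),
    count     = as.vector(x$counts)
  )
}

lineage_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Parse semicolon-ranked lineages
#'
#' Splits `k__;p__;c__;o__;f__;g__`-style lineage strings into one column per
#' rank.  Empty or missing fields become `"Unassigned"`.
#'
#' @param lineage Character vector of lineage strings.
#' @return Tibble with columns `kingdom`, `phylum`, `class`, `order`,
#'   `family`, `genus`.
#' @export
parse_lineage <- function(lineage) {
  pieces <- stringr::str_split(lineage %||% NA_character_, ";")
  out <- purrr::map(pieces, function(p) {
    p <- stringr::str_trim(p)
    p <- stringr::str_remove(p, "^[kpcofg]__")
    p <- p[p != "" | seq_along(p) <= 1]
    vals <- rep("Unassigned", length(lineage_ranks))
    n <- min(length(p), length(lineage_ranks))
    if (n > 0) vals[seq_len(n)] <- p[seq_len(n)]
    vals[vals == "" | is.na(vals)] <- "Unassigned"
    vals
  })
  out <- do.call(rbind, out)
  colnames(out) <- lineage_ranks
  tibble::as_tibble(as.data.frame(out, stringsAsFactors = FALSE))
}

#' Taxonomy table of a count table
#'
#' @param table A [count_table()].
#' @return Tibble with `taxon_id`, `kingdom` (stamped, not parsed), and one
#'   column per lineage rank.
#' @export
taxonomy <- function(table) {
  ranks <- parse_lineage(table$taxa$lineage)
  names(ranks) <- paste0("rank_", names(ranks))
  dplyr::bind_cols(table$taxa[, c("taxon_id", "kingdom")], ranks)
}
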