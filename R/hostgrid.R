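#' Nested abundance-ranked subsets of a count table
#'
#' For each fraction `f`, keeps the top `ceiling(f * T)` taxa by total reads
#' (ties broken lexicographically on taxon id), so the subsets are nested:
#' every taxon in the top-1% subset is also in the top-2% subset, and so on.
#'
#' @param table A [count_table()].
#' @param fractions Numeric vector of fractions in `(0, 1]`.
#' @return A named list of [count_table()]s, one per fraction.
#' @export
nested_subsets <- function(table, fractions) {
  assert_that(all(fractions > 0 & fractions <= 1),
              "fractions must lie in (0, 1]")
  totals <- taxon_totals(table)
  ord <- order(-totals, taxon_ids(table))
  out <- purrr::map(fractions, function(f) {
    subset_taxa(table, ord[seq_len(ceiling(f * ncol(table$counts)))])
  })
  names(out) <- paste0("top_", format(100 * fractions, trim = TRUE), "pct")
  out
}

#' Accession clustering statistic on ordination scores
#'
#' How strongly replicates of the same accession cluster in ordination
#' space: `R^2 = 1 - SS_within / SS_total`, with sums of squared Euclidean
#' deviations taken jointly over the score columns, within-accession around
#' accession centroids and in total around the grand centroid.
#'
#' @param scores Samples x PCs numeric matrix.
#' @param labels Accession label per sample (row).
#' @return `R^2` in `[0, 1]`.  All-singleton labels give a degenerate 1 with
#'   a warning.
#' @export
accession_fit_stat <- function(scores, labels) {
  scores <- as.matrix(scores)
  assert_that(nrow(scores) == length(labels),
              "labels must match score rows")
  f <- factor(labels)
  if (all(tabulate(f) <= 1)) {
    rlang::warn("every accession is a singleton; R^2 is degenerately 1")
    return(1)
  }
  sc <- scale(scores, center = TRUE, scale = FALSE)
  ss_tot <- sum(sc^2)
  if (ss_tot < 1e-300) return(0)
  ng <- tabulate(f)
  ss_between <- sum(rowsum(sc, f)^2 / ng)
  ss_between / ss_tot
}

# log1p of counts rescaled to a common depth, then residualized on
# block + run; the covariate-corrected matrix every grid cell draws from
transformed_residuals <- function(table, meta, transform = c("log1p", "raw"),
                                  depth_ref = 400) {
  transform <- match.arg(transform)
  m <- complete_metadata(meta, table)
  x <- table$counts[m$sample_id, , drop = FALSE]
  x <- x * (depth_ref / m$total_reads)
  if (transform == "log1p") x <- log1p(x)
  fixed <- fixed_terms(m)
  if (length(fixed)) {
    mm <- stats::model.matrix(
      stats::as.formula(paste("~", paste(fixed, collapse = " + "))), data = m)
    x <- stats::resid(stats::lm.fit(mm, x))
    rownames(x) <- m$sample_id
  } else {
    x <- scale(x, center = TRUE, scale = FALSE)
  }
  list(x = x, meta = m)
}

# PCA scores of a residualized matrix restricted to given taxa; NULL when
# fewer than 3 informative columns survive
cell_scores <- function(resid_x, taxa, n_pcs) {
  x <- resid_x[, colnames(resid_x) %in% taxa, drop = FALSE]
  v <- apply(x, 2, stats::var)
  x <- x[, v > 1e-12, drop = FALSE]
  if (ncol(x) < 3) return(NULL)
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  fit$x[, seq_len(min(n_pcs, ncol(fit$x))), drop = FALSE]
}

# permutation p for the accession fit statistic; labels are shuffled within
# strata (blocks) so the design balance of replicates over blocks -- and the
# correlation structure block-residualization leaves behind -- is preserved
# under the null
perm_p <- function(scores, labels, n_perm, seed, strata = NULL) {
  r2 <- accession_fit_stat(scores, labels)
  set.seed(seed)
  f <- factor(labels)
  sc <- scale(scores, center = TRUE, scale = FALSE)
  ss_tot <- sum(sc^2)
  idx_sets <- if (is.null(strata)) {
    list(seq_along(f))
  } else {
    split(seq_along(f), strata)
  }
  r2_perm <- replicate(n_perm, {
    ix <- seq_along(f)
    for (set in idx_sets) ix[set] <- set[sample.int(length(set))]
    fp <- f[ix]
    sum(rowsum(sc, fp)^2 / tabulate(fp)) / ss_tot
  })
  list(r2 = r2, p = (sum(r2_perm >= r2) + 1) / (n_perm + 1))
}

#' Host-genotype clustering over nested subsets of both kingdoms
#'
#' The accession-clustering permutation grid: for every pair of
#' (bacterial fraction, fungal fraction) the two nested subsets are
#' column-concatenated, depth-normalized (`log1p` of counts scaled to a
#' common depth by default), residualized on block and run, ordinated by
#' PCA with unit-variance scaling, and the accession fit statistic
#' ([accession_fit_stat()]) on the first `n_pcs` scores is compared with
#' `n_perm` label permutations.  Margins hold the single-kingdom analyses.
#' p-values use the `(r + 1) / (n + 1)` convention, so 999 permutations
#' floor at 0.001.
#'
#' @param bact,fung [count_table()]s over shared samples.
#' @param meta Metadata tibble.
#' @param fractions Subset fractions (default 1, 2, 3, 4, 5, 10, 25, 50,
#'   100%).
#' @param n_pcs Number of leading PCs for the statistic (default 3).
#' @param n_perm Number of permutations (default 999).
#' @param transform `"log1p"` (default) or `"raw"` pre-PCA abundance scale.
#' @param depth_ref Common depth the counts are rescaled to (default 400).
#' @param seed Integer seed.
#' @return An object of class `host_grid`: `grid` (tibble `frac_bacteria`,
#'   `frac_fungi`, `r2`, `p_value`), `margins` (tibble `kingdom`,
#'   `fraction`, `r2`, `p_value`), plus `n_pcs`, `n_perm`, `seed`.
#'   Cells with fewer than 3 informative taxa are `NA`.
#' @export
grid_scan <- function(bact, fung, meta,
                      fractions = c(0.01, 0.02, 0.03, 0.04, 0.05,
                                    0.10, 0.25, 0.50, 1.00),
                      n_pcs = 3, n_perm = 999,
                      transform = c("log1p", "raw"),
                      depth_ref = 400, seed = 1L) {
  transform <- match.arg(transform)
  rb <- transformed_residuals(bact, meta, transform, depth_ref)
  rf <- transformed_residuals(fung, meta, transform, depth_ref)
  sub_b <- nested_subsets(bact, fractions)
  sub_f <- nested_subsets(fung, fractions)

  margin_one <- function(res, subs, kingdom) {
    purrr::map_dfr(seq_along(fractions), function(i) {
      sc <- cell_scores(res$x, taxon_ids(subs[[i]]), n_pcs)
      if (is.null(sc)) {
        return(tibble::tibble(kingdom = kingdom, fraction = fractions[i],
                              r2 = NA_real_, p_value = NA_real_))
      }
      ix <- match(rownames(sc), res$meta$sample_id)
      pp <- perm_p(sc, res$meta$accession_id[ix], n_perm,
                   derive_seed(seed, i + ifelse(kingdom == "fungi", 100L, 0L)),
                   strata = res$meta$block[ix])
      tibble::tibble(kingdom = kingdom, fraction = fractions[i],
                     r2 = pp$r2, p_value = pp$p)
    })
  }
  margins <- dplyr::bind_rows(margin_one(rb, sub_b, "bacteria"),
                              margin_one(rf, sub_f, "fungi"))

  shared <- intersect(rownames(rb$x), rownames(rf$x))
  assert_that(length(shared) >= 4,
              "combined cells need shared samples across kingdoms")
  xb <- rb$x[shared, , drop = FALSE]
  xf <- rf$x[shared, , drop = FALSE]
  labels <- rb$meta$accession_id[match(shared, rb$meta$sample_id)]
  strata <- rb$meta$block[match(shared, rb$meta$sample_id)]
  grid <- purrr::map_dfr(seq_along(fractions), function(i) {
    purrr::map_dfr(seq_along(fractions), function(j) {
      xx <- cbind(
        xb[, colnames(xb) %in% taxon_ids(sub_b[[i]]), drop = FALSE],
        xf[, colnames(xf) %in% taxon_ids(sub_f[[j]]), drop = FALSE])
      sc <- cell_scores(xx, colnames(xx), n_pcs)
      if (is.null(sc)) {
        return(tibble::tibble(frac_bacteria = fractions[i],
                              frac_fungi = fractions[j],
                              r2 = NA_real_, p_value = NA_real_))
      }
      pp <- perm_p(sc, labels, n_perm, derive_seed(seed, 1000L + 50L * i + j),
                   strata = strata)
      tibble::tibble(frac_bacteria = fractions[i], frac_fungi = fractions[j],
                     r2 = pp$r2, p_value = pp$p)
    })
  })
  structure(list(grid = grid, margins = margins, fractions = fractions,
                 n_pcs = n_pcs, n_perm = n_perm, transform = transform,
                 seed = seed),
            class = "host_grid")
}

#' @export
print.host_grid <- function(x, ...) {
  cat(sprintf("<host_grid> %d x %d cells, %d PCs, %d permutations\n",
              length(x$fractions), length(x$fractions), x$n_pcs, x$n_perm))
  cat(sprintf("  cells with P <= 0.05: %d of %d\n",
              sum(x$grid$p_value <= 0.05, na.rm = TRUE),
              sum(!is.na(x$grid$p_value))))
  invisible(x)
}

#' @export
tidy.host_grid <- function(x, ...) x$grid

#' @export
glance.host_grid <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$grid),
    n_significant = sum(x$grid$p_value <= 0.05, na.rm = TRUE),
    min_p = min(x$grid$p_value, na.rm = TRUE),
    n_pcs = x$n_pcs, n_perm = x$n_perm
  )
}
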