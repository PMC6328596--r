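#' Accession BLUPs of taxon abundances
#'
#' For each of the `top_n` best-sequenced taxa, fits a Poisson GLMM of read
#' counts on block and sequencing run with a `log(total_reads)` offset and a
#' random accession intercept, and extracts the accession conditional modes
#' (BLUPs).  The resulting accessions x taxa matrix is the substrate for the
#' community-structure PCA and the host-genetics analyses.
#'
#' Taxa whose model fails to converge are flagged and their column imputed
#' as zeros; [pca()] drops flagged columns when more than 1% of fits failed.
#'
#' @param table A [count_table()].
#' @param meta Metadata tibble.
#' @param top_n Number of best-sequenced taxa to model (default 100).
#' @return An object of class `blup_matrix`: list with `blups` (accessions x
#'   taxa matrix), `taxa` (tibble `taxon_id`, `kingdom`, `sigma2_accession`,
#'   `converged`).
#' @export
abundance_blups <- function(table, meta, top_n = 100) {
  table <- top_taxa(table, min(top_n, ncol(table$counts)))
  m <- complete_metadata(meta, table)
  counts <- table$counts[m$sample_id, , drop = FALSE]
  fixed <- fixed_terms(m)
  rhs <- paste(c(if (length(fixed)) fixed else "1",
                 "offset(log(total_reads))", "(1 | accession_id)"),
               collapse = " + ")
  accessions <- sort(unique(m$accession_id))
  cols <- purrr::map(seq_len(ncol(counts)), function(j) {
    dat <- m
    dat$count <- counts[, j]
    fit <- tryCatch(
      suppressMessages(lme4::glmer(
        stats::as.formula(paste("count ~", rhs)),
        data = dat, family = stats::poisson())),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(list(blup = setNames(rep(0, length(accessions)), accessions),
                  sigma2 = NA_real_, converged = FALSE))
    }
    re <- lme4::ranef(fit)$accession_id
    blup <- setNames(rep(0, length(accessions)), accessions)
    blup[rownames(re)] <- re[, 1]
    vc <- as.data.frame(lme4::VarCorr(fit))
    list(blup = blup, sigma2 = vc$vcov[1], converged = TRUE)
  })
  blups <- sapply(cols, `[[`, "blup")
  colnames(blups) <- taxon_ids(table)
  failed <- !sapply(cols, `[[`, "converged")
  if (any(failed)) {
    rlang::warn(sprintf("%d of %d taxon GLMMs failed to converge; columns zero-imputed",
                        sum(failed), length(failed)))
  }
  structure(list(
    blups = blups,
    taxa = dplyr::bind_cols(table$taxa[, c("taxon_id", "kingdom")],
                            tibble::tibble(
                              sigma2_accession = sapply(cols, `[[`, "sigma2"),
                              converged = !failed))
  ), class = "blup_matrix")
}

#' @export
print.blup_matrix <- function(x, ...) {
  cat(sprintf("<blup_matrix> %d accessions x %d taxa (%d converged)\n",
              nrow(x$blups), ncol(x$blups), sum(x$taxa$converged)))
  invisible(x)
}

#' Combine BLUP matrices from two kingdoms
#'
#' Column-concatenates the accession-by-taxon BLUP matrices of the bacterial
#' and fungal communities into one combined microbiome, keeping kingdom
#' labels on the columns.  Accession sets must match.
#'
#' @param b1,b2 `blup_matrix` objects over the same accessions.
#' @return A combined `blup_matrix`.
#' @export
combine_kingdoms <- function(b1, b2) {
  if (ncol(b2$blups) == 0) return(b1)
  if (ncol(b1$blups) == 0) return(b2)
  diff <- c(setdiff(rownames(b1$blups), rownames(b2$blups)),
            setdiff(rownames(b2$blups), rownames(b1$blups)))
  assert_that(length(diff) == 0,
              paste("accession sets differ:", paste(diff, collapse = ", ")))
  b2m <- b2$blups[rownames(b1$blups), , drop = FALSE]
  structure(list(
    blups = cbind(b1$blups, b2m),
    taxa = dplyr::bind_rows(b1$taxa, b2$taxa)
  ), class = "blup_matrix")
}

#' Principal component analysis of a BLUP matrix
#'
#' Centered (and by default unit-variance-scaled) PCA.  Zero-variance
#' columns are dropped with a warning before scaling; if more than 1% of the
#' taxon GLMMs behind a `blup_matrix` failed to converge their columns are
#' excluded rather than analyzed as imputed zeros.  PC signs are fixed by
#' making each loading column's largest-magnitude entry positive.
#'
#' @param x A `blup_matrix` or a plain numeric matrix (rows = accessions).
#' @param scale Scale columns to unit variance (default `TRUE`).
#' @return An object of class `pca_result`: `scores` (rows x PCs),
#'   `loadings` (columns orthonormal), `explained_fraction`, and `taxa`
#'   (tibble for the retained columns, when available).
#' @export
pca <- function(x, scale = TRUE) {
  taxa <- NULL
  if (inherits(x, "blup_matrix")) {
    keep <- x$taxa$converged
    if (mean(!keep) > 0.01) {
      rlang::warn(sprintf("excluding %d non-converged taxon columns from PCA",
                          sum(!keep)))
      taxa <- x$taxa[keep, ]
      x <- x$blups[, keep, drop = FALSE]
    } else {
      taxa <- x$taxa
      x <- x$blups
    }
  }
  x <- as.matrix(x)
  assert_that(nrow(x) >= 2 && ncol(x) >= 2, "need at least a 2 x 2 matrix")
  v <- apply(x, 2, stats::var)
  if (any(v < 1e-12)) {
    rlang::warn(sprintf("dropping %d zero-variance columns", sum(v < 1e-12)))
    if (!is.null(taxa)) taxa <- taxa[v >= 1e-12, ]
    x <- x[, v >= 1e-12, drop = FALSE]
  }
  assert_that(ncol(x) >= 2, "fewer than 2 informative columns remain")
  fit <- stats::prcomp(x, center = TRUE, scale. = scale)
  flip <- apply(fit$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  scores <- sweep(fit$x, 2, flip, `*`)
  loadings <- sweep(fit$rotation, 2, flip, `*`)
  structure(list(
    scores = scores,
    loadings = loadings,
    explained_fraction = fit$sdev^2 / sum(fit$sdev^2),
    taxa = taxa
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d rows, %d PCs; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$explained_fraction[1], 100 * x$explained_fraction[2]))
  invisible(x)
}

#' @export
tidy.pca_result <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                            ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble::tibble(pc = seq_along(x$explained_fraction),
                          explained_fraction = x$explained_fraction))
  }
  m <- x[[matrix]]
  out <- tibble::as_tibble(m)
  id <- if (matrix == "scores") "accession_id" else "taxon_id"
  dplyr::bind_cols(tibble::tibble(!!id := rownames(m)), out)
}

#' Correlation between PCs of two ordinations
#'
#' Pearson correlation of score columns, reported as `|r|` (PC signs are
#' arbitrary) with the realized sign noted.
#'
#' @param p1,p2 `pca_result` objects over the same rows, in the same order.
#' @param i,j PC indices in `p1` and `p2`.
#' @return Tibble `pc_1`, `pc_2`, `r_abs`, `sign`.
#' @export
pc_correlation <- function(p1, p2, i = 1, j = 1) {
  assert_that(nrow(p1$scores) == nrow(p2$scores),
              "score matrices differ in length")
  r <- stats::cor(p1$scores[, i], p2$scores[, j])
  tibble::tibble(pc_1 = i, pc_2 = j, r_abs = abs(r),
                 sign = ifelse(r >= 0, 1, -1))
}

# symmetric Procrustes statistic between two centered, unit-norm
# configurations: r = sqrt(1 - m2), m2 = 1 - (sum of singular values)^2
procrustes_r <- function(X, Y) {
  X <- scale(X, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  X <- X / sqrt(sum(X^2))
  Y <- Y / sqrt(sum(Y^2))
  d <- svd(crossprod(X, Y))$d
  ss <- sum(d)^2
  sqrt(max(0, min(1, ss)))
}

#' Procrustes comparison of two ordinations
#'
#' Symmetric Procrustes analysis of the first `n_pcs` score columns: both
#' configurations are centered and scaled to unit sum of squares, the
#' optimal rotation is taken from the SVD of their cross-product, and the
#' correspondence is `r = sqrt(1 - m2)` with `m2` the residual sum of
#' squares.  Significance is assessed by permuting the rows (accessions) of
#' one configuration; `p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)`, so the
#' smallest attainable p with 999 permutations is 0.001.
#'
#' @param p1,p2 `pca_result` objects (or score matrices) over the same
#'   accessions in the same order.
#' @param n_pcs Number of leading PCs to compare (>= 2, default 3).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return An object of class `procrustes_result` with `r`, `m2`,
#'   `p_value`, `n_pcs`, `n_perm`, `seed`.
#' @export
procrustes_test <- function(p1, p2, n_pcs = 3, n_perm = 999, seed = 1L) {
  assert_that(n_pcs >= 2, "n_pcs must be >= 2")
  X <- if (inherits(p1, "pca_result")) p1$scores else as.matrix(p1)
  Y <- if (inherits(p2, "pca_result")) p2$scores else as.matrix(p2)
  assert_that(n_pcs <= ncol(X) && n_pcs <= ncol(Y),
              "n_pcs exceeds available PCs")
  assert_that(nrow(X) == nrow(Y), "configurations differ in rows")
  X <- X[, seq_len(n_pcs), drop = FALSE]
  Y <- Y[, seq_len(n_pcs), drop = FALSE]
  r_obs <- procrustes_r(X, Y)
  set.seed(seed)
  r_perm <- replicate(n_perm, procrustes_r(X, Y[sample.int(nrow(Y)), ,
                                                drop = FALSE]))
  p <- (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  structure(list(r = r_obs, m2 = 1 - r_obs^2, p_value = p, n_pcs = n_pcs,
                 n_perm = n_perm, seed = seed),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("<procrustes_result> r = %.3f, P = %.4g (PCs 1-%d, %d permutations)\n",
              x$r, x$p_value, x$n_pcs, x$n_perm))
  invisible(x)
}

#' @export
glance.procrustes_result <- function(x, ...) {
  tibble::tibble(r = x$r, m2 = x$m2, p_value = x$p_value, n_pcs = x$n_pcs,
                 n_perm = x$n_perm)
}
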