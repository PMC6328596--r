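#' Resample a count table to a fixed depth
#'
#' Each sample with at least `depth` total reads is resampled once, without
#' replacement, from its realized read pool (the raw frequency distribution
#' observed in the sample), so retained rows sum exactly to `depth`.
#' Shallower samples are excluded and listed in the `excluded` attribute.
#' Used for visualization-style depth correction and for the correlation
#' networks; the statistical models correct for depth with offsets instead.
#'
#' @param table A [count_table()].
#' @param depth Target reads per sample (default 400).
#' @param seed Integer seed for the resampling draws.
#' @return A [count_table()] of the retained samples, rows summing to
#'   `depth`, with attributes `depth`, `seed`, and `excluded` (character
#'   vector of dropped sample ids).
#' @export
rarefy <- function(table, depth = 400, seed = 1L) {
  assert_that(is.numeric(depth) && depth >= 1, "`depth` must be >= 1")
  totals <- sample_depths(table)
  keep <- totals >= depth
  excluded <- names(totals)[!keep]
  if (length(excluded)) {
    rlang::inform(sprintf("rarefy: excluding %d samples with < %d reads",
                          length(excluded), depth))
  }
  sub <- table$counts[keep, , drop = FALSE]
  set.seed(seed)
  # vegan warns whenever the smallest nonzero count exceeds 1, which is
  # routine for QC-filtered tables (singletons removed); muffle just that
  res <- withCallingHandlers(
    vegan::rrarefy(sub, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  storage.mode(res) <- "integer"
  out <- structure(list(counts = res,
                        taxa = table$taxa), class = "count_table")
  attr(out, "depth") <- as.integer(depth)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "excluded") <- excluded
  out
}

#' Taxon richness of count vectors
#'
#' Number of taxa observed (count > 0).  Given a matrix, returns one value
#' per row (sample).
#'
#' @param x Numeric vector of counts, or a samples x taxa matrix, or a
#'   [count_table()].
#' @return Integer vector of richness values.
#' @export
richness <- function(x) {
  if (inherits(x, "count_table")) x <- x$counts
  if (is.matrix(x)) return(as.integer(rowSums(x > 0)))
  as.integer(sum(x > 0))
}

#' Whittaker's beta diversity for a pair of samples
#'
#' Species turnover `beta = S / alpha_bar - 1`, where `S` is the richness of
#' the union of the two samples and `alpha_bar` their mean richness.
#' Identical presence sets give 0; disjoint non-empty sets give 1.
#'
#' @param x,y Count or presence vectors over the same taxa.
#' @return A number in `[0, 1]`; `NA` with a warning if both samples are
#'   empty.
#' @export
whittaker_beta <- function(x, y) {
  assert_that(length(x) == length(y), "samples must cover the same taxa")
  px <- x > 0
  py <- y > 0
  abar <- (sum(px) + sum(py)) / 2
  if (abar == 0) {
    rlang::warn("both samples empty; beta undefined")
    return(NA_real_)
  }
  sum(px | py) / abar - 1
}

#' Pairwise beta diversity within groups
#'
#' Computes Whittaker's beta for every unordered pair of samples, within each
#' level of a grouping column of the metadata (typically `organ`), on a
#' rarefied table.
#'
#' @param table A (typically rarefied) [count_table()].
#' @param meta Metadata tibble.
#' @param group Name of the metadata column defining groups (default
#'   `"organ"`).
#' @return Tibble with columns `group`, `sample_i`, `sample_j`, `beta`.
#' @export
beta_pairs <- function(table, meta, group = "organ") {
  meta <- dplyr::filter(meta, .data$sample_id %in% sample_ids(table))
  out <- purrr::map_dfr(split(meta$sample_id, meta[[group]]), function(ids) {
    if (length(ids) < 2) return(NULL)
    pairs <- utils::combn(ids, 2)
    tibble::tibble(
      sample_i = pairs[1, ],
      sample_j = pairs[2, ],
      beta = purrr::map2_dbl(pairs[1, ], pairs[2, ], function(a, b) {
        whittaker_beta(table$counts[a, ], table$counts[b, ])
      })
    )
  }, .id = "group")
  tibble::as_tibble(out)
}

#' Paired leaf-root beta diversity per host plant
#'
#' For every plant with both a leaf and a root sample retained in the table,
#' the turnover between its two organ communities.
#'
#' @param table A (typically rarefied) [count_table()].
#' @param meta Metadata with a `plant_id` column linking organ samples from
#'   the same plant.
#' @return Tibble with `plant_id`, `accession_id`, `beta`.
#' @export
beta_paired <- function(table, meta) {
  assert_that("plant_id" %in% names(meta),
              "paired beta needs a `plant_id` metadata column")
  meta <- dplyr::filter(meta, .data$sample_id %in% sample_ids(table))
  wide <- tidyr::pivot_wider(meta[, c("plant_id", "accession_id", "organ", "sample_id")],
                             names_from = "organ", values_from = "sample_id")
  wide <- dplyr::filter(wide, !is.na(.data$leaf), !is.na(.data$root))
  wide$beta <- purrr::map2_dbl(wide$leaf, wide$root, function(a, b) {
    whittaker_beta(table$counts[a, ], table$counts[b, ])
  })
  wide[, c("plant_id", "accession_id", "beta")]
}

# build the fixed-effect part of a richness / abundance model, dropping
# factors with a single level so small toy designs still fit
fixed_terms <- function(meta, extra = character()) {
  terms <- character()
  for (v in c("block", "run")) {
    if (length(unique(meta[[v]])) > 1) terms <- c(terms, v)
  }
  c(extra, terms)
}

#' Fit the richness GLMM and extract accession BLUPs
#'
#' Poisson log-link mixed model of per-sample richness with block and
#' sequencing-run fixed effects, `log(total_reads)` as offset, and a random
#' accession intercept (Laplace approximation, via [lme4::glmer()]).  With
#' `scope = "combined"` the bacterial and fungal tables are stacked, kingdom
#' enters as a fixed effect, and the run term is nested within kingdom.
#' Accession BLUPs are the conditional modes of the random effects.
#'
#' @param table A [count_table()], or for `scope = "combined"` a named list
#'   `list(bacteria = , fungi = )`.
#' @param meta Metadata tibble (depths are attached per table).
#' @param scope `"kingdom"` (single table) or `"combined"`.
#' @return An object of class `richness_blups` with elements `blups`
#'   (tibble `accession_id`, `blup`), `sigma2_accession`, `fixef`, `scope`,
#'   and the fitted `model`.  Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_richness_glmm <- function(table, meta, scope = c("kingdom", "combined")) {
  scope <- match.arg(scope)
  if (scope == "combined") {
    assert_that(is.list(table) && !inherits(table, "count_table") &&
                  all(c("bacteria", "fungi") %in% names(table)),
                "combined scope needs list(bacteria = , fungi = )")
    dat <- purrr::map_dfr(c("bacteria", "fungi"), function(k) {
      m <- complete_metadata(meta, table[[k]])
      m$richness <- richness(table[[k]])[match(m$sample_id, sample_ids(table[[k]]))]
      m$kingdom <- k
      m
    })
    fixed <- fixed_terms(dat, extra = "kingdom")
    # run nested in kingdom: each kingdom is sequenced on its own runs
    fixed <- setdiff(fixed, "run")
    if (length(unique(dat$run)) > 1) fixed <- c(fixed, "kingdom:run")
  } else {
    dat <- complete_metadata(meta, table)
    dat$richness <- richness(table)[match(dat$sample_id, sample_ids(table))]
    fixed <- fixed_terms(dat)
  }
  rhs <- paste(c(if (length(fixed)) fixed else "1",
                 "offset(log(total_reads))", "(1 | accession_id)"),
               collapse = " + ")
  form <- stats::as.formula(paste("richness ~", rhs))
  model <- lme4::glmer(form, data = dat, family = stats::poisson())
  re <- lme4::ranef(model)$accession_id
  vc <- as.data.frame(lme4::VarCorr(model))
  new_richness_blups(
    blups = tibble::tibble(accession_id = rownames(re), blup = re[, 1]),
    sigma2_accession = vc$vcov[vc$grp == "accession_id"][1],
    fixef = lme4::fixef(model),
    scope = scope,
    model = model,
    data = dat
  )
}

new_richness_blups <- function(blups, sigma2_accession, fixef, scope, model,
                               data) {
  structure(list(blups = blups, sigma2_accession = sigma2_accession,
                 fixef = fixef, scope = scope, model = model, data = data),
            class = "richness_blups")
}

#' @export
print.richness_blups <- function(x, ...) {
  cat(sprintf("<richness_blups> scope=%s, %d accessions, sigma2_accession=%.4g\n",
              x$scope, nrow(x$blups), x$sigma2_accession))
  invisible(x)
}

#' @export
tidy.richness_blups <- function(x, ...) x$blups

#' @export
glance.richness_blups <- function(x, ...) {
  tibble::tibble(
    sigma2_accession = x$sigma2_accession,
    n_accessions = nrow(x$blups),
    n_samples = nrow(x$data),
    scope = x$scope,
    logLik = as.numeric(stats::logLik(x$model))
  )
}

#' Kingdom preference of each accession
#'
#' The per-accession difference between bacterial and fungal richness BLUPs:
#' positive values mark hosts whose microbiome is more diverse in bacteria
#' than fungi relative to the population average.
#'
#' @param bact,fung `richness_blups` objects for the two kingdoms.
#' @return Tibble with `accession_id`, `preference` (bacterial minus fungal
#'   BLUP).  Accessions present in only one kingdom are dropped with a
#'   message.
#' @export
kingdom_preference <- function(bact, fung) {
  joined <- dplyr::inner_join(tidy(bact), tidy(fung),
                              by = "accession_id", suffix = c("_b", "_f"))
  dropped <- dplyr::union(setdiff(bact$blups$accession_id, joined$accession_id),
                          setdiff(fung$blups$accession_id, joined$accession_id))
  if (length(dropped)) {
    rlang::inform(sprintf("kingdom_preference: %d accessions missing in one kingdom",
                          length(dropped)))
  }
  tibble::tibble(accession_id = joined$accession_id,
                 preference = joined$blup_b - joined$blup_f)
}
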