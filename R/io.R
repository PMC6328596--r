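#' Read and write amplicon count tables
#'
#' Count tables are stored as TSV with taxa in rows and samples in columns:
#' first column `taxon_id`, an optional `lineage` column with
#' semicolon-ranked labels, and one integer column per sample.  Taxa are
#' transposed into columns on read, matching the samples-by-taxa orientation
#' used throughout the package.
#'
#' @param path File path.
#' @param kingdom Kingdom label stamped on every taxon in the file
#'   (`"bacteria"` or `"fungi"`).
#' @return [read_count_table()] returns a [count_table()];
#'   [write_count_table()] returns `path` invisibly.
#' @export
read_count_table <- function(path, kingdom) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    taxon_id = readr::col_character(),
    .default = readr::col_guess()))
  assert_that("taxon_id" %in% names(raw), "count table needs a 'taxon_id' column")
  assert_that(!anyDuplicated(raw$taxon_id),
              sprintf("duplicate taxon ids in '%s'", path))
  lineage <- if ("lineage" %in% names(raw)) raw$lineage else NULL
  num <- raw[, setdiff(names(raw), c("taxon_id", "lineage")), drop = FALSE]
  for (j in names(num)) {
    v <- num[[j]]
    bad <- which(!is.numeric(v) | is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      rlang::abort(sprintf(
        "non-integer or negative count at taxon '%s', sample column '%s'",
        raw$taxon_id[bad[1]], j))
    }
  }
  counts <- t(as.matrix(num))
  colnames(counts) <- raw$taxon_id
  count_table(counts, kingdom = kingdom, lineage = lineage)
}

#' @rdname read_count_table
#' @param table A [count_table()] to serialize.
#' @export
write_count_table <- function(table, path) {
  out <- tibble::as_tibble(t(table$counts))
  out <- dplyr::bind_cols(
    tibble::tibble(taxon_id = taxon_ids(table)),
    if (!all(is.na(table$taxa$lineage))) {
      tibble::tibble(lineage = table$taxa$lineage)
    },
    out
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read and write sample metadata
#'
#' Metadata is a TSV with header `sample_id`, `accession_id`, `organ`,
#' `block`, `run`.  `organ` must be `leaf` or `root`; the per-sample
#' sequencing depth (`total_reads`) used as the model offset is taken from
#' the matching count table via [complete_metadata()], never trusted from
#' disk.
#'
#' @param path File path.
#' @return A tibble, one row per sample.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  needed <- c("sample_id", "accession_id", "organ", "block", "run")
  missing <- setdiff(needed, names(meta))
  assert_that(length(missing) == 0,
              paste("metadata missing columns:", paste(missing, collapse = ", ")))
  validate_metadata(meta[needed])
}

#' @rdname read_metadata
#' @param meta Metadata tibble.
#' @export
write_metadata <- function(meta, path) {
  readr::write_tsv(meta[, c("sample_id", "accession_id", "organ", "block", "run")], path)
  invisible(path)
}

validate_metadata <- function(meta) {
  assert_that(!anyDuplicated(meta$sample_id), "duplicate sample ids in metadata")
  assert_that(all(meta$organ %in% c("leaf", "root")),
              "organ must be 'leaf' or 'root'")
  assert_that(!any(is.na(meta$block)) && !any(is.na(meta$run)),
              "block and run must be non-missing")
  tibble::as_tibble(meta)
}

#' Attach sequencing depths to metadata
#'
#' Joins per-sample read totals from a count table onto the metadata as the
#' `total_reads` column, the log of which is the offset in every count model.
#'
#' @param meta Metadata tibble (see [read_metadata()]).
#' @param table A [count_table()] holding the matched samples.
#' @return `meta` restricted to samples present in `table`, with
#'   `total_reads` added.
#' @export
complete_metadata <- function(meta, table) {
  depths <- tibble::tibble(sample_id = sample_ids(table),
                           total_reads = as.integer(sample_depths(table)))
  out <- dplyr::inner_join(meta, depths, by = "sample_id")
  if (nrow(out) < nrow(meta)) {
    rlang::inform(sprintf("%d metadata rows without counts dropped",
                          nrow(meta) - nrow(out)))
  }
  out
}

#' Read accession genotypes
#'
#' Accepts either a TSV dosage matrix (first column `accession_id`, one
#' column per SNP named `chrom_pos`) or a VCF with biallelic SNPs.  Lines are
#' assumed inbred, so dosages are haploid 0/1; VCF heterozygotes are set to
#' missing by default (`het = "missing"`) or rejected (`het = "error"`).
#' SNPs with missingness above `max_missing` are dropped; remaining missing
#' dosages are mean-imputed per SNP.
#'
#' @param path File path (`.vcf`/`.vcf.gz` or TSV).
#' @param het How to treat heterozygous VCF calls: `"missing"` or `"error"`.
#' @param max_missing Drop SNPs missing in more than this fraction of
#'   accessions (default 0.2).
#' @return A `genotype_matrix`: list with `dosages` (accessions x SNPs, in
#'   0/1 after imputation values may be fractional), `snps` (tibble
#'   `snp_id`, `chrom`, `pos`, `ref`, `alt`), and `maf` (per-SNP minor
#'   allele frequency).
#' @export
read_genotypes <- function(path, het = c("missing", "error"), max_missing = 0.2) {
  het <- match.arg(het)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    dos <- read_vcf_dosages(path, het = het)
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(
      accession_id = readr::col_character(), .default = readr::col_double()))
    assert_that("accession_id" %in% names(raw),
                "dosage TSV needs an 'accession_id' column")
    dos <- as.matrix(raw[, -1, drop = FALSE])
    rownames(dos) <- raw$accession_id
  }
  genotype_matrix(dos, max_missing = max_missing)
}

read_vcf_dosages <- function(path, het) {
  assert_that(requireNamespace("vcfR", quietly = TRUE),
              "reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  # biallelic haploid coding: 0 ref, 1 alt
  code <- function(g) {
    g <- sub("\\|", "/", g)
    out <- rep(NA_real_, length(g))
    out[g %in% c("0", "0/0")] <- 0
    out[g %in% c("1", "1/1")] <- 1
    het_idx <- g %in% c("0/1", "1/0")
    if (any(het_idx) && het == "error") {
      rlang::abort("heterozygous call in haploid mode (het = 'error')")
    }
    out
  }
  dos <- matrix(code(as.vector(gt)), nrow = nrow(gt), ncol = ncol(gt))
  dos <- t(dos)  # accessions x SNPs
  rownames(dos) <- colnames(gt)
  colnames(dos) <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  multi <- grepl(",", fix[, "ALT"])
  assert_that(!any(multi), "multiallelic VCF records are not supported")
  attr(dos, "fix") <- fix
  dos
}

genotype_matrix <- function(dosages, max_missing = 0.2) {
  assert_that(!is.null(rownames(dosages)) && !is.null(colnames(dosages)),
              "dosages need accession row names and SNP column names")
  miss <- colMeans(is.na(dosages))
  if (any(miss > max_missing)) {
    rlang::inform(sprintf("dropping %d SNPs with missingness > %.2f",
                          sum(miss > max_missing), max_missing))
    dosages <- dosages[, miss <= max_missing, drop = FALSE]
  }
  # per-SNP mean imputation of residual missingness
  if (anyNA(dosages)) {
    mu <- colMeans(dosages, na.rm = TRUE)
    idx <- which(is.na(dosages), arr.ind = TRUE)
    dosages[idx] <- mu[idx[, 2]]
  }
  ids <- colnames(dosages)
  if (length(ids) == 0) {
    return(structure(list(dosages = dosages,
                          snps = tibble::tibble(snp_id = character(),
                                                chrom = character(),
                                                pos = numeric()),
                          maf = numeric()),
                     class = "genotype_matrix"))
  }
  parts <- stringr::str_match(ids, "^(.*)_([0-9]+)$")
  snps <- tibble::tibble(
    snp_id = ids,
    chrom  = ifelse(is.na(parts[, 2]), "0", parts[, 2]),
    pos    = ifelse(is.na(parts[, 3]), seq_along(ids), as.numeric(parts[, 3]))
  )
  snps <- dplyr::arrange(dplyr::group_by(snps, .data$chrom), .data$pos)
  snps <- dplyr::ungroup(snps)
  dosages <- dosages[, snps$snp_id, drop = FALSE]
  p <- colMeans(dosages)
  structure(list(
    dosages = dosages,
    snps    = snps,
    maf     = pmin(p, 1 - p)
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d accessions x %d SNPs; median MAF %.3f\n",
              nrow(x$dosages), ncol(x$dosages), stats::median(x$maf)))
  invisible(x)
}

#' @rdname read_genotypes
#' @param g A `genotype_matrix`.
#' @export
write_genotypes <- function(g, path) {
  out <- dplyr::bind_cols(tibble::tibble(accession_id = rownames(g$dosages)),
                          tibble::as_tibble(g$dosages))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a gene annotation and a gene-to-GO map
#'
#' [read_gene_annotation()] parses gene features from a GFF3 file (1-based
#' inclusive coordinates); [read_go_map()] reads a two-column TSV
#' (`gene_id`, `go_id`).
#'
#' @param path File path.
#' @param feature GFF3 feature type to keep (default `"gene"`).
#' @return Tibbles: genes with `gene_id`, `chrom`, `start`, `end`; GO map
#'   with `gene_id`, `go_id`.
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  cols <- c("chrom", "source", "type", "start", "end",
            "score", "strand", "phase", "attributes")
  gff <- readr::read_tsv(path, comment = "#", col_names = cols,
                         col_types = "ccciicccc")
  gff <- dplyr::filter(gff, .data$type == feature)
  id <- stringr::str_match(gff$attributes, "ID=([^;]+)")[, 2]
  id <- ifelse(is.na(id), stringr::str_match(gff$attributes, "Name=([^;]+)")[, 2], id)
  tibble::tibble(gene_id = id, chrom = gff$chrom,
                 start = gff$start, end = gff$end)
}

#' @rdname read_gene_annotation
#' @export
read_go_map <- function(path) {
  out <- readr::read_tsv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         col_names = c("gene_id", "go_id"))
  dplyr::filter(out, .data$gene_id != "gene_id")  # tolerate a header line
}
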