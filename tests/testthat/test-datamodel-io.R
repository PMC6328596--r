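test_that("count tables round-trip through TSV bit-identically", {
  tab <- toy_table()
  expect_equal(unname(sample_depths(tab)), c(10, 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  back <- read_count_table(path, kingdom = "bacteria")
  expect_identical(back$counts, tab$counts)
  expect_identical(back$taxa, tab$taxa)

  # a second round trip is also identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed count files are rejected with the offending cell named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "t1\t5\t2", "t2\t-1\t0"), path)
  expect_error(read_count_table(path, "fungi"), "t2.*s1")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1", "t1\t5", "t1\t2"), dup)
  expect_error(read_count_table(dup, "fungi"), "duplicate")

  expect_error(
    count_table(matrix(c(0.5, 1, 2, 3), 2,
                       dimnames = list(c("a", "b"), c("x", "y"))), "fungi"),
    "sample 'a', taxon 'x'")
})

test_that("metadata reads, validates, and gains depths from the count table", {
  tab <- toy_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  meta <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                         accession_id = c("a1", "a1", "a2"),
                         organ = c("leaf", "root", "root"),
                         block = "b1", run = "r1")
  write_metadata(meta, path)
  back <- read_metadata(path)
  expect_identical(back, meta)

  done <- suppressMessages(complete_metadata(back, tab))
  expect_equal(done$total_reads, c(10L, 5L))
  expect_equal(nrow(done), 2)  # s3 has no counts and is dropped

  bad <- meta
  bad$organ[1] <- "stem"
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(bad, p2)
  expect_error(read_metadata(p2), "organ")
})

test_that("qc_filter applies the four removal rules and reports them", {
  counts <- matrix(
    c(5L, 3L, 2L, 1L, 0L, 4L,
      2L, 1L, 3L, 0L, 0L, 5L,
      4L, 2L, 1L, 0L, 2L, 6L), nrow = 3, byrow = TRUE,
    dimnames = list(c("s1", "s2", "s3"),
                    c("ok1", "chl", "mit", "single", "zero", "unk")))
  lineage <- c("k__Bacteria;p__P;c__C;o__O;f__F;g__G",
               "k__Bacteria;p__Cyanobacteria;c__Chloroplast;o__O;f__F;g__G",
               "k__Bacteria;p__P;c__C;o__Rickettsiales;f__Mitochondria;g__G",
               "k__Bacteria;p__P;c__C;o__O;f__F;g__G2",
               "k__Bacteria;p__P;c__C;o__O;f__F;g__G3",
               "Unassigned")
  tab <- count_table(counts, "bacteria", lineage)
  out <- qc_filter(tab)
  expect_identical(taxon_ids(out), "ok1")
  rep <- filter_report(out)
  expect_setequal(rep$rule[match(c("chl", "mit", "single", "zero", "unk"),
                                 rep$taxon_id)],
                  c("chloroplast", "mitochondria", "singleton", "singleton",
                    "unassigned_kingdom"))

  # idempotence
  again <- qc_filter(out)
  expect_identical(again$counts, out$counts)
  expect_equal(nrow(filter_report(again)), 0)
})

test_that("qc_filter keeps all well-annotated taxa seen in 2+ samples", {
  for (seed in 1:5) {
    tab <- random_table(8, 12, seed = seed)
    tab$taxa$lineage <- "k__Bacteria;p__P;c__C;o__O;f__F;g__G"
    out <- qc_filter(tab)
    keep <- colSums(tab$counts > 0) >= 2
    expect_setequal(taxon_ids(out), taxon_ids(tab)[keep])
  }
  # singleton = nonzero in exactly 1 of 8 samples
  counts <- matrix(0L, 8, 2,
                   dimnames = list(paste0("s", 1:8), c("rare", "common")))
  counts[3, 1] <- 50L
  counts[, 2] <- 1L
  out <- qc_filter(count_table(counts, "fungi"))
  expect_identical(taxon_ids(out), "common")
  expect_equal(filter_report(out)$rule, "singleton")
})

test_that("qc_filter warns rather than silently returning an empty table", {
  counts <- matrix(c(1L, 0L), 2, 1, dimnames = list(c("s1", "s2"), "t1"))
  expect_warning(qc_filter(count_table(counts, "fungi")), "empty")
})

test_that("top_taxa ranks by totals with lexicographic ties and warns on n too large", {
  counts <- matrix(c(25L, 5L, 4L, 1L,
                     25L, 4L, 5L, 0L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("t_big", "t_z", "t_a", "t_x")))
  tab <- count_table(counts, "bacteria")
  # totals: t_big 50, t_z 9, t_a 9, t_x 1 -> tie broken toward t_a
  expect_identical(taxon_ids(top_taxa(tab, 2)), c("t_big", "t_a"))
  full <- top_taxa(tab, 4)
  expect_identical(full$counts[, sort(colnames(full$counts))],
                   tab$counts[, sort(colnames(tab$counts))])
  expect_warning(top_taxa(tab, 10), "exceeds")

  # independent sort oracle on a random table
  tab <- random_table(6, 20, seed = 42)
  got <- taxon_ids(top_taxa(tab, 5))
  totals <- colSums(tab$counts)
  oracle <- colnames(tab$counts)[order(-totals, colnames(tab$counts))][1:5]
  expect_identical(got, oracle)
})

test_that("genotype IO, heterozygote policy, and MAF filtering behave", {
  # TSV dosage round trip
  dos <- matrix(rbinom(40, 1, 0.4), 8, 5,
                dimnames = list(sprintf("acc%d", 1:8),
                                sprintf("chr1_%d", c(100, 250, 400, 900, 1500))))
  g <- mkmicrobiome:::genotype_matrix(dos)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  back <- read_genotypes(path)
  expect_equal(back$dosages, g$dosages)
  expect_equal(back$maf, g$maf)

  # maf_filter boundary cases
  freqs <- colMeans(g$dosages)
  kept <- maf_filter(g, 0.05)
  expect_true(all(kept$maf >= 0.05))
  g2 <- mkmicrobiome:::genotype_matrix(
    cbind(g$dosages,
          chr1_9999 = c(1, rep(0, 7))))       # freq 0.125 -> maf 0.125
  expect_true("chr1_9999" %in% colnames(maf_filter(g2, 0.10)$dosages))
  expect_false("chr1_9999" %in% colnames(maf_filter(g2, 0.2)$dosages))

  skip_if_not_installed("vcfR")
  # 10-SNP VCF with 2 SNPs below MAF 0.05 among 20 accessions
  n_acc <- 20
  vcf <- withr::local_tempfile(fileext = ".vcf")
  set.seed(9)
  common <- replicate(8, rbinom(n_acc, 1, runif(1, 0.2, 0.5)))
  common <- apply(common, 2, function(x) {
    if (min(mean(x), 1 - mean(x)) < 0.1) {x[sample(n_acc, 4)] <- 1L}; x
  })
  rare <- replicate(2, c(rep(0L, n_acc)))  # monomorphic ref: maf 0
  geno <- cbind(common, rare)
  rows <- sapply(seq_len(10), function(j) {
    paste(c("1", 1000 * j, paste0("snp", j), "A", "G", ".", "PASS", ".",
            "GT", as.character(geno[, j])), collapse = "\t")
  })
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sprintf("acc%02d", 1:n_acc)),
                     collapse = "\t")), vcf)
  cat(paste(rows, collapse = "\n"), "\n", file = vcf, append = TRUE)
  gv <- read_genotypes(vcf)
  expect_equal(ncol(gv$dosages), 10)
  expect_equal(ncol(maf_filter(gv, 0.05)$dosages), 8)

  # heterozygote in haploid mode: error policy
  hetvcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "a1", "a2", "a3", "a4"), collapse = "\t"),
               paste(c("1", "500", "s", "A", "G", ".", "PASS", ".", "GT",
                       "0/1", "1", "0", "1"), collapse = "\t")), hetvcf)
  expect_error(read_genotypes(hetvcf, het = "error"), "heterozygous")
  gh <- read_genotypes(hetvcf, het = "missing", max_missing = 0.3)
  # het set missing then mean-imputed from the remaining 2/3 alt calls
  expect_equal(unname(gh$dosages["a1", 1]), 2 / 3)
  # the default 20% missingness ceiling drops the SNP instead
  expect_message(gdrop <- read_genotypes(hetvcf, het = "missing"), "missingness")
  expect_equal(ncol(gdrop$dosages), 0)
})

test_that("lineage parsing handles the prefixed dialect and gaps", {
  parsed <- parse_lineage(c("k__Fungi;p__Asco;c__Doth;o__Pleo;f__Dids;g__Para",
                            "k__Fungi;p__Asco",
                            "Unassigned",
                            NA))
  expect_equal(parsed$genus, c("Para", "Unassigned", "Unassigned", "Unassigned"))
  expect_equal(parsed$kingdom[1:3], c("Fungi", "Fungi", "Unassigned"))
})
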