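test_that("melt dialect codes GT as Present-allele counts with NA missing", {
  vcf <- write_toy_melt_vcf(withr::local_tempfile(fileext = ".vcf"))
  res <- read_mei_vcf(vcf, "melt")
  expect_equal(res$loci$locus_id, c("NRL1_9_4265417", "NRL1_20_43323466"))
  expect_equal(res$loci$source, rep("non_reference", 2))
  expect_equal(res$loci$split_reads, c(4L, 1L))
  expect_equal(res$loci$assess_score, c(5L, 3L))
  expect_equal(res$loci$caller_filter, c("PASS", "lc"))
  # 0/1 -> 1; 1/1 -> 2; ./. -> NA; 0/0 -> 0; phased and half-missing handled
  expect_equal(unname(res$geno[, "NRL1_9_4265417"]), c(1L, 2L, NA, 0L))
  expect_equal(unname(res$geno[, "NRL1_20_43323466"]), c(1L, NA, 0L, 2L))
  expect_error(read_mei_vcf(vcf, "nonsense"), "arg")
})

test_that("deletion dialect complements the alt count", {
  loci <- toy_loci(3, source = "reference")
  phen <- toy_phen(2, 2)
  g <- matrix(c(0L, 1L, 2L, NA, 2L, 0L, 1L, 2L, 0L, NA, 1L, 2L), 4, 3,
              dimnames = list(phen$sample_id, loci$locus_id))
  path <- withr::local_tempfile(fileext = ".vcf")
  l1burden:::write_deletion_vcf(loci, g, path)
  res <- read_mei_vcf(path, "deletion_genotyping")
  # element deleted on both haplotypes (alt 1/1) -> 0 Present alleles
  expect_equal(unname(res$geno), unname(g))
  expect_equal(res$loci$source, rep("reference", 3))
})

test_that("a cohort encoded in either dialect gives the same Present matrix", {
  set.seed(4)
  phen <- toy_phen(4, 8)
  loci_nr <- toy_loci(6, "non_reference")
  g <- toy_geno(phen, loci_nr, iaf = 0.4)
  g[2, 3] <- NA
  loci_ref <- toy_loci(6, "reference")
  colnames_ref <- loci_ref$locus_id
  g_ref <- g; colnames(g_ref) <- colnames_ref
  melt_path <- withr::local_tempfile(fileext = ".vcf")
  del_path <- withr::local_tempfile(fileext = ".vcf")
  l1burden:::write_melt_vcf(loci_nr, g, melt_path)
  l1burden:::write_deletion_vcf(loci_ref, g_ref, del_path)
  m <- read_mei_vcf(melt_path, "melt")$geno
  d <- read_mei_vcf(del_path, "deletion_genotyping")$geno
  expect_equal(unname(m), unname(d))
  expect_equal(unname(m), unname(g))
})

test_that("genotype TSV round-trips exactly including missingness", {
  phen <- toy_phen()
  loci <- toy_loci(4)
  g <- toy_geno(phen, loci)
  g[1, 2] <- NA; g[5, 4] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_tsv(g, path)
  expect_identical(read_genotype_tsv(path), g)
})

test_that("IAF is bounded and fixed loci hit the boundary", {
  phen <- toy_phen()
  loci <- toy_loci(3)
  g <- toy_geno(phen, loci)
  g[, 2] <- 2L   # Present-fixed
  g[, 3] <- 0L
  f <- iaf(g)
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(unname(f[2]), 1)
  expect_equal(unname(f[3]), 0)
  expect_equal(locus_maf(g)[[2]], 0)
})

test_that("RC catalog loader counts sources and rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(
    locus_id = c(sprintf("RL1_1_%d", 1:102), sprintf("NRL1_2_%d", 1:177)),
    source = rep(c("reference", "non_reference"), c(102, 177)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat <- read_rc_catalog(path)
  expect_equal(nrow(cat$entries), 279)
  expect_equal(cat$n_reference, 102)
  expect_equal(cat$n_non_reference, 177)
  expect_equal(cat$n_reference + cat$n_non_reference, nrow(cat$entries))

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_equal(nrow(read_rc_catalog(empty)$entries), 0)

  dup <- withr::local_tempfile(fileext = ".tsv")
  write.table(df[c(1, 1, 2), ], dup, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_rc_catalog(dup), "duplicate")
})

test_that("annotate_rc flags catalog members only", {
  loci <- toy_loci(5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(locus_id = loci$locus_id[c(2, 4)],
                         source = "non_reference"),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat2 <- read_rc_catalog(path)
  out <- suppressMessages(annotate_rc(loci, cat2))
  expect_equal(sum(out$rc_flag), 2)
  expect_equal(which(out$rc_flag), c(2L, 4L))
  expect_equal(out[, setdiff(names(out), "rc_flag")],
               loci[, setdiff(names(loci), "rc_flag")])

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  out0 <- suppressMessages(annotate_rc(loci, read_rc_catalog(empty)))
  expect_equal(sum(out0$rc_flag), 0)
})

test_that("a registry built to contain 106 catalog members flags 106", {
  n <- 400
  chrom <- as.character(rep_len(1:22, n))
  pos <- seq_len(n) * 5000L
  loci <- locus_table(make_locus_id(chrom, pos, "non_reference"),
                      chrom, pos, "non_reference")
  member_idx <- seq(3, by = 3, length.out = 106)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(locus_id = c(loci$locus_id[member_idx],
                                      sprintf("RL1_9_%d", 1:50)),
                         source = c(rep("non_reference", 106),
                                    rep("reference", 50))),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- suppressMessages(annotate_rc(loci, read_rc_catalog(path)))
  expect_equal(sum(out$rc_flag), 106)
})

test_that("genomic context uses exon > utr5 > utr3 > intron > intergenic", {
  loci <- locus_table(
    locus_id = paste0("NRL1_1_", c(150, 5000, 250, 650)),
    chrom = "1", pos = c(150, 5000, 250, 650), source = "non_reference")
  iv <- data.frame(
    chrom = "1",
    start = c(100, 100, 200, 600, 600),
    end = c(1000, 300, 300, 700, 700),
    feature = c("gene_body", "exon", "utr5", "intron", "utr3"))
  out <- classify_genomic_context(loci, iv)
  expect_equal(out$genomic_context,
               c("exonic",      # in gene body + exon (+utr5): exon wins
                 "intergenic",  # outside everything
                 "exonic",      # exon + utr5 overlap: exon precedence
                 "utr3"))       # intron + utr3: utr3 precedence
  # unsorted interval table gives the same answer
  out2 <- classify_genomic_context(loci, iv[sample(nrow(iv)), ])
  expect_equal(out2$genomic_context, out$genomic_context)
})

test_that("gene-list intersection returns every overlapping pair", {
  loci <- locus_table(c("NRL1_2_500", "NRL1_2_9000"), "2", c(500, 9000),
                      "non_reference")
  genes <- data.frame(chrom = "2", start = c(100, 400, 20000),
                      end = c(1000, 600, 30000))
  names_g <- c("ERBB4", "SCFD1", "FUS")
  pairs <- intersect_with_gene_list(loci, genes, names_g)
  # one locus inside two overlapping genes -> 2 pairs; other locus in none
  expect_equal(nrow(pairs), 2)
  expect_setequal(pairs$gene, c("ERBB4", "SCFD1"))
  expect_true(all(pairs$locus_id == "NRL1_2_500"))
  none <- intersect_with_gene_list(loci, genes[3, , drop = FALSE], "FUS")
  expect_equal(nrow(none), 0)
})

test_that("malformed VCF input fails with a parse error naming the file", {
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("not a vcf at all", "1\t2\t3"), bad)
  expect_error(read_mei_vcf(bad, "melt"), "malformed VCF|no genotype")
  expect_error(read_mei_vcf(file.path(tempdir(), "absent.vcf"), "melt"),
               "not found")
})

test_that("phenotype validation enforces the field contracts", {
  phen <- toy_phen()
  expect_silent(validate_phenotypes(phen))
  bad <- phen; bad$survival_months[8] <- -1
  expect_error(validate_phenotypes(bad), "survival_months")
  bad2 <- phen; bad2$age_at_onset_years[1] <- 55  # NNC with onset
  expect_error(validate_phenotypes(bad2), "age_at_onset")
  bad3 <- phen; bad3$diagnosis[1] <- "healthy"
  expect_error(validate_phenotypes(bad3), "diagnosis")
})
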