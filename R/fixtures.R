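# plain-text VCF 4.2 emitters for the synthetic fixtures. Parsing always goes
# through vcfR; these only format records the pipeline itself generated.

format_gt <- function(counts) {
  out <- rep("./.", length(counts))
  out[!is.na(counts) & counts == 0L] <- "0/0"
  out[!is.na(counts) & counts == 1L] <- "0/1"
  out[!is.na(counts) & counts == 2L] <- "1/1"
  out
}

vcf_header <- function(chroms, info_lines, seed = NULL, extra = NULL) {
  c("##fileformat=VCFv4.2",
    if (!is.null(seed)) sprintf("##l1burden_seed=%s", seed),
    extra,
    sprintf("##contig=<ID=%s>", unique(chroms)),
    info_lines,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
}

write_melt_vcf <- function(loci, geno, path, seed = NULL) {
  stopifnot(all(loci$source == "non_reference"))
  info <- sprintf("SR=%d;ASSESS=%d", loci$split_reads, loci$assess_score)
  gt <- apply(geno, 1, format_gt)            # loci x samples
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(loci))
  body <- paste(loci$chrom, loci$pos, loci$locus_id, "A", "<INS:ME:LINE1>",
                ".", loci$caller_filter, info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- vcf_header(
    loci$chrom,
    c("##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Split reads\">",
      "##INFO=<ID=ASSESS,Number=1,Type=Integer,Description=\"Assessment score\">",
      "##ALT=<ID=INS:ME:LINE1,Description=\"LINE1 insertion\">"),
    seed)
  col_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(geno)), collapse = "\t")
  writeLines(c(hdr, col_line, body), path)
  invisible(path)
}

write_deletion_vcf <- function(loci, geno, path, seed = NULL) {
  stopifnot(all(loci$source == "reference"))
  # deletion-genotyping dialect: alt allele = deletion of the reference
  # element, so the alt count is 2 - Present count
  del <- 2L - geno
  info <- sprintf("SVTYPE=DEL;END=%d", loci$pos + 6000L)
  gt <- apply(del, 1, format_gt)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(loci))
  body <- paste(loci$chrom, loci$pos, loci$locus_id, "N", "<DEL>", ".",
                "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- vcf_header(
    loci$chrom,
    c("##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
      "##ALT=<ID=DEL,Description=\"Deletion of reference L1\">"),
    seed)
  col_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(geno)), collapse = "\t")
  writeLines(c(hdr, col_line, body), path)
  invisible(path)
}

write_rc_catalog_tsv <- function(catalog, path) {
  write.table(catalog$entries, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a fixture directory
#'
#' Emits the on-disk form of a [simulate_cohort()] result: a melt-dialect VCF
#' for the non-reference loci, a deletion-dialect VCF for the reference loci,
#' the phenotype TSV, the RC catalog TSV, one expression TSV per tissue, and
#' a `sim_meta.yaml` carrying the seed and a config hash. Re-reading the VCFs
#' through [read_mei_vcf()] reproduces the genotype matrix exactly.
#'
#' @param sim output of [simulate_cohort()].
#' @param out_dir directory (created if absent).
#' @return named character vector of the files written.
#' @export
write_fixture <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(out_dir, x)
  nr <- sim$loci$source == "non_reference"
  files <- c(
    melt_vcf = write_melt_vcf(sim$loci[nr, ],
                              sim$geno[, nr, drop = FALSE],
                              f("non_reference_melt.vcf"), sim$seed),
    deletion_vcf = write_deletion_vcf(sim$loci[!nr, ],
                                      sim$geno[, !nr, drop = FALSE],
                                      f("reference_deletions.vcf"), sim$seed),
    phenotypes = write_phenotypes(sim$phen, f("phenotypes.tsv")),
    rc_catalog = write_rc_catalog_tsv(sim$catalog, f("rc_catalog.tsv")))
  for (tissue in names(sim$expr)) {
    p <- f(sprintf("expression_%s.tsv", tissue))
    write_expression_matrix(sim$expr[[tissue]], p)
    files[paste0("expression_", tissue)] <- p
  }
  meta <- list(seed = sim$seed,
               config_hash = config_hash(sim$config),
               special = sim$special[c("onset_locus_id", "cc_locus_id",
                                       "high_missing_locus_id")])
  yaml::write_yaml(meta, f("sim_meta.yaml"))
  files["meta"] <- f("sim_meta.yaml")
  files
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(unclass(config)), tf)
  unname(tools::md5sum(tf))
}
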