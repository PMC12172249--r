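# small in-code fixtures shared across test files

toy_loci <- function(n = 5, source = "non_reference", chrom = NULL) {
  chrom <- chrom %||% as.character(rep_len(c(1, 2, 7), n))
  pos <- seq(1000, by = 1000, length.out = n)
  l1burden::locus_table(
    locus_id = l1burden::make_locus_id(chrom, pos, rep_len(source, n)),
    chrom = chrom, pos = pos, source = rep_len(source, n),
    split_reads = ifelse(rep_len(source, n) == "non_reference", 4L, NA),
    assess_score = ifelse(rep_len(source, n) == "non_reference", 5L, NA),
    caller_filter = "PASS")
}

toy_phen <- function(n_ctrl = 6, n_case = 10, seed = 1) {
  set.seed(seed)
  n <- n_ctrl + n_case
  data.frame(
    sample_id = sprintf("S%03d", 1:n),
    diagnosis = rep(c("NNC", "ALS"), c(n_ctrl, n_case)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_years = round(runif(n, 40, 80), 1),
    age_at_onset_years = c(rep(NA, n_ctrl), round(runif(n_case, 40, 75), 1)),
    site_of_onset = c(rep(NA, n_ctrl),
                      sample(c("bulbar", "limb"), n_case, replace = TRUE)),
    survival_months = c(rep(NA, n_ctrl), round(runif(n_case, 6, 60), 1)),
    event_observed = c(rep(NA, n_ctrl),
                       sample(c(TRUE, TRUE, FALSE), n_case, replace = TRUE)),
    seq_prep = sample(c("prep1", "prep2"), n, replace = TRUE),
    european_fraction = rep(0.97, n),
    stringsAsFactors = FALSE)
}

toy_geno <- function(phen, loci, iaf = 0.3, seed = 2) {
  set.seed(seed)
  g <- matrix(rbinom(nrow(phen) * nrow(loci), 2, iaf),
              nrow(phen), nrow(loci),
              dimnames = list(phen$sample_id, loci$locus_id))
  storage.mode(g) <- "integer"
  g
}

# hand-written melt-dialect VCF text, independent of the package's writer
write_toy_melt_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=9>",
    "##contig=<ID=20>",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Split reads\">",
    "##INFO=<ID=ASSESS,Number=1,Type=Integer,Description=\"Assessment score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "A1", "A2", "A3", "A4"), collapse = "\t"),
    paste(c("9", "4265417", ".", "A", "<INS:ME:LINE1>", ".", "PASS",
            "SR=4;ASSESS=5", "GT", "0/1", "1/1", "./.", "0/0"),
          collapse = "\t"),
    paste(c("20", "43323466", ".", "A", "<INS:ME:LINE1>", ".", "lc",
            "SR=1;ASSESS=3", "GT", "0|1", "0/.", "0/0", "1/1"),
          collapse = "\t"))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
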