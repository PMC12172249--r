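#' Filter accounting ledger
#'
#' Every QC step appends one row: step name, loci (or samples) in, removed,
#' out, and the criterion applied. Conservation (`n_out = n_in - n_removed`,
#' and chaining across steps) is enforced on construction.
#'
#' @param step,n_in,n_removed,n_out,criterion row fields.
#' @return data.frame of class `filter_ledger`.
#' @export
new_ledger <- function(step = character(), n_in = integer(),
                       n_removed = integer(), n_out = integer(),
                       criterion = character()) {
  df <- data.frame(step = step, n_in = n_in, n_removed = n_removed,
                   n_out = n_out, criterion = criterion,
                   stringsAsFactors = FALSE)
  class(df) <- c("filter_ledger", "data.frame")
  validate_ledger(df)
}

validate_ledger <- function(df) {
  if (nrow(df)) {
    if (any(df$n_out != df$n_in - df$n_removed))
      stop("ledger violates n_out = n_in - n_removed", call. = FALSE)
    if (nrow(df) > 1 && any(df$n_in[-1] != df$n_out[-nrow(df)]))
      stop("ledger steps do not chain", call. = FALSE)
  }
  df
}

add_ledger_step <- function(ledger, step, n_in, n_out, criterion) {
  out <- rbind(as.data.frame(ledger),
               data.frame(step = step, n_in = n_in, n_removed = n_in - n_out,
                          n_out = n_out, criterion = criterion,
                          stringsAsFactors = FALSE))
  class(out) <- c("filter_ledger", "data.frame")
  validate_ledger(out)
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("<filter_ledger>\n")
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

#' @rdname new_ledger
#' @param ledger a `filter_ledger`. @param path output TSV.
#' @export
write_ledger_tsv <- function(ledger, path) {
  write.table(as.data.frame(ledger), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Caller-evidence filter for non-reference records
#'
#' Keeps non-reference loci supported by at least 2 split reads, an
#' assessment score of at least 3 (both boundaries inclusive) and a PASS
#' FILTER. Reference-dialect loci pass through untouched. Non-reference loci
#' with missing evidence fail and are counted separately in the ledger.
#'
#' @param loci `l1_loci` table.
#' @return list with `loci` (kept rows) and `ledger`.
#' @export
filter_melt_records <- function(loci) {
  is_nr <- loci$source == "non_reference"
  missing_ev <- is_nr & (is.na(loci$split_reads) | is.na(loci$assess_score) |
                           is.na(loci$caller_filter))
  ev_ok <- !missing_ev &
    !is.na(loci$split_reads) & loci$split_reads >= 2L &
    !is.na(loci$assess_score) & loci$assess_score >= 3L &
    !is.na(loci$caller_filter) & loci$caller_filter == "PASS"
  fails <- is_nr & !ev_ok
  kept <- loci[!fails, , drop = FALSE]
  ledger <- new_ledger()
  ledger <- add_ledger_step(
    ledger, "melt_evidence", nrow(loci), nrow(kept),
    sprintf(paste0("non-reference: split_reads >= 2 & assess_score >= 3 & ",
                   "FILTER == PASS (%d failed, of which %d missing evidence); ",
                   "reference loci untouched"),
            sum(fails), sum(missing_ev)))
  list(loci = kept, ledger = ledger)
}

#' Hardy-Weinberg filter in controls
#'
#' Computes the exact HWE test per locus on the non-neurological-control
#' (NNC) genotypes only and removes loci with p strictly below `threshold`.
#'
#' @param geno genotype matrix. @param phen phenotype table.
#' @param threshold removal threshold (default 1e-6, strict `<`).
#' @return list with `geno` and `ledger`.
#' @export
filter_hwe <- function(geno, phen, threshold = 1e-6) {
  nnc <- phen$sample_id[phen$diagnosis == "NNC"]
  nnc <- intersect(nnc, rownames(geno))
  if (!length(nnc)) stop("no NNC samples to test HWE in", call. = FALSE)
  g <- geno[nnc, , drop = FALSE]
  p <- apply(g, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(1)
    hwe_exact_test(sum(col == 0L), sum(col == 1L), sum(col == 2L))
  })
  keep <- p >= threshold
  out <- geno[, keep, drop = FALSE]
  ledger <- new_ledger("hwe_in_controls", ncol(geno), sum(!keep), ncol(out),
                       sprintf("exact HWE p < %g in NNCs removed", threshold))
  list(geno = out, ledger = ledger, hwe_p = p)
}

#' Minor-allele-frequency filter
#'
#' MAF over the supplied (analysis-cohort) samples, non-missing calls only;
#' loci kept iff MAF is strictly greater than `min_maf`. All-missing loci are
#' removed and counted as degenerate.
#'
#' @param geno genotype matrix (already restricted to the analysis cohort).
#' @param min_maf strict lower bound (default 0.01).
#' @return list with `geno` and `ledger`.
#' @export
filter_maf <- function(geno, min_maf = 0.01) {
  maf <- locus_maf(geno)
  degenerate <- is.nan(maf)
  keep <- !degenerate & maf > min_maf
  out <- geno[, keep, drop = FALSE]
  ledger <- new_ledger(
    "maf", ncol(geno), sum(!keep), ncol(out),
    sprintf("MAF > %g strictly (%d all-missing loci counted degenerate)",
            min_maf, sum(degenerate)))
  list(geno = out, ledger = ledger)
}

#' Restrict to autosomal, well-genotyped RC loci for the burden
#'
#' Keeps catalog-flagged (RC) loci, drops chrX/chrY loci (so male and female
#' genomes are comparable) and drops loci whose missing-genotype fraction is
#' strictly above 5%.
#'
#' @param geno genotype matrix. @param loci annotated `l1_loci` table.
#' @param max_missing strict upper bound on the missing fraction.
#' @return list with `geno` and `ledger`.
#' @export
filter_rc_for_burden <- function(geno, loci, max_missing = 0.05) {
  loci_here <- loci[match(colnames(geno), loci$locus_id), ]
  rc <- !is.na(loci_here$rc_flag) & loci_here$rc_flag
  g_rc <- geno[, rc, drop = FALSE]
  ledger <- new_ledger("rc_restrict", ncol(geno), sum(!rc), ncol(g_rc),
                       "RC-catalog loci only")
  sex_chrom <- normalize_chrom(loci_here$chrom[rc]) %in% c("X", "Y")
  g_auto <- g_rc[, !sex_chrom, drop = FALSE]
  ledger <- add_ledger_step(ledger, "autosomal", ncol(g_rc), ncol(g_auto),
                            "chrX/chrY RC loci removed")
  miss_frac <- colMeans(is.na(g_auto))
  keep <- miss_frac <= max_missing
  out <- g_auto[, keep, drop = FALSE]
  ledger <- add_ledger_step(
    ledger, "missingness", ncol(g_auto), ncol(out),
    sprintf("missing-genotype fraction > %g removed", max_missing))
  list(geno = out, ledger = ledger)
}

#' Complete-case restriction across the burden loci
#'
#' Drops any sample with one or more missing genotypes among the retained
#' burden loci, so every burden is a sum over the identical locus set.
#'
#' @param geno genotype matrix restricted to burden loci.
#' @return list with `geno` and `ledger` (rows are samples here).
#' @export
restrict_complete_individuals <- function(geno) {
  complete <- rowSums(is.na(geno)) == 0L
  out <- geno[complete, , drop = FALSE]
  ledger <- new_ledger(
    "complete_individuals", nrow(geno), sum(!complete), nrow(out),
    sprintf("samples with any missing genotype across %d burden loci dropped",
            ncol(geno)))
  list(geno = out, ledger = ledger)
}

#' Select the analysis cohort
#'
#' Samples with `european_fraction` strictly greater than 0.9 and a diagnosis
#' of ALS, ALSND or NNC.
#'
#' @param phen phenotype table.
#' @return list with `sample_ids`, `phen` (subset) and `ledger`.
#' @export
select_analysis_cohort <- function(phen) {
  keep <- !is.na(phen$european_fraction) & phen$european_fraction > 0.9 &
    phen$diagnosis %in% c("ALS", "ALSND", "NNC")
  sub <- phen[keep, , drop = FALSE]
  ledger <- new_ledger(
    "analysis_cohort", nrow(phen), sum(!keep), nrow(sub),
    "european_fraction > 0.9 (strict) and diagnosis in {ALS, ALSND, NNC}")
  list(sample_ids = sub$sample_id, phen = sub, ledger = ledger)
}

#' Chain ledgers from successive steps
#' @param ... `filter_ledger` objects over the same unit (loci or samples).
#' @export
bind_ledgers <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("filter_ledger", "data.frame")
  validate_ledger(df)
}
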