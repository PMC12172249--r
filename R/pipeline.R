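#' Pipeline stage runners
#'
#' Thin orchestration over the package's analysis functions, one runner per
#' stage (`simulate`, `qc`, `burden`, `assoc`, `eqtl`, `report`). Stages
#' communicate through plain TSV files so each is inspectable and cacheable;
#' every stage updates `manifest.json` in its output directory with the seed,
#' config hash and an md5 checksum of every file it wrote. Filter ledgers are
#' printed to the log and exported as TSV.
#'
#' @name pipeline
NULL

require_files <- function(...) {
  paths <- c(...)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         "; run the earlier pipeline stage first", call. = FALSE)
  invisible(paths)
}

update_manifest <- function(out_dir, stage, files, seed = NULL,
                            config_hash = NULL) {
  mf_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(mf_path))
    jsonlite::read_json(mf_path, simplifyVector = FALSE) else list(stages = list())
  manifest$stages[[stage]] <- list(
    files = as.list(tools::md5sum(files)),
    seed = seed, config_hash = config_hash,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("l1burden")))
  jsonlite::write_json(manifest, mf_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf_path)
}

log_ledger <- function(ledger, label) {
  message(label, ":")
  for (i in seq_len(nrow(ledger)))
    message(sprintf("  %-22s %6d -> %6d (-%d)  %s", ledger$step[i],
                    ledger$n_in[i], ledger$n_out[i], ledger$n_removed[i],
                    ledger$criterion[i]))
}

#' @rdname pipeline
#' @param config a [sim_config()]. @param seed integer seed.
#' @param out_dir output directory.
#' @export
run_simulate <- function(out_dir, config = sim_config(), seed = 1L) {
  sim <- simulate_cohort(config, seed)
  files <- write_fixture(sim, out_dir)
  update_manifest(out_dir, "simulate", files, seed, config_hash(config))
  invisible(files)
}

#' @rdname pipeline
#' @param fixture_dir directory holding the input files (VCFs, phenotype TSV,
#'   RC catalog, expression TSVs), e.g. from [run_simulate()].
#' @export
run_qc <- function(fixture_dir, out_dir) {
  melt_path <- file.path(fixture_dir, "non_reference_melt.vcf")
  del_path <- file.path(fixture_dir, "reference_deletions.vcf")
  phen_path <- file.path(fixture_dir, "phenotypes.tsv")
  cat_path <- file.path(fixture_dir, "rc_catalog.tsv")
  require_files(melt_path, del_path, phen_path, cat_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  nr <- read_mei_vcf(melt_path, "melt")
  rf <- read_mei_vcf(del_path, "deletion_genotyping")
  phen <- read_phenotypes(phen_path)
  catalog <- read_rc_catalog(cat_path)

  ev <- filter_melt_records(nr$loci)
  nr_geno <- nr$geno[, ev$loci$locus_id, drop = FALSE]
  loci <- merge_locus_registry(rf$loci, ev$loci)
  loci <- annotate_rc(loci, catalog)
  geno <- cbind(rf$geno, nr_geno[rownames(rf$geno), , drop = FALSE])
  geno <- geno[, loci$locus_id, drop = FALSE]

  cohort <- select_analysis_cohort(phen)
  geno_c <- geno[intersect(rownames(geno), cohort$sample_ids), , drop = FALSE]
  hwe <- filter_hwe(geno_c, cohort$phen)

  keep_ids <- colnames(hwe$geno)
  loci_kept <- loci[loci$locus_id %in% keep_ids, , drop = FALSE]
  locus_ledger <- bind_ledgers(
    new_ledger("registry", nrow(loci), 0L, nrow(loci),
               "merged reference + non-reference loci (post-evidence filter)"),
    hwe$ledger)
  log_ledger(ev$ledger, "evidence filter (non-reference records)")
  log_ledger(locus_ledger, "locus QC")
  log_ledger(cohort$ledger, "cohort selection (samples)")

  f <- function(x) file.path(out_dir, x)
  write_genotype_tsv(hwe$geno, f("qc_genotypes.tsv"))
  write.table(as.data.frame(loci_kept), f("qc_loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_phenotypes(cohort$phen, f("qc_phenotypes.tsv"))
  write_ledger_tsv(ev$ledger, f("ledger_evidence.tsv"))
  write_ledger_tsv(locus_ledger, f("ledger_locus_qc.tsv"))
  write_ledger_tsv(cohort$ledger, f("ledger_cohort.tsv"))
  files <- f(c("qc_genotypes.tsv", "qc_loci.tsv", "qc_phenotypes.tsv",
               "ledger_evidence.tsv", "ledger_locus_qc.tsv",
               "ledger_cohort.tsv"))
  update_manifest(out_dir, "qc", files)
  invisible(files)
}

read_qc_outputs <- function(qc_dir) {
  g <- file.path(qc_dir, "qc_genotypes.tsv")
  l <- file.path(qc_dir, "qc_loci.tsv")
  p <- file.path(qc_dir, "qc_phenotypes.tsv")
  require_files(g, l, p)
  list(geno = read_genotype_tsv(g),
       loci = validate_loci(read.delim(l, stringsAsFactors = FALSE)),
       phen = read_phenotypes(p))
}

#' @rdname pipeline
#' @param qc_dir directory written by [run_qc()].
#' @param thresholds integer thresholds for the burden scan.
#' @export
run_burden <- function(qc_dir, out_dir, thresholds = 43:48) {
  qc <- read_qc_outputs(qc_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rc <- filter_rc_for_burden(qc$geno, qc$loci)
  cc <- restrict_complete_individuals(rc$geno)
  ledger <- bind_ledgers(rc$ledger)
  log_ledger(ledger, "burden locus filter")
  log_ledger(cc$ledger, "complete-case samples")

  profiles <- compute_burden(cc$geno)
  model <- burden_disease_model(profiles, qc$phen)
  scan <- threshold_scan(profiles, qc$phen, thresholds)
  os <- burden_onset_and_survival(profiles, qc$phen)

  f <- function(x) file.path(out_dir, x)
  write.table(profiles, f("burden_profiles.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(scan), f("threshold_scan.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(threshold_forest_table(scan), f("threshold_forest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(rbind(model, os$onset, os$survival), f("burden_models.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_ledger_tsv(ledger, f("ledger_burden_loci.tsv"))
  write_ledger_tsv(cc$ledger, f("ledger_burden_samples.tsv"))
  files <- f(c("burden_profiles.tsv", "threshold_scan.tsv",
               "threshold_forest.tsv", "burden_models.tsv",
               "ledger_burden_loci.tsv", "ledger_burden_samples.tsv"))
  update_manifest(out_dir, "burden", files)
  invisible(files)
}

#' @rdname pipeline
#' @export
run_assoc <- function(qc_dir, out_dir) {
  qc <- read_qc_outputs(qc_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  maf <- filter_maf(qc$geno)
  log_ledger(maf$ledger, "MAF filter")
  cc <- casecontrol_scan(maf$geno, qc$phen)
  on <- onset_scan(maf$geno, qc$phen)
  sv <- survival_scan(maf$geno, qc$phen)
  f <- function(x) file.path(out_dir, x)
  write.table(cc, f("casecontrol_scan.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(on, f("onset_scan.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sv, f("survival_scan.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(scan_forest_table(sv), f("survival_forest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_ledger_tsv(maf$ledger, f("ledger_maf.tsv"))
  files <- f(c("casecontrol_scan.tsv", "onset_scan.tsv", "survival_scan.tsv",
               "survival_forest.tsv", "ledger_maf.tsv"))
  update_manifest(out_dir, "assoc", files)
  invisible(files)
}

#' @rdname pipeline
#' @export
run_eqtl <- function(qc_dir, fixture_dir, out_dir) {
  qc <- read_qc_outputs(qc_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tissues <- c("medial_motor_cortex", "lateral_motor_cortex")
  paths <- file.path(fixture_dir, sprintf("expression_%s.tsv", tissues))
  require_files(paths)
  expr <- stats::setNames(
    lapply(seq_along(tissues),
           function(i) read_expression_matrix(paths[i], tissues[i])),
    tissues)
  res <- eqtl_scan(qc$geno, expr, qc$phen)
  sig_loci <- eqtl_significant_loci(res)
  tested <- unique(res$locus_id)
  rc_flags <- qc$loci$rc_flag[match(tested, qc$loci$locus_id)]
  enr <- rc_enrichment(sig_loci, tested, rc_flags)
  f <- function(x) file.path(out_dir, x)
  write.table(res[res$significant, , drop = FALSE], f("eqtl_significant.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  enr_df <- data.frame(proportion_rc = enr$proportion_rc,
                       proportion_all = enr$proportion_all,
                       fisher_p = enr$p,
                       n_eqtl_loci = length(sig_loci),
                       n_tested_loci = length(tested))
  write.table(enr_df, f("rc_enrichment.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- f(c("eqtl_significant.tsv", "rc_enrichment.tsv"))
  update_manifest(out_dir, "eqtl", files)
  invisible(files)
}

#' @rdname pipeline
#' @param run_dir directory containing the outputs of the earlier stages.
#' @export
run_report <- function(run_dir, out_dir = run_dir) {
  f_burden <- file.path(run_dir, "burden_profiles.tsv")
  f_scan <- file.path(run_dir, "threshold_scan.tsv")
  require_files(f_burden, f_scan)
  profiles <- read.delim(f_burden)
  scan <- read.delim(f_scan)
  summary <- data.frame(
    quantity = c("n_burden_loci", "n_individuals", "min_burden", "max_burden",
                 "most_significant_threshold"),
    value = c(profiles$n_loci_used[1], nrow(profiles),
              min(profiles$rc_allele_count), max(profiles$rc_allele_count),
              if (all(is.na(scan$p_unadj))) NA_integer_ else
                scan$threshold[which.min(scan$p_unadj)]))
  out <- file.path(out_dir, "report_summary.tsv")
  write.table(summary, out, sep = "\t", quote = FALSE, row.names = FALSE)
  message(paste(utils::capture.output(print(summary, row.names = FALSE)),
                collapse = "\n"))
  update_manifest(out_dir, "report", out)
  invisible(out)
}

#' @rdname pipeline
#' @export
run_pipeline <- function(fixture_dir, out_dir, thresholds = 43:48) {
  run_qc(fixture_dir, out_dir)
  run_burden(out_dir, out_dir, thresholds)
  run_assoc(out_dir, out_dir)
  run_eqtl(out_dir, fixture_dir, out_dir)
  run_report(out_dir)
  invisible(out_dir)
}
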