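#' @importFrom utils read.delim write.table head
NULL

DIAGNOSES <- c("NNC", "ALS", "ALSND", "other_MND", "other_neuro")
CONTEXTS <- c("intergenic", "intronic", "exonic", "utr5", "utr3")

#' Build a locus table
#'
#' One row per polymorphic L1 insertion locus: genomic position (1-based VCF
#' convention), source dialect (`reference` elements genotyped as deletions
#' vs `non_reference` novel insertions), RC-catalog membership, genomic
#' context, and caller evidence for non-reference loci (split reads,
#' assessment score, FILTER column).
#'
#' @param locus_id unique identifiers; non-reference loci follow
#'   `NRL1_<chrom>_<pos>`.
#' @param chrom chromosome names (no `chr` prefix internally).
#' @param pos 1-based positions.
#' @param source `"reference"` or `"non_reference"`.
#' @param rc_flag logical RC-catalog membership.
#' @param genomic_context one of intergenic/intronic/exonic/utr5/utr3 or NA.
#' @param split_reads,assess_score caller evidence (non-reference only).
#' @param caller_filter VCF FILTER value.
#' @return validated data.frame of class `l1_loci`.
#' @export
locus_table <- function(locus_id, chrom, pos, source,
                        rc_flag = FALSE, genomic_context = NA_character_,
                        split_reads = NA_integer_, assess_score = NA_integer_,
                        caller_filter = NA_character_) {
  df <- data.frame(
    locus_id = as.character(locus_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    source = as.character(source),
    rc_flag = as.logical(rc_flag),
    genomic_context = as.character(genomic_context),
    split_reads = as.integer(split_reads),
    assess_score = as.integer(assess_score),
    caller_filter = as.character(caller_filter),
    stringsAsFactors = FALSE
  )
  validate_loci(df)
}

validate_loci <- function(df) {
  stopifnot(is.data.frame(df))
  if (anyDuplicated(df$locus_id))
    stop("duplicate locus_id in locus registry", call. = FALSE)
  if (any(df$pos < 1, na.rm = TRUE)) stop("pos must be >= 1", call. = FALSE)
  if (!all(df$source %in% c("reference", "non_reference")))
    stop("source must be reference/non_reference", call. = FALSE)
  bad_ctx <- !is.na(df$genomic_context) & !(df$genomic_context %in% CONTEXTS)
  if (any(bad_ctx)) stop("invalid genomic_context values", call. = FALSE)
  class(df) <- c("l1_loci", "data.frame")
  df
}

#' Canonical locus identifier
#'
#' Non-reference loci are named `NRL1_<chrom>_<pos>` and reference loci
#' `RL1_<chrom>_<pos>`, chromosome given without a `chr` prefix.
#' @param chrom,pos coordinates. @param source locus source.
#' @return character vector of ids.
#' @export
make_locus_id <- function(chrom, pos, source) {
  prefix <- ifelse(source == "non_reference", "NRL1", "RL1")
  paste(prefix, normalize_chrom(chrom), pos, sep = "_")
}

#' Normalize chromosome names
#' @param chrom chromosome names. @param use_chr add (`TRUE`) or strip
#'   (`FALSE`, default) the `"chr"` prefix.
#' @export
normalize_chrom <- function(chrom, use_chr = FALSE) {
  stripped <- sub("^chr", "", as.character(chrom))
  if (use_chr) paste0("chr", stripped) else stripped
}

# ---- genotype matrix ------------------------------------------------------

validate_geno <- function(geno) {
  stopifnot(is.matrix(geno))
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("genotype matrix needs sample (row) and locus (column) names",
         call. = FALSE)
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    stop("genotypes must be 0/1/2 or NA", call. = FALSE)
  storage.mode(geno) <- "integer"
  geno
}

#' Insertion allele frequency per locus
#'
#' IAF = (sum of Present-allele counts) / (2 x non-missing calls).
#' @param geno samples x loci genotype matrix (0/1/2/NA Present-allele counts).
#' @return named numeric vector; NaN for all-missing loci.
#' @export
iaf <- function(geno) {
  colSums(geno, na.rm = TRUE) / (2 * colSums(!is.na(geno)))
}

#' Minor allele frequency per locus
#' @inheritParams iaf
#' @return `pmin(iaf, 1 - iaf)`.
#' @export
locus_maf <- function(geno) {
  f <- iaf(geno)
  pmin(f, 1 - f)
}

#' Write / read the genotype TSV export
#'
#' Samples x loci table, first column `sample_id`, values 0/1/2/NA. The
#' round trip is exact, including missingness.
#' @param geno genotype matrix. @param path output file.
#' @export
write_genotype_tsv <- function(geno, path) {
  geno <- validate_geno(geno)
  df <- data.frame(sample_id = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample_id
  validate_geno(m)
}

# ---- VCF input ------------------------------------------------------------

#' Read mobile-element-insertion genotypes from VCF
#'
#' Two dialects are supported. `melt`: records are novel (non-reference)
#' insertions and GT allele 1 is the insertion-Present allele. `
#' deletion_genotyping`: records are reference elements genotyped as
#' deletions, so GT allele 1 means the element is *absent* and the
#' Present-allele count is `2 - <alt allele count>`. Missing (`./.`) or
#' half-missing GTs become NA. Evidence fields for the melt dialect are read
#' from INFO keys named in `config` (defaults `SR` and `ASSESS`) together with
#' the FILTER column.
#'
#' @param path VCF file (4.2, plain text or gzipped).
#' @param dialect `"melt"` or `"deletion_genotyping"`.
#' @param config list with `info_split_reads`, `info_assess`, `use_chr`.
#' @return list with `loci` (an `l1_loci` table) and `geno`
#'   (samples x loci Present-allele count matrix).
#' @export
read_mei_vcf <- function(path, dialect = c("melt", "deletion_genotyping"),
                         config = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  key_sr <- config$info_split_reads %||% "SR"
  key_as <- config$info_assess %||% "ASSESS"
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- normalize_chrom(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  filt <- fix[, "FILTER"]
  source <- if (dialect == "melt") "non_reference" else "reference"
  sr <- as_int_or_na(vcfR::extract.info(v, element = key_sr))
  as_score <- as_int_or_na(vcfR::extract.info(v, element = key_as))
  loci <- locus_table(
    locus_id = make_locus_id(chrom, pos, source),
    chrom = chrom, pos = pos, source = source,
    split_reads = if (dialect == "melt") sr else NA_integer_,
    assess_score = if (dialect == "melt") as_score else NA_integer_,
    caller_filter = filt
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0)
    stop("VCF '", path, "' has no genotype columns", call. = FALSE)
  alt_count <- gt_to_alt_count(gt)
  present <- if (dialect == "melt") alt_count else 2L - alt_count
  geno <- t(present)
  colnames(geno) <- loci$locus_id
  list(loci = loci, geno = validate_geno(geno))
}

# diploid GT string -> count of allele "1"; any missing allele -> NA
gt_to_alt_count <- function(gt) {
  flat <- gsub("|", "/", as.character(gt), fixed = TRUE)
  parts <- strsplit(flat, "/", fixed = TRUE)
  cnt <- vapply(parts, function(a) {
    if (length(a) != 2L || any(is.na(a)) || any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
  cnt[is.na(flat)] <- NA_integer_
  matrix(cnt, nrow = nrow(gt), dimnames = dimnames(gt))
}

as_int_or_na <- function(x) {
  suppressWarnings(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge reference and non-reference locus registries
#'
#' @param ... `l1_loci` tables.
#' @return combined registry plus a message of counts by source.
#' @export
merge_locus_registry <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  df <- validate_loci(df)
  n_ref <- sum(df$source == "reference")
  n_non <- sum(df$source == "non_reference")
  message(sprintf("locus registry: %d loci (%d reference + %d non-reference)",
                  nrow(df), n_ref, n_non))
  df
}

# ---- RC catalog -----------------------------------------------------------

#' Read the retrotransposition-competent L1 catalog
#'
#' Tab-separated, header `locus_id<TAB>source`, UTF-8. Duplicated entries are
#' rejected. The returned object carries counts by source.
#'
#' @param path catalog file.
#' @return object of class `rc_catalog`: list with `entries`, `n_reference`,
#'   `n_non_reference`.
#' @export
read_rc_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    df <- data.frame(locus_id = character(), source = character(),
                     stringsAsFactors = FALSE)
  } else df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("locus_id", "source") %in% names(df)))
    stop("catalog needs columns locus_id and source", call. = FALSE)
  if (anyDuplicated(df$locus_id))
    stop("duplicate locus_id in RC catalog: ",
         paste(unique(df$locus_id[duplicated(df$locus_id)]), collapse = ", "),
         call. = FALSE)
  if (!all(df$source %in% c("reference", "non_reference")))
    stop("catalog source must be reference/non_reference", call. = FALSE)
  cat <- list(entries = df,
              n_reference = sum(df$source == "reference"),
              n_non_reference = sum(df$source == "non_reference"))
  class(cat) <- "rc_catalog"
  cat
}

#' @export
print.rc_catalog <- function(x, ...) {
  cat(sprintf("<rc_catalog> %d RC-L1s (%d reference + %d non-reference)\n",
              nrow(x$entries), x$n_reference, x$n_non_reference))
  invisible(x)
}

#' Flag catalog members in a locus registry
#'
#' Sets `rc_flag` by `locus_id` match against the catalog; every other field
#' is left untouched. Loci absent from the catalog get `rc_flag = FALSE`.
#'
#' @param loci `l1_loci` table. @param catalog `rc_catalog`.
#' @return the registry with `rc_flag` updated.
#' @export
annotate_rc <- function(loci, catalog) {
  stopifnot(inherits(catalog, "rc_catalog"))
  loci$rc_flag <- loci$locus_id %in% catalog$entries$locus_id
  message(sprintf("annotate_rc: %d of %d loci are in the RC catalog",
                  sum(loci$rc_flag), nrow(loci)))
  loci
}

# ---- phenotypes -----------------------------------------------------------

#' Read / validate the phenotype table
#'
#' Tab-separated with header. Columns: `sample_id`, `diagnosis` (NNC, ALS,
#' ALSND, other_MND, other_neuro), `sex` (male/female), `age_years` (controls:
#' age at collection; cases: age at symptom onset), `age_at_onset_years`,
#' `site_of_onset`, `survival_months`, `event_observed` (FALSE = censored at
#' last follow-up), `seq_prep` (sequencing-preparation batch), and
#' `european_fraction` in `[0, 1]`.
#'
#' @param path phenotype TSV.
#' @return validated data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_phenotypes(df)
}

#' @rdname read_phenotypes
#' @param df a phenotype data.frame to validate in place.
#' @export
validate_phenotypes <- function(df) {
  need <- c("sample_id", "diagnosis", "sex", "age_years",
            "age_at_onset_years", "site_of_onset", "survival_months",
            "event_observed", "seq_prep", "european_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id", call. = FALSE)
  if (!all(df$diagnosis %in% DIAGNOSES))
    stop("invalid diagnosis values", call. = FALSE)
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be male/female", call. = FALSE)
  if (any(df$survival_months <= 0, na.rm = TRUE))
    stop("survival_months must be > 0 when present", call. = FALSE)
  onset_ok <- is.na(df$age_at_onset_years) | df$diagnosis %in% c("ALS", "ALSND")
  if (!all(onset_ok))
    stop("age_at_onset only allowed for ALS/ALSND", call. = FALSE)
  if (any(df$european_fraction < 0 | df$european_fraction > 1, na.rm = TRUE))
    stop("european_fraction must be in [0,1]", call. = FALSE)
  df$event_observed <- as.logical(df$event_observed)
  df
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- expression -----------------------------------------------------------

#' Read / write an expression matrix
#'
#' Transcripts x samples TSV (first column `transcript_id`), one file per
#' tissue. The tissue label travels as an attribute.
#'
#' @param path TSV file.
#' @param tissue `"medial_motor_cortex"` or `"lateral_motor_cortex"`.
#' @return numeric matrix (transcripts x samples) with attribute `tissue`.
#' @export
read_expression_matrix <- function(path,
                                   tissue = c("medial_motor_cortex",
                                              "lateral_motor_cortex")) {
  tissue <- match.arg(tissue)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyNA(df$transcript_id)) stop("missing transcript ids", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$transcript_id
  storage.mode(m) <- "double"
  attr(m, "tissue") <- tissue
  m
}

#' @rdname read_expression_matrix
#' @param expr matrix to write (transcripts x samples).
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(transcript_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
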