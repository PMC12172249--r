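#' Synthetic-cohort configuration
#'
#' Defaults emulate the structure of a large ALS whole-genome consortium
#' cohort: 320 non-neurological controls and 2,653 ALS/ALSND cases of >90%
#' European ancestry (plus a few excluded-by-design samples so cohort
#' selection is exercised); 205 reference and 2,598 non-reference polymorphic
#' L1 loci with a bimodal insertion-allele-frequency spectrum (89.3% of
#' reference vs 5.7% of non-reference loci common at IAF >= 0.1); 93
#' polymorphic RC loci of which 3 are X-linked and 1 carries >5% missing
#' genotypes, leaving 89 burden loci; a case-control burden shift of 0.40
#' alleles induced by tilting case IAFs at the burden loci; one rare
#' (IAF 0.017) onset-modifier locus with a -6.55-year carrier effect on a
#' 59.2-year baseline; Weibull survival with censoring at last follow-up;
#' and planted eQTL effects in two motor-cortex expression matrices.
#'
#' @param ... overrides for any default listed below.
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_controls = 320L,
    n_cases = 2653L,
    n_extra_non_european = 20L,
    n_extra_other_mnd = 20L,
    n_extra_other_neuro = 20L,
    n_reference_loci = 205L,
    n_non_reference_loci = 2598L,
    rc_reference = 34L,           # RC loci among reference loci
    rc_non_reference = 59L,       # RC loci among non-reference loci (93 total)
    rc_x_linked = 3L,
    rc_high_missing = 1L,
    catalog_reference_total = 102L,
    catalog_non_reference_total = 177L,
    frac_common_reference = 0.893,
    frac_common_non_reference = 0.057,
    common_iaf_range = c(0.1, 0.9),
    rare_iaf_range = c(1e-4, 0.014),  # log-uniform; calibrated so ~500 loci
                                      # clear MAF > 0.01 in the full registry
    rc_iaf_beta = c(0.554, 1.662),    # burden mean ~44.9, sd ~4.8 over 89 loci
    rc_iaf_range = c(0.02, 0.95),
    burden_shift = 0.40,              # case - control mean alleles over 89 loci
    onset_locus = list(iaf = 0.017, carrier_effect = -6.55),
    onset_baseline = 59.2,
    onset_noise_sd = 11,
    cc_plan = NULL,                   # e.g. list(iaf = 0.10, or = 1.5)
    prob_male_controls = 0.491,
    prob_male_cases = 0.601,
    control_age_mean = 57.4,
    control_age_sd = 12,
    missing_age_rate_controls = 43 / 320,
    missing_age_rate_cases = 159 / 2653,
    seq_prep_levels = paste0("prep", 1:4),
    seq_prep_probs = c(0.4, 0.3, 0.2, 0.1),
    site_levels = c("bulbar", "limb"),
    site_probs = c(0.3, 0.7),
    survival = list(shape = 1.3, median_months = 36,
                    loghr_bulbar = 0.4, loghr_onset_per_year = 0.02,
                    loghr_burden = 0),
    followup_months_range = c(6, 120),
    missing_rate = 0.0011,
    high_missing_rate = 0.06,
    expression = list(n_transcripts = 120L, n_samples = 200L, baseline = 10,
                      noise_sd = 1, age_effect = 0.01, sex_effect = 0.2),
    eqtl_plan = list(n_planted = 10L, n_planted_rc = 1L, slope = 1.0),
    rc_only = FALSE,                  # reduced mode: RC + planted loci only
    with_expression = TRUE
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(ov)] <- ov
  structure(cfg, class = "sim_config")
}

# truncated normal by resampling
rtnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

r_loguniform <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

# HWE genotype draw at frequency p for n diploids
r_hwe_geno <- function(n, p) stats::rbinom(n, 2L, p)

# genotype draw tilted by a per-allele odds ratio (case distribution under a
# logistic disease model with additive allelic effect)
r_tilted_geno <- function(n, p, or) {
  w <- c((1 - p)^2, 2 * p * (1 - p) * or, p^2 * or^2)
  sample(0:2, n, replace = TRUE, prob = w / sum(w))
}

#' Simulate a synthetic L1 cohort
#'
#' Generates the full tuple consumed by the pipeline: locus registry,
#' Present-allele genotype matrix, phenotype table, RC catalog, and two
#' motor-cortex expression matrices. Genotypes are drawn under HWE within
#' each group; the case-control burden shift is induced by tilting case IAFs
#' at the 89 autosomal well-genotyped RC loci so that the expected burden
#' difference equals `burden_shift`. Fully reproducible given `seed` (one
#' global seed with derived per-stream substreams).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `loci`, `geno`, `phen`, `catalog`, `expr`, `special`
#'   (designated locus ids and the eQTL plan), `config`, `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  stream <- sample.int(2^31 - 1, 4)   # loci/geno, phenotypes, expression, miss

  # ---- locus registry -----------------------------------------------------
  set.seed(stream[1])
  cfg <- config
  n_ref <- if (cfg$rc_only) cfg$rc_reference else cfg$n_reference_loci
  # rc_only keeps two free non-RC slots for the planted onset/case-control loci
  n_non <- if (cfg$rc_only) cfg$rc_non_reference + 2L else
    cfg$n_non_reference_loci
  n_loci <- n_ref + n_non
  source <- rep(c("reference", "non_reference"), c(n_ref, n_non))
  chrom <- as.character(sample(1:22, n_loci, replace = TRUE))
  pos <- sample.int(2.4e8, n_loci)

  rc_flag_true <- logical(n_loci)
  rc_ref_idx <- seq_len(cfg$rc_reference)
  rc_non_idx <- n_ref + seq_len(cfg$rc_non_reference)
  rc_flag_true[c(rc_ref_idx, rc_non_idx)] <- TRUE
  # 3 X-linked RC loci (placed among the non-reference RC loci)
  x_idx <- rc_non_idx[seq_len(cfg$rc_x_linked)]
  chrom[x_idx] <- "X"
  # 1 RC locus with high missingness (autosomal, non-reference)
  hm_idx <- rc_non_idx[cfg$rc_x_linked + seq_len(cfg$rc_high_missing)]
  burden_idx <- setdiff(which(rc_flag_true), c(x_idx, hm_idx))

  # IAF spectrum
  p_ctrl <- numeric(n_loci)
  is_rc <- rc_flag_true
  common_frac <- ifelse(source == "reference", cfg$frac_common_reference,
                        cfg$frac_common_non_reference)
  is_common <- stats::runif(n_loci) < common_frac
  p_ctrl[is_common] <- stats::runif(sum(is_common), cfg$common_iaf_range[1],
                                    cfg$common_iaf_range[2])
  p_ctrl[!is_common] <- r_loguniform(sum(!is_common), cfg$rare_iaf_range)
  # RC IAFs on a quantile grid of the Beta spectrum (stratified rather than
  # i.i.d.) so the expected burden is stable across seeds; assignment to loci
  # is random
  n_rc <- sum(is_rc)
  rc_grid <- stats::qbeta((seq_len(n_rc) - 0.5) / n_rc, cfg$rc_iaf_beta[1],
                          cfg$rc_iaf_beta[2])
  rc_grid <- pmin(pmax(rc_grid, cfg$rc_iaf_range[1]), cfg$rc_iaf_range[2])
  p_ctrl[is_rc] <- sample(rc_grid)

  # planted special loci (non-reference, non-RC)
  free_non <- setdiff(n_ref + seq_len(n_non), which(rc_flag_true))
  onset_idx <- free_non[1]
  p_ctrl[onset_idx] <- cfg$onset_locus$iaf
  cc_idx <- NA_integer_
  if (!is.null(cfg$cc_plan)) {
    cc_idx <- free_non[2]
    p_ctrl[cc_idx] <- cfg$cc_plan$iaf
  }

  loci <- locus_table(
    locus_id = make_locus_id(chrom, pos, source),
    chrom = chrom, pos = pos, source = source, rc_flag = FALSE,
    split_reads = ifelse(source == "non_reference",
                         2L + stats::rpois(n_loci, 4), NA_integer_),
    assess_score = ifelse(source == "non_reference",
                          sample(3:5, n_loci, replace = TRUE), NA_integer_),
    caller_filter = "PASS")

  # case IAF tilt at the burden loci so E[case - control burden] = shift
  tilt <- cfg$burden_shift / (2 * length(burden_idx))
  p_case <- p_ctrl
  p_case[burden_idx] <- p_ctrl[burden_idx] + tilt
  if (any(p_case > 0.995)) {
    max_shift <- 2 * length(burden_idx) *
      min(0.995 - p_ctrl[burden_idx])
    stop(sprintf("burden_shift unreachable; maximum achievable ~ %.3f",
                 max_shift), call. = FALSE)
  }

  # ---- samples and genotypes ---------------------------------------------
  n_extra <- cfg$n_extra_non_european + cfg$n_extra_other_mnd +
    cfg$n_extra_other_neuro
  n_samp <- cfg$n_controls + cfg$n_cases + n_extra
  sample_id <- sprintf("S%05d", seq_len(n_samp))
  grp <- rep(c("control", "case", "extra"),
             c(cfg$n_controls, cfg$n_cases, n_extra))
  i_ctrl <- which(grp == "control"); i_case <- which(grp == "case")
  i_extra <- which(grp == "extra")

  geno <- matrix(NA_integer_, n_samp, n_loci,
                 dimnames = list(sample_id, loci$locus_id))
  for (j in seq_len(n_loci)) {
    g <- integer(n_samp)
    g[i_ctrl] <- r_hwe_geno(length(i_ctrl), p_ctrl[j])
    g[i_extra] <- r_hwe_geno(length(i_extra), p_ctrl[j])
    if (!is.na(cc_idx) && j == cc_idx) {
      g[i_case] <- r_tilted_geno(length(i_case), p_ctrl[j], cfg$cc_plan$or)
    } else {
      g[i_case] <- r_hwe_geno(length(i_case), p_case[j])
    }
    geno[, j] <- g
  }

  # ---- phenotypes ---------------------------------------------------------
  set.seed(stream[2])
  diagnosis <- character(n_samp)
  diagnosis[i_ctrl] <- "NNC"
  diagnosis[i_case] <- sample(c("ALS", "ALSND"), length(i_case), TRUE,
                              prob = c(0.9, 0.1))
  diagnosis[i_extra] <- rep(c("ALS", "other_MND", "other_neuro"),
                            c(cfg$n_extra_non_european, cfg$n_extra_other_mnd,
                              cfg$n_extra_other_neuro))
  european <- stats::runif(n_samp, 0.91, 1)
  european[i_extra[seq_len(cfg$n_extra_non_european)]] <-
    stats::runif(cfg$n_extra_non_european, 0.2, 0.9)
  sex <- ifelse(stats::runif(n_samp) <
                  ifelse(grp == "control", cfg$prob_male_controls,
                         cfg$prob_male_cases),
                "male", "female")
  seq_prep <- sample(cfg$seq_prep_levels, n_samp, TRUE, cfg$seq_prep_probs)

  onset_carrier <- geno[, onset_idx] > 0
  onset_carrier[is.na(onset_carrier)] <- FALSE
  is_case_like <- grp != "control" & diagnosis %in% c("ALS", "ALSND")
  onset <- rep(NA_real_, n_samp)
  onset[is_case_like] <- rtnorm(
    sum(is_case_like),
    cfg$onset_baseline, cfg$onset_noise_sd, 12, 90) +
    cfg$onset_locus$carrier_effect * onset_carrier[is_case_like]
  onset <- pmax(onset, 12)

  age <- rep(NA_real_, n_samp)
  age[i_ctrl] <- rtnorm(length(i_ctrl), cfg$control_age_mean,
                        cfg$control_age_sd, 17, 90)
  age[is_case_like] <- onset[is_case_like]
  age[i_ctrl][stats::runif(length(i_ctrl)) < cfg$missing_age_rate_controls] <-
    NA_real_
  onset_missing <- is_case_like & stats::runif(n_samp) < cfg$missing_age_rate_cases
  onset[onset_missing] <- NA_real_
  age[onset_missing] <- NA_real_

  site <- rep(NA_character_, n_samp)
  site[is_case_like] <- sample(cfg$site_levels, sum(is_case_like), TRUE,
                               cfg$site_probs)

  # Weibull PH survival for cases, censored at simulated last follow-up
  surv_months <- rep(NA_real_, n_samp)
  event <- rep(NA, n_samp)
  sv <- cfg$survival
  burden_c <- rowSums(geno[, burden_idx, drop = FALSE], na.rm = TRUE)
  lp <- sv$loghr_bulbar * (site == "bulbar") +
    sv$loghr_onset_per_year * (ifelse(is.na(onset), cfg$onset_baseline, onset) -
                                 cfg$onset_baseline) +
    sv$loghr_burden * (burden_c - mean(burden_c))
  lp[is.na(lp)] <- 0
  scale0 <- sv$median_months / log(2)^(1 / sv$shape)
  tt <- scale0 * (-log(stats::runif(n_samp)) / exp(lp))^(1 / sv$shape)
  fu <- stats::runif(n_samp, cfg$followup_months_range[1],
                     cfg$followup_months_range[2])
  surv_months[is_case_like] <- pmax(pmin(tt, fu), 0.25)[is_case_like]
  event[is_case_like] <- (tt <= fu)[is_case_like]

  phen <- validate_phenotypes(data.frame(
    sample_id = sample_id, diagnosis = diagnosis, sex = sex,
    age_years = round(age, 1), age_at_onset_years = round(onset, 1),
    site_of_onset = site, survival_months = round(surv_months, 1),
    event_observed = event, seq_prep = seq_prep,
    european_fraction = round(european, 3), stringsAsFactors = FALSE))

  # ---- missingness --------------------------------------------------------
  set.seed(stream[4])
  protect <- c(onset_idx, cc_idx[!is.na(cc_idx)])
  miss_rate <- rep(cfg$missing_rate, n_loci)
  miss_rate[hm_idx] <- cfg$high_missing_rate
  miss_rate[protect] <- 0
  drop_mask <- matrix(stats::runif(n_samp * n_loci), n_samp, n_loci) <
    rep(miss_rate, each = n_samp)
  geno[drop_mask] <- NA_integer_

  # ---- RC catalog ---------------------------------------------------------
  rc_ids <- loci$locus_id[rc_flag_true]
  rc_src <- loci$source[rc_flag_true]
  n_fill_ref <- cfg$catalog_reference_total - sum(rc_src == "reference")
  n_fill_non <- cfg$catalog_non_reference_total - sum(rc_src == "non_reference")
  if (n_fill_ref < 0 || n_fill_non < 0)
    stop("catalog totals smaller than RC loci in registry", call. = FALSE)
  # catalog members fixed or absent in this cohort: coordinates not in registry
  fill_pos <- sample.int(2.4e8, n_fill_ref + n_fill_non) + 2.5e8
  fill_chrom <- as.character(sample(1:22, n_fill_ref + n_fill_non, TRUE))
  fill_src <- rep(c("reference", "non_reference"), c(n_fill_ref, n_fill_non))
  catalog_df <- data.frame(
    locus_id = c(rc_ids, make_locus_id(fill_chrom, fill_pos, fill_src)),
    source = c(rc_src, fill_src), stringsAsFactors = FALSE)
  catalog <- list(entries = catalog_df,
                  n_reference = sum(catalog_df$source == "reference"),
                  n_non_reference = sum(catalog_df$source == "non_reference"))
  class(catalog) <- "rc_catalog"

  # ---- expression ---------------------------------------------------------
  expr <- NULL
  eqtl_plan <- NULL
  if (cfg$with_expression && !cfg$rc_only) {
    set.seed(stream[3])
    ex <- cfg$expression
    expr_ids <- sample_id[sample.int(cfg$n_controls + cfg$n_cases,
                                     ex$n_samples)]
    # planted eQTL pairs: common non-RC loci plus n_planted_rc RC loci
    common_non_rc <- setdiff(which(!rc_flag_true & p_ctrl >= 0.1), protect)
    n_plain <- cfg$eqtl_plan$n_planted - cfg$eqtl_plan$n_planted_rc
    plant_loci <- c(sample(common_non_rc, n_plain),
                    sample(which(rc_flag_true & p_ctrl >= 0.1),
                           cfg$eqtl_plan$n_planted_rc))
    tx_ids <- sprintf("TX%04d", seq_len(ex$n_transcripts))
    eqtl_plan <- data.frame(
      locus_id = loci$locus_id[plant_loci],
      transcript_id = tx_ids[seq_along(plant_loci)],
      slope = cfg$eqtl_plan$slope, stringsAsFactors = FALSE)
    sexnum <- as.numeric(phen$sex[match(expr_ids, phen$sample_id)] == "male")
    agev <- phen$age_years[match(expr_ids, phen$sample_id)]
    agev[is.na(agev)] <- mean(agev, na.rm = TRUE)
    expr <- list()
    for (tissue in c("medial_motor_cortex", "lateral_motor_cortex")) {
      E <- matrix(stats::rnorm(ex$n_transcripts * ex$n_samples,
                               ex$baseline, ex$noise_sd),
                  ex$n_transcripts, ex$n_samples,
                  dimnames = list(tx_ids, expr_ids))
      E <- E + matrix(ex$age_effect * agev + ex$sex_effect * sexnum,
                      ex$n_transcripts, ex$n_samples, byrow = TRUE)
      for (k in seq_len(nrow(eqtl_plan))) {
        g <- geno[expr_ids, eqtl_plan$locus_id[k]]
        g[is.na(g)] <- mean(g, na.rm = TRUE)
        E[eqtl_plan$transcript_id[k], ] <-
          E[eqtl_plan$transcript_id[k], ] + eqtl_plan$slope[k] * g
      }
      attr(E, "tissue") <- tissue
      expr[[tissue]] <- E
    }
  }

  list(
    loci = loci, geno = validate_geno(geno), phen = phen, catalog = catalog,
    expr = expr,
    special = list(iaf_controls = stats::setNames(p_ctrl, loci$locus_id),
                   iaf_cases = stats::setNames(p_case, loci$locus_id),
                   onset_locus_id = loci$locus_id[onset_idx],
                   cc_locus_id = if (is.na(cc_idx)) NA_character_ else
                     loci$locus_id[cc_idx],
                   high_missing_locus_id = loci$locus_id[hm_idx],
                   x_locus_ids = loci$locus_id[x_idx],
                   burden_locus_ids = loci$locus_id[burden_idx],
                   eqtl_plan = eqtl_plan),
    config = cfg, seed = seed)
}

#' Null variant of the simulator
#'
#' As [simulate_cohort()] with every genotype-linked effect (burden shift,
#' onset carrier effect, survival genotype effect, planted eQTL slopes,
#' planted case-control OR) forced to zero; used by the type-I-error suites.
#'
#' @inheritParams simulate_cohort
#' @export
simulate_null <- function(config = sim_config(), seed = 1L) {
  config$burden_shift <- 0
  config$onset_locus$carrier_effect <- 0
  config$survival$loghr_burden <- 0
  config$eqtl_plan$slope <- 0
  if (!is.null(config$cc_plan)) config$cc_plan$or <- 1
  simulate_cohort(config, seed)
}
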