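# shared per-locus scan machinery: loops loci, applies a fit function to the
# additive Present-allele coding, collects association rows, records skips,
# and Bonferroni-adjusts over the number of non-skipped fits.
scan_loci <- function(geno, base_df, fit_one, scale, model_label) {
  results <- vector("list", ncol(geno))
  skipped <- list()
  for (j in seq_len(ncol(geno))) {
    lid <- colnames(geno)[j]
    g <- geno[base_df$sample_id, j]
    ok <- !is.na(g)
    g_ok <- g[ok]
    if (length(unique(g_ok)) < 2L) {
      skipped[[lid]] <- "monomorphic or < 2 genotype groups"
      next
    }
    row <- tryCatch(fit_one(base_df[ok, , drop = FALSE], g_ok, lid),
                    error = function(e) conditionMessage(e))
    if (is.character(row)) {
      skipped[[lid]] <- row
      next
    }
    results[[j]] <- row
  }
  results <- results[!vapply(results, is.null, logical(1))]
  m <- length(results)
  out <- if (m) do.call(rbind, results) else
    data.frame(locus_id = character(), effect = numeric(),
               p_unadj = numeric(), stringsAsFactors = FALSE)
  out$p_adj <- pmin(1, out$p_unadj * m)
  out <- out[order(out$p_unadj), , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("%s: %d loci fitted (Bonferroni m = %d), %d skipped",
                  model_label, m, m, length(skipped)))
  attr(out, "bonferroni_m") <- m
  attr(out, "skipped") <- data.frame(
    locus_id = as.character(names(skipped)),
    reason = as.character(unlist(skipped, use.names = FALSE)),
    stringsAsFactors = FALSE)
  out
}

#' Per-locus case-control scan
#'
#' For every locus the additive Present-allele count (0/1/2) enters a
#' logistic regression of disease status adjusted for age, sex and
#' sequencing preparation. Reports per-group minor-allele frequencies, the OR
#' per Present allele with Wald 95% CI, and Bonferroni-adjusted p-values over
#' the number of loci actually fitted. Monomorphic loci are skipped with a
#' reason (see `attr(, "skipped")`).
#'
#' @param geno genotype matrix (analysis cohort x MAF-filtered loci).
#' @param phen phenotype table.
#' @return data.frame sorted by unadjusted p: `locus_id`, `minor_allele`,
#'   `maf_nnc`, `maf_case`, OR columns, p-values.
#' @export
casecontrol_scan <- function(geno, phen) {
  df <- phen[phen$sample_id %in% rownames(geno), , drop = FALSE]
  df$status <- is_case(df$diagnosis)
  df <- df[complete_rows(df, c("age_years", "sex", "seq_prep")), , drop = FALSE]
  f_all <- iaf(geno[df$sample_id, , drop = FALSE])
  minor_is_present <- f_all <= 0.5
  nnc_ids <- df$sample_id[df$status == 0]
  case_ids <- df$sample_id[df$status == 1]
  f_nnc <- iaf(geno[nnc_ids, , drop = FALSE])
  f_case <- iaf(geno[case_ids, , drop = FALSE])

  fit_one <- function(d, g, lid) {
    if (length(unique(d$status)) < 2L) stop("single status after missingness")
    X <- cbind(covariate_design(d, c("age_years", "sex", "seq_prep")),
               genotype = g)
    fit <- fit_logistic(d$status, X)
    r <- as_assoc_result(fit, "genotype", lid, scale = "OR",
                         model = "glm: status ~ genotype + age + sex + seq_prep")
    mp <- minor_is_present[[lid]]
    cbind(data.frame(locus_id = lid,
                     minor_allele = if (mp) "P" else "A",
                     maf_nnc = if (mp) f_nnc[[lid]] else 1 - f_nnc[[lid]],
                     maf_case = if (mp) f_case[[lid]] else 1 - f_case[[lid]],
                     stringsAsFactors = FALSE),
          r[, c("effect", "scale", "se", "ci_low", "ci_high", "p_unadj",
                "n_used", "flags")])
  }
  scan_loci(geno, df, fit_one, "OR", "case-control scan")
}

#' Per-locus age-at-onset scan
#'
#' Cases only. Additive genotype in a least-squares model of age at onset
#' with sex, sequencing platform and site of onset as covariates. Also emits
#' carrier-group mean onset ages (Present-carrying, PA or PP, vs homozygous
#' absent AA) for reporting.
#'
#' @inheritParams casecontrol_scan
#' @return data.frame sorted by unadjusted p with effect in years per Present
#'   allele plus `mean_onset_carrier` / `mean_onset_aa`.
#' @export
onset_scan <- function(geno, phen) {
  df <- phen[phen$sample_id %in% rownames(geno) &
               is_case(phen$diagnosis) == 1L, , drop = FALSE]
  df <- df[complete_rows(df, c("age_at_onset_years", "sex", "seq_prep",
                               "site_of_onset")), , drop = FALSE]
  fit_one <- function(d, g, lid) {
    X <- cbind(covariate_design(d, c("sex", "seq_prep", "site_of_onset")),
               genotype = g)
    fit <- fit_linear(d$age_at_onset_years, X)
    r <- as_assoc_result(fit, "genotype", lid, scale = "beta",
                         model = "lm: onset ~ genotype + sex + seq_prep + site")
    carrier <- g > 0
    cbind(data.frame(locus_id = lid,
                     mean_onset_carrier = mean(d$age_at_onset_years[carrier]),
                     mean_onset_aa = mean(d$age_at_onset_years[!carrier]),
                     n_carrier = sum(carrier), n_aa = sum(!carrier),
                     stringsAsFactors = FALSE),
          r[, c("effect", "scale", "se", "ci_low", "ci_high", "p_unadj",
                "n_used", "flags")])
  }
  scan_loci(geno, df, fit_one, "beta", "age-at-onset scan")
}

#' Per-locus survival scan
#'
#' Cases with survival information. Additive genotype in a Cox proportional
#' hazards model (Breslow ties) with sex, sequencing platform, age at onset
#' and site of onset as covariates; individuals still alive are censored at
#' last follow-up. Hazard ratios per Present allele with Wald 95% CI and
#' Bonferroni adjustment over fitted loci.
#'
#' @inheritParams casecontrol_scan
#' @return data.frame sorted by unadjusted p.
#' @export
survival_scan <- function(geno, phen) {
  df <- phen[phen$sample_id %in% rownames(geno) &
               is_case(phen$diagnosis) == 1L, , drop = FALSE]
  df <- df[complete_rows(df, c("survival_months", "event_observed", "sex",
                               "seq_prep", "age_at_onset_years",
                               "site_of_onset")), , drop = FALSE]
  fit_one <- function(d, g, lid) {
    X <- cbind(covariate_design(d, c("sex", "seq_prep", "age_at_onset_years",
                                     "site_of_onset"))[, -1, drop = FALSE],
               genotype = g)
    fit <- fit_coxph(d$survival_months, as.numeric(d$event_observed), X)
    r <- as_assoc_result(fit, "genotype", lid, scale = "HR",
                         model = "coxph: Surv ~ genotype + sex + seq_prep + onset + site")
    cbind(data.frame(locus_id = lid, stringsAsFactors = FALSE),
          r[, c("effect", "scale", "se", "ci_low", "ci_high", "p_unadj",
                "n_used", "flags")])
  }
  scan_loci(geno, df, fit_one, "HR", "survival scan")
}

#' Forest-table export of the top hits of a scan
#' @param scan a scan result data.frame (sorted by `p_unadj`).
#' @param top_n number of rows to export.
#' @return data.frame with `label`, `effect`, `ci_low`, `ci_high`.
#' @export
scan_forest_table <- function(scan, top_n = 5) {
  top <- utils::head(scan, top_n)
  data.frame(label = top$locus_id, effect = top$effect,
             ci_low = top$ci_low, ci_high = top$ci_high,
             stringsAsFactors = FALSE)
}
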