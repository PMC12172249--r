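# covariate design helper: intercept + model.matrix over the named columns
# (characters become factors). Rows must already be complete-case.
covariate_design <- function(df, covars) {
  sub <- df[, covars, drop = FALSE]
  for (v in covars) if (is.character(sub[[v]])) sub[[v]] <- factor(sub[[v]])
  # constant covariates carry no information and would break the contrasts
  constant <- vapply(sub, function(x) length(unique(x)) < 2L, logical(1))
  sub <- sub[, !constant, drop = FALSE]
  stats::model.matrix(~ ., data = sub)
}

complete_rows <- function(df, cols) {
  rowSums(is.na(df[, cols, drop = FALSE])) == 0L
}

is_case <- function(diagnosis) as.integer(diagnosis %in% c("ALS", "ALSND"))

#' Per-genome RC-L1 allele-count burden
#'
#' Row sums of Present-allele counts over the retained burden loci. The input
#' must already be complete-case (see [restrict_complete_individuals()]); a
#' missing value is a contract violation and an error.
#'
#' @param geno genotype matrix restricted to the burden loci.
#' @return data.frame with `sample_id`, `rc_allele_count`, `n_loci_used`.
#' @export
compute_burden <- function(geno) {
  geno <- validate_geno(geno)
  if (anyNA(geno))
    stop("missing genotypes in burden matrix; apply complete-case first",
         call. = FALSE)
  data.frame(sample_id = rownames(geno),
             rc_allele_count = as.integer(rowSums(geno)),
             n_loci_used = ncol(geno),
             stringsAsFactors = FALSE)
}

#' Burden vs disease-status model
#'
#' Default direction regresses the RC allele count on disease status plus
#' covariates (sex, age, sequencing preparation) by least squares, so the
#' effect is in allele units (cases minus controls). The reverse direction
#' (logistic regression of status on the count) is available via `direction`.
#'
#' @param profiles output of [compute_burden()].
#' @param phen phenotype table (analysis cohort).
#' @param direction `"count_on_status"` (default) or `"status_on_count"`.
#' @return one-row association result (see [as_assoc_result()]).
#' @export
burden_disease_model <- function(profiles, phen,
                                 direction = c("count_on_status",
                                               "status_on_count")) {
  direction <- match.arg(direction)
  df <- merge(profiles, phen, by = "sample_id")
  df$status <- is_case(df$diagnosis)
  df <- df[complete_rows(df, c("sex", "age_years", "seq_prep")), , drop = FALSE]
  if (length(unique(df$status)) < 2)
    stop("cohort contains a single disease status", call. = FALSE)
  covars <- covariate_design(df, c("sex", "age_years", "seq_prep"))
  if (direction == "count_on_status") {
    X <- cbind(covars, status = df$status)
    fit <- fit_linear(df$rc_allele_count, X)
    as_assoc_result(fit, "status", "rc_burden_vs_status", scale = "beta",
                    model = "lm: rc_allele_count ~ status + sex + age + seq_prep")
  } else {
    X <- cbind(covars, rc_allele_count = df$rc_allele_count)
    fit <- fit_logistic(df$status, X)
    as_assoc_result(fit, "rc_allele_count", "status_vs_rc_burden", scale = "OR",
                    model = "glm: status ~ rc_allele_count + sex + age + seq_prep")
  }
}

#' Threshold scan of the RC burden
#'
#' For each threshold k the indicator `I(rc_allele_count >= k)` enters a
#' logistic regression of disease status adjusted for sex, age and
#' sequencing preparation. ORs are Bonferroni-adjusted over the thresholds
#' actually fitted; per-group counts and percentages at each k are reported
#' alongside. Thresholds outside the observed count range are recorded as
#' degenerate and skipped.
#'
#' @param profiles output of [compute_burden()].
#' @param phen phenotype table.
#' @param thresholds strictly increasing integer thresholds
#'   (default `43:48`, six categories).
#' @return data.frame (one row per threshold) with counts, percentages, OR,
#'   95% CI, unadjusted and Bonferroni p-values; skipped thresholds carry NA
#'   results and a `"degenerate"` flag.
#' @export
threshold_scan <- function(profiles, phen, thresholds = 43:48) {
  thresholds <- as.integer(thresholds)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing", call. = FALSE)
  df <- merge(profiles, phen, by = "sample_id")
  df$status <- is_case(df$diagnosis)
  df <- df[complete_rows(df, c("sex", "age_years", "seq_prep")), , drop = FALSE]
  covars <- covariate_design(df, c("sex", "age_years", "seq_prep"))
  rows <- lapply(thresholds, function(k) {
    ind <- as.integer(df$rc_allele_count >= k)
    n_ctrl <- sum(df$status == 0)
    n_case <- sum(df$status == 1)
    n_ctrl_ge <- sum(ind == 1 & df$status == 0)
    n_case_ge <- sum(ind == 1 & df$status == 1)
    base <- data.frame(
      threshold = k,
      n_nnc_ge = n_ctrl_ge, pct_nnc_ge = 100 * n_ctrl_ge / n_ctrl,
      n_case_ge = n_case_ge, pct_case_ge = 100 * n_case_ge / n_case,
      stringsAsFactors = FALSE)
    if (all(ind == 0L) || all(ind == 1L)) {
      res <- data.frame(effect = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_unadj = NA_real_,
                        n_used = nrow(df), flags = "degenerate",
                        stringsAsFactors = FALSE)
    } else {
      fit <- fit_logistic(df$status, cbind(covars, ge_k = ind))
      r <- as_assoc_result(fit, "ge_k", paste0("ge_", k), scale = "OR",
                           model = "glm: status ~ I(count>=k) + sex + age + seq_prep")
      res <- r[, c("effect", "ci_low", "ci_high", "p_unadj", "n_used", "flags")]
    }
    cbind(base, res)
  })
  out <- do.call(rbind, rows)
  m <- sum(!is.na(out$p_unadj))
  out$p_adj <- ifelse(is.na(out$p_unadj), NA_real_,
                      pmin(1, out$p_unadj * m))
  attr(out, "bonferroni_m") <- m
  class(out) <- c("threshold_scan", "data.frame")
  out
}

#' Burden vs age-at-onset and survival
#'
#' Cases only. Onset: least-squares regression of age at onset on the RC
#' allele count with sex, sequencing platform and site of onset as
#' covariates. Survival: Cox proportional hazards of survival time (censored
#' individuals at last follow-up) on the count with sex, sequencing platform,
#' age at onset and site of onset as covariates.
#'
#' @param profiles output of [compute_burden()].
#' @param phen phenotype table.
#' @return list with `onset` and `survival` association-result rows.
#' @export
burden_onset_and_survival <- function(profiles, phen) {
  df <- merge(profiles, phen, by = "sample_id")
  df <- df[is_case(df$diagnosis) == 1L, , drop = FALSE]

  on <- df[complete_rows(df, c("age_at_onset_years", "sex", "seq_prep",
                               "site_of_onset")), , drop = FALSE]
  X_on <- cbind(covariate_design(on, c("sex", "seq_prep", "site_of_onset")),
                rc_allele_count = on$rc_allele_count)
  onset_res <- as_assoc_result(
    fit_linear(on$age_at_onset_years, X_on), "rc_allele_count",
    "onset_vs_rc_burden", scale = "beta",
    model = "lm: age_at_onset ~ rc_count + sex + seq_prep + site_of_onset")

  sv <- df[complete_rows(df, c("survival_months", "event_observed", "sex",
                               "seq_prep", "age_at_onset_years",
                               "site_of_onset")), , drop = FALSE]
  X_sv <- cbind(covariate_design(sv, c("sex", "seq_prep", "age_at_onset_years",
                                       "site_of_onset"))[, -1, drop = FALSE],
                rc_allele_count = sv$rc_allele_count)
  surv_res <- as_assoc_result(
    fit_coxph(sv$survival_months, as.numeric(sv$event_observed), X_sv),
    "rc_allele_count", "survival_vs_rc_burden", scale = "HR",
    model = "coxph: Surv ~ rc_count + sex + seq_prep + onset + site_of_onset")

  list(onset = onset_res, survival = surv_res)
}

#' Forest-plot-ready table from a threshold scan
#' @param scan a `threshold_scan` result.
#' @return data.frame with `label`, `effect`, `ci_low`, `ci_high`.
#' @export
threshold_forest_table <- function(scan) {
  data.frame(label = sprintf(">=%d", scan$threshold),
             effect = scan$effect, ci_low = scan$ci_low,
             ci_high = scan$ci_high, stringsAsFactors = FALSE)
}
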