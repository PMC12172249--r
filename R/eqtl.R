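#' Additive linear eQTL scan
#'
#' Every (locus, transcript) pair within a tissue is tested with an additive
#' linear model of normalized expression on the Present-allele count with age
#' and sex as covariates; no cis-window restriction is applied (trans pairs
#' included). P-values are Benjamini-Hochberg adjusted within each tissue.
#' The scan is computed by residualizing expression and genotype on the
#' covariates (Frisch-Waugh), which yields slopes, SEs and p-values identical
#' to a stand-alone least-squares fit per pair. Missing genotypes are
#' mean-imputed per locus before residualization; zero-variance transcripts
#' and monomorphic loci are skipped with a reason.
#'
#' @param geno genotype matrix (samples x loci).
#' @param expr_list named list of expression matrices (transcripts x samples)
#'   as returned by [read_expression_matrix()]; names are tissue labels.
#' @param phen phenotype table (needs `age_years`, `sex`).
#' @param fdr_threshold significance threshold on the FDR (default 0.05).
#' @return data.frame with `locus_id`, `transcript_id`, `tissue`, `slope`,
#'   `se`, `p_unadj`, `fdr`, `significant`; skip reasons in
#'   `attr(, "skipped")`.
#' @export
eqtl_scan <- function(geno, expr_list, phen, fdr_threshold = 0.05) {
  stopifnot(is.list(expr_list), length(names(expr_list)) == length(expr_list))
  out <- list()
  skipped <- list()
  for (tissue in names(expr_list)) {
    expr <- expr_list[[tissue]]
    ph <- phen[complete_rows(phen, c("age_years", "sex")), , drop = FALSE]
    ids <- Reduce(intersect, list(colnames(expr), rownames(geno),
                                  ph$sample_id))
    if (length(ids) < 10)
      stop("fewer than 10 samples shared across genotype/expression/phenotype",
           call. = FALSE)
    ph <- ph[match(ids, ph$sample_id), , drop = FALSE]
    E <- t(expr[, ids, drop = FALSE])                    # samples x transcripts
    G <- geno[ids, , drop = FALSE]
    n <- length(ids)

    # mean-impute missing genotypes per locus
    G <- apply(G, 2, function(g) {
      g <- as.numeric(g)
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      g
    })
    rownames(G) <- ids

    mono <- apply(G, 2, stats::var) < .Machine$double.eps
    zerovar <- apply(E, 2, stats::var) < .Machine$double.eps
    for (l in colnames(G)[mono])
      skipped[[paste(tissue, l, sep = ":")]] <- "monomorphic locus"
    for (tr in colnames(E)[zerovar])
      skipped[[paste(tissue, tr, sep = ":")]] <- "zero-variance transcript"
    G <- G[, !mono, drop = FALSE]
    E <- E[, !zerovar, drop = FALSE]
    if (!ncol(G) || !ncol(E)) next

    C <- covariate_design(ph, c("age_years", "sex"))
    q <- ncol(C)
    qrC <- qr(C)
    Gr <- G - qr.fitted(qrC, G)
    Er <- E - qr.fitted(qrC, E)
    ssg <- colSums(Gr^2)
    sse <- colSums(Er^2)
    num <- crossprod(Gr, Er)                             # loci x transcripts
    slope <- num / ssg
    df_resid <- n - q - 1L
    rss <- pmax(sweep(-slope * num, 2, sse, `+`), 0)
    se <- sqrt(rss / df_resid / ssg)
    tstat <- slope / se
    p <- 2 * stats::pt(-abs(tstat), df_resid)
    res <- data.frame(
      locus_id = rep(rownames(num), times = ncol(num)),
      transcript_id = rep(colnames(num), each = nrow(num)),
      tissue = tissue,
      slope = as.vector(slope),
      se = as.vector(se),
      p_unadj = as.vector(p),
      stringsAsFactors = FALSE)
    res$fdr <- bh_fdr(res$p_unadj)                       # within tissue
    out[[tissue]] <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(locus_id = character(),
                                      transcript_id = character(),
                                      tissue = character(), slope = numeric(),
                                      se = numeric(), p_unadj = numeric(),
                                      fdr = numeric())
  res$significant <- res$fdr < fdr_threshold
  rownames(res) <- NULL
  attr(res, "skipped") <- data.frame(
    key = as.character(names(skipped)),
    reason = as.character(unlist(skipped, use.names = FALSE)),
    stringsAsFactors = FALSE)
  res
}

#' Loci acting as eQTLs
#'
#' A locus counts once as "an eQTL" if it is FDR-significant for at least one
#' transcript in at least one tissue.
#' @param eqtl_results output of [eqtl_scan()].
#' @return character vector of locus ids.
#' @export
eqtl_significant_loci <- function(eqtl_results) {
  unique(eqtl_results$locus_id[eqtl_results$significant])
}

#' RC-enrichment test among eQTL loci
#'
#' Builds the 2x2 table (RC vs non-RC) x (eQTL vs not) over all tested loci
#' and applies the two-sided Fisher exact test. Proportions are reported with
#' explicit denominators: `proportion_rc` is the share of RC loci acting as
#' eQTLs and `proportion_all` the share of all tested loci doing so. An empty
#' eQTL set returns p = 1 with zero proportions.
#'
#' @param eqtl_loci character vector of eQTL locus ids.
#' @param all_loci character vector of all tested locus ids.
#' @param rc_flags logical vector parallel to `all_loci`.
#' @return list with `proportion_rc`, `proportion_all`, `p`, `table`.
#' @export
rc_enrichment <- function(eqtl_loci, all_loci, rc_flags) {
  stopifnot(length(rc_flags) == length(all_loci))
  if (!all(eqtl_loci %in% all_loci))
    stop("eqtl_loci must be a subset of all_loci", call. = FALSE)
  is_eqtl <- all_loci %in% eqtl_loci
  tab <- rbind(rc = c(eqtl = sum(rc_flags & is_eqtl),
                      not_eqtl = sum(rc_flags & !is_eqtl)),
               non_rc = c(eqtl = sum(!rc_flags & is_eqtl),
                          not_eqtl = sum(!rc_flags & !is_eqtl)))
  prop_rc <- if (sum(rc_flags)) sum(rc_flags & is_eqtl) / sum(rc_flags) else 0
  prop_all <- if (length(all_loci)) sum(is_eqtl) / length(all_loci) else 0
  p <- if (!length(eqtl_loci)) 1 else fisher_exact_2x2(tab)
  list(proportion_rc = prop_rc, proportion_all = prop_all, p = p, table = tab)
}
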