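#' Model fit container
#'
#' Lightweight container returned by [fit_linear()], [fit_logistic()] and
#' [fit_coxph()]. Holds coefficients, standard errors, the (partial)
#' log-likelihood, the variance-covariance matrix, a convergence flag and any
#' diagnostic flags raised during fitting (e.g. `"separation"`,
#' `"firth_fallback"`, `"monotone_likelihood"`).
#'
#' @param coefficients named numeric vector of estimates.
#' @param se named numeric vector of standard errors.
#' @param loglik log-likelihood at the estimates.
#' @param vcov variance-covariance matrix of the estimates.
#' @param converged logical.
#' @param n number of observations used.
#' @param flags character vector of diagnostic flags.
#' @return An object of class `l1_fit`.
#' @keywords internal
new_l1_fit <- function(coefficients, se, loglik, vcov, converged, n,
                       flags = character()) {
  structure(
    list(coefficients = coefficients, se = se, loglik = loglik, vcov = vcov,
         converged = converged, n = n, flags = flags),
    class = "l1_fit"
  )
}

#' @export
print.l1_fit <- function(x, ...) {
  cat("<l1_fit> n =", x$n, if (!x$converged) "(NOT converged)", "\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se)
  print(tab, ...)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

check_design <- function(X, n_min = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.numeric(X)) stop("design matrix must be numeric", call. = FALSE)
  if (anyNA(X)) stop("design matrix contains missing values", call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  X
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact two-sided test of Hardy-Weinberg genotype proportions conditional on
#' the observed allele counts (the standard "SNP-HWE" formulation): the p-value
#' is the sum, over all heterozygote counts compatible with the allele counts,
#' of the conditional probabilities that do not exceed the probability of the
#' observed configuration. No mid-p correction is applied.
#'
#' @param n_hom_absent count of homozygous insertion-absent individuals.
#' @param n_het count of heterozygous individuals.
#' @param n_hom_present count of homozygous insertion-present individuals.
#' @return The exact p-value, in (0, 1].
#' @examples
#' hwe_exact_test(5, 0, 0)        # monomorphic: p = 1
#' hwe_exact_test(1469, 138, 5)
#' @export
hwe_exact_test <- function(n_hom_absent, n_het, n_hom_present) {
  counts <- c(n_hom_absent, n_het, n_hom_present)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped individual required", call. = FALSE)
  n_minor <- min(2L * counts[3L] + counts[2L], 2L * counts[1L] + counts[2L])
  if (n_minor == 0L) return(1)
  # heterozygote counts share the parity of the minor-allele count
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  hom_minor <- (n_minor - hets) / 2L
  hom_major <- n - hets - hom_minor
  # log conditional probability of each configuration given allele counts
  logp <- lfactorial(n) - lfactorial(hets) - lfactorial(hom_minor) -
    lfactorial(hom_major) + hets * log(2) +
    lfactorial(n_minor) + lfactorial(2L * n - n_minor) - lfactorial(2L * n)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[hets == counts[2L]]
  if (length(obs) != 1L)
    stop("observed heterozygote count incompatible with allele counts",
         call. = FALSE)
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Ordinary least-squares fit
#'
#' Least-squares coefficients with classical standard errors and the Gaussian
#' log-likelihood. A rank-deficient design is an error naming the collinear
#' columns.
#'
#' @param y numeric response vector.
#' @param X numeric design matrix (include an intercept column if wanted).
#' @return An [new_l1_fit()] object.
#' @export
fit_linear <- function(y, X) {
  X <- check_design(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  if (anyNA(y)) stop("y contains missing values", call. = FALSE)
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("need more observations than coefficients", call. = FALSE)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  R <- qr.R(fit$qr)
  xtx_inv <- chol2inv(R)
  # undo the QR pivot so vcov rows/cols follow the input column order
  piv <- fit$qr$pivot
  vcov <- matrix(NA_real_, p, p)
  vcov[piv, piv] <- xtx_inv * sigma2
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  sigma2_ml <- rss / n
  loglik <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)
  new_l1_fit(beta[colnames(X)], se, loglik, vcov, TRUE, n)
}

#' Logistic regression by maximum likelihood with Firth fallback
#'
#' Fits a binomial GLM by iteratively reweighted least squares. If separation
#' is detected (non-convergence or any coefficient diverging beyond 15 in
#' absolute value) and `firth = TRUE`, the model is refitted with Firth's
#' penalized likelihood (Jeffreys-prior penalty) and the fit is flagged with
#' `"separation"` and `"firth_fallback"`.
#'
#' @param y 0/1 response vector.
#' @param X numeric design matrix.
#' @param firth refit with the Firth penalty when separation is detected?
#' @return An [new_l1_fit()] object.
#' @export
fit_logistic <- function(y, X, firth = TRUE) {
  X <- check_design(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  if (all(y == 0) || all(y == 1)) stop("degenerate outcome", call. = FALSE)
  n <- length(y)
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  ))
  beta <- fit$coefficients
  separated <- !fit$converged || any(abs(beta) > 15)
  if (separated && firth) {
    ff <- firth_logistic(y, X)
    ff$flags <- union(ff$flags, c("separation", "firth_fallback"))
    return(ff)
  }
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  loglik <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  flags <- if (separated) "separation" else character()
  new_l1_fit(beta, se, loglik, vcov, fit$converged, n, flags)
}

# Firth-penalized logistic regression: Newton iterations on the modified
# score U*(b) = X'(y - mu + h (1/2 - mu)), h the leverages under the working
# weights; penalized loglik adds 0.5 log det X'WX.
firth_logistic <- function(y, X, max_iter = 200, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen_ll <- function(b) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    info <- crossprod(X * sqrt(w))
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(info)$modulus
  }
  ll_old <- pen_ll(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    info_inv <- solve(info)
    h <- rowSums((XW %*% info_inv) * XW)
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- drop(info_inv %*% score)
    # step-halving on the penalized likelihood
    fac <- 1
    repeat {
      beta_new <- beta + fac * step
      ll_new <- pen_ll(beta_new)
      if (is.finite(ll_new) && (ll_new >= ll_old - 1e-10 || fac < 1e-4)) break
      fac <- fac / 2
    }
    beta <- beta_new
    if (max(abs(score)) < tol || abs(ll_new - ll_old) < 1e-12) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(X * sqrt(w))
  vcov <- solve(info)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  new_l1_fit(beta, sqrt(diag(vcov)), as.numeric(ll_old), vcov, converged,
             length(y), "firth")
}

#' Cox proportional hazards fit
#'
#' Maximizes the Cox partial likelihood with Breslow handling of tied event
#' times (via the survival package). Censored observations contribute to risk
#' sets only. A monotone partial likelihood (infinite coefficient) is flagged
#' `"monotone_likelihood"` rather than being an error.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicator (0 = censored at `time`).
#' @param X numeric design matrix (no intercept).
#' @return An [new_l1_fit()] object; hazard ratios are `exp(coefficients)`.
#' @export
fit_coxph <- function(time, event, X) {
  X <- check_design(X)
  time <- as.numeric(time); event <- as.numeric(event)
  if (any(time <= 0)) stop("all times must be > 0", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  if (sum(event) < 1) stop("no events observed", call. = FALSE)
  flags <- character()
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ X, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        flags <<- union(flags, "monotone_likelihood")
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  vcov <- stats::vcov(fit)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  new_l1_fit(beta, sqrt(diag(vcov)), fit$loglik[2L], vcov,
             length(flags) == 0L, length(time), flags)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value obtained by summing the hypergeometric probabilities of
#' all tables (with the observed margins) whose probability does not exceed
#' that of the observed table.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2", call. = FALSE)
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers", call. = FALSE)
  if (sum(tab) == 0) return(1)
  stats::fisher.test(tab)$p.value
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' Cross-product odds ratio for a 2x2 table with a Woolf (log-scale Wald)
#' confidence interval. When any cell is zero, 0.5 is added to every cell
#' (Haldane-Anscombe) and the result is flagged.
#'
#' @param tab 2x2 matrix; rows = group, columns = outcome.
#' @return list with `or`, `ci_low`, `ci_high`, `flags`.
#' @export
odds_ratio_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2", call. = FALSE)
  if (anyNA(tab) || any(tab < 0)) stop("cells must be non-negative", call. = FALSE)
  flags <- character()
  if (any(tab == 0)) {
    tab <- tab + 0.5
    flags <- "haldane_anscombe"
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  se <- sqrt(sum(1 / tab))
  list(or = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       flags = flags)
}

#' Bonferroni adjustment
#'
#' @param p vector of p-values.
#' @param m family size (defaults to `length(p)`).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stop("family size m must be >= length(p)", call. = FALSE)
  pmin(1, p * m)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p vector of p-values.
#' @return step-up adjusted values (monotone in rank, capped at 1).
#' @export
bh_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Assemble an association-result row
#'
#' Extracts one coefficient from an `l1_fit` into the standard result row used
#' by every scan: effect (optionally exponentiated to an OR/HR), Wald 95% CI,
#' unadjusted and adjusted p-values.
#'
#' @param fit an `l1_fit`.
#' @param term name of the coefficient to report.
#' @param test_id identifier for the test.
#' @param scale `"beta"` (reported as-is), `"OR"` or `"HR"` (exponentiated).
#' @param model free-text model label.
#' @param m_family Bonferroni family size (NA to defer adjustment).
#' @return one-row data.frame.
#' @export
as_assoc_result <- function(fit, term, test_id, scale = c("beta", "OR", "HR"),
                            model = "", m_family = NA_real_) {
  scale <- match.arg(scale)
  b <- fit$coefficients[[term]]
  se <- fit$se[[term]]
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  lo <- b - 1.96 * se
  hi <- b + 1.96 * se
  if (scale != "beta") {
    eff <- exp(b); lo <- exp(lo); hi <- exp(hi)
  } else eff <- b
  data.frame(
    test_id = test_id,
    effect = eff,
    scale = scale,
    se = se,
    ci_low = lo,
    ci_high = hi,
    p_unadj = p,
    p_adj = if (is.na(m_family)) NA_real_ else min(1, p * m_family),
    n_used = fit$n,
    model = model,
    flags = paste(fit$flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}
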