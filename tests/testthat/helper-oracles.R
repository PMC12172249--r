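# Independent brute-force oracles used to validate the statistical kernels.
# These deliberately use different code paths (choose()-based enumeration,
# general-purpose optimisers) than the implementations they check.

# Exact HWE p-value by full enumeration of genotype configurations with the
# observed allele counts, probabilities from binomial coefficients.
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_minor <- min(2 * n_bb + n_ab, 2 * n_aa + n_ab)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  probs <- vapply(hets, function(b) {
    c_min <- (n_minor - b) / 2
    a_maj <- n - b - c_min
    exp(lchoose(n, c_min) + lchoose(n - c_min, b) + b * log(2) -
          lchoose(2 * n, n_minor))
  }, numeric(1))
  probs <- probs / sum(probs)
  obs <- probs[hets == n_ab]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

# Two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (n == 0) return(1)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Logistic log-likelihood maximized by a general-purpose optimizer.
oracle_logistic <- function(y, X) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}

# Cox partial likelihood (Breslow) written out term by term and maximized
# numerically. Suitable only for tiny n.
oracle_coxph <- function(time, event, X) {
  npll <- function(b) {
    eta <- drop(X %*% b)
    ll <- 0
    for (t_ev in sort(unique(time[event == 1]))) {
      d <- which(time == t_ev & event == 1)
      risk <- which(time >= t_ev)
      ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[risk])))
    }
    -ll
  }
  stats::optim(rep(0, ncol(X)), npll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}

# Normal-equations least squares.
oracle_ols <- function(y, X) drop(solve(crossprod(X), crossprod(X, y)))

# Literal BH step-up recursion.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}
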