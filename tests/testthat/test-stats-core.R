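test_that("HWE exact test matches enumeration and handles edge tables", {
  # monomorphic: only one attainable configuration
  expect_equal(hwe_exact_test(5, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 7), 1)
  # two diploids carrying two minor alleles: het in {0, 2}
  expect_equal(hwe_exact_test(0, 2, 0), oracle_hwe(0, 2, 0), tolerance = 1e-12)
  # realistic cohort-scale table
  expect_equal(hwe_exact_test(1469, 138, 5), oracle_hwe(1469, 138, 5),
               tolerance = 1e-10)
  # random spot-checks across sizes
  set.seed(11)
  for (i in 1:40) {
    n <- sample(1:400, 1)
    g <- as.vector(stats::rmultinom(1, n, prob = c(0.5, 0.3, 0.2)))
    expect_equal(hwe_exact_test(g[1], g[2], g[3]),
                 oracle_hwe(g[1], g[2], g[3]), tolerance = 1e-10)
  }
  expect_error(hwe_exact_test(-1, 0, 2), "non-negative")
})

test_that("linear fit reproduces exact solutions and normal equations", {
  X <- cbind(1, c(1, 2, 3, 4, 5), c(0, 1, 0, 1, 1))
  b_true <- c(2, -1, 0.5)
  y <- drop(X %*% b_true)
  fit <- fit_linear(y, X)
  expect_equal(unname(fit$coefficients), b_true, tolerance = 1e-10)

  y2 <- c(3, 7, 1, 9)
  fit2 <- fit_linear(y2, matrix(1, 4, 1))
  expect_equal(unname(fit2$coefficients), mean(y2))

  set.seed(42)
  X3 <- cbind(1, matrix(rnorm(40), 20, 2))
  y3 <- rnorm(20)
  fit3 <- fit_linear(y3, X3)
  expect_equal(unname(fit3$coefficients), oracle_ols(y3, X3), tolerance = 1e-10)
  # classical SEs against the closed form
  rss <- sum((y3 - X3 %*% fit3$coefficients)^2)
  se_ref <- sqrt(diag(solve(crossprod(X3))) * rss / (20 - 3))
  expect_equal(unname(fit3$se), se_ref, tolerance = 1e-10)

  X_bad <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  colnames(X_bad) <- c("intercept", "a", "b")
  expect_error(fit_linear(rnorm(4), X_bad), "collinear.*b")
})

test_that("logistic MLE matches likelihood-maximization oracle and symmetry", {
  # symmetric two-group data with 50% events in each group: group effect 0
  y <- c(1, 0, 1, 0, 1, 0, 1, 0)
  X <- cbind(1, rep(c(0, 1), each = 4))
  fit <- fit_logistic(y, X)
  expect_equal(unname(fit$coefficients[2]), 0, tolerance = 1e-8)

  set.seed(7)
  X12 <- cbind(1, rnorm(12))
  y12 <- rbinom(12, 1, plogis(0.3 + 0.8 * X12[, 2]))
  if (all(y12 == y12[1])) y12[1] <- 1 - y12[1]
  fit12 <- fit_logistic(y12, X12)
  expect_equal(unname(fit12$coefficients), oracle_logistic(y12, X12),
               tolerance = 1e-6)

  expect_error(fit_logistic(rep(1, 6), cbind(1, rnorm(6))), "degenerate")
})

test_that("separated logistic data triggers flagged Firth fallback", {
  # complete separation on x
  x <- c(-3, -2, -1, -0.5, 0.5, 1, 2, 3)
  y <- as.numeric(x > 0)
  X <- cbind(intercept = 1, x = x)
  fit <- fit_logistic(y, X, firth = TRUE)
  expect_true("separation" %in% fit$flags)
  expect_true("firth_fallback" %in% fit$flags)
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(is.finite(fit$se)))
  expect_true(abs(fit$coefficients["x"]) < 15)
  # without the fallback the raw fit is flagged but returned
  fit_plain <- fit_logistic(y, X, firth = FALSE)
  expect_true("separation" %in% fit_plain$flags)
})

test_that("logistic fit recovers simulated coefficients within 3 SE", {
  set.seed(301)
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    n <- 5000
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.5 + 0.4 * x))
    fit <- fit_logistic(y, cbind(1, x))
    if (abs(fit$coefficients[2] - 0.4) < 3 * fit$se[2]) hits <- hits + 1L
  }
  expect_gte(hits, n_rep - 1L)
})

test_that("Cox fit matches written-out partial likelihood and contracts", {
  # distinct event times, two groups, n = 8, no censoring
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- rep(1, 8)
  X <- cbind(g = c(0, 1, 0, 1, 1, 0, 1, 0))
  fit <- fit_coxph(time, event, X)
  expect_equal(unname(fit$coefficients), oracle_coxph(time, event, X),
               tolerance = 1e-5)

  # identical survival in both groups via paired permuted labels
  t2 <- rep(c(2, 4, 6, 8), 2)
  X2 <- cbind(g = rep(c(0, 1), each = 4))
  fit2 <- fit_coxph(t2, rep(1, 8), X2)
  expect_lt(abs(fit2$coefficients[1]), 1e-6)

  # all censored but one: single event term, still fits
  ev3 <- c(1, rep(0, 7))
  fit3 <- fit_coxph(time, ev3, cbind(x = rnorm(8)))
  expect_true(is.finite(fit3$coefficients[1]))

  expect_error(fit_coxph(time, rep(0, 8), X), "no events")
})

test_that("Cox fit recovers a known log hazard ratio across seeds", {
  set.seed(302)
  hits <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    n <- 400
    g <- rbinom(n, 1, 0.5)
    tt <- rexp(n, rate = exp(log(1.6) * g))
    cens <- runif(n, 0, 3)
    obs <- pmin(tt, cens)
    ev <- as.numeric(tt <= cens)
    fit <- fit_coxph(obs, ev, cbind(g = g))
    if (abs(fit$coefficients[1] - log(1.6)) < 3 * fit$se[1]) hits <- hits + 1L
  }
  expect_gte(hits, n_rep - 1L)
})

test_that("Fisher exact test matches hypergeometric enumeration", {
  # margins (2,2)/(2,2): probabilities 1/6, 4/6, 1/6
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2)), 1)
  set.seed(5)
  for (i in 1:50) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    expect_equal(fisher_exact_2x2(tab), oracle_fisher(tab), tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("odds ratio uses the cross product with Woolf CI", {
  res <- odds_ratio_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$or, 1)
  # rows = group, cols = at-or-above-threshold yes/no
  tab <- matrix(c(111, 177, 1125, 1295), 2, byrow = TRUE)
  expect_equal(odds_ratio_2x2(tab)$or, (111 * 1295) / (177 * 1125),
               tolerance = 1e-12)
  res3 <- odds_ratio_2x2(matrix(c(5, 0, 3, 7), 2))
  expect_true("haldane_anscombe" %in% res3$flags)
  expect_true(is.finite(res3$or) && res3$or > 0)
})

test_that("multiple-testing adjustments follow their definitions", {
  expect_equal(bonferroni(0.003, m = 501), 1)
  expect_equal(bonferroni(0.01, m = 1), 0.01)
  expect_equal(bonferroni(2e-5, m = 501), 0.01002, tolerance = 1e-12)
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
  # already-capped inputs are fixed points and values never exceed 1
  expect_equal(bonferroni(rep(1, 5), m = 10), rep(1, 5))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
})
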