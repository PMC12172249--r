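test_that("evidence filter applies the inclusive >=2 / >=3 / PASS rule", {
  loci <- locus_table(
    locus_id = paste0("NRL1_1_", 1:6 * 100),
    chrom = "1", pos = 1:6 * 100, source = "non_reference",
    split_reads = c(1L, 2L, 4L, 5L, NA, 3L),
    assess_score = c(5L, 3L, 2L, 4L, 3L, NA),
    caller_filter = c("PASS", "PASS", "PASS", "lc", "PASS", "PASS"))
  res <- filter_melt_records(loci)
  # kept: only (2,3,PASS); removed: low SR, low assess, non-PASS, missing ev
  expect_equal(res$loci$locus_id, "NRL1_1_200")
  expect_equal(res$ledger$n_removed, 5)
  expect_match(res$ledger$criterion, "2 missing evidence")

  ref <- locus_table("RL1_2_50", "2", 50, "reference")
  both <- validate_loci(rbind(as.data.frame(loci), as.data.frame(ref)))
  res2 <- filter_melt_records(both)
  expect_true("RL1_2_50" %in% res2$loci$locus_id)  # reference untouched
})

test_that("ledger conservation and chaining are enforced", {
  l <- new_ledger("a", 10L, 3L, 7L, "x")
  l2 <- l1burden:::add_ledger_step(l, "b", 7L, 5L, "y")
  expect_equal(l2$n_in[2], 7)
  expect_error(new_ledger("a", 10L, 3L, 8L, "x"), "n_out")
  expect_error(bind_ledgers(l, new_ledger("c", 99L, 0L, 99L, "z")), "chain")
})

test_that("HWE filter tests controls only, with a strict threshold", {
  phen <- toy_phen(n_ctrl = 50, n_case = 50)
  nnc <- phen$sample_id[phen$diagnosis == "NNC"]
  g <- matrix(0L, 100, 3,
              dimnames = list(phen$sample_id, c("L1", "L2", "L3")))
  # L1: monomorphic in controls -> p = 1, kept
  # L2: extreme het deficit in NNCs (25/0/25)
  g[nnc[1:25], 2] <- 0L; g[nnc[26:50], 2] <- 2L
  # L3: in HWE in controls, wildly out in cases (cases must not matter)
  set.seed(8)
  g[nnc, 3] <- rbinom(50, 2, 0.4)
  g[phen$sample_id[phen$diagnosis == "ALS"], 3] <- 1L
  res <- filter_hwe(g, phen)
  expect_false("L2" %in% colnames(res$geno))
  expect_true(all(c("L1", "L3") %in% colnames(res$geno)))
  expect_lt(res$hwe_p[["L2"]], 1e-6)

  # boundary: a locus at exactly the threshold is kept (strict "<" removal)
  p2 <- res$hwe_p[["L3"]]
  res_eq <- filter_hwe(g[, "L3", drop = FALSE], phen, threshold = p2)
  expect_true("L3" %in% colnames(res_eq$geno))
  res_gt <- filter_hwe(g[, "L3", drop = FALSE], phen,
                       threshold = p2 * (1 + 1e-9))
  expect_false("L3" %in% colnames(res_gt$geno))
})

test_that("MAF filter is strict and counts degenerate loci", {
  phen <- toy_phen(n_ctrl = 50, n_case = 50)
  g <- matrix(0L, 100, 3,
              dimnames = list(phen$sample_id, c("common", "boundary", "gone")))
  set.seed(3)
  g[, 1] <- rbinom(100, 2, 0.77)   # IAF ~0.77 -> MAF ~0.23, kept
  g[1, 2] <- 2L                    # 2/200 alleles -> MAF exactly 0.01
  g[, 3] <- NA_integer_            # all-missing
  res <- filter_maf(g)
  expect_equal(colnames(res$geno), "common")
  expect_match(res$ledger$criterion, "1 all-missing")
  # just above the boundary passes
  g[2, 2] <- 1L                    # 3/200 = 0.015 > 0.01
  res2 <- filter_maf(g[, 2, drop = FALSE])
  expect_equal(ncol(res2$geno), 1)
})

test_that("burden locus filter reproduces the 93 -> 89 accounting", {
  n_samp <- 100
  ids <- sprintf("S%03d", 1:n_samp)
  chrom <- c(rep("1", 89), "X", "X", "X", "5", rep("2", 7))
  rc <- c(rep(TRUE, 93), rep(FALSE, 7))
  loci <- locus_table(
    locus_id = paste0("NRL1_", chrom, "_", 1:100 * 10),
    chrom = chrom, pos = 1:100 * 10, source = "non_reference",
    rc_flag = rc)
  set.seed(5)
  g <- matrix(rbinom(n_samp * 100, 2, 0.3), n_samp, 100,
              dimnames = list(ids, loci$locus_id))
  g[1:6, 93] <- NA_integer_   # the autosomal chr5 RC locus: 6% missing
  res <- filter_rc_for_burden(g, loci)
  expect_equal(ncol(res$geno), 89)
  expect_equal(res$ledger$n_out, c(93, 90, 89))
  expect_false(loci$locus_id[93] %in% colnames(res$geno))
  expect_false(any(c("X") %in% loci$chrom[match(colnames(res$geno),
                                                loci$locus_id)]))
  # exactly 5% missing is kept (strict > 5%)
  g2 <- g; g2[1:6, 93] <- 0L; g2[1:5, 93] <- NA_integer_
  res2 <- filter_rc_for_burden(g2, loci)
  expect_equal(ncol(res2$geno), 90)
  # no RC loci at all: empty matrix, ledger records it
  loci0 <- loci; loci0$rc_flag <- FALSE
  res0 <- filter_rc_for_burden(g, loci0)
  expect_equal(ncol(res0$geno), 0)
  expect_equal(res0$ledger$n_out[1], 0)
})

test_that("complete-case restriction drops samples with any missing call", {
  ids <- sprintf("S%02d", 1:10)
  g <- matrix(1L, 10, 4, dimnames = list(ids, paste0("L", 1:4)))
  g[3, 2] <- NA; g[7, 4] <- NA
  res <- restrict_complete_individuals(g)
  expect_equal(nrow(res$geno), 8)
  expect_false(any(c("S03", "S07") %in% rownames(res$geno)))
  # identity when nothing is missing
  g2 <- matrix(0L, 10, 4, dimnames = list(ids, paste0("L", 1:4)))
  res2 <- restrict_complete_individuals(g2)
  expect_identical(res2$geno, g2)
  expect_equal(res2$ledger$n_removed, 0)
})

test_that("cohort selection uses strict >0.9 European and the diagnosis set", {
  phen <- toy_phen(3, 3)
  phen$european_fraction <- c(0.90, 0.95, 0.91, 0.89, 1.0, 0.95)
  phen$diagnosis <- c("NNC", "NNC", "other_MND", "ALS", "ALS", "ALSND")
  res <- select_analysis_cohort(validate_phenotypes(
    transform(phen, age_at_onset_years = ifelse(diagnosis %in% c("ALS", "ALSND"),
                                                age_at_onset_years, NA))))
  expect_setequal(res$sample_ids, phen$sample_id[c(2, 5, 6)])
  expect_equal(res$ledger$n_removed, 3)
})

test_that("independent locus filters commute and ignore column order", {
  phen <- toy_phen(n_ctrl = 40, n_case = 60)
  loci <- toy_loci(30)
  set.seed(10)
  g <- matrix(rbinom(100 * 30, 2, runif(30, 0.002, 0.5)[rep(1:30, each = 100)]),
              100, 30, dimnames = list(phen$sample_id, loci$locus_id))
  storage.mode(g) <- "integer"
  a <- filter_hwe(filter_maf(g)$geno, phen)$geno
  b <- filter_maf(filter_hwe(g, phen)$geno)$geno
  expect_setequal(colnames(a), colnames(b))
  # permuting input loci leaves the surviving set unchanged
  perm <- sample(ncol(g))
  a2 <- filter_hwe(filter_maf(g[, perm])$geno, phen)$geno
  expect_setequal(colnames(a2), colnames(a))
})
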