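# Fisher exact, chi-square and BH FDR against enumeration and closed-form
# oracles.

# Exhaustive hypergeometric enumeration oracle for the two-sided Fisher
# test (minimum-likelihood convention), using only choose().
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  supp <- max(0, k - n):min(k, m)
  pr <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  pobs <- choose(m, tab[1, 1]) * choose(n, k - tab[1, 1]) /
    choose(m + n, k)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

test_that("Fisher exact matches enumeration on the worked tables", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 7, 7, 3), 2, byrow = TRUE)),
               33052 / 184756, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-12)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)),
               "non-negative")
})

test_that("Fisher exact equals enumeration and base R on random tables", {
  set.seed(17)
  for (i in 1:300) {
    tot <- sample(4:40, 1)
    x <- as.vector(stats::rmultinom(1, tot, runif(4)))
    tab <- matrix(x, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_2x2(tab)
    expect_equal(p, fisher_oracle(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("per-type tests detect planted spectrum differences and pass the null", {
  v <- snv_variants(200)
  ins <- data.frame(chrom = "chr1", pos = 20000L + seq_len(20) * 10L,
                    ref = "A", alt = "AT")
  high <- mk_callset("highland", matrix(1L, 220, 4),
                     rbind(v[1:180, ], ins,
                           data.frame(chrom = "chr1",
                                      pos = 30000L + seq_len(20) * 10L,
                                      ref = "AC", alt = "A")))
  low <- mk_callset("lowland", matrix(1L, 200, 4),
                    rbind(v, data.frame(chrom = "chr1",
                                        pos = 30000L + seq_len(20) * 10L,
                                        ref = "AC", alt = "A"))[-(1:20), ])
  res <- per_type_distribution_test(high, low)
  expect_true(all(c("SNV", "insertion", "deletion") %in%
                    res$per_type$vtype))
  # insertions occur only in highland (20 of 220 vs 0 of 180)
  expect_lt(res$per_type$p[res$per_type$vtype == "insertion"], 0.001)
  # identical spectra: all p = 1
  same <- mk_callset("lowland", matrix(1L, 220, 4),
                     within(rbind(v[1:180, ], ins,
                                  data.frame(chrom = "chr1",
                                             pos = 30000L +
                                               seq_len(20) * 10L,
                                             ref = "AC", alt = "A")),
                            pos <- pos + 1L))
  null_res <- per_type_distribution_test(high, same)
  expect_true(all(null_res$per_type$p >= 0.99))
})

test_that("Pearson chi-square matches the closed form and flags enrichment", {
  expect_equal(pearson_chisq(matrix(c(50, 50, 50, 50), 2))$statistic, 0)
  expect_equal(pearson_chisq(matrix(c(50, 50, 50, 50), 2))$p, 1)
  tab <- matrix(c(30, 70, 10, 90), 2, byrow = TRUE)
  ours <- pearson_chisq(tab)
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  yates <- pearson_chisq(tab, correct = TRUE)
  refy <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  expect_equal(yates$statistic, unname(refy$statistic), tolerance = 1e-12)
  expect_true(pearson_chisq(matrix(c(0, 0, 5, 5), 2))$untestable)
})

test_that("per-chromosome chi-square finds a planted 5x enrichment", {
  set.seed(3)
  mkv <- function(n1, n2) {
    rbind(snv_variants(n1, "chr1", 1000L, 7L),
          snv_variants(n2, "chr2", 1000L, 7L))
  }
  high <- mk_callset("highland", matrix(1L, 700, 4), mkv(500, 200))
  low <- mk_callset("lowland", matrix(1L, 600, 4), mkv(100, 500))
  res <- per_chromosome_chisq(high, low, stratify_by_sex = FALSE)
  expect_true(all(res$significant[res$vtype == "SNV"]))
  # proportional distribution: nothing significant
  high2 <- mk_callset("highland", matrix(1L, 600, 4), mkv(300, 300))
  low2 <- mk_callset("lowland", matrix(1L, 600, 4),
                     within(mkv(300, 300), pos <- pos + 3L))
  res2 <- per_chromosome_chisq(high2, low2, stratify_by_sex = FALSE)
  expect_false(any(res2$significant))
  nr <- nonsignificant_report(res2)
  expect_equal(nr$nonsignificant_chroms, "chr1,chr2")
})

test_that("BH step-up matches the hand computation and p.adjust", {
  expect_equal(bh_fdr(c(0.005, 0.01, 0.02, 0.1)),
               c(0.02, 0.02, 0.08 / 3, 0.1), tolerance = 1e-12)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.03), 0.03)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj <= 1 & adj >= p - 1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Fisher type-vs-rest keeps type-I error at or below nominal", {
  set.seed(77)
  rejections <- 0L
  for (i in 1:1000) {
    n1 <- 60; n2 <- 60
    x1 <- rbinom(1, n1, 0.2); x2 <- rbinom(1, n2, 0.2)
    tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE)
    if (sum(tab[, 1]) == 0) next
    if (fisher_exact_2x2(tab) < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / 1000, 0.07)
})
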