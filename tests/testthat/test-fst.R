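# Weir-Cockerham estimator and the sliding-window scan.

test_that("worked component examples: fixed difference and shared monomorphism", {
  fixed <- wc_fst_site(rep(2L, 10), rep(0L, 10))
  expect_equal(fixed$theta, 1)
  mono <- wc_fst_site(rep(0L, 10), rep(0L, 10))
  expect_false(mono$defined)
  expect_true(is.na(mono$theta))
  expect_error(wc_fst_site(1L, c(0L, 1L)), ">= 2")
  # summary-statistic interface: p = 0.8/0.2, observed het 0.32, n = 10
  comp <- wc_fst_components(0.8, 0.2, 0.32, 0.32, 10, 10)
  orc <- local({   # direct transcription with p/h as given
    r <- 2; n1 <- 10; n2 <- 10; nbar <- 10; nc <- 10
    pbar <- 0.5; s2 <- (10 * 0.09 + 10 * 0.09) / 10; hbar <- 0.32
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / 9)
    b <- (10 / 9) * (pbar * (1 - pbar) - s2 / 2 - (19 / 40) * hbar)
    cc <- hbar / 2
    c(a, b, cc)
  })
  expect_equal(c(comp$a, comp$b, comp$c), orc, tolerance = 1e-12)
  expect_equal(comp$theta, orc[1] / sum(orc), tolerance = 1e-12)
})

test_that("estimator equals the independent oracle on random configurations", {
  set.seed(55)
  for (i in 1:100) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    p <- runif(1, 0.05, 0.95)
    g1 <- rbinom(n1, 2, runif(1, 0, 1) * p + 0.02)
    g2 <- rbinom(n2, 2, p)
    if (sum(g1) + sum(g2) == 0) next
    ours <- wc_fst_site(g1, g2)
    orc <- wc_oracle(g1, g2)
    expect_equal(ours$a, orc$a, tolerance = 1e-10)
    expect_equal(ours$b, orc$b, tolerance = 1e-10)
    expect_equal(ours$c, orc$c, tolerance = 1e-10)
    if (ours$defined) expect_equal(ours$theta, orc$theta,
                                   tolerance = 1e-10)
    # allele-label swap invariance
    sw <- wc_fst_site(2L - g1, 2L - g2)
    if (ours$defined) expect_equal(sw$theta, ours$theta,
                                   tolerance = 1e-10)
  }
})

test_that("theta is calibrated near zero for identical allele frequencies", {
  # large-sample check: 500 haplotypes per population, no divergence
  set.seed(9)
  n_sites <- 400
  p <- runif(n_sites, 0.1, 0.9)
  g1 <- matrix(rbinom(n_sites * 250, 2, p), n_sites)
  g2 <- matrix(rbinom(n_sites * 250, 2, p), n_sites)
  th <- vapply(seq_len(n_sites), function(i)
    wc_fst_site(g1[i, ], g2[i, ])$theta, numeric(1))
  expect_lt(abs(mean(th, na.rm = TRUE)), 0.01)
})

test_that("Balding-Nichols draws hit the target differentiation", {
  set.seed(10)
  p <- runif(2000, 0.2, 0.8)
  theta <- 0.3
  p1 <- bn_draw(p, rep(theta, 2000))
  # Var = theta p (1 - p)
  expect_equal(mean((p1 - p)^2 / (p * (1 - p))), theta, tolerance = 0.05)
})

test_that("window construction follows the half-open convention", {
  w <- make_windows(c(chr1 = 250000), 1e5, 5e4)
  expect_equal(w$start, c(0, 50000, 100000, 150000, 200000))
  expect_equal(w$end, c(1e5, 15e4, 2e5, 25e4, 25e4))
  # contig shorter than the window: single truncated window
  w2 <- make_windows(c(chr1 = 80000), 1e5, 5e4)
  expect_equal(nrow(w2), 1)
  expect_equal(c(w2$start, w2$end), c(0, 80000))
  # sex chromosomes excluded by default; MT always
  w3 <- make_windows(c(chr1 = 2e5, Z = 2e5, W = 1e5, MT = 16500))
  expect_setequal(unique(w3$chrom), "chr1")
  expect_error(make_windows(c(chr1 = 1e5), window = 4e4, step = 5e4),
               "step")
})

test_that("window means equal brute force and respect boundaries", {
  set.seed(12)
  sites <- data.frame(chrom = "chr1",
                      pos = sample.int(250000, 400),
                      a = runif(400), b = runif(400), c = runif(400))
  sites$theta <- sites$a / (sites$a + sites$b + sites$c)
  # shuffle input order; scan must not care
  sites <- sites[sample(nrow(sites)), ]
  w <- window_scan(sites, make_windows(c(chr1 = 250000), 1e5, 5e4))
  for (i in seq_len(nrow(w))) {
    inw <- sites$pos - 1 >= w$start[i] & sites$pos - 1 < w$end[i]
    expect_equal(w$n_snvs[i], sum(inw))
    if (sum(inw) > 0)
      expect_equal(w$mean_theta[i], mean(sites$theta[inw]),
                   tolerance = 1e-12)
  }
  # boundary site at pos = start + window (1-based pos = end + 1)
  bsite <- data.frame(chrom = "chr1", pos = 100001L, a = 1, b = 0, c = 0,
                      theta = 1)
  wb <- window_scan(bsite, make_windows(c(chr1 = 250000), 1e5, 5e4))
  expect_equal(wb$n_snvs, c(0L, 1L, 1L, 0L, 0L))
})

test_that("top-fraction retrieval counts ceil(f n) windows and keeps ties", {
  w <- data.frame(chrom = "chr1", start = 0:99 * 1000,
                  end = 0:99 * 1000 + 1000,
                  window_id = paste0("w", 1:100),
                  n_snvs = 5L, mean_theta = seq(0.01, 1, length.out = 100),
                  ranked = TRUE)
  expect_equal(sum(top_fraction(w, 0.05)$is_top), 5)
  wt <- w[1:10, ]; wt$mean_theta <- 0.5
  expect_equal(sum(top_fraction(wt, 0.05)$is_top), 10)  # all tied
  expect_error(top_fraction(w, 1.5), "fraction")
})

test_that("ratio-of-sums window summary differs but stays consistent", {
  set.seed(21)
  sites <- data.frame(chrom = "chr1", pos = sample.int(1e5, 100),
                      a = runif(100), b = runif(100), c = runif(100))
  sites$theta <- sites$a / (sites$a + sites$b + sites$c)
  w <- make_windows(c(chr1 = 1e5), 1e5, 5e4)
  m1 <- window_scan(sites, w, method = "mean")
  m2 <- window_scan(sites, w, method = "ratio_of_sums")
  expect_equal(m2$mean_theta[1], sum(sites$a) /
                 sum(sites$a + sites$b + sites$c), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(m1$mean_theta[1], m2$mean_theta[1])))
})

test_that("genes are looked up only in top windows", {
  ann <- structure(list(
    contig_lengths = c(chr1 = 3e5),
    genes = data.frame(chrom = "chr1",
                       start = c(10000, 120000, 195000),
                       end = c(20000, 130000, 210000),
                       strand = "+",
                       gene_id = c("gA", "gB", "gC")),
    cds = data.frame()), class = "genome_annotation")
  w <- data.frame(chrom = "chr1", start = c(0, 1e5, 2e5),
                  end = c(1e5, 2e5, 3e5),
                  window_id = c("w1", "w2", "w3"),
                  is_top = c(TRUE, FALSE, TRUE))
  g <- genes_in_windows(w, ann)
  expect_setequal(g$gene_id, c("gA", "gC"))       # gB only in non-top
  # straddling gene listed once with both windows
  w$is_top <- c(TRUE, TRUE, FALSE)
  ann$genes <- rbind(ann$genes,
                     data.frame(chrom = "chr1", start = 95000,
                                end = 105000, strand = "+",
                                gene_id = "gD"))
  g2 <- genes_in_windows(w, ann)
  expect_equal(sum(g2$gene_id == "gD"), 1)
  expect_equal(g2$windows[g2$gene_id == "gD"], "w1,w2")
})
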