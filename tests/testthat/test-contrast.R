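# Population contrast: threshold semantics, monotonicity, partition
# conservation, novelty flagging, mtDNA accounting and validation
# percentages.

test_that("carrier-fraction thresholds include ties and exclude shared variants", {
  v <- snv_variants(3)
  # v1: 3/5 highland, 0/5 lowland; v2: 5/5 vs 1/5; v3: 1/5 vs 0/5
  dos_h <- rbind(c(1, 1, 2, 0, 0), c(1, 1, 1, 2, 1), c(0, 1, 0, 0, 0))
  dos_l <- rbind(rep(0, 5), c(0, 0, 1, 0, 0), rep(0, 5))
  high <- mk_callset("highland", dos_h, v)
  low <- mk_callset("lowland", dos_l[rowSums(dos_l) > 0, , drop = FALSE],
                    v[rowSums(dos_l) > 0, ])
  r50 <- differential_variants(high, low, 50)
  expect_true(v$pos[1] %in% r50$differential$highland$pos)  # 0.60 >= 0.50
  r75 <- differential_variants(high, low, 75)
  expect_false(v$pos[1] %in% r75$differential$highland$pos) # 0.60 < 0.75
  # present in the control population: never differential at any threshold
  for (t in c(0, 25, 50, 75, 100)) {
    rt <- differential_variants(high, low, t)
    expect_false(v$pos[2] %in% rt$differential$highland$pos)
    expect_equal(rt$variants$status[rt$variants$pos == v$pos[2]],
                 "common")
  }
  # tie at the threshold is included ("at least"): 1/5 = 20%... use t = 20
  expect_warning(r20 <- differential_variants(high, low, 20),
                 "unconventional")
  expect_true(v$pos[3] %in% r20$differential$highland$pos)
})

test_that("differential sets shrink monotonically in t and partition the keys", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 40
    v <- snv_variants(n)
    high <- mk_callset("highland", matrix(rbinom(n * 5, 2, 0.3), n), v)
    low <- mk_callset("lowland", matrix(rbinom(n * 5, 2, 0.3), n), v)
    prev_h <- prev_l <- NULL
    for (t in c(100, 75, 50, 25, 0)) {
      ct <- differential_variants(high, low, t)
      # partition: statuses cover every observed key exactly once
      expect_equal(sum(ct$counts), nrow(ct$variants))
      expect_equal(nrow(ct$variants),
                   length(union(high$variants$key, low$variants$key)))
      if (!is.null(prev_h)) {
        expect_true(all(prev_h %in% ct$differential$highland$key))
        expect_true(all(prev_l %in% ct$differential$lowland$key))
      }
      prev_h <- ct$differential$highland$key
      prev_l <- ct$differential$lowland$key
    }
  }
})

test_that("common variants distinguish any-carriage from strict full carriage", {
  v <- snv_variants(3)
  high <- mk_callset("highland", rbind(rep(1, 5), c(1, 0, 0, 0, 0),
                                       c(2, 0, 0, 0, 0)), v)
  low <- mk_callset("lowland", rbind(rep(2, 5), c(0, 0, 0, 1, 0)),
                    v[1:2, ])
  cm <- common_variants(high, low)
  expect_setequal(cm$any, variant_key("chr1", v$pos[1:2], v$ref[1:2],
                                      v$alt[1:2]))
  expect_equal(cm$strict, variant_key("chr1", v$pos[1], v$ref[1],
                                      v$alt[1]))
})

test_that("novelty flagging is allele-aware", {
  v <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                  ref = c("A", "C", "G"), alt = c("G", "T", "A"))
  known <- c("chr1:100:A>G", "chr1:200:C>A")  # pos 200: different alt
  fl <- flag_novel(v, known)
  expect_equal(fl$known, c(TRUE, FALSE, FALSE))
  expect_equal(flag_novel(v, character())$known, rep(FALSE, 3))
})

test_that("validation percentage is 20k% for carriage k of 5", {
  v <- snv_variants(6)
  dos <- matrix(0L, 6, 5)
  for (k in 0:5) if (k > 0) dos[k + 1, seq_len(k)] <- 1L
  cohort <- mk_callset("highland", dos[rowSums(dos) > 0, , drop = FALSE],
                       v[rowSums(dos) > 0, ])
  keys <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  vp <- validation_percentage(keys, cohort)
  expect_equal(unname(vp), c(0, 20, 40, 60, 80, 100))
})

test_that("mtDNA table is restricted to MT and reconciles with planted counts", {
  # highland males carry 7 SNV + 2 insertions + 1 replacement on MT,
  # plus one chr1 SNV that must never enter the table
  mtv <- data.frame(
    chrom = c(rep("MT", 10), "chr1"),
    pos = c(seq(100, 1000, length.out = 10), 500),
    ref = c(rep("A", 7), "C", "C", "AG", "T"),
    alt = c(rep("G", 7), "CTT", "CA", "TGC", "C"))
  dos <- matrix(0L, 11, 5)
  dos[, 1:3] <- 1L   # males carry everything (H01..H03 male)
  high <- mk_callset("highland", dos, mtv,
                     sexes = c("male", "male", "male", "female", "female"))
  low <- mk_callset("lowland", matrix(0L, 0, 5), mtv[0, ])
  tab <- mtdna_classify(high, low)
  hm <- tab[tab$population == "highland" & tab$sex == "male", ]
  expect_equal(hm$SNV, 7)
  expect_equal(hm$insertion, 2)
  expect_equal(hm$replacement, 1)
  expect_equal(hm$total, 10)
  lf <- tab[tab$population == "lowland" & tab$sex == "female", ]
  expect_equal(lf$total, 0)
  expect_equal(sum(tab$total), 10)  # the chr1 variant is excluded
})

test_that("sex-stratified differential summary counts novel/coding columns", {
  s <- get_test_study()
  cs <- get_test_callsets()
  known <- read_known_variants(s$known_vcf)
  g <- read_genome_fasta(s$fasta)
  tab <- contrast_summary(cs$high, cs$low, 50, known, g, s$annotation)
  expect_equal(tab$stratum, c("male", "female"))
  expect_true(all(tab$total == tab$coding + tab$non_coding))
  expect_true(all(tab$novel <= tab$total))
  expect_true(all(tab$aa_changes <= tab$coding))
})
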