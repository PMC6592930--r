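# Nei distance, UPGMA, MCA of genotype indicators, PCA and discriminant
# classification.

test_that("Nei standard distance matches direct formula evaluation", {
  same <- nei_standard_distance(c(0.3, 0.8), c(0.3, 0.8))
  expect_equal(same$I, 1)
  expect_equal(same$D, 0)
  d <- nei_standard_distance(0.8, 0.2)
  expect_equal(d$I, 0.32 / 0.68, tolerance = 1e-12)
  expect_equal(d$D, -log(0.32 / 0.68), tolerance = 1e-6)
  expect_equal(d$D, 0.7538, tolerance = 1e-4)
  disjoint <- nei_standard_distance(1, 0)
  expect_true(disjoint$infinite)
  # symmetry and matrix interface
  x <- cbind(c(0.5, 0.1), c(0.3, 0.7), c(0.2, 0.2))
  y <- cbind(c(0.6, 0.3), c(0.2, 0.3), c(0.2, 0.4))
  expect_equal(nei_standard_distance(x, y)$D,
               nei_standard_distance(y, x)$D, tolerance = 1e-12)
  expect_error(nei_standard_distance(cbind(0.5, 0.4), cbind(0.5, 0.5)),
               "sum to 1")
})

test_that("UPGMA reproduces worked trees and is ultrametric", {
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"),
                                                 c("A", "B")))
  expect_equal(ape::write.tree(upgma_tree(d2)), "(A:1,B:1);")
  d3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  # same tree as ((A:1,B:1):2,C:3); up to rotation
  expect_true(ape::all.equal.phylo(
    upgma_tree(d3), ape::read.tree(text = "((A:1,B:1):2,C:3);"),
    use.edge.length = TRUE))
  expect_error(upgma_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  # random matrices: all root-to-leaf path lengths equal
  set.seed(61)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    m <- matrix(runif(n * n, 1, 10), n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:n], letters[1:n])
    phy <- upgma_tree(m)
    depths <- ape::node.depth.edgelength(phy)[seq_len(n)]
    expect_lt(max(depths) - min(depths), 1e-9)
  }
})

test_that("MCA inertia follows the (K - J)/J closed form and separates groups", {
  set.seed(62)
  # 8 samples, 12 SNV blocks, two clean genotype groups
  g_a <- matrix(sample(0:1, 4 * 12, TRUE), 4)
  g_b <- g_a + 1L   # disjoint categories
  geno <- rbind(g_a, g_b)
  colnames(geno) <- paste0("s", 1:12)
  rownames(geno) <- paste0("ind", 1:8)
  res <- mca_genotypes(geno)
  J <- 12; K <- sum(apply(geno, 2, function(v) length(unique(v))))
  expect_equal(res$total_inertia, (K - J) / J, tolerance = 1e-9)
  ax1 <- res$coordinates[, 1]
  expect_true(all(sign(ax1[1:4]) == sign(ax1[1])))
  expect_true(all(sign(ax1[5:8]) == -sign(ax1[1])))
  # duplicated sample rows get identical coordinates
  geno2 <- rbind(geno, geno[1, , drop = FALSE])
  rownames(geno2)[9] <- "dup"
  res2 <- mca_genotypes(geno2)
  expect_equal(unname(res2$coordinates["dup", ]),
               unname(res2$coordinates["ind1", ]), tolerance = 1e-9)
  # reordering samples permutes coordinates (up to axis sign)
  ord <- sample(nrow(geno))
  res3 <- mca_genotypes(geno[ord, ])
  for (k in 1:2)
    expect_equal(abs(unname(res3$coordinates[match(rownames(geno),
                                                   rownames(geno)[ord]),
                                             k])),
                 abs(unname(res$coordinates[, k])), tolerance = 1e-9)
  # constant block dropped with a warning
  geno_c <- cbind(geno, const = 1L)
  expect_warning(mca_genotypes(geno_c), "dropped")
})

test_that("correlation PCA accounting is exact", {
  set.seed(63)
  x <- matrix(rnorm(400 * 12), 400, 12)
  p <- phenotype_pca(x)
  expect_equal(sum(p$eigenvalues), 12, tolerance = 1e-9)
  expect_true(all(diff(p$cumulative) >= -1e-12))
  expect_equal(p$cumulative[length(p$cumulative)], 1, tolerance = 1e-9)
  # uncorrelated traits: proportions near 1/p
  expect_lt(max(abs(p$proportions - 1 / 12)), 0.03)
  xz <- cbind(x, zero = 0)
  expect_warning(phenotype_pca(xz), "zero-variance")
})

test_that("confusion summaries reproduce the printed two-group table", {
  cm <- confusion_matrix(matrix(c(8, 2, 2, 4), 2, byrow = TRUE,
                                dimnames = list(c("lowland", "highland"),
                                                c("lowland", "highland"))))
  expect_equal(cm$overall, 0.75)
  expect_equal(unname(cm$per_group["lowland"]), 0.80)
  expect_equal(unname(cm$per_group["highland"]), 2 / 3, tolerance = 1e-9)
  expect_equal(cm$total, 16)
})

test_that("discriminant classification separates shifted groups and not null ones", {
  set.seed(64)
  x <- rbind(matrix(rnorm(10 * 4), 10), matrix(rnorm(6 * 4, mean = 4), 6))
  labels <- rep(c("lowland", "highland"), c(10, 6))
  cm <- discriminant_classify(x, labels)
  expect_equal(cm$overall, 1)
  # shuffled labels with no effect: mean accuracy near chance over reps
  accs <- replicate(200, {
    discriminant_classify(matrix(rnorm(16 * 2), 16),
                          sample(labels))$overall
  })
  # resubstitution at n = 16 with 2 predictors inflates chance; compare
  # with the analytic permutation expectation loosely
  expect_lt(abs(mean(accs) - 0.5), 0.25)
  expect_lt(mean(accs), 0.9)
})

test_that("component choice honours the cumulative-variance target", {
  p <- list(cumulative = c(0.43, 0.60, 0.74, 0.82, 0.87, 0.92, 1))
  class(p) <- "phenotype_pca"
  expect_equal(choose_components(p, 0.92), 6)
  expect_equal(choose_components(p, 0.5), 2)
})

test_that("genotype sampling for structure keeps both populations aligned", {
  cs <- get_test_callsets()
  gm <- sample_genotype_matrix(cs$high, cs$low, 500, seed = 3)
  expect_equal(nrow(gm), 10)
  expect_lte(ncol(gm), 500)
  expect_equal(attr(gm, "population"),
               rep(c("highland", "lowland"), each = 5))
  res <- suppressWarnings(mca_genotypes(gm))
  expect_s3_class(res, "mca_result")
  expect_equal(nrow(res$coordinates), 10)
})
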