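# Population structure and phenotype classification: Nei's standard
# genetic distance, UPGMA trees, multiple correspondence analysis of
# genotype indicator matrices, and correlation-matrix PCA followed by
# linear discriminant classification of quantitative traits.

#' Per-population alternate-allele frequencies
#'
#' Frequencies at the union of bi-allelic SNV sites of two call sets,
#' computed from genotype dosages (a site absent from one population's
#' records is at frequency 0 there).
#'
#' @param high,low \code{population_callset}s.
#' @param drop_monomorphic drop loci fixed for the same allele in both
#'   populations (no information for genetic distance).
#' @return \code{data.frame}: key, p_highland, p_lowland.
#' @export
population_allele_freqs <- function(high, low, drop_monomorphic = TRUE) {
  freq <- function(cs, keys) {
    idx <- match(keys, cs$variants$key)
    d <- rowSums(cs$dos)[idx]
    p <- rowSums(cs$pld)[idx]
    out <- ifelse(is.na(idx), 0, d / p)
    out
  }
  keys <- union(high$variants$key[high$variants$vtype == "SNV"],
                low$variants$key[low$variants$vtype == "SNV"])
  out <- data.frame(key = keys,
                    p_highland = freq(high, keys),
                    p_lowland = freq(low, keys),
                    stringsAsFactors = FALSE)
  if (drop_monomorphic) {
    mono <- out$p_highland == out$p_lowland &
      out$p_highland %in% c(0, 1)
    out <- out[!mono, , drop = FALSE]
  }
  out
}

#' Nei's standard genetic distance
#'
#' D = -ln I with I = Jxy / sqrt(Jx Jy), where Jx and Jy are the mean
#' within-population homozygosity sums over loci and Jxy the mean
#' cross-population identity.  Inputs are either per-locus alternate
#' allele frequency vectors (bi-allelic loci, the second allele being the
#' complement) or loci x alleles frequency matrices.
#'
#' @param x,y numeric vectors (alt-allele frequencies) or matrices with
#'   one row per locus whose rows sum to 1.
#' @return Object of class \code{nei_distance}: Jx, Jy, Jxy, I, D and an
#'   \code{infinite} flag (no shared alleles anywhere, I = 0).
#' @examples
#' nei_standard_distance(0.8, 0.2)  # one locus, D ~= 0.7538
#' @export
nei_standard_distance <- function(x, y) {
  if (is.null(dim(x))) x <- cbind(x, 1 - x)
  if (is.null(dim(y))) y <- cbind(y, 1 - y)
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y)))
    stop("populations must share loci and allele order")
  if (any(x < 0) || any(x > 1) || any(y < 0) || any(y > 1))
    stop("frequencies must lie in [0, 1]")
  if (any(abs(rowSums(x) - 1) > 1e-9) || any(abs(rowSums(y) - 1) > 1e-9))
    stop("per-locus allele frequencies must sum to 1")
  Jx <- mean(rowSums(x^2))
  Jy <- mean(rowSums(y^2))
  Jxy <- mean(rowSums(x * y))
  I <- Jxy / sqrt(Jx * Jy)
  structure(list(Jx = Jx, Jy = Jy, Jxy = Jxy, I = I,
                 D = if (I > 0) -log(I) else Inf,
                 infinite = I <= 0, n_loci = nrow(x)),
            class = "nei_distance")
}

#' @export
print.nei_distance <- function(x, ...) {
  cat(sprintf("Nei standard genetic distance over %d loci\n", x$n_loci))
  cat(sprintf("  I = %.6g, D = %s\n", x$I,
              if (x$infinite) "infinite (no shared alleles)" else
                sprintf("%.6g", x$D)))
  invisible(x)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; node heights are half the join
#' distances, so the returned tree is ultrametric.  Tied merges follow
#' \code{hclust}'s deterministic order.
#'
#' @param d symmetric, zero-diagonal, non-negative distance matrix (or
#'   \code{dist}) with taxon names.
#' @return An [ape::phylo] rooted ultrametric tree; serialise with
#'   [ape::write.tree()].
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(upgma_tree(d))  # ((A:1,B:1):2,C:3);
#' @export
upgma_tree <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d)) || any(diag(d) != 0) || any(d < 0))
      stop("need a symmetric, zero-diagonal, non-negative matrix")
    d <- as.dist(d)
  }
  ape::as.phylo(hclust(d, method = "average"))
}

# Indicator (disjunctive) matrix from a samples x SNV genotype category
# matrix.  Blocks with missing entries or a single category are dropped.
genotype_indicator <- function(geno) {
  geno <- as.matrix(geno)
  keep_block <- logical(ncol(geno))
  cols <- list()
  for (j in seq_len(ncol(geno))) {
    v <- geno[, j]
    if (anyNA(v)) next
    cats <- sort(unique(v))
    if (length(cats) < 2) next
    keep_block[j] <- TRUE
    block <- vapply(cats, function(ct) as.integer(v == ct),
                    integer(nrow(geno)))
    colnames(block) <- paste0(colnames(geno)[j], "_", cats)
    cols[[length(cols) + 1L]] <- block
  }
  if (sum(keep_block) < 2) stop("need >= 2 informative SNV blocks")
  ind <- do.call(cbind, cols)
  rownames(ind) <- rownames(geno)
  structure(ind, n_blocks = sum(keep_block),
            dropped = sum(!keep_block))
}

#' Multiple correspondence analysis of SNV genotypes
#'
#' Correspondence analysis of the genotype indicator matrix (row/column
#' mass standardisation, SVD of the standardised residuals).  Constant
#' genotype blocks are dropped with a warning; axis signs are fixed so
#' the largest-magnitude coordinate on each axis is positive.  Total
#' inertia of a complete indicator matrix is (K - J) / J for J blocks and
#' K categories.
#'
#' @param geno samples x SNVs matrix of genotype categories (e.g. alt
#'   dosage 0/1/2), or a prebuilt 0/1 indicator matrix via
#'   \code{indicator = TRUE}.
#' @param n_components number of axes to return.
#' @param indicator set when \code{geno} already is an indicator matrix.
#' @return Object of class \code{mca_result}: sample \code{coordinates},
#'   per-axis \code{inertia} and \code{inertia_pct}, \code{total_inertia},
#'   \code{J} blocks, \code{K} categories.
#' @export
mca_genotypes <- function(geno, n_components = 2, indicator = FALSE) {
  if (nrow(geno) < 2) stop("need >= 2 samples")
  ind <- if (indicator) as.matrix(geno) else genotype_indicator(geno)
  if (!indicator && attr(ind, "dropped") > 0)
    warning(attr(ind, "dropped"),
            " constant or incomplete SNV block(s) dropped")
  P <- ind / sum(ind)
  r <- rowSums(P); cmass <- colSums(P)
  S <- (P - outer(r, cmass)) / sqrt(outer(r, cmass))
  sv <- svd(S)
  pos <- sv$d > 1e-12
  inertia <- sv$d[pos]^2
  ncomp <- min(n_components, sum(pos))
  coords <- sweep(sv$u[, seq_len(ncomp), drop = FALSE] %*%
                    diag(sv$d[seq_len(ncomp)], ncomp), 1, sqrt(r), "/")
  for (k in seq_len(ncomp)) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(ind)
  colnames(coords) <- paste0("axis", seq_len(ncomp))
  J <- if (indicator) NA_integer_ else attr(ind, "n_blocks")
  structure(list(coordinates = coords, inertia = inertia,
                 inertia_pct = 100 * inertia / sum(inertia),
                 total_inertia = sum(inertia),
                 J = J, K = ncol(ind)),
            class = "mca_result")
}

#' @export
print.mca_result <- function(x, ...) {
  cat(sprintf("MCA of %d samples, %d categories (%s blocks)\n",
              nrow(x$coordinates), x$K,
              if (is.na(x$J)) "?" else x$J))
  cat(sprintf("  total inertia %.4g; leading axes: %s\n", x$total_inertia,
              paste(sprintf("%.1f%%", utils::head(x$inertia_pct, 4)),
                    collapse = ", ")))
  invisible(x)
}

#' Sample a genotype matrix for structure analysis
#'
#' Uniform random subset of bi-allelic SNV sites genotyped in every
#' sample of both populations, returned as a samples x SNVs dosage
#' matrix (both populations stacked) with a \code{population} attribute.
#'
#' @param high,low \code{population_callset}s.
#' @param n_sites number of SNV sites to draw (capped at the available
#'   count).
#' @param seed optional seed for the subset draw.
#' @return Integer matrix with attribute \code{population}.
#' @export
sample_genotype_matrix <- function(high, low, n_sites = 10000,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keys <- union(high$variants$key[high$variants$vtype == "SNV"],
                low$variants$key[low$variants$vtype == "SNV"])
  get_dos <- function(cs) {
    idx <- match(keys, cs$variants$key)
    d <- matrix(0L, length(keys), ncol(cs$dos),
                dimnames = list(keys, colnames(cs$dos)))
    has <- !is.na(idx)
    d[has, ] <- cs$dos[idx[has], , drop = FALSE]
    ok <- rep(TRUE, length(keys))
    ok[has] <- apply(cs$pld[idx[has], , drop = FALSE] > 0L, 1, all)
    list(d = d, ok = ok)
  }
  gh <- get_dos(high); gl <- get_dos(low)
  keep <- which(gh$ok & gl$ok)
  pick <- if (length(keep) > n_sites) sort(sample(keep, n_sites)) else keep
  m <- t(cbind(gh$d[pick, , drop = FALSE], gl$d[pick, , drop = FALSE]))
  structure(m, population = rep(c(high$population, low$population),
                                c(ncol(gh$d), ncol(gl$d))))
}

#' Correlation-matrix PCA of a phenotype table
#'
#' Traits are standardised (PCA of the trait correlation matrix);
#' zero-variance traits are dropped with a warning.  Eigenvalues sum to
#' the number of retained traits.
#'
#' @param table \code{data.frame} with a \code{population} column (or a
#'   \code{labels} argument) and numeric trait columns, or a plain
#'   numeric matrix.
#' @param labels optional group labels.
#' @return Object of class \code{phenotype_pca}: eigenvalues,
#'   proportions, cumulative proportions, sample scores, labels.
#' @export
phenotype_pca <- function(table, labels = NULL) {
  if (is.data.frame(table)) {
    if (is.null(labels) && !is.null(table$population))
      labels <- table$population
    num <- vapply(table, is.numeric, logical(1))
    x <- as.matrix(table[, num, drop = FALSE])
  } else x <- as.matrix(table)
  if (nrow(x) < 2) stop("need >= 2 samples")
  v <- apply(x, 2, sd)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance trait(s) dropped")
    x <- x[, v > 0, drop = FALSE]
  }
  pr <- prcomp(x, center = TRUE, scale. = TRUE)
  ev <- pr$sdev^2
  structure(list(eigenvalues = ev,
                 proportions = ev / sum(ev),
                 cumulative = cumsum(ev) / sum(ev),
                 scores = pr$x, n_traits = ncol(x),
                 labels = labels),
            class = "phenotype_pca")
}

#' @export
print.phenotype_pca <- function(x, ...) {
  k <- min(6, length(x$eigenvalues))
  tab <- rbind(Eigenvalue = x$eigenvalues[1:k],
               Proportion = x$proportions[1:k],
               Cumulative = x$cumulative[1:k])
  colnames(tab) <- paste0("PC", 1:k)
  cat(sprintf("PCA of %d traits (correlation matrix), %d samples\n",
              x$n_traits, nrow(x$scores)))
  print(round(tab, 2))
  invisible(x)
}

#' Smallest number of components reaching a cumulative-variance target
#'
#' @param pca a \code{phenotype_pca}.
#' @param target cumulative proportion of variance (default 0.92).
#' @return Integer component count.
#' @export
choose_components <- function(pca, target = 0.92) {
  which(pca$cumulative >= target - 1e-12)[1]
}

#' Confusion matrix summaries
#'
#' Builds a confusion matrix either from true/assigned label vectors or
#' from a counts matrix (rows = assigned group, columns = true group) and
#' reports per-group and overall proportions correct.  Per-group
#' proportion correct is the fraction of each true group assigned to
#' itself; overall is the trace over the total.
#'
#' @param true true group labels, or a square counts matrix when
#'   \code{assigned} is missing.
#' @param assigned assigned group labels.
#' @return Object of class \code{confusion_matrix}: counts, per-group
#'   proportions, overall proportion correct, total.
#' @examples
#' cm <- confusion_matrix(matrix(c(8, 2, 2, 4), 2, byrow = TRUE,
#'   dimnames = list(c("lowland", "highland"), c("lowland", "highland"))))
#' cm$overall  # 0.75
#' @export
confusion_matrix <- function(true, assigned = NULL) {
  if (is.null(assigned)) {
    counts <- as.matrix(true)
    if (nrow(counts) != ncol(counts))
      stop("counts matrix must be square (assigned x true)")
    if (is.null(dimnames(counts)))
      dimnames(counts) <- list(paste0("g", seq_len(nrow(counts))),
                               paste0("g", seq_len(nrow(counts))))
  } else {
    lev <- sort(unique(c(as.character(true), as.character(assigned))))
    counts <- table(factor(assigned, lev), factor(true, lev))
    counts <- unclass(as.matrix(counts))
  }
  total <- sum(counts)
  per_group <- diag(counts) / colSums(counts)
  structure(list(counts = counts, per_group = per_group,
                 overall = sum(diag(counts)) / total, total = total),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = assigned, columns = true):\n")
  print(x$counts)
  cat("per-group proportion correct:",
      paste(sprintf("%s %.3f", colnames(x$counts), x$per_group),
            collapse = ", "), "\n")
  cat(sprintf("overall proportion correct: %.4g (n = %d)\n", x$overall,
              x$total))
  invisible(x)
}

#' Linear discriminant classification of component scores
#'
#' Fits a linear discriminant (pooled covariance) on the first k
#' principal-component scores and reports the resubstitution confusion
#' matrix (leave-one-out optional).  When \code{x} is a
#' \code{phenotype_pca}, k defaults to the smallest number of components
#' reaching \code{cum_target} cumulative variance.
#'
#' @param x a \code{phenotype_pca} or a numeric score matrix.
#' @param labels group labels (taken from the PCA object if present).
#' @param k number of leading components to use.
#' @param cum_target cumulative-variance target used when \code{k} is
#'   missing.
#' @param cv use leave-one-out cross-validated assignments instead of
#'   resubstitution.
#' @return A \code{confusion_matrix} with the fitted \code{MASS::lda}
#'   object attached as attribute \code{fit}.
#' @export
discriminant_classify <- function(x, labels = NULL, k = NULL,
                                  cum_target = 0.92, cv = FALSE) {
  if (inherits(x, "phenotype_pca")) {
    if (is.null(labels)) labels <- x$labels
    if (is.null(k)) k <- choose_components(x, cum_target)
    scores <- x$scores[, seq_len(k), drop = FALSE]
  } else {
    scores <- as.matrix(x)
    if (!is.null(k)) scores <- scores[, seq_len(k), drop = FALSE]
  }
  if (is.null(labels)) stop("group labels required")
  labels <- factor(labels)
  if (nlevels(labels) < 2 || any(table(labels) < 2))
    stop("need two groups with >= 2 samples each")
  fit <- MASS::lda(scores, grouping = labels, CV = cv)
  assigned <- if (cv) fit$class else predict(fit)$class
  cm <- confusion_matrix(labels, assigned)
  attr(cm, "fit") <- fit
  cm
}
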