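# Variant-type distribution tests between populations: exact Fisher 2x2
# (minimum-likelihood two-sided convention), per-chromosome Pearson
# chi-square stratified by sex, and Benjamini-Hochberg step-up FDR.
# Implemented directly so the conventions are explicit and reproducible;
# the test suite cross-checks them against independent routes.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value under the hypergeometric null, two-sided by the
#' minimum-likelihood convention: the sum of probabilities of all tables
#' (with the observed margins) whose probability does not exceed that of
#' the observed table.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 7, 7, 3), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pobs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

#' Per-variant-type distribution test between populations
#'
#' For each variant type, builds the type-vs-rest 2x2 contingency table of
#' record counts (\code{[[count(type, high), count(other, high)],
#' [count(type, low), count(other, low)]]}) and applies the exact Fisher
#' test.  A k x 2 chi-square over the full type spectrum is also reported.
#'
#' @param high,low \code{population_callset}s.
#' @return List with \code{per_type} (\code{data.frame}: vtype, counts,
#'   p, untestable flag) and \code{spectrum_chisq} (statistic, df, p).
#' @export
per_type_distribution_test <- function(high, low) {
  vts <- c("SNV", "MNV", "insertion", "deletion", "replacement")
  ch <- table(factor(high$variants$vtype, levels = vts))
  cl <- table(factor(low$variants$vtype, levels = vts))
  present <- ch + cl > 0
  rows <- lapply(vts[present], function(v) {
    tab <- matrix(c(ch[[v]], sum(ch) - ch[[v]],
                    cl[[v]], sum(cl) - cl[[v]]), 2, byrow = TRUE)
    data.frame(vtype = v, count_highland = ch[[v]],
               count_lowland = cl[[v]],
               p = fisher_exact_2x2(tab), stringsAsFactors = FALSE)
  })
  per_type <- do.call(rbind, rows)
  per_type$significant <- per_type$p < 0.001
  keep <- present & ch + cl > 0
  obs <- rbind(ch[keep], cl[keep])
  chisq <- pearson_chisq(obs)
  list(per_type = per_type, spectrum_chisq = chisq)
}

# Pearson chi-square without continuity correction for an r x c table;
# returns NA p when any expected count is zero.
pearson_chisq <- function(obs, correct = FALSE) {
  obs <- as.matrix(obs)
  E <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(E == 0))
    return(list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                untestable = TRUE))
  adj <- if (correct) pmin(abs(obs - E), 0.5) else 0
  stat <- sum((abs(obs - E) - adj)^2 / E)
  df <- (nrow(obs) - 1L) * (ncol(obs) - 1L)
  list(statistic = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE), untestable = FALSE)
}

#' Per-chromosome chi-square of variant distribution
#'
#' For each (sex stratum, variant type, chromosome) cell, tests whether the
#' proportion of that type's variants falling on the chromosome differs
#' between the populations: Pearson chi-square (df = 1, no continuity
#' correction by default) on \code{[[on-chrom, off-chrom]]} per population.
#' Counts are of variants carried by at least one stratum sample.  Cells
#' with a zero expected count are marked untestable.
#'
#' @param high,low \code{population_callset}s.
#' @param stratify_by_sex when \code{TRUE} (default) the test is run
#'   within males and within females; otherwise pooled.
#' @param correct apply the Yates continuity correction.
#' @param alpha significance level for the \code{significant} flag.
#' @return \code{data.frame} with one row per (sex, vtype, chrom):
#'   counts, statistic, df, p, \code{significant}, \code{untestable}.
#' @export
per_chromosome_chisq <- function(high, low, stratify_by_sex = TRUE,
                                 correct = FALSE, alpha = 0.05) {
  strata <- if (stratify_by_sex) c("male", "female") else "pooled"
  count_by <- function(cs, stratum) {
    ids <- stratum_samples(cs, stratum)
    pres <- rowSums(cs$dos[, ids, drop = FALSE] > 0L) > 0L
    cs$variants[pres, c("chrom", "vtype")]
  }
  out <- list()
  for (s in strata) {
    vh <- count_by(high, s); vl <- count_by(low, s)
    for (vt in intersect(unique(vh$vtype), unique(vl$vtype))) {
      h <- vh$chrom[vh$vtype == vt]; l <- vl$chrom[vl$vtype == vt]
      for (ch in sort(unique(c(h, l)))) {
        tab <- matrix(c(sum(h == ch), sum(h != ch),
                        sum(l == ch), sum(l != ch)), 2, byrow = TRUE)
        ts <- pearson_chisq(tab, correct)
        out[[length(out) + 1L]] <- data.frame(
          sex = s, vtype = vt, chrom = ch,
          on_highland = tab[1, 1], off_highland = tab[1, 2],
          on_lowland = tab[2, 1], off_lowland = tab[2, 2],
          statistic = ts$statistic, df = ts$df, p = ts$p,
          significant = !ts$untestable && !is.na(ts$p) && ts$p < alpha,
          untestable = ts$untestable, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Non-significant chromosome report
#'
#' Condenses [per_chromosome_chisq()] output into one row per
#' (sex, variant type) listing the chromosomes that did \emph{not} reach
#' significance (the presentation used for per-chromosome results).
#'
#' @param chisq_table output of [per_chromosome_chisq()].
#' @return \code{data.frame} with columns sex, vtype,
#'   \code{nonsignificant_chroms} (comma-separated).
#' @export
nonsignificant_report <- function(chisq_table) {
  sp <- split(chisq_table, list(chisq_table$sex, chisq_table$vtype),
              drop = TRUE)
  out <- lapply(sp, function(d) data.frame(
    sex = d$sex[1], vtype = d$vtype[1],
    nonsignificant_chroms = paste(
      d$chrom[!d$significant | d$untestable], collapse = ","),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sex, out$vtype), ]
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved in the output.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_fdr(c(0.005, 0.01, 0.02, 0.1))
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric())
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
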