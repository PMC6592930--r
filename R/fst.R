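# Weir-Cockerham F_ST (variance-component estimator, r = 2 populations,
# full three-level form with observed heterozygosity) and the
# sliding-window selection scan: per-SNV theta, window means, top-fraction
# retrieval and candidate gene lookup.

#' Weir-Cockerham variance components from summary statistics
#'
#' Evaluates the among-population (a), among-individual-within-population
#' (b) and within-individual (c) variance components for one bi-allelic
#' site and r = 2 populations of diploids, from per-population allele
#' frequencies, observed heterozygote proportions and sample sizes.
#' Vectorised over sites.
#'
#' @param p1,p2 alternate-allele frequencies in the two populations.
#' @param h1,h2 observed heterozygote proportions.
#' @param n1,n2 numbers of genotyped diploid individuals.
#' @return \code{data.frame} with columns \code{a}, \code{b}, \code{c},
#'   \code{theta} and \code{defined} (\code{FALSE} where
#'   \code{a + b + c == 0}, e.g. a site monomorphic for the same allele in
#'   both populations).  Negative estimates are reported as computed.
#' @export
wc_fst_components <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) /
       (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc
  defined <- abs(denom) > 0
  theta <- ifelse(defined, a / denom, NA_real_)
  data.frame(a = a, b = b, c = cc, theta = theta, defined = defined)
}

#' Weir-Cockerham F_ST at a single site from genotypes
#'
#' @param geno1,geno2 integer vectors of alternate-allele dosages (0, 1, 2;
#'   \code{NA} = missing) for the diploid individuals of each population.
#' @return A list of class \code{fst_components}: components a, b, c,
#'   theta, per-population frequencies \code{p_hat}, mean observed
#'   heterozygosity \code{h_bar} and sample sizes \code{n_per_pop}.
#' @examples
#' wc_fst_site(rep(2L, 10), rep(0L, 10))  # fixed difference: theta = 1
#' @export
wc_fst_site <- function(geno1, geno2) {
  g1 <- geno1[!is.na(geno1)]; g2 <- geno2[!is.na(geno2)]
  if (length(g1) < 2 || length(g2) < 2)
    stop("need >= 2 genotyped diploid individuals per population")
  if (any(c(g1, g2) < 0) || any(c(g1, g2) > 2))
    stop("dosages must be 0, 1 or 2")
  n1 <- length(g1); n2 <- length(g2)
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1L); h2 <- mean(g2 == 1L)
  comp <- wc_fst_components(p1, p2, h1, h2, n1, n2)
  structure(list(a = comp$a, b = comp$b, c = comp$c,
                 theta = comp$theta, defined = comp$defined,
                 p_hat = c(p1, p2),
                 h_bar = (n1 * h1 + n2 * h2) / (n1 + n2),
                 n_per_pop = c(n1, n2)),
            class = "fst_components")
}

#' @export
print.fst_components <- function(x, ...) {
  cat(sprintf("Weir-Cockerham components: a=%.6g b=%.6g c=%.6g\n",
              x$a, x$b, x$c))
  cat(sprintf("theta = %s (p_hat = %.4g / %.4g, n = %d / %d)\n",
              if (x$defined) sprintf("%.6g", x$theta) else "undefined",
              x$p_hat[1], x$p_hat[2], x$n_per_pop[1], x$n_per_pop[2]))
  invisible(x)
}

#' Per-SNV Weir-Cockerham theta for two call sets
#'
#' Computes theta at every bi-allelic SNV on the included contigs.  A site
#' recorded in only one population is taken as monomorphic reference in
#' the other (variant-detection semantics).  Samples whose expected ploidy
#' at the contig is not 2 are excluded; positions carrying more than one
#' alternate allele are dropped.
#'
#' @param high,low \code{population_callset}s.
#' @param exclude contigs to drop (default sex chromosomes and MT).
#' @return \code{data.frame}: chrom, pos, key, a, b, c, theta, defined.
#' @export
wc_fst_sites <- function(high, low, exclude = c("Z", "W", "MT")) {
  pick <- function(cs) {
    v <- cs$variants
    v$vtype == "SNV" & !(v$chrom %in% exclude)
  }
  va <- high$variants[pick(high), ]
  vb <- low$variants[pick(low), ]
  uni <- rbind(va[, c("chrom", "pos", "ref", "alt", "key")],
               vb[, c("chrom", "pos", "ref", "alt", "key")])
  uni <- uni[!duplicated(uni$key), , drop = FALSE]
  cp <- paste(uni$chrom, uni$pos)
  multi <- cp %in% cp[duplicated(cp)]
  uni <- uni[!multi, , drop = FALSE]

  pop_stats <- function(cs, keys) {
    idx <- match(keys, cs$variants$key)
    m <- ncol(cs$dos)
    dos <- matrix(0L, length(keys), m)
    pld <- matrix(rep(contig_ploidy(uni$chrom, cs$samples$sex[1]), m),
                  length(keys), m)
    for (j in seq_len(m))
      pld[, j] <- contig_ploidy(uni$chrom, cs$samples$sex[j])
    has <- !is.na(idx)
    dos[has, ] <- cs$dos[idx[has], , drop = FALSE]
    pld[has, ] <- cs$pld[idx[has], , drop = FALSE]
    dip <- pld == 2L
    n <- rowSums(dip)
    p <- rowSums(dos * dip) / (2 * n)
    h <- rowSums((dos == 1L) & dip) / n
    list(n = n, p = p, h = h)
  }
  sh <- pop_stats(high, uni$key)
  sl <- pop_stats(low, uni$key)
  ok <- sh$n >= 2 & sl$n >= 2
  comp <- wc_fst_components(sh$p, sl$p, sh$h, sl$h, sh$n, sl$n)
  comp$defined <- comp$defined & ok
  comp$theta[!ok] <- NA_real_
  cbind(uni[, c("chrom", "pos", "key")], comp,
        p_highland = sh$p, p_lowland = sl$p)
}

#' Sliding-window shells over included contigs
#'
#' Windows are \code{[s, min(s + window, L))} (0-based half-open) for
#' \code{s = 0, step, 2 step, ...} while \code{s + step <= L}; a contig
#' shorter than the window yields the single truncated window
#' \code{[0, L)}.  Sex chromosomes are excluded by default, and MT is
#' never scanned.
#'
#' @param contig_lengths named vector of contig lengths (bp).
#' @param window,step window size and step (bp); \code{step <= window}.
#' @param exclude contigs to drop.
#' @return \code{data.frame}: chrom, start, end, window_id.
#' @export
make_windows <- function(contig_lengths, window = 1e5, step = 5e4,
                         exclude = c("Z", "W")) {
  if (step <= 0 || window < step)
    stop("need 0 < step <= window (gaps would drop SNVs)")
  exclude <- union(exclude, "MT")
  keep <- setdiff(names(contig_lengths), exclude)
  out <- lapply(keep, function(ch) {
    L <- contig_lengths[[ch]]
    starts <- if (L <= step) 0 else seq(0, L - step, by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window, L), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$window_id <- sprintf("%s:%d-%d", out$chrom, as.integer(out$start),
                           as.integer(out$end))
  out
}

#' Window means of per-SNV theta
#'
#' Averages defined per-SNV theta over each window (a SNV at position p
#' belongs to windows with \code{start <= p - 1 < end}; with a half-window
#' step each SNV contributes to at most two windows).  Windows holding
#' fewer than \code{min_snvs} defined SNVs are flagged empty and excluded
#' from ranking.
#'
#' @param sites output of [wc_fst_sites()] (needs chrom, pos, theta).
#' @param windows output of [make_windows()].
#' @param min_snvs minimum defined SNVs for a window to be ranked.
#' @param method \code{"mean"} (unweighted mean of per-SNV theta, default)
#'   or \code{"ratio_of_sums"} (sum a / sum (a+b+c)).
#' @return \code{windows} with \code{n_snvs}, \code{mean_theta} and
#'   \code{ranked} columns.
#' @export
window_scan <- function(sites, windows, min_snvs = 1,
                        method = c("mean", "ratio_of_sums")) {
  method <- match.arg(method)
  windows$n_snvs <- 0L
  windows$mean_theta <- NA_real_
  for (ch in unique(windows$chrom)) {
    s <- sites[sites$chrom == ch & !is.na(sites$theta), ]
    if (nrow(s) == 0) next
    ord <- order(s$pos)
    pos0 <- s$pos[ord] - 1L          # 0-based
    cth <- cumsum(c(0, s$theta[ord]))
    ca <- cumsum(c(0, s$a[ord]))
    cden <- cumsum(c(0, s$a[ord] + s$b[ord] + s$c[ord]))
    wi <- which(windows$chrom == ch)
    lo <- findInterval(windows$start[wi] - 0.5, pos0) + 1L
    hi <- findInterval(windows$end[wi] - 0.5, pos0)
    n <- hi - lo + 1L
    n[n < 0] <- 0L
    windows$n_snvs[wi] <- n
    val <- if (method == "mean") {
      (cth[hi + 1L] - cth[lo]) / n
    } else {
      (ca[hi + 1L] - ca[lo]) / (cden[hi + 1L] - cden[lo])
    }
    windows$mean_theta[wi] <- ifelse(n > 0, val, NA_real_)
  }
  windows$ranked <- windows$n_snvs >= min_snvs &
    !is.na(windows$mean_theta)
  windows
}

#' Mark the top fraction of ranked windows
#'
#' Windows whose mean theta reaches the empirical \code{1 - fraction}
#' quantile are marked; the cutoff is the \code{ceiling(fraction x
#' n_ranked)}-th largest mean and ties at the cutoff are all included.
#'
#' @param windows output of [window_scan()].
#' @param fraction top fraction to retrieve (default 0.05).
#' @return \code{windows} with an \code{is_top} logical column.
#' @export
top_fraction <- function(windows, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)")
  ranked <- which(windows$ranked)
  if (length(ranked) == 0) stop("no ranked windows")
  k <- ceiling(fraction * length(ranked))
  cutoff <- sort(windows$mean_theta[ranked], decreasing = TRUE)[k]
  windows$is_top <- windows$ranked & windows$mean_theta >= cutoff
  windows
}

#' Genes overlapping the top windows
#'
#' @param windows window table with \code{is_top} set.
#' @param annotation \code{genome_annotation}.
#' @return \code{data.frame}: gene_id, chrom, start, end and the
#'   comma-separated ids of the top windows it intersects (a gene
#'   straddling several top windows is listed once).
#' @export
genes_in_windows <- function(windows, annotation) {
  top <- windows[windows$is_top, , drop = FALSE]
  g <- annotation$genes
  hits <- lapply(seq_len(nrow(g)), function(i) {
    ov <- top$chrom == g$chrom[i] & top$start + 1L <= g$end[i] &
      top$end >= g$start[i]
    if (!any(ov)) return(NULL)
    data.frame(gene_id = g$gene_id[i], chrom = g$chrom[i],
               start = g$start[i], end = g$end[i],
               windows = paste(top$window_id[ov], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      windows = character())
  out
}

#' Run the full selection scan
#'
#' Per-SNV Weir-Cockerham theta, sliding-window averaging, top-fraction
#' retrieval, candidate gene lookup and (when gene sets are supplied)
#' hypergeometric gene-set enrichment with BH FDR.
#'
#' @param high,low \code{population_callset}s.
#' @param annotation \code{genome_annotation} (provides contig lengths and
#'   gene spans).
#' @param window,step window size and step in bp.
#' @param fraction top fraction of windows to retrieve.
#' @param min_snvs minimum defined SNVs per ranked window.
#' @param exclude contigs excluded from the scan.
#' @param gene_sets optional \code{data.frame} (term, gene_id) for
#'   enrichment.
#' @param alpha enrichment significance level on BH-adjusted p-values.
#' @param method per-window summary, see [window_scan()].
#' @return Object of class \code{fst_scan}: sites, windows, candidate
#'   genes, enrichment table.
#' @export
fst_scan <- function(high, low, annotation, window = 1e5, step = 5e4,
                     fraction = 0.05, min_snvs = 1,
                     exclude = c("Z", "W"), gene_sets = NULL,
                     alpha = 0.01, method = "mean") {
  sites <- wc_fst_sites(high, low, exclude = union(exclude, "MT"))
  windows <- make_windows(annotation$contig_lengths, window, step, exclude)
  windows <- window_scan(sites, windows, min_snvs, method)
  windows <- top_fraction(windows, fraction)
  genes <- genes_in_windows(windows, annotation)
  enrich <- NULL
  if (!is.null(gene_sets))
    enrich <- geneset_enrichment(genes$gene_id,
                                 annotation$genes$gene_id,
                                 gene_sets, alpha = alpha)
  structure(list(sites = sites, windows = windows, genes = genes,
                 enrichment = enrich, fraction = fraction,
                 window = window, step = step),
            class = "fst_scan")
}

#' @export
print.fst_scan <- function(x, ...) {
  cat(sprintf("F_ST selection scan: %d SNVs, %d windows (%g kb / %g kb)\n",
              nrow(x$sites), nrow(x$windows), x$window / 1e3,
              x$step / 1e3))
  cat(sprintf("  top %g%%: %d windows, %d candidate genes\n",
              100 * x$fraction, sum(x$windows$is_top), nrow(x$genes)))
  if (!is.null(x$enrichment))
    cat("  enriched terms:", sum(x$enrichment$significant), "\n")
  invisible(x)
}

#' @export
plot.fst_scan <- function(x, ...) {
  w <- x$windows[x$windows$ranked, ]
  chroms <- unique(w$chrom)
  off <- setNames(cumsum(c(0, vapply(chroms, function(ch)
    max(w$end[w$chrom == ch]), numeric(1))))[seq_along(chroms)], chroms)
  xs <- off[w$chrom] + (w$start + w$end) / 2
  plot(xs, w$mean_theta, pch = 20,
       col = ifelse(w$is_top, "firebrick",
                    c("grey40", "grey70")[1 + match(w$chrom, chroms) %% 2]),
       xlab = "genomic position", ylab = "mean window F_ST", ...)
  invisible(x)
}
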