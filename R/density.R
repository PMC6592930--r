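# Genomic variant-density enrichment: per-chromosome "standard frequency"
# (variants per Mb of chromosome), cumulative variant curves, and an
# algorithmic surrogate for picking the densest region off the cumulative
# plot: the fixed-width window (default 20% of the chromosome) holding the
# maximum variant count, anchored at variant positions.

#' Standard frequency: variants per megabase
#'
#' @param n variant count.
#' @param length_bp chromosome length in bp.
#' @return \code{n / (length_bp / 1e6)}.
#' @examples
#' standard_frequency(500, 50e6)  # 10
#' @export
standard_frequency <- function(n, length_bp) {
  if (any(length_bp <= 0)) stop("chromosome length must be positive")
  n / (length_bp / 1e6)
}

#' Per-chromosome density profiles
#'
#' One row per chromosome with its variant count, length (Mb) and
#' standard frequency.  Lengths come from the annotation's contig table,
#' not from the maximum variant position.
#'
#' @param variants \code{data.frame} with \code{chrom} and \code{pos}.
#' @param contig_lengths named vector of chromosome lengths (bp).
#' @return \code{data.frame}: chrom, n_variants, length_mb,
#'   standard_frequency.
#' @export
density_profiles <- function(variants, contig_lengths) {
  chroms <- names(contig_lengths)
  n <- vapply(chroms, function(ch) sum(variants$chrom == ch), integer(1))
  data.frame(chrom = chroms, n_variants = n,
             length_mb = as.numeric(contig_lengths) / 1e6,
             standard_frequency = standard_frequency(
               n, as.numeric(contig_lengths)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Chromosome with the highest standard frequency
#'
#' @param profiles output of [density_profiles()].
#' @return List with \code{chrom} (argmax; ties broken by chromosome name
#'   order) and \code{tie} flag.
#' @export
rank_chromosomes <- function(profiles) {
  if (nrow(profiles) == 0) stop("no density profiles")
  best <- max(profiles$standard_frequency)
  hits <- sort(profiles$chrom[profiles$standard_frequency == best])
  list(chrom = hits[1], tie = length(hits) > 1,
       standard_frequency = best)
}

#' Cumulative variant curve along a chromosome
#'
#' @param positions 1-based variant positions.
#' @param length_bp chromosome length.
#' @return \code{data.frame} of sorted positions with running counts
#'   (duplicate positions each counted).
#' @export
cumulative_curve <- function(positions, length_bp) {
  if (length(positions) == 0)
    return(data.frame(pos = integer(), cumulative = integer()))
  if (any(positions < 1 | positions > length_bp))
    stop("positions outside [1, chromosome length]")
  p <- sort(as.integer(positions))
  data.frame(pos = p, cumulative = seq_along(p))
}

#' Maximum-density region of fixed relative width
#'
#' Among windows of width \code{target_fraction x length_bp} anchored at 0
#' and at each variant position, returns the window containing the most
#' variants (ties: smallest start).  This makes the by-eye selection of
#' the steepest stretch of the cumulative curve algorithmic and
#' oracle-checkable.
#'
#' @param positions 1-based variant positions on one chromosome.
#' @param length_bp chromosome length.
#' @param target_fraction window width as a fraction of the chromosome
#'   (default 0.2).
#' @param annotation optional \code{genome_annotation} plus \code{chrom}
#'   to attach the genes overlapping the region.
#' @param chrom chromosome name (needed for gene lookup).
#' @return List of class \code{dense_region}: start, end (0-based
#'   half-open, clipped to the chromosome), n_in_region,
#'   fraction_of_variants, fraction_of_length, genes.
#' @export
max_density_region <- function(positions, length_bp, target_fraction = 0.2,
                               annotation = NULL, chrom = NULL) {
  if (length(positions) == 0) stop("no variant positions")
  if (target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must lie in (0, 1]")
  pos0 <- sort(as.integer(positions)) - 1L     # 0-based
  width <- target_fraction * length_bp
  anchors <- unique(c(0, pos0))
  counts <- vapply(anchors, function(a)
    sum(pos0 >= a & pos0 < a + width), integer(1))
  best <- which(counts == max(counts))
  a <- anchors[best[which.min(anchors[best])]]
  start <- a
  end <- min(a + width, length_bp)
  n_in <- max(counts)
  genes <- NULL
  if (!is.null(annotation) && !is.null(chrom)) {
    g <- annotation$genes
    ov <- g$chrom == chrom & g$start <= end & g$end >= start + 1
    genes <- g$gene_id[ov]
  }
  structure(list(chrom = chrom, start = start, end = end,
                 n_in_region = n_in, n_variants = length(pos0),
                 fraction_of_variants = n_in / length(pos0),
                 fraction_of_length = (end - start) / length_bp,
                 genes = genes),
            class = "dense_region")
}

#' @export
print.dense_region <- function(x, ...) {
  cat(sprintf(
    "Dense region%s: [%.0f, %.0f) holds %d of %d variants (%.1f%%) on %.1f%% of the chromosome\n",
    if (is.null(x$chrom)) "" else paste0(" on ", x$chrom),
    x$start, x$end, x$n_in_region, x$n_variants,
    100 * x$fraction_of_variants, 100 * x$fraction_of_length))
  if (!is.null(x$genes))
    cat("  genes:", if (length(x$genes)) paste(x$genes, collapse = ", ")
        else "(none)", "\n")
  invisible(x)
}

#' Genes and transcripts in a region
#'
#' @param region a \code{dense_region} (or list with chrom, start, end;
#'   0-based half-open).
#' @param annotation \code{genome_annotation}.
#' @return List with deduplicated \code{genes} and \code{transcripts}
#'   intersecting the region.
#' @export
region_genes <- function(region, annotation) {
  g <- annotation$genes
  ovg <- g$chrom == region$chrom & g$start <= region$end &
    g$end >= region$start + 1
  cds <- annotation$cds
  ovt <- cds$chrom == region$chrom & cds$start <= region$end &
    cds$end >= region$start + 1
  list(genes = unique(g$gene_id[ovg]),
       transcripts = unique(cds$transcript_id[ovt]))
}
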