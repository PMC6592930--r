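# Offline gene-set enrichment: hypergeometric upper-tail test per term
# with Benjamini-Hochberg correction across terms.  Replaces live
# ontology/enrichment services with a user-supplied gene -> term table.

#' Hypergeometric gene-set enrichment
#'
#' For each term, the upper-tail hypergeometric probability
#' P(X >= overlap) of drawing at least the observed number of term genes
#' in a candidate list of size n from a universe of size N containing K
#' term genes; p-values are BH-adjusted across terms.  An overlap of zero
#' gives p = 1 (the tail convention P(X >= 0) = 1).
#'
#' @param candidates character vector of candidate gene ids (must be a
#'   subset of \code{universe}; ids outside it are dropped with a
#'   warning).
#' @param universe character vector of all gene ids under consideration.
#' @param gene_sets \code{data.frame} with columns \code{term} and
#'   \code{gene_id}.
#' @param alpha significance level applied to the adjusted p-values
#'   (default 0.01).
#' @return \code{data.frame}: term, term_size (K), overlap, overlap_genes
#'   (comma-separated), p, p_adj, significant; ordered by p.
#' @export
geneset_enrichment <- function(candidates, universe, gene_sets,
                               alpha = 0.01) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty gene universe")
  candidates <- unique(as.character(candidates))
  drop <- setdiff(candidates, universe)
  if (length(drop)) {
    warning(length(drop), " candidate gene(s) not in the universe dropped")
    candidates <- intersect(candidates, universe)
  }
  N <- length(universe); n <- length(candidates)
  sets <- split(gene_sets$gene_id, gene_sets$term)
  rows <- lapply(names(sets), function(term) {
    term_genes <- intersect(unique(sets[[term]]), universe)
    K <- length(term_genes)
    ov_genes <- intersect(term_genes, candidates)
    ov <- length(ov_genes)
    p <- if (ov == 0) 1 else phyper(ov - 1, K, N - K, n,
                                    lower.tail = FALSE)
    data.frame(term = term, term_size = K, overlap = ov,
               overlap_genes = paste(sort(ov_genes), collapse = ","),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_fdr(out$p)
  out$significant <- out$p_adj < alpha
  out[order(out$p, out$term), ]
}
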