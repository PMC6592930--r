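# Coding-consequence classification: CDS overlap, codon substitution and
# translation under the standard genetic code (reverse-complemented for
# minus-strand transcripts).  Length-preserving substitutions fully inside
# one CDS exon get codon-level effects; frameshifting indels, junction- or
# boundary-spanning edits and stop-codon losses are reported as "other".

revcomp_chr <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
}

translate_codons <- function(s) {
  n <- nchar(s) %/% 3L
  codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  unname(Biostrings::GENETIC_CODE[codons])
}

# Assemble per-transcript CDS model: ordered exons and spliced sequence in
# reading orientation.
build_transcripts <- function(annotation, genome) {
  seqs <- as.character(genome)
  cds <- annotation$cds
  lapply(split(cds, cds$transcript_id), function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    strand <- ex$strand[1]
    pieces <- substring(seqs[[ex$chrom[1]]], ex$start, ex$end)
    if (strand == "-") pieces <- rev(revcomp_chr(pieces))
    ex$len <- ex$end - ex$start + 1L
    # cumulative CDS offset (0-based) of each exon's first base in reading
    # order
    reading <- if (strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    off <- cumsum(c(0L, ex$len[reading]))[seq_len(nrow(ex))]
    ex$cds_offset <- off[match(seq_len(nrow(ex)), reading)]
    list(transcript_id = ex$transcript_id[1], gene_id = ex$gene_id[1],
         chrom = ex$chrom[1], strand = strand, exons = ex,
         cds_seq = paste(pieces, collapse = ""))
  })
}

#' Classify coding consequences of variants
#'
#' A variant is \code{coding} when its reference span intersects any CDS
#' interval.  For length-preserving substitutions (SNV, MNV) lying fully
#' inside a single CDS exon, the affected codons of the first overlapping
#' transcript are translated before and after the edit with the standard
#' genetic code and the effect is reported as \code{synonymous},
#' \code{missense} or \code{nonsense} (stop gain); every other coding
#' configuration (indels, exon-junction spans, stop-codon loss) is
#' \code{other}.
#'
#' @param variants \code{data.frame} with columns \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}.
#' @param genome \code{DNAStringSet} (see [read_genome_fasta()]).
#' @param annotation \code{genome_annotation} (see
#'   [read_genome_annotation()]).
#' @return \code{data.frame} with one row per variant: \code{key},
#'   \code{region}, \code{gene_id}, \code{transcript_id}, \code{effect},
#'   \code{ref_aa}, \code{codon_index}, \code{alt_aa}.
#' @export
classify_coding <- function(variants, genome, annotation) {
  v <- as.data.frame(variants)
  if (is.null(v$key)) v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  seqs <- as.character(genome)
  tx <- build_transcripts(annotation, genome)
  tx_by_chrom <- split(names(tx),
                       vapply(tx, `[[`, character(1), "chrom"))
  out <- data.frame(key = v$key, region = "non-coding",
                    gene_id = NA_character_, transcript_id = NA_character_,
                    effect = NA_character_, ref_aa = NA_character_,
                    codon_index = NA_integer_, alt_aa = NA_character_,
                    stringsAsFactors = FALSE)
  cds <- annotation$cds
  for (i in seq_len(nrow(v))) {
    chrom <- v$chrom[i]; pos <- v$pos[i]
    ref <- toupper(v$ref[i]); alt <- toupper(v$alt[i])
    span_end <- pos + nchar(ref) - 1L
    gref <- substr(seqs[[chrom]], pos, span_end)
    if (!identical(gref, ref))
      stop(sprintf("reference mismatch at %s:%d: VCF says %s, genome has %s",
                   chrom, pos, ref, gref))
    hit <- cds$chrom == chrom & cds$start <= span_end & cds$end >= pos
    if (!any(hit)) next
    first <- which(hit)[1]
    t <- tx[[cds$transcript_id[first]]]
    out$region[i] <- "coding"
    out$gene_id[i] <- t$gene_id
    out$transcript_id[i] <- t$transcript_id
    out$effect[i] <- "other"
    if (nchar(ref) != nchar(alt)) next            # indel: frameshift etc.
    ex <- t$exons
    j <- which(ex$start <= pos & ex$end >= span_end)
    if (length(j) != 1) next                      # spans an exon junction
    j <- j[1]
    if (t$strand == "+") {
      cds_lo <- ex$cds_offset[j] + (pos - ex$start[j])
      alt_r <- alt
    } else {
      cds_lo <- ex$cds_offset[j] + (ex$end[j] - span_end)
      alt_r <- revcomp_chr(alt)
    }
    cds_hi <- cds_lo + nchar(ref) - 1L
    cod_first <- cds_lo %/% 3L
    cod_last <- cds_hi %/% 3L
    ref_block <- substr(t$cds_seq, 3L * cod_first + 1L, 3L * cod_last + 3L)
    rel <- cds_lo - 3L * cod_first
    alt_block <- paste0(substr(ref_block, 1L, rel),
                        alt_r,
                        substr(ref_block, rel + nchar(ref) + 1L,
                               nchar(ref_block)))
    aa_ref <- translate_codons(ref_block)
    aa_alt <- translate_codons(alt_block)
    if (identical(aa_ref, aa_alt)) {
      out$effect[i] <- "synonymous"
      next
    }
    d <- which(aa_ref != aa_alt)[1]
    if (aa_ref[d] == "*") next                    # stop loss -> other
    out$effect[i] <- if (aa_alt[d] == "*") "nonsense" else "missense"
    out$ref_aa[i] <- aa_ref[d]
    out$codon_index[i] <- cod_first + d           # 1-based protein position
    out$alt_aa[i] <- aa_alt[d]
  }
  out
}
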