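# Readers and writers for the standard formats: VCF 4.x (vcfR), GFF3
# (ape::read.gff), FASTA (Biostrings), and the package's tab-delimited
# variant tables.  Multi-allelic VCF sites are split into one record per
# alternate allele; variant identity is the literal (chrom, pos, ref, alt)
# with no left-alignment or normalisation.

# Parse one VCF file into a long data.frame of per-sample genotype calls:
# chrom, pos, ref, alt, sample_id, dos, pld.  Sites are split per ALT.
parse_vcf_calls <- function(path, keep_samples = NULL) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF '", path,
                                         "': ", conditionMessage(e)))
  fix <- v@fix
  if (nrow(fix) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      sample_id = character(), dos = integer(),
                      pld = integer(), stringsAsFactors = FALSE))
  gt_raw <- v@gt
  samp_ids <- colnames(gt_raw)[-1]
  if (!is.null(keep_samples)) {
    keep <- samp_ids %in% keep_samples
    samp_ids <- samp_ids[keep]
    gt_raw <- gt_raw[, c(TRUE, keep), drop = FALSE]
  }
  if (length(samp_ids) == 0)
    stop("VCF '", path, "' contains no samples from the manifest")
  gt <- sub(":.*$", "", gt_raw[, -1, drop = FALSE])  # GT is first sub-field
  alleles <- strsplit(gt, "[/|]")
  dim(alleles) <- dim(gt)
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ai <- alleles[i, ]
    nal <- vapply(ai, function(a) sum(a != "." & a != ""), integer(1))
    for (k in seq_along(alts[[i]])) {
      dos <- vapply(ai, function(a) sum(a == as.character(k)), integer(1))
      out[[length(out) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[[i]][k],
        sample_id = samp_ids, dos = dos, pld = nal,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Read per-sample (or multi-sample) VCFs into a population call set
#'
#' Reads every VCF named in \code{meta$vcf_path} (or \code{paths}), splits
#' multi-allelic sites into one record per alternate allele, and merges the
#' calls into a single [population_callset()].  A sample is a carrier of a
#' record when its genotype contains at least one copy of that alternate
#' allele; samples with no call at a site listed only in other samples'
#' files are taken as homozygous reference (variant-detection semantics).
#'
#' @param meta sample metadata for one population, with a \code{vcf_path}
#'   column unless \code{paths} is supplied.
#' @param paths optional character vector of VCF paths overriding
#'   \code{meta$vcf_path}; recycled metadata applies when one multi-sample
#'   file carries several samples.
#' @return A \code{population_callset}.
#' @export
read_population_vcfs <- function(meta, paths = NULL) {
  if (is.null(paths)) {
    if (is.null(meta$vcf_path)) stop("no VCF paths given")
    paths <- unique(meta$vcf_path)
  }
  pop <- unique(meta$population)
  if (length(pop) != 1)
    stop("meta must describe a single population")
  calls <- do.call(rbind, lapply(paths, parse_vcf_calls,
                                 keep_samples = meta$sample_id))
  seen <- unique(calls$sample_id)
  missing <- setdiff(meta$sample_id, seen)
  if (length(missing))
    stop("samples absent from the supplied VCFs: ",
         paste(missing, collapse = ", "))
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  # a key becomes a record only when some sample carries the alternate
  # allele; homozygous-reference-only sites are not variant records
  ukey <- unique(key[calls$dos > 0])
  idx <- match(key, ukey)
  variants <- calls[match(ukey, key), c("chrom", "pos", "ref", "alt")]
  n <- length(ukey)
  m <- nrow(meta)
  dos <- matrix(0L, n, m, dimnames = list(ukey, meta$sample_id))
  # default ploidy: expected called alleles for samples without a record
  pld <- t(vapply(seq_len(n), function(i)
    contig_ploidy(rep(variants$chrom[i], m), meta$sex), integer(m)))
  dimnames(pld) <- dimnames(dos)
  j <- match(calls$sample_id, meta$sample_id)
  keep <- !is.na(idx)
  dos[cbind(idx[keep], j[keep])] <- calls$dos[keep]
  pld[cbind(idx[keep], j[keep])] <- calls$pld[keep]
  population_callset(pop, meta, variants, dos, pld)
}

#' Read a known-variants VCF into a key set
#'
#' @param path VCF of known (database) variants; genotypes are ignored.
#' @return Character vector of \code{chrom:pos:ref>alt} keys, one per
#'   alternate allele.
#' @export
read_known_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) return(character())
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n <- lengths(alts)
  unique(variant_key(rep(fix[, "CHROM"], n),
                     rep(as.integer(fix[, "POS"]), n),
                     rep(fix[, "REF"], n), unlist(alts)))
}

#' Write / read a variant table
#'
#' Tab-delimited table with one row per variant record: chrom, pos, ref,
#' alt, vtype, comma-separated carrier sample ids, and the known flag.
#' \code{read_variant_table(write_variant_table(x))} round-trips losslessly.
#'
#' @param records \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, optionally \code{carriers} (character,
#'   comma-separated) and \code{known} (logical).
#' @param path output path.
#' @return \code{write_variant_table} returns \code{path} invisibly;
#'   \code{read_variant_table} returns the records \code{data.frame}.
#' @export
write_variant_table <- function(records, path) {
  df <- as.data.frame(records)
  if (is.null(df$vtype) && nrow(df) > 0)
    df$vtype <- classify_variant_type(df$ref, df$alt)
  if (is.null(df$carriers)) df$carriers <- ""
  if (is.null(df$known)) df$known <- NA
  cols <- c("chrom", "pos", "ref", "alt", "vtype", "carriers", "known")
  if (nrow(df) == 0)
    df <- data.frame(chrom = character(), pos = integer(),
                     ref = character(), alt = character(),
                     vtype = character(), carriers = character(),
                     known = logical())
  write.table(df[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character", ref = "character",
                                  alt = "character", carriers = "character"))
  df$pos <- as.integer(df$pos)
  df$known <- as.logical(df$known)
  df$carriers[is.na(df$carriers)] <- ""
  df
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet] named by contig (description text
#'   after the first whitespace is dropped).
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# Extract one attribute (e.g. "ID") from GFF3 column-9 strings.
gff_attr <- function(attributes, name) {
  hit <- regexpr(paste0("(^|;)", name, "=[^;]+"), attributes)
  val <- substr(attributes, hit, hit + attr(hit, "match.length") - 1L)
  val <- sub(paste0("^;?", name, "="), "", val)
  val[hit < 0] <- NA
  val
}

#' Read a GFF3 gene/CDS annotation
#'
#' Parses gene, mRNA and CDS features and returns contig lengths (from
#' \code{##sequence-region} pragmas, or from \code{genome} when supplied),
#' gene spans and CDS intervals with strand, phase and transcript linkage.
#'
#' @param path GFF3 path.
#' @param genome optional \code{DNAStringSet} supplying contig lengths when
#'   the GFF carries no \code{##sequence-region} pragmas.
#' @return An object of class \code{genome_annotation}: a list with
#'   \code{contig_lengths} (named numeric), \code{genes} and \code{cds}
#'   data frames.
#' @export
read_genome_annotation <- function(path, genome = NULL) {
  gff <- ape::read.gff(path, GFF3 = TRUE)
  lines <- grep("^##sequence-region", readLines(path), value = TRUE)
  contig_lengths <- numeric()
  if (length(lines)) {
    parts <- strsplit(trimws(lines), "\\s+")
    contig_lengths <- setNames(
      vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
      vapply(parts, function(p) p[2], character(1)))
  }
  if (!is.null(genome))
    contig_lengths <- setNames(Biostrings::width(genome), names(genome))
  gff$seqid <- as.character(gff$seqid)
  gff$strand <- as.character(gff$strand)
  genes <- gff[gff$type == "gene", ]
  genes <- data.frame(chrom = genes$seqid, start = genes$start,
                      end = genes$end, strand = genes$strand,
                      gene_id = gff_attr(genes$attributes, "ID"),
                      stringsAsFactors = FALSE)
  tx <- gff[gff$type %in% c("mRNA", "transcript"), ]
  tx_gene <- setNames(gff_attr(tx$attributes, "Parent"),
                      gff_attr(tx$attributes, "ID"))
  cds <- gff[gff$type == "CDS", ]
  tx_id <- gff_attr(cds$attributes, "Parent")
  cds <- data.frame(chrom = cds$seqid, start = cds$start, end = cds$end,
                    strand = cds$strand,
                    phase = suppressWarnings(as.integer(as.character(cds$phase))),
                    transcript_id = tx_id,
                    gene_id = unname(tx_gene[tx_id]),
                    stringsAsFactors = FALSE)
  bad <- tapply(cds$end - cds$start + 1L, cds$transcript_id, sum) %% 3L
  if (any(bad != 0, na.rm = TRUE))
    stop("CDS length not divisible by 3 for transcript(s): ",
         paste(names(bad)[bad != 0], collapse = ", "))
  structure(list(contig_lengths = contig_lengths, genes = genes, cds = cds),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("Genome annotation:", length(x$contig_lengths), "contigs,",
      nrow(x$genes), "genes,", nrow(x$cds), "CDS segments\n")
  invisible(x)
}
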