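# Shared fixtures: hand-built call sets, a tiny coding genome, and a
# lazily simulated synthetic study reused across test files.

# Internal helpers exercised directly by the suite.
contig_ploidy <- altiscan:::contig_ploidy
pearson_chisq <- altiscan:::pearson_chisq
bn_draw <- altiscan:::bn_draw
genotype_indicator <- altiscan:::genotype_indicator

# Build a population_callset from a dosage matrix (variants x samples).
mk_callset <- function(population, dos, variants, sexes = NULL,
                       pld = NULL) {
  dos <- as.matrix(dos)
  n <- ncol(dos)
  if (is.null(sexes)) sexes <- rep(c("male", "female"), length.out = n)
  prefix <- if (population == "highland") "H" else "L"
  meta <- sample_meta(sprintf("%s%02d", prefix, seq_len(n)), population,
                      sexes)
  if (is.null(pld)) {
    pld <- matrix(2L, nrow(dos), n)
    for (j in seq_len(n))
      pld[, j] <- contig_ploidy(variants$chrom, meta$sex[j])
  }
  population_callset(population, meta, variants, dos, pld)
}

snv_variants <- function(n, chrom = "chr1", start = 100L, by = 50L) {
  data.frame(chrom = chrom, pos = start + by * (seq_len(n) - 1L),
             ref = rep(c("A", "C", "G", "T"), length.out = n),
             alt = rep(c("G", "T", "A", "C"), length.out = n),
             stringsAsFactors = FALSE)
}

# A tiny genome with one plus-strand and one minus-strand single-exon CDS
# whose sequences are fully controlled.
tiny_coding_genome <- function() {
  left <- paste(rep("A", 99), collapse = "")
  plus_cds <- "ATGGATTAA"                     # M D *
  mid <- paste(rep("C", 91), collapse = "")
  # minus-strand CDS: reading sequence ATGGATTAA; genomic = revcomp
  minus_genomic <- "TTAATCCAT"
  right <- paste(rep("G", 101), collapse = "")
  seq <- paste0(left, plus_cds, mid, minus_genomic, right)
  genome <- Biostrings::DNAStringSet(setNames(seq, "chr1"))
  gff <- c("##gff-version 3",
           sprintf("##sequence-region chr1 1 %d", nchar(seq)),
           "chr1\ttest\tgene\t100\t108\t.\t+\t.\tID=geneP",
           "chr1\ttest\tmRNA\t100\t108\t.\t+\t.\tID=txP;Parent=geneP",
           "chr1\ttest\tCDS\t100\t108\t.\t+\t0\tID=cdsP;Parent=txP",
           "chr1\ttest\tgene\t200\t208\t.\t-\t.\tID=geneM",
           "chr1\ttest\tmRNA\t200\t208\t.\t-\t.\tID=txM;Parent=geneM",
           "chr1\ttest\tCDS\t200\t208\t.\t-\t0\tID=cdsM;Parent=txM")
  path <- tempfile(fileext = ".gff3")
  writeLines(gff, path)
  list(genome = genome, annotation = read_genome_annotation(path, genome))
}

# Full-transcript translation oracle for coding consequences: rebuild the
# spliced CDS before and after the edit and translate with Biostrings.
oracle_consequence <- function(chrom, pos, ref, alt, genome, annotation) {
  cds <- annotation$cds
  span_end <- pos + nchar(ref) - 1L
  hit <- which(cds$chrom == chrom & cds$start <= span_end &
                 cds$end >= pos)
  if (length(hit) == 0) return(list(region = "non-coding",
                                    effect = NA_character_))
  t_id <- cds$transcript_id[hit[1]]
  ex <- cds[cds$transcript_id == t_id, ]
  ex <- ex[order(ex$start), ]
  if (nchar(ref) != nchar(alt))
    return(list(region = "coding", effect = "other"))
  inside <- any(ex$start <= pos & ex$end >= span_end)
  if (!inside) return(list(region = "coding", effect = "other"))
  seq <- as.character(genome[[chrom]])
  edited <- paste0(substr(seq, 1, pos - 1), alt,
                   substr(seq, span_end + 1, nchar(seq)))
  splice <- function(s) {
    pieces <- substring(s, ex$start, ex$end)
    cdsseq <- paste(pieces, collapse = "")
    if (ex$strand[1] == "-")
      cdsseq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cdsseq)))
    cdsseq
  }
  aa0 <- as.character(Biostrings::translate(
    Biostrings::DNAString(splice(seq)), no.init.codon = TRUE))
  aa1 <- as.character(Biostrings::translate(
    Biostrings::DNAString(splice(edited)), no.init.codon = TRUE))
  if (aa0 == aa1) return(list(region = "coding", effect = "synonymous"))
  d <- which(strsplit(aa0, "")[[1]] != strsplit(aa1, "")[[1]])[1]
  r <- substr(aa0, d, d); a <- substr(aa1, d, d)
  eff <- if (r == "*") "other" else if (a == "*") "nonsense" else "missense"
  list(region = "coding", effect = eff, ref_aa = r, codon_index = d,
       alt_aa = a)
}

# Independent transcription of the Weir-Cockerham (1984) two-population
# variance components, written as scalar sums over populations.
wc_oracle <- function(g1, g2) {
  gl <- list(g1[!is.na(g1)], g2[!is.na(g2)])
  r <- 2
  n <- vapply(gl, length, numeric(1))
  p <- vapply(gl, function(g) sum(g) / (2 * length(g)), numeric(1))
  h <- vapply(gl, function(g) mean(g == 1), numeric(1))
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       theta = if (a + b + cc == 0) NA_real_ else a / (a + b + cc))
}

# Lazily simulated default study, shared by the heavier tests.
.fixture_env <- new.env(parent = emptyenv())
get_test_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- simulate_study(sim_config(seed = 20240601 %% 1000),
                                         tempfile("study_"))
  .fixture_env$study
}
get_test_callsets <- function() {
  if (is.null(.fixture_env$callsets)) {
    s <- get_test_study()
    .fixture_env$callsets <- list(
      high = read_population_vcfs(s$meta[s$meta$population == "highland", ]),
      low = read_population_vcfs(s$meta[s$meta$population == "lowland", ]))
  }
  .fixture_env$callsets
}
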