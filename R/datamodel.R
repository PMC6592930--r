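# Core data model: sample metadata, variant keys/records, population call
# sets.  Coordinates are 1-based inclusive at the VCF/GFF boundary; internal
# interval arithmetic (windows, regions) is 0-based half-open.

#' Sample metadata table
#'
#' Validates and normalises a sample manifest.  Every sample carries a
#' population label (\code{"highland"} or \code{"lowland"}) and a sex
#' (\code{"male"} or \code{"female"}); both drive the sex-stratified
#' contrasts downstream.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param population character vector, one of \code{"highland"},
#'   \code{"lowland"} per sample.
#' @param sex character vector, one of \code{"male"}, \code{"female"}.
#' @param vcf_path optional character vector of per-sample VCF paths.
#' @return A \code{data.frame} with columns \code{sample_id},
#'   \code{population}, \code{sex} and (if given) \code{vcf_path}.
#' @examples
#' sample_meta(c("H1", "L1"), c("highland", "lowland"), c("male", "female"))
#' @export
sample_meta <- function(sample_id, population, sex, vcf_path = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  population <- match.arg(as.character(population),
                          c("highland", "lowland"), several.ok = TRUE)
  sex <- match.arg(as.character(sex), c("male", "female"), several.ok = TRUE)
  n <- length(sample_id)
  if (length(population) == 1) population <- rep(population, n)
  if (length(sex) == 1) sex <- rep(sex, n)
  stopifnot(length(population) == n, length(sex) == n)
  out <- data.frame(sample_id = sample_id, population = population,
                    sex = sex, stringsAsFactors = FALSE)
  if (!is.null(vcf_path)) out$vcf_path <- as.character(vcf_path)
  out
}

#' Read a sample manifest file
#'
#' The manifest is a tab-delimited file with columns \code{sample_id},
#' \code{population}, \code{sex} and optionally \code{vcf_path}.  Relative
#' VCF paths are resolved against the manifest's own directory.
#'
#' @param path path to the manifest TSV.
#' @return A validated sample metadata \code{data.frame} (see
#'   [sample_meta()]).
#' @export
read_sample_manifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "sex")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  vp <- df$vcf_path
  if (!is.null(vp)) {
    rel <- !grepl("^(/|[A-Za-z]:)", vp)
    vp[rel] <- file.path(dirname(path), vp[rel])
  }
  sample_meta(df$sample_id, df$population, df$sex, vp)
}

#' Classify variant type from reference and alternate alleles
#'
#' Five-class scheme: SNV (single-base substitution), MNV (equal-length
#' multi-base substitution), insertion (reference is a proper prefix of the
#' alternate), deletion (alternate is a proper prefix of the reference), and
#' replacement for every other length-changing edit.
#'
#' @param ref,alt character vectors of reference/alternate alleles over
#'   A, C, G, T.
#' @return Character vector with values in \code{c("SNV", "MNV",
#'   "insertion", "deletion", "replacement")}.
#' @examples
#' classify_variant_type("C", "T")       # SNV
#' classify_variant_type("A", "ACG")     # insertion
#' classify_variant_type("ACG", "TT")    # replacement
#' @export
classify_variant_type <- function(ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (length(alt) != length(ref)) stop("ref and alt must have equal length")
  if (any(!grepl("^[ACGT]+$", ref)) || any(!grepl("^[ACGT]+$", alt)))
    stop("alleles must be non-empty strings over {A,C,G,T}")
  if (any(ref == alt)) stop("ref and alt must differ")
  nr <- nchar(ref); na <- nchar(alt)
  out <- rep("replacement", length(ref))
  out[nr == 1 & na == 1] <- "SNV"
  out[nr == na & nr > 1] <- "MNV"
  ins <- nr < na & substr(alt, 1L, nr) == ref
  del <- nr > na & substr(ref, 1L, na) == alt
  out[ins] <- "insertion"
  out[del] <- "deletion"
  out
}

#' Lander-Waterman expected fold-coverage
#'
#' Computes C = L N / G for read length L (bp), read count N and haploid
#' genome length G (bp).
#'
#' @param L read length in bp.
#' @param N number of reads.
#' @param G haploid genome length in bp.
#' @return Expected fold-coverage (dimensionless).
#' @examples
#' lander_waterman_coverage(125, 8e6, 1e8)  # 10
#' @export
lander_waterman_coverage <- function(L, N, G) {
  if (any(c(L, N, G) <= 0)) stop("L, N and G must all be positive")
  L * N / G
}

# Canonical string key for a variant: chrom:pos:ref>alt.
variant_key <- function(chrom, pos, ref, alt) {
  if (length(chrom) == 0) return(character())
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

# Expected number of called alleles for a sample at a contig.  MT and W are
# haploid; Z is haploid in females (ZW) and diploid in males (ZZ); W absent
# in males.
contig_ploidy <- function(chrom, sex) {
  p <- rep(2L, length(chrom))
  p[chrom == "MT"] <- 1L
  p[chrom == "W"] <- ifelse(sex == "female", 1L, 0L)
  p[chrom == "Z"] <- ifelse(sex == "female", 1L, 2L)
  p
}

#' Construct a population call set
#'
#' Low-level constructor used by [read_population_vcfs()] and the
#' simulator.  A call set holds one record per distinct variant key
#' (chrom, pos, ref, alt) plus per-sample genotype evidence as an
#' alternate-allele dosage matrix and a called-allele (ploidy) matrix.
#'
#' @param population \code{"highland"} or \code{"lowland"}.
#' @param samples sample metadata (see [sample_meta()]); all must belong to
#'   \code{population}.
#' @param variants \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} (and optionally \code{known}).
#' @param dos integer matrix, variants x samples, of alternate-allele
#'   dosages.
#' @param pld integer matrix of called allele counts per genotype (2 for
#'   diploid, 1 haploid, 0 absent).
#' @return An object of class \code{population_callset}.
#' @export
population_callset <- function(population, samples, variants, dos, pld) {
  population <- match.arg(population, c("highland", "lowland"))
  if (!all(samples$population == population))
    stop("all samples must belong to population '", population, "'")
  variants <- as.data.frame(variants)
  variants$pos <- as.integer(variants$pos)
  if (nrow(variants) == 0) {
    variants$vtype <- character()
    variants$key <- character()
  } else {
    variants$vtype <- classify_variant_type(variants$ref, variants$alt)
    variants$key <- variant_key(variants$chrom, variants$pos,
                                variants$ref, variants$alt)
  }
  if (anyDuplicated(variants$key)) stop("duplicate variant keys")
  if (is.null(variants$known))
    variants$known <- rep(NA, nrow(variants))
  dos <- as.matrix(dos); pld <- as.matrix(pld)
  stopifnot(nrow(dos) == nrow(variants), nrow(pld) == nrow(variants),
            ncol(dos) == nrow(samples), ncol(pld) == nrow(samples))
  dimnames(dos) <- dimnames(pld) <- list(variants$key, samples$sample_id)
  if (any(dos > pld)) stop("dosage exceeds number of called alleles")
  ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
  structure(list(population = population, samples = samples,
                 variants = variants[ord, , drop = FALSE],
                 dos = dos[ord, , drop = FALSE],
                 pld = pld[ord, , drop = FALSE]),
            class = "population_callset")
}

#' @export
print.population_callset <- function(x, ...) {
  cat("Population call set:", x$population, "\n")
  cat("  samples:", nrow(x$samples),
      sprintf("(%d male, %d female)", sum(x$samples$sex == "male"),
              sum(x$samples$sex == "female")), "\n")
  cat("  variants:", nrow(x$variants), "on",
      length(unique(x$variants$chrom)), "contigs\n")
  print(table(x$variants$vtype))
  invisible(x)
}

# Samples of a call set belonging to a sex stratum ("male"/"female"/"pooled").
stratum_samples <- function(callset, stratum = "pooled") {
  stratum <- match.arg(stratum, c("pooled", "male", "female"))
  s <- callset$samples
  ids <- if (stratum == "pooled") s$sample_id else
    s$sample_id[s$sex == stratum]
  if (length(ids) == 0)
    stop("no ", stratum, " samples in population ", callset$population)
  ids
}

# Logical carrier matrix (>= 1 alternate allele), variants x samples.
carrier_matrix <- function(callset) callset$dos > 0L

#' Subset a call set to one contig
#'
#' @param callset a \code{population_callset}.
#' @param chrom contig name (e.g. \code{"MT"}).
#' @return A \code{population_callset} restricted to variants on
#'   \code{chrom} (possibly with zero records).
#' @export
subset_contig <- function(callset, chrom) {
  keep <- callset$variants$chrom %in% chrom
  out <- callset
  out$variants <- callset$variants[keep, , drop = FALSE]
  out$dos <- callset$dos[keep, , drop = FALSE]
  out$pld <- callset$pld[keep, , drop = FALSE]
  out
}
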