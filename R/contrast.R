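# Population contrast: differential / common variant extraction under
# carrier-fraction thresholds, novelty flagging, mtDNA accounting and
# replication-cohort validation.  "Present in a sample" means at least one
# alternate allele in the genotype; the carrier-fraction denominator is the
# number of stratum samples of the focal population.

# Union of two call sets' variants with per-stratum carrier counts.
contrast_counts <- function(a, b, stratum = "pooled") {
  sa <- stratum_samples(a, stratum)
  sb <- stratum_samples(b, stratum)
  va <- a$variants; vb <- b$variants
  uni <- rbind(va[, c("chrom", "pos", "ref", "alt", "vtype", "key")],
               vb[, c("chrom", "pos", "ref", "alt", "vtype", "key")])
  uni <- uni[!duplicated(uni$key), , drop = FALSE]
  ca <- rowSums(a$dos[, sa, drop = FALSE] > 0L)
  cb <- rowSums(b$dos[, sb, drop = FALSE] > 0L)
  uni$carriers_a <- ifelse(is.na(match(uni$key, va$key)), 0L,
                           ca[match(uni$key, va$key)])
  uni$carriers_b <- ifelse(is.na(match(uni$key, vb$key)), 0L,
                           cb[match(uni$key, vb$key)])
  attr(uni, "n_a") <- length(sa)
  attr(uni, "n_b") <- length(sb)
  uni
}

#' Differential variants between two populations
#'
#' A variant is differential for population A when it is carried by at
#' least one of A's stratum samples, absent from all of B's stratum
#' samples, and carried by at least \code{threshold}\% of A's stratum
#' samples (ties at the threshold included); and symmetrically for B.  A
#' variant observed in both populations is a common candidate and is never
#' differential at any threshold.
#'
#' @param a,b \code{population_callset}s for the two populations (disjoint
#'   sample sets).
#' @param threshold carrier-fraction threshold in percent; the
#'   conventional values are 0, 25, 50, 75 and 100 (others are accepted
#'   with a warning).
#' @param stratum \code{"pooled"}, \code{"male"} or \code{"female"}:
#'   samples are restricted by sex before computing carrier fractions.
#' @return An object of class \code{contrast_result} with the classified
#'   variant table (\code{$variants}, column \code{status}), per-population
#'   differential sets (\code{$differential}), common keys
#'   (\code{$common_any}, \code{$common_strict}) and counts.
#' @export
differential_variants <- function(a, b, threshold = 50,
                                  stratum = "pooled") {
  if (length(intersect(a$samples$sample_id, b$samples$sample_id)))
    stop("populations share sample ids")
  if (!threshold %in% c(0, 25, 50, 75, 100))
    warning("unconventional frequency threshold: ", threshold)
  if (threshold < 0 || threshold > 100)
    stop("threshold must be a percentage in [0, 100]")
  uni <- contrast_counts(a, b, stratum)
  n_a <- attr(uni, "n_a"); n_b <- attr(uni, "n_b")
  frac_a <- uni$carriers_a / n_a
  frac_b <- uni$carriers_b / n_b
  t <- threshold / 100
  status <- rep("below_threshold", nrow(uni))
  status[uni$carriers_a > 0L & uni$carriers_b > 0L] <- "common"
  da <- uni$carriers_a > 0L & uni$carriers_b == 0L & frac_a >= t
  db <- uni$carriers_b > 0L & uni$carriers_a == 0L & frac_b >= t
  status[da] <- paste0("differential_", a$population)
  status[db] <- paste0("differential_", b$population)
  uni$frac_a <- frac_a; uni$frac_b <- frac_b
  uni$status <- status
  diff_sets <- list(uni[da, , drop = FALSE], uni[db, , drop = FALSE])
  names(diff_sets) <- c(a$population, b$population)
  structure(list(
    threshold = threshold, stratum = stratum,
    populations = c(a$population, b$population),
    n_stratum = c(n_a, n_b),
    variants = uni,
    differential = diff_sets,
    common_any = uni$key[status == "common"],
    common_strict = uni$key[uni$carriers_a == n_a & uni$carriers_b == n_b],
    counts = c(table(factor(status, levels = c(
      paste0("differential_", a$population),
      paste0("differential_", b$population),
      "common", "below_threshold"))))),
    class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("Population contrast (%s vs %s), stratum %s, threshold %g%%\n",
              x$populations[1], x$populations[2], x$stratum, x$threshold))
  print(x$counts)
  cat("strict common (carried by every stratum sample of both):",
      length(x$common_strict), "\n")
  invisible(x)
}

#' Common variants between two populations
#'
#' Variants observed in both populations' stratum samples.  The
#' \code{any} set requires at least one carrier on each side; the
#' \code{strict} set requires carriage by every stratum sample of both
#' populations (the headline set when the frequency threshold is 100\%).
#'
#' @inheritParams differential_variants
#' @return List with character key vectors \code{any} and \code{strict}.
#' @export
common_variants <- function(a, b, stratum = "pooled") {
  uni <- contrast_counts(a, b, stratum)
  n_a <- attr(uni, "n_a"); n_b <- attr(uni, "n_b")
  list(any = uni$key[uni$carriers_a > 0L & uni$carriers_b > 0L],
       strict = uni$key[uni$carriers_a == n_a & uni$carriers_b == n_b])
}

#' Flag novel variants against a known-variants database
#'
#' Allele-aware matching: a record is known only when its full
#' (chrom, pos, ref, alt) key has an entry in the database; a different
#' alternate allele at the same position is novel.
#'
#' @param x a \code{population_callset} or a variant \code{data.frame}
#'   with a \code{key} column (or chrom/pos/ref/alt columns).
#' @param known character vector of known keys (see
#'   [read_known_variants()]).
#' @return \code{x} with its \code{known} logical column set.
#' @export
flag_novel <- function(x, known) {
  set_known <- function(df) {
    if (is.null(df$key))
      df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
    df$known <- df$key %in% known
    df
  }
  if (inherits(x, "population_callset")) {
    x$variants <- set_known(x$variants)
    x
  } else set_known(as.data.frame(x))
}

#' Replication-cohort validation percentage
#'
#' For each variant key, 100 x (number of cohort samples carrying the
#' variant) / (cohort size), following the convention that validation is
#' computed over the samples sequenced for replication.
#'
#' @param keys character vector of variant keys
#'   (\code{chrom:pos:ref>alt}).
#' @param cohort a \code{population_callset} holding the replication
#'   samples.
#' @return Numeric vector of percentages in [0, 100], named by key.
#' @export
validation_percentage <- function(keys, cohort) {
  n <- nrow(cohort$samples)
  if (n < 1) stop("empty replication cohort")
  carr <- rowSums(carrier_matrix(cohort))
  out <- 100 * ifelse(is.na(match(keys, cohort$variants$key)), 0,
                      carr[match(keys, cohort$variants$key)]) / n
  setNames(out, keys)
}

#' Mitochondrial variant classification table
#'
#' Restricts both call sets to the MT contig and tabulates, per
#' population x sex group, the variants carried by at least one group
#' sample: counts by variant type, total, novel (when \code{known} is
#' given) and, when genome and annotation are given, coding and
#' amino-acid-changing counts.
#'
#' @param a,b \code{population_callset}s.
#' @param known optional known-variant key vector.
#' @param genome optional \code{DNAStringSet}.
#' @param annotation optional \code{genome_annotation}.
#' @return \code{data.frame} with one row per (population, sex) group.
#' @export
mtdna_classify <- function(a, b, known = NULL, genome = NULL,
                           annotation = NULL) {
  groups <- expand.grid(population = c(a$population, b$population),
                        sex = c("male", "female"),
                        stringsAsFactors = FALSE)
  groups <- groups[order(groups$population, groups$sex), ]
  vts <- c("SNV", "MNV", "insertion", "deletion", "replacement")
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    cs <- if (groups$population[i] == a$population) a else b
    mt <- subset_contig(cs, "MT")
    ids <- cs$samples$sample_id[cs$samples$sex == groups$sex[i]]
    pres <- if (nrow(mt$variants) == 0) logical(0) else
      rowSums(mt$dos[, ids, drop = FALSE] > 0L) > 0L
    v <- mt$variants[pres, , drop = FALSE]
    out <- as.list(table(factor(v$vtype, levels = vts)))
    out$total <- nrow(v)
    out$novel <- if (is.null(known)) NA_integer_ else
      sum(!(v$key %in% known))
    if (!is.null(genome) && !is.null(annotation) && nrow(v) > 0) {
      cons <- classify_coding(v, genome, annotation)
      out$coding <- sum(cons$region == "coding")
      out$aa_changes <- sum(cons$effect %in% c("missense", "nonsense"))
    } else {
      out$coding <- if (nrow(v) == 0) 0L else NA_integer_
      out$aa_changes <- if (nrow(v) == 0) 0L else NA_integer_
    }
    cbind(groups[i, , drop = FALSE], as.data.frame(out))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sex-stratified differential variant summary
#'
#' For each sex stratum, counts total differential variants (both
#' populations), novel, coding, non-coding and amino-acid-changing
#' variants.
#'
#' @param a,b \code{population_callset}s.
#' @param threshold carrier-fraction threshold in percent.
#' @param known optional known-variant key vector.
#' @param genome,annotation optional genome and annotation for the coding
#'   columns.
#' @param strata strata to report (default male, female).
#' @return \code{data.frame} with one row per stratum.
#' @export
contrast_summary <- function(a, b, threshold = 50, known = NULL,
                             genome = NULL, annotation = NULL,
                             strata = c("male", "female")) {
  rows <- lapply(strata, function(s) {
    cr <- differential_variants(a, b, threshold, s)
    d <- rbind(cr$differential[[1]], cr$differential[[2]])
    novel <- if (is.null(known)) NA_integer_ else sum(!(d$key %in% known))
    if (!is.null(genome) && !is.null(annotation) && nrow(d) > 0) {
      cons <- classify_coding(d, genome, annotation)
      coding <- sum(cons$region == "coding")
      aa <- sum(cons$effect %in% c("missense", "nonsense"))
    } else {
      coding <- if (nrow(d) == 0) 0L else NA_integer_
      aa <- if (nrow(d) == 0) 0L else NA_integer_
    }
    data.frame(stratum = s, total = nrow(d), novel = novel,
               coding = coding, non_coding = nrow(d) - coding,
               aa_changes = aa, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
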