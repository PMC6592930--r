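# Synthetic two-ecotype resequencing study: genome + annotation, two
# populations diverged under a Balding-Nichols model with planted
# high-F_ST sweep windows, mitochondrial variants, a known-variants
# database, gene sets, a 24-trait phenotype table and a replication
# cohort.  Every output parses with the package's own readers.

#' Configuration for the synthetic study generator
#'
#' Defaults are sized for desk scale: five 1 Mb autosomes plus Z, W and MT,
#' five diploid samples per population (highland 3 males + 2 females,
#' lowland 2 males + 3 females), roughly one variant per kb, neutral
#' background differentiation \code{background_fst = 0.02} and three
#' planted 100 kb windows at \code{sweep_fst = 0.5}.  Per-population allele
#' frequencies are drawn from a Balding-Nichols Beta distribution whose
#' parameter is the target F_ST; a fraction of sites is made private to one
#' population (and a quarter of those fixed) to provide differential-variant
#' truth.  Phenotypes cover 16 birds (10 lowland, 6 highland) with 24
#' correlated traits and a standardized mean shift of
#' \code{phenotype_effect} on the first \code{n_effect_traits} traits.
#'
#' @param seed integer master seed; all stages derive their streams from it.
#' @param n_autosomes,autosome_length autosome count and length (bp).
#' @param include_z,include_w,include_mt include the Z, W and MT contigs.
#' @param z_length,w_length,mt_length contig lengths (bp).
#' @param n_samples_per_pop diploid samples per population.
#' @param background_fst,sweep_fst target F_ST outside/inside planted
#'   windows; \code{0 <= background_fst < sweep_fst <= 1}.
#' @param n_sweep_windows,sweep_window_size number and width (bp) of
#'   planted windows (grid-aligned on autosomes).
#' @param snv_density expected variants per bp.
#' @param fraction_known proportion of sites listed in the known-variants
#'   VCF.
#' @param fraction_private proportion of non-sweep sites private to one
#'   population; \code{fraction_private_fixed} of those are fixed there.
#' @param vtype_prop named numeric proportions over the five variant
#'   classes.
#' @param genes_per_mb gene density for the simulated annotation.
#' @param n_traits,n_effect_traits,phenotype_effect,n_pheno_lowland,n_pheno_highland
#'   phenotype table shape and the per-trait standardized population shift.
#' @param n_replicates size of the highland replication cohort.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_autosomes = 5L, autosome_length = 1e6,
                       include_z = TRUE, include_w = TRUE,
                       include_mt = TRUE,
                       z_length = 5e5, w_length = 2e5, mt_length = 16500,
                       n_samples_per_pop = 5L,
                       background_fst = 0.02, sweep_fst = 0.5,
                       n_sweep_windows = 3L, sweep_window_size = 1e5,
                       snv_density = 1e-3,
                       fraction_known = 0.3,
                       fraction_private = 0.2,
                       fraction_private_fixed = 0.25,
                       vtype_prop = c(SNV = 0.92, MNV = 0.02,
                                      insertion = 0.02, deletion = 0.02,
                                      replacement = 0.02),
                       genes_per_mb = 20,
                       n_traits = 24L, n_effect_traits = 6L,
                       phenotype_effect = 3,
                       n_pheno_lowland = 10L, n_pheno_highland = 6L,
                       n_replicates = 5L) {
  cfg <- as.list(environment())
  stopifnot(background_fst >= 0, background_fst < sweep_fst, sweep_fst <= 1,
            snv_density > 0, snv_density <= 1,
            fraction_known >= 0, fraction_known <= 1,
            fraction_private >= 0, fraction_private <= 1,
            n_samples_per_pop >= 2)
  cfg$vtype_prop <- vtype_prop / sum(vtype_prop)
  class(cfg) <- "sim_config"
  cfg
}

# Contig name/length vector implied by a config.
sim_contigs <- function(cfg) {
  len <- setNames(rep(cfg$autosome_length, cfg$n_autosomes),
                  paste0("chr", seq_len(cfg$n_autosomes)))
  if (cfg$include_z) len <- c(len, Z = cfg$z_length)
  if (cfg$include_w) len <- c(len, W = cfg$w_length)
  if (cfg$include_mt) len <- c(len, MT = cfg$mt_length)
  len
}

# Sample metadata mirroring the study design: highland 3M+2F, lowland 2M+3F
# (pattern recycled/truncated for other sample counts).
sim_sample_meta <- function(cfg) {
  n <- cfg$n_samples_per_pop
  sex_h <- rep(c("male", "female"), c(ceiling(0.6 * n), n - ceiling(0.6 * n)))
  sex_l <- rep(c("male", "female"), c(floor(0.4 * n), n - floor(0.4 * n)))
  rbind(sample_meta(sprintf("H%02d", seq_len(n)), "highland", sex_h),
        sample_meta(sprintf("L%02d", seq_len(n)), "lowland", sex_l))
}

#' Simulate a genome FASTA and GFF3 annotation
#'
#' Uniform-random contigs with non-overlapping genes of one to three CDS
#' exons on both strands; every exon length is a multiple of three, so CDS
#' totals translate cleanly.  Deterministic given \code{cfg$seed}.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return List with \code{fasta}/\code{gff} paths, the \code{genome}
#'   (\code{DNAStringSet}) and parsed \code{annotation}.
#' @export
simulate_genome <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 101L)
  lens <- sim_contigs(cfg)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(lens)
  gff <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", names(lens), as.integer(lens)))
  for (chrom in names(lens)) {
    L <- lens[[chrom]]
    n_genes <- if (chrom == "MT") 2L else max(1L, round(L / 1e6 * cfg$genes_per_mb))
    slot <- floor(L / n_genes)
    if (slot < 2000) n_genes <- max(1L, floor(L / 2000)); slot <- floor(L / n_genes)
    for (i in seq_len(n_genes)) {
      n_ex <- sample(1:3, 1)
      ex_len <- sample(c(150L, 300L, 450L), n_ex, replace = TRUE)
      introns <- if (n_ex > 1) sample(100:500, n_ex - 1, replace = TRUE) else integer()
      span <- sum(ex_len) + sum(introns)
      lo <- (i - 1L) * slot + 1L
      hi <- i * slot - span - 10L
      if (hi <= lo) next
      gstart <- sample(lo:hi, 1)
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("gene_%s_%03d", chrom, i)
      tid <- sprintf("tx_%s_%03d", chrom, i)
      starts <- gstart + cumsum(c(0L, ex_len[-n_ex] + introns))
      ends <- starts + ex_len - 1L
      gff <- c(gff,
        sprintf("%s\taltiscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom,
                gstart, max(ends), strand, gid),
        sprintf("%s\taltiscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                chrom, gstart, max(ends), strand, tid, gid),
        sprintf("%s\taltiscan\tCDS\t%d\t%d\t.\t%s\t0\tID=cds_%s_%d;Parent=%s",
                chrom, starts, ends, strand, tid, seq_len(n_ex), tid))
    }
  }
  fasta <- file.path(dir, "genome.fa")
  gff_path <- file.path(dir, "genes.gff3")
  Biostrings::writeXStringSet(genome, fasta, width = 70L)
  writeLines(gff, gff_path)
  list(fasta = fasta, gff = gff_path, genome = genome,
       annotation = read_genome_annotation(gff_path, genome))
}

# Balding-Nichols per-population frequency draw: Beta with mean p and
# variance theta * p * (1 - p).
bn_draw <- function(p, theta) {
  out <- p
  i <- theta > 0
  out[i] <- rbeta(sum(i), p[i] * (1 - theta[i]) / theta[i],
                  (1 - p[i]) * (1 - theta[i]) / theta[i])
  out
}

# Draw ref/alt alleles for one site of a given class from the contig
# sequence (plain character string).
draw_alleles <- function(seq_chr, pos, vtype) {
  base_at <- function(a, b) substr(seq_chr, a, b)
  other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)
  switch(vtype,
    SNV = {
      ref <- base_at(pos, pos); list(ref = ref, alt = other(ref))
    },
    MNV = {
      w <- sample(2:3, 1); ref <- base_at(pos, pos + w - 1)
      alt <- ref
      while (alt == ref)
        alt <- paste(sample(c("A", "C", "G", "T"), w, TRUE), collapse = "")
      list(ref = ref, alt = alt)
    },
    insertion = {
      ref <- base_at(pos, pos)
      list(ref = ref, alt = paste0(ref, paste(
        sample(c("A", "C", "G", "T"), sample(1:3, 1), TRUE), collapse = "")))
    },
    deletion = {
      w <- sample(2:4, 1); ref <- base_at(pos, pos + w - 1)
      list(ref = ref, alt = substr(ref, 1, 1))
    },
    replacement = {
      ref <- base_at(pos, pos + 1)
      first <- other(substr(ref, 1, 1))
      list(ref = ref, alt = paste0(first, paste(
        sample(c("A", "C", "G", "T"), 2, TRUE), collapse = "")))
    })
}

# Write a minimal single-sample VCF 4.2 of carried sites.
write_sample_vcf <- function(path, sample_id, records, contig_lengths) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=altiscan_simulator",
           sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                   as.integer(contig_lengths)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_id))
  ord <- order(match(records$chrom, names(contig_lengths)), records$pos)
  records <- records[ord, , drop = FALSE]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  records$chrom, records$pos, records$ref, records$alt,
                  records$gt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate the two diverged populations
#'
#' Draws an ancestral frequency per polymorphic site, then per-population
#' frequencies under the Balding-Nichols divergence model (target
#' \code{background_fst} outside and \code{sweep_fst} inside the planted
#' windows), designates private/differential sites, samples genotypes
#' binomially at each sample's contig ploidy, and writes one VCF per
#' sample, a known-variants VCF and a truth table.
#'
#' @param cfg a [sim_config()].
#' @param genome result of [simulate_genome()].
#' @param dir output directory.
#' @return List with the sample metadata (\code{meta}, including
#'   \code{vcf_path}), the \code{truth} table, planted \code{sweep_windows}
#'   and the \code{known_vcf} path.
#' @export
simulate_populations <- function(cfg, genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 202L)
  lens <- sim_contigs(cfg)
  meta <- sim_sample_meta(cfg)

  auto <- grep("^chr", names(lens), value = TRUE)
  grid <- do.call(rbind, lapply(auto, function(ch) {
    starts <- seq(0, lens[[ch]] - cfg$sweep_window_size,
                  by = cfg$sweep_window_size)
    data.frame(chrom = ch, start = starts, stringsAsFactors = FALSE)
  }))
  pick <- sample(nrow(grid), min(cfg$n_sweep_windows, nrow(grid)))
  sweeps <- grid[pick, , drop = FALSE]
  sweeps$end <- sweeps$start + cfg$sweep_window_size
  sweeps$window_id <- sprintf("%s:%d-%d", sweeps$chrom, sweeps$start,
                              sweeps$end)

  sites <- do.call(rbind, lapply(names(lens), function(ch) {
    n <- max(1L, round(lens[[ch]] * cfg$snv_density))
    pos <- sort(sample.int(as.integer(lens[[ch]]) - 10L, n))
    props <- cfg$vtype_prop
    if (ch == "MT") {  # mitochondrial calls: SNV, insertion, replacement
      props <- props[c("SNV", "insertion", "replacement")]
      props <- props / sum(props)
    }
    data.frame(chrom = ch, pos = pos,
               vtype = sample(names(props), n, TRUE, prob = props),
               stringsAsFactors = FALSE)
  }))
  seq_chars <- as.character(genome$genome)
  al <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites)))
    al[[i]] <- draw_alleles(seq_chars[[sites$chrom[i]]],
                            sites$pos[i], sites$vtype[i])
  sites$ref <- vapply(al, `[[`, character(1), "ref")
  sites$alt <- vapply(al, `[[`, character(1), "alt")
  sites <- sites[!duplicated(paste(sites$chrom, sites$pos)), ]

  sw <- rep(NA_character_, nrow(sites))
  for (k in seq_len(nrow(sweeps))) {
    hit <- sites$chrom == sweeps$chrom[k] &
      sites$pos - 1L >= sweeps$start[k] & sites$pos - 1L < sweeps$end[k]
    sw[hit] <- sweeps$window_id[k]
  }
  sites$is_sweep <- !is.na(sw)
  sites$window_id <- sw

  n <- nrow(sites)
  p_anc <- runif(n, 0.05, 0.95)
  theta <- ifelse(sites$is_sweep, cfg$sweep_fst, cfg$background_fst)
  p_high <- bn_draw(p_anc, theta)
  p_low <- bn_draw(p_anc, theta)
  priv_pool <- which(!sites$is_sweep)
  n_priv <- round(cfg$fraction_private * length(priv_pool))
  priv <- sample(priv_pool, n_priv)
  private_to <- rep("none", n)
  half <- seq_len(floor(n_priv / 2))
  private_to[priv[half]] <- "highland"
  private_to[priv[-half]] <- "lowland"
  fixed <- runif(n) < cfg$fraction_private_fixed
  pf <- ifelse(fixed, 1, runif(n, 0.3, 0.95))
  p_high[private_to == "highland"] <- pf[private_to == "highland"]
  p_low[private_to == "highland"] <- 0
  p_low[private_to == "lowland"] <- pf[private_to == "lowland"]
  p_high[private_to == "lowland"] <- 0
  sites$private_to <- private_to
  sites$p_highland <- p_high
  sites$p_lowland <- p_low
  sites$known <- runif(n) < cfg$fraction_known

  # genotypes: binomial at each sample's ploidy for the site's contig
  dos <- matrix(0L, n, nrow(meta),
                dimnames = list(NULL, meta$sample_id))
  pld <- dos
  for (j in seq_len(nrow(meta))) {
    pj <- if (meta$population[j] == "highland") p_high else p_low
    plo <- contig_ploidy(sites$chrom, meta$sex[j])
    dos[, j] <- rbinom(n, plo, pj)
    pld[, j] <- plo
  }
  carried <- rowSums(dos) > 0L
  sites <- sites[carried, , drop = FALSE]
  dos <- dos[carried, , drop = FALSE]
  pld <- pld[carried, , drop = FALSE]
  sites$carriers_highland <- rowSums(dos[, meta$population == "highland",
                                         drop = FALSE] > 0L)
  sites$carriers_lowland <- rowSums(dos[, meta$population == "lowland",
                                        drop = FALSE] > 0L)

  meta$vcf_path <- file.path(dir, paste0(meta$sample_id, ".vcf"))
  for (j in seq_len(nrow(meta))) {
    has <- dos[, j] > 0L
    rec <- sites[has, c("chrom", "pos", "ref", "alt")]
    d <- dos[has, j]; p <- pld[has, j]
    rec$gt <- ifelse(p == 1L, "1", ifelse(d == 2L, "1/1", "0/1"))
    write_sample_vcf(meta$vcf_path[j], meta$sample_id[j], rec, lens)
  }

  known_vcf <- file.path(dir, "known_variants.vcf")
  kn <- sites[sites$known, c("chrom", "pos", "ref", "alt")]
  hdr <- c("##fileformat=VCFv4.2", "##source=altiscan_known_db",
           sprintf("##contig=<ID=%s,length=%d>", names(lens),
                   as.integer(lens)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", kn$chrom,
                            kn$pos, kn$ref, kn$alt)), known_vcf)

  truth_path <- file.path(dir, "truth_sites.tsv")
  write.table(sites, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(meta = meta, truth = sites, truth_path = truth_path,
       sweep_windows = sweeps, known_vcf = known_vcf)
}

#' Simulate the 24-trait phenotype table
#'
#' Correlated Gaussian traits from a three-factor model; the highland group
#' is shifted by \code{phenotype_effect} within-group standard deviations
#' on the first \code{n_effect_traits} traits.
#'
#' @param cfg a [sim_config()].
#' @return \code{data.frame} with \code{sample_id}, \code{population} and
#'   \code{n_traits} numeric trait columns.
#' @export
simulate_phenotypes <- function(cfg) {
  set.seed(cfg$seed + 303L)
  n_l <- cfg$n_pheno_lowland; n_h <- cfg$n_pheno_highland
  n <- n_l + n_h; p <- cfg$n_traits
  loadings <- matrix(rnorm(p * 3, sd = 0.6), p, 3)
  f <- matrix(rnorm(n * 3), n, 3)
  x <- f %*% t(loadings) + matrix(rnorm(n * p, sd = 0.8), n, p)
  pop <- rep(c("lowland", "highland"), c(n_l, n_h))
  shift <- cfg$phenotype_effect * apply(x, 2, sd)
  k <- min(cfg$n_effect_traits, p)
  x[pop == "highland", seq_len(k)] <-
    x[pop == "highland", seq_len(k), drop = FALSE] +
    rep(shift[seq_len(k)], each = n_h)
  colnames(x) <- sprintf("trait_%02d", seq_len(p))
  data.frame(sample_id = sprintf("P%02d", seq_len(n)), population = pop,
             x, stringsAsFactors = FALSE)
}

#' Simulate the highland replication cohort
#'
#' Draws \code{n_replicates} new highland samples from the truth table's
#' highland allele frequencies and writes one VCF each; used to exercise
#' replication-based validation percentages.
#'
#' @param cfg a [sim_config()].
#' @param truth truth table from [simulate_populations()].
#' @param dir output directory.
#' @return Sample metadata for the cohort, with \code{vcf_path}.
#' @export
simulate_replication_cohort <- function(cfg, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 404L)
  lens <- sim_contigs(cfg)
  n_rep <- cfg$n_replicates
  sex <- rep(c("male", "female"), length.out = n_rep)
  meta <- sample_meta(sprintf("R%02d", seq_len(n_rep)), "highland", sex)
  meta$vcf_path <- file.path(dir, paste0(meta$sample_id, ".vcf"))
  for (j in seq_len(n_rep)) {
    plo <- contig_ploidy(truth$chrom, meta$sex[j])
    dos <- rbinom(nrow(truth), plo, truth$p_highland)
    has <- dos > 0L
    rec <- truth[has, c("chrom", "pos", "ref", "alt")]
    rec$gt <- ifelse(plo[has] == 1L, "1",
                     ifelse(dos[has] == 2L, "1/1", "0/1"))
    write_sample_vcf(meta$vcf_path[j], meta$sample_id[j], rec, lens)
  }
  meta
}

#' Generate the complete synthetic study
#'
#' Runs every simulator stage under one master seed and writes genome,
#' annotation, per-sample VCFs, known-variants VCF, truth table, gene-set
#' table, phenotype table, replication cohort and a sample manifest into
#' \code{dir}.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @return A list of class \code{synthetic_study} with all file paths and
#'   in-memory objects.
#' @export
simulate_study <- function(cfg = sim_config(), dir = tempfile("altiscan_")) {
  genome <- simulate_genome(cfg, dir)
  pops <- simulate_populations(cfg, genome, dir)
  pheno <- simulate_phenotypes(cfg)
  pheno_path <- file.path(dir, "phenotypes.tsv")
  write.table(pheno, pheno_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  rep_meta <- simulate_replication_cohort(cfg, pops$truth,
                                          file.path(dir, "replication"))
  set.seed(cfg$seed + 505L)
  genes <- genome$annotation$genes$gene_id
  gs <- data.frame(
    term = sprintf("T%02d", sample.int(25L, length(genes) * 2, TRUE)),
    gene_id = rep(genes, 2), stringsAsFactors = FALSE)
  gs <- gs[!duplicated(gs), ]
  geneset_path <- file.path(dir, "gene_sets.tsv")
  write.table(gs, geneset_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest_path <- file.path(dir, "samples.tsv")
  man <- pops$meta
  man$vcf_path <- basename(man$vcf_path)
  write.table(man, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  structure(list(config = cfg, dir = dir,
                 fasta = genome$fasta, gff = genome$gff,
                 genome = genome$genome, annotation = genome$annotation,
                 meta = pops$meta, truth = pops$truth,
                 truth_path = pops$truth_path,
                 sweep_windows = pops$sweep_windows,
                 known_vcf = pops$known_vcf,
                 phenotypes = pheno, phenotype_path = pheno_path,
                 replication_meta = rep_meta,
                 gene_sets = gs, geneset_path = geneset_path,
                 manifest_path = manifest_path),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic two-ecotype study in", x$dir, "\n")
  cat("  contigs:", paste(names(x$annotation$contig_lengths),
                          collapse = ", "), "\n")
  cat("  sites in truth table:", nrow(x$truth),
      sprintf("(%d in planted sweep windows)", sum(x$truth$is_sweep)), "\n")
  cat("  samples:", nrow(x$meta), "+", nrow(x$replication_meta),
      "replication\n")
  invisible(x)
}
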