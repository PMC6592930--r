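# End-to-end orchestration: ingest -> contrast -> novelty/coding ->
# distribution tests -> F_ST scan + enrichment -> density enrichment ->
# mtDNA table -> structure/phenotypes -> validation, with seeded
# reproducibility, per-stage logging and TSV reports.

pipeline_defaults <- function() {
  list(threshold = 50, window = 1e5, step = 5e4, top_fraction = 0.05,
       alpha = 0.01, target_fraction = 0.2, mca_sites = 10000,
       cum_target = 0.92, min_snvs = 1, seed = 1)
}

# Resolve a config list or JSON file into a validated config.
load_run_config <- function(config) {
  if (is.character(config)) {
    base <- dirname(config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    for (f in c("manifest", "genome_fasta", "gff", "known_vcf",
                "gene_sets", "phenotypes", "replication_manifest")) {
      if (!is.null(config[[f]]) && !grepl("^(/|[A-Za-z]:)", config[[f]]))
        config[[f]] <- file.path(base, config[[f]])
    }
  }
  cfg <- modifyList(pipeline_defaults(), config)
  for (f in c("manifest", "genome_fasta", "gff"))
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("config field '", f, "' must name an existing file")
  cfg
}

tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the inputs named in the configuration and
#' writes the report TSVs into \code{outdir}.  The configuration is a
#' list (or path to a JSON file) with paths \code{manifest},
#' \code{genome_fasta}, \code{gff} and optionally \code{known_vcf},
#' \code{gene_sets}, \code{phenotypes}, \code{replication_manifest}, plus
#' the thresholds \code{threshold}, \code{window}, \code{step},
#' \code{top_fraction}, \code{alpha}, \code{target_fraction},
#' \code{mca_sites}, \code{cum_target} and \code{seed}.  A missing
#' known-variants path degrades gracefully: novelty columns become NA and
#' the run continues with a warning.  A count-conservation invariant
#' (differential + common + below-threshold = observed keys) is asserted
#' per stratum at run time.
#'
#' @param config configuration list or JSON path.
#' @param outdir output directory (defaults to \code{config$outdir}).
#' @return Invisibly, a list of class \code{altiscan_run} with the stage
#'   objects and all report paths.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- load_run_config(config)
  if (is.null(outdir)) outdir <- cfg$outdir
  if (is.null(outdir)) stop("no output directory configured")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  log_stage <- function(...) message("[altiscan] ", sprintf(...))
  paths <- list()

  log_stage("ingest: reading manifest %s", cfg$manifest)
  meta <- read_sample_manifest(cfg$manifest)
  genome <- read_genome_fasta(cfg$genome_fasta)
  ann <- read_genome_annotation(cfg$gff, genome)
  high <- read_population_vcfs(meta[meta$population == "highland", ])
  low <- read_population_vcfs(meta[meta$population == "lowland", ])
  log_stage("ingest: %d highland / %d lowland records",
            nrow(high$variants), nrow(low$variants))

  known <- NULL
  if (!is.null(cfg$known_vcf) && file.exists(cfg$known_vcf)) {
    known <- read_known_variants(cfg$known_vcf)
  } else warning("no known-variants VCF; novelty columns reported as NA")

  log_stage("contrast: threshold %g%%", cfg$threshold)
  strata <- c("male", "female", "pooled")
  contrasts <- lapply(setNames(strata, strata), function(s)
    differential_variants(high, low, cfg$threshold, s))
  for (s in strata) {
    cr <- contrasts[[s]]
    stopifnot(sum(cr$counts) == nrow(cr$variants))  # count conservation
    log_stage("contrast[%s]: %s", s,
              paste(names(cr$counts), cr$counts, collapse = ", "))
  }
  diff_all <- do.call(rbind, lapply(strata, function(s) {
    cr <- contrasts[[s]]
    d <- rbind(cr$differential[[1]], cr$differential[[2]])
    if (nrow(d) == 0) return(NULL)
    cbind(stratum = s, d)
  }))
  if (!is.null(diff_all) && !is.null(known))
    diff_all <- flag_novel(diff_all, known)
  paths$differential <- tsv(diff_all, outdir, "differential.tsv")
  common_all <- do.call(rbind, lapply(strata, function(s)
    data.frame(stratum = s,
               key = contrasts[[s]]$common_any,
               strict = contrasts[[s]]$common_any %in%
                 contrasts[[s]]$common_strict)))
  paths$common <- tsv(common_all, outdir, "common.tsv")
  paths$differential_summary <- tsv(contrast_summary(high, low, cfg$threshold, known,
                                       genome, ann), outdir, "differential_summary.tsv")

  log_stage("distribution tests")
  tt <- per_type_distribution_test(high, low)
  paths$type_tests <- tsv(tt$per_type, outdir, "type_distribution_tests.tsv")
  chisq <- per_chromosome_chisq(high, low)
  paths$chisq_nonsignificant <- tsv(nonsignificant_report(chisq), outdir,
                            "chromosome_chisq_nonsignificant.tsv")

  log_stage("F_ST scan: %g kb windows, %g kb step", cfg$window / 1e3,
            cfg$step / 1e3)
  gene_sets <- NULL
  if (!is.null(cfg$gene_sets) && file.exists(cfg$gene_sets))
    gene_sets <- read.delim(cfg$gene_sets, stringsAsFactors = FALSE)
  scan <- fst_scan(high, low, ann, cfg$window, cfg$step,
                   cfg$top_fraction, cfg$min_snvs,
                   gene_sets = gene_sets, alpha = cfg$alpha)
  paths$fst_windows <- tsv(scan$windows, outdir, "fst_windows.tsv")
  top <- scan$windows[scan$windows$is_top, ]
  writeLines(sprintf("%s\t%d\t%d\t%s\t%.6g", top$chrom,
                     as.integer(top$start), as.integer(top$end),
                     top$window_id, top$mean_theta),
             file.path(outdir, "top_windows.bed"))
  paths$top_windows <- file.path(outdir, "top_windows.bed")
  if (!is.null(scan$enrichment))
    paths$enrichment <- tsv(scan$enrichment, outdir, "enrichment.tsv")
  log_stage("F_ST scan: %d top windows, %d candidate genes",
            sum(scan$windows$is_top), nrow(scan$genes))

  log_stage("density enrichment")
  dens <- list(); regions <- list()
  for (s in c("male", "female")) {
    cr <- contrasts[[s]]
    d <- rbind(cr$differential[[1]], cr$differential[[2]])
    prof <- density_profiles(d, ann$contig_lengths)
    dens[[s]] <- cbind(stratum = s, prof)
    if (nrow(d) > 0) {
      topch <- rank_chromosomes(prof)
      pos <- d$pos[d$chrom == topch$chrom]
      if (length(pos) > 0)
        regions[[s]] <- max_density_region(
          pos, ann$contig_lengths[[topch$chrom]], cfg$target_fraction,
          ann, topch$chrom)
    }
  }
  paths$density_profiles <- tsv(do.call(rbind, dens), outdir,
                                "density_profiles.tsv")
  bed <- vapply(names(regions), function(s) {
    r <- regions[[s]]
    sprintf("%s\t%d\t%d\t%s_dense\t%d", r$chrom, as.integer(r$start),
            as.integer(r$end), s, r$n_in_region)
  }, character(1))
  writeLines(bed, file.path(outdir, "dense_regions.bed"))
  paths$dense_regions <- file.path(outdir, "dense_regions.bed")
  rg <- do.call(rbind, lapply(names(regions), function(s) {
    r <- regions[[s]]
    if (length(r$genes) == 0) return(NULL)
    data.frame(stratum = s, chrom = r$chrom, gene_id = r$genes)
  }))
  if (!is.null(rg))
    paths$region_genes <- tsv(rg, outdir, "region_genes.tsv")

  log_stage("mtDNA accounting")
  paths$mtdna_summary <- tsv(
    mtdna_classify(high, low, known, genome, ann), outdir,
    "mtdna_summary.tsv")

  log_stage("structure: MCA on up to %d SNV genotypes", cfg$mca_sites)
  gm <- sample_genotype_matrix(high, low, cfg$mca_sites, cfg$seed)
  mca <- withCallingHandlers(
    mca_genotypes(gm),
    warning = function(w) {
      if (grepl("block", conditionMessage(w))) {
        log_stage("structure: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    })
  mca_df <- data.frame(sample_id = rownames(mca$coordinates),
                       population = attr(gm, "population"),
                       mca$coordinates)
  paths$mca_coords <- tsv(mca_df, outdir, "mca_coords.tsv")
  freqs <- population_allele_freqs(high, low)
  nei <- nei_standard_distance(freqs$p_highland, freqs$p_lowland)
  dmat <- matrix(c(0, nei$D, nei$D, 0), 2,
                 dimnames = list(c("highland", "lowland"),
                                 c("highland", "lowland")))
  ape::write.tree(upgma_tree(dmat), file.path(outdir, "upgma.nwk"))
  paths$upgma <- file.path(outdir, "upgma.nwk")

  pca <- cm <- NULL
  if (!is.null(cfg$phenotypes) && file.exists(cfg$phenotypes)) {
    log_stage("phenotypes: PCA + discriminant classification")
    pheno <- read.delim(cfg$phenotypes, stringsAsFactors = FALSE)
    pca <- phenotype_pca(pheno)
    k <- min(6, length(pca$eigenvalues))
    paths$pca_summary <- tsv(data.frame(
      component = seq_len(k), eigenvalue = pca$eigenvalues[1:k],
      proportion = pca$proportions[1:k],
      cumulative = pca$cumulative[1:k]), outdir, "pca_summary.tsv")
    cm <- discriminant_classify(pca, cum_target = cfg$cum_target)
    conf <- as.data.frame.matrix(cm$counts)
    conf <- cbind(assigned = rownames(conf), conf)
    conf <- rbind(conf,
                  data.frame(assigned = "proportion_correct",
                             as.list(round(cm$per_group, 4)),
                             check.names = FALSE))
    paths$classification_confusion <- tsv(conf, outdir, "classification_confusion.tsv")
    log_stage("phenotypes: overall proportion correct %.3f", cm$overall)
  }

  validation <- NULL
  if (!is.null(cfg$replication_manifest) &&
      file.exists(cfg$replication_manifest)) {
    log_stage("validation against replication cohort")
    rmeta <- read_sample_manifest(cfg$replication_manifest)
    cohort <- read_population_vcfs(rmeta)
    novel_keys <- if (!is.null(diff_all) && !is.null(known))
      unique(diff_all$key[!diff_all$known & diff_all$vtype == "SNV"])
    else unique(diff_all$key[diff_all$vtype == "SNV"])
    vp <- validation_percentage(novel_keys, cohort)
    validation <- data.frame(key = novel_keys, validation_pct = unname(vp))
    paths$validation <- tsv(validation, outdir,
                                    "validation.tsv")
    log_stage("validation: %d/%d keys seen in the cohort",
              sum(vp > 0), length(vp))
  }

  manifest <- list(
    package = "altiscan",
    version = as.character(utils::packageVersion("altiscan")),
    r_version = R.version.string,
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "outdir")],
    outputs = lapply(paths, basename))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths$manifest <- file.path(outdir, "run_manifest.json")
  log_stage("done: %d report files in %s", length(paths), outdir)
  invisible(structure(list(config = cfg, contrasts = contrasts,
                           scan = scan, density = dens,
                           regions = regions, mca = mca, nei = nei,
                           pca = pca, confusion = cm,
                           validation = validation, paths = paths),
                      class = "altiscan_run"))
}

#' @export
print.altiscan_run <- function(x, ...) {
  cat("altiscan pipeline run\n")
  cat("  reports:", paste(basename(unlist(x$paths)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a demonstration synthetic dataset and run configuration
#'
#' Generates the default synthetic study under \code{dir} and writes a
#' \code{run_config.json} pointing at its files, ready for
#' [run_pipeline()].
#'
#' @param dir output directory.
#' @param seed master seed passed to [sim_config()].
#' @param cfg optional [sim_config()] overriding the default (its seed
#'   wins over \code{seed}).
#' @return Path to the run-config JSON (invisibly); the truth-table
#'   location is printed.
#' @export
make_demo <- function(dir = tempfile("altiscan_demo_"), seed = 1L,
                      cfg = NULL) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed)
  seed <- cfg$seed
  study <- simulate_study(cfg, dir)
  rep_manifest <- file.path(dir, "replication", "samples.tsv")
  rmeta <- study$replication_meta
  rmeta$vcf_path <- basename(rmeta$vcf_path)
  write.table(rmeta, rep_manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfgpath <- file.path(dir, "run_config.json")
  cfg <- c(list(manifest = "samples.tsv", genome_fasta = "genome.fa",
                gff = "genes.gff3", known_vcf = "known_variants.vcf",
                gene_sets = "gene_sets.tsv", phenotypes = "phenotypes.tsv",
                replication_manifest = file.path("replication",
                                                 "samples.tsv"),
                outdir = file.path(dir, "reports")),
           pipeline_defaults())
  cfg$seed <- seed
  jsonlite::write_json(cfg, cfgpath, auto_unbox = TRUE, pretty = TRUE)
  message("demo dataset in ", dir,
          "\n  truth table: ", study$truth_path,
          "\n  run config:  ", cfgpath)
  invisible(cfgpath)
}
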