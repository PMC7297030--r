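## Reproducible-run surface: each run_* function executes one pipeline stage
## end to end, writes its outputs plus a manifest (config, seed, package
## version, input checksums) sufficient to reproduce them byte-identically.

write_manifest <- function(out_dir, stage, config_list, inputs = character()) {
  manifest <- list(
    stage = stage,
    package = "afddd",
    version = as.character(utils::packageVersion("afddd")),
    config = config_list,
    inputs = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else {
      stats::setNames(list(), character())
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

config_as_list <- function(config) {
  list(
    genome = list(chromosomes = config$genome$chromosomes,
                  snv_density = config$genome$snv_density,
                  seg_type_mixture = as.list(config$genome$seg_type_mixture)),
    dominant_locus = config$dominant_locus,
    suppressor_loci = config$suppressor_loci,
    locus2_zygosity = as.list(config$locus2_zygosity),
    dominant_phase = as.list(config$dominant_phase),
    n_offspring = config$n_offspring,
    recomb_rate = config$recomb_rate,
    penetrance = config$penetrance,
    leak = config$leak,
    pool_sizes = as.list(config$pool_sizes),
    depth_means = as.list(config$depth_means),
    seq_error = config$seq_error,
    seed = config$seed
  )
}

#' Run the simulation stage and write its outputs
#'
#' Simulates the cross, phenotypes, pools and pooled reads, then writes per
#' pool a minimal VCF and the TSV dialect, the truth files (causal-locus
#' BED, individual genotype/phenotype TSV), a chromosome-length table and a
#' manifest.
#'
#' @param config a \code{\link{cross_config}}.
#' @param out_dir output directory (created if needed).
#' @param round_index evaluation round used for pooling.
#' @return The \code{\link{simulate_pooled_experiment}} result, invisibly.
#' @export
run_simulate <- function(config = cross_config(), out_dir,
                         round_index = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_pooled_experiment(config, round_index)
  chroms <- config$genome$chromosomes
  write_pool_vcf(sim$recessive, file.path(out_dir, "pool_recessive.vcf"),
                 sample = "recessive_pool", chrom_lengths = chroms)
  write_pool_vcf(sim$dominant, file.path(out_dir, "pool_dominant.vcf"),
                 sample = "dominant_pool", chrom_lengths = chroms)
  write_pool_tsv(sim$recessive, file.path(out_dir, "pool_recessive.tsv"))
  write_pool_tsv(sim$dominant, file.path(out_dir, "pool_dominant.tsv"))
  write_truth_bed(sim$truth, file.path(out_dir, "truth_loci.bed"))
  utils::write.table(individual_table(sim$pop),
                     file.path(out_dir, "individuals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(chroms, file.path(out_dir, "chrom_lengths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "simulate",
                 c(config_as_list(config), round_index = round_index))
  invisible(sim)
}

#' Run the scan stage and write its outputs
#'
#' Composes QC, pool partition, zygosity grouping, informative-SNV
#' selection, window scoring and peak calling; writes the per-window TSV
#' track, the peak BED6, a JSON summary (tallies, per-type counts, peaks)
#' and a manifest.
#'
#' @param recessive,dominant per-pool variant tables or file paths.
#' @param chrom_lengths chromosome-length data frame or file path.
#' @param out_dir output directory.
#' @param ... passed to \code{\link{afddd_scan}}.
#' @return The \code{\link{afddd_scan}} object, invisibly.
#' @export
run_scan <- function(recessive, dominant, chrom_lengths, out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- c(
    if (is.character(recessive)) recessive,
    if (is.character(dominant)) dominant,
    if (is.character(chrom_lengths)) chrom_lengths
  )
  if (is.character(chrom_lengths)) {
    chrom_lengths <- read_chrom_lengths(chrom_lengths)
  }
  scan <- afddd_scan(recessive, dominant, chrom_lengths, ...)
  write_window_track(scan$scores, file.path(out_dir, "windows.tsv"))
  write_peaks_bed(scan$peaks, file.path(out_dir, "peaks.bed"))
  summary_list <- list(
    qc_tally = lapply(scan$qc_tally, as.list),
    partition = as.list(scan$partition),
    group_tally = as.list(scan$group_tally),
    informative = as.list(scan$informative_tally),
    peaks = scan$peaks
  )
  jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "scan", scan$params, inputs)
  invisible(scan)
}

#' Run the confirmation-statistics stage and write its outputs
#'
#' From an individual-level table (as written by \code{\link{run_simulate}}),
#' computes the dominant-locus 1:2:1 goodness of fit, the per-round
#' dominant:recessive phenotype ratio tests, parental-allele distortion
#' tests at each suppressor marker within the suppressed (Std2) group,
#' the genotype-class phenotype-frequency table, and phenotype-score
#' regressions; writes JSON/TSV reports and a manifest.
#'
#' @param individuals data frame or TSV path with the columns written by
#'   \code{\link{run_simulate}}.
#' @param out_dir output directory.
#' @param phenotype_ratio expected dominant:recessive phenotype ratio
#'   (default 3:1).
#' @return A list of results, invisibly.
#' @export
run_stats <- function(individuals, out_dir, phenotype_ratio = c(3, 1)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- if (is.character(individuals)) individuals else character()
  if (is.character(individuals)) {
    individuals <- utils::read.table(individuals, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE)
  }
  for (col in c("co_geno")) {
    if (is.null(individuals[[col]])) {
      stop("individual table is missing column `", col, "`", call. = FALSE)
    }
  }
  score_cols <- grep("^score_round", names(individuals), value = TRUE)
  if (!length(score_cols)) {
    stop("individual table is missing column `score_round1`", call. = FALSE)
  }

  co_counts <- table(factor(individuals$co_geno,
                            c("CoCo", "Coco", "coco")))
  co_test <- gof_chisq(as.integer(co_counts), c(1, 2, 1))

  ratio_tests <- lapply(score_cols, function(col) {
    columnar <- sum(individuals[[col]] %in% c(1L, 2L))
    standard <- sum(individuals[[col]] %in% c(3L, 4L))
    gof_chisq(c(columnar, standard), phenotype_ratio)
  })
  names(ratio_tests) <- score_cols

  sup_loci <- unique(sub("_(seed|pollen)_allele$", "",
                         grep("^sup[0-9]+_(seed|pollen)_allele$",
                              names(individuals), value = TRUE)))
  status_cols <- grep("^status_round", names(individuals), value = TRUE)
  distortion <- list()
  if (length(sup_loci) && length(status_cols)) {
    std2 <- individuals[individuals[[status_cols[1]]] == "Std2", ,
                        drop = FALSE]
    for (locus in sup_loci) {
      tab <- data.frame(
        seed_allele = std2[[paste0(locus, "_seed_allele")]],
        pollen_allele = std2[[paste0(locus, "_pollen_allele")]],
        stringsAsFactors = FALSE)
      distortion[[locus]] <- allele_distortion_test(tab)
    }
  }

  geno_cols <- grep("_rec_alleles$", names(individuals), value = TRUE)
  freq_table <- NULL
  regressions <- list()
  if (length(geno_cols)) {
    freq_table <- phenotype_frequency_table(individuals, geno_cols,
                                            score_cols)
    utils::write.table(as.data.frame(freq_table),
                       file.path(out_dir, "phenotype_frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    carriers <- individuals$co_geno %in% c("CoCo", "Coco")
    for (col in score_cols) {
      g1 <- individuals[[geno_cols[1]]][carriers]
      g2 <- if (length(geno_cols) > 1L) {
        individuals[[geno_cols[2]]][carriers]
      }
      regressions[[col]] <- tryCatch(
        phenotype_score_regression(individuals[[col]][carriers], g1, g2),
        error = function(e) NULL)
    }
  }

  gof_as_list <- function(g) {
    list(chi2 = g$chi2, df = g$df, p = g$p,
         observed = g$observed, expected = g$expected)
  }
  report <- list(
    dominant_locus_1_2_1 = gof_as_list(co_test),
    phenotype_ratio_tests = lapply(ratio_tests, gof_as_list),
    allele_distortion_std2 = lapply(distortion, function(locus) {
      lapply(locus, function(parent) {
        if (is.character(parent$result)) {
          list(result = parent$result,
               counts = as.list(parent$counts))
        } else {
          c(gof_as_list(parent$result),
            list(counts = as.list(parent$counts)))
        }
      })
    }),
    regressions = lapply(regressions, function(r) {
      if (is.null(r)) NULL else list(r2 = r$r2, model_p = r$model_p,
                                     n = r$n)
    })
  )
  jsonlite::write_json(report, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "stats",
                 list(phenotype_ratio = phenotype_ratio), inputs)
  invisible(list(co_test = co_test, ratio_tests = ratio_tests,
                 distortion = distortion, freq_table = freq_table,
                 regressions = regressions))
}
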