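#' Genome specification for the cross simulator
#'
#' A desk-scale stand-in for an outcrossing tree-fruit genome: a handful of
#' chromosomes, a target SNV density, and a mixture over marker segregation
#' types. The default (5 chromosomes of 30 Mb at one SNV per 10 kb, about
#' 15,000 sites) keeps whole-pipeline runs fast while leaving hundreds of
#' markers per 1-Mb window; it can be scaled up to apple scale (17 x ~40 Mb)
#' if desired.
#'
#' @param chromosomes data frame with columns \code{name} and \code{length}
#'   (bp, positive).
#' @param snv_density expected segregating SNVs per bp.
#' @param seg_type_mixture named probability vector over the 12
#'   phase-resolved derivatives (names like \code{"V|R x V|V"}) plus
#'   \code{"nonseg"} for non-segregating variant-homozygous sites
#'   (both parents \code{V|V}); must sum to 1. Default: 0.2 non-segregating,
#'   the rest uniform over the 12 derivatives.
#' @return An object of class \code{"genome_spec"}.
#' @export
genome_spec <- function(chromosomes = NULL,
                        snv_density = 1e-4,
                        seg_type_mixture = NULL) {
  if (is.null(chromosomes)) {
    chromosomes <- data.frame(name = paste0("chr", 1:5),
                              length = rep(30e6, 5),
                              stringsAsFactors = FALSE)
  }
  if (!all(c("name", "length") %in% names(chromosomes))) {
    stop("config field `genome$chromosomes` needs columns name, length",
         call. = FALSE)
  }
  if (any(chromosomes$length <= 0)) {
    stop("config field `genome$chromosomes$length` must be positive",
         call. = FALSE)
  }
  if (anyDuplicated(chromosomes$name)) {
    stop("config field `genome$chromosomes$name` has duplicates",
         call. = FALSE)
  }
  if (!is.numeric(snv_density) || snv_density <= 0) {
    stop("config field `genome$snv_density` must be positive", call. = FALSE)
  }
  if (is.null(seg_type_mixture)) {
    keys <- derivative_keys()
    seg_type_mixture <- c(stats::setNames(rep(0.8 / 12, 12), keys),
                          nonseg = 0.2)
  }
  if (abs(sum(seg_type_mixture) - 1) > 1e-8) {
    stop("config field `genome$seg_type_mixture` must sum to 1",
         call. = FALSE)
  }
  bad <- setdiff(names(seg_type_mixture), c(derivative_keys(), "nonseg"))
  if (length(bad)) {
    stop("config field `genome$seg_type_mixture` has unknown keys: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(chromosomes = chromosomes, snv_density = snv_density,
                 seg_type_mixture = seg_type_mixture),
            class = "genome_spec")
}

derivative_keys <- function() {
  vapply(all_derivatives(), function(d) {
    paste(paste(d$seed, collapse = "|"), "x", paste(d$pollen, collapse = "|"))
  }, character(1))
}

#' Cross/simulation configuration
#'
#' Parameters of the simulated F1 mapping design: a dominant trait locus
#' (both parents heterozygous, like the retroposon-borne columnar locus),
#' one or two recessive suppressor loci, recombination, age-dependent
#' incomplete penetrance, phenotype pooling, and pooled sequencing depth.
#' Defaults mirror the published mapping design: 275 offspring, a
#' recessive (Std2-like) pool of 16 and a dominant (columnar-like) pool of
#' 18 individuals sequenced at 22.5x and 34.6x mean mapped depth, and a
#' penetrance schedule of 0.867, 0.667, 0.448 over three evaluation rounds.
#' Suppressor locus 1 (both parents heterozygous) sits 2 Mb from the
#' dominant locus on chr1; suppressor locus 2 is homozygous recessive in
#' the seed parent and heterozygous in the pollen parent, echoing the
#' published second locus.
#'
#' @param genome a \code{\link{genome_spec}}.
#' @param dominant_locus list/vector with \code{chrom} and \code{pos} of the
#'   dominant (Co-like) locus; both parents heterozygous.
#' @param suppressor_loci data frame (\code{chrom}, \code{pos}) with 1 or 2
#'   rows; locus 1 is heterozygous in both parents.
#' @param locus2_zygosity named character vector with entries \code{seed}
#'   and \code{pollen}, each one of \code{"het"}, \code{"hom_rec"},
#'   \code{"hom_dom"}; only used when two suppressor loci are given.
#' @param dominant_phase named character vector (\code{seed}, \code{pollen}),
#'   each \code{"coupling"} (dominant allele on the haplotype carrying the
#'   locus-1 recessive allele) or \code{"repulsion"}.
#' @param n_offspring number of F1 individuals.
#' @param recomb_rate recombination rate in cM per Mb (>= 0).
#' @param penetrance per-round probability that a Co-carrier homozygous
#'   recessive at all suppressor loci expresses the suppressed (Std2)
#'   phenotype; one entry per evaluation round, each in [0, 1].
#' @param leak per-round probability that any other Co-carrier expresses
#'   the suppressed phenotype (scalar or one per round).
#' @param pool_sizes named vector: \code{recessive} and \code{dominant}
#'   pool sizes.
#' @param depth_means named vector: mean mapped depth per pool.
#' @param seq_error per-base substitution error rate.
#' @param seed integer master seed; every stochastic stage derives a child
#'   seed from it.
#' @return An object of class \code{"cross_config"}.
#' @export
cross_config <- function(genome = genome_spec(),
                         dominant_locus = list(chrom = "chr1", pos = 28e6),
                         suppressor_loci = data.frame(
                           chrom = c("chr1", "chr2"),
                           pos = c(26e6, 15e6),
                           stringsAsFactors = FALSE),
                         locus2_zygosity = c(seed = "hom_rec",
                                             pollen = "het"),
                         dominant_phase = c(seed = "coupling",
                                            pollen = "repulsion"),
                         n_offspring = 275L,
                         recomb_rate = 2,
                         penetrance = c(0.867, 0.667, 0.448),
                         leak = 0.03,
                         pool_sizes = c(recessive = 16L, dominant = 18L),
                         depth_means = c(recessive = 22.5, dominant = 34.6),
                         seq_error = 0.001,
                         seed = 1L) {
  stopifnot(inherits(genome, "genome_spec"))
  suppressor_loci <- as.data.frame(suppressor_loci)
  if (!nrow(suppressor_loci) %in% 1:2) {
    stop("config field `suppressor_loci` must have 1 or 2 rows",
         call. = FALSE)
  }
  check_locus <- function(chrom, pos, field) {
    i <- match(chrom, genome$chromosomes$name)
    if (is.na(i)) {
      stop("config field `", field, "`: chromosome ", chrom,
           " not in genome", call. = FALSE)
    }
    if (pos < 1 || pos > genome$chromosomes$length[i]) {
      stop("config field `", field, "`: position ", pos,
           " outside chromosome ", chrom, call. = FALSE)
    }
  }
  check_locus(dominant_locus$chrom, dominant_locus$pos, "dominant_locus")
  for (j in seq_len(nrow(suppressor_loci))) {
    check_locus(suppressor_loci$chrom[j], suppressor_loci$pos[j],
                paste0("suppressor_loci[", j, "]"))
  }
  if (any(penetrance < 0 | penetrance > 1)) {
    stop("config field `penetrance` entries must be in [0, 1]",
         call. = FALSE)
  }
  if (length(penetrance) < 1L) {
    stop("config field `penetrance` must have at least one round",
         call. = FALSE)
  }
  leak <- rep(leak, length.out = length(penetrance))
  if (any(leak < 0 | leak > 1)) {
    stop("config field `leak` entries must be in [0, 1]", call. = FALSE)
  }
  if (recomb_rate < 0) {
    stop("config field `recomb_rate` must be >= 0", call. = FALSE)
  }
  if (n_offspring < 1) {
    stop("config field `n_offspring` must be positive", call. = FALSE)
  }
  if (!all(c("recessive", "dominant") %in% names(pool_sizes)) ||
      any(pool_sizes < 1)) {
    stop("config field `pool_sizes` needs positive entries named ",
         "recessive and dominant", call. = FALSE)
  }
  if (!all(c("recessive", "dominant") %in% names(depth_means)) ||
      any(depth_means <= 0)) {
    stop("config field `depth_means` needs positive entries named ",
         "recessive and dominant", call. = FALSE)
  }
  if (seq_error < 0 || seq_error >= 1) {
    stop("config field `seq_error` must be in [0, 1)", call. = FALSE)
  }
  if (nrow(suppressor_loci) == 2L) {
    if (!all(locus2_zygosity[c("seed", "pollen")] %in%
             c("het", "hom_rec", "hom_dom"))) {
      stop("config field `locus2_zygosity` entries must be het, hom_rec ",
           "or hom_dom", call. = FALSE)
    }
    if (all(locus2_zygosity[c("seed", "pollen")] == "hom_dom")) {
      stop("config field `locus2_zygosity`: at least one parent must carry ",
           "the recessive allele at locus 2", call. = FALSE)
    }
  }
  if (!all(dominant_phase[c("seed", "pollen")] %in%
           c("coupling", "repulsion"))) {
    stop("config field `dominant_phase` entries must be coupling or ",
         "repulsion", call. = FALSE)
  }
  structure(
    list(genome = genome, dominant_locus = dominant_locus,
         suppressor_loci = suppressor_loci,
         locus2_zygosity = locus2_zygosity,
         dominant_phase = dominant_phase,
         n_offspring = as.integer(n_offspring),
         recomb_rate = recomb_rate, penetrance = penetrance, leak = leak,
         pool_sizes = pool_sizes, depth_means = depth_means,
         seq_error = seq_error, seed = as.integer(seed)),
    class = "cross_config"
  )
}

#' @export
print.cross_config <- function(x, ...) {
  g <- x$genome
  cat("cross_config:\n")
  cat(sprintf("  genome: %d chromosomes, %.0f Mb total, SNV density %g/bp\n",
              nrow(g$chromosomes), sum(g$chromosomes$length) / 1e6,
              g$snv_density))
  cat(sprintf("  dominant locus %s:%.0f; %d suppressor locus/loci\n",
              x$dominant_locus$chrom, x$dominant_locus$pos,
              nrow(x$suppressor_loci)))
  cat(sprintf("  %d offspring, recomb %.1f cM/Mb, %d phenotype rounds\n",
              x$n_offspring, x$recomb_rate, length(x$penetrance)))
  cat(sprintf("  pools %d (recessive) / %d (dominant) at depth %.1fx/%.1fx\n",
              x$pool_sizes[["recessive"]], x$pool_sizes[["dominant"]],
              x$depth_means[["recessive"]], x$depth_means[["dominant"]]))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
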