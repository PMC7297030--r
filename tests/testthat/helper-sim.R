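# Small simulator configurations shared across tests.

tiny_genome <- function(n_chrom = 1L, length = 30e6, density = 1e-7) {
  genome_spec(data.frame(name = paste0("chr", seq_len(n_chrom)),
                         length = rep(length, n_chrom),
                         stringsAsFactors = FALSE),
              snv_density = density)
}

# essentially site-free config: fast, for trait-locus genetics only
trait_only_config <- function(seed, n_offspring = 275L, ...) {
  cross_config(genome = tiny_genome(2L),
               dominant_locus = list(chrom = "chr1", pos = 28e6),
               suppressor_loci = data.frame(chrom = c("chr1", "chr2"),
                                            pos = c(26e6, 15e6)),
               n_offspring = n_offspring, seed = seed, ...)
}

# deterministic-limit config for model-vs-simulation comparisons: complete
# penetrance, no leak, no sequencing error, dominant locus unlinked to the
# suppressor(s); tiny chromosomes so every chr1 site is tightly linked to
# the suppressor at chr1:0.5 Mb
clean_config <- function(seed, n_loci = 1L, n_offspring = 2000L,
                         pool_sizes = c(recessive = 100L, dominant = 150L),
                         depth = 150, density = 1e-3) {
  chroms <- data.frame(
    name = c("chr1", "chr2", "chr3"),
    length = c(1e6, 0.5e6, 0.5e6), stringsAsFactors = FALSE)
  sup <- if (n_loci == 1L) {
    data.frame(chrom = "chr1", pos = 0.5e6, stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = c("chr1", "chr3"), pos = c(0.5e6, 0.25e6),
               stringsAsFactors = FALSE)
  }
  cross_config(
    genome = genome_spec(chroms, snv_density = density),
    dominant_locus = list(chrom = "chr2", pos = 0.25e6),
    suppressor_loci = sup,
    locus2_zygosity = c(seed = "het", pollen = "het"),
    n_offspring = n_offspring,
    penetrance = 1, leak = 0,
    pool_sizes = pool_sizes,
    depth_means = c(recessive = depth, dominant = depth),
    seq_error = 0, seed = seed)
}

# QC-clean synthetic variant records
make_records <- function(n, seed = 1, chrom = "chr1") {
  withr::with_seed(seed, {
    pos <- sort(sample.int(30e6, n))
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1), USE.NAMES = FALSE)
    depth <- stats::rpois(n, 60) + 5L
    alt_count <- stats::rbinom(n, depth, 0.5)
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               depth = depth, alt_count = alt_count,
               af = 100 * alt_count / depth, stringsAsFactors = FALSE)
  })
}
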