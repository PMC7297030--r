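grouped_row <- function(group, af_R, af_D, pos = 100L) {
  data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
             af_R = af_R, af_D = af_D, group = group,
             stringsAsFactors = FALSE)
}

test_that("informative selection respects groups, windows and directionality", {
  g <- rbind(grouped_row("Ho-R/He-D", 95, 40, 1L),   # afdd 55 -> A
             grouped_row("Ho-R/He-D", 90, 65, 2L),   # afdd 25 -> B/C
             grouped_row("He-R/He-D", 50, 20, 3L),   # afdd 30 -> D/E
             grouped_row("He-R/He-D", 50, 50, 4L),   # afdd 0 -> out
             grouped_row("He-R/He-D", 20, 50, 5L),   # negative -> out
             grouped_row("He-R/Ho-D", 95, 40, 6L),   # wrong group -> out
             grouped_row("Ho-R/He-D", 90, 46.7, 7L)) # afdd 43.3 -> A, not B/C
  sel <- select_informative(g)
  expect_equal(sel$type_set[match(1:3, sel$pos)], c("A", "B/C", "D/E"))
  expect_false(any(sel$pos %in% 4:6))
  expect_equal(sel$type_set[sel$pos == 7L], "A")
  expect_equal(sel$afdd, sel$af_R - sel$af_D)
  # partition: one type set per SNV
  expect_false(any(duplicated(sel[c("chrom", "pos", "ref", "alt")])))
})

test_that("window counts tile chromosomes and conserve totals", {
  chroms <- data.frame(name = "chr1", length = 2e6)
  snvs <- data.frame(chrom = "chr1", pos = c(0.2e6, 0.5e6, 1.5e6))
  w <- window_counts(snvs, chroms)
  expect_equal(w$count, c(2L, 1L))
  expect_equal(w$start, c(0, 1e6))
  expect_equal(w$end, c(1e6, 2e6))
  expect_false(any(w$partial))

  empty <- window_counts(snvs[0, ], chroms)
  expect_equal(empty$count, c(0L, 0L))

  # trailing partial window is retained and flagged
  wp <- window_counts(snvs, data.frame(name = "chr1", length = 2.5e6))
  expect_equal(wp$partial, c(FALSE, FALSE, TRUE))

  expect_error(window_counts(data.frame(chrom = "chr1", pos = 3e6), chroms),
               "outside chromosome")
  expect_error(window_counts(data.frame(chrom = "chrX", pos = 1e3), chroms),
               "chrX")
})

test_that("overlapping windows match a brute-force interval oracle", {
  withr::with_seed(42, {
    snvs <- data.frame(chrom = "chr1", pos = sort(sample.int(5e6, 200)))
  })
  chroms <- data.frame(name = "chr1", length = 5e6)
  w <- window_counts(snvs, chroms, window_size = 1e6, step = 0.5e6)
  oracle <- vapply(seq_len(nrow(w)), function(i) {
    sum(snvs$pos > w$start[i] & snvs$pos <= w$end[i])
  }, numeric(1))
  expect_equal(w$count, as.integer(oracle))
  # interior SNVs fall in exactly window/step = 2 windows; only SNVs in the
  # first half-window have a single covering window
  expect_equal(sum(w$count), 2L * nrow(snvs) - sum(snvs$pos <= 0.5e6))
  # conservation under non-overlapping tiling
  w1 <- window_counts(snvs, chroms)
  expect_equal(sum(w1$count), nrow(snvs))
})

test_that("z scores and LODz follow the two-tailed normal relation", {
  chroms <- data.frame(name = "chr1", length = 12e6)
  flat <- data.frame(chrom = "chr1", start = 0:11 * 1e6, end = 1:12 * 1e6,
                     count = rep(7L, 12), partial = FALSE)
  s <- lodz_scores(flat)
  expect_equal(s$z, rep(0, 12))
  expect_equal(s$p, rep(1, 12))
  expect_equal(s$lodz, rep(0, 12))

  # engineered counts whose mean is 100 and SD exactly 1: first window z=1.96
  dev <- c(1.96, -1.96, 1.288022, -1.288022, rep(0, 8))
  eng <- flat
  eng$count <- 100 + dev
  se <- lodz_scores(eng)
  expect_equal(se$z[1], 1.96, tolerance = 1e-4)
  expect_equal(se$lodz[1], -log10(2 * pnorm(-1.96)), tolerance = 1e-3)
  expect_equal(se$lodz[1], 1.30, tolerance = 0.01)
  # LODz 2.5 corresponds to |z| = qnorm(1 - 10^-2.5 / 2) ~ 2.95
  z_cut <- qnorm(1 - 10^(-2.5) / 2)
  expect_equal(-log10(2 * pnorm(-z_cut)), 2.5, tolerance = 1e-12)

  # oracle: lodz = -log10(2 * pnorm(-|z|)) for arbitrary counts
  withr::with_seed(1, { eng$count <- rpois(12, 20) })
  sr <- lodz_scores(eng)
  expect_equal(sr$lodz, -log10(2 * pnorm(-abs(sr$z))), tolerance = 1e-10)

  expect_error(lodz_scores(flat[1, ]), "at least two windows")
})

test_that("partial windows are scored but excluded from the baseline", {
  w <- data.frame(chrom = "chr1", start = c(0, 1e6, 2e6),
                  end = c(1e6, 2e6, 2.5e6),
                  count = c(10L, 20L, 500L), partial = c(FALSE, FALSE, TRUE))
  s <- lodz_scores(w)
  # mean/sd from the two full windows only: mean 15, sd ~7.07
  expect_equal(s$z[1], (10 - 15) / sd(c(10, 20)))
  expect_equal(s$z[3], (500 - 15) / sd(c(10, 20)))
})

test_that("extreme peaks keep finite LODz", {
  w <- data.frame(chrom = "chr1", start = 0:99 * 1e6, end = 1:100 * 1e6,
                  count = c(rep(10L, 99), 10000L), partial = FALSE)
  s <- lodz_scores(w)
  expect_true(is.finite(s$lodz[100]))
  expect_gt(s$lodz[100], 20)
})

test_that("peak calling merges runs and reports the leftmost apex on ties", {
  w <- data.frame(chrom = "chr1", start = 0:9 * 1e6, end = 1:10 * 1e6,
                  count = 0L, partial = FALSE,
                  z = c(0, 0, 4, 4, 0, 0, 0, 4, 0, 0),
                  p = 1, lodz = c(0, 0, 3, 3, 0, 0, 0, 3, 0, 0))
  pk <- call_peaks(w, cutoff = 2.5)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$start, c(2e6, 7e6))
  expect_equal(pk$end, c(4e6, 8e6))
  expect_equal(pk$apex_start[1], 2e6)  # leftmost of the tied pair
  # a single sub-threshold gap is bridged when allowed
  pk1 <- call_peaks(w, cutoff = 2.5, merge_gap = 3L)
  expect_equal(nrow(pk1), 1L)
  expect_equal(c(pk1$start, pk1$end), c(2e6, 8e6))
  # nothing above cutoff -> empty frame
  expect_equal(nrow(call_peaks(w, cutoff = 10)), 0L)
  # negative-z windows never seed a peak
  wneg <- transform(w, z = -z)
  expect_equal(nrow(call_peaks(wneg, cutoff = 2.5)), 0L)
})

test_that("lodz is invariant under chromosome relabeling and window permutation", {
  withr::with_seed(3, {
    w <- data.frame(chrom = rep(c("chr1", "chr2"), each = 10),
                    start = rep(0:9 * 1e6, 2), end = rep(1:10 * 1e6, 2),
                    count = rpois(20, 15), partial = FALSE)
  })
  s <- lodz_scores(w)
  w2 <- w
  w2$chrom <- rep(c("alpha", "beta"), each = 10)
  expect_equal(lodz_scores(w2)$lodz, s$lodz)
  perm <- sample(nrow(w))
  expect_equal(lodz_scores(w[perm, ])$lodz, s$lodz[perm])
})

test_that("the whole scan composes and flags foreign contigs", {
  # a short signal chromosome against a long quiet background, in the
  # deterministic penetrance limit
  cfg <- cross_config(
    genome = genome_spec(data.frame(name = c("chr1", "chr2", "chr3"),
                                    length = c(2e6, 20e6, 20e6)),
                         snv_density = 5e-4),
    dominant_locus = list(chrom = "chr2", pos = 10e6),
    suppressor_loci = data.frame(chrom = "chr1", pos = 1e6),
    n_offspring = 200L, penetrance = 1, leak = 0,
    pool_sizes = c(recessive = 30L, dominant = 40L),
    depth_means = c(recessive = 60, dominant = 60),
    seq_error = 0, seed = 23L)
  sim <- simulate_pooled_experiment(cfg)
  scan <- afddd_scan(sim$recessive, sim$dominant, cfg$genome$chromosomes)
  # group tallies partition the common set
  expect_equal(sum(scan$group_tally), scan$partition[["common"]])
  # window conservation
  expect_equal(sum(scan$scores$count), nrow(scan$informative))
  # the clean one-locus signal is found at chr1:1 Mb
  expect_gt(nrow(scan$peaks), 0L)
  hit <- scan$peaks$chrom == "chr1" & scan$peaks$start <= 1e6 &
    scan$peaks$end >= 1e6
  expect_true(any(hit))
  expect_match(scan$peaks$type_sets[hit][1], "A")

  bad <- sim$recessive
  bad$chrom[1] <- "chrZ"
  expect_error(afddd_scan(bad, sim$dominant, cfg$genome$chromosomes),
               "chrZ")
})
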