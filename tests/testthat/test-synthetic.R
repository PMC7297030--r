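test_that("identical config and seed give identical output tables", {
  cfg <- clean_config(seed = 11L, n_offspring = 200L,
                      pool_sizes = c(recessive = 20L, dominant = 30L))
  a <- simulate_pooled_experiment(cfg)
  b <- simulate_pooled_experiment(cfg)
  expect_identical(a$recessive, b$recessive)
  expect_identical(a$dominant, b$dominant)
  expect_identical(a$pop$geno_seed, b$pop$geno_seed)
  expect_identical(a$pools, b$pools)
})

test_that("every offspring carries exactly one allele per parent per site", {
  cfg <- clean_config(seed = 3L, n_offspring = 50L,
                      pool_sizes = c(recessive = 5L, dominant = 5L))
  pop <- simulate_cross(cfg)
  expect_true(all(pop$geno_seed %in% 0:1))
  expect_true(all(pop$geno_pollen %in% 0:1))
  total <- pop$geno_seed + pop$geno_pollen
  expect_true(all(total >= 0 & total <= 2))
})

test_that("with zero recombination every gamete is an intact parental haplotype", {
  cfg <- cross_config(genome = genome_spec(
                        data.frame(name = "chr1", length = 10e6),
                        snv_density = 5e-5),
                      dominant_locus = list(chrom = "chr1", pos = 9e6),
                      suppressor_loci = data.frame(chrom = "chr1", pos = 5e6),
                      n_offspring = 60L, recomb_rate = 0,
                      pool_sizes = c(recessive = 5L, dominant = 5L),
                      seed = 5L)
  pop <- simulate_cross(cfg)
  h1 <- pop$sites$seed_h1
  h2 <- pop$sites$seed_h2
  for (i in seq_len(nrow(pop$trait))) {
    gam <- pop$geno_seed[i, ]
    expect_true(identical(gam, h1) || identical(gam, h2))
  }
  # and a coupling-phase marker then equals the suppressor genotype exactly
  a_sites <- which(pop$sites$label == "A")
  for (s in a_sites) {
    expect_equal(pop$geno_seed[, s] + pop$geno_pollen[, s],
                 pop$trait$sup1_rec_alleles)
  }
})

test_that("recombination fraction between linked sites follows the Haldane map", {
  cfg <- cross_config(genome = genome_spec(
                        data.frame(name = "chr1", length = 2e6),
                        snv_density = 1e-4),
                      dominant_locus = list(chrom = "chr1", pos = 1.9e6),
                      suppressor_loci = data.frame(chrom = "chr1", pos = 1e6),
                      n_offspring = 2500L, recomb_rate = 2,
                      pool_sizes = c(recessive = 5L, dominant = 5L),
                      seed = 9L)
  pop <- simulate_cross(cfg)
  # need a pair of sites ~1 Mb apart where the seed parent is heterozygous
  # with known phase (haplotype 1 carries the variant)
  het <- which(pop$sites$seed_h1 == 1L & pop$sites$seed_h2 == 0L)
  pos <- pop$sites$pos[het]
  pair <- NULL
  for (i in seq_along(het)) {
    j <- which(abs(pos - pos[i] - 1e6) < 0.05e6)
    if (length(j)) { pair <- c(het[i], het[j[1]]); break }
  }
  expect_false(is.null(pair))
  d_bp <- abs(diff(pop$sites$pos[pair]))
  # Haldane: r = (1 - exp(-2d_Morgan)) / 2 with d = 2 cM/Mb * distance
  d_morgan <- 2 * d_bp / 1e6 / 100
  r_expected <- (1 - exp(-2 * d_morgan)) / 2
  # seed gametes: allele mismatch between the two sites marks a recombinant
  gam <- pop$geno_seed[, pair]
  r_hat <- mean(gam[, 1] != gam[, 2])
  se <- sqrt(r_expected * (1 - r_expected) / nrow(gam))
  expect_lt(abs(r_hat - r_expected), 3 * se)
})

test_that("the dominant locus segregates 1:2:1 across seeds", {
  # trait-locus-only populations keep this cheap: 100 seeds x 275 offspring
  pass <- vapply(1:100, function(s) {
    pop <- simulate_cross(trait_only_config(seed = s))
    counts <- table(factor(pop$trait$co_geno, c("CoCo", "Coco", "coco")))
    suppressWarnings(
      stats::chisq.test(as.integer(counts), p = c(1, 2, 1) / 4)$p.value
    ) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("per-round suppressed fractions track the penetrance schedule", {
  cfg <- trait_only_config(seed = 21L, n_offspring = 2000L)
  pop <- assign_phenotypes(simulate_cross(cfg))
  qual_carrier <- pop$trait$qualifies & pop$trait$co_geno != "coco"
  n <- sum(qual_carrier)
  for (t in seq_along(cfg$penetrance)) {
    frac <- mean(pop$status[qual_carrier, t] == "Std2")
    se <- sqrt(cfg$penetrance[t] * (1 - cfg$penetrance[t]) / n)
    expect_lt(abs(frac - cfg$penetrance[t]), 3 * se)
  }
  # nestedness: with a non-increasing schedule, suppressed sets shrink
  std2_by_round <- lapply(seq_along(cfg$penetrance), function(t) {
    which(pop$status[, t] == "Std2" & pop$trait$qualifies)
  })
  for (t in 2:length(std2_by_round)) {
    expect_true(all(std2_by_round[[t]] %in% std2_by_round[[t - 1]]))
  }
  # coco individuals are always standard, never Std2
  coco <- pop$trait$co_geno == "coco"
  expect_true(all(pop$status[coco, ] == "Std1"))
  expect_true(all(pop$phenotype[coco, ] %in% 3:4))
})

test_that("deterministic penetrance limit makes phenotype a genotype readout", {
  cfg <- trait_only_config(seed = 8L, penetrance = 1, leak = 0)
  pop <- assign_phenotypes(simulate_cross(cfg))
  carrier <- pop$trait$co_geno != "coco"
  expect_true(all(pop$status[carrier & pop$trait$qualifies, 1] == "Std2"))
  expect_true(all(pop$status[carrier & !pop$trait$qualifies, 1] ==
                    "columnar"))
})

test_that("pool construction is sized, seeded and guarded", {
  cfg <- trait_only_config(seed = 13L)
  pop <- assign_phenotypes(simulate_cross(cfg))
  pools <- build_pools(pop, 1L)
  expect_length(pools$recessive, 16L)
  expect_length(pools$dominant, 18L)
  expect_identical(pools, build_pools(pop, 1L))
  # pooled individuals have the right phenotype and carry the dominant allele
  expect_true(all(pop$status[pools$recessive, 1] == "Std2"))
  expect_true(all(pop$status[pools$dominant, 1] == "columnar"))
  # requesting more than available names the shortfall
  cfg_big <- trait_only_config(seed = 13L,
                               pool_sizes = c(recessive = 270L,
                                              dominant = 18L))
  pop_big <- assign_phenotypes(simulate_cross(cfg_big))
  expect_error(build_pools(pop_big, 1L), "short by")
})

test_that("pooled read sampling has the right first moments", {
  # a hand-built population: every member heterozygous at every site (f = 1/2)
  n_sites <- 1000L
  sites <- data.frame(chrom = "chr1", pos = seq_len(n_sites) * 1000L,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  pop <- structure(list(
    sites = sites,
    geno_seed = matrix(1L, 10L, n_sites),
    geno_pollen = matrix(0L, 10L, n_sites)
  ), class = "cross_pop")
  cfg_like <- list(depth_means = c(recessive = 100, dominant = 100),
                   seq_error = 0, seed = 4L)
  rec <- simulate_pool_reads(pop, 1:10, "recessive", config = cfg_like)
  expect_true(all(rec$alt_count <= rec$depth))
  se <- 100 * sqrt(0.25 / 100) / sqrt(n_sites)
  expect_lt(abs(mean(rec$af) - 50), 3 * se)

  # substitution errors hit one of three alternative bases uniformly:
  # a monomorphic-reference site reads the recorded alt at rate eps / 3
  pop0 <- pop
  pop0$geno_seed[] <- 0L
  cfg_err <- list(depth_means = c(recessive = 100, dominant = 100),
                  seq_error = 0.006, seed = 4L)
  rec0 <- simulate_pool_reads(pop0, 1:10, "recessive", config = cfg_err)
  frac <- sum(rec0$alt_count) / sum(rec0$depth)
  se0 <- sqrt(0.002 * 0.998 / sum(rec0$depth))
  expect_lt(abs(frac - 0.002), 3 * se0)

  expect_error(simulate_pool_reads(pop, integer(0), "recessive",
                                   config = cfg_like), "empty")
})

test_that("pool AF at a fully linked type-A site approaches the analytic value", {
  cfg <- clean_config(seed = 31L, n_loci = 1L)
  sim <- simulate_pooled_experiment(cfg)
  near <- sim$pop$sites$chrom == "chr1" &
    abs(sim$pop$sites$pos - 0.5e6) < 1e5 & sim$pop$sites$label == "A"
  expect_gt(sum(near), 3)
  e <- expected_pool_af(seg_type("A"), 1)
  # sites within 100 kb recombine at r <= 0.002 per gamete, so the
  # recessive-pool AF can dip below 100 by at most a few tenths of a point
  expect_gt(mean(sim$recessive$af[near]), 99.2)
  expect_lte(max(sim$recessive$af[near]), 100)
  m <- length(sim$pools$dominant)
  # one-gene dominant class draws marker genotypes {VR, RR} at 2:1 odds,
  # so allele-count variance is 2/9; read noise adds (1/3)(2/3)/depth per site
  se <- 100 * sqrt((2 / 9) / (4 * m) +
                     (1 / 3) * (2 / 3) / (sum(near) * 150))
  expect_lt(abs(mean(sim$dominant$af[near]) - e$af_dominant), 3 * se)
})
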