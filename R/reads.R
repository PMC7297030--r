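#' Simulate pooled sequencing allele counts
#'
#' For each segregating site, the true pool variant frequency is
#' \eqn{f = (\textrm{variant alleles in the pool}) / (2 \times \textrm{pool size})}.
#' Read depth is Poisson with the pool's mean mapped depth; the variant read
#' count is Binomial(depth, \eqn{f (1-\epsilon) + (1-f)\,\epsilon/3}) where
#' \eqn{\epsilon} is the per-base substitution error rate (an erroneous base
#' is one of the three alternatives uniformly). Sequencing errors are
#' injected at the allele-count level; no reads are simulated.
#'
#' @param pop a \code{\link{simulate_cross}} population.
#' @param members integer indices of the pooled individuals.
#' @param pool \code{"recessive"} or \code{"dominant"}; selects the mean
#'   depth and the RNG stream.
#' @param config a \code{\link{cross_config}}.
#' @param tag extra RNG tag (e.g. the pooling round) so repeated poolings
#'   of the same population stay independent yet reproducible.
#' @return A data frame of per-site records: \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{depth}, \code{alt_count}, \code{af}
#'   (percent; \code{NA} where depth is 0).
#' @export
simulate_pool_reads <- function(pop, members, pool = c("recessive", "dominant"),
                                config = pop$config, tag = "") {
  stopifnot(inherits(pop, "cross_pop"))
  pool <- match.arg(pool)
  if (length(members) == 0L) {
    stop("pool is empty", call. = FALSE)
  }
  depth_mean <- config$depth_means[[pool]]
  eps <- config$seq_error
  m <- length(members)
  counts <- colSums(pop$geno_seed[members, , drop = FALSE]) +
    colSums(pop$geno_pollen[members, , drop = FALSE])
  f <- counts / (2 * m)
  p <- f * (1 - eps) + (1 - f) * eps / 3
  with_child_seed(config$seed, paste0("reads-", pool, "-", tag), {
    depth <- stats::rpois(length(f), depth_mean)
    alt <- stats::rbinom(length(f), depth, p)
    data.frame(
      chrom = pop$sites$chrom, pos = pop$sites$pos,
      ref = pop$sites$ref, alt = pop$sites$alt,
      depth = depth, alt_count = alt,
      af = ifelse(depth > 0, 100 * alt / depth, NA_real_),
      stringsAsFactors = FALSE
    )
  })
}

#' Run the full simulated pooled-sequencing experiment
#'
#' Convenience wrapper: simulates the cross, assigns phenotypes, builds the
#' two phenotype pools at one round, and samples pooled allele counts for
#' both pools.
#'
#' @param config a \code{\link{cross_config}}.
#' @param round_index evaluation round used for pooling.
#' @return A list with \code{pop}, \code{pools}, \code{recessive} and
#'   \code{dominant} per-pool variant tables, \code{truth} (data frame of
#'   causal loci), and \code{config}.
#' @export
simulate_pooled_experiment <- function(config = cross_config(),
                                       round_index = 1L) {
  pop <- assign_phenotypes(simulate_cross(config))
  pools <- build_pools(pop, round_index)
  rec <- simulate_pool_reads(pop, pools$recessive, "recessive",
                             tag = round_index)
  dom <- simulate_pool_reads(pop, pools$dominant, "dominant",
                             tag = round_index)
  truth <- rbind(
    data.frame(chrom = config$dominant_locus$chrom,
               pos = config$dominant_locus$pos, what = "dominant_locus",
               stringsAsFactors = FALSE),
    data.frame(chrom = config$suppressor_loci$chrom,
               pos = config$suppressor_loci$pos,
               what = paste0("suppressor_", seq_len(nrow(config$suppressor_loci))),
               stringsAsFactors = FALSE)
  )
  list(pop = pop, pools = pools, recessive = rec, dominant = dom,
       truth = truth, config = config)
}
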