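#' Assign phenotypes over evaluation rounds
#'
#' Scores every individual in each evaluation round on the 1--4 scale
#' (1 = columnar, 2 = columnar-like, 3 = standard-like, 4 = standard).
#' Individuals homozygous reference at the dominant locus (\code{coco}) are
#' always standard (Std1). Carriers of the dominant allele that are
#' homozygous recessive at all required suppressor loci express the
#' suppressed standard phenotype (Std2) in round \code{t} with probability
#' \code{penetrance[t]}; all other carriers express Std2 with the small
#' \code{leak} probability. Each individual draws a single latent uniform
#' per mechanism, so with a non-increasing penetrance schedule the set of
#' suppressed individuals shrinks with age (trees "return" to columnar,
#' never the reverse), while per-round marginal frequencies equal the
#' schedule exactly in expectation.
#'
#' The split of standard into S vs SL (and columnar into C vs CL) is a
#' cosmetic Bernoulli(0.5) label fixed per individual; downstream analyses
#' use only the binary classes.
#'
#' @param pop a \code{\link{simulate_cross}} population.
#' @param config a \code{\link{cross_config}}; defaults to the one stored
#'   in \code{pop}.
#' @return \code{pop} with a \code{phenotype} matrix (individuals x rounds,
#'   integer scores 1--4) and a \code{status} matrix with values
#'   \code{"columnar"}, \code{"Std1"}, \code{"Std2"}.
#' @export
assign_phenotypes <- function(pop, config = pop$config) {
  stopifnot(inherits(pop, "cross_pop"))
  pen <- config$penetrance
  leak <- config$leak
  if (length(pen) < 1L) {
    stop("config field `penetrance` must have at least one round",
         call. = FALSE)
  }
  n <- nrow(pop$trait)
  rounds <- length(pen)
  carrier <- pop$trait$co_geno != "coco"
  qualifies <- pop$trait$qualifies

  draws <- with_child_seed(config$seed, "phenotypes", {
    list(u_pen = stats::runif(n), u_leak = stats::runif(n),
         u_split = stats::runif(n))
  })
  std_score <- ifelse(draws$u_split < 0.5, 4L, 3L)
  col_score <- ifelse(draws$u_split < 0.5, 1L, 2L)

  phen <- matrix(0L, n, rounds)
  status <- matrix("", n, rounds)
  for (t in seq_len(rounds)) {
    suppressed <- carrier &
      ifelse(qualifies, draws$u_pen < pen[t], draws$u_leak < leak[t])
    phen[, t] <- ifelse(!carrier | suppressed, std_score, col_score)
    status[, t] <- ifelse(!carrier, "Std1",
                          ifelse(suppressed, "Std2", "columnar"))
  }
  pop$phenotype <- phen
  pop$status <- status
  pop
}

#' Build phenotype pools for sequencing
#'
#' Samples the recessive (Std2: standard-scored carriers of the dominant
#' allele) and dominant (columnar-scored carriers) pools at one evaluation
#' round, without replacement. Individuals homozygous reference at the
#' dominant locus (Std1) are never pooled.
#'
#' @param pop a population with phenotypes assigned.
#' @param round_index which evaluation round to pool on (default 1).
#' @param config a \code{\link{cross_config}}.
#' @return A list with integer index vectors \code{recessive} and
#'   \code{dominant} (class \code{"pool_pair"}).
#' @export
build_pools <- function(pop, round_index = 1L, config = pop$config) {
  stopifnot(inherits(pop, "cross_pop"))
  if (is.null(pop$status)) {
    stop("phenotypes not assigned; run assign_phenotypes() first",
         call. = FALSE)
  }
  status <- pop$status[, round_index]
  std2 <- which(status == "Std2")
  columnar <- which(status == "columnar")
  want_r <- config$pool_sizes[["recessive"]]
  want_d <- config$pool_sizes[["dominant"]]
  if (length(std2) < want_r) {
    stop(sprintf(
      "recessive pool needs %d Std2 individuals but only %d available (short by %d)",
      want_r, length(std2), want_r - length(std2)), call. = FALSE)
  }
  if (length(columnar) < want_d) {
    stop(sprintf(
      "dominant pool needs %d columnar individuals but only %d available (short by %d)",
      want_d, length(columnar), want_d - length(columnar)), call. = FALSE)
  }
  with_child_seed(config$seed, paste0("pools-round-", round_index), {
    structure(list(
      recessive = sort(sample(std2, want_r)),
      dominant = sort(sample(columnar, want_d)),
      round_index = round_index
    ), class = "pool_pair")
  })
}

#' @export
print.pool_pair <- function(x, ...) {
  cat(sprintf("pool_pair (round %d): %d recessive (Std2), %d dominant (columnar)\n",
              x$round_index, length(x$recessive), length(x$dominant)))
  invisible(x)
}

#' Individual-level genotype/phenotype table
#'
#' Flattens a simulated population into the TSV-style table consumed by the
#' confirmation statistics: per individual, the dominant-locus genotype,
#' suppressor genotypes, transmitted parental alleles at each suppressor
#' locus, and the phenotype score per round.
#'
#' @param pop a population with phenotypes assigned.
#' @return A data frame.
#' @export
individual_table <- function(pop) {
  stopifnot(inherits(pop, "cross_pop"))
  out <- pop$trait
  n_sup <- dim(pop$sup_allele)[3]
  for (j in seq_len(n_sup)) {
    out[[paste0("sup", j, "_seed_allele")]] <-
      ifelse(pop$sup_allele[, "seed", j] == 1L, "rec", "dom")
    out[[paste0("sup", j, "_pollen_allele")]] <-
      ifelse(pop$sup_allele[, "pollen", j] == 1L, "rec", "dom")
  }
  if (!is.null(pop$phenotype)) {
    for (t in seq_len(ncol(pop$phenotype))) {
      out[[paste0("score_round", t)]] <- pop$phenotype[, t]
      out[[paste0("status_round", t)]] <- pop$status[, t]
    }
  }
  out
}
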