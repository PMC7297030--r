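#' Phase-resolved marker segregation type
#'
#' Describes one biallelic SNV marker in a biparental outcross. Each parent
#' carries an ordered pair of marker alleles, each either \code{"V"} (the
#' variant allele relative to the reference genome) or \code{"R"} (the
#' reference allele). The pair is phase-resolved: the first allele sits on
#' the haplotype carrying that parent's recessive suppressor allele, so the
#' ordering encodes coupling/repulsion between the marker and the trait
#' locus.
#'
#' Five configurations are informative for mapping a recessive trait and
#' carry conventional names:
#' \itemize{
#'   \item A: \code{(V|R, V|R)} -- both parents heterozygous, variant in
#'     coupling with the recessive allele in both.
#'   \item B: \code{(V|R, V|V)} -- seed parent heterozygous in coupling,
#'     pollen parent homozygous variant.
#'   \item C: \code{(V|V, V|R)} -- mirror image of B.
#'   \item D: \code{(V|R, R|R)} -- seed parent heterozygous in coupling,
#'     pollen parent homozygous reference.
#'   \item E: \code{(R|R, V|R)} -- mirror image of D.
#' }
#' Any other configuration is labelled \code{"other"}.
#'
#' @param seed,pollen ordered allele pairs for the seed and pollen parent.
#'   Either a character vector of length 2 with entries \code{"V"}/\code{"R"},
#'   or a string such as \code{"V|R"}.
#' @return An object of class \code{"marker_seg"}: a list with elements
#'   \code{seed}, \code{pollen} (character pairs) and \code{label}.
#' @examples
#' marker_segregation("V|R", "V|R")   # type A
#' marker_segregation("R|V", "R|V")   # repulsion in both parents: "other"
#' @export
marker_segregation <- function(seed, pollen) {
  seed <- parse_allele_pair(seed, "seed")
  pollen <- parse_allele_pair(pollen, "pollen")
  structure(
    list(seed = seed, pollen = pollen,
         label = seg_label(seed, pollen)),
    class = "marker_seg"
  )
}

parse_allele_pair <- function(x, which) {
  if (is.character(x) && length(x) == 1L && grepl("|", x, fixed = TRUE)) {
    x <- strsplit(x, "|", fixed = TRUE)[[1L]]
  }
  x <- toupper(as.character(x))
  if (length(x) != 2L || !all(x %in% c("V", "R"))) {
    stop("`", which, "` must be an ordered pair of alleles in {V, R}, ",
         "e.g. \"V|R\"", call. = FALSE)
  }
  x
}

seg_label <- function(seed, pollen) {
  key <- paste(paste(seed, collapse = ""), paste(pollen, collapse = ""))
  switch(key,
    "VR VR" = "A",
    "VR VV" = "B",
    "VV VR" = "C",
    "VR RR" = "D",
    "RR VR" = "E",
    "other"
  )
}

#' @export
print.marker_seg <- function(x, ...) {
  cat(sprintf("<%s|%s x %s|%s> marker segregation (type %s)\n",
              x$seed[1], x$seed[2], x$pollen[1], x$pollen[2], x$label))
  cat("  first allele of each pair rides the recessive-linked haplotype\n")
  invisible(x)
}

#' Named informative segregation type
#'
#' Convenience constructor for the five named types (see
#' \code{\link{marker_segregation}}).
#'
#' @param label one of \code{"A"}, \code{"B"}, \code{"C"}, \code{"D"},
#'   \code{"E"}.
#' @return A \code{"marker_seg"} object.
#' @export
seg_type <- function(label) {
  pairs <- switch(toupper(label),
    A = list("V|R", "V|R"),
    B = list("V|R", "V|V"),
    C = list("V|V", "V|R"),
    D = list("V|R", "R|R"),
    E = list("R|R", "V|R"),
    stop("unknown segregation type label: ", label, call. = FALSE)
  )
  marker_segregation(pairs[[1L]], pairs[[2L]])
}

#' Recessive trait model
#'
#' The trait is expressed only in offspring homozygous for the recessive
#' allele at all of \code{n_loci} unlinked suppressor loci; the marker under
#' study is completely linked to locus 1. Under \code{n_loci = 2} the second
#' locus segregates independently with both parents heterozygous.
#'
#' @param n_loci 1 or 2.
#' @return An object of class \code{"recessive_model"}.
#' @export
recessive_model <- function(n_loci = 1L) {
  n_loci <- as.integer(n_loci)
  if (length(n_loci) != 1L || is.na(n_loci) || !n_loci %in% c(1L, 2L)) {
    stop("`n_loci` must be 1 or 2", call. = FALSE)
  }
  structure(list(n_loci = n_loci, linked_locus = 1L),
            class = "recessive_model")
}

as_recessive_model <- function(model) {
  if (inherits(model, "recessive_model")) return(model)
  recessive_model(model)
}

## Exhaustive enumeration over equiprobable gamete combinations.
## One locus: each parent transmits haplotype 1 (marker allele in coupling
## with its recessive allele) or haplotype 2 -> 4 combinations.
## Two loci: additionally each parent transmits the recessive or dominant
## allele at the unlinked second locus -> 16 combinations.
## All counts are small integers, so allele frequencies computed from them
## are exact ratios.
enumerate_combos <- function(seg, model) {
  model <- as_recessive_model(model)
  if (model$n_loci == 1L) {
    g <- expand.grid(hs = 1:2, hp = 1:2)
    g$rec <- g$hs == 1L & g$hp == 1L
  } else {
    g <- expand.grid(hs = 1:2, hp = 1:2, ls = 1:2, lp = 1:2)
    g$rec <- g$hs == 1L & g$hp == 1L & g$ls == 1L & g$lp == 1L
  }
  g$seed_allele <- seg$seed[g$hs]
  g$pollen_allele <- seg$pollen[g$hp]
  g$n_variant <- (g$seed_allele == "V") + (g$pollen_allele == "V")
  g
}

#' Enumerate offspring marker genotypes and trait classes
#'
#' Exhaustively enumerates the equally likely gamete combinations of a
#' biparental cross for a phase-resolved marker completely linked to
#' recessive suppressor locus 1, and tabulates the joint distribution of
#' marker genotype and trait class.
#'
#' @param seg a \code{\link{marker_segregation}} object.
#' @param model a \code{\link{recessive_model}} (or 1/2 for convenience).
#' @return A data frame with one row per (genotype, trait) combination:
#'   \code{genotype} (\code{"VV"}, \code{"VR"}, \code{"RR"}), \code{trait}
#'   (\code{"recessive"} or \code{"dominant"}), \code{n_variant_alleles},
#'   and exact \code{prob} (probabilities sum to 1).
#' @examples
#' enumerate_offspring(seg_type("A"), recessive_model(1))
#' @export
enumerate_offspring <- function(seg, model = recessive_model(1L)) {
  stopifnot(inherits(seg, "marker_seg"))
  g <- enumerate_combos(seg, model)
  geno <- c("RR", "VR", "VV")[g$n_variant + 1L]
  trait <- ifelse(g$rec, "recessive", "dominant")
  tab <- aggregate(list(weight = rep(1L, nrow(g))),
                   by = list(genotype = geno, trait = trait,
                             n_variant_alleles = g$n_variant),
                   FUN = sum)
  tab$prob <- tab$weight / nrow(g)
  tab$weight <- NULL
  tab[order(tab$trait, -tab$n_variant_alleles), , drop = FALSE]
}

#' Expected pool allele frequencies and AFDD for a segregation type
#'
#' Computes the expected variant allele frequency, as a percentage, among
#' offspring of the recessive phenotype class (the recessive, Std2-like
#' pool) and among all other offspring (the dominant, columnar-like pool),
#' for a marker completely linked to suppressor locus 1, together with
#' their directional difference AFDD = AF(recessive pool) - AF(dominant
#' pool) in percentage points. A type is informative when AFDD > 0.
#'
#' Enumeration is over exact integer gamete counts, so the returned values
#' are exact up to the final division.
#'
#' @inheritParams enumerate_offspring
#' @return An object of class \code{"pool_expectation"}: a list with
#'   \code{af_recessive}, \code{af_dominant} (percent), \code{afdd}
#'   (percentage points), \code{informative}, \code{label}, \code{n_loci}.
#' @examples
#' expected_pool_af(seg_type("A"), 1)  # AF 100 vs 33.3, AFDD 66.7
#' expected_pool_af(seg_type("D"), 2)  # AF 50 vs 23.3, AFDD 26.7
#' @export
expected_pool_af <- function(seg, model = recessive_model(1L)) {
  stopifnot(inherits(seg, "marker_seg"))
  model <- as_recessive_model(model)
  g <- enumerate_combos(seg, model)
  n_rec <- sum(g$rec)
  n_dom <- sum(!g$rec)
  af_rec <- 100 * sum(g$n_variant[g$rec]) / (2 * n_rec)
  af_dom <- 100 * sum(g$n_variant[!g$rec]) / (2 * n_dom)
  afdd <- af_rec - af_dom
  structure(
    list(af_recessive = af_rec, af_dominant = af_dom, afdd = afdd,
         informative = afdd > 0, label = seg$label, n_loci = model$n_loci),
    class = "pool_expectation"
  )
}

#' @export
print.pool_expectation <- function(x, ...) {
  cat(sprintf(
    "pool AF expectation (type %s, %d-gene model)\n", x$label, x$n_loci))
  cat(sprintf("  recessive pool AF: %6.2f %%\n", x$af_recessive))
  cat(sprintf("  dominant  pool AF: %6.2f %%\n", x$af_dominant))
  cat(sprintf("  AFDD: %6.2f pp (%s)\n", x$afdd,
              if (x$informative) "informative" else "not informative"))
  invisible(x)
}

#' All 12 phase-resolved segregation-type derivatives
#'
#' The three two-base segregation types usable in an outcross (both parents
#' heterozygous; seed heterozygous with pollen homozygous; seed homozygous
#' with pollen heterozygous), each phase- and variant-resolved, yield 12
#' derivatives. Types with 3--4 distinct bases are rare in real genomes and
#' excluded.
#'
#' @return A list of 12 \code{"marker_seg"} objects.
#' @export
all_derivatives <- function() {
  het <- list(c("V", "R"), c("R", "V"))
  hom <- list(c("V", "V"), c("R", "R"))
  out <- list()
  for (s in het) for (p in het) out <- c(out, list(marker_segregation(s, p)))
  for (s in het) for (p in hom) out <- c(out, list(marker_segregation(s, p)))
  for (s in hom) for (p in het) out <- c(out, list(marker_segregation(s, p)))
  out
}

#' Table of expected pool AFs for all derivatives and models
#'
#' @param n_loci integer vector of recessive-gene models to tabulate.
#' @return A data frame with columns \code{seed_pair}, \code{pollen_pair},
#'   \code{label}, \code{n_loci}, \code{af_recessive}, \code{af_dominant},
#'   \code{afdd}, \code{informative}.
#' @export
segregation_expectations <- function(n_loci = c(1L, 2L)) {
  derivs <- all_derivatives()
  rows <- list()
  for (k in n_loci) {
    for (d in derivs) {
      e <- expected_pool_af(d, recessive_model(k))
      rows[[length(rows) + 1L]] <- data.frame(
        seed_pair = paste(d$seed, collapse = "|"),
        pollen_pair = paste(d$pollen, collapse = "|"),
        label = d$label, n_loci = as.integer(k),
        af_recessive = e$af_recessive, af_dominant = e$af_dominant,
        afdd = e$afdd, informative = e$informative,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Write the segregation-expectation table as TSV
#'
#' @param path output file path.
#' @param n_loci models to include.
#' @return \code{path}, invisibly.
#' @export
write_segregation_table <- function(path, n_loci = c(1L, 2L)) {
  utils::write.table(segregation_expectations(n_loci), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Type-specific AF/AFDD filter windows for informative SNVs
#'
#' The published selection filters for informative SNVs, one window per
#' type set. Bounds are fixed decimal constants on the percent scale,
#' chosen to bracket the expected values under both the one- and
#' two-recessive-gene models:
#' \itemize{
#'   \item A: recessive-pool AF >= 85, AFDD >= 43.3 pp;
#'   \item B/C: recessive-pool AF >= 85, 16.7 <= AFDD < 43.3 pp
#'     (upper bound open so no SNV satisfies both the A and B/C windows);
#'   \item D/E: recessive-pool AF in [35, 65], 16.7 <= AFDD <= 43.3 pp.
#' }
#'
#' @param models a list of \code{\link{recessive_model}}s (or an integer
#'   vector of \code{n_loci} values); must be nonempty. The bounds are
#'   constants and do not depend on the particular models supplied, but the
#'   windows are checked to bracket the expected AFDDs of those models.
#' @return A data frame with columns \code{type_set}, \code{af_recessive_min},
#'   \code{af_recessive_max}, \code{afdd_min}, \code{afdd_max},
#'   \code{afdd_max_inclusive}.
#' @export
informative_filter_windows <- function(models = c(1L, 2L)) {
  if (length(models) == 0L) {
    stop("`models` must contain at least one recessive model", call. = FALSE)
  }
  if (inherits(models, "recessive_model")) models <- list(models)
  models <- lapply(models, as_recessive_model)
  data.frame(
    type_set = c("A", "B/C", "D/E"),
    af_recessive_min = c(85, 85, 35),
    af_recessive_max = c(100, 100, 65),
    afdd_min = c(43.3, 16.7, 16.7),
    afdd_max = c(Inf, 43.3, 43.3),
    afdd_max_inclusive = c(TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}
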