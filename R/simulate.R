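#' Simulate an F1 cross
#'
#' Draws a set of segregating SNV sites from the genome specification,
#' assigns each a phase-resolved segregation-type derivative, and forms
#' \code{n_offspring} F1 individuals, each from one recombinant gamete per
#' parent. Crossovers per chromosome are Poisson with no interference
#' (map length = \code{recomb_rate} x chromosome length), so recombination
#' fractions between sites follow the Haldane map function. Parent
#' haplotype 1 carries the recessive suppressor allele(s); the first allele
#' of each derivative's pair sits on haplotype 1, which makes marker-trait
#' phase explicit.
#'
#' @param config a \code{\link{cross_config}}.
#' @return An object of class \code{"cross_pop"}: a list with
#'   \code{sites} (data frame: chrom, pos, ref, alt, derivative key and
#'   label, parental haplotype alleles), \code{geno_seed} /
#'   \code{geno_pollen} (n x sites 0/1 matrices of transmitted variant
#'   alleles), \code{trait} (per-individual dominant-locus genotype,
#'   suppressor genotypes and trait class), and \code{config}. Phenotypes
#'   are added by \code{\link{assign_phenotypes}}.
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  genome <- config$genome
  chroms <- genome$chromosomes

  sites <- with_child_seed(config$seed, "sites", draw_sites(genome))

  ## parent haplotypes at the trait loci (1 = recessive / dominant allele
  ## present on that haplotype)
  n_sup <- nrow(config$suppressor_loci)
  sup_hap <- trait_haplotypes(config)

  ## gamete formation, one chromosome at a time
  n <- config$n_offspring
  geno_seed <- matrix(0L, n, nrow(sites))
  geno_pollen <- matrix(0L, n, nrow(sites))
  co_allele <- matrix(0L, n, 2, dimnames = list(NULL, c("seed", "pollen")))
  sup_allele <- array(0L, dim = c(n, 2, n_sup),
                      dimnames = list(NULL, c("seed", "pollen"), NULL))

  with_child_seed(config$seed, "meiosis", {
    for (ci in seq_len(nrow(chroms))) {
      chrom <- chroms$name[ci]
      len <- chroms$length[ci]
      site_idx <- which(sites$chrom == chrom)
      pos <- sites$pos[site_idx]
      dom_here <- identical(config$dominant_locus$chrom, chrom)
      sup_here <- which(config$suppressor_loci$chrom == chrom)
      extra <- c(if (dom_here) config$dominant_locus$pos,
                 config$suppressor_loci$pos[sup_here])
      all_pos <- c(pos, extra)
      cm <- config$recomb_rate * len / 1e6
      for (parent in c("seed", "pollen")) {
        h1 <- c(sites[[paste0(parent, "_h1")]][site_idx],
                if (dom_here) sup_hap$dom[[parent]][1],
                sup_hap$sup[[parent]][sup_here, 1])
        h2 <- c(sites[[paste0(parent, "_h2")]][site_idx],
                if (dom_here) sup_hap$dom[[parent]][2],
                sup_hap$sup[[parent]][sup_here, 2])
        for (i in seq_len(n)) {
          gam <- gamete_alleles(all_pos, len, cm, h1, h2)
          k <- length(site_idx)
          if (k) {
            if (parent == "seed") geno_seed[i, site_idx] <- gam[seq_len(k)]
            else geno_pollen[i, site_idx] <- gam[seq_len(k)]
          }
          j <- k
          if (dom_here) {
            j <- j + 1L
            co_allele[i, parent] <- gam[j]
          }
          for (s in seq_along(sup_here)) {
            sup_allele[i, parent, sup_here[s]] <- gam[j + s]
          }
        }
      }
    }
  })

  trait <- trait_table(co_allele, sup_allele, n_sup)
  structure(
    list(sites = sites, geno_seed = geno_seed, geno_pollen = geno_pollen,
         trait = trait, co_allele = co_allele, sup_allele = sup_allele,
         config = config),
    class = "cross_pop"
  )
}

## alleles transmitted by one recombinant gamete at the given positions
gamete_alleles <- function(pos, len, cm, h1, h2) {
  n_xo <- stats::rpois(1L, cm / 100)
  start <- sample.int(2L, 1L)
  if (n_xo == 0L) {
    hap <- rep.int(start, length(pos))
  } else {
    xo <- sort(stats::runif(n_xo, 0, len))
    hap <- (start - 1L + findInterval(pos, xo)) %% 2L + 1L
  }
  ifelse(hap == 1L, h1, h2)
}

draw_sites <- function(genome) {
  mix <- genome$seg_type_mixture
  keys <- names(mix)
  out <- list()
  for (ci in seq_len(nrow(genome$chromosomes))) {
    len <- genome$chromosomes$length[ci]
    n <- stats::rpois(1L, genome$snv_density * len)
    if (n == 0L) next
    pos <- sort(sample.int(len, n))
    deriv <- sample(keys, n, replace = TRUE, prob = mix)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1), USE.NAMES = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      chrom = genome$chromosomes$name[ci], pos = pos, ref = ref, alt = alt,
      deriv = deriv, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    sites <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        deriv = character(), stringsAsFactors = FALSE)
  } else {
    sites <- do.call(rbind, out)
  }
  hap <- derivative_haplotypes(sites$deriv)
  cbind(sites, hap)
}

## expand derivative keys like "V|R x V|V" into per-parent haplotype alleles
derivative_haplotypes <- function(keys) {
  lab <- character(length(keys))
  m <- matrix(0L, length(keys), 4,
              dimnames = list(NULL, c("seed_h1", "seed_h2",
                                      "pollen_h1", "pollen_h2")))
  for (i in seq_along(keys)) {
    if (keys[i] == "nonseg") {
      m[i, ] <- 1L
      lab[i] <- "nonseg"
    } else {
      parts <- strsplit(keys[i], " x ", fixed = TRUE)[[1]]
      seed <- strsplit(parts[1], "|", fixed = TRUE)[[1]]
      pollen <- strsplit(parts[2], "|", fixed = TRUE)[[1]]
      m[i, ] <- as.integer(c(seed, pollen) == "V")
      lab[i] <- seg_label(seed, pollen)
    }
  }
  data.frame(label = lab, m, stringsAsFactors = FALSE)
}

## haplotype content of each parent at the trait loci; haplotype 1 carries
## the recessive allele wherever the parent is heterozygous
trait_haplotypes <- function(config) {
  n_sup <- nrow(config$suppressor_loci)
  sup <- list(seed = matrix(0L, n_sup, 2), pollen = matrix(0L, n_sup, 2))
  for (parent in c("seed", "pollen")) {
    sup[[parent]][1, ] <- c(1L, 0L)  # locus 1: heterozygous, rec on hap 1
    if (n_sup == 2L) {
      z <- config$locus2_zygosity[[parent]]
      sup[[parent]][2, ] <- switch(z,
        het = c(1L, 0L), hom_rec = c(1L, 1L), hom_dom = c(0L, 0L))
    }
  }
  dom <- list()
  for (parent in c("seed", "pollen")) {
    dom[[parent]] <- if (config$dominant_phase[[parent]] == "coupling") {
      c(1L, 0L)
    } else {
      c(0L, 1L)
    }
  }
  list(sup = sup, dom = dom)
}

trait_table <- function(co_allele, sup_allele, n_sup) {
  n <- nrow(co_allele)
  co_n <- co_allele[, "seed"] + co_allele[, "pollen"]
  co_geno <- c("coco", "Coco", "CoCo")[co_n + 1L]
  hom_rec <- matrix(FALSE, n, n_sup)
  for (j in seq_len(n_sup)) {
    hom_rec[, j] <- sup_allele[, "seed", j] + sup_allele[, "pollen", j] == 2L
  }
  n_hom <- rowSums(hom_rec)
  qualifies <- n_hom == n_sup
  class <- if (n_sup == 2L) {
    c("non-recessive", "single-recessive", "double-recessive")[n_hom + 1L]
  } else {
    c("non-recessive", "double-recessive")[n_hom + 1L]
  }
  out <- data.frame(id = seq_len(n), co_geno = co_geno,
                    n_hom_rec = n_hom, qualifies = qualifies,
                    genotype_class = class, stringsAsFactors = FALSE)
  for (j in seq_len(n_sup)) {
    out[[paste0("sup", j, "_rec_alleles")]] <-
      sup_allele[, "seed", j] + sup_allele[, "pollen", j]
  }
  out
}

#' @export
print.cross_pop <- function(x, ...) {
  cat(sprintf("cross_pop: %d offspring, %d SNV sites on %d chromosomes\n",
              nrow(x$trait), nrow(x$sites),
              nrow(x$config$genome$chromosomes)))
  print(table(dominant_locus = x$trait$co_geno))
  print(table(genotype_class = x$trait$genotype_class))
  if (!is.null(x$phenotype)) {
    cat(sprintf("phenotypes assigned for %d round(s)\n", ncol(x$phenotype)))
  } else {
    cat("phenotypes not yet assigned (see assign_phenotypes)\n")
  }
  invisible(x)
}
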