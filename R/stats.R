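#' Goodness-of-fit chi-square against an expected ratio
#'
#' Pearson chi-square without continuity correction (via
#' \code{\link[stats]{chisq.test}}), df = number of classes - 1.
#'
#' @param observed non-negative counts.
#' @param ratio expected ratio, e.g. \code{c(1, 2, 1)} or \code{c(3, 1)}.
#' @return An object of class \code{"gof_result"}: \code{chi2}, \code{df},
#'   \code{p}, \code{observed}, \code{expected}.
#' @examples
#' gof_chisq(c(76, 132, 67), c(1, 2, 1))  # chi2 = 1.029, p = 0.598
#' @export
gof_chisq <- function(observed, ratio) {
  if (length(observed) != length(ratio)) {
    stop("`observed` and `ratio` must have equal length", call. = FALSE)
  }
  if (any(observed < 0) || sum(observed) <= 0) {
    stop("`observed` must be non-negative with a positive total",
         call. = FALSE)
  }
  if (any(ratio <= 0)) {
    stop("`ratio` entries must be positive", call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::chisq.test(observed, p = ratio / sum(ratio), correct = FALSE))
  structure(
    list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, observed = observed,
         expected = unname(ht$expected)),
    class = "gof_result"
  )
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("chi-square goodness of fit: chi2 = %.4g, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  print(data.frame(observed = x$observed, expected = x$expected))
  invisible(x)
}

#' Parental-allele segregation-distortion test
#'
#' For each parent, tests whether the transmitted marker alleles within a
#' phenotype group deviate from the 1:1 expected of a heterozygous parent.
#' A parent homozygous at the marker transmits a single allele and the test
#' is skipped with an explicit \code{"uninformative parent"} result.
#' Individuals whose parental origin cannot be resolved (NA alleles) are
#' excluded and tallied.
#'
#' @param individuals data frame with columns \code{seed_allele} and
#'   \code{pollen_allele} (transmitted allele labels; NA = unresolved) and
#'   optionally \code{group}.
#' @param group if \code{individuals$group} exists, restrict to this value.
#' @return A list per parent: either a \code{\link{gof_chisq}} result with
#'   attached allele counts, or the string \code{"uninformative parent"};
#'   plus \code{n_excluded}.
#' @export
allele_distortion_test <- function(individuals, group = NULL) {
  if (!is.null(group)) {
    if (is.null(individuals$group)) {
      stop("`individuals` has no `group` column", call. = FALSE)
    }
    individuals <- individuals[individuals$group %in% group, , drop = FALSE]
  }
  out <- list()
  for (parent in c("seed", "pollen")) {
    alleles <- individuals[[paste0(parent, "_allele")]]
    if (is.null(alleles)) {
      stop("`individuals` needs a `", parent, "_allele` column",
           call. = FALSE)
    }
    n_excluded <- sum(is.na(alleles))
    alleles <- alleles[!is.na(alleles)]
    counts <- table(alleles)
    if (length(counts) < 2L) {
      out[[parent]] <- list(result = "uninformative parent",
                            counts = counts, n_excluded = n_excluded)
    } else {
      g <- gof_chisq(as.integer(counts), rep(1, length(counts)))
      out[[parent]] <- list(result = g, counts = counts,
                            n_excluded = n_excluded)
    }
  }
  out
}

#' Phenotype-frequency table by genotype class
#'
#' Tabulates, per genotype class and evaluation round, the frequency of the
#' suppressed standard phenotype (scores 3--4) among carriers of the
#' dominant allele. Individuals homozygous reference at the dominant locus
#' are excluded (their standard phenotype is not the suppressed trait), as
#' are individuals with missing genotypes (tallied). Recombinants between
#' the dominant locus and the first marker can be excluded by flag.
#'
#' @param individuals data frame with \code{co_geno}, one or more genotype
#'   columns, and per-round score columns.
#' @param genotype_cols names of the genotype columns defining the classes.
#' @param score_cols names of the per-round phenotype score columns.
#' @param exclude_recombinants drop rows where a logical
#'   \code{recombinant} column is TRUE.
#' @return An object of class \code{"genotype_class_table"}: a data frame
#'   with one row per genotype class and, per round, the class total,
#'   suppressed count and frequency; attribute \code{n_excluded}.
#' @export
phenotype_frequency_table <- function(individuals, genotype_cols,
                                      score_cols,
                                      exclude_recombinants = FALSE) {
  df <- individuals
  if (exclude_recombinants) {
    if (is.null(df$recombinant)) {
      stop("`individuals` has no `recombinant` column", call. = FALSE)
    }
    df <- df[!df$recombinant, , drop = FALSE]
  }
  carrier <- df$co_geno %in% c("CoCo", "Coco")
  df <- df[carrier, , drop = FALSE]
  known <- stats::complete.cases(df[, genotype_cols, drop = FALSE])
  n_excluded <- sum(!known)
  df <- df[known, , drop = FALSE]
  class_key <- interaction(df[, genotype_cols, drop = FALSE],
                           sep = " ", drop = TRUE)
  out <- data.frame(genotype_class = levels(class_key),
                    stringsAsFactors = FALSE)
  for (t in seq_along(score_cols)) {
    sc <- df[[score_cols[t]]]
    supp <- sc %in% c(3L, 4L)
    totals <- as.integer(table(class_key))
    hits <- as.integer(tapply(supp, class_key, sum))
    out[[paste0("n_round", t)]] <- totals
    out[[paste0("std2_round", t)]] <- hits
    out[[paste0("freq_round", t)]] <- hits / totals
  }
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("genotype_class_table", "data.frame")
  out
}

#' Regression of phenotype score on genotype classes
#'
#' Least-squares fit of the 1--4 phenotype score on genotype-class
#' indicators at one or two marker loci (factors, additive when two loci
#' are given). Returns the coefficient of determination and the overall
#' F-test p-value.
#'
#' @param score numeric phenotype scores.
#' @param g1 genotype classes at the first locus.
#' @param g2 optional genotype classes at a second locus.
#' @return An object of class \code{"score_regression"}: \code{r2},
#'   \code{model_p}, \code{n}, and the underlying \code{lm} fit.
#' @export
phenotype_score_regression <- function(score, g1, g2 = NULL) {
  keep <- !is.na(score) & !is.na(g1) & (if (is.null(g2)) TRUE else !is.na(g2))
  score <- score[keep]
  g1 <- factor(g1[keep])
  if (length(score) < 10L) {
    stop("need at least 10 scored individuals", call. = FALSE)
  }
  if (nlevels(g1) < 2L) {
    stop("only one genotype class present at locus 1; fit undefined",
         call. = FALSE)
  }
  if (is.null(g2)) {
    fit <- stats::lm(score ~ g1)
  } else {
    g2 <- factor(g2[keep])
    if (nlevels(g2) < 2L) {
      stop("only one genotype class present at locus 2; fit undefined",
           call. = FALSE)
    }
    fit <- stats::lm(score ~ g1 + g2)
  }
  sm <- summary(fit)
  f <- sm$fstatistic
  structure(
    list(r2 = sm$r.squared,
         model_p = stats::pf(f[["value"]], f[["numdf"]], f[["dendf"]],
                             lower.tail = FALSE),
         n = length(score), fit = fit),
    class = "score_regression"
  )
}

#' @export
print.score_regression <- function(x, ...) {
  cat(sprintf("phenotype-score regression: r2 = %.4f, model p = %.3g, n = %d\n",
              x$r2, x$model_p, x$n))
  invisible(x)
}
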