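#' QC thresholds for per-pool variant tables
#'
#' Defaults follow the published pipeline: variant calls require coverage
#' >= 10 and >= 2 variant-carrying reads; retained records must be
#' non-reference single-nucleotide variants with coverage between 20x and
#' 200x.
#'
#' @param call_min_coverage,call_min_alt_count call-time thresholds.
#' @param keep_min_coverage,keep_max_coverage coverage window for retained
#'   records.
#' @param snv_only drop non-SNVs (multi-base ref or alt).
#' @param drop_reference_calls drop records whose alternate equals the
#'   reference (or is missing).
#' @return An object of class \code{"qc_thresholds"}.
#' @export
qc_thresholds <- function(call_min_coverage = 10L, call_min_alt_count = 2L,
                          keep_min_coverage = 20L, keep_max_coverage = 200L,
                          snv_only = TRUE, drop_reference_calls = TRUE) {
  if (keep_min_coverage < call_min_coverage) {
    stop("`keep_min_coverage` must be >= `call_min_coverage`", call. = FALSE)
  }
  if (keep_max_coverage <= keep_min_coverage) {
    stop("`keep_max_coverage` must be > `keep_min_coverage`", call. = FALSE)
  }
  structure(list(call_min_coverage = call_min_coverage,
                 call_min_alt_count = call_min_alt_count,
                 keep_min_coverage = keep_min_coverage,
                 keep_max_coverage = keep_max_coverage,
                 snv_only = snv_only,
                 drop_reference_calls = drop_reference_calls),
            class = "qc_thresholds")
}

#' QC-filter a per-pool variant table
#'
#' Applies the call-time thresholds and the retention filters in a fixed,
#' auditable order: call coverage, call variant-read count, reference-allele
#' calls, non-SNVs, low coverage, high coverage. Each record is charged to
#' the first rule that removes it.
#'
#' @param records per-pool variant data frame (\code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{depth}, \code{alt_count}).
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @return A list with \code{records} (survivors, with \code{af} refreshed)
#'   and \code{tally} (named removal counts in application order, plus
#'   \code{kept}).
#' @export
qc_filter <- function(records, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  need <- c("chrom", "pos", "ref", "alt", "depth", "alt_count")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("variant records missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(records$alt_count > records$depth |
                 records$alt_count < 0 | records$depth < 0)
  if (length(bad)) {
    stop("malformed record(s): alt_count > depth at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ...", call. = FALSE)
  }

  removed_by <- rep(NA_character_, nrow(records))
  mark <- function(cond, rule) {
    hit <- is.na(removed_by) & cond
    removed_by[hit] <<- rule
  }
  mark(records$depth < thresholds$call_min_coverage, "call_coverage")
  mark(records$alt_count < thresholds$call_min_alt_count, "call_alt_count")
  if (thresholds$drop_reference_calls) {
    mark(is.na(records$alt) | records$alt == "" |
           records$alt == records$ref, "reference_allele")
  }
  if (thresholds$snv_only) {
    mark(nchar(records$ref) != 1L | nchar(records$alt) != 1L |
           !records$ref %in% c("A", "C", "G", "T") |
           !records$alt %in% c("A", "C", "G", "T"), "non_snv")
  }
  mark(records$depth < thresholds$keep_min_coverage, "low_coverage")
  mark(records$depth > thresholds$keep_max_coverage, "high_coverage")

  rules <- c("call_coverage", "call_alt_count", "reference_allele",
             "non_snv", "low_coverage", "high_coverage")
  tally <- vapply(rules, function(r) sum(removed_by == r, na.rm = TRUE),
                  integer(1))
  keep <- is.na(removed_by)
  out <- records[keep, , drop = FALSE]
  out$af <- ifelse(out$depth > 0, 100 * out$alt_count / out$depth, NA_real_)
  rownames(out) <- NULL
  list(records = out, tally = c(tally, kept = sum(keep)))
}

#' Partition two pools' variants into pool-specific and pool-common sets
#'
#' Site identity is the full key (chrom, pos, ref, alt), so a position with
#' different alternate bases in the two pools yields two pool-specific
#' records rather than a spurious common record.
#'
#' @param recessive,dominant QC-filtered per-pool variant data frames.
#' @return A list with \code{specific_recessive}, \code{specific_dominant}
#'   (per-pool records) and \code{common} (one row per shared site with
#'   suffixed columns \code{depth_R}, \code{alt_count_R}, \code{af_R},
#'   \code{depth_D}, \code{alt_count_D}, \code{af_D}).
#' @export
partition_pools <- function(recessive, dominant) {
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  kr <- key(recessive)
  kd <- key(dominant)
  if (anyDuplicated(kr)) {
    stop("duplicate site key in recessive pool: ",
         kr[duplicated(kr)][1L], call. = FALSE)
  }
  if (anyDuplicated(kd)) {
    stop("duplicate site key in dominant pool: ",
         kd[duplicated(kd)][1L], call. = FALSE)
  }
  shared <- intersect(kr, kd)
  ir <- match(shared, kr)
  id <- match(shared, kd)
  common <- data.frame(
    chrom = recessive$chrom[ir], pos = recessive$pos[ir],
    ref = recessive$ref[ir], alt = recessive$alt[ir],
    depth_R = recessive$depth[ir], alt_count_R = recessive$alt_count[ir],
    af_R = recessive$af[ir],
    depth_D = dominant$depth[id], alt_count_D = dominant$alt_count[id],
    af_D = dominant$af[id],
    stringsAsFactors = FALSE
  )
  list(
    specific_recessive = recessive[!(kr %in% shared), , drop = FALSE],
    specific_dominant = dominant[!(kd %in% shared), , drop = FALSE],
    common = common
  )
}

zygosity_class <- function(af) {
  ifelse(af >= 85, "homozygous",
         ifelse(af >= 15, "heterozygous", "low-frequency"))
}

#' Zygosity grouping of pool-common SNVs
#'
#' Classifies each pool-common SNV as homozygous (AF >= 85\%),
#' heterozygous (15\% <= AF < 85\%) or low-frequency (AF < 15\%) in each
#' pool, and assigns the four zygosity groups (R = recessive pool,
#' D = dominant pool): \code{Ho-R/He-D}, \code{He-R/He-D}, \code{He-R/Ho-D},
#' \code{Ho-R/Ho-D}. A record that is low-frequency in either pool is left
#' \code{ungrouped}.
#'
#' @param common pool-common data frame from \code{\link{partition_pools}}.
#' @return A list with \code{records} (input plus \code{zygosity_R},
#'   \code{zygosity_D}, \code{group}) and \code{tally} (counts over the four
#'   groups plus \code{ungrouped}; the five counts partition the input).
#' @export
zygosity_group <- function(common) {
  zr <- zygosity_class(common$af_R)
  zd <- zygosity_class(common$af_D)
  short <- c(homozygous = "Ho", heterozygous = "He")
  group <- ifelse(
    zr == "low-frequency" | zd == "low-frequency", "ungrouped",
    paste0(short[zr], "-R/", short[zd], "-D"))
  out <- common
  out$zygosity_R <- zr
  out$zygosity_D <- zd
  out$group <- group
  levels <- c("Ho-R/He-D", "He-R/He-D", "He-R/Ho-D", "Ho-R/Ho-D",
              "ungrouped")
  tally <- vapply(levels, function(g) sum(group == g), integer(1))
  list(records = out, tally = tally)
}
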