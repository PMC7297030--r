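#' Select informative SNVs by type-specific AF/AFDD filter windows
#'
#' Applies the published filters to zygosity-grouped pool-common SNVs.
#' Type A and B/C candidates are drawn only from group \code{Ho-R/He-D};
#' D/E candidates only from \code{He-R/He-D}. AFDD is directional: only
#' \code{af_R - af_D > 0} can pass. The A vs B/C boundary at 43.3 pp is
#' half-open on the B/C side, so the three type sets partition the selected
#' SNVs.
#'
#' @param grouped the \code{records} element of \code{\link{zygosity_group}}.
#' @param windows filter windows from
#'   \code{\link{informative_filter_windows}}.
#' @return A data frame of informative SNVs: site key columns, \code{af_R},
#'   \code{af_D}, \code{afdd}, \code{type_set} (\code{"A"}, \code{"B/C"},
#'   \code{"D/E"}).
#' @export
select_informative <- function(grouped, windows = informative_filter_windows()) {
  afdd <- grouped$af_R - grouped$af_D
  assign_window <- function(w, group_needed) {
    in_af <- grouped$af_R >= w$af_recessive_min &
      grouped$af_R <= w$af_recessive_max
    in_low <- afdd >= w$afdd_min
    in_high <- if (w$afdd_max_inclusive) afdd <= w$afdd_max else
      afdd < w$afdd_max
    grouped$group == group_needed & in_af & in_low & in_high
  }
  type_set <- rep(NA_character_, nrow(grouped))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    group_needed <- if (w$type_set %in% c("A", "B/C")) "Ho-R/He-D" else
      "He-R/He-D"
    hit <- assign_window(w, group_needed) & is.na(type_set)
    type_set[hit] <- w$type_set
  }
  out <- grouped[!is.na(type_set),
                 c("chrom", "pos", "ref", "alt", "af_R", "af_D")]
  out$afdd <- afdd[!is.na(type_set)]
  out$type_set <- type_set[!is.na(type_set)]
  rownames(out) <- NULL
  out
}

#' Count SNVs in sliding genomic windows
#'
#' Tiles each chromosome from position 1 with windows of \code{window_size}
#' advancing by \code{step} (default: non-overlapping tiling). Window
#' coordinates are returned 0-based half-open (BED convention); input
#' positions are 1-based (VCF convention). A trailing window truncated by
#' the chromosome end is retained and flagged \code{partial}.
#'
#' @param snvs data frame with \code{chrom} and \code{pos}.
#' @param chrom_lengths data frame with \code{name} and \code{length}.
#' @param window_size window width in bp.
#' @param step distance between window starts in bp.
#' @return A data frame: \code{chrom}, \code{start}, \code{end},
#'   \code{count}, \code{partial}.
#' @export
window_counts <- function(snvs, chrom_lengths, window_size = 1e6,
                          step = window_size) {
  stopifnot(window_size > 0, step > 0)
  bad_chrom <- setdiff(unique(snvs$chrom), chrom_lengths$name)
  if (length(bad_chrom)) {
    stop("SNVs on contig(s) absent from the chromosome table: ",
         paste(bad_chrom, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (ci in seq_len(nrow(chrom_lengths))) {
    chrom <- chrom_lengths$name[ci]
    len <- chrom_lengths$length[ci]
    pos <- snvs$pos[snvs$chrom == chrom]
    if (any(pos < 1 | pos > len)) {
      stop("SNV position outside chromosome ", chrom, call. = FALSE)
    }
    starts <- seq(0, max(0, len - 1), by = step)
    ends <- pmin(starts + window_size, len)
    pos <- sort(pos)
    ## SNV at 1-based pos lies in [start, end) 0-based <=> start < pos <= end
    count <- findInterval(ends, pos) - findInterval(starts, pos)
    out[[ci]] <- data.frame(
      chrom = chrom, start = starts, end = ends, count = as.integer(count),
      partial = (ends - starts) < window_size, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score windows by z-test against the genome-average density
#'
#' Standardises each window's SNV count against the mean and dispersion of
#' counts over full (non-partial) windows, by default genome-wide with the
#' empirical standard deviation. The two-tailed standard-normal tail
#' probability gives \code{lodz = -log10(p)}. Partial terminal windows are
#' scored but excluded from the mean/SD estimate (length bias). If the
#' dispersion is zero every z is 0.
#'
#' @param counts window-count data frame from \code{\link{window_counts}}.
#' @param per_chromosome estimate mean/SD per chromosome instead of
#'   genome-wide.
#' @param dispersion \code{"empirical"} (SD across windows) or
#'   \code{"poisson"} (SD = sqrt(mean)).
#' @return The input with columns \code{z}, \code{p}, \code{lodz} appended.
#' @export
lodz_scores <- function(counts, per_chromosome = FALSE,
                        dispersion = c("empirical", "poisson")) {
  dispersion <- match.arg(dispersion)
  if (nrow(counts) < 2L) {
    stop("need at least two windows to estimate dispersion", call. = FALSE)
  }
  score_block <- function(block) {
    full <- !block$partial
    base <- if (sum(full) >= 2L) block$count[full] else block$count
    m <- mean(base)
    s <- if (dispersion == "empirical") stats::sd(base) else sqrt(m)
    z <- if (is.na(s) || s == 0) rep(0, nrow(block)) else
      (block$count - m) / s
    block$z <- z
    ## two-tailed p computed in log space so extreme peaks keep finite LODz
    logp <- log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
    logp <- pmin(logp, 0)
    block$p <- exp(logp)
    block$lodz <- -logp / log(10)
    block
  }
  if (per_chromosome) {
    parts <- split(counts, counts$chrom)
    res <- do.call(rbind, lapply(parts, score_block))
    res <- res[order(match(res$chrom, unique(counts$chrom)), res$start), ]
  } else {
    res <- score_block(counts)
  }
  rownames(res) <- NULL
  res
}

#' Call peak regions from scored windows
#'
#' Maximal runs of windows with \code{lodz > cutoff} and positive z become
#' peak regions; up to \code{merge_gap} consecutive sub-threshold windows
#' may be bridged. The apex is the member window with the highest LODz
#' (leftmost on ties).
#'
#' @param scores scored windows from \code{\link{lodz_scores}}, ordered by
#'   chromosome and start.
#' @param cutoff LODz cutoff (default 2.5).
#' @param merge_gap number of sub-threshold windows allowed inside a region.
#' @return A data frame of regions: \code{chrom}, \code{start}, \code{end},
#'   \code{apex_start}, \code{apex_end}, \code{apex_lodz}, \code{n_windows}.
#' @export
call_peaks <- function(scores, cutoff = 2.5, merge_gap = 0L) {
  sig <- scores$lodz > cutoff & scores$z > 0
  out <- list()
  for (chrom in unique(scores$chrom)) {
    idx <- which(scores$chrom == chrom)
    hit <- which(sig[idx])
    if (!length(hit)) next
    gaps <- c(Inf, diff(hit))
    run_id <- cumsum(gaps > merge_gap + 1L)
    for (r in split(hit, run_id)) {
      sub <- scores[idx[r], , drop = FALSE]
      apex <- sub[which.max(sub$lodz), , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start = min(sub$start), end = max(sub$end),
        apex_start = apex$start, apex_end = apex$end,
        apex_lodz = apex$lodz, n_windows = nrow(sub),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), apex_start = numeric(),
                      apex_end = numeric(), apex_lodz = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' AFDDD genome scan for a recessive trait
#'
#' The package's central fitting routine. Takes the two per-pool variant
#' tables (recessive-phenotype pool and dominant-phenotype pool), applies
#' QC, partitions shared sites, groups them by pool zygosity, selects
#' informative SNVs with the type-specific AF/AFDD filters, counts them in
#' genomic windows, scores window density against the genome average
#' (z-test, LODz), and calls peak regions. Peaks mark genomic regions
#' putatively linked to the recessive trait.
#'
#' @param recessive,dominant per-pool variant data frames (or file paths
#'   accepted by \code{\link{read_pool_table}}).
#' @param chrom_lengths data frame (\code{name}, \code{length}).
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @param windows type filter windows.
#' @param window_size,step window tiling in bp.
#' @param lodz_cutoff peak-calling cutoff on LODz.
#' @param merge_gap sub-threshold windows allowed inside a peak.
#' @param per_chromosome,dispersion passed to \code{\link{lodz_scores}}.
#' @return An object of class \code{"afddd_scan"}: a list with the QC
#'   tallies, partition sizes, zygosity \code{group_tally}, the informative
#'   SNVs, per-window \code{scores} (combined and per type set), called
#'   \code{peaks} with contributing type sets, and the call parameters.
#' @seealso \code{\link{summary.afddd_scan}}, \code{\link{plot.afddd_scan}}
#' @export
afddd_scan <- function(recessive, dominant, chrom_lengths,
                       thresholds = qc_thresholds(),
                       windows = informative_filter_windows(),
                       window_size = 1e6, step = window_size,
                       lodz_cutoff = 2.5, merge_gap = 0L,
                       per_chromosome = FALSE,
                       dispersion = c("empirical", "poisson")) {
  dispersion <- match.arg(dispersion)
  if (is.character(recessive)) recessive <- read_pool_table(recessive)
  if (is.character(dominant)) dominant <- read_pool_table(dominant)
  for (tbl in list(recessive, dominant)) {
    extra <- setdiff(unique(tbl$chrom), chrom_lengths$name)
    if (length(extra)) {
      stop("pool table contains contig(s) absent from the chromosome ",
           "table: ", paste(extra, collapse = ", "), call. = FALSE)
    }
  }

  qc_r <- qc_filter(recessive, thresholds)
  qc_d <- qc_filter(dominant, thresholds)
  parts <- partition_pools(qc_r$records, qc_d$records)
  grouped <- zygosity_group(parts$common)
  informative <- select_informative(grouped$records, windows)

  scores <- lodz_scores(
    window_counts(informative, chrom_lengths, window_size, step),
    per_chromosome = per_chromosome, dispersion = dispersion)
  per_type_counts <- lapply(split(informative, informative$type_set),
                            function(s) {
                              window_counts(s, chrom_lengths, window_size,
                                            step)
                            })
  peaks <- call_peaks(scores, cutoff = lodz_cutoff, merge_gap = merge_gap)
  peaks$type_sets <- vapply(seq_len(nrow(peaks)), function(i) {
    present <- vapply(names(per_type_counts), function(ts) {
      w <- per_type_counts[[ts]]
      any(w$chrom == peaks$chrom[i] & w$start < peaks$end[i] &
            w$end > peaks$start[i] & w$count > 0)
    }, logical(1))
    paste(names(per_type_counts)[present], collapse = ",")
  }, character(1))

  structure(
    list(qc_tally = list(recessive = qc_r$tally, dominant = qc_d$tally),
         partition = c(specific_recessive = nrow(parts$specific_recessive),
                       specific_dominant = nrow(parts$specific_dominant),
                       common = nrow(parts$common)),
         group_tally = grouped$tally,
         grouped = grouped$records,
         informative = informative,
         informative_tally = table(factor(informative$type_set,
                                          c("A", "B/C", "D/E"))),
         scores = scores, per_type_counts = per_type_counts,
         peaks = peaks,
         params = list(window_size = window_size, step = step,
                       lodz_cutoff = lodz_cutoff, merge_gap = merge_gap,
                       per_chromosome = per_chromosome,
                       dispersion = dispersion)),
    class = "afddd_scan"
  )
}

#' @export
print.afddd_scan <- function(x, ...) {
  cat("AFDDD scan\n")
  cat(sprintf("  common SNVs: %d (specific: %d recessive, %d dominant)\n",
              x$partition[["common"]],
              x$partition[["specific_recessive"]],
              x$partition[["specific_dominant"]]))
  cat(sprintf("  informative SNVs: %d A, %d B/C, %d D/E\n",
              x$informative_tally[["A"]], x$informative_tally[["B/C"]],
              x$informative_tally[["D/E"]]))
  cat(sprintf("  %d windows scored; %d peak region(s) at LODz > %.2f\n",
              nrow(x$scores), nrow(x$peaks), x$params$lodz_cutoff))
  if (nrow(x$peaks)) {
    apex_mb <- (x$peaks$apex_start + x$peaks$apex_end) / 2e6
    for (i in seq_len(nrow(x$peaks))) {
      cat(sprintf("    %s:%.0f-%.0f  apex %.1f Mb  LODz %.2f  types %s\n",
                  x$peaks$chrom[i], x$peaks$start[i], x$peaks$end[i],
                  apex_mb[i], x$peaks$apex_lodz[i], x$peaks$type_sets[i]))
    }
  }
  invisible(x)
}

#' Summary of an AFDDD scan
#'
#' @param object an \code{"afddd_scan"}.
#' @param ... unused.
#' @return A list with the tallies and the peak table, printed compactly.
#' @export
summary.afddd_scan <- function(object, ...) {
  out <- list(qc_tally = object$qc_tally, partition = object$partition,
              group_tally = object$group_tally,
              informative_tally = object$informative_tally,
              peaks = object$peaks)
  class(out) <- "summary.afddd_scan"
  out
}

#' @export
print.summary.afddd_scan <- function(x, ...) {
  cat("QC removal tallies (recessive pool):\n")
  print(x$qc_tally$recessive)
  cat("QC removal tallies (dominant pool):\n")
  print(x$qc_tally$dominant)
  cat("Pool partition:\n")
  print(x$partition)
  cat("Zygosity groups (R = recessive pool, D = dominant pool):\n")
  print(x$group_tally)
  cat("Informative SNVs per type set:\n")
  print(x$informative_tally)
  cat("Peak regions:\n")
  print(x$peaks)
  invisible(x)
}

#' Manhattan-style LODz track of an AFDDD scan
#'
#' Plots per-window LODz along a concatenated genome coordinate with the
#' peak cutoff as a dashed line.
#'
#' @param x an \code{"afddd_scan"}.
#' @param ... passed to \code{plot.default}.
#' @return \code{x}, invisibly.
#' @export
plot.afddd_scan <- function(x, ...) {
  sc <- x$scores
  chroms <- unique(sc$chrom)
  offsets <- stats::setNames(
    cumsum(c(0, vapply(chroms, function(ch) max(sc$end[sc$chrom == ch]),
                       numeric(1))))[seq_along(chroms)], chroms)
  mid <- (sc$start + sc$end) / 2 + offsets[sc$chrom]
  cols <- (match(sc$chrom, chroms) %% 2) + 1
  graphics::plot(mid / 1e6, sc$lodz, pch = 16, cex = 0.6,
                 col = c("grey40", "steelblue")[cols],
                 xlab = "genome position (Mb)", ylab = "LODz", ...)
  graphics::abline(h = x$params$lodz_cutoff, lty = 2, col = "red")
  invisible(x)
}
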