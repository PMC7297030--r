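#' Write a per-pool variant table as minimal VCF v4.2
#'
#' One sample column carrying \code{DP} (depth) and \code{AD}
#' (ref,alt read counts), the conventional encoding for pooled
#' allele-depth data.
#'
#' @param records data frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{depth}, \code{alt_count}.
#' @param path output path.
#' @param sample sample (pool) name for the header.
#' @param chrom_lengths optional data frame (\code{name}, \code{length})
#'   written as contig header lines.
#' @return \code{path}, invisibly.
#' @export
write_pool_vcf <- function(records, path, sample = "pool",
                           chrom_lengths = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=afddd",
    if (!is.null(chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", chrom_lengths$name,
              as.integer(chrom_lengths$length))
    },
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tDP:AD\t%d:%d,%d",
                  records$chrom, as.integer(records$pos), records$ref,
                  records$alt, as.integer(records$depth),
                  as.integer(records$depth - records$alt_count),
                  as.integer(records$alt_count))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a per-pool variant table as TSV
#'
#' The TSV dialect equivalent to the minimal VCF: columns \code{chrom},
#' \code{pos}, \code{ref}, \code{alt}, \code{depth}, \code{alt_count},
#' \code{af}.
#'
#' @param records per-pool variant data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pool_tsv <- function(records, path) {
  cols <- c("chrom", "pos", "ref", "alt", "depth", "alt_count", "af")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-pool variant table (VCF or TSV)
#'
#' VCF input (\code{.vcf}/\code{.vcf.gz}, parsed with \pkg{vcfR}) must carry
#' per-sample \code{DP} and \code{AD}; the first sample column is used.
#' Otherwise the file is read as the package's TSV dialect.
#'
#' @param path input file.
#' @return A per-pool variant data frame (\code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{depth}, \code{alt_count}, \code{af}).
#' @export
read_pool_table <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    dp <- suppressWarnings(
      as.integer(vcfR::extract.gt(v, "DP")[, 1L]))
    ad <- vcfR::extract.gt(v, "AD")[, 1L]
    alt_count <- suppressWarnings(
      as.integer(vapply(strsplit(ad, ",", fixed = TRUE), `[`, character(1), 2L)))
    out <- data.frame(
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT,
      depth = dp, alt_count = alt_count,
      stringsAsFactors = FALSE
    )
  } else {
    out <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "depth", "alt_count")
    miss <- setdiff(need, names(out))
    if (length(miss)) {
      stop("variant table ", path, " is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  out$af <- ifelse(out$depth > 0, 100 * out$alt_count / out$depth, NA_real_)
  out
}

#' Write causal trait loci as BED
#'
#' @param truth data frame with \code{chrom}, \code{pos}, \code{what}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", truth$chrom,
                   as.integer(truth$pos - 1L), as.integer(truth$pos),
                   truth$what)
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromosome-length table
#'
#' Two-column TSV: chromosome name and length in bp (header optional;
#' detected by a non-numeric second field on line 1).
#'
#' @param path input file.
#' @return Data frame with columns \code{name}, \code{length}.
#' @export
read_chrom_lengths <- function(path) {
  first <- utils::read.table(path, sep = "\t", nrows = 1L,
                             stringsAsFactors = FALSE)
  header <- is.na(suppressWarnings(as.numeric(first[[2L]])))
  out <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE)[, 1:2]
  names(out) <- c("name", "length")
  out$length <- as.numeric(out$length)
  out
}

#' Write window scores as a TSV track
#'
#' @param scores a window-score data frame (see \code{\link{lodz_scores}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_window_track <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write called peak regions as BED6
#'
#' Name = contributing type sets; score = \code{round(10 * apex LODz)},
#' capped at 1000 per BED convention.
#'
#' @param peaks a peak data frame (see \code{\link{call_peaks}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (nrow(peaks) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   peaks$chrom, as.integer(peaks$start),
                   as.integer(peaks$end),
                   gsub("[ ,]+", "_", peaks$type_sets),
                   pmin(1000L, as.integer(round(10 * peaks$apex_lodz))))
  writeLines(lines, path)
  invisible(path)
}
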