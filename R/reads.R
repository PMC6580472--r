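#' Construct a read set
#'
#' Holds aligned read intervals for one or more samples along with each
#' sample's total mapped read count. The total may exceed the number of
#' stored intervals (reads mapping outside regions of interest need not
#' be stored) but never falls below it.
#'
#' @param reads Data frame with columns `chrom`, `start`, `end`, `sample`
#'   (0-based half-open intervals).
#' @param totals Named numeric vector: total mapped reads per sample.
#'   Defaults to the stored interval counts.
#' @return Object of class `read_set`.
#' @export
read_set <- function(reads, totals = NULL) {
  reads <- as.data.frame(reads, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "sample") %in% names(reads)))
  stored <- table(reads$sample)
  if (is.null(totals)) {
    totals <- stats::setNames(as.numeric(stored), names(stored))
  }
  for (s in names(stored)) {
    if (is.na(totals[s]) || totals[s] < stored[[s]]) {
      stop("total mapped count for sample '", s,
           "' is below the number of stored reads")
    }
  }
  structure(list(reads = reads, totals = totals), class = "read_set")
}

#' Read and write read intervals as BED6
#'
#' One BED6 file per sample; the name and score columns are ignored on
#' input and written as `.`/0. The total mapped count defaults to the
#' number of intervals in the file.
#'
#' @param path BED6 file.
#' @param sample Sample label attached to every interval.
#' @param total Total mapped reads for the sample (optional).
#' @return A [read_set()] with a single sample.
#' @export
read_reads <- function(path, sample, total = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  reads <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      sample = sample,
                      stringsAsFactors = FALSE)
  totals <- if (is.null(total)) NULL else stats::setNames(total, sample)
  read_set(reads, totals)
}

#' @rdname read_reads
#' @param rs A [read_set()].
#' @export
write_reads <- function(rs, sample, path) {
  d <- rs$reads[rs$reads$sample == sample, , drop = FALSE]
  out <- data.frame(d$chrom, d$start, d$end, ".", 0L, ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge read sets from different samples
#' @param ... `read_set` objects with disjoint sample labels.
#' @return A combined [read_set()].
#' @export
combine_read_sets <- function(...) {
  sets <- list(...)
  reads <- do.call(rbind, lapply(sets, function(s) s$reads))
  totals <- do.call(c, lapply(sets, function(s) s$totals))
  if (anyDuplicated(names(totals))) stop("duplicate sample labels")
  read_set(reads, totals)
}

#' Write and re-read tab-separated result tables
#'
#' All emitted tables use a header line, tab separators and `.` for
#' missing values.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = ".")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
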