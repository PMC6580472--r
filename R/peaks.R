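#' Construct a peak table
#'
#' Peaks follow ENCODE narrowPeak semantics: 0-based half-open interval,
#' an enrichment (signalValue) column and a summit offset from the peak
#' start. A summit offset of -1 (MACS2's "no summit" marker) is replaced
#' by the interval midpoint on construction.
#'
#' @param chrom,start,end Interval (0-based half-open).
#' @param name Unique peak names; autogenerated when missing.
#' @param enrichment Non-negative ChIP enrichment values (signalValue).
#' @param summit Summit offset from `start` in bp, or -1.
#' @param pvalue,qvalue -log10 scores carried through from the caller;
#'   default -1 (not available).
#' @return Data frame of class `peak_table` with columns `chrom`, `start`,
#'   `end`, `name`, `enrichment`, `pvalue`, `qvalue`, `summit`.
#' @export
peak_table <- function(chrom, start, end, name = NULL, enrichment,
                       summit = -1L, pvalue = -1, qvalue = -1) {
  n <- length(start)
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  d <- data.frame(chrom = rep_len(as.character(chrom), n),
                  start = as.integer(start),
                  end = as.integer(end), name = as.character(name),
                  enrichment = as.numeric(enrichment),
                  pvalue = rep_len(as.numeric(pvalue), n),
                  qvalue = rep_len(as.numeric(qvalue), n),
                  summit = rep_len(as.integer(summit), n),
                  stringsAsFactors = FALSE)
  if (any(d$end <= d$start)) stop("peaks must have positive width")
  if (any(d$enrichment < 0)) stop("enrichment values must be non-negative")
  no_summit <- d$summit < 0
  d$summit[no_summit] <- (d$end[no_summit] - d$start[no_summit]) %/% 2L
  if (any(d$summit >= d$end - d$start)) {
    stop("summit offset must lie inside the peak interval")
  }
  class(d) <- c("peak_table", "data.frame")
  d
}

#' Absolute summit positions of a peak table
#' @param peaks A [peak_table()].
#' @return Integer vector `start + summit`, named by peak name.
#' @export
peak_summits <- function(peaks) {
  stats::setNames(peaks$start + peaks$summit, peaks$name)
}

#' Read and write ENCODE narrowPeak files
#'
#' The 10 columns are chrom, start, end, name, score, strand, signalValue,
#' pValue, qValue, summit offset. Column 7 populates the enrichment value
#' and column 10 the summit offset; a -1 summit is replaced by the
#' interval midpoint.
#'
#' @param path File path.
#' @return [read_narrowpeak()]: a [peak_table()]. An empty file yields an
#'   empty table.
#' @export
read_narrowpeak <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(peak_table(character(), integer(), integer(),
                      name = character(), enrichment = numeric()))
  }
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != 10)) {
    stop("narrowPeak line ", which(nf != 10)[1], " has ", nf[nf != 10][1],
         " columns, expected 10: ", path)
  }
  d <- utils::read.table(text = lines, sep = "\t",
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand", "signalValue",
                                       "pValue", "qValue", "peak"),
                         colClasses = c("character", "integer", "integer",
                                        "character", "numeric", "character",
                                        "numeric", "numeric", "numeric",
                                        "integer"))
  peak_table(d$chrom, d$start, d$end, name = d$name,
             enrichment = d$signalValue, summit = d$peak,
             pvalue = d$pValue, qvalue = d$qValue)
}

#' @rdname read_narrowpeak
#' @param peaks A [peak_table()].
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    0L, ".", peaks$enrichment, peaks$pvalue, peaks$qvalue,
                    peaks$summit)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
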