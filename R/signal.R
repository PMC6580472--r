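#' Construct a signal track
#'
#' A `signal_track` stores one value per fixed-size step along each
#' chromosome (a dense in-memory equivalent of a wig/bedGraph file).
#' Regions never written to are 0. The final step on a chromosome may be
#' shorter than `step`; its value is the average over the covered bases.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param step Step size in bp (>= 1).
#' @param values Optional named list of per-chromosome numeric vectors of
#'   length `ceiling(length / step)`; defaults to all zero.
#' @return Object of class `signal_track`: list with `step`, `chrom_sizes`
#'   and `values`.
#' @export
signal_track <- function(chrom_sizes, step, values = NULL) {
  stopifnot(step >= 1)
  step <- as.integer(step)
  nbin <- ceiling(chrom_sizes / step)
  if (is.null(values)) {
    values <- lapply(nbin, function(n) numeric(n))
  } else {
    if (!setequal(names(values), names(chrom_sizes))) {
      stop("values must cover exactly the declared chromosomes")
    }
    values <- values[names(chrom_sizes)]
    bad <- lengths(values) != nbin
    if (any(bad)) {
      stop("value vector length does not cover chromosome: ",
           paste(names(chrom_sizes)[bad], collapse = ", "))
    }
  }
  structure(list(step = step, chrom_sizes = chrom_sizes, values = values),
            class = "signal_track")
}

#' Per-base signal lookup
#'
#' Returns the track value at each (chrom, pos) pair; positions outside
#' the chromosome return NA.
#'
#' @param track A [signal_track()].
#' @param chrom Chromosome name (scalar).
#' @param pos Integer vector of 0-based positions.
#' @return Numeric vector of values.
#' @export
track_values_at <- function(track, chrom, pos) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("chromosome not in track: ", chrom)
  len <- track$chrom_sizes[[chrom]]
  out <- rep(NA_real_, length(pos))
  ok <- pos >= 0 & pos < len
  out[ok] <- v[pos[ok] %/% track$step + 1L]
  out
}

#' Read a bedGraph file into a signal track
#'
#' Values are resampled onto the declared step by length-weighted
#' averaging; regions absent from the file contribute 0. Overlapping
#' bedGraph intervals are rejected.
#'
#' @param path bedGraph file.
#' @param step Step size in bp for the resulting track.
#' @param chrom_sizes Named numeric vector or chrom.sizes path.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, step, chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  track <- signal_track(chrom_sizes, step)
  if (length(gr) == 0) return(track)
  if (any(!as.character(GenomicRanges::seqnames(gr)) %in% names(chrom_sizes))) {
    stop("bedGraph interval on undeclared chromosome in ", path)
  }
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  if (length(hits) > 0) stop("overlapping bedGraph intervals in ", path)
  step <- as.integer(step)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  val <- S4Vectors::mcols(gr)$score
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    len <- chrom_sizes[[cn]]
    acc <- numeric(length(track$values[[cn]]))
    for (i in idx) {
      s <- s0[i]; e <- min(e0[i], len)
      if (e <= s) next
      b0 <- s %/% step
      b1 <- (e - 1L) %/% step
      bins <- b0:b1
      lo <- pmax(bins * step, s)
      hi <- pmin((bins + 1L) * step, e)
      acc[bins + 1L] <- acc[bins + 1L] + val[i] * (hi - lo)
    }
    width <- pmin(step, len - (seq_along(acc) - 1L) * step)
    track$values[[cn]] <- acc / width
  }
  track
}

#' @rdname read_bedgraph
#' @param track A [signal_track()].
#' @details `write_bedgraph` emits maximal constant-value runs at step
#'   resolution and omits zero regions, so a write/read cycle at the same
#'   step reproduces the track.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cn in names(track$values)) {
    v <- track$values[[cn]]
    if (length(v) == 0) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    s <- starts[keep] * track$step
    e <- pmin(ends[keep] * track$step, track$chrom_sizes[[cn]])
    writeLines(sprintf("%s\t%d\t%d\t%s", cn, s, e,
                       formatC(r$values[keep], format = "g", digits = 15)),
               con)
  }
  invisible(path)
}

#' Total signal mass of a track
#'
#' Sum over steps of value times covered width, i.e. the integral of the
#' piecewise-constant signal. Resampling a bedGraph conserves this mass.
#'
#' @param track A [signal_track()].
#' @return Numeric scalar.
#' @export
track_mass <- function(track) {
  total <- 0
  for (cn in names(track$values)) {
    v <- track$values[[cn]]
    width <- pmin(track$step,
                  track$chrom_sizes[[cn]] - (seq_along(v) - 1) * track$step)
    total <- total + sum(v * width)
  }
  total
}
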