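# Transcript biotype categories used throughout target calling.
TRANSCRIPT_CATEGORIES <- c("coding_mRNA", "non_coding_RNA", "21uRNA")

#' Construct a genome annotation
#'
#' A `GenomeAnnotation` bundles chromosome lengths with a transcript table.
#' All coordinates are 0-based, half-open; conversion to the 1-based closed
#' convention of GFF3 happens only at the I/O boundary.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param transcripts Data frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand` (`"+"` or `"-"`), `category` (one of
#'   `"coding_mRNA"`, `"non_coding_RNA"`, `"21uRNA"`), and list columns
#'   `exon_starts`, `exon_ends` holding the per-transcript exon intervals
#'   (0-based half-open, genomic coordinates). Exons are sorted and merged
#'   on construction.
#' @param sex_chrom Optional name of the designated sex chromosome.
#'
#' @return An object of class `GenomeAnnotation`: a list with elements
#'   `chromosomes`, `transcripts` and `sex_chrom`.
#' @export
genome_annotation <- function(chromosomes, transcripts = empty_transcripts(),
                              sex_chrom = NA_character_) {
  stopifnot(is.numeric(chromosomes), length(names(chromosomes)) == length(chromosomes))
  if (any(chromosomes < 1)) stop("chromosome lengths must be positive")
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  required <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand",
                "category", "exon_starts", "exon_ends")
  missing_cols <- setdiff(required, names(transcripts))
  if (length(missing_cols) > 0) {
    stop("transcript table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!is.na(sex_chrom) && !sex_chrom %in% names(chromosomes)) {
    stop("sex_chrom '", sex_chrom, "' is not a declared chromosome")
  }
  if (nrow(transcripts) > 0) {
    if (anyDuplicated(transcripts$transcript_id)) {
      stop("transcript ids are not unique")
    }
    if (!all(transcripts$strand %in% c("+", "-"))) {
      stop("strand must be '+' or '-'")
    }
    if (!all(transcripts$category %in% TRANSCRIPT_CATEGORIES)) {
      stop("unknown transcript category; expected one of: ",
           paste(TRANSCRIPT_CATEGORIES, collapse = ", "))
    }
    unknown <- setdiff(unique(transcripts$chrom), names(chromosomes))
    if (length(unknown) > 0) {
      stop("transcripts on undeclared chromosomes: ", paste(unknown, collapse = ", "))
    }
    bad <- transcripts$start < 0 |
      transcripts$end > chromosomes[transcripts$chrom] |
      transcripts$start >= transcripts$end
    if (any(bad)) {
      stop("transcripts outside [0, chromosome length): ",
           paste(transcripts$transcript_id[bad], collapse = ", "))
    }
    # one gene id per transcript id is structural; also merge/sort exons and
    # check containment within the transcript interval
    for (i in seq_len(nrow(transcripts))) {
      es <- transcripts$exon_starts[[i]]
      ee <- transcripts$exon_ends[[i]]
      if (length(es) == 0) {
        stop("transcript ", transcripts$transcript_id[i], " has no exons")
      }
      r <- IRanges::reduce(IRanges::IRanges(start = es + 1, end = ee))
      es <- IRanges::start(r) - 1
      ee <- IRanges::end(r)
      if (es[1] < transcripts$start[i] || ee[length(ee)] > transcripts$end[i]) {
        stop("exons of ", transcripts$transcript_id[i],
             " extend beyond the transcript interval")
      }
      transcripts$exon_starts[[i]] <- as.integer(es)
      transcripts$exon_ends[[i]] <- as.integer(ee)
    }
  }
  structure(list(chromosomes = chromosomes,
                 transcripts = transcripts,
                 sex_chrom = sex_chrom),
            class = "GenomeAnnotation")
}

empty_transcripts <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), category = character(),
             exon_starts = I(list()), exon_ends = I(list()),
             stringsAsFactors = FALSE)
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", length(x$chromosomes), "chromosomes (",
      format(sum(x$chromosomes), big.mark = ","), "bp ),",
      nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$gene_id)), "genes\n")
  if (!is.na(x$sex_chrom)) cat("  sex chromosome:", x$sex_chrom, "\n")
  invisible(x)
}

#' Strand-aware transcription start and end sites
#'
#' The TSS is the first transcribed base: `start` on the plus strand and
#' `end - 1` on the minus strand. The TES is the opposite end.
#'
#' @param ann A `GenomeAnnotation`.
#' @return Integer vector of positions (0-based), named by transcript id.
#' @export
transcript_tss <- function(ann) {
  tx <- ann$transcripts
  pos <- ifelse(tx$strand == "+", tx$start, tx$end - 1L)
  stats::setNames(as.integer(pos), tx$transcript_id)
}

#' @rdname transcript_tss
#' @export
transcript_tes <- function(ann) {
  tx <- ann$transcripts
  pos <- ifelse(tx$strand == "+", tx$end - 1L, tx$start)
  stats::setNames(as.integer(pos), tx$transcript_id)
}

#' Derive intron intervals
#'
#' Introns are the complement of a transcript's exons within its interval;
#' they are always derived, never stored. `gene_introns` unions intron
#' intervals over all transcripts of each gene (the footprint used when
#' counting intronic reads).
#'
#' @param ann A `GenomeAnnotation`.
#' @return For `transcript_introns`, a data frame with `transcript_id`,
#'   `gene_id`, `chrom`, `start`, `end` (one row per intron). For
#'   `gene_introns`, the same with `gene_id` only.
#' @export
transcript_introns <- function(ann) {
  tx <- ann$transcripts
  out <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    body <- IRanges::IRanges(start = tx$start[i] + 1, end = tx$end[i])
    exons <- IRanges::IRanges(start = tx$exon_starts[[i]] + 1,
                              end = tx$exon_ends[[i]])
    introns <- IRanges::setdiff(body, exons)
    if (length(introns) == 0) next
    out[[i]] <- data.frame(transcript_id = tx$transcript_id[i],
                           gene_id = tx$gene_id[i],
                           chrom = tx$chrom[i],
                           start = IRanges::start(introns) - 1L,
                           end = IRanges::end(introns),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), start = integer(), end = integer()))
  }
  do.call(rbind, out)
}

#' @rdname transcript_introns
#' @export
gene_introns <- function(ann) {
  per_tx <- transcript_introns(ann)
  if (nrow(per_tx) == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer()))
  }
  pieces <- split(per_tx, paste(per_tx$gene_id, per_tx$chrom, sep = "\r"))
  out <- lapply(pieces, function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = IRanges::start(r) - 1L, end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$gene_id, out$start), , drop = FALSE]
}

#' Read chromosome sizes
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path File path.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  if (anyDuplicated(d$chrom)) stop("duplicated chromosome in ", path)
  stats::setNames(d$length, d$chrom)
}

#' @rdname read_chrom_sizes
#' @param sizes Named numeric vector.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), format(sizes, scientific = FALSE, trim = TRUE)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome annotation from GFF3 or BED12
#'
#' GFF3 input must contain one feature row per transcript (any of types
#' `mRNA`, `transcript`, `ncRNA`, `piRNA`) carrying `ID`, and `exon` rows
#' carrying `Parent`. A `gene_id` attribute on the transcript row is used
#' when present, otherwise `Parent`, otherwise the transcript id with a
#' trailing `.N` stripped; a `category` attribute sets the biotype
#' (defaults by feature type: `mRNA` is coding, `piRNA` is 21uRNA,
#' anything else non-coding). BED12 input takes exons from the block
#' fields; all BED12 transcripts default to coding unless the name carries
#' no information. GFF3's 1-based closed coordinates are converted to the
#' package's 0-based half-open convention on entry.
#'
#' Transcripts shorter than `min_length` are dropped at load time,
#' mirroring the upstream filter applied to the UCSC annotation.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED12 (`.bed`) file.
#' @param chrom_sizes Named numeric vector or path to a chrom.sizes file.
#' @param min_length Minimum transcript length in bp kept (default 50).
#' @param sex_chrom Optional sex chromosome name.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, chrom_sizes, min_length = 50,
                            sex_chrom = NA_character_) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  fmt <- annotation_format(path)
  tx <- if (fmt == "gff3") parse_gff3_transcripts(path) else parse_bed12_transcripts(path)
  keep <- (tx$end - tx$start) >= min_length
  tx <- tx[keep, , drop = FALSE]
  rownames(tx) <- NULL
  genome_annotation(chrom_sizes, tx, sex_chrom = sex_chrom)
}

annotation_format <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gff3"
}

# Cheap structural scan so malformed lines are reported with their number
# (rtracklayer's own errors do not carry one).
check_gff3_lines <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    bad <- which(body)[which(nf != 9)[1]]
    stop("malformed GFF3 line ", bad, " in ", path, " (", nf[which(nf != 9)[1]],
         " fields, expected 9)")
  }
  invisible(TRUE)
}

parse_gff3_transcripts <- function(path) {
  check_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  tx_types <- c("mRNA", "transcript", "ncRNA", "piRNA")
  is_tx <- type %in% tx_types
  is_exon <- type == "exon"
  if (!any(is_tx)) {
    return(empty_transcripts())
  }
  first_or_na <- function(x) {
    vapply(x, function(v) if (length(v) >= 1) as.character(v)[1] else NA_character_,
           character(1))
  }
  tid <- as.character(meta$ID[is_tx])
  parent <- if (!is.null(meta$Parent)) first_or_na(meta$Parent[is_tx]) else NA_character_
  gene <- if (!is.null(meta$gene_id)) as.character(meta$gene_id[is_tx]) else rep(NA_character_, sum(is_tx))
  gene <- ifelse(is.na(gene), parent, gene)
  gene <- ifelse(is.na(gene), sub("\\.[0-9]+$", "", tid), gene)
  cat_attr <- if (!is.null(meta$category)) as.character(meta$category[is_tx]) else rep(NA_character_, sum(is_tx))
  cat_default <- c(mRNA = "coding_mRNA", transcript = "coding_mRNA",
                   ncRNA = "non_coding_RNA", piRNA = "21uRNA")[type[is_tx]]
  category <- ifelse(is.na(cat_attr), unname(cat_default), cat_attr)

  exon_parent <- first_or_na(meta$Parent[is_exon])
  ex_start <- GenomicRanges::start(gr)[is_exon] - 1L
  ex_end <- GenomicRanges::end(gr)[is_exon]
  exon_by_tx <- split(seq_along(exon_parent), exon_parent)

  n <- sum(is_tx)
  exon_starts <- vector("list", n)
  exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- exon_by_tx[[tid[i]]]
    if (is.null(idx)) {
      # transcripts without explicit exon rows are single-exon
      exon_starts[[i]] <- GenomicRanges::start(gr)[is_tx][i] - 1L
      exon_ends[[i]] <- GenomicRanges::end(gr)[is_tx][i]
    } else {
      o <- order(ex_start[idx])
      exon_starts[[i]] <- ex_start[idx][o]
      exon_ends[[i]] <- ex_end[idx][o]
    }
  }
  data.frame(transcript_id = tid, gene_id = gene,
             chrom = as.character(GenomicRanges::seqnames(gr))[is_tx],
             start = GenomicRanges::start(gr)[is_tx] - 1L,
             end = GenomicRanges::end(gr)[is_tx],
             strand = as.character(GenomicRanges::strand(gr))[is_tx],
             category = category,
             exon_starts = I(exon_starts), exon_ends = I(exon_ends),
             stringsAsFactors = FALSE)
}

parse_bed12_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) return(empty_transcripts())
  blocks <- rtracklayer::blocks(gr)
  n <- length(gr)
  exon_starts <- vector("list", n)
  exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    b <- blocks[[i]]
    exon_starts[[i]] <- GenomicRanges::start(b) - 1L
    exon_ends[[i]] <- GenomicRanges::end(b)
  }
  tid <- as.character(S4Vectors::mcols(gr)$name)
  data.frame(transcript_id = tid,
             gene_id = sub("\\.[0-9]+$", "", tid),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             category = "coding_mRNA",
             exon_starts = I(exon_starts), exon_ends = I(exon_ends),
             stringsAsFactors = FALSE)
}

#' Write a genome annotation as GFF3
#'
#' Emits one `transcript`-level row per transcript (type by category) and
#' its `exon` rows, with `ID`, `Parent`, `gene_id` and `category`
#' attributes, so that [read_annotation()] round-trips the transcript set
#' exactly.
#'
#' @param ann A `GenomeAnnotation`.
#' @param path Output path.
#' @export
write_annotation <- function(ann, path) {
  tx <- ann$transcripts
  type_for <- c(coding_mRNA = "mRNA", non_coding_RNA = "ncRNA",
                `21uRNA` = "piRNA")
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(tx))) {
    attrs <- sprintf("ID=%s;gene_id=%s;category=%s", tx$transcript_id[i],
                     tx$gene_id[i], tx$category[i])
    lines <- c(lines, paste(tx$chrom[i], "germchrome",
                            type_for[[tx$category[i]]],
                            tx$start[i] + 1L, tx$end[i], ".", tx$strand[i],
                            ".", attrs, sep = "\t"))
    es <- tx$exon_starts[[i]]
    ee <- tx$exon_ends[[i]]
    for (j in seq_along(es)) {
      lines <- c(lines, paste(tx$chrom[i], "germchrome", "exon",
                              es[j] + 1L, ee[j], ".", tx$strand[i], ".",
                              sprintf("ID=%s.exon%d;Parent=%s",
                                      tx$transcript_id[i], j,
                                      tx$transcript_id[i]),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
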