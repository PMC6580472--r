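#' Construct an expression table
#'
#' Per-gene FPKM for one condition of a two-condition contrast, plus the
#' contrast's log2 fold change (first condition over second), q-value
#' and enrichment status.
#'
#' @param gene_id Character vector of gene ids (unique).
#' @param fpkm Non-negative FPKM values.
#' @param log2fc Signed log2 fold change of condition `conditions[1]`
#'   over `conditions[2]` (optional).
#' @param qvalue q-values in `[0, 1]` (optional).
#' @param status One of `"<A>-enriched"`, `"<B>-enriched"`,
#'   `"not-significant"` (optional).
#' @param conditions Length-2 character vector naming the contrast.
#' @param extra Optional data frame of additional columns.
#' @return Data frame of class `expression_table` with attribute
#'   `conditions`.
#' @export
expression_table <- function(gene_id, fpkm, log2fc = NA_real_,
                             qvalue = NA_real_, status = NA_character_,
                             conditions = c("A", "B"), extra = NULL) {
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  if (any(fpkm < 0, na.rm = TRUE)) stop("FPKM must be non-negative")
  if (any(qvalue < 0 | qvalue > 1, na.rm = TRUE)) {
    stop("q-values must lie in [0, 1]")
  }
  d <- data.frame(gene_id = as.character(gene_id), fpkm = as.numeric(fpkm),
                  log2fc = log2fc, qvalue = qvalue, status = status,
                  stringsAsFactors = FALSE)
  if (!is.null(extra)) d <- cbind(d, extra)
  attr(d, "conditions") <- conditions
  class(d) <- c("expression_table", "data.frame")
  d
}

#' Classify enrichment status from q-value and fold change
#'
#' A gene is called enriched in the first condition when its q-value is
#' strictly below the threshold and its log2 fold change is positive,
#' enriched in the second when the q-value passes and the fold change is
#' negative, and not significant otherwise. A q-value exactly at the
#' threshold does not pass. (At the default 0.05 threshold the upstream
#' differential caller's significance boundary corresponds to a
#' 1.36-fold expression difference.)
#'
#' @param table An [expression_table()] with `qvalue` and `log2fc`
#'   columns populated.
#' @param q_threshold Significance threshold on the q-value
#'   (default 0.05, strict less-than).
#' @return The table with its `status` column recomputed.
#' @export
classify_enriched <- function(table, q_threshold = 0.05) {
  if (!"qvalue" %in% names(table) || all(is.na(table$qvalue))) {
    stop("expression table has no q-value column to classify on")
  }
  if (!"log2fc" %in% names(table) || all(is.na(table$log2fc))) {
    stop("expression table has no log2 fold-change column to classify on")
  }
  conds <- attr(table, "conditions")
  sig <- !is.na(table$qvalue) & table$qvalue < q_threshold
  table$status <- ifelse(sig & table$log2fc > 0,
                         paste0(conds[1], "-enriched"),
                         ifelse(sig & table$log2fc < 0,
                                paste0(conds[2], "-enriched"),
                                "not-significant"))
  table
}

#' Nuclear-retention ratios per gene set
#'
#' For each gene set, the per-gene ratio of nuclear to whole-tissue FPKM
#' with a pseudocount on both sides:
#' `(nuclear + epsilon) / (whole + epsilon)`. Transcripts degraded in
#' the cytoplasm after export show elevated ratios (they are present in
#' the nuclear pool but depleted from the whole-tissue pool). Genes with
#' zero FPKM in both tables are excluded. Both the arithmetic mean and
#' the median of the per-gene ratios are reported, the median because
#' ratio means are outlier-sensitive.
#'
#' @param nuclear_table,whole_table [expression_table()]s sharing gene
#'   ids (e.g. isolated germ nuclei vs dissected whole gonad).
#' @param gene_sets Named list of gene id vectors.
#' @param epsilon Pseudocount added to numerator and denominator FPKM
#'   (default 0.1).
#' @return Data frame of class `retention_summary` with one row per set:
#'   `set`, `n`, `mean_ratio`, `median_ratio`; the per-gene ratio
#'   vectors are attached as the `ratios` attribute (named list).
#' @export
retention_ratio <- function(nuclear_table, whole_table, gene_sets,
                            epsilon = 0.1) {
  stopifnot(epsilon >= 0)
  rows <- list()
  ratios <- list()
  for (nm in names(gene_sets)) {
    ids <- unique(gene_sets[[nm]])
    i_n <- match(ids, nuclear_table$gene_id)
    i_w <- match(ids, whole_table$gene_id)
    ok <- !is.na(i_n) & !is.na(i_w)
    nuc <- nuclear_table$fpkm[i_n[ok]]
    who <- whole_table$fpkm[i_w[ok]]
    expressed <- nuc > 0 | who > 0
    nuc <- nuc[expressed]
    who <- who[expressed]
    if (length(nuc) == 0) {
      stop("gene set '", nm, "' resolves to no expressed gene in both tables")
    }
    r <- (nuc + epsilon) / (who + epsilon)
    names(r) <- ids[ok][expressed]
    ratios[[nm]] <- r
    rows[[nm]] <- data.frame(set = nm, n = length(r),
                             mean_ratio = mean(r),
                             median_ratio = stats::median(r),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ratios") <- ratios
  class(out) <- c("retention_summary", "data.frame")
  out
}

#' Intron-read statistics
#'
#' A read counts as intronic for a gene when it overlaps any interval of
#' the gene's intron union (over all its transcripts) by at least 1 bp.
#' Per sample, the intronic percentage is computed over the total mapped
#' read count; per gene, intronic counts are normalized to 10 million
#' mapped reads (TP10M = count / total * 1e7). Genes accumulating more
#' than 10 intronic reads summed over all samples are flagged as
#' retained for downstream analysis.
#'
#' @param reads A [read_set()]; every sample must have a positive total
#'   mapped count.
#' @param annotation A `GenomeAnnotation`.
#' @return List of class `intron_stats`: `samples` (per-sample
#'   `intronic`, `total`, `percent`), `genes` (per gene and sample:
#'   `intronic`, `tp10m`), `retained` (per gene: total intronic count
#'   and logical flag).
#' @export
intron_stats <- function(reads, annotation) {
  samples <- names(reads$totals)
  if (any(reads$totals <= 0)) {
    stop("sample with zero mapped reads: ",
         paste(samples[reads$totals <= 0], collapse = ", "))
  }
  introns <- gene_introns(annotation)
  rd <- reads$reads
  sample_rows <- data.frame(sample = samples,
                            intronic = 0L,
                            total = as.numeric(reads$totals[samples]),
                            percent = 0,
                            stringsAsFactors = FALSE)
  gene_rows <- data.frame(gene_id = character(), sample = character(),
                          intronic = integer(), tp10m = numeric(),
                          stringsAsFactors = FALSE)
  if (nrow(introns) > 0 && nrow(rd) > 0) {
    lv <- union(unique(introns$chrom), unique(rd$chrom))
    gr_introns <- GenomicRanges::GRanges(
      factor(introns$chrom, levels = lv),
      IRanges::IRanges(introns$start + 1, introns$end))
    gr_reads <- GenomicRanges::GRanges(
      factor(rd$chrom, levels = lv),
      IRanges::IRanges(rd$start + 1, rd$end))
    hits <- GenomicRanges::findOverlaps(gr_reads, gr_introns, minoverlap = 1)
    if (length(hits) > 0) {
      ri <- S4Vectors::queryHits(hits)
      gi <- introns$gene_id[S4Vectors::subjectHits(hits)]
      si <- rd$sample[ri]
      # one count per (read, gene) pair; a read spanning two introns of
      # the same gene still counts once
      pair <- !duplicated(paste(ri, gi, sep = "\r"))
      per_gene <- table(gene = gi[pair], sample = si[pair])
      gene_rows <- as.data.frame(per_gene, stringsAsFactors = FALSE)
      names(gene_rows) <- c("gene_id", "sample", "intronic")
      gene_rows$tp10m <- gene_rows$intronic /
        as.numeric(reads$totals[gene_rows$sample]) * 1e7
      # sample-level percentage counts each read once even if it hits
      # introns of several genes
      per_read <- !duplicated(ri)
      cnt <- table(factor(si[per_read], levels = samples))
      sample_rows$intronic <- as.integer(cnt)
      sample_rows$percent <- 100 * sample_rows$intronic / sample_rows$total
    }
  }
  totals_per_gene <- if (nrow(gene_rows) > 0) {
    rowsum(gene_rows$intronic, gene_rows$gene_id)
  } else NULL
  retained <- if (is.null(totals_per_gene)) {
    data.frame(gene_id = character(), intronic_total = integer(),
               retained = logical(), stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = rownames(totals_per_gene),
               intronic_total = as.integer(totals_per_gene[, 1]),
               retained = totals_per_gene[, 1] > 10,
               stringsAsFactors = FALSE)
  }
  structure(list(samples = sample_rows, genes = gene_rows,
                 retained = retained),
            class = "intron_stats")
}

#' Modification-status by expression cross-tabulation
#'
#' Places each gene of a list into exactly one of four cells by its
#' membership in the H3K27ac and H3K4me3 target tables of a tissue:
#' both marks, H3K27ac only, H3K4me3 only, or neither. Each cell's FPKM
#' distribution is summarized and the fraction of genes carrying at
#' least one mark is derived.
#'
#' @param k27_targets,k4_targets Target tables (as from
#'   [assign_targets_k27()] / [assign_targets_k4()]), or any data frame
#'   with a `gene_id` column.
#' @param gene_list Character vector of gene ids to tabulate.
#' @param expression An [expression_table()] supplying FPKM (genes
#'   missing from it get NA summaries but still count).
#' @return List of class `modification_crosstab`: `cells` (data frame
#'   with `cell`, `n`, `median_fpkm`, `q1_fpkm`, `q3_fpkm`),
#'   `fraction_marked` (genes with >= 1 mark / list size), and
#'   `assignments` (per-gene cell).
#' @export
modification_crosstab <- function(k27_targets, k4_targets, gene_list,
                                  expression) {
  genes <- unique(gene_list)
  in27 <- genes %in% k27_targets$gene_id
  in4 <- genes %in% k4_targets$gene_id
  cell <- ifelse(in27 & in4, "both",
                 ifelse(in27, "h3k27ac_only",
                        ifelse(in4, "h3k4me3_only", "neither")))
  levels <- c("both", "h3k27ac_only", "h3k4me3_only", "neither")
  fpkm <- expression$fpkm[match(genes, expression$gene_id)]
  cells <- do.call(rbind, lapply(levels, function(cl) {
    v <- fpkm[cell == cl]
    v <- v[!is.na(v)]
    data.frame(cell = cl, n = sum(cell == cl),
               median_fpkm = if (length(v)) stats::median(v) else NA_real_,
               q1_fpkm = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
               q3_fpkm = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  structure(list(cells = cells,
                 fraction_marked = sum(cell != "neither") / length(genes),
                 assignments = data.frame(gene_id = genes, cell = cell,
                                          stringsAsFactors = FALSE)),
            class = "modification_crosstab")
}

#' @export
print.modification_crosstab <- function(x, ...) {
  print(x$cells)
  cat(sprintf("fraction with >= 1 mark: %.1f%%\n", 100 * x$fraction_marked))
  invisible(x)
}
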