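#' Pick the anchor transcript of each gene
#'
#' Genes with multiple transcripts (hence multiple TSSs) are represented
#' by one transcript chosen at random but deterministically under the
#' seed: the choice depends only on the seed and the gene id, never on
#' call order. Single-transcript genes return their only transcript. The
#' same anchors are used for summit-to-TSS distances in target calling
#' and for metagene anchoring, so the two analyses agree on what "the"
#' TSS of a gene is.
#'
#' @param ann A `GenomeAnnotation`.
#' @param gene_id A gene id present in the annotation.
#' @param seed Integer seed.
#' @return `pick_anchor_transcript`: a one-row transcript data frame.
#'   `anchor_transcripts`: the transcript table subset to one row per
#'   gene, ordered by gene id.
#' @export
pick_anchor_transcript <- function(ann, gene_id, seed = 1L) {
  idx <- which(ann$transcripts$gene_id == gene_id)
  if (length(idx) == 0) stop("unknown gene id: ", gene_id)
  if (length(idx) > 1) {
    tids <- sort(ann$transcripts$transcript_id[idx])
    pick <- with_stream_seed(seed, paste0("anchor:", gene_id),
                             sample.int(length(idx), 1))
    idx <- idx[match(tids[pick], ann$transcripts$transcript_id[idx])]
  }
  ann$transcripts[idx, , drop = FALSE]
}

#' @rdname pick_anchor_transcript
#' @export
anchor_transcripts <- function(ann, seed = 1L) {
  tx <- ann$transcripts
  genes <- sort(unique(tx$gene_id))
  counts <- table(tx$gene_id)
  multi <- names(counts)[counts > 1]
  if (length(multi) == 0) {
    out <- tx[match(genes, tx$gene_id), , drop = FALSE]
  } else {
    rows <- integer(length(genes))
    for (i in seq_along(genes)) {
      g <- genes[i]
      idx <- which(tx$gene_id == g)
      if (length(idx) == 1) {
        rows[i] <- idx
      } else {
        tids <- sort(tx$transcript_id[idx])
        pick <- with_stream_seed(seed, paste0("anchor:", g),
                                 sample.int(length(idx), 1))
        rows[i] <- idx[match(tids[pick], tx$transcript_id[idx])]
      }
    }
    out <- tx[rows, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# Unsigned distance from a summit to the closest base of [start, end);
# 0 when the summit lies inside.
summit_feature_distance <- function(summit, start, end) {
  pmax(0L, start - summit, summit - (end - 1L))
}

#' Nearest features of each peak summit
#'
#' For every peak summit the `k` closest features (anchor transcripts) in
#' each biotype category are reported with their distances, regardless of
#' strand: features on either strand are eligible, but 5'/3' end labels
#' and TSS distances remain strand-aware. The closest feature overall is
#' additionally labeled with whether the summit is nearest its 5' or 3'
#' end and whether it lies upstream or downstream of that end (in the
#' feature's transcriptional orientation).
#'
#' @param peaks A [peak_table()].
#' @param annotation A `GenomeAnnotation`.
#' @param k Number of nearest features reported per category (default 4).
#' @param seed Seed for the anchor-transcript choice of multi-transcript
#'   genes.
#' @return A list of reports, one per peak, each a list with elements
#'   `peak`, `enrichment`, `missing_chrom`, `categories` (named list of
#'   data frames with `gene_id`, `transcript_id`, `distance`,
#'   `signed_distance` — negative when the summit lies to the genomic
#'   left of the feature — `tss_distance`, `end`, `side`) and `closest`
#'   (one-row data frame or NULL).
#' @export
nearest_features <- function(peaks, annotation, k = 4, seed = 1L) {
  anchors <- anchor_transcripts(annotation, seed = seed)
  summits <- peaks$start + peaks$summit
  reports <- vector("list", nrow(peaks))
  anchors_by_chrom <- split(seq_len(nrow(anchors)), anchors$chrom)
  tss <- ifelse(anchors$strand == "+", anchors$start, anchors$end - 1L)
  tes <- ifelse(anchors$strand == "+", anchors$end - 1L, anchors$start)
  for (p in seq_len(nrow(peaks))) {
    cn <- peaks$chrom[p]
    idx <- anchors_by_chrom[[cn]]
    missing_chrom <- !cn %in% names(annotation$chromosomes)
    if (missing_chrom || length(idx) == 0) {
      reports[[p]] <- list(peak = peaks$name[p],
                           enrichment = peaks$enrichment[p],
                           missing_chrom = missing_chrom,
                           categories = stats::setNames(
                             rep(list(NULL), length(TRANSCRIPT_CATEGORIES)),
                             TRANSCRIPT_CATEGORIES),
                           closest = NULL)
      next
    }
    s <- summits[p]
    dist <- summit_feature_distance(s, anchors$start[idx], anchors$end[idx])
    signed <- ifelse(dist == 0L, 0L,
                     ifelse(s < anchors$start[idx], -dist, dist))
    d5 <- abs(s - tss[idx])
    d3 <- abs(s - tes[idx])
    end_lab <- ifelse(d5 <= d3, "5prime", "3prime")
    end_base <- ifelse(d5 <= d3, tss[idx], tes[idx])
    side <- ifelse(anchors$strand[idx] == "+",
                   ifelse(s < end_base, "upstream", "downstream"),
                   ifelse(s > end_base, "upstream", "downstream"))
    detail <- data.frame(gene_id = anchors$gene_id[idx],
                         transcript_id = anchors$transcript_id[idx],
                         category = anchors$category[idx],
                         distance = dist, signed_distance = signed,
                         tss_distance = d5, end = end_lab, side = side,
                         stringsAsFactors = FALSE)
    cats <- lapply(TRANSCRIPT_CATEGORIES, function(cat) {
      d <- detail[detail$category == cat, , drop = FALSE]
      if (nrow(d) == 0) return(NULL)
      d <- d[order(d$distance, d$gene_id), , drop = FALSE]
      d <- utils::head(d, k)
      rownames(d) <- NULL
      d[, setdiff(names(d), "category"), drop = FALSE]
    })
    names(cats) <- TRANSCRIPT_CATEGORIES
    closest <- detail[order(detail$distance, detail$gene_id)[1], , drop = FALSE]
    rownames(closest) <- NULL
    reports[[p]] <- list(peak = peaks$name[p],
                         enrichment = peaks$enrichment[p],
                         missing_chrom = FALSE,
                         categories = cats, closest = closest)
  }
  reports
}

#' Candidate peaks per coding gene (H3K27ac)
#'
#' Each peak nominates the coding genes in its nearest-feature report; a
#' gene's candidate list collects every peak that nominated it, with the
#' per-pair end label and summit-to-TSS distance needed by the
#' representative-peak rules.
#'
#' @param reports Output of [nearest_features()].
#' @return Named list, gene id to data frame of candidates (`peak`,
#'   `enrichment`, `distance`, `tss_distance`, `end`, `side`).
#' @export
assign_candidates_k27 <- function(reports) {
  rows <- list()
  for (r in reports) {
    d <- r$categories[["coding_mRNA"]]
    if (is.null(d) || nrow(d) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = d$gene_id, peak = r$peak, enrichment = r$enrichment,
      distance = d$distance, tss_distance = d$tss_distance,
      end = d$end, side = d$side, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(list())
  all_rows <- do.call(rbind, rows)
  split(all_rows[, setdiff(names(all_rows), "gene_id"), drop = FALSE],
        all_rows$gene_id)
}

# Deterministic preference order among candidate peaks: highest
# enrichment, then smallest TSS distance, then lexicographic peak name.
order_candidates <- function(cand) {
  cand[order(-cand$enrichment, cand$tss_distance, cand$peak), , drop = FALSE]
}

#' Representative H3K27ac peak of one gene
#'
#' Applies the rule cascade for selecting the single peak that carries a
#' gene's unique enrichment value:
#' 1. candidates whose closest-end label for this gene is 3' are removed;
#' 2. among candidates with summit-to-TSS distance at most 1 kb, the
#'    highest-enrichment peak is selected;
#' 3. if the highest-enrichment remaining candidate lies 1000-1200 bp
#'    from the TSS and its enrichment is more than twice the best peak
#'    within 1 kb, it overrides the within-1 kb choice.
#' Candidates beyond 1200 bp never become representative; genes left
#' with no candidate within that range yield `NULL`. Enrichment ties are
#' broken by smaller TSS distance, then peak name. A distance of exactly
#' 1000 bp falls under rule 2 (the rules apply in their stated order).
#'
#' @param gene_id Gene the candidates belong to.
#' @param candidates Data frame as produced by [assign_candidates_k27()]
#'   (columns `peak`, `enrichment`, `tss_distance`, `end`).
#' @param mark Mark label recorded in the assignment.
#' @return One-row data frame (`gene_id`, `mark`, `peak`, `enrichment`,
#'   `tss_distance`, `rule`) or NULL.
#' @export
select_representative_k27 <- function(gene_id, candidates,
                                      mark = "h3k27ac") {
  cand <- candidates[candidates$end != "3prime", , drop = FALSE]
  cand <- cand[cand$tss_distance <= 1200, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand <- order_candidates(cand)
  within <- cand[cand$tss_distance <= 1000, , drop = FALSE]
  assignment <- function(row, rule) {
    data.frame(gene_id = gene_id, mark = mark, peak = row$peak,
               enrichment = row$enrichment,
               tss_distance = row$tss_distance, rule = rule,
               stringsAsFactors = FALSE)
  }
  if (nrow(within) == 0) {
    # only distal (1000-1200 bp) candidates exist; the override has
    # nothing to be compared against and the best distal peak stands
    return(assignment(cand[1, ], "distal-override"))
  }
  best_within <- within[1, , drop = FALSE]
  top <- cand[1, , drop = FALSE]
  if (top$tss_distance > 1000 &&
      top$enrichment > 2 * best_within$enrichment) {
    return(assignment(top, "distal-override"))
  }
  assignment(best_within, "within-1kb-max")
}

#' Assign H3K27ac peaks to representative coding targets
#'
#' Convenience wrapper running [nearest_features()],
#' [assign_candidates_k27()] and [select_representative_k27()] over a
#' whole peak set. Only coding genes appear in the output.
#'
#' @param peaks A [peak_table()].
#' @param annotation A `GenomeAnnotation`.
#' @param k Nearest features per category passed to [nearest_features()].
#' @param seed Anchor-transcript seed.
#' @return Data frame with one row per targeted gene: `gene_id`, `mark`,
#'   `peak`, `enrichment`, `tss_distance`, `rule`.
#' @export
assign_targets_k27 <- function(peaks, annotation, k = 4, seed = 1L) {
  reports <- nearest_features(peaks, annotation, k = k, seed = seed)
  cand <- assign_candidates_k27(reports)
  rows <- lapply(names(cand), function(g) {
    select_representative_k27(g, cand[[g]])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(), mark = character(),
                      peak = character(), enrichment = numeric(),
                      tss_distance = integer(), rule = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign H3K4me3 peaks to coding targets by overlap
#'
#' A gene is a candidate of every peak whose interval overlaps it by at
#' least 1 bp; per gene, the overlapping peak with the highest enrichment
#' value becomes representative (ties broken by smaller summit-to-TSS
#' distance, then peak name). Only coding genes are reported.
#'
#' @inheritParams assign_targets_k27
#' @return Data frame as in [assign_targets_k27()] with rule
#'   `k4-overlap-max`.
#' @export
assign_targets_k4 <- function(peaks, annotation, seed = 1L) {
  empty <- data.frame(gene_id = character(), mark = character(),
                      peak = character(), enrichment = numeric(),
                      tss_distance = integer(), rule = character(),
                      stringsAsFactors = FALSE)
  anchors <- anchor_transcripts(annotation, seed = seed)
  anchors <- anchors[anchors$category == "coding_mRNA", , drop = FALSE]
  if (nrow(anchors) == 0 || nrow(peaks) == 0) return(empty)
  lv <- union(unique(anchors$chrom), unique(peaks$chrom))
  gr_genes <- GenomicRanges::GRanges(
    factor(anchors$chrom, levels = lv),
    IRanges::IRanges(anchors$start + 1, anchors$end))
  gr_peaks <- GenomicRanges::GRanges(
    factor(peaks$chrom, levels = lv),
    IRanges::IRanges(peaks$start + 1, peaks$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_peaks, minoverlap = 1)
  if (length(hits) == 0) return(empty)
  gi <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  tss <- ifelse(anchors$strand == "+", anchors$start, anchors$end - 1L)
  cand <- data.frame(gene_id = anchors$gene_id[gi],
                     peak = peaks$name[pi],
                     enrichment = peaks$enrichment[pi],
                     tss_distance = abs(peaks$start[pi] + peaks$summit[pi] -
                                          tss[gi]),
                     stringsAsFactors = FALSE)
  cand <- cand[order(cand$gene_id, -cand$enrichment, cand$tss_distance,
                     cand$peak), , drop = FALSE]
  best <- cand[!duplicated(cand$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = best$gene_id, mark = "h3k4me3",
                    peak = best$peak, enrichment = best$enrichment,
                    tss_distance = best$tss_distance,
                    rule = "k4-overlap-max", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
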