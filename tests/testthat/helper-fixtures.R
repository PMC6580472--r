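# Shared fixture builders and independent brute-force oracles.

# Compact transcript-row constructor; exons default to a single exon
# spanning the transcript.
tx_row <- function(tid, chrom, start, end, strand = "+",
                   category = "coding_mRNA", gene = sub("\\.[0-9]+$", "", tid),
                   exon_starts = NULL, exon_ends = NULL) {
  if (is.null(exon_starts)) {
    exon_starts <- start
    exon_ends <- end
  }
  data.frame(transcript_id = tid, gene_id = gene, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = strand, category = category,
             exon_starts = I(list(as.integer(exon_starts))),
             exon_ends = I(list(as.integer(exon_ends))),
             stringsAsFactors = FALSE)
}

make_ann <- function(..., chroms = c(chrI = 100000L), sex_chrom = NA_character_) {
  rows <- list(...)
  tx <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(tx)) genome_annotation(chroms, sex_chrom = sex_chrom)
  else genome_annotation(chroms, tx, sex_chrom = sex_chrom)
}

# Constant-step track with values set per base via intervals.
make_track <- function(chroms, step, intervals = NULL) {
  tr <- signal_track(chroms, step)
  if (!is.null(intervals)) {
    for (i in seq_len(nrow(intervals))) {
      cn <- intervals$chrom[i]
      v <- tr$values[[cn]]
      b0 <- intervals$start[i] %/% step
      b1 <- (intervals$end[i] - 1L) %/% step
      bins <- b0:b1
      lo <- pmax(bins * step, intervals$start[i])
      hi <- pmin((bins + 1L) * step, intervals$end[i])
      v[bins + 1L] <- v[bins + 1L] + intervals$value[i] * (hi - lo) / step
      tr$values[[cn]] <- v
    }
  }
  tr
}

# Reflect an annotation + track through the chromosome midpoint:
# position p -> L - 1 - p, strands flipped, per-step values reversed
# (chromosome lengths are kept multiples of the step).
reflect_genome <- function(ann, track) {
  tx <- ann$transcripts
  L <- ann$chromosomes[tx$chrom]
  new_tx <- tx
  new_tx$start <- as.integer(L - tx$end)
  new_tx$end <- as.integer(L - tx$start)
  new_tx$strand <- ifelse(tx$strand == "+", "-", "+")
  for (i in seq_len(nrow(tx))) {
    es <- tx$exon_starts[[i]]; ee <- tx$exon_ends[[i]]
    new_tx$exon_starts[[i]] <- rev(as.integer(L[i] - ee))
    new_tx$exon_ends[[i]] <- rev(as.integer(L[i] - es))
  }
  new_track <- track
  for (cn in names(track$values)) {
    new_track$values[[cn]] <- rev(track$values[[cn]])
  }
  list(ann = genome_annotation(ann$chromosomes, new_tx), track = new_track)
}

# ---- brute-force oracles -------------------------------------------------

# Scalar re-derivation of per-feature geometry for one summit.
bf_feature_geometry <- function(s, f) {
  d <- if (s >= f$start && s < f$end) 0L
       else if (s < f$start) f$start - s
       else s - (f$end - 1L)
  tss <- if (f$strand == "+") f$start else f$end - 1L
  tes <- if (f$strand == "+") f$end - 1L else f$start
  d5 <- abs(s - tss); d3 <- abs(s - tes)
  end <- if (d5 <= d3) "5prime" else "3prime"
  eb <- if (d5 <= d3) tss else tes
  side <- if (f$strand == "+") {
    if (s < eb) "upstream" else "downstream"
  } else {
    if (s > eb) "upstream" else "downstream"
  }
  list(distance = d, tss_distance = d5, end = end, side = side)
}

# Exhaustive nearest-feature scan over an anchor table (one row per gene).
bf_nearest <- function(peaks, anchors, k = 4) {
  fch <- anchors$chrom; fst <- anchors$start; fen <- anchors$end
  fsd <- anchors$strand; fgid <- anchors$gene_id; fcat <- anchors$category
  lapply(seq_len(nrow(peaks)), function(p) {
    s <- peaks$start[p] + peaks$summit[p]
    on <- which(fch == peaks$chrom[p])
    d <- NULL
    if (length(on) > 0) {
      geo <- lapply(on, function(i) {
        bf_feature_geometry(s, list(start = fst[i], end = fen[i],
                                    strand = fsd[i]))
      })
      d <- data.frame(
        gene_id = fgid[on], category = fcat[on],
        distance = vapply(geo, function(g) as.integer(g$distance),
                          integer(1)),
        tss_distance = vapply(geo, function(g) as.integer(g$tss_distance),
                              integer(1)),
        end = vapply(geo, `[[`, character(1), "end"),
        side = vapply(geo, `[[`, character(1), "side"),
        stringsAsFactors = FALSE)
    }
    cats <- lapply(c("coding_mRNA", "non_coding_RNA", "21uRNA"), function(cat) {
      if (is.null(d)) return(NULL)
      dd <- d[d$category == cat, , drop = FALSE]
      if (nrow(dd) == 0) return(NULL)
      dd <- dd[order(dd$distance, dd$gene_id), , drop = FALSE]
      head(dd, k)
    })
    names(cats) <- c("coding_mRNA", "non_coding_RNA", "21uRNA")
    closest <- if (is.null(d)) NULL else d[order(d$distance, d$gene_id)[1], ]
    list(peak = peaks$name[p], categories = cats, closest = closest)
  })
}

# TRUE iff a nearest_features() output agrees with a bf_nearest() output
# on gene order, distances and end/side labels.
reports_agree <- function(got, want) {
  for (p in seq_along(got)) {
    for (cat in names(got[[p]]$categories)) {
      g <- got[[p]]$categories[[cat]]
      w <- want[[p]]$categories[[cat]]
      if (is.null(w) || is.null(g)) {
        if (!is.null(w) || !is.null(g)) return(FALSE)
        next
      }
      if (!identical(g$gene_id, w$gene_id)) return(FALSE)
      if (!identical(as.integer(g$distance), as.integer(w$distance))) return(FALSE)
      if (!identical(as.integer(g$tss_distance),
                     as.integer(w$tss_distance))) return(FALSE)
      if (!identical(g$end, w$end) || !identical(g$side, w$side)) return(FALSE)
    }
    gc <- got[[p]]$closest
    wc <- want[[p]]$closest
    if (is.null(wc) != is.null(gc)) return(FALSE)
    if (!is.null(wc)) {
      if (gc$gene_id != wc$gene_id || gc$distance != wc$distance) return(FALSE)
    }
  }
  TRUE
}

# Independent rule-by-rule winner derivation for the H3K27ac cascade.
bf_select_k27 <- function(cand) {
  keep <- cand[cand$end != "3prime" & cand$tss_distance <= 1200, , drop = FALSE]
  if (nrow(keep) == 0) return(NULL)
  key <- function(d) order(-d$enrichment, d$tss_distance, d$peak)
  W <- keep[keep$tss_distance <= 1000, , drop = FALSE]
  D <- keep[keep$tss_distance > 1000, , drop = FALSE]
  if (nrow(W) == 0) return(keep[key(keep)[1], ]$peak)
  bw <- W[key(W)[1], ]
  top <- keep[key(keep)[1], ]
  if (top$tss_distance > 1000 && top$enrichment > 2 * bw$enrichment) {
    return(top$peak)
  }
  bw$peak
}

# Quadratic interval-overlap oracle for H3K4me3 targets: every
# (gene, peak) pair is checked for >= 1 bp overlap.
bf_k4 <- function(peaks, anchors) {
  gids <- character(0)
  pks <- character(0)
  for (i in seq_len(nrow(anchors))) {
    if (anchors$category[i] != "coding_mRNA") next
    ov <- which(peaks$chrom == anchors$chrom[i] &
                  peaks$start < anchors$end[i] &
                  peaks$end > anchors$start[i])
    if (length(ov) == 0) next
    tss <- if (anchors$strand[i] == "+") anchors$start[i] else anchors$end[i] - 1L
    dist <- abs(peaks$start[ov] + peaks$summit[ov] - tss)
    best <- ov[order(-peaks$enrichment[ov], dist, peaks$name[ov])[1]]
    gids <- c(gids, anchors$gene_id[i])
    pks <- c(pks, peaks$name[best])
  }
  d <- data.frame(gene_id = gids, peak = pks, stringsAsFactors = FALSE)
  d[order(d$gene_id), , drop = FALSE]
}

# Random small genome + peak set for oracle-equivalence properties.
# Features are single-exon and may overlap (the target rules do not
# require disjoint genes).
rand_instance <- function(n_feat, n_peak, chrom_len = 50000L, n_chrom = 2L) {
  chroms <- setNames(rep(chrom_len, n_chrom), paste0("c", seq_len(n_chrom)))
  fs <- sample.int(chrom_len - 2000L, n_feat, replace = TRUE)
  fl <- sample(60:3000, n_feat, replace = TRUE)
  fe <- pmin(fs + fl, chrom_len)
  tx <- do.call(rbind, lapply(seq_len(n_feat), function(i) {
    tx_row(sprintf("g%03d.1", i), sample(names(chroms), 1), fs[i], fe[i],
           strand = sample(c("+", "-"), 1),
           category = sample(c("coding_mRNA", "non_coding_RNA", "21uRNA"),
                             1, prob = c(0.7, 0.2, 0.1)))
  }))
  ann <- genome_annotation(chroms, tx)
  ps <- sample.int(chrom_len - 1000L, n_peak, replace = TRUE)
  pw <- sample(100:800, n_peak, replace = TRUE)
  peaks <- peak_table(sample(names(chroms), n_peak, replace = TRUE),
                      ps, ps + pw,
                      name = sprintf("pk%03d", seq_len(n_peak)),
                      enrichment = round(rlnorm(n_peak, 1.5, 0.8), 3),
                      summit = sapply(pw, function(w) sample.int(w, 1) - 1L))
  list(ann = ann, peaks = peaks)
}

# Exhaustive hypergeometric enumeration: upper/lower tail probabilities
# by summing exact subset counts C(K, j) * C(N-K, n-j) / C(N, n).
bf_hyper <- function(N, K, n, k) {
  total <- choose(N, n)
  js <- 0:n
  counts <- choose(K, js) * choose(N - K, n - js)
  list(p_upper = sum(counts[js >= k]) / total,
       p_lower = sum(counts[js <= k]) / total)
}

# Literal subset enumeration (only feasible for tiny C(N, n)): draws
# every possible list of size n and counts overlaps.
bf_hyper_subsets <- function(universe, category, n, k) {
  draws <- combn(length(universe), n)
  ov <- apply(draws, 2, function(ix) length(intersect(universe[ix], category)))
  list(p_upper = mean(ov >= k), p_lower = mean(ov <= k))
}
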