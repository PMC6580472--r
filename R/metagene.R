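# Oriented per-base positions for offsets o (5'->3' axis) around an
# anchor at position t: t + o on the plus strand, t - o on the minus.
oriented_positions <- function(t, strand, offsets) {
  if (strand == "+") t + offsets else t - offsets
}

new_metagene_profile <- function(coord, mean, n, mode, params) {
  structure(data.frame(bin = seq_along(coord), coord = coord,
                       mean = mean, n = n),
            mode = mode, params = params,
            class = c("metagene_profile", "data.frame"))
}

#' TSS-anchored metagene profile
#'
#' Averages a signal track over strand-oriented windows around each
#' gene's anchor TSS: `flank_up` bp upstream through `flank_dn` bp
#' downstream, in bins of `bin` bp. Minus-strand windows are reversed so
#' that upstream always reads left. Every gene contributes with equal
#' weight; windows truncated at chromosome ends contribute only their
#' covered bins (a bin's per-gene value is the mean over its covered
#' bases).
#'
#' @param track A [signal_track()]; the track step must divide `bin`.
#' @param annotation A `GenomeAnnotation`.
#' @param genes Character vector of gene ids to profile (required,
#'   non-empty).
#' @param flank_up,flank_dn Flank sizes in bp (defaults 2000/2000).
#' @param bin Bin size in bp (default 50).
#' @param seed Anchor-transcript seed for multi-TSS genes.
#' @return A `metagene_profile` data frame: `bin`, `coord` (bin start
#'   offset relative to the TSS, bp), `mean` (average signal across
#'   contributing genes), `n` (contributing gene count).
#' @export
tss_profile <- function(track, annotation, genes, flank_up = 2000,
                        flank_dn = 2000, bin = 50, seed = 1L) {
  if (length(genes) == 0) stop("empty gene list: nothing to profile")
  if ((flank_up + flank_dn) %% bin != 0) {
    stop("flank_up + flank_dn must be a multiple of the bin size")
  }
  if (bin %% track$step != 0) {
    stop("track step (", track$step, ") must divide the bin size (", bin, ")")
  }
  anchors <- anchor_transcripts(annotation, seed = seed)
  anchors <- anchors[anchors$gene_id %in% genes, , drop = FALSE]
  if (nrow(anchors) == 0) stop("no requested gene is present in the annotation")
  nb <- (flank_up + flank_dn) %/% bin
  offsets <- seq.int(-flank_up, flank_dn - 1L)
  bin_of <- (offsets + flank_up) %/% bin + 1L
  sums <- numeric(nb)
  counts <- integer(nb)
  tss <- ifelse(anchors$strand == "+", anchors$start, anchors$end - 1L)
  for (i in seq_len(nrow(anchors))) {
    pos <- oriented_positions(tss[i], anchors$strand[i], offsets)
    vals <- track_values_at(track, anchors$chrom[i], pos)
    ok <- !is.na(vals)
    if (!any(ok)) next
    bs <- rowsum(vals[ok], bin_of[ok])
    bn <- rowsum(rep(1L, sum(ok)), bin_of[ok])
    at <- as.integer(rownames(bs))
    sums[at] <- sums[at] + bs[, 1] / bn[, 1]
    counts[at] <- counts[at] + 1L
  }
  coord <- seq.int(-flank_up, by = bin, length.out = nb)
  mean_val <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  new_metagene_profile(coord, mean_val, counts, "tss",
                       list(flank_up = flank_up, flank_dn = flank_dn,
                            bin = bin))
}

# Integral of an oriented per-base signal from the body 5' end to
# fractional coordinate x (cumulative-sum interpolation), used for exact
# length-weighted rescaling of gene bodies.
body_integral <- function(cum, u, x) {
  lo <- floor(x)
  frac <- x - lo
  base <- ifelse(lo >= 1, cum[pmax(lo, 1)], 0)
  base[lo < 1] <- 0
  add <- ifelse(frac > 0 & lo + 1 <= length(u), frac * u[pmin(lo + 1, length(u))], 0)
  base + add
}

#' Scaled gene-body metagene profile
#'
#' Rescales every gene body to `body_bins` equal-fraction bins by exact
#' length-weighted averaging, flanked by fixed-bp bins upstream of the
#' TSS and downstream of the TES (as in [tss_profile()]). Genes shorter
#' than `body_bins` bp cannot fill every scaled bin and are excluded with
#' a message.
#'
#' @inheritParams tss_profile
#' @param flank Flank size on each side in bp (default 2000).
#' @param body_bins Number of scaled bins across the gene body
#'   (default 40).
#' @return A `metagene_profile` data frame; `coord` holds the bp offset
#'   for flank bins and the body fraction (0-1) for body bins, with the
#'   body occupying bins `flank/bin + 1` through `flank/bin + body_bins`.
#' @export
gene_body_profile <- function(track, annotation, genes, flank = 2000,
                              bin = 50, body_bins = 40, seed = 1L) {
  if (length(genes) == 0) stop("empty gene list: nothing to profile")
  if (flank %% bin != 0) stop("flank must be a multiple of the bin size")
  if (bin %% track$step != 0) {
    stop("track step (", track$step, ") must divide the bin size (", bin, ")")
  }
  anchors <- anchor_transcripts(annotation, seed = seed)
  anchors <- anchors[anchors$gene_id %in% genes, , drop = FALSE]
  if (nrow(anchors) == 0) stop("no requested gene is present in the annotation")
  lens <- anchors$end - anchors$start
  short <- lens < body_bins
  if (any(short)) {
    message(sum(short), " gene(s) shorter than ", body_bins,
            " bp excluded from the scaled profile")
    anchors <- anchors[!short, , drop = FALSE]
    lens <- lens[!short]
    if (nrow(anchors) == 0) stop("all requested genes are too short to scale")
  }
  nf <- flank %/% bin
  nb <- 2L * nf + body_bins
  sums <- numeric(nb)
  counts <- integer(nb)
  tss <- ifelse(anchors$strand == "+", anchors$start, anchors$end - 1L)
  for (i in seq_len(nrow(anchors))) {
    L <- lens[i]
    offsets <- seq.int(-flank, L + flank - 1L)
    pos <- oriented_positions(tss[i], anchors$strand[i], offsets)
    vals <- track_values_at(track, anchors$chrom[i], pos)
    up <- vals[seq_len(flank)]
    body <- vals[flank + seq_len(L)]
    dn <- vals[flank + L + seq_len(flank)]

    gene_bins <- rep(NA_real_, nb)
    flank_bin_means <- function(v) {
      b <- (seq_along(v) - 1L) %/% bin + 1L
      ok <- !is.na(v)
      out <- rep(NA_real_, nf)
      if (any(ok)) {
        m <- rowsum(v[ok], b[ok]) / rowsum(rep(1, sum(ok)), b[ok])
        out[as.integer(rownames(m))] <- m[, 1]
      }
      out
    }
    gene_bins[seq_len(nf)] <- flank_bin_means(up)
    gene_bins[nf + body_bins + seq_len(nf)] <- flank_bin_means(dn)
    cum <- cumsum(body)
    bounds <- L * (0:body_bins) / body_bins
    ints <- body_integral(cum, body, bounds)
    gene_bins[nf + seq_len(body_bins)] <-
      diff(ints) / diff(bounds)

    ok <- !is.na(gene_bins)
    sums[ok] <- sums[ok] + gene_bins[ok]
    counts[ok] <- counts[ok] + 1L
  }
  coord <- c(seq.int(-flank, by = bin, length.out = nf),
             (seq_len(body_bins) - 0.5) / body_bins,
             seq.int(0, by = bin, length.out = nf))
  mean_val <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  new_metagene_profile(coord, mean_val, counts, "body",
                       list(flank = flank, bin = bin,
                            body_bins = body_bins))
}
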