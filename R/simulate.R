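# Derive a reproducible sub-stream seed from the global seed and a stream
# label, so regenerating one output (e.g. peaks) never perturbs the draws
# of another (e.g. expression).
stream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 100003L
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

with_stream_seed <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, label))
  expr
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic two-tissue study: a small
#' genome with five autosomes and one X chromosome, genes in four
#' expression classes, tissue-coupled histone-mark peaks, and reads with
#' tissue-specific intronic fractions. The defaults encode the study
#' conditions the downstream analyses assume:
#' germline-enriched genes are depleted from the X (placement probability
#' 0.02), soma-specific transcripts are nuclear-retained with a 9.8-fold
#' nuclear/whole-gonad FPKM ratio, and intronic read fractions are 16.8%
#' in the germ-nucleus sample versus 10.2% in the somatic sample.
#'
#' @param seed Integer master seed; every generator derives its own
#'   sub-stream from it.
#' @param chrom_sizes Named chromosome lengths in bp.
#' @param sex_chrom Name of the sex chromosome.
#' @param n_genes Number of genes to place.
#' @param category_props Proportions of the expression classes
#'   `germline_enriched`, `soma_enriched`, `ubiquitous`, `silent`
#'   (must sum to 1).
#' @param p_sex_germline Probability that a germline-enriched gene is
#'   placed on the sex chromosome; all other genes are placed
#'   uniformly by chromosome length.
#' @param biotype_props Proportions of `coding_mRNA`, `non_coding_RNA`
#'   and `21uRNA` transcripts.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal parameters for baseline FPKM.
#' @param retained_meanlog,retained_sdlog Log-normal parameters for the
#'   nuclear FPKM of soma-specific (nuclear-retained) transcripts.
#' @param enriched_lfc_mean,enriched_lfc_sd Mean/sd of the half-normal
#'   log2 fold-change excess added on top of the significance-equivalent
#'   1.36-fold floor for designated enriched genes.
#' @param ubiq_lfc_sd sd of the log2 fold change of ubiquitous genes
#'   (centred at 0).
#' @param retention_multiplier Nuclear/whole-gonad FPKM ratio applied to
#'   soma-specific genes (whole-gonad FPKM = nuclear / multiplier).
#' @param peak_coupling P(mark peak near TSS | gene expressed in tissue).
#' @param peak_offset_sd sd (bp) of the normal summit offset around the TSS.
#' @param peak_enr_meanlog,peak_enr_sdlog Log-normal parameters of peak
#'   enrichment values.
#' @param expressed_fpkm_min FPKM at or above which a gene counts as
#'   expressed in a tissue.
#' @param intron_fraction Named per-sample probability that a read is
#'   placed in an intron.
#' @param reads_per_sample Reads generated (and total mapped count) per
#'   sample.
#' @param read_length Read length in bp.
#' @param track_step Step (bp) of generated signal tracks.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       chrom_sizes = c(chrI = 1e6, chrII = 1e6, chrIII = 1e6,
                                       chrIV = 1e6, chrV = 1e6, chrX = 1e6),
                       sex_chrom = "chrX",
                       n_genes = 1000,
                       category_props = c(germline_enriched = 0.25,
                                          soma_enriched = 0.20,
                                          ubiquitous = 0.35,
                                          silent = 0.20),
                       p_sex_germline = 0.02,
                       biotype_props = c(coding_mRNA = 0.90,
                                         non_coding_RNA = 0.07,
                                         `21uRNA` = 0.03),
                       fpkm_meanlog = log(10), fpkm_sdlog = 0.8,
                       retained_meanlog = log(25), retained_sdlog = 0.5,
                       enriched_lfc_mean = 1.5, enriched_lfc_sd = 0.7,
                       ubiq_lfc_sd = 0.3,
                       retention_multiplier = 9.8,
                       peak_coupling = 0.9,
                       peak_offset_sd = 100,
                       peak_enr_meanlog = log(8), peak_enr_sdlog = 0.6,
                       expressed_fpkm_min = 1,
                       intron_fraction = c(IGN = 0.168, SOM = 0.102),
                       reads_per_sample = 50000,
                       read_length = 30,
                       track_step = 10) {
  stopifnot(abs(sum(category_props) - 1) < 1e-9,
            abs(sum(biotype_props) - 1) < 1e-9,
            p_sex_germline >= 0, p_sex_germline <= 1,
            all(intron_fraction >= 0 & intron_fraction <= 1),
            retention_multiplier > 0, peak_offset_sd >= 0)
  coupling <- peak_coupling
  if (is.numeric(coupling) && length(coupling) == 1) {
    coupling <- list(
      h3k27ac = c(IGN = coupling, SOM = coupling),
      h3k4me3 = c(IGN = coupling, SOM = coupling))
  }
  if (any(unlist(coupling) < 0 | unlist(coupling) > 1)) {
    stop("peak coupling probabilities must lie in [0, 1]")
  }
  if (!sex_chrom %in% names(chrom_sizes)) {
    stop("sex_chrom must be one of the declared chromosomes")
  }
  structure(list(seed = seed, chrom_sizes = chrom_sizes,
                 sex_chrom = sex_chrom, n_genes = n_genes,
                 category_props = category_props,
                 p_sex_germline = p_sex_germline,
                 biotype_props = biotype_props,
                 fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
                 retained_meanlog = retained_meanlog,
                 retained_sdlog = retained_sdlog,
                 enriched_lfc_mean = enriched_lfc_mean,
                 enriched_lfc_sd = enriched_lfc_sd,
                 ubiq_lfc_sd = ubiq_lfc_sd,
                 retention_multiplier = retention_multiplier,
                 peak_coupling = coupling,
                 peak_offset_sd = peak_offset_sd,
                 peak_enr_meanlog = peak_enr_meanlog,
                 peak_enr_sdlog = peak_enr_sdlog,
                 expressed_fpkm_min = expressed_fpkm_min,
                 intron_fraction = intron_fraction,
                 reads_per_sample = reads_per_sample,
                 read_length = read_length,
                 track_step = track_step),
            class = "sim_config")
}

# Exon/intron architecture: alternating segments with floors of 60 bp per
# exon and 40 bp per intron; spare length is spread multinomially.
MIN_EXON <- 60L
MIN_INTRON <- 40L

gene_structure <- function(length, n_exons) {
  repeat {
    need <- n_exons * MIN_EXON + (n_exons - 1L) * MIN_INTRON
    if (need <= length || n_exons == 2L) break
    n_exons <- n_exons - 1L
  }
  need <- n_exons * MIN_EXON + (n_exons - 1L) * MIN_INTRON
  if (need > length) stop("gene too short for a 2-exon structure")
  segs <- 2L * n_exons - 1L
  mins <- rep(c(MIN_EXON, MIN_INTRON), length.out = segs)
  extra <- as.integer(length - sum(mins))
  alloc <- if (extra > 0) {
    as.vector(stats::rmultinom(1, extra, prob = stats::runif(segs) + 0.1))
  } else integer(segs)
  seglen <- mins + alloc
  bounds <- cumsum(c(0L, seglen))
  exon_idx <- seq(1L, segs, by = 2L)
  list(exon_starts = bounds[exon_idx], exon_ends = bounds[exon_idx + 1L])
}

#' Generate a synthetic genome annotation
#'
#' Places `n_genes` non-overlapping genes on the configured chromosomes.
#' Each gene carries a biotype, an expression class label (column
#' `expr_class`) and a 2-8 exon structure. Germline-enriched genes land
#' on the sex chromosome only with probability `p_sex_germline`; all
#' other genes are placed on chromosomes in proportion to length.
#'
#' @param config A [sim_config()].
#' @return A [genome_annotation()] whose transcript table carries the
#'   extra `expr_class` column.
#' @export
generate_genome <- function(config) {
  with_stream_seed(config$seed, "genome", {
    n <- config$n_genes
    if (n == 0) {
      return(genome_annotation(config$chrom_sizes,
                               sex_chrom = config$sex_chrom))
    }
    cats <- sample(names(config$category_props), n, replace = TRUE,
                   prob = config$category_props)
    biotype <- sample(names(config$biotype_props), n, replace = TRUE,
                      prob = config$biotype_props)
    len <- integer(n)
    nexp <- integer(n)
    for (i in seq_len(n)) {
      if (biotype[i] == "coding_mRNA") {
        len[i] <- sample(1000:6000, 1)
        nexp[i] <- sample(2:8, 1)
      } else if (biotype[i] == "non_coding_RNA") {
        len[i] <- sample(300:1200, 1)
        nexp[i] <- sample(2:4, 1)
      } else {
        len[i] <- sample(170:260, 1)
        nexp[i] <- 2L
      }
    }
    autos <- setdiff(names(config$chrom_sizes), config$sex_chrom)
    chrom <- character(n)
    for (i in seq_len(n)) {
      if (cats[i] == "germline_enriched") {
        if (stats::runif(1) < config$p_sex_germline) {
          chrom[i] <- config$sex_chrom
        } else {
          chrom[i] <- sample(autos, 1, prob = config$chrom_sizes[autos])
        }
      } else {
        chrom[i] <- sample(names(config$chrom_sizes), 1,
                           prob = config$chrom_sizes)
      }
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)

    rows <- vector("list", n)
    gid <- sprintf("gene_%04d", seq_len(n))
    for (cn in unique(chrom)) {
      idx <- which(chrom == cn)
      L <- config$chrom_sizes[[cn]]
      used <- sum(len[idx])
      if (used > L) {
        stop("gene capacity exceeded on ", cn, ": ", used, " bp of genes on a ",
             L, " bp chromosome")
      }
      free <- L - used
      w <- stats::runif(length(idx) + 1)
      gaps <- floor(free * w / sum(w))
      ord <- sample(idx)  # random gene order along the chromosome
      pos <- 0L
      for (j in seq_along(ord)) {
        i <- ord[j]
        pos <- pos + gaps[j]
        st <- gene_structure(len[i], nexp[i])
        rows[[i]] <- data.frame(
          transcript_id = paste0(gid[i], ".1"), gene_id = gid[i],
          chrom = cn, start = as.integer(pos), end = as.integer(pos + len[i]),
          strand = strand[i], category = biotype[i],
          exon_starts = I(list(as.integer(pos + st$exon_starts))),
          exon_ends = I(list(as.integer(pos + st$exon_ends))),
          expr_class = cats[i], stringsAsFactors = FALSE)
        pos <- pos + len[i]
      }
    }
    tx <- do.call(rbind, rows)
    genome_annotation(config$chrom_sizes, tx, sex_chrom = config$sex_chrom)
  })
}

#' Generate synthetic expression tables
#'
#' Draws per-gene FPKM for the germ-nucleus (IGN) and somatic (SOM)
#' conditions by expression class, plus a whole-gonad table. Designated
#' enriched genes receive a fold change of at least 1.36 in the favoured
#' direction and q-value 0; all other genes get q-value 1, so the
#' threshold classifier recovers the designated sets exactly. The
#' whole-gonad table equals the IGN (nuclear) table except that
#' soma-specific genes' FPKM is divided by the retention multiplier,
#' emulating post-transcriptional degradation of somatic transcripts in
#' the germline cytoplasm.
#'
#' @param annotation Output of [generate_genome()].
#' @param config The same [sim_config()].
#' @return List of three [expression_table()]s: `IGN`, `SOM`, `gonad`.
#' @export
generate_expression <- function(annotation, config) {
  with_stream_seed(config$seed, "expression", {
    tx <- annotation$transcripts
    n <- nrow(tx)
    cls <- tx$expr_class
    fpkm_ign <- numeric(n)
    fpkm_som <- numeric(n)
    lfc_floor <- log2(1.36)

    i <- cls == "germline_enriched"
    base <- stats::rlnorm(sum(i), config$fpkm_meanlog, config$fpkm_sdlog)
    d <- lfc_floor + abs(stats::rnorm(sum(i), config$enriched_lfc_mean,
                                      config$enriched_lfc_sd))
    fpkm_som[i] <- base
    fpkm_ign[i] <- base * 2^d

    i <- cls == "soma_enriched"
    nuc <- stats::rlnorm(sum(i), config$retained_meanlog, config$retained_sdlog)
    d <- lfc_floor + abs(stats::rnorm(sum(i), config$enriched_lfc_mean,
                                      config$enriched_lfc_sd))
    fpkm_ign[i] <- nuc
    fpkm_som[i] <- nuc * 2^d

    i <- cls == "ubiquitous"
    base <- stats::rlnorm(sum(i), config$fpkm_meanlog, config$fpkm_sdlog)
    eps <- stats::rnorm(sum(i), 0, config$ubiq_lfc_sd)
    fpkm_ign[i] <- base * 2^(eps / 2)
    fpkm_som[i] <- base * 2^(-eps / 2)

    i <- cls == "silent"
    fpkm_ign[i] <- stats::rlnorm(sum(i), log(0.05), 0.5)
    fpkm_som[i] <- stats::rlnorm(sum(i), log(0.05), 0.5)

    log2fc <- log2(fpkm_ign / fpkm_som)
    qval <- ifelse(cls %in% c("germline_enriched", "soma_enriched"), 0, 1)
    status <- ifelse(cls == "germline_enriched", "IGN-enriched",
                     ifelse(cls == "soma_enriched", "SOM-enriched",
                            "not-significant"))
    fpkm_gonad <- fpkm_ign
    soma <- cls == "soma_enriched"
    fpkm_gonad[soma] <- fpkm_ign[soma] / config$retention_multiplier

    mk <- function(fpkm) {
      expression_table(gene_id = tx$gene_id, fpkm = fpkm, log2fc = log2fc,
                       qvalue = qval, status = status,
                       conditions = c("IGN", "SOM"),
                       extra = data.frame(category = cls))
    }
    list(IGN = mk(fpkm_ign), SOM = mk(fpkm_som), gonad = mk(fpkm_gonad))
  })
}

#' Generate a tissue- and mark-specific peak set with a matching track
#'
#' Every gene expressed in the tissue (FPKM at or above
#' `expressed_fpkm_min` in that tissue's table) receives a peak with the
#' configured coupling probability. The summit is drawn normally around
#' the gene's TSS; enrichment values are log-normal. The returned signal
#' track is the sum of box-shaped bumps of height equal to each peak's
#' enrichment over its interval.
#'
#' @param annotation Output of [generate_genome()].
#' @param expression Output of [generate_expression()].
#' @param config The same [sim_config()].
#' @param mark `"h3k27ac"` or `"h3k4me3"`.
#' @param tissue `"IGN"` or `"SOM"`.
#' @return List with elements `peaks` (a [peak_table()]) and `track`
#'   (a [signal_track()]).
#' @export
generate_peaks <- function(annotation, expression, config, mark, tissue) {
  mark <- match.arg(mark, c("h3k27ac", "h3k4me3"))
  tissue <- match.arg(tissue, c("IGN", "SOM"))
  with_stream_seed(config$seed, paste("peaks", mark, tissue), {
    tx <- annotation$transcripts
    expr <- expression[[tissue]]
    fpkm <- expr$fpkm[match(tx$gene_id, expr$gene_id)]
    expressed <- which(!is.na(fpkm) & fpkm >= config$expressed_fpkm_min)
    p <- config$peak_coupling[[mark]][[tissue]]
    take <- expressed[stats::runif(length(expressed)) < p]
    if (length(take) == 0) {
      return(list(
        peaks = peak_table(character(), integer(), integer(),
                           name = character(), enrichment = numeric()),
        track = signal_track(config$chrom_sizes, config$track_step)))
    }
    tss <- transcript_tss(annotation)[tx$transcript_id[take]]
    summit <- as.integer(round(tss + stats::rnorm(length(take), 0,
                                                  config$peak_offset_sd)))
    w_up <- sample(150:400, length(take), replace = TRUE)
    w_dn <- sample(150:400, length(take), replace = TRUE)
    chrom <- tx$chrom[take]
    lims <- config$chrom_sizes[chrom]
    summit <- pmin(pmax(summit, 1L), as.integer(lims) - 2L)
    start <- pmax(summit - w_up, 0L)
    end <- pmin(summit + w_dn + 1L, as.integer(lims))
    enr <- stats::rlnorm(length(take), config$peak_enr_meanlog,
                         config$peak_enr_sdlog)
    o <- order(chrom, start)
    peaks <- peak_table(chrom[o], start[o], end[o],
                        name = sprintf("%s_%s_p%04d", mark, tissue,
                                       seq_along(take)),
                        enrichment = enr[o],
                        summit = (summit - start)[o])
    track <- signal_track(config$chrom_sizes, config$track_step)
    step <- track$step
    for (i in seq_len(nrow(peaks))) {
      cn <- peaks$chrom[i]
      v <- track$values[[cn]]
      s <- peaks$start[i]; e <- peaks$end[i]
      b0 <- s %/% step; b1 <- (e - 1L) %/% step
      bins <- b0:b1
      lo <- pmax(bins * step, s)
      hi <- pmin((bins + 1L) * step, e)
      v[bins + 1L] <- v[bins + 1L] + peaks$enrichment[i] * (hi - lo) / step
      track$values[[cn]] <- v
    }
    list(peaks = peaks, track = track)
  })
}

#' Generate a synthetic read sample
#'
#' Per-gene read counts are multinomial with weights FPKM times
#' transcript length (the expected coverage of a length-normalized
#' expression measure). Each read is placed wholly inside a uniformly
#' chosen intron with the sample's configured intronic probability, and
#' wholly inside an exon otherwise, so the realized intronic read
#' fraction matches the configured one up to binomial error.
#'
#' @param annotation Output of [generate_genome()].
#' @param expression Output of [generate_expression()].
#' @param config The same [sim_config()].
#' @param sample Sample label; must name an entry of
#'   `config$intron_fraction` and of the expression list.
#' @return A [read_set()] with `reads_per_sample` stored intervals.
#' @export
generate_reads <- function(annotation, expression, config, sample) {
  if (!sample %in% names(config$intron_fraction)) {
    stop("no intron fraction configured for sample '", sample, "'")
  }
  with_stream_seed(config$seed, paste("reads", sample), {
    tx <- annotation$transcripts
    expr <- expression[[sample]]
    fpkm <- expr$fpkm[match(tx$gene_id, expr$gene_id)]
    w <- fpkm * (tx$end - tx$start)
    w[is.na(w)] <- 0
    counts <- as.vector(stats::rmultinom(1, config$reads_per_sample, w))
    frac <- config$intron_fraction[[sample]]
    rlen <- config$read_length
    out <- vector("list", nrow(tx))
    for (i in which(counts > 0)) {
      es <- tx$exon_starts[[i]]; ee <- tx$exon_ends[[i]]
      is_s <- ee[-length(ee)]; is_e <- es[-1]  # introns between exons
      n_i <- stats::rbinom(1, counts[i], frac)
      if (length(is_s) == 0) n_i <- 0L
      n_e <- counts[i] - n_i
      place <- function(starts, ends, k) {
        if (k == 0) return(NULL)
        lens <- ends - starts
        pick <- sample.int(length(starts), k, replace = TRUE, prob = lens)
        s <- starts[pick] +
          floor(stats::runif(k) * pmax(lens[pick] - rlen + 1, 1))
        data.frame(chrom = tx$chrom[i], start = as.integer(s),
                   end = as.integer(s + rlen), stringsAsFactors = FALSE)
      }
      out[[i]] <- rbind(place(es, ee, n_e), place(is_s, is_e, n_i))
    }
    reads <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    reads$sample <- sample
    read_set(reads, stats::setNames(config$reads_per_sample, sample))
  })
}
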