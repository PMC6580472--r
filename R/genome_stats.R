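#' Chromosome distribution of peaks relative to chromosome length
#'
#' Under a uniform null, a chromosome carrying fraction `L_c / L_total`
#' of the genome is expected to carry the same fraction of all peaks.
#' For each chromosome a 1-df Pearson goodness-of-fit chi-square compares
#' the on-chromosome / elsewhere split of observed peak counts against
#' those expected proportions; the observed/expected ratio is 1 under the
#' null.
#'
#' @param peaks A [peak_table()] (or any data frame with a `chrom`
#'   column).
#' @param chrom_sizes Named numeric vector or chrom.sizes path; the
#'   genome length is the sum of the provided sizes.
#' @return Data frame with one row per chromosome: `chrom`, `observed`,
#'   `expected`, `ratio`, `chisq`, `pvalue`.
#' @export
chrom_distribution <- function(peaks, chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  total <- nrow(peaks)
  if (total == 0) stop("no peaks: chromosome distribution is undefined")
  unknown <- setdiff(unique(peaks$chrom), names(chrom_sizes))
  if (length(unknown) > 0) {
    stop("peaks on chromosomes absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  }
  obs <- table(factor(peaks$chrom, levels = names(chrom_sizes)))
  frac <- chrom_sizes / sum(chrom_sizes)
  expected <- total * frac
  obs <- as.numeric(obs)
  chisq <- (obs - expected)^2 / expected +
    ((total - obs) - (total - expected))^2 / (total - expected)
  data.frame(chrom = names(chrom_sizes),
             observed = obs,
             expected = as.numeric(expected),
             ratio = obs / as.numeric(expected),
             chisq = as.numeric(chisq),
             pvalue = stats::pchisq(as.numeric(chisq), df = 1,
                                    lower.tail = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric gene-category enrichment
#'
#' Exact test of whether a gene list contains more (upper tail) or fewer
#' (lower tail) members of a category than expected from drawing the
#' list uniformly from the universe. Both tail probabilities are
#' reported; the caller states which direction is of interest (the
#' figure-style "more genes than expected" claim uses the upper tail).
#' No multiple-testing correction is applied unless requested.
#'
#' @param gene_list Character vector of gene ids (must be a subset of
#'   `universe`).
#' @param category_members Character vector of category gene ids (subset
#'   of `universe`).
#' @param universe Character vector: all genes eligible for the draw.
#' @param category Optional category name recorded in the result.
#' @return One-row data frame: `category`, `universe_size` (N),
#'   `category_size` (K), `list_size` (n), `observed` (k), `expected`
#'   (n*K/N), `p_upper` (P(X >= k)), `p_lower` (P(X <= k)).
#' @export
category_enrichment <- function(gene_list, category_members, universe,
                                category = NA_character_) {
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  category_members <- unique(category_members)
  stray <- setdiff(gene_list, universe)
  if (length(stray) > 0) {
    stop("gene list members outside the universe: ",
         paste(utils::head(stray, 10), collapse = ", "),
         if (length(stray) > 10) " ..." else "")
  }
  stray <- setdiff(category_members, universe)
  if (length(stray) > 0) {
    stop("category members outside the universe: ",
         paste(utils::head(stray, 10), collapse = ", "),
         if (length(stray) > 10) " ..." else "")
  }
  N <- length(universe)
  K <- length(category_members)
  n <- length(gene_list)
  k <- length(intersect(gene_list, category_members))
  data.frame(category = category,
             universe_size = N, category_size = K, list_size = n,
             observed = k, expected = n * K / N,
             p_upper = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
             p_lower = stats::phyper(k, K, N - K, n),
             stringsAsFactors = FALSE)
}

#' @rdname category_enrichment
#' @param categories Named list of category member vectors.
#' @param bonferroni Apply a Bonferroni correction across the categories
#'   (adds `p_upper_adj`/`p_lower_adj` columns; off by default).
#' @export
category_enrichment_table <- function(gene_list, categories, universe,
                                      bonferroni = FALSE) {
  out <- do.call(rbind, lapply(names(categories), function(nm) {
    category_enrichment(gene_list, categories[[nm]], universe, category = nm)
  }))
  if (bonferroni) {
    out$p_upper_adj <- pmin(out$p_upper * nrow(out), 1)
    out$p_lower_adj <- pmin(out$p_lower * nrow(out), 1)
  }
  out
}

#' Overlap of two gene lists
#'
#' Set semantics after de-duplication: `a_only` + `both` partitions list
#' A and `b_only` + `both` partitions list B.
#'
#' @param list_a,list_b Character vectors of gene ids.
#' @return List of class `overlap_result` with id vectors `a_only`,
#'   `both`, `b_only`; use `lengths()` for the counts.
#' @export
overlap <- function(list_a, list_b) {
  a <- unique(list_a)
  b <- unique(list_b)
  structure(list(a_only = setdiff(a, b),
                 both = intersect(a, b),
                 b_only = setdiff(b, a)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap: A-only", length(x$a_only), "| both", length(x$both),
      "| B-only", length(x$b_only), "\n")
  invisible(x)
}
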