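test_that("status classification applies the strict q threshold and fold direction", {
  t <- expression_table(c("g1", "g2", "g3", "g4"),
                        fpkm = c(5, 5, 5, 5),
                        log2fc = c(1, -2, 0.5, -0.1),
                        qvalue = c(0.049, 0.01, 0.05, 1),
                        conditions = c("IGN", "SOM"))
  out <- classify_enriched(t)
  expect_equal(out$status,
               c("IGN-enriched", "SOM-enriched", "not-significant",
                 "not-significant"))  # q = 0.05 exactly does not pass
  allq1 <- expression_table("g1", 1, log2fc = 3, qvalue = 1)
  expect_equal(classify_enriched(allq1)$status, "not-significant")
  noq <- expression_table("g1", 1, log2fc = 3)
  expect_error(classify_enriched(noq), "q-value")
})

test_that("classification recovers the generator's designated sets exactly", {
  cfg <- sim_config(17, n_genes = 400,
                    chrom_sizes = c(chrI = 1e6, chrII = 1e6, chrX = 1e6))
  ann <- generate_genome(cfg)
  expr <- generate_expression(ann, cfg)
  out <- classify_enriched(expr$IGN)
  want <- ifelse(out$category == "germline_enriched", "IGN-enriched",
                 ifelse(out$category == "soma_enriched", "SOM-enriched",
                        "not-significant"))
  expect_identical(out$status, want)
})

test_that("retention ratios: identities, arithmetic and pseudocount limit", {
  nuc <- expression_table(c("g1", "g2", "g3"), fpkm = c(4, 16, 7))
  whole <- expression_table(c("g1", "g2", "g3"), fpkm = c(4, 16, 7))
  r <- retention_ratio(nuc, whole, list(all = c("g1", "g2", "g3")))
  expect_equal(r$mean_ratio, 1)
  expect_equal(r$median_ratio, 1)

  nuc <- expression_table(c("g1", "g2"), fpkm = c(4, 16))
  whole <- expression_table(c("g1", "g2"), fpkm = c(2, 2))
  r0 <- retention_ratio(nuc, whole, list(s = c("g1", "g2")), epsilon = 0)
  expect_equal(r0$mean_ratio, 5)    # ratios 2 and 8
  expect_equal(r0$median_ratio, 5)
  # epsilon -> 0 converges to the raw FPKM ratios on positive tables
  r1 <- retention_ratio(nuc, whole, list(s = c("g1", "g2")), epsilon = 1e-9)
  expect_equal(r1$mean_ratio, 5, tolerance = 1e-8)

  # genes at zero in both tables are excluded; empty sets error
  nuc <- expression_table(c("g1", "g2"), fpkm = c(0, 3))
  whole <- expression_table(c("g1", "g2"), fpkm = c(0, 3))
  r <- retention_ratio(nuc, whole, list(s = c("g1", "g2")))
  expect_equal(r$n, 1)
  expect_error(retention_ratio(nuc, whole, list(bad = "g1")), "'bad'")
})

test_that("synthetic retention recovery: soma-specific near 9.8x, germline near 1x", {
  cfg <- sim_config(23)
  ann <- generate_genome(cfg)
  expr <- generate_expression(ann, cfg)
  sets <- split(expr$IGN$gene_id, expr$IGN$category)
  r <- retention_ratio(expr$IGN, expr$gonad,
                       sets[c("soma_enriched", "germline_enriched",
                              "ubiquitous")])
  soma <- r$mean_ratio[r$set == "soma_enriched"]
  expect_lt(abs(soma - cfg$retention_multiplier),
            0.1 * cfg$retention_multiplier)
  expect_equal(r$mean_ratio[r$set == "germline_enriched"], 1)
  expect_equal(r$mean_ratio[r$set == "ubiquitous"], 1)
})

test_that("intron statistics: overlap rule, percentages, TP10M and retention flag", {
  ann <- make_ann(
    tx_row("gA.1", "chrI", 1000, 2000, "+",
           exon_starts = c(1000, 1600), exon_ends = c(1400, 2000))
  )
  # intron is [1400, 1600); reads: one inside, one exon-only, one spanning
  rs <- read_set(data.frame(chrom = "chrI",
                            start = c(1450L, 1100L, 1380L),
                            end = c(1480L, 1130L, 1420L),
                            sample = "s1"),
                 totals = c(s1 = 3))
  st <- intron_stats(rs, ann)
  expect_equal(st$samples$intronic, 2)
  expect_equal(st$samples$percent, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(st$genes$intronic[st$genes$gene_id == "gA"], 2)

  # TP10M: 5 intronic reads at 2e6 mapped = 25; total 5 <= 10 not retained
  rs2 <- read_set(data.frame(chrom = "chrI",
                             start = rep(1450L, 5), end = rep(1480L, 5),
                             sample = "s1"),
                  totals = c(s1 = 2e6))
  st2 <- intron_stats(rs2, ann)
  expect_equal(st2$genes$tp10m, 25)
  expect_false(st2$retained$retained)
  expect_equal(st2$retained$intronic_total, 5L)

  # no intronic reads at all
  rs3 <- read_set(data.frame(chrom = "chrI", start = 1100L, end = 1130L,
                             sample = "s1"), totals = c(s1 = 10))
  st3 <- intron_stats(rs3, ann)
  expect_equal(st3$samples$percent, 0)
  expect_equal(nrow(st3$genes), 0)
  expect_error(intron_stats(read_set(rs3$reads, c(s1 = 0)), ann))
})

test_that("the retained flag sums intronic reads across samples (> 10, strict)", {
  ann <- make_ann(
    tx_row("gA.1", "chrI", 1000, 2000, "+",
           exon_starts = c(1000, 1600), exon_ends = c(1400, 2000))
  )
  mk <- function(n, sample) {
    data.frame(chrom = "chrI", start = rep(1450L, n), end = rep(1480L, n),
               sample = sample)
  }
  # 5 + 5 = 10 intronic reads: not retained (strict >)
  rs <- read_set(rbind(mk(5, "a"), mk(5, "b")), c(a = 100, b = 100))
  expect_false(intron_stats(rs, ann)$retained$retained)
  # 6 + 5 = 11: retained
  rs <- read_set(rbind(mk(6, "a"), mk(5, "b")), c(a = 100, b = 100))
  expect_true(intron_stats(rs, ann)$retained$retained)
})

test_that("synthetic intronic fractions are recovered at 50k reads", {
  cfg <- sim_config(29)
  ann <- generate_genome(cfg)
  expr <- generate_expression(ann, cfg)
  rd <- combine_read_sets(generate_reads(ann, expr, cfg, "IGN"),
                          generate_reads(ann, expr, cfg, "SOM"))
  st <- intron_stats(rd, ann)
  pct <- setNames(st$samples$percent, st$samples$sample)
  expect_lt(abs(pct[["IGN"]] - 16.8), 1)
  expect_lt(abs(pct[["SOM"]] - 10.2), 1)
})

test_that("modification crosstab conserves counts and summarizes cells", {
  k27 <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"))
  k4 <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g6", "g7", "g8"))
  lst <- sprintf("g%d", 1:10)
  expr <- expression_table(lst, fpkm = 1:10)
  ct <- modification_crosstab(k27, k4, lst, expr)
  counts <- setNames(ct$cells$n, ct$cells$cell)
  expect_equal(counts[["both"]], 4)
  expect_equal(counts[["h3k27ac_only"]], 1)
  expect_equal(counts[["h3k4me3_only"]], 3)
  expect_equal(counts[["neither"]], 2)
  expect_equal(sum(ct$cells$n), 10)
  expect_equal(ct$fraction_marked, 0.8)
  expect_equal(ct$assignments$cell[ct$assignments$gene_id == "g1"], "both")
  # FPKM summaries come from the expression table
  expect_equal(ct$cells$median_fpkm[ct$cells$cell == "neither"],
               median(c(9, 10)))
})

test_that("crosstab cell counts sum to list size on random inputs", {
  set.seed(44)
  for (i in 1:20) {
    genes <- sprintf("g%03d", 1:50)
    k27 <- data.frame(gene_id = sample(genes, sample(0:40, 1)))
    k4 <- data.frame(gene_id = sample(genes, sample(0:40, 1)))
    lst <- sample(genes, sample(5:50, 1))
    expr <- expression_table(genes, fpkm = runif(50, 0, 50))
    ct <- modification_crosstab(k27, k4, lst, expr)
    expect_equal(sum(ct$cells$n), length(unique(lst)))
    expect_gte(ct$fraction_marked, 0)
    expect_lte(ct$fraction_marked, 1)
  }
})
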