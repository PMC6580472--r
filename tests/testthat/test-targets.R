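cand_df <- function(peak, enrichment, tss_distance, end = "5prime") {
  data.frame(peak = peak, enrichment = enrichment,
             tss_distance = tss_distance,
             end = rep_len(end, length(peak)), stringsAsFactors = FALSE)
}

test_that("summit geometry: inside genes, upstream of TSS, end labels", {
  ann <- make_ann(
    tx_row("gA.1", "chrI", 1000, 2000, "+"),
    tx_row("gB.1", "chrI", 5000, 6000, "-")
  )
  pk <- peak_table("chrI", c(1400L, 700L, 6100L), c(1500L, 900L, 6300L),
                   name = c("in", "up", "upminus"),
                   enrichment = c(1, 1, 1), summit = c(50L, 100L, 100L))
  rep <- nearest_features(pk, ann)
  # summit inside gA: distance 0, first in its category
  r1 <- rep[[1]]$categories$coding_mRNA
  expect_equal(r1$gene_id[1], "gA")
  expect_equal(r1$distance[1], 0L)
  # summit 200 bp 5' of +strand gA start: end 5prime, side upstream
  r2 <- rep[[2]]$closest
  expect_equal(r2$distance, 200L)
  expect_equal(r2$tss_distance, 200L)
  expect_equal(r2$end, "5prime")
  expect_equal(r2$side, "upstream")
  # summit 200 bp beyond the - strand gene's end coordinate is upstream
  # of its 5' end (TSS at end - 1)
  r3 <- rep[[3]]$closest
  expect_equal(r3$gene_id, "gB")
  expect_equal(r3$end, "5prime")
  expect_equal(r3$side, "upstream")
  expect_equal(r3$tss_distance, 6200L - 5999L)
})

test_that("peaks on chromosomes absent from the annotation yield flagged reports", {
  ann <- make_ann(tx_row("gA.1", "chrI", 1000, 2000))
  pk <- peak_table("chrM", 10L, 100L, name = "stray", enrichment = 1,
                   summit = 5L)
  rep <- nearest_features(pk, ann)[[1]]
  expect_true(rep$missing_chrom)
  expect_null(rep$closest)
  expect_true(all(vapply(rep$categories, is.null, logical(1))))
})

test_that("nearest_features agrees with an exhaustive scan on random instances", {
  set.seed(2024)
  mismatch <- 0
  for (i in 1:60) {
    inst <- rand_instance(sample(3:40, 1), sample(2:15, 1))
    anchors <- anchor_transcripts(inst$ann)
    got <- nearest_features(inst$peaks, inst$ann)
    want <- bf_nearest(inst$peaks, anchors)
    if (!reports_agree(got, want)) mismatch <- mismatch + 1
  }
  expect_equal(mismatch, 0)
})

test_that("per-category neighbour distances are non-decreasing", {
  set.seed(7)
  inst <- rand_instance(60, 20)
  for (rep in nearest_features(inst$peaks, inst$ann)) {
    for (d in rep$categories) {
      if (!is.null(d)) expect_true(all(diff(d$distance) >= 0))
    }
  }
})

test_that("peaks nominate coding genes and candidate lists accumulate", {
  ann <- make_ann(
    tx_row("gA.1", "chrI", 1000, 2000, "+"),
    tx_row("nc.1", "chrI", 1100, 1400, "+", category = "non_coding_RNA")
  )
  pk <- peak_table("chrI", c(800L, 2100L), c(900L, 2200L),
                   name = c("p1", "p2"), enrichment = c(2, 3),
                   summit = c(50L, 50L))
  cand <- assign_candidates_k27(nearest_features(pk, ann))
  expect_equal(names(cand), "gA")
  expect_equal(sort(cand$gA$peak), c("p1", "p2"))
  expect_equal(nrow(cand$gA), 2)
})

test_that("representative H3K27ac selection follows the rule cascade", {
  # highest enrichment within 1 kb wins
  sel <- select_representative_k27("g", cand_df(c("A", "B"), c(4, 7),
                                                c(300, 800)))
  expect_equal(sel$peak, "B")
  expect_equal(sel$rule, "within-1kb-max")
  # distal override: 7 > 2 * 3 at 1100 bp
  sel <- select_representative_k27("g", cand_df(c("A", "B"), c(3, 7),
                                                c(400, 1100)))
  expect_equal(sel$peak, "B")
  expect_equal(sel$rule, "distal-override")
  # no override: 5 <= 2 * 3
  sel <- select_representative_k27("g", cand_df(c("A", "B"), c(3, 5),
                                                c(400, 1100)))
  expect_equal(sel$peak, "A")
  # 3' candidates are removed entirely
  expect_null(select_representative_k27("g", cand_df("A", 9, 200, "3prime")))
  # candidates beyond 1200 bp never become representative
  expect_null(select_representative_k27("g", cand_df("A", 9, 1300)))
  # exactly 1000 bp falls under the within-1kb rule
  sel <- select_representative_k27("g", cand_df(c("A", "B"), c(3, 7),
                                                c(400, 1000)))
  expect_equal(sel$peak, "B")
  expect_equal(sel$rule, "within-1kb-max")
  # enrichment ties break by distance then name
  sel <- select_representative_k27("g", cand_df(c("B", "A"), c(5, 5),
                                                c(300, 300)))
  expect_equal(sel$peak, "A")
  sel <- select_representative_k27("g", cand_df(c("B", "A"), c(5, 5),
                                                c(300, 200)))
  expect_equal(sel$peak, "A")
})

test_that("selection is order-invariant and monotone in enrichment", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    cand <- cand_df(sprintf("p%d", sample(n)),
                    round(rlnorm(n, 1, 0.8), 2),
                    sample(0:1400, n),
                    sample(c("5prime", "3prime"), n, replace = TRUE,
                           prob = c(0.8, 0.2)))
    sel <- select_representative_k27("g", cand)
    perm <- cand[sample(n), , drop = FALSE]
    sel_p <- select_representative_k27("g", perm)
    if (is.null(sel)) {
      expect_null(sel_p)
    } else {
      expect_equal(sel$peak, sel_p$peak)
      # rule-by-rule oracle agrees
      expect_equal(sel$peak, bf_select_k27(cand))
      # raising the winner's enrichment under rule 2 never dethrones it
      if (sel$rule == "within-1kb-max") {
        boosted <- cand
        boosted$enrichment[boosted$peak == sel$peak] <-
          boosted$enrichment[boosted$peak == sel$peak] + 5
        expect_equal(select_representative_k27("g", boosted)$peak, sel$peak)
      }
    }
  }
})

test_that("H3K4me3 targets: overlap candidacy, max enrichment, coding only", {
  ann <- make_ann(
    tx_row("gA.1", "chrI", 1000, 2000, "+"),
    tx_row("gB.1", "chrI", 2100, 3000, "-"),
    tx_row("nc.1", "chrI", 1500, 1900, "+", category = "non_coding_RNA")
  )
  # one broad peak spans both coding genes
  pk <- peak_table("chrI", c(1900L, 900L), c(2200L, 1100L),
                   name = c("broad", "weak"), enrichment = c(9, 2),
                   summit = c(100L, 100L))
  tg <- assign_targets_k4(pk, ann)
  expect_setequal(tg$gene_id, c("gA", "gB"))
  expect_equal(tg$enrichment[tg$gene_id == "gA"], 9)  # max of {2, 9}
  expect_false("nc" %in% tg$gene_id)
  expect_true(all(tg$rule == "k4-overlap-max"))
})

test_that("H3K4me3 assignment matches the quadratic overlap oracle", {
  set.seed(31)
  for (i in 1:40) {
    inst <- rand_instance(sample(5:50, 1), sample(2:20, 1))
    got <- assign_targets_k4(inst$peaks, inst$ann)
    want <- bf_k4(inst$peaks, anchor_transcripts(inst$ann))
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$peak, want$peak)
  }
})

test_that("high coupling with tight offsets targets every expressed coding gene", {
  cfg <- sim_config(55, n_genes = 300,
                    chrom_sizes = c(chrI = 5e5, chrII = 5e5, chrX = 5e5),
                    peak_coupling = 1, peak_offset_sd = 10)
  ann <- generate_genome(cfg)
  expr <- generate_expression(ann, cfg)
  coding <- ann$transcripts$gene_id[ann$transcripts$category == "coding_mRNA"]
  expressed <- intersect(
    expr$IGN$gene_id[expr$IGN$fpkm >= cfg$expressed_fpkm_min], coding)
  t27 <- assign_targets_k27(generate_peaks(ann, expr, cfg, "h3k27ac",
                                           "IGN")$peaks, ann)
  t4 <- assign_targets_k4(generate_peaks(ann, expr, cfg, "h3k4me3",
                                         "IGN")$peaks, ann)
  expect_true(all(expressed %in% t27$gene_id))
  expect_true(all(expressed %in% t4$gene_id))
  # enrichment value recorded equals the representative peak's value
  pk <- generate_peaks(ann, expr, cfg, "h3k27ac", "IGN")$peaks
  expect_equal(t27$enrichment,
               pk$enrichment[match(t27$peak, pk$name)])
})
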