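test_that("table percentages and Fisher bounds reproduce the printed values", {
  # intron content: 53/97 vs 68/736
  expect_equal(group_percentage(53, 97), 54.6)
  expect_equal(group_percentage(68, 736), 9.2)
  expect_lt(fisher.test(contingency_2x2(53, 97, 68, 736))$p.value, 1e-23)
  # shortest-transcript usage: 22/35 vs 87/284
  expect_equal(group_percentage(22, 35), 62.9)
  expect_equal(group_percentage(87, 284), 30.6)
  expect_lt(fisher.test(contingency_2x2(22, 35, 87, 284))$p.value, 3e-4)
})

test_that("structure summary counts TSS usage and introns per group", {
  # gA: multi-TSS pre-MBT gene whose representative is the shortest
  # transcript; gB: single-TSS intron-containing zygotic gene; gC: multi-TSS
  # zygotic gene using the longest transcript
  tx <- rbind(
    make_transcripts("gA", c("tA1", "tA2"), "chr1", c(1000, 400),
                     c(2000, 2000), "+", coding = TRUE, n_exons = 1L),
    make_transcripts("gB", "tB1", "chr1", 10000, 16000, "-", coding = TRUE,
                     n_exons = 3L),
    make_transcripts("gC", c("tC1", "tC2"), "chr1", c(30000, 31000),
                     c(38000, 38000), "+", coding = TRUE, n_exons = 2L))
  classes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    transcript_id = c("tA1", "tB1", "tC1"),
    group = c("pre-MBT paused", "MBT active", "MBT poised"),
    stringsAsFactors = FALSE)
  res <- structure_summary(classes, tx)
  tab <- res$table
  pre <- tab[tab$group == "All pre-MBT", ]
  zyg <- tab[tab$group == "MBT zygotic", ]
  expect_equal(pre$n_genes, 1)
  expect_equal(pre$median_width, 1000)
  expect_equal(pre$multiple_tss, 1)
  expect_equal(pre$uses_shortest, 1)
  expect_equal(pre$uses_shortest_pct, 100)
  expect_equal(pre$intronless, 1)
  expect_equal(zyg$n_genes, 2)
  expect_equal(zyg$multiple_tss, 1)
  expect_equal(zyg$uses_shortest, 0)  # tC1 is the longer transcript
  expect_equal(zyg$intronless, 0)
  expect_equal(zyg$intronless_pct, 0)
  expect_true(!is.null(res$tests))
  # a group of identical widths has that width as its median
  same <- make_transcripts(paste0("g", 1:5), paste0("t", 1:5), "chr1",
                           seq(0, by = 5000, length.out = 5),
                           seq(0, by = 5000, length.out = 5) + 1500, "+")
  cls_same <- data.frame(gene_id = same$gene_id,
                         transcript_id = same$transcript_id,
                         group = "MBT maternal")
  expect_equal(structure_summary(cls_same, same)$table$median_width[2], 1500)
})

test_that("synthetic annotation reproduces the pre-MBT structural contrasts", {
  plan <- simulation_plan(n_genes = 2000, seed = 3)
  ann <- generate_annotation(plan)
  g <- ann$truth$genes
  classes <- data.frame(gene_id = g$gene_id,
                        transcript_id = g$primary_transcript,
                        group = g$group, stringsAsFactors = FALSE)
  res <- structure_summary(classes, ann$transcripts)
  tab <- res$table
  expect_lt(tab$median_width[tab$group == "All pre-MBT"],
            tab$median_width[tab$group == "MBT zygotic"])
  expect_gt(tab$intronless_pct[tab$group == "All pre-MBT"],
            tab$intronless_pct[tab$group == "MBT zygotic"])
  expect_gt(tab$uses_shortest_pct[tab$group == "All pre-MBT"],
            tab$uses_shortest_pct[tab$group == "MBT zygotic"])
  expect_lt(res$tests$width_mann_whitney_p, 0.01)
  expect_lt(res$tests$intronless_fisher_p, 0.01)
  # percentages recompute exactly from the counts at one-decimal rounding
  expect_equal(tab$intronless_pct,
               round(100 * tab$intronless / tab$coding, 1))
})

test_that("conservation means match brute-force per-base averaging", {
  # constant track
  trk <- structure(list(coverage = list(chr1 = S4Vectors::Rle(rep(0.5, 5000))),
                        chrom_sizes = c(chr1 = 5000L)),
                   class = "score_track")
  tx <- make_transcripts("g1", "t1", "chr1", 1000, 3000, "+")
  expect_equal(conservation_summary(trk, tx)$scores$mean_score, 0.5)
  # half ones, half zeros
  v <- c(rep(1, 2000), rep(0, 3000))
  trk2 <- structure(list(coverage = list(chr1 = S4Vectors::Rle(v)),
                         chrom_sizes = c(chr1 = 5000L)),
                    class = "score_track")
  expect_equal(conservation_summary(trk2, tx)$scores$mean_score, 0.5)
  # random track, many transcripts, against a direct oracle
  set.seed(14)
  v3 <- runif(20000)
  trk3 <- structure(list(coverage = list(chr1 = S4Vectors::Rle(v3)),
                         chrom_sizes = c(chr1 = 20000L)),
                    class = "score_track")
  starts <- sample.int(15000, 50)
  tx3 <- make_transcripts(sprintf("g%02d", 1:50), sprintf("t%02d", 1:50),
                          "chr1", starts, starts + sample(500:4000, 50, TRUE),
                          sample(c("+", "-"), 50, TRUE))
  res <- conservation_summary(trk3, tx3)
  oracle <- vapply(seq_len(50), function(i)
    mean(v3[(tx3$start[i] + 1):tx3$end[i]]), numeric(1))
  expect_equal(res$scores$mean_score, oracle)
  # invariance under per-base permutation within the transcript span
  perm <- v3
  span <- (tx3$start[1] + 1):tx3$end[1]
  perm[span] <- sample(perm[span])
  trk_perm <- structure(list(coverage = list(chr1 = S4Vectors::Rle(perm)),
                             chrom_sizes = c(chr1 = 20000L)),
                        class = "score_track")
  expect_equal(conservation_summary(trk_perm, tx3)$scores$mean_score[1],
               res$scores$mean_score[1])
})

test_that("earliest-expression analysis filters and ranks as specified", {
  patterns <- data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g3", "g4"),
    stage = c(1L, 4L, 2L, 9L, 5L, 1L),
    term = c("maternal", "blastoderm", "no staining", "germ band",
             "blastoderm", "maternal"),
    stringsAsFactors = FALSE)
  res <- first_expression_enrichment(patterns, group = c("g1", "g2"))
  # g1's 'maternal' entry is removed; its earliest remaining is stage 4
  expect_equal(res$first$stage[res$first$gene_id == "g1"], 4)
  expect_equal(res$first$term[res$first$gene_id == "g1"], "blastoderm")
  # g4 has nothing left after filtering
  expect_false("g4" %in% res$first$gene_id)
  expect_equal(res$n_unannotated, 1)
  # group = universe: all enrichments are 1
  res_all <- first_expression_enrichment(patterns,
                                         group = c("g1", "g2", "g3"))
  expect_true(all(res_all$enrichment$enrichment == 1))
})

test_that("a planted threefold stage bias is detected", {
  set.seed(6)
  n <- 600
  genes <- sprintf("g%03d", 1:n)
  poised <- genes[1:150]
  stage9_rate <- ifelse(genes %in% poised, 0.6, 0.2)
  stage <- ifelse(runif(n) < stage9_rate, 9L, 5L)
  patterns <- data.frame(gene_id = genes, stage = stage,
                         term = ifelse(stage == 9, "germ band",
                                       "blastoderm"),
                         stringsAsFactors = FALSE)
  res <- first_expression_enrichment(patterns, group = poised)
  s9 <- res$enrichment[res$enrichment$category == "stage9:germ band", ]
  expect_gt(s9$enrichment, 1.5)
  expect_lt(s9$q_value, 0.05)
  expect_true(s9$significant)
})
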