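test_that("empty plans yield empty annotation; invalid plans are rejected", {
  empty <- generate_annotation(simulation_plan(n_genes = 0))
  expect_equal(nrow(empty$transcripts), 0)
  expect_equal(nrow(empty$truth$genes), 0)
  expect_error(simulation_plan(chrom_sizes = c(chr1 = 0)), "positive")
  bad_props <- c("pre-MBT not-paused" = 0.5, "pre-MBT dual" = 0,
                 "pre-MBT paused" = 0, "MBT maternal" = 0.4,
                 "MBT active" = 0, "MBT poised" = 0, "unbound" = 0.2)
  expect_error(simulation_plan(group_proportions = bad_props), "sum to 1")
})

test_that("generators are pure functions of (plan, seed)", {
  plan <- small_plan(seed = 5)
  a1 <- generate_annotation(plan)
  a2 <- generate_annotation(plan)
  expect_identical(a1, a2)
  r1 <- simulate_reads(plan, a1$truth, "MBT", 2)
  r2 <- simulate_reads(plan, a1$truth, "MBT", 2)
  expect_identical(r1, r2)
  # different replicates differ
  r3 <- simulate_reads(plan, a1$truth, "MBT", 3)
  expect_false(identical(r1$ip$reads, r3$ip$reads))
  expect_identical(generate_expression(plan, a1$truth),
                   generate_expression(plan, a1$truth))
})

test_that("unknown stage labels are rejected", {
  plan <- small_plan()
  ann <- generate_annotation(plan)
  expect_error(simulate_reads(plan, ann$truth, "gastrula", 1),
               "unknown stage")
})

test_that("group-wise width medians track the plan parameters", {
  plan <- simulation_plan(n_genes = 2000, pre_mbt_median_width = 1200,
                          mbt_median_width = 6000, seed = 21)
  ann <- generate_annotation(plan)
  g <- ann$truth$genes
  pre_med <- median(g$width[g$group %in% c("pre-MBT not-paused",
                                           "pre-MBT dual", "pre-MBT paused")])
  mbt_med <- median(g$width[g$group %in% c("MBT active", "MBT poised")])
  expect_lt(abs(pre_med - 1200) / 1200, 0.15)
  expect_lt(abs(mbt_med - 6000) / 6000, 0.15)
  expect_setequal(unique(g$strand), c("+", "-"))
  # pre-MBT genes are more often intronless than MBT-zygotic genes
  expect_gt(mean(g$intronless[g$group %in% c("pre-MBT not-paused",
                                             "pre-MBT dual",
                                             "pre-MBT paused")]),
            mean(g$intronless[g$group %in% c("MBT active", "MBT poised")]))
})

test_that("transcripts never overlap across genes and stay in bounds", {
  plan <- small_plan(seed = 13)
  ann <- generate_annotation(plan)
  tx <- ann$transcripts
  expect_true(all(tx$start >= 0))
  expect_true(all(tx$end <= ann$truth$chrom_sizes[tx$chrom]))
  for (ch in names(ann$truth$chrom_sizes)) {
    g <- ann$truth$genes[ann$truth$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
})

test_that("zero IP depth yields an empty IP read set", {
  plan <- small_plan(read_depth_ip = 0, read_depth_wce = 1000)
  ann <- generate_annotation(plan)
  rr <- simulate_reads(plan, ann$truth, "MBT", 1)
  expect_equal(rr$ip$n_reads, 0)
  expect_equal(rr$wce$n_reads, 1000)
})

test_that("planted duplicate stacks appear verbatim at recorded coordinates", {
  plan <- small_plan(seed = 3)
  ann <- generate_annotation(plan)
  rr <- simulate_reads(plan, ann$truth, "pre-MBT", 1)
  art <- ann$truth$artifacts
  expect_equal(nrow(art), plan$stack_artifact_count)
  for (i in seq_len(nrow(art))) {
    hits <- rr$ip$reads$chrom == art$chrom[i] &
      rr$ip$reads$start == art$start[i] &
      rr$ip$reads$strand == art$strand[i]
    expect_gte(sum(hits), art$size[i])
  }
})

test_that("simulated pausing indexes separate paused from non-paused genes", {
  plan <- small_plan(seed = 7)
  ann <- generate_annotation(plan)
  cs <- ann$truth$chrom_sizes
  rr <- simulate_reads(plan, ann$truth, "pre-MBT", 1)
  ip <- compute_coverage(extend_reads(
    remove_duplicate_stacks(rr$ip)$reads, chrom_sizes = cs), cs)
  wce <- compute_coverage(extend_reads(rr$wce, chrom_sizes = cs), cs)
  rec <- compute_enrichment(ip, wce, ann$transcripts)
  g <- ann$truth$genes
  rec <- rec[match(g$primary_transcript, rec$transcript_id), ]
  paused <- rec$pausing_index[g$group == "pre-MBT paused"]
  notp <- rec$pausing_index[g$group == "pre-MBT not-paused"]
  expect_true(min(paused) > max(notp))
  # paused gene bodies carry background only
  expect_true(all(rec$tu_enrichment[g$group == "pre-MBT paused"] < 1))
})

test_that("expression tables encode the maternal/zygotic thresholds", {
  plan <- small_plan(seed = 19)
  ann <- generate_annotation(plan)
  expr <- generate_expression(plan, ann$truth)
  g <- ann$truth$genes
  m <- match(g$gene_id, expr$gene_id)
  expect_true(all(expr$nc10[m[g$group == "MBT maternal"]] >= 1))
  expect_true(all(expr$nc14D[m[g$group == "MBT active"]] >= 5))
  expect_true(all(expr$nc10[m[g$group == "MBT active"]] < 1))
  expect_true(all(expr$nc14D[m[g$group == "MBT poised"]] < 5))
})

test_that("motif planting at rate 1 round-trips exactly through the scanner", {
  rates <- default_plant_rates() * 0
  rates[, "TATA"] <- 1
  plan <- small_plan(seed = 23, motif_plant_rates = rates,
                     n_genes = 60)
  ann <- generate_annotation(plan)
  prom <- generate_promoters(plan, ann$truth, ann$transcripts)
  hits <- scan_promoters(prom$sequences, seq_offset = prom$offset)
  expect_true(all(hits$TATA))
  # every recorded plant is recovered at its recorded offset
  tata <- motif_catalog()[motif_catalog()$name == "TATA", ]
  pl <- prom$plants[prom$plants$motif == "TATA", ]
  for (i in sample(nrow(pl), 10)) {
    sc <- scan_motif(prom$sequences[[pl$transcript_id[i]]], tata,
                     seq_offset = prom$offset)
    expect_true(pl$offset[i] %in% sc$positions)
  }
})

test_that("unknown motif names in plant rates are rejected", {
  rates <- default_plant_rates()
  colnames(rates)[1] <- "NotAMotif"
  plan <- small_plan(motif_plant_rates = rates, n_genes = 10)
  ann <- generate_annotation(plan)
  expect_error(generate_promoters(plan, ann$truth, ann$transcripts),
               "NotAMotif")
})

test_that("background promoters match the brute-force scanner hit rates", {
  rates <- default_plant_rates() * 0
  plan <- small_plan(seed = 29, motif_plant_rates = rates, n_genes = 80)
  ann <- generate_annotation(plan)
  prom <- generate_promoters(plan, ann$truth, ann$transcripts)
  catalog <- motif_catalog()
  hits <- scan_promoters(prom$sequences, catalog, seq_offset = prom$offset)
  for (k in seq_len(nrow(catalog))) {
    counts <- vapply(seq_along(prom$sequences), function(i)
      oracle_scan(as.character(prom$sequences[[i]]), catalog$consensus[k],
                  catalog$directional[k], catalog$window_start[k],
                  catalog$window_end[k], seq_offset = prom$offset),
      integer(1))
    expect_equal(hits[[paste0(catalog$name[k], "_count")]], counts,
                 info = catalog$name[k])
  }
})

test_that("score track, reference ranking and TBP peaks reflect the truth", {
  plan <- small_plan(seed = 31)
  ann <- generate_annotation(plan)
  g <- ann$truth$genes
  trk <- generate_score_track(plan, ann$truth)
  cons <- conservation_summary(trk, ann$transcripts)
  sc <- cons$scores$mean_score[match(g$primary_transcript,
                                     cons$scores$transcript_id)]
  pre <- g$group %in% c("pre-MBT not-paused", "pre-MBT dual",
                        "pre-MBT paused")
  expect_gt(mean(sc[pre]), mean(sc[!pre]) + 0.2)

  ref <- generate_reference_ranking(plan, ann$truth, ann$transcripts)
  dual_tx <- ann$transcripts$gene_id %in% g$gene_id[g$group == "pre-MBT dual"]
  expect_true(all(ref$percentile[dual_tx] >= 0.8))
  expect_true(all(ref$percentile[!dual_tx] <= 0.8))

  peaks <- generate_tbp_peaks(plan, ann$truth)
  bound <- g[g$group != "unbound", ]
  expect_equal(nrow(peaks), nrow(bound))
  expect_true(all(peaks$summit >= peaks$start & peaks$summit < peaks$end))
})
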