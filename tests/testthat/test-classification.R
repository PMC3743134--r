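# Classification uses hand-built enrichment records so every criterion can be
# checked against a known construction.

test_that("pre-MBT identification applies all three criteria exactly", {
  n <- 200
  ids <- sprintf("t%03d", seq_len(n))
  genes <- sprintf("g%03d", seq_len(n))
  tx <- make_transcripts(genes, ids, "chr1",
                         start = seq(0, by = 3000, length.out = n),
                         end = seq(0, by = 3000, length.out = n) + 2000,
                         strand = "+")
  planted <- 1:5
  enr <- ifelse(seq_len(n) %in% planted, 4.0, 1.2)
  sig <- ifelse(seq_len(n) %in% planted, 1e-3, 1e-6)
  rec <- make_records(ids, genes, replicates = 4,
                      tss_enrichment = enr, tu_enrichment = 1,
                      tss_signal = sig)
  peaks <- data.frame(chrom = "chr1", start = tx$start[planted] - 50L,
                      end = tx$start[planted] + 50L)
  res <- identify_pre_mbt(rec, tx, peaks)
  expect_setequal(res$candidates, ids[planted])
  # brute-force re-check of the three criteria on every transcript
  cutoff <- quantile(sig, 0.99, names = FALSE)
  for (i in seq_len(n)) {
    ok <- enr[i] >= 2 && sig[i] >= cutoff &&
      any(abs(peaks$start + 50 - tx$start[i]) <= 550)
    expect_equal(ids[i] %in% res$candidates, ok)
  }

  # failing the enrichment cutoff in a single replicate disqualifies
  rec_drop <- rec
  rec_drop$tss_enrichment[rec_drop$replicate == "r3" &
                            rec_drop$transcript_id == "t001"] <- 1.5
  res_drop <- identify_pre_mbt(rec_drop, tx, peaks)
  expect_false("t001" %in% res_drop$candidates)
})

test_that("TBP distance is boundary-inclusive at 500 bp and reported", {
  tx <- make_transcripts(c("gA", "gB"), c("tA", "tB"), "chr1",
                         c(10000, 50000), c(12000, 52000), "+")
  rec <- make_records(c("tA", "tB"), c("gA", "gB"), 4,
                      tss_enrichment = 4, tu_enrichment = 0.5,
                      tss_signal = 1e-3)
  # peak ends 500 bp and 501 bp upstream of the two TSSs
  peaks <- data.frame(chrom = "chr1", start = c(10000 - 600, 50000 - 601),
                      end = c(10000 - 500 + 1, 50000 - 501 + 1))
  res <- identify_pre_mbt(rec, tx, peaks)
  expect_true("tA" %in% res$candidates)
  expect_false("tB" %in% res$candidates)
  expect_equal(res$rejected$transcript_id, "tB")
  expect_equal(res$rejected$nearest_tbp_peak, 501)
  # an empty peak set rejects everything with a warning
  expect_warning(
    res0 <- identify_pre_mbt(rec, tx, peaks[0, ]),
    "empty TBP peak set")
  expect_length(res0$candidates, 0)
})

test_that("lowering the signal percentile never shrinks the candidate set", {
  set.seed(11)
  n <- 100
  ids <- sprintf("t%03d", 1:n)
  tx <- make_transcripts(ids, ids, "chr1", seq(0, by = 3000, length.out = n),
                         seq(0, by = 3000, length.out = n) + 2000, "+")
  rec <- make_records(ids, ids, 2, tss_enrichment = runif(n, 0, 6),
                      tu_enrichment = 1, tss_signal = runif(n))
  peaks <- data.frame(chrom = "chr1", start = tx$start - 10L,
                      end = tx$start + 10L)
  strict <- identify_pre_mbt(rec, tx, peaks, percentile = 0.99)$candidates
  loose <- identify_pre_mbt(rec, tx, peaks, percentile = 0.90)$candidates
  expect_true(all(strict %in% loose))
})

test_that("pre-MBT groups: paused by TU, dual by reference percentile", {
  pre <- data.frame(gene_id = c("g1", "g2", "g3"),
                    transcript_id = c("t1", "t2", "t3"),
                    stringsAsFactors = FALSE)
  rec <- make_records(c("t1", "t2", "t3"), c("g1", "g2", "g3"), 4,
                      tss_enrichment = 4,
                      tu_enrichment = c(0.8, 1.5, 1.5),
                      tss_signal = 1e-3)
  ref <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    percentile = c(0.1, 0.85, 0.50))
  cls <- classify_pre_mbt(pre, rec, ref)
  expect_equal(cls$group,
               c("pre-MBT paused", "pre-MBT dual", "pre-MBT not-paused"))
  # candidates missing from the reference fall back to not-paused
  expect_warning(
    cls2 <- classify_pre_mbt(pre, rec, ref[-3, ]),
    "missing from reference")
  expect_equal(cls2$group[3], "pre-MBT not-paused")
})

test_that("MBT representative: highest TSS signal, ties broken by TU", {
  tx <- make_transcripts(c("g1", "g1", "g2", "g2", "g3"),
                         c("t1a", "t1b", "t2a", "t2b", "t3"), "chr1",
                         c(0, 300, 9000, 9300, 20000),
                         c(2000, 2000, 11000, 11000, 22000), "+")
  rec <- make_records(tx$transcript_id, tx$gene_id, 3,
                      tss_enrichment = c(4, 4, 4, 4, 4),
                      tu_enrichment = c(1, 1, 2.0, 1.0, 1),
                      tss_signal = c(500, 300, 400, 400, 10) * 1e-6)
  res <- identify_mbt(rec, tx)
  reps <- res$genes
  expect_equal(reps$transcript_id[reps$gene_id == "g1"], "t1a")
  expect_equal(reps$transcript_id[reps$gene_id == "g2"], "t2a")
  # a transcript below twofold in one replicate disqualifies the gene
  rec2 <- rec
  rec2$tss_enrichment[rec2$replicate == "r2" & rec2$gene_id == "g3"] <- 1.9
  res2 <- identify_mbt(rec2, tx)
  expect_false("g3" %in% res2$genes$gene_id)
  # pre-MBT genes are reported separately, never re-classified
  res3 <- identify_mbt(rec, tx, pre_mbt_genes = "g1")
  expect_false("g1" %in% res3$genes$gene_id)
  expect_equal(res3$pre_mbt_also, "g1")
})

test_that("MBT classification thresholds are boundary-inclusive", {
  mbt <- data.frame(gene_id = c("g1", "g2", "g3"),
                    transcript_id = c("t1", "t2", "t3"))
  expr <- data.frame(gene_id = c("g1", "g2", "g3"),
                     nc10 = c(1.0, 0.5, 0), nc14D = c(0, 5.0, 0))
  cls <- classify_mbt(mbt, expr)
  expect_equal(cls$group, c("MBT maternal", "MBT active", "MBT poised"))
  expect_error(classify_mbt(mbt, transform(expr, nc10 = c(-1, 0, 0))),
               "negative RPKM")
  expect_message(cls2 <- classify_mbt(mbt, expr[-3, ]), "missing")
  expect_equal(cls2$group[3], "MBT poised")
})

test_that("the maternal time-course filter removes on either criterion", {
  expr <- data.frame(gene_id = c("g1", "g2", "g3"),
                     nc10 = c(20, 1, 16),
                     nc10_maternal = c(0.1, 4, 1),
                     nc10_zygotic = c(5, 2, 2))
  kept <- maternal_timecourse_filter(expr)
  expect_false("g1" %in% kept)  # nc10 > 16
  expect_false("g2" %in% kept)  # maternal >= 2x zygotic
  expect_true("g3" %in% kept)   # both criteria fail (boundaries)
})

test_that("custom TSS sits 19 bp downstream of the TBP maximum", {
  v <- rep(0, 6000)
  v[5001] <- 10                      # 0-based position 5000
  trk <- make_track(v)
  peak <- list(chrom = "chr1", start = 4900L, end = 5100L)
  expect_equal(assign_custom_tss(trk, peak, "+"), 5019)
  expect_equal(assign_custom_tss(trk, peak, "-"), 4981)
  # plateau maximum over [5000, 5010): 5'-most position wins
  v2 <- rep(0, 6000); v2[5001:5010] <- 10
  expect_equal(assign_custom_tss(make_track(v2), peak, "+"), 5019)
  expect_equal(assign_custom_tss(make_track(v2), peak, "-"), 5009 - 19)
  expect_error(assign_custom_tss(make_track(rep(0, 6000)), peak, "+"),
               "all-zero")
})

test_that("classification partitions genes into disjoint groups", {
  plan <- small_plan(seed = 7)
  study <- simulate_study(plan, n_pre_replicates = 2, n_mbt_replicates = 2)
  cs <- study$truth$chrom_sizes
  pre_rec <- enrichment_records(study$pre_replicates, study$transcripts, cs)
  mbt_rec <- enrichment_records(study$mbt_replicates, study$transcripts, cs)
  cls <- classify_genes(pre_rec, mbt_rec, study$transcripts, study$tbp_peaks,
                        study$expression, study$reference_ranking)
  classes <- cls$classes
  expect_equal(anyDuplicated(classes$gene_id), 0)
  expect_equal(nrow(classes), length(unique(study$transcripts$gene_id)))
  pre_g <- classes$gene_id[grepl("^pre-MBT", classes$group)]
  mbt_g <- classes$gene_id[grepl("^MBT", classes$group)]
  expect_length(intersect(pre_g, mbt_g), 0)
})
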