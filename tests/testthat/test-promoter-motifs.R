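test_that("IUPAC scanning matches a hand-expanded example", {
  tata <- motif_catalog()[motif_catalog()$name == "TATA", ]
  # S=C, T, A, T, A, W=A, A, W=A, R=G at offset -30
  res <- scan_motif("CTATAAAAG", tata, seq_offset = -30L)
  expect_equal(res$count, 1)
  expect_equal(res$positions, -30)
  # same sequence placed downstream of the window: no hit
  expect_equal(scan_motif("CTATAAAAG", tata, seq_offset = 10L)$count, 0)
  # invalid IUPAC letters are rejected
  bad <- list(consensus = "TAXA", directional = TRUE,
              window_start = -100L, window_end = 0L)
  expect_error(scan_motif("CTATAAAAG", bad, -30L), "invalid IUPAC")
})

test_that("non-directional motifs are counted on both strands", {
  zelda <- motif_catalog()[motif_catalog()$name == "Zelda", ]
  # CAGGTAG matches YAGGTAR forward; its reverse complement CTACCTG placed
  # in the window matches on the minus strand
  fw <- scan_motif("CAGGTAGCCCCC", zelda, seq_offset = -10L)
  expect_equal(fw$count, 1)
  expect_equal(fw$strand, "+")
  rc <- scan_motif("CTACCTGCCCCC", zelda, seq_offset = -10L)
  expect_equal(rc$count, 1)
  expect_equal(rc$strand, "-")
  # N in the subject never matches
  expect_equal(scan_motif("CAGGTANCCCCC", zelda, seq_offset = -10L)$count, 0)
})

test_that("scanner agrees with the brute-force regex oracle", {
  set.seed(17)
  catalog <- motif_catalog()
  n <- 300
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""), "")
  names(seqs) <- sprintf("t%03d", seq_len(n))
  offset <- -300L
  hits <- scan_promoters(seqs, catalog, seq_offset = offset)
  for (k in seq_len(nrow(catalog))) {
    oracle <- vapply(seqs, function(s)
      oracle_scan(s, catalog$consensus[k], catalog$directional[k],
                  catalog$window_start[k], catalog$window_end[k],
                  seq_offset = offset), integer(1), USE.NAMES = FALSE)
    expect_equal(hits[[paste0(catalog$name[k], "_count")]], oracle,
                 info = catalog$name[k])
  }
})

test_that("element enrichment: identity, negative reciprocal, exact test", {
  ids <- sprintf("t%02d", 1:100)
  hits <- data.frame(transcript_id = ids,
                     M = c(rep(TRUE, 10), rep(FALSE, 90)),
                     stringsAsFactors = FALSE)
  # group = universe
  all_res <- element_enrichment(ids, hits, motifs = "M")
  expect_equal(all_res$enrichment, 1)
  expect_equal(all_res$p_value, 1)
  # group of 10 with 5 carriers; universe carries 10 of 100
  hits$M <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 85))
  res <- element_enrichment(ids[1:10], hits, motifs = "M")
  expect_equal(res$observed, 0.5)
  expect_equal(res$expected, 0.1)
  expect_equal(res$enrichment, 5)
  expect_equal(res$p_value,
               oracle_fisher_p(matrix(c(5, 5, 5, 85), 2, byrow = TRUE)),
               tolerance = 1e-10)
  # depletion: raw enrichment 0.5 reported as -2
  expect_equal(signed_enrichment(0.5), -2)
  expect_true(all(abs(signed_enrichment(runif(100, 0.01, 5))) >= 1))
  expect_error(element_enrichment(character(), hits), "empty")
})

test_that("Fisher p-values match exhaustive hypergeometric summation", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(20:1000, 1)
    k <- sample(5:min(n - 5, 200), 1)
    hit <- sample(0:n, 1)
    group <- sample(n, k)
    has <- seq_len(n) %in% sample(n, hit)
    tab <- matrix(c(sum(has[group]), k - sum(has[group]),
                    sum(has[-group]), (n - k) - sum(has[-group])),
                  2, byrow = TRUE)
    expect_equal(fisher.test(tab)$p.value, oracle_fisher_p(tab),
                 tolerance = 1e-8)
  }
})

test_that("BH adjustment matches an independent step-up oracle", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p))
  }
})

test_that("Zelda resampling test behaves at the trivial extremes", {
  ids <- sprintf("t%02d", 1:50)
  counts <- stats::setNames(rpois(50, 2) + 1, ids)
  # group = universe
  res <- zelda_sampling_test(ids, counts, n_samples = 50, seed = 1)
  expect_equal(res$enrichment, 1)
  # a zero-count group in a universe with sites: enrichment 0, p ~ 1
  counts0 <- counts; counts0[1:5] <- 0
  res0 <- zelda_sampling_test(ids[1:5], counts0, n_samples = 200, seed = 1)
  expect_equal(res0$enrichment, 0)
  expect_gt(res0$p_value, 0.95)
  expect_error(zelda_sampling_test(c(ids, "x"), counts), "larger than")
})

test_that("Zelda enrichment recovers a planted twofold group", {
  set.seed(31)
  n <- 1000
  ids <- sprintf("t%04d", 1:n)
  counts <- stats::setNames(rpois(n, 2), ids)
  grp <- ids[1:80]
  counts[grp] <- rpois(80, 4)
  res <- zelda_sampling_test(grp, counts, n_samples = 10000, seed = 9)
  expect_lt(abs(res$enrichment - 2), 0.35)
  expect_lt(res$p_value, 0.01)
})

test_that("co-occurrence detects independence and forced pairing", {
  set.seed(41)
  n <- 2000
  ids <- sprintf("t%04d", 1:n)
  a <- runif(n) < 0.3
  b <- runif(n) < 0.3
  hits <- data.frame(transcript_id = ids, A = a, B = b,
                     C = runif(n) < 0.5, stringsAsFactors = FALSE)
  res <- motif_cooccurrence(hits, motifs = c("A", "B", "C"))
  # independent plants: enrichment within a binomial CI of 1
  se <- sqrt((1 - 0.09) / (n * 0.09))
  expect_lt(abs(res$enrichment["A", "B"] - 1), 3 * se)
  expect_false(res$significant["A", "B"])
  # structural properties
  expect_equal(res$enrichment, t(res$enrichment))
  expect_true(all(is.na(diag(res$enrichment))))
  expect_setequal(res$order, c("A", "B", "C"))

  # pair planted always together in 10% of promoters, never apart
  d <- e <- rep(FALSE, n); together <- sample(n, n / 10)
  d[together] <- e[together] <- TRUE
  hits2 <- data.frame(transcript_id = ids, D = d, E = e,
                      F = runif(n) < 0.4)
  res2 <- motif_cooccurrence(hits2, motifs = c("D", "E", "F"))
  expect_equal(res2$enrichment["D", "E"], 10)
  expect_true(res2$significant["D", "E"])
  expect_error(motif_cooccurrence(hits2, motifs = c("D", "Zelda")), "absent")
})
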