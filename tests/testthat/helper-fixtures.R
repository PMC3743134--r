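# Shared fixture builders. Everything is generated in code; coordinates are
# 0-based half-open as in the package.

make_reads <- function(chrom, start, strand, len = 36L) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len), strand = strand,
             stringsAsFactors = FALSE)
}

# A coverage track from an explicit per-base vector.
make_track <- function(values, chrom = "chr1", n_reads = 1e6,
                       fragment_length = 200) {
  coverage_track(stats::setNames(list(values), chrom),
                 stats::setNames(length(values), chrom),
                 n_reads = n_reads, fragment_length = fragment_length)
}

make_transcripts <- function(gene_id, transcript_id, chrom, start, end,
                             strand, coding = TRUE, n_exons = 1L) {
  n <- length(transcript_id)
  data.frame(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = strand, coding = rep_len(coding, n),
             n_exons = rep_len(as.integer(n_exons), n),
             exon_sizes = as.character(end - start), exon_starts = "0",
             stringsAsFactors = FALSE)
}

# Hand-built per-replicate enrichment records for classification tests.
make_records <- function(transcript_id, gene_id, replicates,
                         tss_enrichment, tu_enrichment, tss_signal,
                         downstream_enrichment = 1) {
  do.call(rbind, lapply(seq_len(replicates), function(r) data.frame(
    gene_id = gene_id, transcript_id = transcript_id,
    replicate = paste0("r", r),
    tss_enrichment = tss_enrichment,
    downstream_enrichment = rep_len(downstream_enrichment,
                                    length(transcript_id)),
    tu_enrichment = tu_enrichment,
    tss_signal = tss_signal,
    pausing_index = pausing_index(tss_enrichment,
                                  rep_len(downstream_enrichment,
                                          length(transcript_id))),
    short_transcript = FALSE, wce_floored = FALSE,
    stringsAsFactors = FALSE)))
}

# Small simulation plan for fast end-to-end tests; any simulation_plan()
# argument can be overridden.
small_plan <- function(seed = 7, ...) {
  args <- list(
    n_genes = 150, read_depth_ip = 3e5, read_depth_wce = 3e5,
    group_proportions = c("pre-MBT not-paused" = 0.03, "pre-MBT dual" = 0.02,
                          "pre-MBT paused" = 0.01, "MBT maternal" = 0.30,
                          "MBT active" = 0.10, "MBT poised" = 0.15,
                          "unbound" = 0.39),
    seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_plan, args)
}

# Brute-force IUPAC scanner used as the independent oracle: expands the
# consensus to a regex character class and finds all (overlapping) matches
# on the requested strands with gregexpr lookahead.
oracle_scan <- function(sequence, consensus, directional, window_start,
                        window_end, seq_offset = -2000L) {
  map <- Biostrings::IUPAC_CODE_MAP
  rx <- paste0(vapply(strsplit(consensus, "")[[1]], function(ch)
    paste0("[", map[[ch]], "]"), ""), collapse = "")
  find_all <- function(s, rx) {
    m <- gregexpr(paste0("(?=", rx, ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1) integer() else as.integer(m)
  }
  L <- nchar(sequence)
  w <- nchar(consensus)
  pos <- seq_offset + find_all(sequence, rx) - 1L
  if (!directional) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sequence)))
    s_rev <- find_all(rc, rx)
    pos <- c(pos, seq_offset + L - s_rev)
  }
  sum(pos >= window_start & pos <= window_end)
}

# Exhaustive hypergeometric two-sided p-value for a 2x2 table: sum the
# probabilities of all tables (same margins) no more likely than the
# observed one.
oracle_fisher_p <- function(tab) {
  k <- tab[1, 1]
  m <- sum(tab[1, ])     # group 1 size
  n <- sum(tab[2, ])     # group 2 size
  K <- sum(tab[, 1])     # total successes
  support <- max(0, K - n):min(K, m)
  probs <- stats::dhyper(support, m, n, K)
  p_obs <- stats::dhyper(k, m, n, K)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent Benjamini-Hochberg step-up implementation.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}
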