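# Synthetic transcript annotation with planted gene-group structure.

#' Generate a synthetic transcript annotation and its ground truth
#'
#' Draws a gene set with the structural features the downstream statistics
#' assume: pre-MBT genes are shorter and more often intronless than
#' MBT-zygotic genes, a configurable fraction of genes carries 2-4
#' alternative TSSs, and both strands are represented. Chromosomes are sized
#' automatically (with ~60% intergenic headroom) unless the plan fixes them.
#'
#' The ground truth records, per gene, the planted group label, the primary
#' (signal-bearing) transcript, and whether that transcript is the shortest
#' of the gene; it also records the genomic coordinates at which PCR
#' duplicate-stack artifacts will be planted by [simulate_reads()].
#'
#' @param plan A [simulation_plan()].
#' @return A list with elements:
#'   * `transcripts`: data frame (gene_id, transcript_id, chrom, start, end,
#'     strand, coding, n_exons, exon_sizes, exon_starts); 0-based half-open
#'     coordinates.
#'   * `truth`: list with `genes` (per-gene labels and primary transcript),
#'     `artifacts` (planted duplicate-stack coordinates) and `chrom_sizes`.
#' @export
generate_annotation <- function(plan) {
  validate_plan(plan)
  empty <- list(
    transcripts = data.frame(
      gene_id = character(), transcript_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character(),
      coding = logical(), n_exons = integer(), exon_sizes = character(),
      exon_starts = character(), stringsAsFactors = FALSE),
    truth = list(genes = data.frame(), artifacts = data.frame(),
                 chrom_sizes = plan$chrom_sizes)
  )
  if (plan$n_genes == 0) return(empty)

  with_seed(derive_seed(plan$seed, "annotation"), {
    groups <- rep(gene_groups(),
                  apportion(plan$n_genes, plan$group_proportions[gene_groups()]))
    groups <- sample(groups)
    n <- length(groups)
    is_pre <- groups %in% pre_mbt_groups()

    med <- ifelse(is_pre, plan$pre_mbt_median_width, plan$mbt_median_width)
    width <- pmax(600L, as.integer(round(
      exp(rnorm(n, mean = log(med), sd = plan$width_sdlog)))))

    multi <- runif(n) < plan$multi_tss_fraction
    shortest_primary <- runif(n) < ifelse(is_pre,
                                          plan$shortest_tss_fraction[["pre_mbt"]],
                                          plan$shortest_tss_fraction[["other"]])
    # downstream alternative TSSs need room inside the transcript
    multi[multi & !shortest_primary & width < 900] <- FALSE
    n_alt <- ifelse(multi, sample(1:3, n, replace = TRUE), 0L)

    strand <- sample(c("+", "-"), n, replace = TRUE)
    coding <- runif(n) < ifelse(is_pre, plan$coding_prob[["pre_mbt"]],
                                plan$coding_prob[["other"]])
    p_intronless <- ifelse(is_pre, plan$intronless_prob[["pre_mbt"]],
                           ifelse(groups == "MBT maternal",
                                  plan$intronless_prob[["maternal"]],
                                  plan$intronless_prob[["other"]]))
    intronless <- runif(n) < p_intronless

    up_extra <- ifelse(multi & shortest_primary, 1500L, 0L)
    slot <- width + up_extra

    chrom_sizes <- plan$chrom_sizes
    if (is.null(chrom_sizes)) {
      size <- max(1e5, ceiling(1.6 * sum(slot) / plan$n_chroms))
      chrom_sizes <- stats::setNames(rep(as.integer(size), plan$n_chroms),
                                     paste0("chr", seq_len(plan$n_chroms)))
    }
    if (sum(chrom_sizes) < 1.1 * sum(slot))
      stop("chromosomes too small to place ", n, " genes without overlap")

    # greedy balanced placement: assign each gene to the emptiest chromosome
    free <- as.numeric(chrom_sizes)
    chrom_idx <- integer(n)
    for (i in seq_len(n)) {
      j <- which.max(free)
      chrom_idx[i] <- j
      free[j] <- free[j] - slot[i] - 1
    }

    offset <- integer(n)
    for (j in seq_along(chrom_sizes)) {
      on_j <- which(chrom_idx == j)
      if (!length(on_j)) next
      on_j <- on_j[sample.int(length(on_j))]
      total_gap <- chrom_sizes[j] - sum(slot[on_j])
      w <- runif(length(on_j) + 1)
      gaps <- floor(total_gap * w / sum(w))
      offset[on_j] <- cumsum(c(0L, slot[on_j][-length(on_j)])) +
        cumsum(gaps[-length(gaps)])
    }
    chrom <- names(chrom_sizes)[chrom_idx]

    tx_rows <- vector("list", n)
    gene_rows <- vector("list", n)
    for (i in seq_len(n)) {
      # local coordinates: TSS at local start, shared 3' end at up+width
      up <- up_extra[i]; wd <- width[i]
      starts_local <- up
      if (n_alt[i] > 0) {
        if (shortest_primary[i]) {
          d <- sample(seq(200L, up, by = 50L), n_alt[i])
          starts_local <- c(up, up - d)
        } else {
          d <- sample(seq(400L, wd - 400L, by = 50L),
                      min(n_alt[i], max(1, (wd - 800L) %/% 50L)))
          starts_local <- c(up, up + d)
        }
      }
      end_local <- up + wd
      k <- length(starts_local)
      if (strand[i] == "+") {
        g_start <- offset[i] + starts_local
        g_end <- rep(offset[i] + end_local, k)
      } else {
        g_start <- rep(offset[i] + slot[i] - end_local, k)
        g_end <- offset[i] + slot[i] - starts_local
      }
      tx_len <- g_end - g_start

      n_ex <- if (intronless[i]) rep(1L, k) else
        pmin(sample(2:6, 1), pmax(1L, tx_len %/% 150L))
      ex_sizes <- character(k); ex_starts <- character(k)
      for (t in seq_len(k)) {
        ne <- n_ex[t]
        if (ne == 1) {
          ex_sizes[t] <- as.character(tx_len[t]); ex_starts[t] <- "0"
        } else {
          cuts <- sort(sample(seq(50L, tx_len[t] - 50L, by = 10L),
                              2L * (ne - 1L)))
          bs <- c(0L, cuts[seq(2, length(cuts), by = 2)])
          be <- c(cuts[seq(1, length(cuts), by = 2)], tx_len[t])
          ex_sizes[t] <- paste(be - bs, collapse = ",")
          ex_starts[t] <- paste(bs, collapse = ",")
        }
      }
      gid <- sprintf("g%04d", i)
      tids <- sprintf("%s.t%d", gid, seq_len(k))
      tx_rows[[i]] <- data.frame(
        gene_id = gid, transcript_id = tids, chrom = chrom[i],
        start = as.integer(g_start), end = as.integer(g_end),
        strand = strand[i], coding = coding[i], n_exons = as.integer(n_ex),
        exon_sizes = ex_sizes, exon_starts = ex_starts,
        stringsAsFactors = FALSE)
      gene_rows[[i]] <- data.frame(
        gene_id = gid, group = groups[i], chrom = chrom[i], strand = strand[i],
        primary_transcript = tids[1],
        tss = if (strand[i] == "+") as.integer(g_start[1]) else
          as.integer(g_end[1] - 1L),
        start = as.integer(min(g_start)), end = as.integer(max(g_end)),
        width = as.integer(wd), coding = coding[i], intronless = intronless[i],
        multi_tss = n_alt[i] > 0, shortest_primary = shortest_primary[i],
        stringsAsFactors = FALSE)
    }
    transcripts <- do.call(rbind, tx_rows)
    genes <- do.call(rbind, gene_rows)

    artifacts <- data.frame(chrom = character(), start = integer(),
                            strand = character(), size = integer(),
                            stringsAsFactors = FALSE)
    if (plan$stack_artifact_count > 0) {
      a_chrom <- sample(names(chrom_sizes), plan$stack_artifact_count,
                        replace = TRUE)
      artifacts <- data.frame(
        chrom = a_chrom,
        start = as.integer(floor(runif(plan$stack_artifact_count) *
                                   (chrom_sizes[a_chrom] - 2L * plan$read_length)) +
                             plan$read_length),
        strand = sample(c("+", "-"), plan$stack_artifact_count, replace = TRUE),
        size = plan$stack_artifact_size,
        stringsAsFactors = FALSE)
    }

    list(transcripts = transcripts,
         truth = list(genes = genes, artifacts = artifacts,
                      chrom_sizes = chrom_sizes))
  })
}

#' TSS position of transcripts
#'
#' Strand-aware transcription start site as a 0-based base coordinate:
#' `start` on the plus strand, `end - 1` on the minus strand.
#'
#' @param transcripts Annotation data frame with start, end, strand.
#' @return Integer vector of TSS coordinates.
#' @export
tss_position <- function(transcripts) {
  ifelse(transcripts$strand == "+", transcripts$start,
         transcripts$end - 1L)
}
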