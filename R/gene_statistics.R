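# Gene-structure, conservation and expression-pattern group statistics.

#' Percentage of a count over a denominator, rounded to one decimal
#'
#' The convention used for all reported table percentages.
#'
#' @param count,total Counts.
#' @return Numeric percentage (one decimal).
#' @export
group_percentage <- function(count, total) {
  round(100 * count / total, 1)
}

# Per-gene structure features derived from annotation + a representative
# transcript choice.
.gene_features <- function(classes, transcripts) {
  tx_by_gene <- split(transcripts, transcripts$gene_id)
  feats <- lapply(seq_len(nrow(classes)), function(i) {
    g <- classes$gene_id[i]
    tx <- tx_by_gene[[g]]
    rep_id <- classes$transcript_id[i]
    if (is.na(rep_id) || !rep_id %in% tx$transcript_id)
      rep_id <- tx$transcript_id[1]
    rep_tx <- tx[tx$transcript_id == rep_id, ]
    widths <- tx$end - tx$start
    n_tss <- length(unique(tss_position(tx)))
    data.frame(
      gene_id = g, group = classes$group[i],
      width = rep_tx$end - rep_tx$start,
      multiple_tss = n_tss >= 2,
      uses_shortest = n_tss >= 2 &&
        (rep_tx$end - rep_tx$start) == min(widths),
      coding = rep_tx$coding,
      intronless = rep_tx$n_exons == 1,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, feats)
}

#' Gene-structure summary by group (transcript size, TSS usage, introns)
#'
#' For each gene group (and the pooled "All pre-MBT" and "MBT zygotic"
#' rows): gene count, median transcript width of the representative
#' transcript, number of genes with multiple distinct TSSs, number and
#' percentage of multi-TSS genes whose representative is the shortest
#' transcript, protein-coding count, and number and percentage of
#' protein-coding genes with no introns. Pre-MBT vs MBT-zygotic contrasts
#' are tested with a two-sided Mann-Whitney test on widths and two-sided
#' Fisher exact tests on the shortest-usage and intron 2x2 tables.
#'
#' @param classes Gene classification data frame (gene_id, transcript_id,
#'   group) from [classify_genes()].
#' @param transcripts Annotation data frame.
#' @return List: `table` (one row per group), `tests` (width Mann-Whitney,
#'   shortest-usage Fisher, intronless Fisher for pre-MBT vs MBT zygotic).
#' @export
structure_summary <- function(classes, transcripts) {
  classes <- classes[classes$group %in% bound_groups(), , drop = FALSE]
  feats <- .gene_features(classes, transcripts)

  row_groups <- list(
    "All pre-MBT" = pre_mbt_groups(),
    "MBT maternal" = "MBT maternal",
    "MBT zygotic" = c("MBT active", "MBT poised"),
    "MBT active" = "MBT active",
    "MBT poised" = "MBT poised")
  rows <- lapply(names(row_groups), function(nm) {
    f <- feats[feats$group %in% row_groups[[nm]], , drop = FALSE]
    if (nrow(f) == 0)
      return(data.frame(group = nm, n_genes = 0L, median_width = NA_real_,
                        multiple_tss = 0L, uses_shortest = 0L,
                        uses_shortest_pct = NA_real_, coding = 0L,
                        intronless = 0L, intronless_pct = NA_real_))
    multi <- f[f$multiple_tss, , drop = FALSE]
    cod <- f[f$coding, , drop = FALSE]
    data.frame(
      group = nm, n_genes = nrow(f),
      median_width = stats::median(f$width),
      multiple_tss = nrow(multi),
      uses_shortest = sum(multi$uses_shortest),
      uses_shortest_pct = if (nrow(multi)) group_percentage(
        sum(multi$uses_shortest), nrow(multi)) else NA_real_,
      coding = nrow(cod),
      intronless = sum(cod$intronless),
      intronless_pct = if (nrow(cod)) group_percentage(
        sum(cod$intronless), nrow(cod)) else NA_real_)
  })
  table <- do.call(rbind, rows)

  pre <- feats[feats$group %in% pre_mbt_groups(), , drop = FALSE]
  zyg <- feats[feats$group %in% c("MBT active", "MBT poised"), , drop = FALSE]
  tests <- NULL
  if (nrow(pre) > 0 && nrow(zyg) > 0) {
    mw <- stats::wilcox.test(pre$width, zyg$width)$p.value
    shortest_tab <- contingency_2x2(
      sum(pre$uses_shortest[pre$multiple_tss]), sum(pre$multiple_tss),
      sum(zyg$uses_shortest[zyg$multiple_tss]), sum(zyg$multiple_tss))
    intron_tab <- contingency_2x2(
      sum(pre$intronless[pre$coding]), sum(pre$coding),
      sum(zyg$intronless[zyg$coding]), sum(zyg$coding))
    tests <- data.frame(
      contrast = "pre-MBT vs MBT zygotic",
      width_mann_whitney_p = mw,
      shortest_fisher_p = if (all(is.finite(shortest_tab)) &&
                              sum(shortest_tab) > 0)
        stats::fisher.test(shortest_tab)$p.value else NA_real_,
      intronless_fisher_p = if (sum(intron_tab) > 0)
        stats::fisher.test(intron_tab)$p.value else NA_real_)
  }
  list(table = table, tests = tests)
}

#' Build a 2x2 contingency table from two (count, total) pairs
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return 2x2 integer matrix (rows = groups, cols = success/failure).
#' @export
contingency_2x2 <- function(k1, n1, k2, n2) {
  matrix(as.numeric(c(k1, n1 - k1, k2, n2 - k2)), nrow = 2, byrow = TRUE,
         dimnames = list(c("group1", "group2"), c("yes", "no")))
}

#' Mean conservation score per transcript, summarized by group
#'
#' Each transcript's score is the mean of the per-base track values along its
#' annotated span; track gaps (NA) are skipped and the covered fraction is
#' reported. Transcripts entirely outside the track are excluded (and
#' counted).
#'
#' @param track A `score_track` (per-chrom vectors, NA for gaps).
#' @param transcripts Annotation data frame.
#' @param classes Optional classification to attach a `group` and produce
#'   per-group quartile summaries.
#' @return List: `scores` (per-transcript mean, covered fraction, group),
#'   `summary` (per-group quartiles), `n_excluded`.
#' @export
conservation_summary <- function(track, transcripts, classes = NULL) {
  scores <- vapply(seq_len(nrow(transcripts)), function(i) {
    ch <- transcripts$chrom[i]
    v <- track$coverage[[ch]]
    if (is.null(v)) return(NA_real_)
    s <- max(transcripts$start[i], 0L) + 1L
    e <- min(transcripts$end[i], length(v))
    if (e < s) return(NA_real_)
    mean(as.numeric(S4Vectors::window(v, s, e)), na.rm = TRUE)
  }, numeric(1))
  covered <- vapply(seq_len(nrow(transcripts)), function(i) {
    ch <- transcripts$chrom[i]
    v <- track$coverage[[ch]]
    if (is.null(v)) return(0)
    s <- max(transcripts$start[i], 0L) + 1L
    e <- min(transcripts$end[i], length(v))
    if (e < s) return(0)
    w <- as.numeric(S4Vectors::window(v, s, e))
    sum(!is.na(w)) / (transcripts$end[i] - transcripts$start[i])
  }, numeric(1))
  out <- data.frame(transcript_id = transcripts$transcript_id,
                    gene_id = transcripts$gene_id,
                    mean_score = scores, covered_fraction = covered,
                    stringsAsFactors = FALSE)
  n_excluded <- sum(is.na(scores) | is.nan(scores))
  summary <- NULL
  if (!is.null(classes)) {
    out$group <- classes$group[match(out$gene_id, classes$gene_id)]
    ok <- !is.na(out$mean_score) & !is.na(out$group)
    summary <- do.call(rbind, lapply(split(out[ok, ], out$group[ok]),
                                     function(d) data.frame(
      group = d$group[1], n = nrow(d),
      q1 = stats::quantile(d$mean_score, 0.25, names = FALSE),
      median = stats::median(d$mean_score),
      q3 = stats::quantile(d$mean_score, 0.75, names = FALSE))))
    if (!is.null(summary)) rownames(summary) <- NULL
  }
  list(scores = out, summary = summary, n_excluded = n_excluded)
}

#' Earliest annotated expression enrichment per gene group
#'
#' From a gene -> ordered (stage, term) annotation table, removes 'maternal'
#' and 'no staining' entries, keeps only each gene's earliest remaining
#' annotation (in stage order), and computes per-(stage, term) category
#' enrichment for a gene group against the annotated universe with the same
#' exact-test + Benjamini-Hochberg machinery as the promoter element
#' analysis.
#'
#' @param patterns Data frame gene_id, stage (ordered integer), term.
#' @param group Character vector of gene ids.
#' @param universe Gene ids forming the universe; defaults to all annotated
#'   genes (after filtering).
#' @param alpha Significance level on the adjusted p-value.
#' @return List: `first` (earliest annotation per gene), `enrichment` (per
#'   category: observed, expected, enrichment, signed, p, q, significant),
#'   `n_unannotated` (genes with no remaining annotation).
#' @export
first_expression_enrichment <- function(patterns, group, universe = NULL,
                                        alpha = 0.05) {
  keep <- !(patterns$term %in% c("maternal", "no staining"))
  filt <- patterns[keep, , drop = FALSE]
  filt <- filt[order(filt$gene_id, filt$stage), , drop = FALSE]
  first <- filt[!duplicated(filt$gene_id), , drop = FALSE]
  n_unannotated <- length(setdiff(unique(patterns$gene_id), first$gene_id))

  if (is.null(universe)) universe <- first$gene_id
  first <- first[first$gene_id %in% universe, , drop = FALSE]
  group <- intersect(group, first$gene_id)
  if (!length(group)) stop("no group genes with a remaining annotation")

  first$category <- paste0("stage", first$stage, ":", first$term)
  cats <- sort(unique(first$category))
  # presence table: gene x category (a gene has exactly one category)
  hits <- data.frame(transcript_id = first$gene_id, stringsAsFactors = FALSE)
  for (cat in cats) hits[[cat]] <- first$category == cat
  enr <- element_enrichment(group, hits, motifs = cats,
                            universe = first$gene_id, alpha = alpha)
  names(enr)[names(enr) == "motif"] <- "category"
  list(first = first[, c("gene_id", "stage", "term")], enrichment = enr,
       n_unannotated = n_unannotated)
}
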