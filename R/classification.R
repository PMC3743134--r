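# Identification and classification of pre-MBT and MBT gene groups.

# Distance from a TSS point to the nearest interval in a peak set (0 when the
# TSS lies inside a peak). Half-open peak intervals.
.peak_distance <- function(chrom, tss, peaks) {
  vapply(seq_along(tss), function(i) {
    p <- peaks[peaks$chrom == chrom[i], , drop = FALSE]
    if (nrow(p) == 0) return(Inf)
    inside <- tss[i] >= p$start & tss[i] < p$end
    if (any(inside)) return(0)
    min(pmax(p$start - tss[i], tss[i] - (p$end - 1L)))
  }, numeric(1))
}

#' Identify pre-MBT candidate transcripts
#'
#' A transcript qualifies when (a) its TSS enrichment is at least
#' `min_fold`-fold over WCE in every replicate, (b) its IP-normalized TSS
#' signal is in the top `1 - percentile` of all transcripts in every
#' replicate (so high enrichment is backed by high absolute Pol II signal),
#' and (c) a TBP peak lies within `max_tss_distance` bp of its TSS. The
#' TBP-proximity filter operationalizes the read-through screen: transcripts
#' passing (a) and (b) but failing (c) are returned in the rejection report
#' as likely read-through signal from a neighboring gene.
#'
#' @param records Per-replicate enrichment records
#'   ([enrichment_records()]), covering all transcripts in all replicates.
#' @param transcripts Annotation data frame (for TSS positions).
#' @param tbp_peaks Peak data frame (chrom, start, end); empty peak set
#'   rejects all candidates with a warning.
#' @param min_fold TSS enrichment cutoff (boundary inclusive).
#' @param percentile Signal percentile cutoff; computed per replicate with
#'   linear interpolation over all transcripts.
#' @param max_tss_distance Maximum TBP peak distance in bp (boundary
#'   inclusive: a peak exactly at this distance qualifies).
#' @return List: `candidates` (qualifying transcript ids), `genes`
#'   (data frame gene_id, transcript_id of the representative: the
#'   qualifying transcript with highest mean TSS signal, ties broken by mean
#'   TU enrichment), `rejected` (report of transcripts failing only the TBP
#'   filter, with nearest-peak distance).
#' @export
identify_pre_mbt <- function(records, transcripts, tbp_peaks,
                             min_fold = 2, percentile = 0.99,
                             max_tss_distance = 500) {
  stopifnot(length(unique(records$replicate)) >= 1)
  sp <- split(records, records$replicate)
  pass_ab <- Reduce(`&`, lapply(sp, function(d) {
    d <- d[match(transcripts$transcript_id, d$transcript_id), ]
    cutoff <- stats::quantile(d$tss_signal, percentile, na.rm = TRUE,
                              names = FALSE)
    d$tss_enrichment >= min_fold & d$tss_signal >= cutoff
  }))
  pass_ab[is.na(pass_ab)] <- FALSE

  if (nrow(tbp_peaks) == 0 && any(pass_ab))
    warning("empty TBP peak set: all pre-MBT candidates rejected")
  tss <- tss_position(transcripts)
  dist <- rep(Inf, nrow(transcripts))
  dist[pass_ab] <- .peak_distance(transcripts$chrom[pass_ab], tss[pass_ab],
                                  tbp_peaks)
  pass_c <- dist <= max_tss_distance

  candidates <- transcripts$transcript_id[pass_ab & pass_c]
  rejected <- data.frame(
    transcript_id = transcripts$transcript_id[pass_ab & !pass_c],
    gene_id = transcripts$gene_id[pass_ab & !pass_c],
    nearest_tbp_peak = dist[pass_ab & !pass_c],
    stringsAsFactors = FALSE)

  genes <- .representative_transcripts(records, transcripts, candidates)
  list(candidates = candidates, genes = genes, rejected = rejected)
}

# Per gene, pick the qualifying transcript with the highest mean TSS signal,
# breaking ties with the mean TU enrichment (then lexicographic id for full
# determinism).
.representative_transcripts <- function(records, transcripts, qualifying) {
  if (!length(qualifying))
    return(data.frame(gene_id = character(), transcript_id = character(),
                      stringsAsFactors = FALSE))
  summ <- summarize_enrichment(
    records[records$transcript_id %in% qualifying, , drop = FALSE])
  summ <- summ[order(summ$gene_id, -summ$mean_tss_signal,
                     -summ$mean_tu_enrichment, summ$transcript_id), ]
  reps <- summ[!duplicated(summ$gene_id), c("gene_id", "transcript_id")]
  rownames(reps) <- NULL
  reps
}

#' Custom transcription start site from a TBP coverage maximum
#'
#' For a gene whose Pol II signal originates from an un-annotated start site,
#' place the TSS `offset` bp downstream (in transcript orientation) of the
#' position of maximum TBP coverage within a peak. Plateau maxima resolve to
#' the 5'-most position in transcript orientation.
#'
#' @param tbp_coverage A `coverage_track` of the TBP sample.
#' @param peak One-row data frame or list with chrom, start, end.
#' @param strand Transcript strand ("+" or "-").
#' @param offset Downstream shift in bp.
#' @return Integer TSS coordinate (0-based).
#' @export
assign_custom_tss <- function(tbp_coverage, peak, strand, offset = 19L) {
  stopifnot(peak$end > peak$start, strand %in% c("+", "-"))
  v <- coverage_window(tbp_coverage, peak$chrom, peak$start, peak$end)
  if (all(is.na(v)) || max(v, na.rm = TRUE) == 0)
    stop("all-zero TBP coverage in peak; cannot place a custom TSS")
  at_max <- which(v == max(v, na.rm = TRUE))
  pos <- if (strand == "+") peak$start + min(at_max) - 1L
  else peak$start + max(at_max) - 1L
  as.integer(pos + if (strand == "+") offset else -offset)
}

#' Classify pre-MBT genes into paused / dual / not-paused
#'
#' A gene is 'pre-MBT paused' when the mean (across replicates) TU
#' enrichment of its representative transcript is below `tu_cutoff`;
#' otherwise 'pre-MBT dual' when its reference TSS-enrichment percentile (an
#' external late-stage dataset) is in the top `dual_top_fraction`; otherwise
#' 'pre-MBT not-paused'.
#'
#' @param pre_mbt `genes` element of [identify_pre_mbt()].
#' @param records Per-replicate enrichment records.
#' @param reference_ranking Data frame transcript_id, percentile. Candidates
#'   missing from it fall back to 'not-paused' with a warning.
#' @param tu_cutoff Mean TU enrichment cutoff (strict: `< tu_cutoff`).
#' @param dual_top_fraction Reference top fraction (boundary inclusive:
#'   percentile >= 1 - dual_top_fraction).
#' @return Data frame: gene_id, transcript_id, group.
#' @export
classify_pre_mbt <- function(pre_mbt, records, reference_ranking,
                             tu_cutoff = 1, dual_top_fraction = 0.2) {
  if (nrow(pre_mbt) == 0)
    return(data.frame(gene_id = character(), transcript_id = character(),
                      group = character(), stringsAsFactors = FALSE))
  summ <- summarize_enrichment(
    records[records$transcript_id %in% pre_mbt$transcript_id, , drop = FALSE])
  summ <- summ[match(pre_mbt$transcript_id, summ$transcript_id), ]
  ref <- reference_ranking$percentile[
    match(pre_mbt$transcript_id, reference_ranking$transcript_id)]
  if (any(is.na(ref))) {
    warning(sum(is.na(ref)),
            " candidate(s) missing from reference ranking; treated as",
            " below the dual cutoff")
    ref[is.na(ref)] <- 0
  }
  group <- ifelse(summ$mean_tu_enrichment < tu_cutoff, "pre-MBT paused",
                  ifelse(ref >= 1 - dual_top_fraction, "pre-MBT dual",
                         "pre-MBT not-paused"))
  data.frame(gene_id = pre_mbt$gene_id, transcript_id = pre_mbt$transcript_id,
             group = group, stringsAsFactors = FALSE)
}

#' Identify MBT genes and their representative transcripts
#'
#' A transcript qualifies when its TSS enrichment is at least `min_fold` in
#' every replicate. Per gene the representative is the qualifying transcript
#' with the highest mean TSS signal, ties broken by mean TU enrichment.
#' Genes already identified as pre-MBT are reported separately, not
#' re-classified.
#'
#' @param records Per-replicate enrichment records for the MBT stage.
#' @param transcripts Annotation data frame.
#' @param pre_mbt_genes Character vector of pre-MBT gene ids.
#' @param min_fold TSS enrichment cutoff (boundary inclusive: "at least
#'   twofold").
#' @return List: `genes` (gene_id, transcript_id), `pre_mbt_also` (pre-MBT
#'   genes that also qualify at the MBT stage).
#' @export
identify_mbt <- function(records, transcripts, pre_mbt_genes = character(),
                         min_fold = 2) {
  sp <- split(records, records$replicate)
  pass <- Reduce(`&`, lapply(sp, function(d) {
    d <- d[match(transcripts$transcript_id, d$transcript_id), ]
    d$tss_enrichment >= min_fold
  }))
  pass[is.na(pass)] <- FALSE
  qualifying <- transcripts$transcript_id[pass]
  reps <- .representative_transcripts(records, transcripts, qualifying)
  is_pre <- reps$gene_id %in% pre_mbt_genes
  list(genes = reps[!is_pre, , drop = FALSE],
       pre_mbt_also = reps$gene_id[is_pre])
}

#' Classify MBT genes by maternal deposition and zygotic expression
#'
#' 'MBT maternal' when nc10 RPKM >= `maternal_min` (maternally provided
#' transcripts are already present at nuclear cycle 10); otherwise
#' 'MBT active' when nc14D RPKM >= `active_min`; otherwise 'MBT poised'.
#'
#' @param mbt_genes Data frame gene_id, transcript_id from [identify_mbt()].
#' @param expression Expression table with gene_id, nc10, nc14D columns.
#'   Genes missing from it are treated as RPKM 0 (with a message); negative
#'   RPKM values are rejected.
#' @param maternal_min,active_min RPKM cutoffs (boundary inclusive).
#' @return Data frame: gene_id, transcript_id, group.
#' @export
classify_mbt <- function(mbt_genes, expression, maternal_min = 1,
                         active_min = 5) {
  if (any(expression$nc10 < 0, na.rm = TRUE) ||
      any(expression$nc14D < 0, na.rm = TRUE))
    stop("negative RPKM values in expression table")
  m <- match(mbt_genes$gene_id, expression$gene_id)
  if (anyNA(m))
    message(sum(is.na(m)), " MBT gene(s) missing from expression table;",
            " treated as RPKM 0")
  nc10 <- ifelse(is.na(m), 0, expression$nc10[m])
  nc14D <- ifelse(is.na(m), 0, expression$nc14D[m])
  group <- ifelse(nc10 >= maternal_min, "MBT maternal",
                  ifelse(nc14D >= active_min, "MBT active", "MBT poised"))
  data.frame(gene_id = mbt_genes$gene_id,
             transcript_id = mbt_genes$transcript_id,
             group = group, stringsAsFactors = FALSE)
}

#' Filter genes with evidence of maternally deposited mRNA
#'
#' For expression time-course analyses: a gene is removed when its total
#' nc10 RPKM exceeds `rpkm_cutoff`, or when its maternal nc10 expression is
#' at least `maternal_fold`-fold above its zygotic nc10 expression.
#'
#' @param expression Table with gene_id, nc10, nc10_maternal, nc10_zygotic.
#' @param rpkm_cutoff nc10 RPKM cutoff (strict: `> rpkm_cutoff` removes).
#' @param maternal_fold Maternal/zygotic ratio cutoff (boundary inclusive).
#' @return Character vector of retained gene ids.
#' @export
maternal_timecourse_filter <- function(expression, rpkm_cutoff = 16,
                                       maternal_fold = 2) {
  stopifnot(all(c("gene_id", "nc10", "nc10_maternal", "nc10_zygotic") %in%
                  names(expression)))
  removed <- expression$nc10 > rpkm_cutoff |
    expression$nc10_maternal >= maternal_fold * expression$nc10_zygotic
  expression$gene_id[!removed]
}

#' End-to-end gene classification
#'
#' Runs pre-MBT identification/classification on the pre-MBT stage records
#' and MBT identification/classification on the MBT stage records, and
#' assigns every annotated gene to one of the six study groups or
#' 'unclassified'.
#'
#' @param pre_records,mbt_records Per-replicate enrichment records for the
#'   two stages.
#' @param transcripts Annotation data frame.
#' @param tbp_peaks TBP peak set.
#' @param expression Expression table.
#' @param reference_ranking Reference TSS-enrichment percentiles.
#' @param min_fold,percentile,max_tss_distance,tu_cutoff,dual_top_fraction,
#'   maternal_min,active_min Thresholds; see the stage functions.
#' @return List: `classes` (gene_id, transcript_id, group, flags for every
#'   gene), `pre_mbt`, `mbt` (stage outputs), `log` (record counts).
#' @export
classify_genes <- function(pre_records, mbt_records, transcripts, tbp_peaks,
                           expression, reference_ranking,
                           min_fold = 2, percentile = 0.99,
                           max_tss_distance = 500, tu_cutoff = 1,
                           dual_top_fraction = 0.2, maternal_min = 1,
                           active_min = 5) {
  pre <- identify_pre_mbt(pre_records, transcripts, tbp_peaks,
                          min_fold = min_fold, percentile = percentile,
                          max_tss_distance = max_tss_distance)
  pre_classes <- classify_pre_mbt(pre$genes, pre_records, reference_ranking,
                                  tu_cutoff = tu_cutoff,
                                  dual_top_fraction = dual_top_fraction)
  mbt <- identify_mbt(mbt_records, transcripts,
                      pre_mbt_genes = pre_classes$gene_id,
                      min_fold = min_fold)
  mbt_classes <- classify_mbt(mbt$genes, expression,
                              maternal_min = maternal_min,
                              active_min = active_min)

  all_genes <- unique(transcripts$gene_id)
  classes <- rbind(pre_classes, mbt_classes)
  m <- match(all_genes, classes$gene_id)
  out <- data.frame(
    gene_id = all_genes,
    transcript_id = ifelse(is.na(m), NA_character_, classes$transcript_id[m]),
    group = ifelse(is.na(m), "unclassified", classes$group[m]),
    rejected_no_tbp_peak = all_genes %in% pre$rejected$gene_id &
      is.na(m), stringsAsFactors = FALSE)
  log <- list(pre_mbt_candidates = length(pre$candidates),
              pre_mbt_rejected = nrow(pre$rejected),
              pre_mbt_genes = nrow(pre_classes),
              mbt_genes = nrow(mbt_classes),
              mbt_also_pre_mbt = length(mbt$pre_mbt_also))
  list(classes = out, pre_mbt = pre, mbt = mbt, log = log)
}
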