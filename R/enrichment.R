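# Region enrichments over input and the pausing (stalling) index.

#' Define TSS, downstream and TU regions for transcripts
#'
#' In transcript orientation: the TSS region is the first 200 bp of the
#' transcript, the downstream region is +201 to +400 bp, and the
#' transcription-unit (TU) region is +401 to the transcript end -- except for
#' transcripts shorter than 600 bp, whose TU region is the entire transcript.
#' Transcripts shorter than 400 bp get a downstream region truncated at the
#' transcript end; at 200 bp or less the downstream region is empty and the
#' pausing index is undefined. On the minus strand all regions are reflected
#' genomically.
#'
#' @param transcripts Annotation data frame (transcript_id, chrom, start,
#'   end, strand; 0-based half-open).
#' @return Data frame with one row per transcript x region
#'   (`region` in `"tss"`, `"downstream"`, `"tu"`), genomic start/end.
#' @export
define_regions <- function(transcripts) {
  len <- transcripts$end - transcripts$start
  stopifnot(all(len >= 1))
  # local (transcript-oriented) half-open intervals
  tss_lo <- 0L
  tss_hi <- pmin(200L, len)
  dn_lo <- pmin(200L, len)
  dn_hi <- pmin(400L, len)
  tu_lo <- ifelse(len < 600L, 0L, 400L)
  tu_hi <- len

  local_to_genomic <- function(lo, hi) {
    plus <- transcripts$strand == "+"
    gs <- ifelse(plus, transcripts$start + lo, transcripts$end - hi)
    ge <- ifelse(plus, transcripts$start + hi, transcripts$end - lo)
    list(start = as.integer(gs), end = as.integer(ge))
  }
  one <- function(region, lo, hi) {
    g <- local_to_genomic(lo, hi)
    data.frame(transcript_id = transcripts$transcript_id,
               chrom = transcripts$chrom, region = region,
               start = g$start, end = g$end, stringsAsFactors = FALSE)
  }
  out <- rbind(one("tss", tss_lo, tss_hi),
               one("downstream", dn_lo, dn_hi),
               one("tu", tu_lo, tu_hi))
  rownames(out) <- NULL
  out
}

#' Input-normalized region enrichment
#'
#' Enrichment = (IP signal / [IP read count x IP fragment length]) /
#' (WCE signal / [WCE read count x WCE fragment length]), where "signal" is
#' the coverage sum over the region. A WCE region signal of zero is floored
#' at one fragment-equivalent (fragment_length x 1) and flagged.
#'
#' @param ip,wce `coverage_track`s carrying read count and fragment length.
#' @param regions Data frame with chrom, start, end.
#' @return Data frame: ip_signal, wce_signal, enrichment,
#'   ip_normalized_signal, wce_floored. Empty regions yield NA enrichment.
#' @export
region_enrichment <- function(ip, wce, regions) {
  if (ip$n_reads <= 0 || wce$n_reads <= 0)
    stop("read counts must be > 0 for enrichment")
  ip_sig <- region_signal(ip, regions)
  wce_sig <- region_signal(wce, regions)
  nonempty <- regions$end > regions$start
  floored <- nonempty & wce_sig == 0
  wce_eff <- ifelse(floored, wce$fragment_length, wce_sig)
  ip_norm <- ip_sig / (ip$n_reads * ip$fragment_length)
  wce_norm <- wce_eff / (wce$n_reads * wce$fragment_length)
  enr <- ifelse(nonempty, ip_norm / wce_norm, NA_real_)
  data.frame(ip_signal = ip_sig, wce_signal = wce_sig,
             enrichment = enr, ip_normalized_signal = ip_norm,
             wce_floored = floored)
}

#' Pausing (stalling) index
#'
#' log2(TSS enrichment) - log2(downstream enrichment) after flooring both
#' enrichment values at 1 (background). Per-gene indexes are averaged over
#' replicates downstream.
#'
#' @param tss_enrichment,downstream_enrichment Non-negative enrichment
#'   ratios (vectorized).
#' @return Pausing index in log2 units (NA where downstream is NA).
#' @export
pausing_index <- function(tss_enrichment, downstream_enrichment) {
  stopifnot(all(tss_enrichment >= 0, na.rm = TRUE),
            all(downstream_enrichment >= 0, na.rm = TRUE))
  log2(pmax(tss_enrichment, 1)) - log2(pmax(downstream_enrichment, 1))
}

#' Per-transcript enrichment records for one replicate
#'
#' Computes TSS, downstream and TU enrichments, the IP-normalized TSS signal
#' (the numerator of the enrichment formula, used by the 99th-percentile
#' identification filter) and the pausing index for every transcript.
#'
#' @param ip,wce `coverage_track`s for the IP and WCE libraries.
#' @param transcripts Annotation data frame.
#' @param replicate Replicate label stored in the records.
#' @return Data frame with one row per transcript: gene_id, transcript_id,
#'   replicate, tss/downstream/tu enrichment, tss_signal (IP-normalized),
#'   pausing_index, flags (short_transcript, wce_floored).
#' @export
compute_enrichment <- function(ip, wce, transcripts, replicate = "r1") {
  regions <- define_regions(transcripts)
  enr <- region_enrichment(ip, wce, regions)
  enr$transcript_id <- regions$transcript_id
  enr$region <- regions$region
  wide <- function(region, col) {
    sel <- enr[enr$region == region, ]
    sel[match(transcripts$transcript_id, sel$transcript_id), col]
  }
  tss <- wide("tss", "enrichment")
  dn <- wide("downstream", "enrichment")
  tu <- wide("tu", "enrichment")
  len <- transcripts$end - transcripts$start
  out <- data.frame(
    gene_id = transcripts$gene_id,
    transcript_id = transcripts$transcript_id,
    replicate = replicate,
    tss_enrichment = tss,
    downstream_enrichment = dn,
    tu_enrichment = tu,
    tss_signal = wide("tss", "ip_normalized_signal"),
    pausing_index = ifelse(is.na(dn), NA_real_, pausing_index(tss, dn)),
    short_transcript = len <= 200L,
    wce_floored = wide("tss", "wce_floored") | wide("downstream", "wce_floored") |
      wide("tu", "wce_floored"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Enrichment records for a set of replicates
#'
#' Runs read extension, duplicate-stack filtering, coverage and
#' [compute_enrichment()] for each IP/WCE replicate pair.
#'
#' @param replicate_pairs List of lists with `ip` and `wce` [read_set()]s
#'   (unextended), as produced by [simulate_reads()].
#' @param transcripts Annotation data frame.
#' @param chrom_sizes Named chromosome sizes.
#' @param max_duplicates Duplicate-stack cutoff (see
#'   [remove_duplicate_stacks()]).
#' @return Data frame of stacked per-replicate records ("r1", "r2", ...).
#' @export
enrichment_records <- function(replicate_pairs, transcripts, chrom_sizes,
                               max_duplicates = 10) {
  recs <- lapply(seq_along(replicate_pairs), function(r) {
    pair <- replicate_pairs[[r]]
    tracks <- lapply(pair[c("ip", "wce")], function(rs) {
      filtered <- remove_duplicate_stacks(rs, max_duplicates)$reads
      compute_coverage(extend_reads(filtered, chrom_sizes = chrom_sizes),
                       chrom_sizes)
    })
    compute_enrichment(tracks$ip, tracks$wce, transcripts,
                       replicate = paste0("r", r))
  })
  do.call(rbind, recs)
}

#' Per-transcript summary over replicates
#'
#' Means of the enrichment quantities across replicates, plus the
#' replicate-averaged pausing index ("stalling indexes for all replicates
#' were averaged").
#'
#' @param records Data frame from [compute_enrichment()] /
#'   [enrichment_records()] over one or more replicates.
#' @return One row per transcript with mean_tss/downstream/tu enrichment,
#'   mean_tss_signal, mean_pausing_index, n_replicates.
#' @export
summarize_enrichment <- function(records) {
  sp <- split(records, records$transcript_id)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    gene_id = d$gene_id[1],
    transcript_id = d$transcript_id[1],
    n_replicates = nrow(d),
    mean_tss_enrichment = mean(d$tss_enrichment),
    mean_downstream_enrichment = mean(d$downstream_enrichment),
    mean_tu_enrichment = mean(d$tu_enrichment),
    mean_tss_signal = mean(d$tss_signal),
    mean_pausing_index = mean(d$pausing_index),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$transcript_id), ]
}
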