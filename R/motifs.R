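# Core-promoter element scanning and group-wise enrichment statistics.

#' Core-promoter element catalog
#'
#' The eleven Drosophila core-promoter elements scored by the pipeline, with
#' IUPAC consensus, directionality and TSS-relative search window (bp; the
#' window constrains the 5'-most matched base in the scanned orientation).
#' DRE, Ohler1/6/7 mark dispersed (housekeeping) initiation; TATA, Inr, DPE,
#' PB and MTE mark focused initiation and pausing; GAGA is the GAGA-factor
#' element and Zelda the TAGteam activator motif scanned over 2 kb upstream.
#'
#' The GAGA match string defaults to "GAGAG" (the canonical GAF element);
#' pass `gaga_consensus = "GAGA"` to restore the shorter variant.
#'
#' @param gaga_consensus Match string used for the GAGA element.
#' @return Data frame: name, consensus, directional, window_start,
#'   window_end.
#' @export
motif_catalog <- function(gaga_consensus = "GAGAG") {
  df <- data.frame(
    name = c("DRE", "Ohler1", "Ohler6", "Ohler7", "TATA", "Inr", "DPE",
             "PB", "MTE", "GAGA", "Zelda"),
    consensus = c("WATCGATW", "YGGTCACACTR", "YRGTATWTTY", "CAKCNCTR",
                  "STATAWAWR", "TCAKTY", "KCGGTTSK", "KCGRWCG", "CSARCSSA",
                  gaga_consensus, "YAGGTAR"),
    directional = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                    FALSE, FALSE),
    window_start = c(-100L, -100L, -150L, -100L, -100L, -50L, 0L, -50L, 0L,
                     -100L, -2000L),
    window_end = c(0L, 50L, 25L, 50L, 0L, 50L, 75L, 100L, 30L, 0L, 0L),
    stringsAsFactors = FALSE)
  df
}

.check_iupac <- function(consensus) {
  letters <- strsplit(consensus, "")[[1]]
  bad <- setdiff(letters, names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad))
    stop("invalid IUPAC letter(s) in consensus '", consensus, "': ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Scan one promoter sequence for a motif
#'
#' Exact (no-mismatch) IUPAC matching. Directional motifs are scanned on the
#' sense strand only; non-directional motifs on both strands. An occurrence
#' counts when the 5'-most matched base, in the scanned orientation, lies
#' within the motif's TSS-relative window. `N` bases in the subject never
#' match any consensus letter.
#'
#' @param sequence Promoter sequence (character or
#'   [Biostrings::DNAString]) anchored at the TSS.
#' @param motif One-row data frame or list with consensus, directional,
#'   window_start, window_end (see [motif_catalog()]).
#' @param seq_offset TSS-relative offset of the first sequence base
#'   (e.g. -2000 for a sequence spanning -2000..+99).
#' @return List: `count`, `positions` (TSS-relative offsets of the 5'-most
#'   matched base), `strand`.
#' @export
scan_motif <- function(sequence, motif, seq_offset = -2000L) {
  .check_iupac(motif$consensus)
  subject <- if (methods::is(sequence, "DNAString")) sequence
  else Biostrings::DNAString(as.character(sequence))
  pat <- Biostrings::DNAString(motif$consensus)
  w <- length(pat)

  fwd <- Biostrings::matchPattern(pat, subject, fixed = "subject")
  pos <- seq_offset + IRanges::start(fwd) - 1L
  strand <- rep("+", length(pos))
  if (!motif$directional) {
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                    subject, fixed = "subject")
    # 5'-most base of a reverse-orientation occurrence is its sense-strand
    # end position
    rpos <- seq_offset + IRanges::end(rev) - 1L
    pos <- c(pos, rpos)
    strand <- c(strand, rep("-", length(rpos)))
  }
  keep <- pos >= motif$window_start & pos <= motif$window_end
  ord <- order(pos[keep], strand[keep])
  list(count = sum(keep), positions = pos[keep][ord],
       strand = strand[keep][ord])
}

#' Scan a promoter set against a motif catalog
#'
#' @param promoters Named [Biostrings::DNAStringSet] (or named character
#'   vector), one sequence per transcript, all anchored at the same
#'   TSS-relative offset.
#' @param catalog Motif catalog ([motif_catalog()]).
#' @param seq_offset TSS-relative offset of the first base.
#' @return A motif hit table: data frame with transcript_id and, per motif,
#'   `<name>_count` and logical `<name>` presence columns.
#' @export
scan_promoters <- function(promoters, catalog = motif_catalog(),
                           seq_offset = -2000L) {
  ids <- names(promoters)
  stopifnot(!is.null(ids))
  out <- data.frame(transcript_id = ids, stringsAsFactors = FALSE)
  seqs <- lapply(seq_along(promoters), function(i)
    Biostrings::DNAString(as.character(promoters[[i]])))
  for (k in seq_len(nrow(catalog))) {
    motif <- catalog[k, ]
    counts <- vapply(seqs, function(s)
      scan_motif(s, motif, seq_offset)$count, integer(1))
    out[[paste0(motif$name, "_count")]] <- counts
    out[[motif$name]] <- counts >= 1L
  }
  out
}

# Signed enrichment: values below 1 are reported as the negative reciprocal
# (depletion); |signed| >= 1 always.
signed_enrichment <- function(enrichment) {
  ifelse(is.na(enrichment) | enrichment >= 1, enrichment, -1 / enrichment)
}

#' Promoter element enrichment for a transcript group
#'
#' Observed = fraction of group transcripts with the element; Expected = the
#' universe fraction; Enrichment = Observed/Expected, reported as the
#' negative reciprocal when below 1. P-values come from a two-sided Fisher
#' exact test on the (in group vs not) x (has element vs not) table, adjusted
#' across motifs with Benjamini-Hochberg; significance at q <= `alpha`.
#'
#' @param group Character vector of transcript ids (subset of the universe).
#' @param hits Hit table from [scan_promoters()] (presence columns).
#' @param motifs Motif names to test; default all presence columns.
#' @param universe Transcript ids forming the universe; defaults to all
#'   transcripts in `hits`.
#' @param alpha Significance level on the adjusted p-value.
#' @return Data frame per motif: observed, expected, enrichment,
#'   signed_enrichment, p_value, q_value, significant.
#' @export
element_enrichment <- function(group, hits, motifs = NULL,
                               universe = hits$transcript_id, alpha = 0.05) {
  if (!length(group)) stop("empty transcript group")
  if (!all(group %in% universe)) stop("group must be a subset of universe")
  if (is.null(motifs))
    motifs <- setdiff(names(hits)[vapply(hits, is.logical, TRUE)],
                      "transcript_id")
  missing <- setdiff(motifs, names(hits))
  if (length(missing))
    stop("motif(s) absent from hit table: ", paste(missing, collapse = ", "))
  hu <- hits[match(universe, hits$transcript_id), , drop = FALSE]
  in_group <- universe %in% group
  rows <- lapply(motifs, function(mo) {
    has <- hu[[mo]]
    observed <- mean(has[in_group])
    expected <- mean(has)
    enr <- if (expected == 0) NA_real_ else observed / expected
    tab <- matrix(c(sum(in_group & has), sum(in_group & !has),
                    sum(!in_group & has), sum(!in_group & !has)),
                  nrow = 2, byrow = TRUE)
    p <- stats::fisher.test(tab)$p.value
    data.frame(motif = mo, n_group = sum(in_group),
               observed = observed, expected = expected,
               enrichment = enr, signed_enrichment = signed_enrichment(enr),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value <= alpha
  rownames(out) <- NULL
  out
}

#' Resampling enrichment test for per-promoter motif counts
#'
#' For motifs counted per promoter rather than scored as present/absent
#' (Zelda): enrichment is the mean count per transcript in the group divided
#' by the mean count in the universe. The empirical p-value is the fraction
#' of `n_samples` random equal-size transcript samples (drawn without
#' replacement from the universe) with strictly higher enrichment.
#'
#' @param group Transcript ids.
#' @param counts Named numeric vector of per-transcript motif counts (the
#'   `<motif>_count` column of [scan_promoters()], named by transcript id).
#' @param universe Transcript ids; defaults to all names of `counts`.
#' @param n_samples Number of random samples.
#' @param seed Integer seed making the test deterministic.
#' @return List: `enrichment`, `p_value`, `n_samples`.
#' @export
zelda_sampling_test <- function(group, counts, universe = names(counts),
                                n_samples = 10000, seed = 1L) {
  stopifnot(n_samples >= 1)
  if (length(group) > length(universe))
    stop("group larger than universe")
  cu <- counts[universe]
  if (anyNA(cu)) stop("universe transcripts missing from counts")
  obs <- mean(counts[group]) / mean(cu)
  k <- length(group)
  with_seed(seed, {
    samp <- vapply(seq_len(n_samples), function(i)
      mean(cu[sample.int(length(cu), k)]), numeric(1)) / mean(cu)
  })
  list(enrichment = obs, p_value = mean(samp > obs), n_samples = n_samples)
}

#' Pairwise co-occurrence of promoter elements
#'
#' For each motif pair, the observed co-occurrence frequency is compared with
#' the product of the marginal frequencies (independence); p-values are
#' two-sided Fisher exact tests on the 2x2 presence table. The display order
#' comes from hierarchical clustering of the enrichment matrix (Euclidean
#' distance, complete linkage).
#'
#' @param hits Hit table from [scan_promoters()].
#' @param motifs Motif names (>= 2); must be presence columns of `hits`.
#' @param transcripts Optional transcript-id subset to analyze.
#' @param alpha Star threshold on the (unadjusted) Fisher p-value.
#' @return List: `enrichment`, `p_value` (symmetric matrices, NA diagonal),
#'   `significant`, `order` (clustering display order of motif names).
#' @export
motif_cooccurrence <- function(hits, motifs = NULL, transcripts = NULL,
                               alpha = 0.05) {
  if (is.null(motifs))
    motifs <- setdiff(names(hits)[vapply(hits, is.logical, TRUE)],
                      "transcript_id")
  if (length(motifs) < 2) stop("need at least two motifs")
  missing <- setdiff(motifs, names(hits))
  if (length(missing))
    stop("motif(s) absent from hit table: ", paste(missing, collapse = ", "))
  h <- if (is.null(transcripts)) hits else
    hits[match(transcripts, hits$transcript_id), , drop = FALSE]
  pres <- as.matrix(h[motifs])
  n <- nrow(pres)
  m <- length(motifs)
  enr <- matrix(NA_real_, m, m, dimnames = list(motifs, motifs))
  pv <- enr
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      a <- pres[, i]; b <- pres[, j]
      obs <- mean(a & b)
      exp <- mean(a) * mean(b)
      enr[i, j] <- enr[j, i] <- if (exp == 0) NA_real_ else obs / exp
      tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                    nrow = 2, byrow = TRUE)
      pv[i, j] <- pv[j, i] <- stats::fisher.test(tab)$p.value
    }
  }
  cl_input <- enr
  cl_input[is.na(cl_input)] <- 1
  diag(cl_input) <- 1
  ord <- if (m > 2)
    motifs[stats::hclust(stats::dist(cl_input), method = "complete")$order]
  else motifs
  list(enrichment = enr, p_value = pv, significant = pv <= alpha,
       order = ord)
}
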