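# Anchor-centered metapeaks, TSS group-average profiles and the heatmap
# normalization scheme.

# Per-base read-count-normalized enrichment over one window.
.window_enrichment <- function(ip, wce, chrom, start, end, wce_floor) {
  ipv <- coverage_window(ip, chrom, start, end) / ip$n_reads
  wcev <- coverage_window(wce, chrom, start, end) / wce$n_reads
  wcev <- pmax(wcev, wce_floor)
  ipv / wcev
}

#' Anchor-centered average enrichment profile (metapeak)
#'
#' Windows of `+/- flank` bp around each anchor midpoint are extracted from
#' read-count-normalized IP and WCE coverage; the per-base enrichment
#' (IP / WCE) is averaged across anchors at each offset. Oriented anchors
#' are flipped so offsets increase 5' to 3'. Zero WCE positions are floored
#' at one tenth of the genome-wide mean WCE coverage (flagged in the result).
#'
#' @param ip,wce `coverage_track`s.
#' @param anchors Data frame with chrom and either `pos` or start/end
#'   (midpoint taken), plus optional `strand`.
#' @param flank Half-window in bp.
#' @param binsize Offset bin width in bp; `NULL` picks 1 for flank <= 5 kb
#'   and 100 otherwise. Binned profiles average per-base values within bins.
#' @return Data frame: offset (bin center, bp), enrichment, n_anchors.
#' @export
metapeak <- function(ip, wce, anchors, flank = 80000, binsize = NULL) {
  if (nrow(anchors) == 0) stop("empty anchor set")
  if (is.null(binsize)) binsize <- if (flank <= 5000) 1L else 100L
  mid <- if ("pos" %in% names(anchors)) anchors$pos
  else (anchors$start + anchors$end) %/% 2L
  strand <- if ("strand" %in% names(anchors)) anchors$strand
  else rep("+", nrow(anchors))

  genome <- sum(as.numeric(wce$chrom_sizes))
  wce_mean <- sum(vapply(wce$coverage, function(v)
    sum(as.numeric(S4Vectors::runValue(v)) * S4Vectors::runLength(v)),
    numeric(1))) / genome
  wce_floor <- 0.1 * wce_mean / wce$n_reads

  L <- 2L * flank + 1L
  acc <- numeric(L)
  n_ok <- numeric(L)
  for (i in seq_len(nrow(anchors))) {
    v <- .window_enrichment(ip, wce, anchors$chrom[i],
                            mid[i] - flank, mid[i] + flank + 1L, wce_floor)
    if (strand[i] == "-") v <- base::rev(v)
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    n_ok <- n_ok + ok
  }
  prof <- acc / pmax(n_ok, 1)
  prof[n_ok == 0] <- NA_real_
  offsets <- seq(-flank, flank)
  if (binsize > 1) {
    nb <- L %/% binsize
    idx <- seq_len(nb * binsize)
    prof <- colMeans(matrix(prof[idx], nrow = binsize))
    offsets <- colMeans(matrix(offsets[idx], nrow = binsize))
    n_ok <- colMeans(matrix(n_ok[idx], nrow = binsize))
  }
  data.frame(offset = offsets, enrichment = prof, n_anchors = n_ok)
}

#' Sliding-window enrichment along a chromosome
#'
#' IP and WCE coverage are summed in a centered window of `window` bp around
#' each base (truncated at chromosome edges), normalized for read count and
#' fragment length, and divided. Zero WCE windows are floored at one
#' fragment-equivalent.
#'
#' @param ip,wce `coverage_track`s.
#' @param chrom Chromosome name.
#' @param window Window width in bp.
#' @return Numeric vector of per-base enrichment values.
#' @export
sliding_window_enrichment <- function(ip, wce, chrom, window = 100L) {
  half <- window %/% 2L
  sums <- function(track) {
    v <- as.numeric(track$coverage[[chrom]])
    cs <- cumsum(c(0, v))
    n <- length(v)
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + (window - half - 1L), n)
    cs[hi + 1L] - cs[lo]
  }
  ip_s <- sums(ip) / (ip$n_reads * ip$fragment_length)
  wce_s <- sums(wce) / (wce$n_reads * wce$fragment_length)
  wce_s <- pmax(wce_s, wce$fragment_length / (wce$n_reads * wce$fragment_length))
  ip_s / wce_s
}

#' Heatmap normalization of replicate enrichment tracks
#'
#' Replicates are combined by taking the minimum enrichment value at each
#' base (a conservative consensus), then linearly rescaled so that an
#' enrichment of 1 (background) maps to 0 and the 99th-percentile enrichment
#' among all displayed bases maps to 1, clipped to [0, 1]. Samples with no
#' real enrichment (99th percentile <= 1) must supply `reference_max`, the
#' scale of a comparable enriched sample, instead of amplifying noise.
#'
#' @param replicates List of numeric per-base enrichment vectors (equal
#'   length), e.g. from [sliding_window_enrichment()].
#' @param probs Upper quantile defining the display maximum.
#' @param reference_max Optional externally supplied maximum enrichment.
#' @return List: `values` (normalized vector in [0, 1]), `max` (the
#'   enrichment mapped to 1), `used_reference` flag.
#' @export
heatmap_normalize <- function(replicates, probs = 0.99,
                              reference_max = NULL) {
  stopifnot(length(replicates) >= 1)
  combined <- Reduce(pmin, replicates)
  mx <- stats::quantile(combined, probs, na.rm = TRUE, names = FALSE)
  used_reference <- FALSE
  if (mx <= 1) {
    if (is.null(reference_max))
      stop("no enrichment above background (99th percentile <= 1); ",
           "supply reference_max from a comparable enriched sample")
    mx <- reference_max
    used_reference <- TRUE
  }
  vals <- pmin(1, pmax(0, (combined - 1) / (mx - 1)))
  list(values = vals, max = mx, used_reference = used_reference)
}

#' Group-average TSS-anchored profiles
#'
#' Extracts a strand-aware window around each transcript's TSS from a
#' coverage (or enrichment) track, averages within gene groups, and scales
#' all profiles by the maximum value encountered across the displayed
#' groups.
#'
#' @param track A `coverage_track` or `score_track`.
#' @param transcripts Annotation data frame with a `group` column (one row
#'   per displayed transcript).
#' @param span TSS-relative window `c(from, to)` in bp.
#' @param scale Divide by the maximum across groups (the display convention).
#' @return Data frame: group, offset, value (long format).
#' @export
group_average_profile <- function(track, transcripts, span = c(-200, 800),
                                  scale = TRUE) {
  stopifnot(nrow(transcripts) > 0, "group" %in% names(transcripts))
  tss <- tss_position(transcripts)
  offsets <- seq(span[1], span[2])
  groups <- unique(transcripts$group)
  profs <- lapply(groups, function(g) {
    idx <- which(transcripts$group == g)
    acc <- numeric(length(offsets))
    n_ok <- numeric(length(offsets))
    for (i in idx) {
      if (transcripts$strand[i] == "+") {
        v <- coverage_window(track, transcripts$chrom[i],
                             tss[i] + span[1], tss[i] + span[2] + 1L)
      } else {
        v <- base::rev(coverage_window(track, transcripts$chrom[i],
                                       tss[i] - span[2], tss[i] - span[1] + 1L))
      }
      ok <- !is.na(v)
      acc[ok] <- acc[ok] + v[ok]
      n_ok <- n_ok + ok
    }
    acc / pmax(n_ok, 1)
  })
  mx <- max(unlist(profs))
  out <- do.call(rbind, lapply(seq_along(groups), function(k)
    data.frame(group = groups[k], offset = offsets,
               value = if (scale && mx > 0) profs[[k]] / mx else profs[[k]],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
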