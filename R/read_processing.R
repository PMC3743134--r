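# Aligned-read interval processing: fragment extension, duplicate-stack
# filtering and per-base coverage. All coordinates are 0-based half-open.

#' Construct an aligned-read set
#'
#' A light container for aligned-read intervals plus the library metadata the
#' enrichment normalization needs (fragment length, total read count).
#'
#' @param reads Data frame with columns chrom, start, end, strand
#'   (0-based half-open; strand "+" or "-").
#' @param fragment_length Estimated library insert size in bp.
#' @param extended Logical; whether reads have already been extended to
#'   `fragment_length`.
#' @return Object of class `read_set`.
#' @export
read_set <- function(reads, fragment_length, extended = FALSE) {
  stopifnot(is.data.frame(reads),
            all(c("chrom", "start", "end", "strand") %in% names(reads)))
  if (nrow(reads) > 0) {
    stopifnot(all(reads$start >= 0), all(reads$end > reads$start),
              all(reads$strand %in% c("+", "-")))
  }
  if (fragment_length <= 0) stop("fragment_length must be > 0")
  structure(list(reads = reads, fragment_length = as.integer(fragment_length),
                 n_reads = nrow(reads), extended = extended),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", x$n_reads, "reads, fragment_length", x$fragment_length,
      "bp,", if (x$extended) "extended" else "unextended", "\n")
  invisible(x)
}

# 5' end position of each read: start on "+", end on "-".
# (For a minus-strand read [s, e), the 5'-most base is e - 1; using the
# half-open boundary e keeps extension arithmetic symmetric.)
read_five_prime <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end)
}

#' Extend single-end reads to the library fragment length
#'
#' Each read is replaced by an interval of `fragment_length` bp starting at
#' the read's 5' end and running in the read's strand direction, clipped at
#' chromosome bounds when `chrom_sizes` is supplied.
#'
#' @param rs A [read_set()].
#' @param fragment_length Target length in bp; defaults to the read set's
#'   recorded fragment length. Values shorter than the read length truncate
#'   the read (allowed, with a message).
#' @param chrom_sizes Optional named vector for boundary clipping.
#' @return The extended [read_set()].
#' @export
extend_reads <- function(rs, fragment_length = rs$fragment_length,
                         chrom_sizes = NULL) {
  stopifnot(inherits(rs, "read_set"))
  if (fragment_length <= 0) stop("fragment_length must be > 0")
  reads <- rs$reads
  if (nrow(reads) > 0) {
    if (any(fragment_length < reads$end - reads$start))
      message("fragment_length shorter than some reads; truncating")
    plus <- reads$strand == "+"
    reads$end[plus] <- reads$start[plus] + fragment_length
    reads$start[!plus] <- reads$end[!plus] - fragment_length
    reads$start <- pmax(reads$start, 0L)
    if (!is.null(chrom_sizes)) {
      reads$end <- pmin(reads$end, unname(chrom_sizes[reads$chrom]))
      reads <- reads[reads$end > reads$start, , drop = FALSE]
    }
  }
  read_set(reads, fragment_length, extended = TRUE)
}

#' Remove PCR amplification artifacts (duplicate read stacks)
#'
#' Reads sharing (chrom, start, strand) form a stack. Stacks larger than
#' `max_duplicates` are alignment/amplification artifacts and are removed,
#' unless a corresponding number of reads sit on the opposite strand with 5'
#' ends approximately one fragment length away in the stack's 3' direction
#' (the signature of a genuine ChIP fragment pileup). "Approximately" is
#' `fragment_length * (1 +/- tolerance_fraction)` and "corresponding" is
#' `>= partner_fraction * stack size`; both are exposed because the exact
#' values are conventions, not measurements.
#'
#' Support is evaluated against the retained read set: removal is iterated to
#' a fixed point so that stacks supported only by removed artifacts are
#' themselves removed, which makes the filter idempotent.
#'
#' @param rs A [read_set()] of unextended reads.
#' @param max_duplicates Stacks strictly larger than this are candidates for
#'   removal (a stack of exactly `max_duplicates` reads is retained).
#' @param tolerance_fraction Relative window around one fragment length.
#' @param partner_fraction Minimum opposite-strand support, as a fraction of
#'   stack size.
#' @return List with `reads` (filtered [read_set()]) and `report` (one row
#'   per stack over the size cutoff: coordinates, size, partner support,
#'   whether removed).
#' @export
remove_duplicate_stacks <- function(rs, max_duplicates = 10,
                                    tolerance_fraction = 0.2,
                                    partner_fraction = 0.5) {
  stopifnot(inherits(rs, "read_set"))
  reads <- rs$reads
  fl <- rs$fragment_length
  lo <- fl * (1 - tolerance_fraction)
  hi <- fl * (1 + tolerance_fraction)

  empty_report <- data.frame(chrom = character(), start = integer(),
                             strand = character(), size = integer(),
                             partners = integer(), removed = logical(),
                             stringsAsFactors = FALSE)
  if (nrow(reads) == 0)
    return(list(reads = rs, report = empty_report))

  # group reads by (chrom, start, strand) via an exact numeric key
  chrom_f <- factor(reads$chrom)
  key <- (as.numeric(chrom_f) * 2 + (reads$strand == "+")) * 2^31 +
    reads$start
  ord <- order(key)
  grp <- rle(key[ord])
  is_stack_grp <- grp$lengths > max_duplicates
  if (!any(is_stack_grp))
    return(list(reads = rs, report = empty_report))

  grp_end <- cumsum(grp$lengths)
  grp_first <- ord[grp_end - grp$lengths + 1L]          # one read per group
  s_first <- grp_first[is_stack_grp]
  s_size <- grp$lengths[is_stack_grp]
  s_chrom <- reads$chrom[s_first]
  s_strand <- reads$strand[s_first]
  s_start <- reads$start[s_first]
  s_key <- grp$values[is_stack_grp]
  fivep <- as.numeric(read_five_prime(reads))
  s_fivep <- fivep[s_first]
  n_stacks <- length(s_first)

  # the partner search window of stack j on the opposite strand, 3' of the
  # stack
  win_lo <- ifelse(s_strand == "+", s_fivep + lo, s_fivep - hi)
  win_hi <- ifelse(s_strand == "+", s_fivep + hi, s_fivep - lo)

  # sorted opposite-strand 5' positions per (chrom, strand) for O(log n)
  # window counts
  side <- paste0(reads$chrom, "/", reads$strand)
  sorted_fp <- lapply(split(fivep, side), sort)
  opp_side <- paste0(s_chrom, "/", ifelse(s_strand == "+", "-", "+"))
  total_partners <- integer(n_stacks)
  for (sd in unique(opp_side)) {
    at <- which(opp_side == sd)
    sorted <- sorted_fp[[sd]]
    if (is.null(sorted)) next
    total_partners[at] <- findInterval(win_hi[at], sorted) -
      findInterval(win_lo[at] - 0.5, sorted)
  }

  # iterate to a fixed point: partners contributed by removed stacks no
  # longer count as support
  removed <- rep(FALSE, n_stacks)
  s_side <- paste0(s_chrom, "/", s_strand)
  repeat {
    removed_partners <- integer(n_stacks)
    if (any(removed)) {
      rem <- which(removed)
      rem_by_side <- split(rem, s_side[rem])
      for (sd in names(rem_by_side)) {
        ix <- rem_by_side[[sd]]
        o <- order(s_fivep[ix])
        pos <- s_fivep[ix][o]
        csz <- cumsum(s_size[ix][o])
        at <- which(!removed & opp_side == sd)
        if (!length(at)) next
        hi_i <- findInterval(win_hi[at], pos)
        lo_i <- findInterval(win_lo[at] - 0.5, pos)
        removed_partners[at] <- (c(0, csz)[hi_i + 1L] - c(0, csz)[lo_i + 1L])
      }
    }
    newly <- !removed &
      (total_partners - removed_partners) < partner_fraction * s_size
    if (!any(newly)) break
    removed[newly] <- TRUE
  }
  keep <- !(key %in% s_key[removed])

  report <- data.frame(chrom = s_chrom, start = s_start, strand = s_strand,
                       size = s_size,
                       partners = as.integer(total_partners),
                       removed = removed, stringsAsFactors = FALSE)

  out <- read_set(reads[keep, , drop = FALSE], fl, extended = rs$extended)
  list(reads = out, report = report)
}

#' Per-base coverage from extended reads
#'
#' Assigns to each genomic coordinate the number of extended reads that
#' overlap it, as a run-length encoded track per chromosome.
#'
#' @param rs A [read_set()] of extended reads.
#' @param chrom_sizes Named vector of chromosome sizes; reads on chromosomes
#'   absent from it are rejected.
#' @return A `coverage_track`: list with `coverage` (named list of
#'   [S4Vectors::Rle] vectors), `chrom_sizes`, `n_reads` and
#'   `fragment_length`.
#' @export
compute_coverage <- function(rs, chrom_sizes) {
  stopifnot(inherits(rs, "read_set"))
  reads <- rs$reads
  unknown <- setdiff(unique(reads$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("reads on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  cov <- lapply(names(chrom_sizes), function(ch) {
    on_ch <- reads[reads$chrom == ch, , drop = FALSE]
    if (nrow(on_ch) == 0)
      return(S4Vectors::Rle(0L, chrom_sizes[[ch]]))
    ir <- IRanges::IRanges(start = pmax(on_ch$start, 0L) + 1L,
                           end = pmin(on_ch$end, chrom_sizes[[ch]]))
    IRanges::coverage(ir, width = chrom_sizes[[ch]])
  })
  names(cov) <- names(chrom_sizes)
  coverage_track(cov, chrom_sizes, n_reads = rs$n_reads,
                 fragment_length = rs$fragment_length)
}

#' @rdname compute_coverage
#' @param coverage Named list of per-chromosome Rle (or numeric) vectors.
#' @param n_reads Total read count of the originating library.
#' @param fragment_length Fragment length of the originating library.
#' @export
coverage_track <- function(coverage, chrom_sizes, n_reads, fragment_length) {
  coverage <- lapply(coverage, function(v)
    if (inherits(v, "Rle")) v else S4Vectors::Rle(v))
  stopifnot(setequal(names(coverage), names(chrom_sizes)))
  for (ch in names(coverage))
    stopifnot(length(coverage[[ch]]) == chrom_sizes[[ch]])
  structure(list(coverage = coverage,
                 chrom_sizes = chrom_sizes,
                 n_reads = n_reads,
                 fragment_length = as.integer(fragment_length)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$coverage), "chromosomes (",
      format(sum(as.numeric(x$chrom_sizes)), big.mark = ","), "bp ),",
      x$n_reads, "reads, fragment_length", x$fragment_length, "bp\n")
  invisible(x)
}

#' Sum of coverage over genomic regions
#'
#' @param track A `coverage_track` (or a score-track-like list of per-chrom
#'   vectors under `$coverage`).
#' @param regions Data frame with chrom, start, end (0-based half-open).
#' @return Numeric vector of per-region coverage sums; 0 for empty regions.
#' @export
region_signal <- function(track, regions) {
  out <- numeric(nrow(regions))
  nonempty <- regions$end > regions$start
  for (ch in unique(regions$chrom[nonempty])) {
    idx <- which(nonempty & regions$chrom == ch)
    v <- track$coverage[[ch]]
    if (is.null(v)) stop("region on unknown chromosome: ", ch)
    s <- pmax(regions$start[idx], 0L) + 1L
    e <- pmin(regions$end[idx], length(v))
    ok <- e >= s
    if (any(ok)) {
      vw <- IRanges::Views(v, start = s[ok], end = e[ok])
      out[idx[ok]] <- IRanges::viewSums(vw)
    }
  }
  out
}

#' Extract a per-base window from a coverage track
#'
#' Positions outside chromosome bounds are returned as NA.
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open window.
#' @return Numeric vector of length `end - start`.
#' @export
coverage_window <- function(track, chrom, start, end) {
  v <- track$coverage[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  out <- rep(NA_real_, end - start)
  s <- max(start, 0L)
  e <- min(end, length(v))
  if (e > s)
    out[(s - start + 1):(e - start)] <-
      as.numeric(S4Vectors::window(v, s + 1L, e))
  out
}
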