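# Readers and writers for the plain-text interchange formats the pipeline
# uses: BED6 reads, BED12-dialect annotation, narrowPeak, fixed-step WIG,
# bedGraph and TSV tables. BED coordinates are 0-based half-open and are
# stored unchanged internally.

#' Read aligned reads from a BED6 file
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @param fragment_length Library fragment length to attach to the set.
#' @return A [read_set()].
#' @export
read_bed_reads <- function(path, fragment_length) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character"))
  read_set(df[, c("chrom", "start", "end", "strand")], fragment_length)
}

#' Write aligned reads as BED6
#'
#' @param rs A [read_set()].
#' @param path Output path.
#' @export
write_bed_reads <- function(rs, path) {
  r <- rs$reads
  df <- data.frame(r$chrom, r$start, r$end,
                   name = if (nrow(r)) sprintf("read%d", seq_len(nrow(r)))
                   else character(),
                   score = if (nrow(r)) 0L else integer(), strand = r$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a transcript annotation as 12+2 column BED dialect
#'
#' Standard BED12 (name = transcript id, thick = span, blocks = exons) plus
#' two extra columns: gene id and a protein-coding flag.
#'
#' @param transcripts Annotation data frame from [generate_annotation()].
#' @param path Output path.
#' @export
write_annotation_bed <- function(transcripts, path) {
  tx <- transcripts
  n_ex <- tx$n_exons
  df <- data.frame(tx$chrom, tx$start, tx$end, tx$transcript_id, 0L,
                   tx$strand, tx$start, tx$end, "0,0,0", n_ex,
                   tx$exon_sizes, tx$exon_starts, tx$gene_id,
                   as.integer(tx$coding))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:14] <- c("chrom", "start", "end", "transcript_id", "score",
                       "strand", "thick_start", "thick_end", "rgb",
                       "n_exons", "exon_sizes", "exon_starts", "gene_id",
                       "coding")
  data.frame(gene_id = df$gene_id, transcript_id = df$transcript_id,
             chrom = df$chrom, start = as.integer(df$start),
             end = as.integer(df$end), strand = df$strand,
             coding = df$coding == 1, n_exons = as.integer(df$n_exons),
             exon_sizes = as.character(df$exon_sizes),
             exon_starts = as.character(df$exon_starts),
             stringsAsFactors = FALSE)
}

#' Read a peak set from BED or narrowPeak
#'
#' Columns beyond the third are optional; a narrowPeak 10th column (summit
#' offset from start, -1 when absent) is used when present.
#'
#' @param path BED3+/narrowPeak file.
#' @return Data frame with chrom, start, end and optional summit (absolute
#'   0-based coordinate).
#' @export
read_peaks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom = df[[1]], start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  if (ncol(df) >= 10) {
    summit <- as.integer(df[[10]])
    out$summit <- ifelse(summit >= 0, out$start + summit, NA_integer_)
  }
  out
}

#' Export a per-base track as fixed-step WIG
#'
#' @param track A `coverage_track` or score track (list of per-chrom vectors
#'   under `$coverage` plus `$chrom_sizes`).
#' @param path Output path.
#' @param step Step/span in bp; values are averaged within each step.
#' @export
write_wig <- function(track, path, step = 1L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$coverage)) {
    v <- as.numeric(track$coverage[[ch]])
    if (step > 1) {
      nb <- length(v) %/% step
      v <- colMeans(matrix(v[seq_len(nb * step)], nrow = step))
    }
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       ch, step, step), con)
    writeLines(format(v, trim = TRUE, scientific = FALSE), con)
  }
  invisible(path)
}

#' @rdname write_wig
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  heads <- grep("^fixedStep", lines)
  stopifnot(length(heads) > 0)
  bounds <- c(heads, length(lines) + 1L)
  values <- list()
  for (i in seq_along(heads)) {
    hdr <- lines[heads[i]]
    ch <- sub(".*chrom=([^ ]+).*", "\\1", hdr)
    step <- as.integer(sub(".*step=([0-9]+).*", "\\1", hdr))
    block <- as.numeric(lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)])
    values[[ch]] <- if (step == 1) block else rep(block, each = step)
  }
  sizes <- vapply(values, length, integer(1))
  list(coverage = values, chrom_sizes = sizes)
}

#' Export a coverage track as bedGraph
#'
#' Run-length encoded; zero runs are skipped.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$coverage)) {
    v <- track$coverage[[ch]]
    if (!inherits(v, "Rle")) v <- S4Vectors::Rle(v)
    ends <- cumsum(S4Vectors::runLength(v))
    starts <- c(0L, ends[-length(ends)])
    vals <- S4Vectors::runValue(v)
    nz <- vals != 0
    if (any(nz))
      writeLines(sprintf("%s\t%d\t%d\t%g", ch, starts[nz], ends[nz],
                         vals[nz]), con)
  }
  invisible(path)
}

#' Write/read a TSV table with a parameterization header comment
#'
#' @param df Data frame.
#' @param path Output path.
#' @param params Optional named list recorded as `# key=value` header lines.
#' @export
write_tsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params))
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, function(p)
                         paste(format(p, trim = TRUE), collapse = ","), "")),
               con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
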