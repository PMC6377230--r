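#' Read a genome from a FASTA file
#'
#' Parses a (possibly multi-record) FASTA file into a named
#' [Biostrings::DNAStringSet]. Record order is preserved and sequence is
#' case-folded to upper case, so lower-case soft-masked bases scan
#' identically for GATC motifs.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`, one element per record.
#' @seealso [write_fasta()], [scan_gatc()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  headers <- grep("^>", lines)
  if (!length(headers) || headers[1] != 1L) {
    stop(sprintf("malformed FASTA %s: line 1 is not a header", path),
         call. = FALSE)
  }
  bad <- grep("^>\\s*$", lines[headers])
  if (length(bad)) {
    stop(sprintf("malformed FASTA %s: empty header at line %d",
                 path, headers[bad[1]]), call. = FALSE)
  }
  starts <- headers + 1L
  ends <- c(headers[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(headers), function(i) {
    if (starts[i] > ends[i]) return("")
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  empty <- which(!nzchar(seqs))
  if (length(empty)) {
    stop(sprintf("malformed FASTA %s: empty record at line %d",
                 path, headers[empty[1]]), call. = FALSE)
  }
  nm <- sub("^>\\s*", "", lines[headers])
  nm <- sub("\\s.*$", "", nm)
  out <- Biostrings::DNAStringSet(toupper(seqs))
  names(out) <- nm
  out
}

#' Write a genome to FASTA (60-column wrap)
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, filepath = path, width = 60L)
  invisible(path)
}

# shared validated reader for tab-separated interval files
read_interval_table <- function(path, n_fields, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer())[, 0])
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < n_fields)
  if (length(bad)) {
    stop(sprintf("%s parse error at line %d: %d field(s), expected >= %d",
                 what, bad[1], nf[bad[1]], n_fields), call. = FALSE)
  }
  mat <- t(vapply(parts, function(p) p[seq_len(n_fields)],
                  character(n_fields)))
  start <- suppressWarnings(as.integer(mat[, 2]))
  end <- suppressWarnings(as.integer(mat[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0L | end <= start)
  if (length(bad)) {
    stop(sprintf(
      "%s parse error at line %d: invalid half-open interval [%s, %s)",
      what, bad[1], mat[bad[1], 2], mat[bad[1], 3]), call. = FALSE)
  }
  out <- data.frame(chrom = mat[, 1], start = start, end = end)
  if (n_fields > 3L) out$extra <- I(mat[, 4:n_fields, drop = FALSE])
  out
}

#' Read a BED6 file of aligned reads or intervals
#'
#' Coordinates are BED-standard 0-based half-open; records with
#' `end <= start` are rejected. Returns a [GenomicRanges::GRanges] (1-based
#' internally, as usual for Bioconductor) carrying `name` and `score`
#' metadata columns and read strand.
#'
#' @param path path to a tab-separated BED6 (or BED3) file.
#' @param seqlengths optional named chromosome lengths; records on unknown
#'   chromosomes raise an error.
#' @return a `GRanges`.
#' @export
read_bed <- function(path, seqlengths = NULL) {
  tab <- read_interval_table(path, 3L, "BED")
  if (!nrow(tab)) return(GenomicRanges::GRanges())
  lines6 <- tryCatch(read_interval_table(path, 6L, "BED"), error = function(e) NULL)
  if (!is.null(seqlengths)) check_same_genome(unique(tab$chrom), names(seqlengths), "BED records")
  if (!is.null(lines6)) {
    strand <- lines6$extra[, 3]
    strand[!strand %in% c("+", "-")] <- "*"
    gr <- granges0(tab$chrom, tab$start, tab$end, seqlengths,
                   strand = factor(strand, levels = c("+", "-", "*")))
    gr$name <- lines6$extra[, 1]
    gr$score <- suppressWarnings(as.numeric(lines6$extra[, 2]))
  } else {
    gr <- granges0(tab$chrom, tab$start, tab$end, seqlengths)
  }
  gr
}

#' Write intervals as BED6
#'
#' @param gr a [GenomicRanges::GRanges]; `name` and `score` metadata columns
#'   are used when present (defaults: `region_<i>` and 0).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  n <- length(gr)
  name <- if (!is.null(gr$name)) gr$name else sprintf("region_%d", seq_len(n))
  score <- if (!is.null(gr$score)) gr$score else rep(0L, n)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  out <- paste(as.character(GenomicRanges::seqnames(gr)),
               start0(gr), end0(gr), name, format_num(score), strand,
               sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Read a 4-column bedGraph into a GRanges signal track
#'
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open).
#' @param seqlengths optional named chromosome lengths for validation.
#' @return `GRanges` with a numeric `value` metadata column.
#' @export
read_bedgraph <- function(path, seqlengths = NULL) {
  tab <- read_interval_table(path, 4L, "bedGraph")
  if (!nrow(tab)) {
    gr <- GenomicRanges::GRanges()
    gr$value <- numeric(0)
    return(gr)
  }
  if (!is.null(seqlengths)) check_same_genome(unique(tab$chrom), names(seqlengths), "bedGraph records")
  value <- suppressWarnings(as.numeric(tab$extra[, 1]))
  bad <- which(is.na(value))
  if (length(bad)) {
    stop(sprintf("bedGraph parse error at line %d: non-numeric value %s",
                 bad[1], tab$extra[bad[1], 1]), call. = FALSE)
  }
  gr <- granges0(tab$chrom, tab$start, tab$end, seqlengths)
  gr$value <- value
  gr
}

# fixed 6-significant-digit representation used for all emitted signal values
format_num <- function(x) {
  out <- sprintf("%.6g", as.numeric(x))
  out[is.na(x)] <- "NA"
  out
}

#' Write a signal track (GRanges with `value`, or a [ratio_track]) as bedGraph
#'
#' Values are written with 6 significant digits, one line per interval,
#' 0-based half-open.
#'
#' @param track a `GRanges` with a `value` column, or a `ratio_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- as_signal_granges(track)
  out <- paste(as.character(GenomicRanges::seqnames(gr)),
               start0(gr), end0(gr), format_num(gr$value), sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Read a narrowPeak (BED6+4) peak file
#'
#' @param path narrowPeak path.
#' @param seqlengths optional named chromosome lengths.
#' @return `GRanges` with `name`, `score`, `signalValue`, `pValue`,
#'   `qValue` (both -log10), and `peak` (summit offset) columns.
#' @export
read_narrowpeak <- function(path, seqlengths = NULL) {
  tab <- read_interval_table(path, 10L, "narrowPeak")
  if (!nrow(tab)) return(empty_peakset())
  if (!is.null(seqlengths)) check_same_genome(unique(tab$chrom), names(seqlengths), "narrowPeak records")
  gr <- granges0(tab$chrom, tab$start, tab$end, seqlengths)
  gr$name <- tab$extra[, 1]
  gr$score <- as.numeric(tab$extra[, 2])
  gr$signalValue <- as.numeric(tab$extra[, 4])
  gr$pValue <- as.numeric(tab$extra[, 5])
  gr$qValue <- as.numeric(tab$extra[, 6])
  gr$peak <- as.integer(tab$extra[, 7])
  gr
}

#' Write a peakset as narrowPeak (BED6+4)
#'
#' The integer `score` column is `round(10 * -log10(q))` capped at 1000, as
#' in common peak-caller output.
#'
#' @param peaks `GRanges` as produced by [call_peaks_ratio()] /
#'   [call_peaks_accessibility()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- length(peaks)
  name <- if (!is.null(peaks$name)) peaks$name else sprintf("peak_%d", seq_len(n))
  qv <- if (!is.null(peaks$qValue)) peaks$qValue else rep(0, n)
  pv <- if (!is.null(peaks$pValue)) peaks$pValue else rep(0, n)
  sv <- if (!is.null(peaks$signalValue)) peaks$signalValue else rep(0, n)
  pk <- if (!is.null(peaks$peak)) peaks$peak else floor((end0(peaks) - start0(peaks)) / 2)
  score <- pmin(1000L, as.integer(round(10 * qv)))
  out <- paste(as.character(GenomicRanges::seqnames(peaks)),
               start0(peaks), end0(peaks), name, score, ".",
               format_num(sv), format_num(pv), format_num(qv), pk,
               sep = "\t")
  writeLines(out, path)
  invisible(path)
}

empty_peakset <- function() {
  gr <- GenomicRanges::GRanges()
  gr$name <- character(0)
  gr$score <- numeric(0)
  gr$signalValue <- numeric(0)
  gr$pValue <- numeric(0)
  gr$qValue <- numeric(0)
  gr$peak <- integer(0)
  gr
}

# coerce ratio_track / GRanges(value) / GRanges(score) to GRanges with $value
as_signal_granges <- function(track) {
  if (inherits(track, "ratio_track")) {
    gr <- track$fragments
    gr$value <- track$value
    return(gr)
  }
  stopifnot(methods::is(track, "GRanges"))
  if (is.null(track$value)) {
    if (!is.null(track$score)) track$value <- track$score
    else stop("signal GRanges needs a 'value' column", call. = FALSE)
  }
  track
}
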