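#' Reference-point signal matrix around region centers
#'
#' Builds a regions x bins matrix of mean signal in fixed-width bins
#' spanning `[-W, +W)` around each region's center (the reference point).
#' Each cell is the length-weighted mean of the signal over its bin, with
#' uncovered bases counted as 0; bins extending past a chromosome end are
#' marked absent (`NA`) rather than zero-filled. Regions are treated as
#' unstranded.
#'
#' @param signal `ratio_track` or `GRanges` with `value`.
#' @param regions peak `GRanges`.
#' @param W window half-width in bp (default 5000).
#' @param b bin width in bp (default 50); `W` must be divisible by `b`.
#' @param seqlengths named chromosome lengths; default from `signal`.
#' @return a `profile_matrix`: list with `matrix` (regions x 2W/b),
#'   `bin_starts` (bin offsets from the center), `W`, `b`, `regions`.
#' @export
reference_point_matrix <- function(signal, regions, W = 5000L, b = 50L,
                                   seqlengths = NULL) {
  if (!length(regions)) stop("empty region set", call. = FALSE)
  if (W %% b != 0L) {
    stop(sprintf("invalid config: window %d not divisible by bin %d", W, b),
         call. = FALSE)
  }
  sig <- as_signal_granges(signal)
  seqlengths <- seqlengths %||% GenomeInfoDb::seqlengths(sig)
  if (any(is.na(seqlengths))) {
    stop("chromosome lengths required (set seqlengths on the signal)",
         call. = FALSE)
  }
  n_bins <- as.integer(2L * W / b)
  offsets <- seq(-W, W - b, by = b)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  mid <- center0(regions)
  # all region x bin cells at once
  cell_chrom <- rep(chrom, each = n_bins)
  cell_start <- rep(mid, each = n_bins) + rep(offsets, length(regions))
  cell_end <- cell_start + b
  clen <- seqlengths[cell_chrom]
  absent <- cell_start < 0 | cell_end > clen
  vals <- rep(NA_real_, length(cell_start))
  if (any(!absent)) {
    ok <- which(!absent)
    cells <- granges0(cell_chrom[ok], cell_start[ok], cell_end[ok])
    hits <- GenomicRanges::findOverlaps(cells, sig, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(end0(cells)[qh], end0(sig)[sh]) -
      pmax(start0(cells)[qh], start0(sig)[sh])
    sums <- numeric(length(cells))
    contrib <- tapply(ov * sig$value[sh], qh, sum)
    sums[as.integer(names(contrib))] <- contrib
    vals[ok] <- sums / b
  }
  mat <- matrix(vals, nrow = length(regions), ncol = n_bins, byrow = TRUE)
  rownames(mat) <- if (!is.null(regions$name)) regions$name else
    sprintf("region_%d", seq_along(regions))
  colnames(mat) <- sprintf("%d", offsets)
  structure(list(matrix = mat, bin_starts = offsets, W = W, b = b,
                 regions = regions, n_absent = sum(absent)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf(
    "<profile_matrix> %d regions x %d bins (+/-%d bp, bin %d bp), %d absent cells\n",
    nrow(x$matrix), ncol(x$matrix), x$W, x$b, x$n_absent))
  invisible(x)
}

#' Column-mean profile of a profile matrix
#'
#' Arithmetic mean per bin over present (non-absent) cells; a bin with no
#' present cell is reported `NA`.
#'
#' @param pm a `profile_matrix`.
#' @return data.frame with `offset` (bin start relative to center) and
#'   `mean_signal`.
#' @export
mean_profile <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (!nrow(pm$matrix)) stop("empty profile matrix", call. = FALSE)
  m <- colMeans(pm$matrix, na.rm = TRUE)
  m[!is.finite(m)] <- NA_real_
  data.frame(offset = pm$bin_starts, mean_signal = unname(m))
}

#' Write a profile matrix as TSV
#'
#' deepTools-like layout: one row per region, one column per bin, header
#' lines recording window and bin sizes.
#'
#' @param pm `profile_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(pm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# window=%d bin=%d", pm$W, pm$b), con)
  writeLines(paste(c("region", colnames(pm$matrix)), collapse = "\t"), con)
  body <- apply(pm$matrix, 1, function(r)
    paste(format_num(r), collapse = "\t"))
  writeLines(paste(rownames(pm$matrix), body, sep = "\t"), con)
  invisible(path)
}

#' Bin read 5' ends over the genome
#'
#' Partitions every chromosome into fixed-width bins (the last bin
#' truncated) and counts read 5' ends per bin, so the total equals the
#' library size.
#'
#' @param reads `GRanges` read set with strand.
#' @param seqlengths named chromosome lengths.
#' @param bin_width bin width in bp (default 1000).
#' @return integer vector of counts over the genome-wide bin sequence.
#' @export
bin_reads <- function(reads, seqlengths, bin_width = 1000L) {
  stopifnot(bin_width >= 1L)
  n_bins <- pmax(ceiling(seqlengths / bin_width), 1L)
  offsets <- c(0L, cumsum(n_bins))[seq_along(seqlengths)]
  names(offsets) <- names(seqlengths)
  chrom <- as.character(GenomicRanges::seqnames(reads))
  str <- as.character(GenomicRanges::strand(reads))
  five0 <- ifelse(str == "-", end0(reads) - 1L, start0(reads))
  idx <- offsets[chrom] + five0 %/% bin_width + 1L
  tabulate(idx, nbins = sum(n_bins))
}

#' Pairwise Pearson correlation of binned read counts
#'
#' Counts read 5' ends in fixed-width genome bins for every sample, drops
#' bins that are zero across all samples, and returns the Pearson
#' correlation matrix (optionally on log1p-transformed counts).
#'
#' @param read_sets named list of >= 2 `GRanges` read sets on one genome.
#' @param seqlengths named chromosome lengths.
#' @param bin_width bin width in bp (default 1000).
#' @param transform `"raw"` (default) or `"log1p"`.
#' @return a `correlation_matrix`: list with `r` (samples x samples),
#'   `bin_width`, `n_bins_used`. Zero-variance samples yield `NA`
#'   correlations and a warning.
#' @export
pairwise_pearson <- function(read_sets, seqlengths, bin_width = 1000L,
                             transform = c("raw", "log1p")) {
  transform <- match.arg(transform)
  if (length(read_sets) < 2L) stop("need >= 2 samples", call. = FALSE)
  counts <- vapply(read_sets, bin_reads, seqlengths = seqlengths,
                   bin_width = bin_width,
                   numeric(sum(pmax(ceiling(seqlengths / bin_width), 1L))))
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  if (transform == "log1p") counts <- log1p(counts)
  zero_var <- apply(counts, 2, stats::sd) == 0
  if (any(zero_var)) {
    warning("zero-variance sample(s): ",
            paste(colnames(counts)[zero_var], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(counts, method = "pearson"))
  colnames(r) <- rownames(r) <- names(read_sets) %||%
    paste0("sample", seq_along(read_sets))
  structure(list(r = r, bin_width = bin_width, n_bins_used = nrow(counts),
                 transform = transform),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d samples, %d bins of %d bp (%s)\n",
              nrow(x$r), x$n_bins_used, x$bin_width, x$transform))
  print(round(x$r, 3))
  invisible(x)
}
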