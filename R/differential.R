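#' Build a consensus peakset across replicate peaksets
#'
#' Peaks from all input sets are chained by >= 1 bp overlap and merged into
#' maximal connected intervals; a merged interval is kept when it contains
#' peaks from at least `min_samples` distinct input sets. Per-interval
#' membership is recorded.
#'
#' @param peaksets list of peak `GRanges` (one per replicate/sample), all
#'   on the same genome.
#' @param min_samples minimum number of contributing peaksets (default 2).
#' @return `GRanges` of consensus intervals with `n_support` and a
#'   logical membership matrix column `membership` (interval x peakset).
#' @export
build_consensus <- function(peaksets, min_samples = 2L) {
  if (!length(peaksets)) stop("empty peakset list", call. = FALSE)
  stopifnot(min_samples >= 1L, min_samples <= length(peaksets))
  all_peaks <- suppressWarnings(
    do.call(c, lapply(peaksets, GenomicRanges::granges)))
  if (!length(all_peaks)) {
    out <- GenomicRanges::GRanges()
    out$n_support <- integer(0)
    S4Vectors::metadata(out) <- list(min_samples = min_samples)
    return(out)
  }
  # min.gapwidth = 0: adjacency is not overlap; chains need >= 1 shared bp
  merged <- GenomicRanges::reduce(all_peaks, ignore.strand = TRUE,
                                  min.gapwidth = 0L)
  membership <- vapply(peaksets, function(ps)
    IRanges::overlapsAny(merged, ps, minoverlap = 1L), logical(length(merged)))
  membership <- matrix(membership, nrow = length(merged))
  n_support <- rowSums(membership)
  keep <- n_support >= min_samples
  out <- merged[keep]
  out$n_support <- as.integer(n_support[keep])
  out$membership <- membership[keep, , drop = FALSE]
  S4Vectors::metadata(out) <- list(min_samples = min_samples)
  out
}

#' Count reads over consensus peaks: the binding affinity matrix
#'
#' For every consensus interval and sample, counts the (extended) reads
#' overlapping the interval by >= 1 bp.
#'
#' @param consensus consensus `GRanges` from [build_consensus()].
#' @param read_sets named list of `GRanges` read sets (extended reads), one
#'   per sample.
#' @param groups factor/character of length `length(read_sets)` assigning
#'   each sample to lineage `"A"` or `"B"`.
#' @return an `affinity_matrix`: peaks x samples count matrix plus peak
#'   coordinates, group labels and library sizes.
#' @export
count_affinity <- function(consensus, read_sets, groups) {
  if (!length(consensus)) stop("empty consensus peakset", call. = FALSE)
  stopifnot(length(read_sets) == length(groups))
  counts <- vapply(read_sets, function(r) {
    check_same_genome(as.character(unique(GenomicRanges::seqnames(r))),
                      GenomeInfoDb::seqlevels(consensus), "read set")
    GenomicRanges::countOverlaps(consensus, r, minoverlap = 1L,
                                 ignore.strand = TRUE)
  }, numeric(length(consensus)))
  counts <- matrix(counts, nrow = length(consensus))
  colnames(counts) <- names(read_sets) %||%
    paste0(as.character(groups), ".", seq_along(read_sets))
  structure(list(counts = counts, peaks = consensus,
                 groups = factor(as.character(groups), levels = c("A", "B")),
                 lib_sizes = vapply(read_sets, length, 1L)),
            class = "affinity_matrix")
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("<affinity_matrix> %d peaks x %d samples (A: %d, B: %d)\n",
              nrow(x$counts), ncol(x$counts), sum(x$groups == "A"),
              sum(x$groups == "B")))
  invisible(x)
}

# median-of-ratios size factors (geometric-mean reference over peaks with
# all-positive counts); falls back to total-count ratios when no peak
# qualifies.
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    loggeo <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2, function(x)
      exp(stats::median(log(x) - loggeo)))
  } else {
    warning("no peak with all-positive counts; using total-count size factors")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
  }
  sf
}

#' Test differential occupancy between two lineages
#'
#' A transparent negative-binomial Wald test on the affinity matrix:
#' samples are normalized by median-of-ratios size factors, a single common
#' dispersion is estimated by method-of-moments on normalized counts pooled
#' across peaks (floored at 1e-6), and the per-peak log2 fold change
#' (A over B) is tested with a Wald statistic whose variance follows the
#' NB model `var = mu + phi mu^2`. P-values are BH-adjusted and peaks are
#' classified `enriched_A` / `enriched_B` when `FDR <= fdr_max` and
#' `|log2FC| >= log2(min_fold)` (inclusive), `not_differential` otherwise.
#'
#' @param am `affinity_matrix` from [count_affinity()]; both groups need
#'   >= 2 replicates.
#' @param fdr_max FDR threshold (default 0.01).
#' @param min_fold minimum fold change (default 2).
#' @return a `differential_result`: data.frame with coordinates (0-based
#'   half-open), per-group normalized means, `log2_fc`, `pvalue`, `fdr`,
#'   `class`; the consensus `GRanges` and parameters as attributes.
#' @export
test_differential <- function(am, fdr_max = 0.01, min_fold = 2) {
  stopifnot(inherits(am, "affinity_matrix"))
  a_idx <- which(am$groups == "A")
  b_idx <- which(am$groups == "B")
  if (length(a_idx) < 2L || length(b_idx) < 2L) {
    stop("invalid design: each group needs >= 2 replicates", call. = FALSE)
  }
  counts <- am$counts
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  mean_a <- rowMeans(norm[, a_idx, drop = FALSE])
  mean_b <- rowMeans(norm[, b_idx, drop = FALSE])

  # pooled method-of-moments common dispersion:
  # var(norm count) ~ mu * mean(1/sf) + phi * mu^2
  phi_of <- function(idx) {
    m <- rowMeans(norm[, idx, drop = FALSE])
    v <- apply(norm[, idx, drop = FALSE], 1, stats::var)
    ok <- m > 0
    (v[ok] - m[ok] * mean(1 / sf[idx])) / m[ok]^2
  }
  phis <- c(phi_of(a_idx), phi_of(b_idx))
  phi <- max(mean(phis[is.finite(phis)]), 1e-6)

  all_zero <- mean_a == 0 & mean_b == 0
  # continuity: a half-count pseudo-mean where one group is all zero
  ps <- ifelse(mean_a == 0 | mean_b == 0, 0.5, 0)
  ma <- mean_a + ps
  mb <- mean_b + ps
  log2_fc <- log2(ma / mb)
  var_mean <- function(m, idx) {
    (1 / length(idx)^2) * sum(m / sf[idx] + phi * m^2)
  }
  se_log2 <- sqrt(
    vapply(seq_along(ma), function(i)
      var_mean(ma[i], a_idx) / ma[i]^2 + var_mean(mb[i], b_idx) / mb[i]^2,
      numeric(1))) / log(2)
  wald <- log2_fc / se_log2
  pvalue <- 2 * stats::pnorm(-abs(wald))
  pvalue[all_zero] <- 1
  log2_fc[all_zero] <- 0
  fdr <- stats::p.adjust(pvalue, method = "BH")
  class <- ifelse(fdr <= fdr_max & abs(log2_fc) >= log2(min_fold),
                  ifelse(log2_fc > 0, "enriched_A", "enriched_B"),
                  "not_differential")
  res <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(am$peaks)),
    start = start0(am$peaks), end = end0(am$peaks),
    mean_A = mean_a, mean_B = mean_b, log2_fc = log2_fc,
    pvalue = pvalue, fdr = fdr, class = class,
    stringsAsFactors = FALSE)
  attr(res, "peaks") <- am$peaks
  attr(res, "params") <- list(fdr_max = fdr_max, min_fold = min_fold,
                              dispersion = phi, size_factors = sf)
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Extract one class of a differential result as GRanges
#'
#' @param res a `differential_result`.
#' @param which `"enriched_A"`, `"enriched_B"` or `"not_differential"`.
#' @return `GRanges` of the matching consensus peaks.
#' @export
differential_class <- function(res, which = c("enriched_A", "enriched_B",
                                              "not_differential")) {
  which <- match.arg(which)
  peaks <- attr(res, "peaks")
  out <- GenomicRanges::granges(peaks[res$class == which])
  out$name <- sprintf("%s_%d", which, seq_along(out))
  out
}

#' Write a differential result as TSV (and per-class BEDs)
#'
#' @param res `differential_result`.
#' @param path TSV output path.
#' @param bed_dir if non-NULL, writes `enriched_A.bed`, `enriched_B.bed`
#'   and `not_differential.bed` there.
#' @return `path`, invisibly.
#' @export
write_differential <- function(res, path, bed_dir = NULL) {
  df <- as.data.frame(res)
  num <- vapply(df, is.numeric, TRUE) & names(df) %in%
    c("mean_A", "mean_B", "log2_fc", "pvalue", "fdr")
  df[num] <- lapply(df[num], format_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_dir)) {
    dir.create(bed_dir, recursive = TRUE, showWarnings = FALSE)
    for (cls in c("enriched_A", "enriched_B", "not_differential")) {
      write_bed(differential_class(res, cls),
                file.path(bed_dir, paste0(cls, ".bed")))
    }
  }
  invisible(path)
}
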