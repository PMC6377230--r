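#' Peak calling configuration
#'
#' @param q_threshold BH FDR threshold for significant fragments
#'   (default 0.05).
#' @param merge_gap maximum number of non-significant fragments allowed
#'   between merged significant fragments (default 1).
#' @param min_fragments minimum significant fragments per reported peak
#'   (default 2).
#' @param local_lambda_windows window widths (bp) for the local background
#'   rate in control-free (accessibility) mode; default 5 and 10 kb.
#' @return a `peak_call_config` list.
#' @export
peak_call_config <- function(q_threshold = 0.05, merge_gap = 1L,
                             min_fragments = 2L,
                             local_lambda_windows = c(5000L, 10000L)) {
  stopifnot(q_threshold > 0, q_threshold < 1, merge_gap >= 0L,
            min_fragments >= 1L, all(local_lambda_windows > 0))
  structure(list(q_threshold = q_threshold,
                 merge_gap = as.integer(merge_gap),
                 min_fragments = as.integer(min_fragments),
                 local_lambda_windows = as.integer(local_lambda_windows)),
            class = "peak_call_config")
}

# merge significant fragments into peaks; shared by both calling modes.
# p, q: per-fragment; signal: per-fragment signal reported in output.
merge_significant <- function(fragments, p, q, signal, cfg, mode) {
  sig <- which(q <= cfg$q_threshold)
  if (!length(sig)) {
    out <- empty_peakset()
    S4Vectors::metadata(out) <- list(mode = mode, config = cfg)
    return(out)
  }
  chrom <- as.character(GenomicRanges::seqnames(fragments))
  # break groups at chromosome changes or gaps > merge_gap fragments
  brk <- c(TRUE, diff(sig) - 1L > cfg$merge_gap |
                 chrom[sig[-1]] != chrom[sig[-length(sig)]])
  grp <- cumsum(brk)
  keep_grp <- which(tabulate(grp) >= cfg$min_fragments)
  if (!length(keep_grp)) {
    out <- empty_peakset()
    S4Vectors::metadata(out) <- list(mode = mode, config = cfg)
    return(out)
  }
  peaks <- lapply(keep_grp, function(g) {
    idx <- sig[grp == g]
    # best fragment: smallest p, ties to highest signal then leftmost
    best <- idx[order(p[idx], -signal[idx], idx)][1]
    qv <- max(q[best], 1e-300)
    pv <- max(p[best], 1e-300)
    data.frame(
      chrom = chrom[idx[1]],
      start = GenomicRanges::start(fragments)[idx[1]],
      end = GenomicRanges::end(fragments)[idx[length(idx)]],
      summit0 = center0(fragments[best]),
      score = -log10(qv), signal = signal[best],
      p_log10 = -log10(pv), q_log10 = -log10(qv))
  })
  df <- do.call(rbind, peaks)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               seqinfo = GenomeInfoDb::seqinfo(fragments))
  gr$name <- sprintf("%s_peak_%d", mode, seq_along(gr))
  gr$score <- df$score
  gr$signalValue <- df$signal
  gr$pValue <- df$p_log10
  gr$qValue <- df$q_log10
  gr$peak <- df$summit0 - start0(gr)  # summit offset from peak start
  S4Vectors::metadata(gr) <- list(mode = mode, config = cfg)
  gr
}

#' Call bound regions from fusion vs Dam-only counts (TaDa mode)
#'
#' A transparent fragment-resolution caller: for each GATC fragment the
#' fusion count is tested against a Poisson expectation given by the
#' Dam-only count rescaled by the library-size ratio, floored at the
#' genome-wide control rate times fragment length (and at 0.25), so
#' zero-control fragments are tested against the global background rather
#' than against nothing; one-sided for enrichment. Benjamini-Hochberg FDR is applied genome-wide, significant
#' fragments separated by at most `merge_gap` non-significant fragments are
#' merged, and merged runs with fewer than `min_fragments` significant
#' fragments are dropped.
#'
#' @param fusion,dam `fragment_counts` on the same fragment table.
#' @param cfg a [peak_call_config()].
#' @return `GRanges` peakset with narrowPeak-style metadata columns
#'   (`score` = -log10 q of the best fragment, `signalValue` = fusion cpm at
#'   the best fragment, `pValue`/`qValue` -log10, `peak` summit offset).
#' @export
call_peaks_ratio <- function(fusion, dam, cfg = peak_call_config()) {
  stopifnot(inherits(fusion, "fragment_counts"),
            inherits(dam, "fragment_counts"))
  if (length(fusion$counts) != length(dam$counts) ||
      !identical(IRanges::ranges(fusion$fragments),
                 IRanges::ranges(dam$fragments))) {
    stop("fusion and dam counts are on different fragment tables",
         call. = FALSE)
  }
  if (fusion$lib_size <= 0 || dam$lib_size <= 0) {
    stop("library sizes must be positive", call. = FALSE)
  }
  scaled <- dam$counts * (fusion$lib_size / dam$lib_size)
  # background floor: the genome-wide control rate per bp, so zero-control
  # fragments are tested against the global expectation, not against ~0
  len <- GenomicRanges::width(fusion$fragments)
  bg <- sum(scaled) / sum(len) * len
  expected <- pmax(scaled, bg, 0.25)
  p <- stats::ppois(fusion$counts - 1, expected, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  merge_significant(fusion$fragments, p, q, cpm(fusion), cfg, "tada")
}

#' Call accessible regions from Dam-only counts (CaTaDa mode)
#'
#' Control-free calling: each fragment's count is tested against a Poisson
#' expectation `lambda = rate * fragment_length`, where the rate (counts
#' per bp) is the maximum of the genome-wide rate and local rates computed
#' over windows centered on the fragment (`local_lambda_windows`), in the
#' spirit of a local-lambda background model. Merging as in
#' [call_peaks_ratio()].
#'
#' @param dam `fragment_counts` for the Dam-only channel.
#' @param cfg a [peak_call_config()].
#' @return `GRanges` peakset (see [call_peaks_ratio()]).
#' @export
call_peaks_accessibility <- function(dam, cfg = peak_call_config()) {
  stopifnot(inherits(dam, "fragment_counts"))
  if (dam$lib_size <= 0) stop("library size must be positive", call. = FALSE)
  frag <- dam$fragments
  len <- GenomicRanges::width(frag)
  counts <- dam$counts
  rate <- rep(sum(counts) / sum(len), length(frag))  # genome-wide rate
  chrom <- as.character(GenomicRanges::seqnames(frag))
  mid <- center0(frag)
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    clen <- GenomeInfoDb::seqlengths(frag)[[chr]]
    starts <- start0(frag)[idx]
    ccum <- c(0, cumsum(counts[idx]))
    lcum <- c(0, cumsum(as.numeric(len[idx])))
    for (w in cfg$local_lambda_windows) {
      ws <- pmax(mid[idx] - w %/% 2, 0)
      we <- pmin(mid[idx] + w %/% 2, clen)
      # fragments overlapping [ws, we): the tiling makes this a prefix range
      first <- findInterval(ws, starts)
      last <- findInterval(we - 1L, starts)
      local_rate <- (ccum[last + 1L] - ccum[first]) /
        (lcum[last + 1L] - lcum[first])
      rate[idx] <- pmax(rate[idx], local_rate)
    }
  }
  lambda <- rate * len
  p <- stats::ppois(counts - 1, lambda, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  merge_significant(frag, p, q, cpm(dam), cfg, "catada")
}
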