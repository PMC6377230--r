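#' Scan a genome for GATC motifs
#'
#' DamID signal lives on the fragments produced by DpnI digestion of
#' methylated GATC sites. DpnI cuts between the A and the T (GA^TC), so each
#' motif occurrence at 0-based position `m` contributes one cut point at
#' `m + 2`. Matching is case-insensitive; the motif cannot overlap itself.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @return a `gatc_map`: named list with, per chromosome, the sorted integer
#'   vector of 0-based cut coordinates; chromosome lengths kept as an
#'   attribute.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "AAGATCAA"))
#' scan_gatc(g)$chr  # 4
#' @export
scan_gatc <- function(genome) {
  lens <- genome_lengths(genome)
  if (!length(genome) || any(lens == 0L)) {
    stop("genome is empty", call. = FALSE)
  }
  freq <- Biostrings::alphabetFrequency(genome)
  allowed <- c("A", "C", "G", "T", "N")
  other <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE])
  if (any(other > 0)) {
    i <- which(other > 0)[1]
    pos <- regexpr("[^ACGTNacgtn]", as.character(genome[[i]]))
    stop(sprintf("non-ACGTN character in %s at position %d",
                 names(genome)[i], as.integer(pos)), call. = FALSE)
  }
  hits <- Biostrings::vmatchPattern("GATC", genome)
  cuts <- lapply(seq_along(genome), function(i) {
    s <- BiocGenerics::start(hits[[i]])  # 1-based motif starts
    as.integer(sort(s + 1L))             # 0-based motif start + 2
  })
  names(cuts) <- names(genome)
  structure(cuts, class = "gatc_map", seqlengths = lens)
}

#' Build the GATC fragment table
#'
#' Tiles every chromosome into the fragments between successive GATC cut
#' points: `[0, cut_1)`, `[cut_i, cut_{i+1})`, `[cut_k, length)`. A
#' chromosome with `k` cuts yields exactly `k + 1` fragments. This table is
#' the coordinate system of all DamID signals.
#'
#' @param gatc a `gatc_map` from [scan_gatc()].
#' @param genome the same genome (for chromosome lengths), or a named
#'   length vector.
#' @return a [GenomicRanges::GRanges] of fragments, sorted, with an `id`
#'   column (1..n over the whole genome) and seqlengths set.
#' @export
build_fragments <- function(gatc, genome) {
  stopifnot(inherits(gatc, "gatc_map"))
  lens <- if (methods::is(genome, "DNAStringSet")) genome_lengths(genome)
          else genome
  check_same_genome(names(gatc), names(lens), "GATC map and genome")
  pieces <- lapply(names(gatc), function(chr) {
    cuts <- gatc[[chr]]
    len <- lens[[chr]]
    if (length(cuts) && (any(cuts <= 0L) || any(cuts >= len))) {
      stop(sprintf("GATC cut outside (0, %d) on %s", len, chr),
           call. = FALSE)
    }
    bounds <- c(0L, cuts, len)
    data.frame(chrom = chr, start0 = bounds[-length(bounds)],
               end0 = bounds[-1])
  })
  df <- do.call(rbind, pieces)
  gr <- granges0(df$chrom, df$start0, df$end0, lens)
  gr$id <- seq_along(gr)
  gr
}

#' Extend aligned reads to DpnI fragment boundaries
#'
#' Each read is extended from its 5' end in the direction of its strand to a
#' total length of `L` bp, or to the closest GATC cut strictly beyond the
#' read's original 3' end, whichever comes first. Reads are never shortened
#' and extension is clipped at chromosome bounds. Minus-strand reads extend
#' leftwards.
#'
#' @param reads `GRanges` of aligned reads with strand (`+`/`-`).
#' @param gatc `gatc_map` from [scan_gatc()].
#' @param L maximum extended length in bp (default 300).
#' @return `GRanges` of extended intervals, same order and metadata as
#'   `reads`.
#' @export
extend_reads <- function(reads, gatc, L = 300L) {
  stopifnot(inherits(gatc, "gatc_map"), L >= 1L)
  lens <- attr(gatc, "seqlengths")
  chrom <- as.character(GenomicRanges::seqnames(reads))
  check_same_genome(unique(chrom), names(gatc), "reads")
  s0 <- start0(reads)
  e0 <- end0(reads)
  if (any(s0 < 0L) || any(e0 > lens[chrom])) {
    stop("read outside chromosome bounds", call. = FALSE)
  }
  str <- as.character(GenomicRanges::strand(reads))
  plus <- str != "-"
  ns0 <- s0
  ne0 <- e0
  for (chr in unique(chrom)) {
    cuts <- gatc[[chr]]
    len <- lens[[chr]]
    idx <- which(chrom == chr)
    ip <- idx[plus[idx]]
    if (length(ip)) {
      # first cut >= e0 (cut at the end boundary stops extension there)
      nxt <- findInterval(e0[ip] - 1L, cuts) + 1L
      cut <- if (length(cuts)) {
        ifelse(nxt <= length(cuts), cuts[pmin(nxt, length(cuts))], Inf)
      } else Inf
      ne0[ip] <- pmax(e0[ip], pmin(s0[ip] + L, cut, len))
    }
    im <- idx[!plus[idx]]
    if (length(im)) {
      # last cut <= s0
      prv <- findInterval(s0[im], cuts)
      cut <- if (length(cuts)) {
        ifelse(prv >= 1L, cuts[pmax(prv, 1L)], -Inf)
      } else -Inf
      ns0[im] <- pmin(s0[im], pmax(e0[im] - L, cut, 0))
    }
  }
  out <- reads
  IRanges::ranges(out) <- IRanges::IRanges(start = as.integer(ns0) + 1L,
                                           end = as.integer(ne0))
  out
}

#' Per-fragment read counts
#'
#' Every (extended) read increments the count of each fragment it overlaps
#' by at least one bp. The library size is the number of reads, not the sum
#' of counts, since one extended read may span several fragments.
#'
#' @param reads `GRanges` of (extended) read intervals.
#' @param fragments fragment `GRanges` from [build_fragments()].
#' @param sample sample label.
#' @param channel `"dam_fusion"` or `"dam_only"`.
#' @param lib_size library size; defaults to `length(reads)`.
#' @return a `fragment_counts` object (integer counts parallel to
#'   `fragments`).
#' @export
count_fragments <- function(reads, fragments,
                            sample = "sample",
                            channel = c("dam_fusion", "dam_only"),
                            lib_size = length(reads)) {
  channel <- match.arg(channel)
  check_same_genome(as.character(unique(GenomicRanges::seqnames(reads))),
                    GenomeInfoDb::seqlevels(fragments), "reads")
  counts <- GenomicRanges::countOverlaps(fragments, reads, minoverlap = 1L,
                                         ignore.strand = TRUE)
  fragment_counts(counts, fragments, sample = sample, channel = channel,
                  lib_size = lib_size)
}

#' Construct a fragment_counts object from a count vector
#'
#' @param counts non-negative integer vector, one entry per fragment.
#' @param fragments fragment `GRanges`.
#' @param sample,channel labels.
#' @param lib_size library size (reads); defaults to `sum(counts)` so that
#'   count vectors built directly (e.g. in tests) are cpm-consistent.
#' @return `fragment_counts` object.
#' @export
fragment_counts <- function(counts, fragments, sample = "sample",
                            channel = "dam_fusion",
                            lib_size = sum(counts)) {
  stopifnot(length(counts) == length(fragments), all(counts >= 0),
            lib_size > 0)
  structure(
    list(counts = as.numeric(counts), fragments = fragments,
         sample = sample, channel = channel, lib_size = as.numeric(lib_size)),
    class = "fragment_counts"
  )
}

#' @export
print.fragment_counts <- function(x, ...) {
  cat(sprintf("<fragment_counts> %s [%s]: %d fragments, library %g reads\n",
              x$sample, x$channel, length(x$counts), x$lib_size))
  invisible(x)
}

# counts-per-million by library size
cpm <- function(fc) fc$counts / fc$lib_size * 1e6

# equal-frequency decile rank bins (1 = lowest); ties broken by fragment id
decile_bins <- function(x) {
  n <- length(x)
  ord <- order(x, seq_len(n))
  bins <- integer(n)
  bins[ord] <- floor((seq_len(n) - 1L) * 10 / n) + 1L
  bins
}

#' Decile-exclusion normalized log2 ratio track
#'
#' Computes the per-fragment normalized `log2(fusion/Dam)` signal, the
#' "ratio file" of a DamID experiment. Both channels are scaled to counts
#' per million, fragments are ranked into equal-frequency deciles on each
#' channel, and the normalization factor is estimated on the retained set:
#' fragments outside the fusion top decile (likely true signal) and outside
#' the Dam-only bottom three deciles (noise), with a non-zero raw count in
#' both channels. The factor `f` is the median retained log2 ratio and is
#' subtracted from every fragment's ratio, so the retained-set median of the
#' track is exactly zero.
#'
#' @param fusion,dam `fragment_counts` on the same fragment table
#'   (Dam-fusion and Dam-only channels).
#' @param pseudocount pseudo-cpm added to both channels (default 0.5) so
#'   zero-count fragments stay finite.
#' @return a `ratio_track`: list with `fragments`, `value`, `factor`,
#'   `retained` (logical), `pseudocount` and sample labels.
#' @export
normalize_decile <- function(fusion, dam, pseudocount = 0.5) {
  stopifnot(inherits(fusion, "fragment_counts"),
            inherits(dam, "fragment_counts"),
            length(fusion$counts) == length(dam$counts))
  if (fusion$lib_size <= 0 || dam$lib_size <= 0) {
    stop("library sizes must be positive", call. = FALSE)
  }
  fcpm <- cpm(fusion)
  dcpm <- cpm(dam)
  ratio <- log2((fcpm + pseudocount) / (dcpm + pseudocount))
  fbin <- decile_bins(fcpm)
  dbin <- decile_bins(dcpm)
  retained <- fbin < 10L & dbin > 3L & fusion$counts > 0 & dam$counts > 0
  if (!any(retained)) {
    stop(paste("decile normalization retained no fragments;",
               "review pseudocount and count thresholds"), call. = FALSE)
  }
  f <- stats::median(ratio[retained])
  structure(
    list(fragments = fusion$fragments, value = ratio - f, factor = f,
         retained = retained, pseudocount = pseudocount,
         fusion_sample = fusion$sample, dam_sample = dam$sample),
    class = "ratio_track"
  )
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf(
    "<ratio_track> log2(%s/%s): %d fragments, factor %.4f, %d retained\n",
    x$fusion_sample, x$dam_sample, length(x$value), x$factor,
    sum(x$retained)))
  invisible(x)
}
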