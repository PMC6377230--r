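#' Overlap between two peaksets (>= 1 bp rule)
#'
#' An overlap of one basepair or more counts as an overlap. Reported in
#' both directions: how many A peaks touch at least one B peak, and vice
#' versa.
#'
#' @param A,B peak `GRanges` on the same genome.
#' @return an `overlap_result` list: `n_A`, `n_B`, `A_in_B`, `B_in_A`,
#'   `frac_A`, `frac_B`.
#' @export
overlap_peaks <- function(A, B) {
  a_in_b <- sum(IRanges::overlapsAny(A, B, minoverlap = 1L))
  b_in_a <- sum(IRanges::overlapsAny(B, A, minoverlap = 1L))
  structure(list(n_A = length(A), n_B = length(B),
                 A_in_B = a_in_b, B_in_A = b_in_a,
                 frac_A = if (length(A)) a_in_b / length(A) else NA_real_,
                 frac_B = if (length(B)) b_in_a / length(B) else NA_real_),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> A: %d/%d (%.1f%%), B: %d/%d (%.1f%%)\n",
              x$A_in_B, x$n_A, 100 * x$frac_A,
              x$B_in_A, x$n_B, 100 * x$frac_B))
  invisible(x)
}

#' Random peakset preserving per-chromosome counts and lengths
#'
#' For every chromosome, each reference peak's length is placed at a start
#' drawn uniformly from `[0, chrom_length - length]`; placements are
#' independent, so random peaks may overlap each other. The per-chromosome
#' multiset of peak lengths is preserved exactly on every draw.
#'
#' @param reference peak `GRanges` whose chromosome/length structure is
#'   reproduced.
#' @param seqlengths named chromosome lengths (bp); defaults to the
#'   seqlengths of `reference`.
#' @param seed optional integer seed; `NULL` uses (and advances) the
#'   current RNG stream.
#' @return `GRanges` of randomized peaks.
#' @export
random_peakset <- function(reference, seqlengths = NULL, seed = NULL) {
  seqlengths <- seqlengths %||% GenomeInfoDb::seqlengths(reference)
  if (any(is.na(seqlengths))) {
    stop("chromosome lengths required (set seqlengths)", call. = FALSE)
  }
  chrom <- as.character(GenomicRanges::seqnames(reference))
  w <- GenomicRanges::width(reference)
  if (any(w > seqlengths[chrom])) {
    stop("reference peak longer than its chromosome", call. = FALSE)
  }
  with_seed(seed, {
    max_start0 <- seqlengths[chrom] - w  # inclusive upper bound
    s0 <- floor(stats::runif(length(w)) * (max_start0 + 1))
    s0 <- pmin(s0, max_start0)  # guard the measure-zero runif(1) == 1 edge
    granges0(chrom, s0, s0 + w, seqlengths)
  })
}

mc_result <- function(observed, null, n_iter, seed, extra = list()) {
  mu <- mean(null)
  sd0 <- stats::sd(null)
  degenerate <- !is.finite(sd0) || sd0 == 0
  z <- if (degenerate) NA_real_ else (observed - mu) / sd0
  n_ge <- sum(null >= observed)
  n_tie <- sum(null == observed)
  structure(c(list(
    observed = observed, null_mean = mu, null_sd = sd0,
    z = z,
    p_parametric = if (degenerate) NA_real_ else
      stats::pnorm(z, lower.tail = FALSE),
    p_empirical = (n_ge + 1) / (length(null) + 1),
    # tie-corrected mid-p: exactly calibrated under exchangeability even
    # when the statistic is discrete; p_empirical is conservative then
    p_mid = (n_ge - 0.5 * n_tie + 0.5) / (length(null) + 1),
    null_ties = n_tie,
    degenerate = degenerate, n_iter = n_iter, seed = seed), extra),
    class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "<mc_result> observed %.4g vs null %.4g +/- %.4g (n=%d): Z=%.2f, p_param=%.3g, p_emp=%.3g%s\n",
    x$observed, x$null_mean, x$null_sd, x$n_iter,
    ifelse(is.na(x$z), NaN, x$z), x$p_parametric, x$p_empirical,
    if (x$degenerate) " [degenerate null]" else ""))
  invisible(x)
}

#' Monte Carlo overlap test
#'
#' Tests whether the fraction of A peaks overlapping B exceeds chance. The
#' null is built by randomizing A with [random_peakset()] (B stays fixed)
#' `n_iter` times and recomputing the overlap fraction. Reports the null
#' mean/sd, Z-score, one-sided parametric normal-tail p, the empirical
#' p `(r + 1)/(n + 1)` with `r` the null draws `>=` observed, and the
#' tie-corrected mid-p (the overlap count is integer-valued, so null draws
#' tie with the observed value at appreciable rates for sparse peaksets;
#' the empirical p is then conservative while the mid-p stays calibrated).
#'
#' @param A query peakset (randomized under the null).
#' @param B fixed comparator peakset.
#' @param n_iter iterations (default 100).
#' @param seed integer seed.
#' @param seqlengths named chromosome lengths; default from `A`.
#' @return an `mc_result`.
#' @export
mc_overlap <- function(A, B, n_iter = 100L, seed = 1L, seqlengths = NULL) {
  if (!length(A) || !length(B)) stop("empty peakset", call. = FALSE)
  seqlengths <- seqlengths %||% GenomeInfoDb::seqlengths(A)
  observed <- mean(IRanges::overlapsAny(A, B, minoverlap = 1L))
  null <- with_seed(derive_seed(seed, "mc_overlap"), {
    vapply(seq_len(n_iter), function(i) {
      mean(IRanges::overlapsAny(random_peakset(A, seqlengths), B,
                                minoverlap = 1L))
    }, numeric(1))
  })
  mc_result(observed, null, n_iter, seed)
}

#' Mean signal over peak-centered windows
#'
#' Each region is replaced by a window of `2 * half_width` bp centered on
#' its midpoint (clipped at chromosome ends); the per-window mean is the
#' length-weighted average of the signal over covered bases, with bases
#' lacking signal counted as 0. The grand mean is the unweighted mean of
#' per-window means.
#'
#' @param regions peak `GRanges`.
#' @param signal a `ratio_track` or `GRanges` with a `value` column.
#' @param half_width half window width in bp (default 2000).
#' @param seqlengths named chromosome lengths for clipping; default from
#'   `regions` or `signal`.
#' @return list with `means` (per region) and `grand_mean`.
#' @export
mean_signal_at <- function(regions, signal, half_width = 2000L,
                           seqlengths = NULL) {
  if (!length(regions)) stop("empty region set", call. = FALSE)
  sig <- as_signal_granges(signal)
  seqlengths <- seqlengths %||% GenomeInfoDb::seqlengths(regions)
  if (any(is.na(seqlengths))) {
    seqlengths <- GenomeInfoDb::seqlengths(sig)
  }
  chrom <- as.character(GenomicRanges::seqnames(regions))
  mid <- center0(regions)
  ws <- pmax(mid - half_width, 0)
  we <- pmin(mid + half_width,
             if (all(is.na(seqlengths))) mid + half_width
             else seqlengths[chrom])
  win <- granges0(chrom, ws, we)
  hits <- GenomicRanges::findOverlaps(win, sig, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(end0(win)[qh], end0(sig)[sh]) -
    pmax(start0(win)[qh], start0(sig)[sh])
  wsum <- numeric(length(win))
  contrib <- tapply(ov * sig$value[sh], qh, sum)
  wsum[as.integer(names(contrib))] <- contrib
  means <- wsum / GenomicRanges::width(win)
  list(means = means, grand_mean = mean(means))
}

#' Monte Carlo signal-ratio test between two peaksets
#'
#' The observed statistic is the ratio of grand mean signal over A's
#' windows to that over B's windows (the raw difference is also reported).
#' Each null draw randomizes both peaksets with [random_peakset()] and
#' recomputes the statistic. Z, parametric and empirical p are reported
#' for the ratio; difference statistics are carried alongside.
#'
#' @param signal `ratio_track` or `GRanges` signal track.
#' @param A,B peaksets to compare.
#' @param n_iter iterations (default 1000).
#' @param seed integer seed.
#' @param half_width window half-width (default 2000 bp, i.e. 4-kb
#'   windows).
#' @param seqlengths named chromosome lengths.
#' @return an `mc_result` with extra fields `observed_diff`,
#'   `null_diff_mean`, `null_diff_sd`, `z_diff`, `p_parametric_diff`.
#' @export
mc_signal_ratio <- function(signal, A, B, n_iter = 1000L, seed = 1L,
                            half_width = 2000L, seqlengths = NULL) {
  if (!length(A) || !length(B)) stop("empty peakset", call. = FALSE)
  sig <- as_signal_granges(signal)
  seqlengths <- seqlengths %||% GenomeInfoDb::seqlengths(sig)
  gm_a <- mean_signal_at(A, sig, half_width, seqlengths)$grand_mean
  gm_b <- mean_signal_at(B, sig, half_width, seqlengths)$grand_mean
  obs_diff <- gm_a - gm_b
  obs_ratio <- if (gm_b == 0) NA_real_ else gm_a / gm_b
  draws <- with_seed(derive_seed(seed, "mc_signal_ratio"), {
    vapply(seq_len(n_iter), function(i) {
      ra <- mean_signal_at(random_peakset(A, seqlengths), sig, half_width,
                           seqlengths)$grand_mean
      rb <- mean_signal_at(random_peakset(B, seqlengths), sig, half_width,
                           seqlengths)$grand_mean
      c(ratio = if (rb == 0) NA_real_ else ra / rb, diff = ra - rb)
    }, numeric(2))
  })
  null_diff <- draws["diff", ]
  sd_diff <- stats::sd(null_diff)
  z_diff <- if (sd_diff > 0) (obs_diff - mean(null_diff)) / sd_diff
            else NA_real_
  extra <- list(
    observed_diff = obs_diff, null_diff_mean = mean(null_diff),
    null_diff_sd = sd_diff, z_diff = z_diff,
    p_parametric_diff = if (is.na(z_diff)) NA_real_ else
      stats::pnorm(z_diff, lower.tail = FALSE),
    half_width = half_width)
  if (is.na(obs_ratio) || anyNA(draws["ratio", ])) {
    # ratio undefined somewhere: difference-only result
    res <- mc_result(obs_diff, null_diff, n_iter, seed, extra)
    res$ratio_defined <- FALSE
    return(res)
  }
  res <- mc_result(obs_ratio, draws["ratio", ], n_iter, seed, extra)
  res$ratio_defined <- TRUE
  res
}

# two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# enumeration: sum of the probabilities of all tables with the observed
# margins whose probability does not exceed the observed table's.
fisher_p_2x2 <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Closest-peak distances and Fisher enrichment test
#'
#' For each peak in A and in B, computes the distance from its center to
#' the nearest edge of a reference peak (0 when the center lies inside
#' one), counts peaks with distance <= `d`, and tests association with a
#' two-sided Fisher exact test on the 2x2 table
#' `[[within_A, |A| - within_A], [within_B, |B| - within_B]]`, computed by
#' exhaustive hypergeometric enumeration.
#'
#' @param A,B query peaksets.
#' @param reference reference peakset.
#' @param d distance threshold in bp (default 2000).
#' @return a `closest_result` list: per-set distance vectors, within
#'   counts, the 2x2 table and `p_fisher`.
#' @export
closest_fisher <- function(A, B, reference, d = 2000L) {
  if (!length(A) || !length(B) || !length(reference)) {
    stop("empty peakset", call. = FALSE)
  }
  dist_to_ref <- function(x) {
    mid <- center0(x)
    chrom <- as.character(GenomicRanges::seqnames(x))
    rs <- start0(reference)
    re <- end0(reference)
    rchrom <- as.character(GenomicRanges::seqnames(reference))
    vapply(seq_along(x), function(i) {
      j <- which(rchrom == chrom[i])
      if (!length(j)) return(Inf)
      inside <- rs[j] <= mid[i] & mid[i] < re[j]
      if (any(inside)) return(0)
      min(pmax(rs[j] - mid[i], mid[i] - re[j] + 1))
    }, numeric(1))
  }
  da <- dist_to_ref(A)
  db <- dist_to_ref(B)
  wa <- sum(da <= d)
  wb <- sum(db <= d)
  tab <- matrix(c(wa, length(A) - wa, wb, length(B) - wb), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("A", "B"), c("within", "beyond")))
  structure(list(dist_A = da, dist_B = db, within_A = wa, within_B = wb,
                 d = d, table = tab,
                 p_fisher = fisher_p_2x2(wa, length(A) - wa,
                                         wb, length(B) - wb)),
            class = "closest_result")
}

#' @export
print.closest_result <- function(x, ...) {
  cat(sprintf(
    "<closest_result> within %d bp: A %d/%d, B %d/%d; Fisher p = %.3g\n",
    x$d, x$within_A, length(x$dist_A), x$within_B, length(x$dist_B),
    x$p_fisher))
  invisible(x)
}

#' Serialize a Monte Carlo or closest result to JSON
#'
#' @param x an `mc_result`, `overlap_result` or `closest_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(x, path) {
  obj <- unclass(x)
  obj$dist_A <- NULL
  obj$dist_B <- NULL
  obj$table <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
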