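# Independent brute-force oracles. These deliberately take the naive route
# (per-base loops, all-pairs scans, independent sorting) so they share no
# code path with the implementation they check.

# 0-based GATC cut positions by sliding-window substring comparison
oracle_scan_gatc <- function(seq_char) {
  s <- toupper(seq_char)
  n <- nchar(s)
  if (n < 4) return(integer(0))
  cuts <- integer(0)
  for (i in seq_len(n - 3)) {
    if (substr(s, i, i + 3) == "GATC") cuts <- c(cuts, i + 1L)  # (i-1) + 2
  }
  cuts
}

# extend one read (0-based s0/e0, strand) against sorted 0-based cuts
oracle_extend_one <- function(s0, e0, strand, cuts, L, chrom_len) {
  if (strand != "-") {
    beyond <- cuts[cuts >= e0]
    stop_at <- if (length(beyond)) min(beyond) else Inf
    new_e <- max(e0, min(s0 + L, stop_at, chrom_len))
    c(s0, new_e)
  } else {
    before <- cuts[cuts <= s0]
    stop_at <- if (length(before)) max(before) else -Inf
    new_s <- min(s0, max(e0 - L, stop_at, 0))
    c(new_s, e0)
  }
}

# all-pairs overlap counts of reads over fragments (0-based half-open)
oracle_count_fragments <- function(read_s0, read_e0, frag_s0, frag_e0) {
  counts <- integer(length(frag_s0))
  for (i in seq_along(read_s0)) {
    hit <- read_s0[i] < frag_e0 & frag_s0 < read_e0[i]
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

# how many of A overlap >= 1 bp with any of B (all-pairs; one chromosome)
oracle_overlap_count <- function(a_s0, a_e0, b_s0, b_e0) {
  sum(vapply(seq_along(a_s0), function(i)
    any(a_s0[i] < b_e0 & b_s0 < a_e0[i]), logical(1)))
}

# independent decile-exclusion normalization: sorts value/id pairs rather
# than ranking, and computes deciles from sorted boundaries
oracle_decile_norm <- function(fus_counts, dam_counts, fus_lib, dam_lib,
                               pseudo = 0.5) {
  n <- length(fus_counts)
  fcpm <- fus_counts / fus_lib * 1e6
  dcpm <- dam_counts / dam_lib * 1e6
  # equal-frequency bins: fragment at sorted position r gets bin
  # floor((r-1)*10/n)+1; explicit per-position loop, ties by id
  bin_of <- function(x) {
    key <- order(x, seq_len(n))
    bins <- integer(n)
    for (r in seq_len(n)) bins[key[r]] <- floor((r - 1) * 10 / n) + 1
    bins
  }
  fbin <- bin_of(fcpm)
  dbin <- bin_of(dcpm)
  keep <- fbin != 10 & dbin >= 4 & fus_counts > 0 & dam_counts > 0
  ratio <- log2((fcpm + pseudo) / (dcpm + pseudo))
  f <- stats::median(ratio[keep])
  list(factor = f, value = ratio - f, retained = keep)
}

# per-base mean signal over a window [ws, we) given a signal data.frame
# (s0, e0, value); uncovered bases are 0
oracle_window_mean <- function(ws, we, sig_s0, sig_e0, sig_val) {
  base_vals <- numeric(we - ws)
  for (j in seq_along(sig_s0)) {
    lo <- max(ws, sig_s0[j])
    hi <- min(we, sig_e0[j])
    if (hi > lo) base_vals[(lo - ws + 1):(hi - ws)] <- sig_val[j]
  }
  mean(base_vals)
}

# consensus by quadratic union-find over pairwise overlaps
oracle_consensus <- function(peak_dfs, min_samples) {
  all <- do.call(rbind, lapply(seq_along(peak_dfs), function(i)
    cbind(peak_dfs[[i]], set = i)))
  n <- nrow(all)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && all$chrom[i] == all$chrom[j] &&
          all$s0[i] < all$e0[j] && all$s0[j] < all$e0[i]) {
        parent[find(j)] <- find(i)
      }
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  out <- do.call(rbind, lapply(unique(root), function(r) {
    idx <- which(root == r)
    data.frame(chrom = all$chrom[idx[1]], s0 = min(all$s0[idx]),
               e0 = max(all$e0[idx]),
               support = length(unique(all$set[idx])))
  }))
  out <- out[out$support >= min_samples, , drop = FALSE]
  out[order(out$chrom, out$s0), , drop = FALSE]
}

# GRanges -> plain 0-based data.frame
gr_to_df0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             s0 = GenomicRanges::start(gr) - 1L,
             e0 = GenomicRanges::end(gr))
}
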