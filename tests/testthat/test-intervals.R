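test_that("peak overlap uses the 1-bp rule and matches the all-pairs oracle", {
  sl <- c(chr1 = 1e5)
  A <- random_peaks_gr(50, sl)
  expect_equal(overlap_peaks(A, A)$frac_A, 1)
  expect_equal(overlap_peaks(A, A)$frac_B, 1)

  left <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  right <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  ovr <- overlap_peaks(left, right)   # adjacent, zero shared bases
  expect_equal(ovr$A_in_B, 0L)

  set.seed(61)
  sl2 <- c(chr1 = 5e4, chr2 = 5e4)
  for (i in 1:5) {
    A <- random_peaks_gr(60, sl2)
    B <- random_peaks_gr(80, sl2)
    got <- overlap_peaks(A, B)
    ad <- gr_to_df0(A)
    bd <- gr_to_df0(B)
    exp_a <- sum(vapply(seq_len(nrow(ad)), function(i) {
      j <- bd$chrom == ad$chrom[i]
      any(ad$s0[i] < bd$e0[j] & bd$s0[j] < ad$e0[i])
    }, logical(1)))
    expect_equal(got$A_in_B, exp_a)
  }
})

test_that("random peaksets preserve per-chromosome count and length multisets", {
  set.seed(62)
  sl <- c(chr1 = 3e4, chr2 = 6e4)
  ref <- random_peaks_gr(70, sl)
  for (i in 1:20) {
    rnd <- random_peakset(ref, sl)
    for (chr in names(sl)) {
      w_ref <- sort(GenomicRanges::width(ref[
        GenomicRanges::seqnames(ref) == chr]))
      w_rnd <- sort(GenomicRanges::width(rnd[
        GenomicRanges::seqnames(rnd) == chr]))
      expect_identical(w_ref, w_rnd)
      expect_true(all(GenomicRanges::start(rnd) >= 1L))
      expect_true(all(GenomicRanges::end(rnd) <= sl[
        as.character(GenomicRanges::seqnames(rnd))]))
    }
  }
  # a peak as long as its chromosome is forced to position 0
  full <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  forced <- random_peakset(full, c(chr1 = 100L), seed = 1L)
  expect_equal(GenomicRanges::start(forced) - 1L, 0L)
  expect_error(random_peakset(full, c(chr1 = 50L)), "longer than")
  # deterministic per seed
  r1 <- random_peakset(ref, sl, seed = 99L)
  r2 <- random_peakset(ref, sl, seed = 99L)
  expect_identical(gr_to_df0(r1), gr_to_df0(r2))
})

test_that("random placement is uniform over valid starts", {
  ref <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50))
  sl <- c(chr1 = 1050L)
  set.seed(63)
  starts <- vapply(1:10000, function(i)
    GenomicRanges::start(random_peakset(ref, sl)) - 1L, numeric(1))
  expect_true(all(starts >= 0 & starts <= 1000))
  # chi-square against discrete uniform over 10 equal bins
  bins <- table(cut(starts, breaks = seq(-0.5, 1000.5, length.out = 11)))
  expect_gt(chisq.test(bins)$p.value, 0.01)
})

test_that("Monte Carlo overlap flags constructed enrichment and degenerate nulls", {
  set.seed(64)
  sl <- c(chr1 = 5e6, chr2 = 5e6)
  A <- random_peaks_gr(100, sl, min_w = 200, max_w = 400)
  jit <- sample(c(-100L, 100L), length(A), replace = TRUE)
  B <- GenomicRanges::shift(A, jit)
  res <- mc_overlap(A, B, n_iter = 100L, seed = 2L, seqlengths = sl)
  expect_lt(res$p_parametric, 1e-10)
  expect_equal(res$p_empirical, 1 / 101)

  # same seed reproduces; different seeds agree within 3 combined SE
  res_b <- mc_overlap(A, B, n_iter = 100L, seed = 2L, seqlengths = sl)
  expect_identical(res[c("observed", "null_mean", "z")],
                   res_b[c("observed", "null_mean", "z")])
  res_c <- mc_overlap(A, B, n_iter = 100L, seed = 3L, seqlengths = sl)
  se <- sqrt(res$null_sd^2 / 100 + res_c$null_sd^2 / 100)
  expect_lt(abs(res$null_mean - res_c$null_mean), 3 * se)

  # B covering the genome: every draw overlaps -> degenerate, p_emp = 1
  cover <- GenomicRanges::GRanges(
    c("chr1", "chr2"), IRanges::IRanges(1, 5e6), seqlengths = sl)
  deg <- mc_overlap(A, cover, n_iter = 20L, seed = 5L, seqlengths = sl)
  expect_true(deg$degenerate)
  expect_equal(deg$observed, 1)
  expect_equal(deg$p_empirical, 1)
})

test_that("windowed mean signal matches the per-base oracle", {
  sl <- c(chr1 = 2e4)
  fr <- toy_fragments(rep(100L, 200))
  sig <- fr
  sig$value <- rep(2, 200)
  regions <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(5001, 9001),
                                                     width = 200),
                                    seqlengths = sl)
  ms <- mean_signal_at(regions, sig, half_width = 2000L)
  expect_equal(ms$means, c(2, 2))

  # signal on exactly half the window
  half <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3001, 5000),
                                 seqlengths = sl)
  half$value <- 1
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4901, 5100),
                                seqlengths = sl)
  expect_equal(mean_signal_at(win, half, half_width = 100L)$means, 0.5)

  set.seed(65)
  sig$value <- rnorm(200)
  regions <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(sample(2500:17500, 40), width = 150),
    seqlengths = sl)
  ms <- mean_signal_at(regions, sig, half_width = 1000L)
  sd0 <- gr_to_df0(sig)
  rd <- gr_to_df0(regions)
  mids <- floor((rd$s0 + rd$e0) / 2)
  orc <- vapply(seq_along(mids), function(i)
    oracle_window_mean(mids[i] - 1000, mids[i] + 1000, sd0$s0, sd0$e0,
                       sig$value), numeric(1))
  expect_equal(ms$means, orc, tolerance = 1e-12)
  expect_equal(ms$grand_mean, mean(orc), tolerance = 1e-12)
})

test_that("signal-ratio Monte Carlo detects constructed enrichment symmetrically", {
  set.seed(66)
  sl <- c(chr1 = 2e5)
  fr <- toy_fragments(rep(250L, 800))
  sig <- fr
  sig$value <- rep(1, 800)
  a_frag <- sample(50:750, 30)
  sig$value[a_frag] <- 8
  A <- fr[a_frag]
  B <- fr[sample(setdiff(50:750, a_frag), 30)]
  res <- mc_signal_ratio(sig, A, B, n_iter = 200L, seed = 7L,
                         half_width = 500L, seqlengths = sl)
  expect_true(res$ratio_defined)
  expect_lt(res$p_parametric, 1e-6)
  expect_gt(res$observed, 2)
  swapped <- mc_signal_ratio(sig, B, A, n_iter = 10L, seed = 7L,
                             half_width = 500L, seqlengths = sl)
  expect_equal(swapped$observed, 1 / res$observed, tolerance = 1e-12)
  same <- mc_signal_ratio(sig, A, A, n_iter = 10L, seed = 7L,
                          half_width = 500L, seqlengths = sl)
  expect_equal(same$observed, 1)
  expect_equal(res$observed_diff, -swapped$observed_diff,
               tolerance = 1e-12)
})

test_that("closest-peak distances and Fisher test follow their definitions", {
  sl <- c(chr1 = 1e5)
  ref <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(10001, 50001),
                                                 width = 1000),
                                seqlengths = sl)
  # centers: inside ref -> 0; left of ref; right of ref
  A <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(10401, 8001, 12501), width = 200),
    seqlengths = sl)
  B <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(70001, 90001), width = 200),
    seqlengths = sl)
  res <- closest_fisher(A, B, ref, d = 2000L)
  expect_equal(res$dist_A, c(0, 10000 - 8100, 12600 - 11000 + 1))
  expect_equal(res$within_A, 3L)
  expect_equal(res$within_B, 0L)
  expect_equal(res$p_fisher,
               fisher.test(matrix(c(3, 0, 0, 2), 2))$p.value,
               tolerance = 1e-12)

  # reference covering the genome: everything within, p = 1
  cover <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e5),
                                  seqlengths = sl)
  res2 <- closest_fisher(A, B, cover, d = 2000L)
  expect_equal(res2$within_A, 3L)
  expect_equal(res2$within_B, 2L)
  expect_equal(res2$p_fisher, 1)
})

test_that("balanced 2x2 tables give p = 1 and extreme tables match enumeration", {
  expect_equal(tadakit:::fisher_p_2x2(5, 5, 5, 5), 1)
  # [[10,0],[0,10]]: exhaustive enumeration over the hypergeometric support
  p_hand <- sum(dhyper(0:10, 10, 10, 10)[
    dhyper(0:10, 10, 10, 10) <= dhyper(10, 10, 10, 10) * (1 + 1e-7)])
  expect_equal(tadakit:::fisher_p_2x2(10, 0, 0, 10), p_hand)
  expect_equal(p_hand, fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value,
               tolerance = 1e-12)
  # symmetric under simultaneous row and column swaps
  expect_equal(tadakit:::fisher_p_2x2(7, 2, 3, 9),
               tadakit:::fisher_p_2x2(9, 3, 2, 7), tolerance = 1e-12)
})
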