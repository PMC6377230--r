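test_that("genome generation is deterministic and honors GC content", {
  cfg <- small_sim_config(seed = 5L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))

  # GATC count within 4 sd of the motif expectation at GC 0.5
  cfg1 <- sim_config(n_chroms = 1L, chrom_length = 1e6,
                     reads_per_sample = 1000L, n_open_shared = 2L,
                     n_open_A = 2L, n_open_B = 2L, n_bound_shared = 1L,
                     n_bound_A = 1L, n_bound_B = 1L, seed = 9L)
  g <- generate_genome(cfg1)
  n_gatc <- length(scan_gatc(g)$chr1)
  p <- 0.25^4                            # i.i.d. motif probability
  n_pos <- 1e6 - 3
  expect_lt(abs(n_gatc - n_pos * p), 4 * sqrt(n_pos * p * (1 - p)))

  # GC 0 -> no G/C emitted -> no GATC -> one fragment per chromosome
  cfg0 <- small_sim_config(gc_fraction = 0)
  g0 <- generate_genome(cfg0)
  expect_equal(sum(Biostrings::letterFrequency(g0, "GC")), 0)
  fr0 <- build_fragments(scan_gatc(g0), g0)
  expect_equal(length(fr0), cfg0$n_chroms)

  expect_error(sim_config(chrom_length = 500L, read_length = 100L),
               "chrom_length")
})

test_that("truth construction places bound loci inside matching open domains", {
  cfg <- small_sim_config(seed = 7L)
  fr <- build_fragments(scan_gatc(generate_genome(cfg)), c(chr1 = 2e5, chr2 = 2e5))
  tr <- build_truth(cfg, fr)

  open_ok <- c(tr$domains$open_A, tr$domains$open_shared)
  for (cls in c("A", "B")) {
    host <- c(tr$domains[[paste0("open_", cls)]], tr$domains$open_shared)
    bound <- tr$domains[[paste0("bound_", cls)]]
    within <- IRanges::overlapsAny(bound, host, type = "within")
    expect_true(all(within))
  }
  # occupancy above baseline only where accessibility is above baseline
  for (lin in c("A", "B")) {
    expect_true(all(tr$accessibility[[lin]][tr$occupancy[[lin]] > 1] > 1))
  }

  # accessibility fold is assigned deterministically
  open_a_frags <- unlist(lapply(seq_along(tr$domains$open_A), function(i)
    tr$domains$open_A$frag_first[i]:tr$domains$open_A$frag_last[i]))
  labelled <- unique(unlist(lapply(tr$domains[1:3], function(d)
    unlist(mapply(`:`, d$frag_first, d$frag_last, SIMPLIFY = FALSE)))))
  baseline <- setdiff(seq_along(fr), labelled)
  expect_equal(mean(tr$accessibility$A[open_a_frags]) /
                 mean(tr$accessibility$A[baseline]),
               cfg$accessibility_fold)

  # no A-specific domains -> A accessibility baseline outside shared
  cfg0 <- small_sim_config(n_open_A = 0L, n_bound_A = 0L)
  tr0 <- build_truth(cfg0, fr)
  sh <- unique(unlist(mapply(`:`, tr0$domains$open_shared$frag_first,
                             tr0$domains$open_shared$frag_last,
                             SIMPLIFY = FALSE)))
  expect_true(all(tr0$accessibility$A[-sh] == 1))

  # capacity violations are reported as placement errors
  tiny <- build_fragments(
    structure(list(chr1 = c(100L, 200L)), class = "gatc_map",
              seqlengths = c(chr1 = 300L)), c(chr1 = 300L))
  expect_error(build_truth(small_sim_config(), tiny), "placement")
})

test_that("read simulation follows the Poisson/NB count model", {
  # phi = 0, one fragment: library size is Poisson(reads_per_sample)
  cfg <- sim_config(n_chroms = 1L, chrom_length = 5e4, gc_fraction = 0,
                    reads_per_sample = 500L, n_open_shared = 0L,
                    n_open_A = 0L, n_open_B = 0L, open_domain_len = 1L,
                    n_bound_shared = 0L, n_bound_A = 0L, n_bound_B = 0L,
                    bound_locus_len = 1L, nb_dispersion = 0,
                    accessibility_fold = 1, seed = 3L)
  fr <- build_fragments(scan_gatc(generate_genome(cfg)), c(chr1 = 5e4))
  expect_equal(length(fr), 1L)
  tr <- build_truth(cfg, fr)
  totals <- vapply(1:100, function(s)
    length(simulate_reads(tr, "A", "dam_only", s)), numeric(1))
  expect_lt(abs(mean(totals) - 500), 3 * sqrt(500 / 100))
  expect_lt(abs(var(totals) - 500), 500 * 0.5)  # Poisson variance ~ mean

  # all-unity occupancy: fusion and dam expectations coincide
  cfg2 <- small_sim_config(occupancy_fold = 1, nb_dispersion = 0,
                           reads_per_sample = 50000L)
  fr2 <- build_fragments(scan_gatc(generate_genome(cfg2)),
                         c(chr1 = 2e5, chr2 = 2e5))
  tr2 <- build_truth(cfg2, fr2)
  dam_n <- count_fragments(simulate_reads(tr2, "A", "dam_only", 1L), fr2)
  fus_n <- count_fragments(simulate_reads(tr2, "A", "dam_fusion", 2L), fr2)
  # identical expectations: grand totals and per-fragment means agree
  expect_equal(sum(fus_n$counts) / sum(dam_n$counts), 1, tolerance = 0.05)
  expect_gt(cor(fus_n$counts, dam_n$counts), 0.9)

  # a zero-accessibility fragment receives no reads
  tr3 <- tr2
  tr3$accessibility$A[10] <- 0
  rd <- simulate_reads(tr3, "A", "dam_only", 5L)
  s0 <- GenomicRanges::start(rd) - 1L
  on_chr1 <- as.character(GenomicRanges::seqnames(rd)) == "chr1"
  f10 <- c(GenomicRanges::start(fr2)[10] - 1L, GenomicRanges::end(fr2)[10])
  expect_equal(sum(on_chr1 & s0 >= f10[1] & s0 < f10[2]), 0L)
})

test_that("replicate noise matches the var = mu + phi mu^2 model", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 4e4,
                    reads_per_sample = 4000L, n_open_shared = 5L,
                    n_open_A = 5L, n_open_B = 5L, open_domain_len = 2L,
                    n_bound_shared = 2L, n_bound_A = 2L, n_bound_B = 2L,
                    nb_dispersion = 0.3, seed = 13L)
  g <- generate_genome(cfg)
  fr <- build_fragments(scan_gatc(g), g)
  tr <- build_truth(cfg, fr)
  lens <- genome_lengths(g)
  # count 5' starts per fragment (extension-free view of the raw draw)
  mat <- vapply(1:220, function(s) {
    rd <- simulate_reads(tr, "A", "dam_only", s)
    starts <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(rd),
      IRanges::IRanges(GenomicRanges::start(rd), width = 1L))
    GenomicRanges::countOverlaps(fr, starts)
  }, numeric(length(fr)))
  mu <- rowMeans(mat)
  vm <- apply(mat, 1, var) / mu
  big <- mu > 10                      # stable variance estimation
  expect_gt(sum(big), 20)
  ratio <- mean(vm[big]) / mean(1 + 0.3 * mu[big])
  expect_lt(abs(ratio - 1), 0.2)
})

test_that("doubling occupancy fold raises fusion signal only at bound loci", {
  base <- small_sim_config(nb_dispersion = 0, reads_per_sample = 60000L,
                           occupancy_fold = 4)
  dbl <- small_sim_config(nb_dispersion = 0, reads_per_sample = 60000L,
                          occupancy_fold = 8)
  g <- generate_genome(base)
  fr <- build_fragments(scan_gatc(g), g)
  tr4 <- build_truth(base, fr)
  tr8 <- build_truth(dbl, fr)
  # same placements (same derived seed), different folds
  expect_equal(tr4$domains$bound_A$frag_first, tr8$domains$bound_A$frag_first)
  bound <- tr4$occupancy$A > 1
  f4 <- count_fragments(simulate_reads(tr4, "A", "dam_fusion", 1L), fr)
  f8 <- count_fragments(simulate_reads(tr8, "A", "dam_fusion", 1L), fr)
  d4 <- count_fragments(simulate_reads(tr4, "A", "dam_only", 2L), fr)
  ratio4 <- sum(f4$counts[bound]) / sum(d4$counts[bound])
  ratio8 <- sum(f8$counts[bound]) / sum(d4$counts[bound])
  expect_gt(ratio8 / ratio4, 1.5)
  unbound_open <- tr4$accessibility$A > 1 & !bound
  expect_equal(sum(f8$counts[unbound_open]) / sum(f4$counts[unbound_open]),
               1, tolerance = 0.1)
})

test_that("a full simulated experiment is deterministic and complete", {
  cfg <- small_sim_config(seed = 31L, reads_per_sample = 5000L,
                          n_replicates = 2L)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(as.character(e1$genome), as.character(e2$genome))
  for (lin in c("A", "B")) {
    for (ch in c("dam_only", "dam_fusion")) {
      expect_length(e1$reads[[lin]][[ch]], 2L)
      for (r in 1:2) {
        expect_identical(gr_to_df0(e1$reads[[lin]][[ch]][[r]]),
                         gr_to_df0(e2$reads[[lin]][[ch]][[r]]))
        # every read within its chromosome
        rd <- e1$reads[[lin]][[ch]][[r]]
        lens <- genome_lengths(e1$genome)
        expect_true(all(GenomicRanges::start(rd) >= 1L))
        expect_true(all(GenomicRanges::end(rd) <=
          lens[as.character(GenomicRanges::seqnames(rd))]))
      }
    }
  }
  # distinct samples are independent draws
  expect_false(identical(
    gr_to_df0(e1$reads$A$dam_only[[1]]),
    gr_to_df0(e1$reads$A$dam_only[[2]])))
})
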