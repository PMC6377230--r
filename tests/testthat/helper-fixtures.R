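# Shared fixtures, all generated in code.

# a toy fragment table: one chromosome tiled by `widths`
toy_fragments <- function(widths, chrom = "chr1") {
  ends <- cumsum(widths)
  starts <- c(0, ends[-length(ends)])
  sl <- stats::setNames(sum(widths), chrom)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(starts + 1L, ends),
                               seqlengths = sl)
  gr$id <- seq_along(gr)
  gr
}

# random peak GRanges on a toy genome
random_peaks_gr <- function(n, seqlengths, min_w = 50L, max_w = 500L) {
  chrom <- sample(names(seqlengths), n, replace = TRUE)
  w <- sample(min_w:max_w, n, replace = TRUE)
  s0 <- floor(runif(n) * (seqlengths[chrom] - w))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1L, s0 + w),
                               seqlengths = seqlengths)
  sort(gr)
}

# small but complete synthetic experiment config (fast: ~1 s)
small_sim_config <- function(seed = 11L, ...) {
  args <- list(n_chroms = 2L, chrom_length = 2e5, reads_per_sample = 3e4,
               n_open_shared = 15L, n_open_A = 12L, n_open_B = 12L,
               n_bound_shared = 8L, n_bound_A = 8L, n_bound_B = 8L,
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# cache expensive shared fixtures across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the default-condition pipeline run used by the acceptance checks
default_pipeline_run <- function() {
  cached("default_run", {
    dir <- file.path(tempdir(), "tadakit-default-run")
    run_pipeline(pipeline_config(seed = 1L), outdir = dir)
  })
}

default_run_dir <- function() {
  default_pipeline_run()
  file.path(tempdir(), "tadakit-default-run")
}
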