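#' Pipeline configuration
#'
#' Collects every stage's tunable parameters with the analysis defaults
#' used throughout: 300-bp read extension, pseudocount 0.5 cpm, peak q
#' 0.05, consensus support 2, differential thresholds FDR 0.01 and 2-fold,
#' 1-bp overlap rule, 100 overlap / 1000 signal Monte Carlo iterations,
#' 2-kb closest-distance threshold, 4-kb signal windows, +/-5-kb profile
#' window with 50-bp bins, and 1-kb correlation bins. The configuration is
#' serializable to YAML and round-trippable.
#'
#' @param sim a [sim_config()] describing the synthetic experiment.
#' @param extension_length read extension limit L (bp).
#' @param pseudocount ratio-track pseudo-cpm.
#' @param peak a [peak_call_config()].
#' @param min_samples consensus support threshold.
#' @param fdr_max,min_fold differential thresholds.
#' @param mc_overlap_iters,mc_signal_iters Monte Carlo iteration counts.
#' @param closest_d closest-peak distance threshold (bp).
#' @param signal_half_width signal-window half-width (bp).
#' @param profile_W,profile_b metaprofile window half-width and bin (bp).
#' @param correlation_bin correlation bin width (bp).
#' @param seed global seed; all stage seeds derive from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            extension_length = 300L,
                            pseudocount = 0.5,
                            peak = peak_call_config(),
                            min_samples = 2L,
                            fdr_max = 0.01, min_fold = 2,
                            mc_overlap_iters = 100L,
                            mc_signal_iters = 1000L,
                            closest_d = 2000L,
                            signal_half_width = 2000L,
                            profile_W = 5000L, profile_b = 50L,
                            correlation_bin = 1000L,
                            seed = 1L) {
  stopifnot(inherits(sim, "sim_config"),
            inherits(peak, "peak_call_config"),
            extension_length >= 1L, pseudocount > 0,
            min_samples >= 1L, fdr_max > 0, fdr_max < 1, min_fold >= 1,
            mc_overlap_iters >= 1L, mc_signal_iters >= 1L,
            closest_d >= 0L, signal_half_width >= 1L,
            profile_W %% profile_b == 0L, correlation_bin >= 1L)
  structure(list(sim = sim, extension_length = as.integer(extension_length),
                 pseudocount = pseudocount, peak = peak,
                 min_samples = as.integer(min_samples),
                 fdr_max = fdr_max, min_fold = min_fold,
                 mc_overlap_iters = as.integer(mc_overlap_iters),
                 mc_signal_iters = as.integer(mc_signal_iters),
                 closest_d = as.integer(closest_d),
                 signal_half_width = as.integer(signal_half_width),
                 profile_W = as.integer(profile_W),
                 profile_b = as.integer(profile_b),
                 correlation_bin = as.integer(correlation_bin),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @return [read_pipeline_config()] returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  peak <- do.call(peak_call_config, y$peak %||% list())
  rest <- y[setdiff(names(y), c("sim", "peak"))]
  do.call(pipeline_config, c(list(sim = sim, peak = peak), rest))
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config` to serialize.
#' @export
write_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  obj$sim <- unclass(obj$sim)
  obj$peak <- unclass(obj$peak)
  yaml::write_yaml(obj, path)
  invisible(path)
}

# recall/precision of enriched classes against the simulator's truth
score_recovery <- function(diff_res, truth) {
  pred <- list(A = differential_class(diff_res, "enriched_A"),
               B = differential_class(diff_res, "enriched_B"))
  true <- list(A = truth$domains$bound_A, B = truth$domains$bound_B)
  hit_true <- hit_pred <- n_true <- n_pred <- 0
  for (cls in c("A", "B")) {
    n_true <- n_true + length(true[[cls]])
    n_pred <- n_pred + length(pred[[cls]])
    if (length(true[[cls]]) && length(pred[[cls]])) {
      hit_true <- hit_true +
        sum(IRanges::overlapsAny(true[[cls]], pred[[cls]]))
      hit_pred <- hit_pred +
        sum(IRanges::overlapsAny(pred[[cls]], true[[cls]]))
    }
  }
  list(recall = if (n_true) hit_true / n_true else NA_real_,
       precision = if (n_pred) hit_pred / n_pred else NA_real_,
       n_true = n_true, n_pred = n_pred)
}

#' Run the full synthetic TaDa/CaTaDa analysis pipeline
#'
#' Executes the analysis graph end to end on a simulated experiment:
#' simulate -> ratio profiles per lineage/replicate -> TaDa and CaTaDa
#' peak calling per replicate -> consensus and differential binding (Hb
#' fusion) and differential accessibility (Dam-only) -> Monte Carlo
#' overlap of lineage-enriched binding vs lineage-enriched accessibility
#' -> signal-ratio and closest-peak tests of enriched loci against the
#' lineage-A accessibility track -> metaprofiles and replicate
#' correlations. All randomness derives from `config$seed`. When `outdir`
#' is given, tracks, peaks, tables and a JSON manifest (with md5 hashes of
#' every emitted file) are written.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @param write_reads also write every simulated read set as BED6
#'   (default FALSE; they dominate the output volume).
#' @return a `pipeline_run`: list with the experiment, ratio tracks,
#'   peaksets, differential results, interval statistics, metaprofile,
#'   correlations, recovery scores and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         write_reads = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$sim$n_replicates < 2L) {
    stop("invalid design: differential stage needs n_replicates >= 2",
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cfg <- config
  sim_cfg <- cfg$sim
  sim_cfg$seed <- derive_seed(cfg$seed, "simulate")
  exp <- stage("simulate", simulate_experiment(sim_cfg))
  lens <- genome_lengths(exp$genome)
  n_rep <- sim_cfg$n_replicates

  # per (lineage, channel, replicate): extended reads and fragment counts
  extended <- list()
  fcounts <- list()
  for (lineage in c("A", "B")) {
    for (channel in c("dam_only", "dam_fusion")) {
      for (rep in seq_len(n_rep)) {
        key <- paste(lineage, channel, rep, sep = ".")
        ext <- stage("extend", extend_reads(
          exp$reads[[lineage]][[channel]][[rep]], exp$gatc,
          cfg$extension_length))
        extended[[key]] <- ext
        fcounts[[key]] <- stage("count", count_fragments(
          ext, exp$fragments, sample = key,
          channel = if (channel == "dam_only") "dam_only" else "dam_fusion"))
      }
    }
  }

  # ratio tracks per lineage/replicate, and a mean track per lineage
  ratios <- list()
  for (lineage in c("A", "B")) {
    ratios[[lineage]] <- lapply(seq_len(n_rep), function(rep) {
      stage("profile", normalize_decile(
        fcounts[[paste(lineage, "dam_fusion", rep, sep = ".")]],
        fcounts[[paste(lineage, "dam_only", rep, sep = ".")]],
        cfg$pseudocount))
    })
  }
  mean_track <- function(tracks) {
    t0 <- tracks[[1]]
    t0$value <- rowMeans(vapply(tracks, `[[`, "value",
                                FUN.VALUE = numeric(length(t0$value))))
    t0
  }
  mean_ratio <- lapply(ratios, mean_track)

  # accessibility (dam-only cpm) track per lineage, averaged over reps
  access_track <- lapply(c(A = "A", B = "B"), function(lineage) {
    gr <- exp$fragments
    gr$value <- rowMeans(vapply(seq_len(n_rep), function(rep)
      cpm(fcounts[[paste(lineage, "dam_only", rep, sep = ".")]]),
      numeric(length(gr))))
    gr
  })

  # peak calling per replicate
  tada_peaks <- catada_peaks <- list(A = list(), B = list())
  for (lineage in c("A", "B")) {
    for (rep in seq_len(n_rep)) {
      tada_peaks[[lineage]][[rep]] <- stage("callpeaks", call_peaks_ratio(
        fcounts[[paste(lineage, "dam_fusion", rep, sep = ".")]],
        fcounts[[paste(lineage, "dam_only", rep, sep = ".")]], cfg$peak))
      catada_peaks[[lineage]][[rep]] <- stage("callpeaks",
        call_peaks_accessibility(
          fcounts[[paste(lineage, "dam_only", rep, sep = ".")]], cfg$peak))
    }
  }

  # consensus + differential, for binding (fusion) and accessibility (dam)
  run_diff <- function(peaksets, channel) {
    consensus <- stage("consensus",
                       build_consensus(peaksets, cfg$min_samples))
    keys <- as.vector(outer(seq_len(n_rep), c("A", "B"),
                            function(r, l) paste(l, channel, r, sep = ".")))
    groups <- rep(c("A", "B"), each = n_rep)
    am <- stage("affinity", count_affinity(
      consensus, stats::setNames(extended[keys], keys), groups))
    res <- stage("differential",
                 test_differential(am, cfg$fdr_max, cfg$min_fold))
    list(consensus = consensus, affinity = am, result = res)
  }
  hb <- stage("diff_binding",
              run_diff(c(tada_peaks$A, tada_peaks$B), "dam_fusion"))
  accessibility <- stage("diff_accessibility",
                         run_diff(c(catada_peaks$A, catada_peaks$B),
                                  "dam_only"))

  recovery <- score_recovery(hb$result, exp$truth)

  # interval statistics: lineage-enriched binding vs lineage-enriched
  # accessibility (the open-chromatin-gates-binding comparison)
  enriched <- list(
    hb_A = differential_class(hb$result, "enriched_A"),
    hb_B = differential_class(hb$result, "enriched_B"),
    open_A = differential_class(accessibility$result, "enriched_A"),
    open_B = differential_class(accessibility$result, "enriched_B"))
  mc <- list()
  ov <- list()
  for (lineage in c("A", "B")) {
    a <- enriched[[paste0("hb_", lineage)]]
    b <- enriched[[paste0("open_", lineage)]]
    if (length(a) && length(b)) {
      ov[[lineage]] <- overlap_peaks(a, b)
      mc[[lineage]] <- stage("overlap_test", mc_overlap(
        a, b, cfg$mc_overlap_iters,
        derive_seed(cfg$seed, "mc_overlap", lineage), lens))
    }
  }
  signal_test <- if (length(enriched$hb_A) && length(enriched$hb_B)) {
    stage("signal_test", mc_signal_ratio(
      access_track$A, enriched$hb_A, enriched$hb_B,
      cfg$mc_signal_iters, derive_seed(cfg$seed, "mc_signal"),
      cfg$signal_half_width, lens))
  }
  closest <- if (length(enriched$hb_A) && length(enriched$hb_B) &&
                 length(enriched$open_A)) {
    stage("closest_test", closest_fisher(
      enriched$hb_A, enriched$hb_B, enriched$open_A, cfg$closest_d))
  }

  # metaprofile of the lineage-A ratio signal around A-enriched loci,
  # and replicate correlation on the fusion channel
  profile <- if (length(enriched$hb_A)) {
    pm <- stage("metaprofile", reference_point_matrix(
      mean_ratio$A, enriched$hb_A, cfg$profile_W, cfg$profile_b, lens))
    list(matrix = pm, profile = mean_profile(pm))
  }
  fusion_keys <- as.vector(outer(seq_len(n_rep), c("A", "B"),
                                 function(r, l)
                                   paste(l, "dam_fusion", r, sep = ".")))
  correlation <- stage("correlate", pairwise_pearson(
    stats::setNames(exp$reads[["A"]][["dam_fusion"]],
                    paste0("A.rep", seq_len(n_rep))) |>
      c(stats::setNames(exp$reads[["B"]][["dam_fusion"]],
                        paste0("B.rep", seq_len(n_rep)))),
    lens, cfg$correlation_bin))

  run <- structure(list(
    config = cfg, experiment = exp, fragment_counts = fcounts,
    ratio_tracks = ratios, mean_ratio = mean_ratio,
    access_track = access_track,
    tada_peaks = tada_peaks, catada_peaks = catada_peaks,
    hb = hb, accessibility = accessibility, enriched = enriched,
    recovery = recovery, overlap = ov, mc_overlap = mc,
    signal_test = signal_test, closest = closest, profile = profile,
    correlation = correlation), class = "pipeline_run")

  if (!is.null(outdir)) {
    run$manifest <- stage("write",
                          write_pipeline_outputs(run, outdir, write_reads))
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf(
    "<pipeline_run> seed %d: %d/%d enriched A/B binding loci, recall %.3f, precision %.3f\n",
    x$config$seed, length(x$enriched$hb_A), length(x$enriched$hb_B),
    x$recovery$recall, x$recovery$precision))
  invisible(x)
}

# write tracks/peaks/tables + JSON manifest with md5 hashes
write_pipeline_outputs <- function(run, outdir, write_reads = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add <- function(paths, key, path) {
    paths[key] <- path
    paths
  }
  paths <- add(paths, "genome", file.path(outdir, "genome.fa"))
  write_fasta(run$experiment$genome, paths[["genome"]])
  n_rep <- run$config$sim$n_replicates
  for (lineage in c("A", "B")) {
    for (rep in seq_len(n_rep)) {
      key <- sprintf("ratio_%s_rep%d", lineage, rep)
      paths <- add(paths, key, file.path(outdir, paste0(key, ".bedgraph")))
      write_bedgraph(run$ratio_tracks[[lineage]][[rep]], paths[[key]])
      key <- sprintf("tada_peaks_%s_rep%d", lineage, rep)
      paths <- add(paths, key, file.path(outdir, paste0(key, ".narrowPeak")))
      write_narrowpeak(run$tada_peaks[[lineage]][[rep]], paths[[key]])
      key <- sprintf("catada_peaks_%s_rep%d", lineage, rep)
      paths <- add(paths, key, file.path(outdir, paste0(key, ".narrowPeak")))
      write_narrowpeak(run$catada_peaks[[lineage]][[rep]], paths[[key]])
    }
    key <- sprintf("access_track_%s", lineage)
    paths <- add(paths, key, file.path(outdir, paste0(key, ".bedgraph")))
    write_bedgraph(run$access_track[[lineage]], paths[[key]])
  }
  paths <- add(paths, "diff_binding", file.path(outdir, "diff_binding.tsv"))
  write_differential(run$hb$result, paths[["diff_binding"]],
                     bed_dir = file.path(outdir, "diff_binding_classes"))
  paths <- add(paths, "diff_accessibility",
               file.path(outdir, "diff_accessibility.tsv"))
  write_differential(run$accessibility$result,
                     paths[["diff_accessibility"]],
                     bed_dir = file.path(outdir, "diff_accessibility_classes"))
  for (cls in names(run$enriched)) {
    if (length(run$enriched[[cls]])) {
      key <- paste0("enriched_", cls)
      paths <- add(paths, key, file.path(outdir, paste0(key, ".bed")))
      write_bed(run$enriched[[cls]], paths[[key]])
    }
  }
  for (lineage in names(run$mc_overlap)) {
    key <- paste0("mc_overlap_", lineage)
    paths <- add(paths, key, file.path(outdir, paste0(key, ".json")))
    write_stats_json(run$mc_overlap[[lineage]], paths[[key]])
  }
  if (!is.null(run$signal_test)) {
    paths <- add(paths, "signal_test", file.path(outdir, "signal_test.json"))
    write_stats_json(run$signal_test, paths[["signal_test"]])
  }
  if (!is.null(run$closest)) {
    paths <- add(paths, "closest_test",
                 file.path(outdir, "closest_test.json"))
    write_stats_json(run$closest, paths[["closest_test"]])
  }
  if (!is.null(run$profile)) {
    paths <- add(paths, "profile_matrix",
                 file.path(outdir, "profile_matrix.tsv"))
    write_profile_matrix(run$profile$matrix, paths[["profile_matrix"]])
    paths <- add(paths, "mean_profile", file.path(outdir, "mean_profile.tsv"))
    utils::write.table(
      data.frame(offset = run$profile$profile$offset,
                 mean_signal = format_num(run$profile$profile$mean_signal)),
      paths[["mean_profile"]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths <- add(paths, "correlation", file.path(outdir, "correlation.tsv"))
  utils::write.table(
    cbind(sample = rownames(run$correlation$r),
          as.data.frame(apply(run$correlation$r, 2, format_num))),
    paths[["correlation"]], sep = "\t", quote = FALSE, row.names = FALSE)
  if (write_reads) {
    for (lineage in c("A", "B")) {
      for (channel in c("dam_only", "dam_fusion")) {
        for (rep in seq_len(n_rep)) {
          key <- sprintf("reads_%s_%s_rep%d", lineage, channel, rep)
          paths <- add(paths, key, file.path(outdir, paste0(key, ".bed")))
          write_bed(run$experiment$reads[[lineage]][[channel]][[rep]],
                    paths[[key]])
        }
      }
    }
  }
  hashes <- tools::md5sum(unname(paths))
  manifest <- list(
    package_version = as.character(utils::packageVersion("tadakit")),
    seed = run$config$seed,
    parameters = list(
      extension_length = run$config$extension_length,
      pseudocount = run$config$pseudocount,
      peak_q = run$config$peak$q_threshold,
      min_samples = run$config$min_samples,
      fdr_max = run$config$fdr_max, min_fold = run$config$min_fold,
      mc_overlap_iters = run$config$mc_overlap_iters,
      mc_signal_iters = run$config$mc_signal_iters,
      closest_d = run$config$closest_d,
      signal_half_width = run$config$signal_half_width),
    recovery = run$recovery,
    stats = list(
      n_consensus_binding = length(run$hb$consensus),
      n_consensus_accessibility = length(run$accessibility$consensus),
      n_enriched_hb_A = length(run$enriched$hb_A),
      n_enriched_hb_B = length(run$enriched$hb_B),
      n_enriched_open_A = length(run$enriched$open_A),
      n_enriched_open_B = length(run$enriched$open_B)),
    files = as.list(stats::setNames(unname(hashes), names(paths))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  manifest
}
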