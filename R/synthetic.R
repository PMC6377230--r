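#' Configuration for the synthetic DamID experiment
#'
#' The generator encodes the model the downstream analysis assumes: two
#' neuroblast-like lineages share a genome, each lineage has its own open
#' chromatin domains plus a set shared between lineages, transcription
#' factor binding is confined to open domains of the matching class,
#' Dam-only read density tracks accessibility and Dam-fusion density tracks
#' accessibility times occupancy, with negative-binomial replicate noise.
#'
#' Defaults define the standard study conditions used throughout the test
#' suite: three 2-Mb chromosomes at GC 0.5, 150 shared plus 120
#' lineage-specific open domains of 8 GATC fragments each, 100 bound loci
#' per class (2 fragments each), accessibility and occupancy folds of 4,
#' 4e5 reads of 100 bp per sample, dispersion 0.1 and 3 replicates.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length (bp).
#' @param gc_fraction genome GC content in (0,1).
#' @param n_open_shared,n_open_A,n_open_B open-domain counts per class.
#' @param open_domain_len open-domain width in GATC fragments.
#' @param n_bound_shared,n_bound_A,n_bound_B bound-locus counts per class;
#'   each class X requires `n_bound_X <= n_open_X`.
#' @param bound_locus_len bound-locus width in fragments.
#' @param accessibility_fold accessibility multiplier in open domains
#'   (>= 1).
#' @param occupancy_fold occupancy multiplier at bound loci (>= 1).
#' @param reads_per_sample expected reads per sample.
#' @param read_length read length (bp).
#' @param nb_dispersion negative-binomial overdispersion phi >= 0
#'   (variance = mu + phi mu^2); 0 gives Poisson counts.
#' @param n_replicates replicates per (lineage, channel).
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_chroms = 3L, chrom_length = 2e6, gc_fraction = 0.5,
                       n_open_shared = 150L, n_open_A = 120L,
                       n_open_B = 120L, open_domain_len = 8L,
                       n_bound_shared = 100L, n_bound_A = 100L,
                       n_bound_B = 100L, bound_locus_len = 2L,
                       accessibility_fold = 4, occupancy_fold = 4,
                       reads_per_sample = 4e5, read_length = 100L,
                       nb_dispersion = 0.1, n_replicates = 3L, seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              gc_fraction = gc_fraction,
              n_open_shared = as.integer(n_open_shared),
              n_open_A = as.integer(n_open_A),
              n_open_B = as.integer(n_open_B),
              open_domain_len = as.integer(open_domain_len),
              n_bound_shared = as.integer(n_bound_shared),
              n_bound_A = as.integer(n_bound_A),
              n_bound_B = as.integer(n_bound_B),
              bound_locus_len = as.integer(bound_locus_len),
              accessibility_fold = accessibility_fold,
              occupancy_fold = occupancy_fold,
              reads_per_sample = as.integer(reads_per_sample),
              read_length = as.integer(read_length),
              nb_dispersion = nb_dispersion,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_chroms >= 1L, chrom_length >= 1L,
              gc_fraction >= 0, gc_fraction < 1,
              open_domain_len >= 1L, bound_locus_len >= 1L,
              bound_locus_len <= open_domain_len,
              accessibility_fold >= 1, occupancy_fold >= 1,
              reads_per_sample > 0L, read_length >= 1L,
              nb_dispersion >= 0, n_replicates >= 1L)
    if (n_bound_shared > n_open_shared || n_bound_A > n_open_A ||
        n_bound_B > n_open_B) {
      stop("n_bound_X must not exceed n_open_X for each class",
           call. = FALSE)
    }
    if (chrom_length < 10L * read_length) {
      stop("invalid config: chrom_length < 10 * read_length", call. = FALSE)
    }
  })
  structure(cfg, class = "sim_config")
}

#' Generate a random genome
#'
#' Nucleotides are i.i.d. at the requested GC fraction (G and C each with
#' probability `gc_fraction/2`), so GATC motifs arise naturally with
#' expected spacing `1/(p_G p_A p_T p_C)` (256 bp at GC 0.5). Deterministic
#' for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return named [Biostrings::DNAStringSet] (`chr1`, `chr2`, ...).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p_gc <- config$gc_fraction / 2
  p_at <- (1 - config$gc_fraction) / 2
  with_seed(derive_seed(config$seed, "genome"), {
    seqs <- vapply(seq_len(config$n_chroms), function(i) {
      paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                   replace = TRUE, prob = c(p_at, p_gc, p_gc, p_at)),
            collapse = "")
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- paste0("chr", seq_len(config$n_chroms))
    out
  })
}

# place n non-overlapping runs of `width` fragments, avoiding `taken`
# (logical over fragments); runs never span chromosomes. Returns start
# fragment indices.
place_domains <- function(n, width, fragments, taken, max_tries = 10000L) {
  if (n == 0L) return(list(starts = integer(0), taken = taken))
  chrom <- as.character(GenomicRanges::seqnames(fragments))
  nfrag <- length(fragments)
  # candidate starts: run of `width` fragments fully on one chromosome
  ok_start <- seq_len(nfrag - width + 1L)
  ok_start <- ok_start[chrom[ok_start] == chrom[ok_start + width - 1L]]
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf(
        "domain placement failed: could not place %d domains of %d fragments (%d placed); genome capacity exceeded",
        n, width, length(starts)), call. = FALSE)
    }
    cand <- ok_start[sample.int(length(ok_start), 1L)]
    span <- cand:(cand + width - 1L)
    if (any(taken[span])) next
    taken[span] <- TRUE
    starts <- c(starts, cand)
  }
  list(starts = sort(starts), taken = taken)
}

#' Build the ground-truth accessibility/occupancy model
#'
#' Open domains (shared, A-specific, B-specific) are placed uniformly over
#' the fragment table without any overlap between labelled domains. Within
#' each lineage, accessibility is 1 at baseline and `accessibility_fold`
#' inside that lineage's open domains (shared domains are open in both).
#' Bound loci of each class are placed inside distinct open domains of the
#' same class; occupancy is 1 at baseline and `occupancy_fold` over a bound
#' locus's fragments in the lineage(s) where that class binds.
#'
#' @param config [sim_config()].
#' @param fragments fragment `GRanges` from [build_fragments()].
#' @return a `truth_model`: per-lineage accessibility and occupancy vectors
#'   over fragments, plus labelled domain/locus `GRanges` (with fragment
#'   index ranges) for the six classes.
#' @export
build_truth <- function(config, fragments) {
  stopifnot(inherits(config, "sim_config"))
  nfrag <- length(fragments)
  need <- (config$n_open_shared + config$n_open_A + config$n_open_B) *
    config$open_domain_len
  if (need > nfrag) {
    stop(sprintf(
      "domain placement impossible: %d fragments needed for open domains, %d available",
      need, nfrag), call. = FALSE)
  }
  with_seed(derive_seed(config$seed, "truth"), {
    taken <- logical(nfrag)
    doms <- list()
    for (cls in c("open_shared", "open_A", "open_B")) {
      n <- config[[sub("open", "n_open", cls)]]
      res <- place_domains(n, config$open_domain_len, fragments, taken)
      taken <- res$taken
      doms[[cls]] <- res$starts
    }
    # bound loci: one per sampled open domain of the matching class,
    # uniform offset within the domain
    loci <- list()
    for (cls in c("shared", "A", "B")) {
      n <- config[[paste0("n_bound_", cls)]]
      hosts <- doms[[paste0("open_", cls)]]
      if (n > 0L) {
        chosen <- hosts[sample.int(length(hosts), n)]
        off <- sample.int(config$open_domain_len - config$bound_locus_len + 1L,
                          n, replace = TRUE) - 1L
        loci[[paste0("bound_", cls)]] <- sort(chosen + off)
      } else {
        loci[[paste0("bound_", cls)]] <- integer(0)
      }
    }
    frag_runs <- function(starts, width) {
      if (!length(starts)) {
        gr <- fragments[0]
        gr$frag_first <- integer(0)
        gr$frag_last <- integer(0)
        return(gr)
      }
      first <- starts
      last <- starts + width - 1L
      gr <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(fragments)[first],
        IRanges::IRanges(GenomicRanges::start(fragments)[first],
                         GenomicRanges::end(fragments)[last]),
        seqinfo = GenomeInfoDb::seqinfo(fragments))
      gr$frag_first <- first
      gr$frag_last <- last
      gr
    }
    run_mask <- function(starts, width) {
      m <- logical(nfrag)
      for (s in starts) m[s:(s + width - 1L)] <- TRUE
      m
    }
    open_masks <- lapply(doms, run_mask, width = config$open_domain_len)
    bound_masks <- lapply(loci, run_mask, width = config$bound_locus_len)
    access <- list(
      A = ifelse(open_masks$open_shared | open_masks$open_A,
                 config$accessibility_fold, 1),
      B = ifelse(open_masks$open_shared | open_masks$open_B,
                 config$accessibility_fold, 1))
    occupancy <- list(
      A = ifelse(bound_masks$bound_shared | bound_masks$bound_A,
                 config$occupancy_fold, 1),
      B = ifelse(bound_masks$bound_shared | bound_masks$bound_B,
                 config$occupancy_fold, 1))
    domains <- c(
      lapply(stats::setNames(nm = names(doms)), function(k)
        frag_runs(doms[[k]], config$open_domain_len)),
      lapply(stats::setNames(nm = names(loci)), function(k)
        frag_runs(loci[[k]], config$bound_locus_len)))
    structure(list(fragments = fragments, accessibility = access,
                   occupancy = occupancy, domains = domains,
                   config = config),
              class = "truth_model")
  })
}

#' @export
print.truth_model <- function(x, ...) {
  cat("<truth_model>", length(x$fragments), "fragments;",
      paste(sprintf("%s=%d", names(x$domains),
                    vapply(x$domains, length, 1L)), collapse = " "), "\n")
  invisible(x)
}

#' Simulate aligned reads for one sample
#'
#' Per-fragment expected counts are proportional to
#' `length * accessibility` (Dam-only channel) or
#' `length * accessibility * occupancy` (Dam-fusion channel) in the given
#' lineage, scaled to sum to `reads_per_sample`. Realized counts are drawn
#' independently per fragment: Poisson when `nb_dispersion = 0`, otherwise
#' negative binomial with variance `mu + phi mu^2`, so the total library
#' size equals `reads_per_sample` in expectation. Read 5' starts are
#' uniform within their fragment, strands are Bernoulli(1/2), and the fixed
#' read length is truncated at chromosome ends rather than the read being
#' discarded.
#'
#' @param truth a `truth_model` from [build_truth()].
#' @param lineage `"A"` or `"B"`.
#' @param channel `"dam_only"` or `"dam_fusion"`.
#' @param replicate_seed integer seed for this sample's draws.
#' @return `GRanges` of aligned reads (BED6-equivalent: name, score 0,
#'   strand), sorted by position.
#' @export
simulate_reads <- function(truth, lineage = c("A", "B"),
                           channel = c("dam_only", "dam_fusion"),
                           replicate_seed = 1L) {
  stopifnot(inherits(truth, "truth_model"))
  lineage <- match.arg(lineage)
  channel <- match.arg(channel)
  cfg <- truth$config
  frag <- truth$fragments
  len <- GenomicRanges::width(frag)
  w <- len * truth$accessibility[[lineage]]
  if (channel == "dam_fusion") w <- w * truth$occupancy[[lineage]]
  mu <- w / sum(w) * cfg$reads_per_sample
  with_seed(replicate_seed, {
    counts <- if (cfg$nb_dispersion == 0) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    }
    total <- sum(counts)
    if (total == 0L) {
      gr <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(frag))
      gr$name <- character(0)
      gr$score <- integer(0)
      gr
    } else {
    fs0 <- rep.int(start0(frag), counts)
    flen <- rep.int(len, counts)
    chrom <- rep.int(as.character(GenomicRanges::seqnames(frag)),
                     counts)
    clen <- GenomeInfoDb::seqlengths(frag)[chrom]
    s0 <- fs0 + floor(stats::runif(total) * flen)
    e0 <- pmin(s0 + cfg$read_length, clen)  # truncate at chromosome end
    strand <- ifelse(stats::runif(total) < 0.5, "+", "-")
    ord <- order(chrom, s0)
    gr <- granges0(chrom[ord], s0[ord], e0[ord],
                   GenomeInfoDb::seqlengths(frag), strand = strand[ord])
    gr$name <- sprintf("read_%07d", seq_len(total))
    gr$score <- rep(0L, total)
    gr
    }
  })
}

#' Simulate a complete two-lineage DamID experiment
#'
#' Generates the genome, fragment table, truth model and all read sets:
#' for each lineage, channel (`dam_only`, `dam_fusion`) and replicate, one
#' aligned read set. Fully deterministic for a fixed `config$seed`; each
#' sample's seed is derived with [derive_seed()] so samples are
#' independent.
#'
#' @param config [sim_config()].
#' @return a `sim_experiment`: list with `genome`, `gatc`, `fragments`,
#'   `truth`, `reads[[lineage]][[channel]][[replicate]]` and `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  genome <- generate_genome(config)
  gatc <- scan_gatc(genome)
  fragments <- build_fragments(gatc, genome)
  truth <- build_truth(config, fragments)
  reads <- list()
  for (lineage in c("A", "B")) {
    reads[[lineage]] <- list()
    for (channel in c("dam_only", "dam_fusion")) {
      reads[[lineage]][[channel]] <- lapply(
        seq_len(config$n_replicates), function(rep) {
          simulate_reads(truth, lineage, channel,
                         derive_seed(config$seed, "reads", lineage,
                                     channel, rep))
        })
    }
  }
  structure(list(genome = genome, gatc = gatc, fragments = fragments,
                 truth = truth, reads = reads, config = config),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "<sim_experiment> %d chrom x %g bp, %d fragments, 2 lineages x 2 channels x %d replicates\n",
    x$config$n_chroms, x$config$chrom_length, length(x$fragments),
    x$config$n_replicates))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits the genome as FASTA, every read set as BED6, the fragment-level
#' truth as TSV (fragment id, coordinates, per-lineage accessibility and
#' occupancy) and each labelled domain class as BED.
#'
#' @param exp a `sim_experiment`.
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_experiment <- function(exp, outdir) {
  stopifnot(inherits(exp, "sim_experiment"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(outdir, "genome.fa"))
  write_fasta(exp$genome, paths[["genome"]])
  frag <- exp$fragments
  truth_df <- data.frame(
    fragment_id = frag$id,
    chrom = as.character(GenomicRanges::seqnames(frag)),
    start = start0(frag), end = end0(frag),
    accessibility_A = exp$truth$accessibility$A,
    accessibility_B = exp$truth$accessibility$B,
    occupancy_A = exp$truth$occupancy$A,
    occupancy_B = exp$truth$occupancy$B)
  paths[["truth"]] <- file.path(outdir, "truth_fragments.tsv")
  utils::write.table(truth_df, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (cls in names(exp$truth$domains)) {
    p <- file.path(outdir, paste0("truth_", cls, ".bed"))
    gr <- exp$truth$domains[[cls]]
    gr$name <- sprintf("%s_%d", cls, seq_along(gr))
    write_bed(gr, p)
    paths[[paste0("truth_", cls)]] <- p
  }
  for (lineage in names(exp$reads)) {
    for (channel in names(exp$reads[[lineage]])) {
      for (rep in seq_along(exp$reads[[lineage]][[channel]])) {
        key <- sprintf("reads_%s_%s_rep%d", lineage, channel, rep)
        p <- file.path(outdir, paste0(key, ".bed"))
        write_bed(exp$reads[[lineage]][[channel]][[rep]], p)
        paths[[key]] <- p
      }
    }
  }
  invisible(paths)
}
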