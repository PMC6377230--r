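#' Derive a deterministic stage seed from a global seed
#'
#' Stage-level random draws are seeded independently so that adding or
#' reordering pipeline stages never perturbs the draws of earlier stages.
#' The stage seed is a deterministic integer hash of the global seed and an
#' arbitrary set of string/integer labels (stage name, lineage, replicate...).
#'
#' @param seed integer global seed.
#' @param ... labels (coerced to character) identifying the stage.
#' @return an integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' derive_seed(1, "simulate", "A", 2)
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(key)) {
    h <- (h * 69069 + code) %% 2147483647
  }
  as.integer(h)
}

# run expr with a temporary RNG state seeded by `seed`; if seed is NULL the
# current RNG stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chromosome lengths of a genome
#'
#' @param genome a named [Biostrings::DNAStringSet] as returned by
#'   [read_fasta()] or [generate_genome()].
#' @return named integer vector of chromosome lengths (bp).
#' @export
genome_lengths <- function(genome) {
  stopifnot(methods::is(genome, "DNAStringSet"),
            !is.null(names(genome)), !anyDuplicated(names(genome)))
  stats::setNames(Biostrings::width(genome), names(genome))
}

# common check that two objects refer to the same chromosome set
check_same_genome <- function(a_names, b_names, what = "inputs") {
  extra <- setdiff(a_names, b_names)
  if (length(extra)) {
    stop(sprintf("%s refer to different genomes: chromosome(s) %s unknown",
                 what, paste(extra, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# GRanges constructor from 0-based half-open coordinates
granges0 <- function(chrom, start0, end0, seqlengths = NULL, ...) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    ...
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

# 0-based starts / half-open ends of a GRanges
start0 <- function(gr) GenomicRanges::start(gr) - 1L
end0 <- function(gr) GenomicRanges::end(gr)

# interval centers (bp, 0-based): midpoint of [start0, end0)
center0 <- function(gr) floor((start0(gr) + end0(gr)) / 2)
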