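# Seeded synthetic genome generator with planted promoters, so every
# pipeline stage (annotation parsing, window labeling, training, analysis)
# runs end-to-end without downloading a real genome. The background is
# i.i.d. with a configurable GC content; each planted promoter is a 300-base
# TSS-anchored region (249 upstream + TSS + 50 downstream) carrying core
# motifs at fixed TSS-relative offsets, on either strand.

#' Synthetic genome configuration
#'
#' Defaults emulate the core-promoter geometry used throughout the package:
#' a TATAAA box starting at -31 and a TCAKTY initiator (INR) straddling the
#' TSS at -2, planted in a background of hg38-like GC content (0.41).
#' Reverse-strand promoters are planted as reverse complements of the
#' forward-sense promoter text.
#'
#' @param length Genome length in bases.
#' @param n_promoters Number of planted promoters.
#' @param motifs Data frame with columns `consensus` (IUPAC) and `offset`
#'   (TSS-relative start, negative upstream); `NULL` for the default pair,
#'   or a zero-row data frame to plant promoters without motifs (negative
#'   control).
#' @param gc_content Background GC fraction (default 0.41).
#' @param n_blocks Optional data frame with columns `start`, `length`: runs
#'   of `N` overwritten after everything else (as in assembly gaps).
#' @param strand_mix Fraction of promoters planted on the reverse strand
#'   (default 0.5).
#' @param spec A [region_spec()] fixing the promoter geometry.
#' @param seed Integer seed.
#' @return An object of class `synthetic_genome_config`.
#' @export
synthetic_genome_config <- function(length = 50000L, n_promoters = 10L,
                                    motifs = NULL, gc_content = 0.41,
                                    n_blocks = NULL, strand_mix = 0.5,
                                    spec = region_spec(), seed = 1L) {
  if (is.null(motifs)) {
    motifs <- data.frame(consensus = c("TATAAA", "TCAKTY"),
                         offset = c(-31L, -2L), stringsAsFactors = FALSE)
  }
  stopifnot(gc_content >= 0, gc_content <= 1,
            strand_mix >= 0, strand_mix <= 1)
  structure(list(length = as.integer(length),
                 n_promoters = as.integer(n_promoters), motifs = motifs,
                 gc_content = gc_content, n_blocks = n_blocks,
                 strand_mix = strand_mix, spec = spec,
                 seed = as.integer(seed)),
            class = "synthetic_genome_config")
}

# draw one IUPAC-consensus instance
sample_consensus <- function(consensus) {
  paste(vapply(split_chars(toupper(consensus)), function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (is.null(set)) stop("unknown IUPAC code '", ch, "' in motif")
    if (length(set) == 1L) set else sample(set, 1L)
  }, ""), collapse = "")
}

#' Generate a synthetic genome with planted promoters
#'
#' Background bases are drawn i.i.d. at the configured GC content. Each
#' promoter occupies a non-overlapping region of `spec$length` bases; its
#' motifs are planted at their TSS-relative offsets, reverse-strand
#' promoters are written as reverse complements, and `N` blocks are
#' overwritten last. Deterministic under the config seed.
#'
#' @param cfg A [synthetic_genome_config()].
#' @param name Chromosome name (default `"chrS"`).
#' @return List with `genome` ([genome_seq()]), `tss` ([tss_annotation()]
#'   rows for every planted TSS), `regions` (ground-truth promoter
#'   [interval()]s, so labeling tests need no re-derivation) and `config`.
#' @export
generate_synthetic_genome <- function(cfg, name = "chrS") {
  stopifnot(inherits(cfg, "synthetic_genome_config"))
  rs <- cfg$spec
  rlen <- rs$length
  if (cfg$n_promoters > 0L && cfg$length < rlen) {
    stop("genome too short for a single ", rlen, "-base promoter region")
  }
  with_seed(cfg$seed, {
    pA <- (1 - cfg$gc_content) / 2
    pC <- cfg$gc_content / 2
    bases <- sample(BASES, cfg$length, replace = TRUE,
                    prob = c(pA, pC, pC, pA))
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < cfg$n_promoters) {
      tries <- tries + 1L
      if (tries > 200L * max(1L, cfg$n_promoters)) {
        stop("could not place ", cfg$n_promoters,
             " non-overlapping promoter regions after ", tries, " attempts")
      }
      s <- sample.int(cfg$length - rlen + 1L, 1L) - 1L
      if (all(abs(s - starts) >= rlen)) starts <- c(starts, s)
    }
    starts <- sort(starts)
    strands <- ifelse(stats::runif(cfg$n_promoters) < cfg$strand_mix,
                      "-", "+")
    for (i in seq_along(starts)) {
      s <- starts[i]
      region <- bases[(s + 1L):(s + rlen)]
      if (nrow(cfg$motifs)) {
        for (m in seq_len(nrow(cfg$motifs))) {
          inst <- split_chars(sample_consensus(cfg$motifs$consensus[m]))
          at <- tss_rel_to_index(cfg$motifs$offset[m], rs$upstream)
          if (at < 0L || at + length(inst) > rlen) {
            stop("motif '", cfg$motifs$consensus[m],
                 "' does not fit in the promoter region at offset ",
                 cfg$motifs$offset[m])
          }
          region[(at + 1L):(at + length(inst))] <- inst
        }
      }
      if (strands[i] == "-") {
        region <- split_chars(reverse_complement(paste(region,
                                                       collapse = "")))
      }
      bases[(s + 1L):(s + rlen)] <- region
    }
    if (!is.null(cfg$n_blocks) && nrow(cfg$n_blocks)) {
      for (b in seq_len(nrow(cfg$n_blocks))) {
        s <- cfg$n_blocks$start[b]
        l <- cfg$n_blocks$length[b]
        stopifnot(s >= 0L, s + l <= cfg$length)
        bases[(s + 1L):(s + l)] <- "N"
      }
    }
    pos0 <- ifelse(strands == "+", starts + rs$upstream,
                   starts + rs$downstream)
    genome <- genome_seq(name, paste(bases, collapse = ""))
    tss <- if (cfg$n_promoters > 0L) {
      tss_annotation(name, pos0, strands,
                     sprintf("synthP%02d", seq_along(starts)))
    } else {
      tss_annotation(character(0), integer(0), character(0), character(0))
    }
    regions <- if (cfg$n_promoters > 0L) {
      interval(name, starts, starts + rlen, strands)
    } else {
      structure(data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), strand = character(0),
                           stringsAsFactors = FALSE),
                class = c("genomic_interval", "data.frame"))
    }
    list(genome = genome, tss = tss, regions = regions, config = cfg)
  })
}

#' Generate a labeled benchmark dataset from a synthetic genome
#'
#' Convenience wrapper: generate a genome, derive promoter regions from the
#' planted TSS annotations, and run the sliding-window benchmark builder.
#'
#' @param cfg A [synthetic_genome_config()].
#' @param config A [benchmark_config()].
#' @return List with the generator output plus `dataset`
#'   (a [promoter_dataset()]).
#' @export
synthetic_benchmark <- function(cfg, config = benchmark_config()) {
  g <- generate_synthetic_genome(cfg)
  ds <- build_benchmark(g$genome, g$regions, config)
  c(g, list(dataset = ds))
}

#' The frozen worked example
#'
#' A tiny fixed bundle shipped with the package: a 2,000-base genome with
#' two planted promoters (one per strand), its SGA annotation, and the
#' benchmark dataset expected from the default recipe. The expected windows
#' and tags were computed once with a brute-force interval oracle and frozen
#' as golden files, so dataset construction can be verified byte-for-byte.
#'
#' @return List with `genome_path`, `annotation_path`, `golden_dataset_path`,
#'   the parsed `genome` and `tss`, the derived promoter `regions`, and the
#'   `golden` dataset read back from the frozen file.
#' @export
worked_example <- function() {
  gp <- system.file("extdata", "worked_example_genome.fa",
                    package = "prombench", mustWork = TRUE)
  ap <- system.file("extdata", "worked_example_tss.sga",
                    package = "prombench", mustWork = TRUE)
  dp <- system.file("extdata", "worked_example_dataset.tsv",
                    package = "prombench", mustWork = TRUE)
  genome <- read_fasta(gp)[[1L]]
  tss <- parse_tss_annotations(ap, "sga")
  regions <- promoter_region_from_tss(
    tss, region_spec(), stats::setNames(genome$length, genome$name))
  list(genome_path = gp, annotation_path = ap, golden_dataset_path = dp,
       genome = genome, tss = tss, regions = regions,
       golden = read_dataset(dp))
}
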