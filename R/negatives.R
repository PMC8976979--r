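# Non-promoter sequence generators: substitution-based synthetic negatives
# (uniform-distribution UD and original-promoter-distribution OPD), genomic
# negatives sampled after first exons, and motif-containing genomic negatives.

#' Substitution configuration for synthetic negatives
#'
#' Controls how promoter sequences are degraded into synthetic non-promoters.
#' `fraction` is the proportion of the sequence substituted; `unit` selects
#' whether that proportion applies to contiguous equal-length segments
#' (default, 32 segments per sequence, so the default fraction 20/32 means 20
#' of 32 segments) or to scattered individual positions.
#'
#' @param fraction Proportion substituted in `[0,1]` (default `20/32`).
#' @param mode `"uniform"` (UD: substituted bases drawn uniformly from
#'   A/C/G/T, so the expected change rate is 3/4 per substituted position) or
#'   `"promoter_distribution"` (OPD: substituted bases are permuted among
#'   themselves, conserving the base multiset exactly).
#' @param unit `"segment"` or `"position"`.
#' @param n_segments Number of equal-length segments when `unit = "segment"`.
#' @param seed Integer seed.
#' @return An object of class `substitution_config`.
#' @export
substitution_config <- function(fraction = 20 / 32,
                                mode = c("uniform", "promoter_distribution"),
                                unit = c("segment", "position"),
                                n_segments = 32L, seed = 1L) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]")
  }
  structure(list(fraction = fraction, mode = mode, unit = unit,
                 n_segments = as.integer(n_segments),
                 seed = as.integer(seed)),
            class = "substitution_config")
}

# positions selected for substitution under a config (0 or more indices)
choose_positions <- function(L, cfg) {
  if (cfg$unit == "position") {
    k <- floor(cfg$fraction * L)
    if (k == 0L) return(integer(0))
    sample.int(L, k)
  } else {
    nseg <- min(cfg$n_segments, L)
    k <- floor(cfg$fraction * nseg)
    if (k == 0L) return(integer(0))
    bounds <- floor(seq(0L, L, length.out = nseg + 1L))
    segs <- sample.int(nseg, k)
    unlist(lapply(segs, function(s) seq.int(bounds[s] + 1L, bounds[s + 1L])))
  }
}

#' Uniform-substitution (UD) synthetic negatives
#'
#' A seeded random subset of positions (per [substitution_config()]) receives
#' a base drawn uniformly from `{A,C,G,T}`; the draw may reproduce the
#' original base, so the expected change rate is 3/4 per substituted
#' position. Length is preserved.
#'
#' @param seq Character vector of sequences over `{A,C,G,T,N}`.
#' @param cfg A [substitution_config()] with `mode = "uniform"`.
#' @return Character vector of substituted sequences.
#' @export
substitute_uniform <- function(seq, cfg = substitution_config()) {
  stopifnot(inherits(cfg, "substitution_config"))
  if (cfg$mode != "uniform") stop("cfg$mode must be 'uniform'")
  assert_dna(seq)
  with_seed(cfg$seed, vapply(seq, function(s) {
    ch <- split_chars(s)
    pos <- choose_positions(length(ch), cfg)
    if (length(pos)) ch[pos] <- sample(BASES, length(pos), replace = TRUE)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE))
}

#' Composition-preserving (OPD) synthetic negatives
#'
#' The selected positions' bases are permuted among themselves ("shuffled
#' instead of replaced"), so with `fraction = 1` the output is an exact
#' seeded permutation of the input and the base multiset is conserved
#' per sequence; unselected positions are untouched.
#'
#' @param seq Character vector of sequences.
#' @param cfg A [substitution_config()] with `mode = "promoter_distribution"`.
#' @return Character vector of shuffled sequences.
#' @export
substitute_promoter_distribution <- function(
    seq, cfg = substitution_config(mode = "promoter_distribution")) {
  stopifnot(inherits(cfg, "substitution_config"))
  if (cfg$mode != "promoter_distribution") {
    stop("cfg$mode must be 'promoter_distribution'")
  }
  assert_dna(seq)
  with_seed(cfg$seed, vapply(seq, function(s) {
    ch <- split_chars(s)
    pos <- choose_positions(length(ch), cfg)
    if (length(pos) > 1L) ch[pos] <- ch[sample(pos)]
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE))
}

#' Sample genomic negatives downstream of first exons
#'
#' Draws fixed-length subsequences from within gene bodies strictly after
#' each gene's first exon, the classical genomic non-promoter class. Genes
#' whose post-first-exon interval is shorter than `length` are skipped with
#' a warning.
#'
#' @param genome A [genome_seq()].
#' @param gene_models Data frame with columns `chrom`, `first_exon_end`
#'   (0-based, exclusive end of the first exon) and `gene_end` (0-based,
#'   exclusive).
#' @param length Sequence length to sample.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Character vector of `n` sequences.
#' @export
sample_post_first_exon <- function(genome, gene_models, length, n, seed = 1L) {
  gm <- gene_models[gene_models$chrom == genome$name, , drop = FALSE]
  widths <- gm$gene_end - gm$first_exon_end
  eligible <- which(widths >= length)
  if (base::length(eligible) < nrow(gm)) {
    warning(nrow(gm) - base::length(eligible),
            " gene(s) shorter than the requested length were skipped")
  }
  if (base::length(eligible) == 0L) {
    stop("no gene has a post-first-exon interval of at least ", length,
         " bases")
  }
  with_seed(seed, {
    genes <- sample(eligible, n, replace = TRUE)
    starts <- gm$first_exon_end[genes] +
      floor(stats::runif(n) * (widths[genes] - length + 1))
    substring(genome$bases, starts + 1, starts + length)
  })
}

#' Sample motif-containing genomic negatives
#'
#' Draws fixed-length windows that are disjoint from every excluded
#' (promoter) interval and contain at least one occurrence of the consensus
#' motif — non-promoters that nevertheless carry, e.g., a TATA motif. Drawing
#' is rejection sampling with a bounded number of attempts.
#'
#' @param genome A [genome_seq()].
#' @param excluded A [interval()] data frame of promoter regions to avoid.
#' @param motif IUPAC consensus string (e.g. `"TATAAA"`).
#' @param length Window length.
#' @param n Number of windows.
#' @param seed Integer seed.
#' @param max_tries Attempt budget (default `1000 * n`).
#' @return Character vector of `n` sequences.
#' @export
sample_genomic_with_motif <- function(genome, excluded, motif, length, n,
                                      seed = 1L, max_tries = NULL) {
  if (n == 0L) return(character(0))
  if (is.null(max_tries)) max_tries <- 1000L * n
  pat <- iupac_to_regex(motif)
  excl <- excluded[excluded$chrom == genome$name, , drop = FALSE]
  L <- genome$length
  if (L < length) stop("genome shorter than the requested window length")
  with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (base::length(out) < n && tries < max_tries) {
      tries <- tries + 1L
      s <- floor(stats::runif(1) * (L - length + 1))
      if (nrow(excl) &&
          any(pmin(s + length, excl$end) - pmax(s, excl$start) > 0)) next
      win <- substring(genome$bases, s + 1, s + length)
      if (grepl(pat, win)) out <- c(out, win)
    }
    if (base::length(out) < n) {
      stop("only ", base::length(out), " of ", n, " motif-containing ",
           "non-promoter windows found within ", max_tries, " draws")
    }
    out
  })
}
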