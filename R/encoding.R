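# Sequence -> model-input conversions: one-hot matrices (row order A,C,G,T
# throughout the package), element/non-element decomposition for the
# element-based CNN, and overlapping k-mer token text for external-tool
# interchange.

#' One-hot encode a DNA sequence
#'
#' Returns a 4 x L matrix in the fixed row order (A, C, G, T). `N` becomes an
#' all-zero column (not 0.25s): benchmark datasets drop N windows, but the
#' converters must not fail on user data.
#'
#' @param seq A single sequence over `{A,C,G,T,N}`.
#' @return A 4 x L numeric matrix with rownames `A`, `C`, `G`, `T`.
#' @export
one_hot <- function(seq) {
  stopifnot(length(seq) == 1L)
  assert_dna(seq)
  ch <- split_chars(seq)
  m <- matrix(0, nrow = 4L, ncol = length(ch),
              dimnames = list(BASES, NULL))
  hit <- match(ch, BASES)
  ok <- !is.na(hit)
  m[cbind(hit[ok], which(ok))] <- 1
  m
}

# map a TSS-relative coordinate (negative upstream, +1 = TSS base, no zero)
# to a 0-based window index, given the number of upstream bases in the window
tss_rel_to_index <- function(pos, upstream = 249L) {
  if (any(pos == 0L)) stop("TSS-relative coordinates have no position 0")
  ifelse(pos < 0L, upstream + pos, upstream + pos - 1L)
}

#' Element profile for element/non-element decomposition
#'
#' Element sequences are short motif stretches at fixed TSS-relative
#' locations (e.g. the TATA box and the initiator); non-element context is
#' the whole window compressed by max pooling. Coordinates are TSS-relative
#' (negative upstream, +1 = TSS base) and inclusive on both ends. The shipped
#' default covers the TATA box at -33..-23 and the INR at -2..+4 in a
#' 300-base window with 249 upstream bases.
#'
#' @param elements Data frame with columns `name`, `from`, `to`
#'   (TSS-relative, inclusive).
#' @param pool_size Width of the non-overlapping max pooling applied to the
#'   full-window one-hot (default 3, compressing 300 columns to 100).
#' @param window Window length the profile applies to (default 300).
#' @param upstream Upstream bases in the window (default 249).
#' @return An object of class `element_profile`.
#' @export
element_profile <- function(elements = NULL, pool_size = 3L, window = 300L,
                            upstream = 249L) {
  if (is.null(elements)) {
    elements <- data.frame(name = c("TATA", "INR"),
                           from = c(-33L, -2L), to = c(-23L, 4L),
                           stringsAsFactors = FALSE)
  }
  start <- tss_rel_to_index(elements$from, upstream)
  end <- tss_rel_to_index(elements$to, upstream) + 1L
  if (any(start < 0L) || any(end > window)) {
    stop("element offsets fall outside the ", window, "-base window")
  }
  o <- order(start)
  if (any(start[o][-1L] < end[o][-length(end)])) {
    stop("elements must not overlap")
  }
  if (window %% pool_size != 0L) {
    stop("pool_size must divide the window length")
  }
  structure(list(elements = data.frame(name = elements$name, start = start,
                                       end = end, stringsAsFactors = FALSE),
                 pool_size = as.integer(pool_size),
                 window = as.integer(window),
                 upstream = as.integer(upstream)),
            class = "element_profile")
}

#' Decompose a window into elements and compressed context
#'
#' Each element's subsequence is one-hot encoded at its fixed offsets; the
#' full-window one-hot is reduced by non-overlapping max pooling of width
#' `pool_size`. Output shapes depend only on the profile, never on the data.
#'
#' @param seq A window whose length equals the profile's window length.
#' @param profile An [element_profile()].
#' @return List with `elements` (named list of 4 x width one-hot matrices)
#'   and `context` (4 x (window / pool_size) matrix of per-block maxima).
#' @export
extract_elements <- function(seq, profile) {
  stopifnot(inherits(profile, "element_profile"))
  if (nchar(seq) != profile$window) {
    stop("sequence length ", nchar(seq), " does not match the profile ",
         "window length ", profile$window)
  }
  oh <- one_hot(seq)
  els <- lapply(seq_len(nrow(profile$elements)), function(i) {
    oh[, (profile$elements$start[i] + 1L):profile$elements$end[i],
       drop = FALSE]
  })
  names(els) <- profile$elements$name
  p <- profile$pool_size
  nblk <- profile$window %/% p
  ctx <- matrix(0, 4L, nblk, dimnames = list(BASES, NULL))
  for (i in seq_len(p)) {
    ctx <- pmax(ctx, oh[, seq.int(i, by = p, length.out = nblk),
                        drop = FALSE])
  }
  list(elements = els, context = ctx)
}

#' Convert a sequence to overlapping k-mer tokens
#'
#' @param seq A single sequence.
#' @param k k-mer size, `1 <= k <= nchar(seq)`; 6 is the conventional size
#'   for external-tool interchange.
#' @return Space-separated overlapping k-mers (`nchar(seq) - k + 1` tokens).
#' @export
to_kmer_tokens <- function(seq, k = 6L) {
  n <- nchar(seq)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= sequence length")
  starts <- seq_len(n - k + 1L)
  paste(substring(seq, starts, starts + k - 1L), collapse = " ")
}

#' Reconstruct a sequence from overlapping k-mer tokens
#'
#' Inverse of [to_kmer_tokens()]: consecutive tokens must overlap by `k - 1`
#' characters; the first inconsistent token is an error.
#'
#' @param tokens Space-separated k-mer tokens.
#' @param k k-mer size.
#' @return The reconstructed sequence.
#' @export
from_kmer_tokens <- function(tokens, k = 6L) {
  toks <- strsplit(trimws(tokens), " +")[[1]]
  if (any(nchar(toks) != k)) {
    stop("token ", which(nchar(toks) != k)[1L], " does not have length ", k)
  }
  if (length(toks) > 1L && k > 1L) {
    prev_suffix <- substring(toks[-length(toks)], 2L, k)
    next_prefix <- substring(toks[-1L], 1L, k - 1L)
    bad <- which(prev_suffix != next_prefix)
    if (length(bad)) {
      stop("overlap error at token ", bad[1L] + 1L, ": '", toks[bad[1L] + 1L],
           "' does not extend '", toks[bad[1L]], "'")
    }
  }
  paste0(toks[1L], paste(substring(toks[-1L], k, k), collapse = ""))
}

#' Write a labeled k-mer token file
#'
#' One example per line: space-separated tokens, a tab, then the I/O tag —
#' the interchange format consumed by transformer-style external tools.
#'
#' @param ds A [promoter_dataset()].
#' @param path Output path.
#' @param k k-mer size (default 6).
#' @return The path, invisibly.
#' @export
write_kmer_dataset <- function(ds, path, k = 6L) {
  toks <- vapply(ds$windows$sequence, to_kmer_tokens, "", k = k,
                 USE.NAMES = FALSE)
  writeLines(paste(toks, ds$windows$tag, sep = "\t"), path)
  invisible(path)
}

#' Read a labeled k-mer token file back into a dataset
#'
#' @param path Input path.
#' @param k k-mer size used to write the file.
#' @return A [promoter_dataset()].
#' @export
read_kmer_dataset <- function(path, k = 6L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  seqs <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) < 2L) {
      stop("k-mer dataset parse error at line ", i,
           ": expected 'tokens<TAB>tag'")
    }
    from_kmer_tokens(parts[[i]][1L], k)
  }, "")
  promoter_dataset(
    data.frame(sequence = seqs, tag = vapply(parts, `[[`, "", 2L),
               stringsAsFactors = FALSE),
    source = list(file = path, k = k))
}

#' Read externally produced predictions
#'
#' Ingests a two-column tab-separated file (sequence, predicted tag) such as
#' a third-party model's output, for evaluation against a reference dataset.
#'
#' @param path Input path.
#' @return Data frame with columns `sequence` and `tag`.
#' @export
read_predictions <- function(path) {
  ds <- read_dataset(path)
  ds$windows
}
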