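# Seeded evaluation without disturbing the caller's RNG stream. All package
# randomness flows through this helper with an explicit seed so every
# generator, sampler and training run is reproducible. RNG kinds are pinned
# so results are stable across R sessions and platforms.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max,
           kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

# derive a distinct child seed from a base seed, kept inside 32-bit range
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1000003L + as.integer(offset)) %% 2147483647L
}

split_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

BASES <- c("A", "C", "G", "T")

# IUPAC code -> allowed base sets, used for consensus motifs
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# regex character class for an IUPAC consensus, for motif scanning
iupac_to_regex <- function(motif) {
  chars <- split_chars(toupper(motif))
  cls <- vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (is.null(set)) stop("unknown IUPAC code '", ch, "' in motif")
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, "")
  paste(cls, collapse = "")
}
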