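# Shared fixtures and independent oracles used across the suite.

# deterministic random DNA
rand_seq <- function(L, seed, probs = c(0.25, 0.25, 0.25, 0.25)) {
  prombench:::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs),
    collapse = ""))
}

rand_seqs <- function(n, L, seed, probs = c(0.25, 0.25, 0.25, 0.25)) {
  prombench:::with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs),
          collapse = "")
  }, ""))
}

# brute-force contiguous-overlap oracle: best single-promoter intersection
# computed by explicit per-base position sets
oracle_best_overlap <- function(win_start, win_end, promoters) {
  win_pos <- win_start:(win_end - 1L)
  best <- 0L
  for (i in seq_len(nrow(promoters))) {
    prom_pos <- promoters$start[i]:(promoters$end[i] - 1L)
    best <- max(best, length(intersect(win_pos, prom_pos)))
  }
  best
}

# planted-motif classification dataset: positives carry a TATA box at
# TSS-relative -31 (window index 218) and an INR instance at -2 (index 247)
# in an hg38-like background; negatives are background only. Mirrors the
# synthetic-genome generator's default promoter composition as flat windows.
make_planted_dataset <- function(n_pos, n_neg, seed, motifs = TRUE) {
  bg_probs <- c(0.295, 0.205, 0.205, 0.295)
  pos <- rand_seqs(n_pos, 300L, seed, bg_probs)
  if (motifs) {
    inr <- prombench:::with_seed(seed + 7L, vapply(seq_len(n_pos), function(i)
      prombench:::sample_consensus("TCAKTY"), ""))
    pos <- vapply(seq_len(n_pos), function(i) {
      s <- pos[i]
      substr(s, 219L, 224L) <- "TATAAA"
      substr(s, 248L, 253L) <- inr[i]
      s
    }, "")
  }
  neg <- rand_seqs(n_neg, 300L, seed + 1L, bg_probs)
  promoter_dataset(data.frame(
    sequence = c(pos, neg),
    tag = c(rep("I", n_pos), rep("O", n_neg)),
    stringsAsFactors = FALSE))
}

# small architecture variants used to keep unit-level training fast
tiny_cnn_spec <- function(L = 60L, head = "sigmoid") {
  architecture_spec("cnnprom_tata", input_length = L, conv_filters = 8L,
                    filter_lengths = c(5L, 7L), pool_size = 2L,
                    hidden_units = 8L, output_head = head)
}

tiny_dprom_spec <- function(L = 60L, head = "sigmoid") {
  architecture_spec("dprom", input_length = L, conv_filters = 6L,
                    filter_lengths = 5L, pool_size = 4L,
                    recurrent_units = 4L, hidden_units = 8L,
                    output_head = head, dropout = 0)
}

# tiny separable dataset at window length 60: positives carry GATTACA at a
# fixed offset
tiny_planted_dataset <- function(n_pos, n_neg, seed) {
  pos <- vapply(rand_seqs(n_pos, 60L, seed), function(s) {
    substr(s, 21L, 27L) <- "GATTACA"
    s
  }, "", USE.NAMES = FALSE)
  neg <- rand_seqs(n_neg, 60L, seed + 1L)
  promoter_dataset(data.frame(
    sequence = c(pos, neg),
    tag = c(rep("I", n_pos), rep("O", n_neg)),
    stringsAsFactors = FALSE))
}

# memoized CNN-BiLSTM trained on the standard planted-motif benchmark
# (1,000 training windows), shared by the end-to-end checks
.acc_cache <- new.env(parent = emptyenv())
get_smoke_model <- function() {
  if (is.null(.acc_cache$model)) {
    train_ds <- make_planted_dataset(500L, 500L, 1001L)
    .acc_cache$model <- train(
      build_model(architecture_spec("dprom"), seed = 31L),
      train_ds, training_config(seed = 31L))
  }
  .acc_cache$model
}

# write a temporary JASPAR PFM file from a named list of count matrices
write_pfm_file <- function(motifs) {
  path <- tempfile(fileext = ".jaspar")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(motifs)) {
    writeLines(paste0(">", nm), con)
    M <- motifs[[nm]]
    for (r in 1:4) {
      writeLines(paste0(c("A", "C", "G", "T")[r], " [ ",
                        paste(M[r, ], collapse = " "), " ]"), con)
    }
  }
  path
}
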