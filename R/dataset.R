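# Benchmark dataset construction: sliding windows over a genome, IO tagging
# by contiguous overlap with TSS-anchored promoter regions, cleaning, splits.

#' Promoter region geometry
#'
#' The number of bases taken strictly upstream and strictly downstream of the
#' TSS base. The region length is `upstream + 1 + downstream`: the default
#' 249/50 yields the 300-base core-promoter region spanning -249..+50 around
#' a TSS denoted +1, and 200/50 yields the 251-base region used by
#' fixed-length CNN classifiers.
#'
#' @param upstream Bases strictly before the TSS base (default 249).
#' @param downstream Bases strictly after the TSS base (default 50).
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(upstream = 249L, downstream = 50L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  stopifnot(upstream >= 0L, downstream >= 0L)
  structure(list(upstream = upstream, downstream = downstream,
                 length = upstream + 1L + downstream),
            class = "region_spec")
}

#' Benchmark construction parameters
#'
#' @param window Window length in bases (default 300).
#' @param stride Step between window starts (default 50).
#' @param min_overlap Minimum contiguous overlap with a single promoter
#'   region for an `I` tag (default 250, i.e. at least 250 of 300 bases).
#' @param drop_n Remove windows containing an `N` base (default `TRUE`).
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(window = 300L, stride = 50L,
                             min_overlap = 250L, drop_n = TRUE) {
  window <- as.integer(window); stride <- as.integer(stride)
  min_overlap <- as.integer(min_overlap)
  stopifnot(stride > 0L, stride <= window,
            min_overlap > 0L, min_overlap <= window)
  structure(list(window = window, stride = stride, min_overlap = min_overlap,
                 drop_n = isTRUE(drop_n)),
            class = "benchmark_config")
}

#' Construct a promoter dataset
#'
#' An ordered collection of fixed-length labeled windows plus the recipe that
#' produced it. `windows` needs at least columns `sequence` and `tag`
#' (`I` = promoter, `O` = non-promoter); provenance columns `chrom`, `start`,
#' `end` are carried when available.
#'
#' @param windows Data frame with columns `sequence`, `tag` (and optionally
#'   `chrom`, `start`, `end`).
#' @param config A [benchmark_config()] or `NULL`.
#' @param source Free-form provenance (genome / annotation identifiers).
#' @return An object of class `promoter_dataset`.
#' @export
promoter_dataset <- function(windows, config = NULL, source = list()) {
  stopifnot(is.data.frame(windows),
            all(c("sequence", "tag") %in% names(windows)))
  if (nrow(windows) && !all(windows$tag %in% c("I", "O"))) {
    stop("tags must be 'I' or 'O'")
  }
  rownames(windows) <- NULL
  structure(list(windows = windows, config = config, source = source),
            class = "promoter_dataset")
}

#' @export
print.promoter_dataset <- function(x, ...) {
  st <- dataset_stats(x)
  cat(sprintf(
    "<promoter_dataset> %d windows (%d I / %d O, promoter fraction %.4f)\n",
    st$total, st$n_promoter, st$n_nonpromoter, st$promoter_fraction))
  invisible(x)
}

#' @export
length.promoter_dataset <- function(x) nrow(x$windows)

#' Extrapolate a promoter region from a TSS
#'
#' On the forward strand the region is `[pos0 - upstream, pos0 + downstream + 1)`;
#' on the reverse strand it is mirrored: `[pos0 - downstream, pos0 + upstream + 1)`.
#' The interval carries the TSS strand. Vectorized over annotation rows.
#'
#' @param tss A [tss_annotation()] data frame.
#' @param spec A [region_spec()].
#' @param chrom_lengths Optional named vector of chromosome lengths; regions
#'   extending past either end raise an error naming the annotation.
#' @return A [interval()] data frame, one row per TSS.
#' @export
promoter_region_from_tss <- function(tss, spec = region_spec(),
                                     chrom_lengths = NULL) {
  stopifnot(inherits(spec, "region_spec"))
  plus <- tss$strand == "+"
  start <- ifelse(plus, tss$pos0 - spec$upstream, tss$pos0 - spec$downstream)
  end <- ifelse(plus, tss$pos0 + spec$downstream + 1L,
                tss$pos0 + spec$upstream + 1L)
  bad <- start < 0
  if (!is.null(chrom_lengths)) {
    lens <- chrom_lengths[tss$chrom]
    bad <- bad | (!is.na(lens) & end > lens)
  }
  if (any(bad)) {
    off <- which(bad)[1L]
    stop("promoter region extends past a chromosome end for annotation ",
         if (!is.na(tss$label[off])) tss$label[off] else off,
         " (", tss$chrom[off], ":", tss$pos0[off], tss$strand[off], ")")
  }
  interval(tss$chrom, start, end, tss$strand)
}

# vectorized labeler: for each window [ws, we) the best contiguous overlap is
# the maximum single-promoter intersection; overlaps with different promoters
# are never summed, which is what makes the overlap contiguous.
best_overlap <- function(win_start, win_end, promoters) {
  best <- integer(length(win_start))
  if (is.null(promoters) || nrow(promoters) == 0L) return(best)
  for (i in seq_len(nrow(promoters))) {
    ov <- pmin(win_end, promoters$end[i]) - pmax(win_start, promoters$start[i])
    best <- pmax(best, ov)
  }
  best
}

#' Tag a window as promoter (I) or non-promoter (O)
#'
#' A window is tagged `I` iff a *single* promoter interval intersects it by
#' at least `min_overlap` bases (boundary inclusive). Disjoint overlaps with
#' several promoters are not summed.
#'
#' @param win A single-row [interval()].
#' @param promoters A [interval()] data frame of promoter regions (possibly
#'   empty) on the same chromosome.
#' @param min_overlap Minimum contiguous overlap (default 250).
#' @return `"I"` or `"O"`.
#' @export
label_window <- function(win, promoters, min_overlap = 250L) {
  stopifnot(nrow(win) == 1L)
  proms <- promoters[promoters$chrom == win$chrom, , drop = FALSE]
  if (best_overlap(win$start, win$end, proms) >= min_overlap) "I" else "O"
}

#' Build a sliding-window benchmark dataset
#'
#' Windows start at `0, stride, 2 stride, ...` with `start + window <= L`
#' (`floor((L - window)/stride) + 1` windows before filtering). Windows
#' containing `N` are removed when `drop_n`; survivors are tagged by
#' [label_window()]. Windows store the forward-strand sequence regardless of
#' the promoter's strand: a scanning classifier sees forward-strand text,
#' while reverse-strand promoter regions still drive labeling through genomic
#' overlap. Windows never span chromosome boundaries; pass a list of genomes
#' to process several chromosomes.
#'
#' @param genome A [genome_seq()] or list of them.
#' @param promoters A [interval()] data frame of promoter regions.
#' @param config A [benchmark_config()].
#' @return A [promoter_dataset()].
#' @export
build_benchmark <- function(genome, promoters, config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  genomes <- if (inherits(genome, "genome_seq")) list(genome) else genome
  parts <- lapply(genomes, build_benchmark_one, promoters = promoters,
                  config = config)
  windows <- do.call(rbind, parts)
  if (is.null(windows)) {
    windows <- data.frame(sequence = character(0), tag = character(0),
                          chrom = character(0), start = integer(0),
                          end = integer(0), stringsAsFactors = FALSE)
  }
  promoter_dataset(windows, config,
                   source = list(genomes = vapply(genomes, `[[`, "", "name")))
}

build_benchmark_one <- function(genome, promoters, config) {
  L <- genome$length
  w <- config$window
  if (L < w) {
    warning("genome ", genome$name, " (", L, " bases) is shorter than the ",
            w, "-base window; no windows produced")
    return(NULL)
  }
  starts <- seq.int(0L, L - w, by = config$stride)
  seqs <- substring(genome$bases, starts + 1L, starts + w)
  keep <- rep(TRUE, length(starts))
  if (config$drop_n) keep <- !grepl("N", seqs, fixed = TRUE)
  starts <- starts[keep]; seqs <- seqs[keep]
  proms <- promoters[promoters$chrom == genome$name, , drop = FALSE]
  ov <- best_overlap(starts, starts + w, proms)
  data.frame(sequence = seqs,
             tag = ifelse(ov >= config$min_overlap, "I", "O"),
             chrom = genome$name, start = starts, end = starts + w,
             stringsAsFactors = FALSE)
}

#' Remove duplicate sequences from a dataset
#'
#' Keeps the first occurrence (in dataset order) of each distinct sequence
#' string. Duplicates whose tags conflict with the kept occurrence are
#' counted and reported via a warning and in the returned conflict count.
#'
#' @param ds A [promoter_dataset()].
#' @return List with elements `dataset` (deduplicated), `removed` (count) and
#'   `tag_conflicts` (count of removed rows disagreeing with the kept tag).
#' @export
deduplicate <- function(ds) {
  w <- ds$windows
  dup <- duplicated(w$sequence)
  conflicts <- 0L
  if (any(dup)) {
    first_tag <- w$tag[match(w$sequence, w$sequence)]
    conflicts <- sum(dup & w$tag != first_tag)
    if (conflicts > 0L) {
      warning(conflicts, " duplicate window(s) had a tag conflicting with ",
              "the first occurrence; first occurrence kept")
    }
  }
  out <- promoter_dataset(w[!dup, , drop = FALSE], ds$config, ds$source)
  list(dataset = out, removed = sum(dup), tag_conflicts = conflicts)
}

#' Dataset composition report
#'
#' @param ds A [promoter_dataset()].
#' @return List with `total`, `n_promoter`, `n_nonpromoter`,
#'   `promoter_fraction` and an `empty` flag; the fraction of an empty
#'   dataset is reported as 0 with `empty = TRUE`.
#' @export
dataset_stats <- function(ds) {
  n <- nrow(ds$windows)
  ni <- sum(ds$windows$tag == "I")
  list(total = n, n_promoter = ni, n_nonpromoter = n - ni,
       promoter_fraction = if (n > 0L) ni / n else 0,
       empty = n == 0L)
}

#' Disjoint train/test splits for several models
#'
#' Builds a master train/test split of the shared promoter pool first (sized
#' for the model requesting the most promoters), then draws each smaller
#' model's promoters from within the corresponding master side, so every
#' model's promoter test set is disjoint from every model's promoter train
#' set. Non-promoters are likewise split into master sides before per-model
#' sampling. After assembly, the split is verified by exhaustive sequence
#' comparison: any string shared between a train side and a test side is an
#' error.
#'
#' @param full A deduplicated [promoter_dataset()] holding the full pool.
#' @param requests Named list; each element is
#'   `list(promoters = c(train, test), nonpromoters = c(train, test))`.
#' @param seed Integer seed driving all sampling.
#' @return Named list (one element per request) of `list(train, test)`
#'   [promoter_dataset()]s.
#' @export
disjoint_split <- function(full, requests, seed = 1L) {
  w <- full$windows
  if (anyDuplicated(w$sequence)) {
    stop("disjoint_split requires a deduplicated dataset; run deduplicate()")
  }
  ip <- which(w$tag == "I"); io <- which(w$tag == "O")
  p_tr <- vapply(requests, function(r) r$promoters[1L], numeric(1))
  p_te <- vapply(requests, function(r) r$promoters[2L], numeric(1))
  o_tr <- vapply(requests, function(r) r$nonpromoters[1L], numeric(1))
  o_te <- vapply(requests, function(r) r$nonpromoters[2L], numeric(1))
  if (max(p_tr) + max(p_te) > length(ip)) {
    stop("infeasible promoter counts: need ", max(p_tr) + max(p_te),
         ", pool has ", length(ip))
  }
  if (max(o_tr) + max(o_te) > length(io)) {
    stop("infeasible non-promoter counts: need ", max(o_tr) + max(o_te),
         ", pool has ", length(io))
  }
  with_seed(seed, {
    ip <- sample(ip)
    io <- sample(io)
    master_p_train <- ip[seq_len(max(p_tr))]
    master_p_test <- ip[max(p_tr) + seq_len(max(p_te))]
    master_o_train <- io[seq_len(max(o_tr))]
    master_o_test <- io[max(o_tr) + seq_len(max(o_te))]
    out <- lapply(seq_along(requests), function(i) {
      tr_idx <- c(sample(master_p_train, p_tr[i]),
                  sample(master_o_train, o_tr[i]))
      te_idx <- c(sample(master_p_test, p_te[i]),
                  sample(master_o_test, o_te[i]))
      src <- c(full$source, list(split_seed = seed,
                                 model = names(requests)[i]))
      list(train = promoter_dataset(w[sort(tr_idx), , drop = FALSE],
                                    full$config, src),
           test = promoter_dataset(w[sort(te_idx), , drop = FALSE],
                                   full$config, src))
    })
  })
  names(out) <- names(requests)
  verify_disjoint(out)
  out
}

# exhaustive leak check: no sequence string shared between any train side and
# any test side
verify_disjoint <- function(splits) {
  train_seqs <- unique(unlist(lapply(splits, function(s) s$train$windows$sequence)))
  test_seqs <- unique(unlist(lapply(splits, function(s) s$test$windows$sequence)))
  leak <- intersect(train_seqs, test_seqs)
  if (length(leak)) {
    stop("train/test leak: ", length(leak), " sequence(s) appear on both ",
         "sides of the split")
  }
  invisible(TRUE)
}

#' Map promoter sequences onto a genome by exact matching
#'
#' Finds every exact occurrence of each promoter sequence on both strands.
#' Reverse-strand hits (occurrences of the reverse complement in the forward
#' text) are reported with strand `-` in forward coordinates. This is the
#' exact-match core of alignment-based dataset creation; approximate hits
#' from an external aligner can be imported as [interval()]s instead.
#'
#' @param genome A [genome_seq()].
#' @param promoter_seqs Character vector of promoter sequences over
#'   `{A,C,G,T}`.
#' @return A [interval()] data frame (zero rows when nothing matches).
#' @export
map_promoters_by_exact_match <- function(genome, promoter_seqs) {
  assert_dna(promoter_seqs, allow_n = FALSE)
  subject <- Biostrings::DNAString(genome$bases)
  hits <- lapply(promoter_seqs, function(p) {
    fwd <- Biostrings::matchPattern(Biostrings::DNAString(p), subject)
    rev <- Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(p)), subject)
    rbind(
      if (length(fwd)) data.frame(start = Biostrings::start(fwd) - 1L,
                                  end = Biostrings::end(fwd), strand = "+"),
      if (length(rev)) data.frame(start = Biostrings::start(rev) - 1L,
                                  end = Biostrings::end(rev), strand = "-")
    )
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("genomic_interval", "data.frame")
    return(out)
  }
  hits <- unique(hits)
  interval(genome$name, hits$start, hits$end, hits$strand)
}

#' Write a dataset to a tab-separated file
#'
#' Two columns (sequence, tag) preceded by `#`-comment header lines recording
#' the construction recipe and provenance.
#'
#' @param ds A [promoter_dataset()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dataset <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- ds$config
  if (!is.null(cfg)) {
    writeLines(sprintf("# window=%d stride=%d min_overlap=%d drop_n=%s",
                       cfg$window, cfg$stride, cfg$min_overlap, cfg$drop_n),
               con)
  }
  if (length(ds$source)) {
    writeLines(paste0("# source: ",
                      paste(names(ds$source),
                            vapply(ds$source, function(x)
                              paste(format(x), collapse = ","), ""),
                            sep = "=", collapse = " ")), con)
  }
  utils::write.table(ds$windows[, c("sequence", "tag")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path Input path.
#' @return A [promoter_dataset()] (construction recipe restored when the
#'   header comment is present).
#' @export
read_dataset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  cfg <- NULL
  m <- regmatches(hdr, regexec(
    "window=(\\d+) stride=(\\d+) min_overlap=(\\d+) drop_n=(\\w+)", hdr))
  m <- Filter(length, m)
  if (length(m)) {
    v <- m[[1L]]
    cfg <- benchmark_config(as.integer(v[2L]), as.integer(v[3L]),
                            as.integer(v[4L]), v[5L] == "TRUE")
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad)) {
    stop("dataset parse error at line ", bad[1L] + length(hdr),
         ": expected 'sequence<TAB>tag'")
  }
  promoter_dataset(
    data.frame(sequence = vapply(parts, `[[`, "", 1L),
               tag = vapply(parts, `[[`, "", 2L), stringsAsFactors = FALSE),
    cfg, source = list(file = path))
}

#' Export a dataset as FASTA with tags in descriptions
#'
#' @param ds A [promoter_dataset()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dataset_fasta <- function(ds, path) {
  w <- ds$windows
  ids <- if (all(c("chrom", "start", "end") %in% names(w))) {
    sprintf("%s:%d-%d %s", w$chrom, w$start, w$end, w$tag)
  } else {
    sprintf("window%d %s", seq_len(nrow(w)), w$tag)
  }
  writeLines(paste0(">", ids, "\n", w$sequence), path)
  invisible(path)
}
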