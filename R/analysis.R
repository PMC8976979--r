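# Interpretability tools: per-position class-discrimination logos,
# TSS-relative subsequence slicing, and filter activation maps over trained
# or fixed-filter models. Logos are emitted as matrices; plotting is a thin
# optional layer on top, so tests assert numbers rather than images.

#' Per-position base frequencies of a sequence set
#'
#' @param seqs Character vector of equal-length sequences.
#' @return 4 x L matrix of frequencies (rows A, C, G, T; `N` bases count
#'   toward no row, so columns may sum to less than 1).
#' @keywords internal
base_frequencies <- function(seqs) {
  L <- nchar(seqs[1L])
  if (any(nchar(seqs) != L)) stop("sequences must have equal length")
  X <- encode_batch(seqs)
  counts <- colSums(X)
  matrix(counts, 4L, L, dimnames = list(BASES, NULL)) / length(seqs)
}

#' Class-discrimination logo matrix
#'
#' Per position and base: frequency among positives minus frequency among
#' negatives (`frequency_difference` semantics; rows sum to ~0 per position),
#' or the information-content-weighted frequency difference
#' (`information_content` semantics, where each set's frequencies are scaled
#' by the per-position information content, in bits, before subtracting).
#' The matrix is antisymmetric under swapping the two sets. The TSS-anchored
#' coordinate of each column is attached following the window convention
#' (TSS base at 0-based window index `upstream`).
#'
#' @param pos_seqs,neg_seqs Character vectors of equal-length sequences.
#' @param semantics `"frequency_difference"` (default) or
#'   `"information_content"`.
#' @param upstream Upstream bases in the window coordinate (default 249).
#' @return 4 x L matrix of class `seq_logo_matrix` with attributes
#'   `semantics` and `tss_relative` (per-column TSS-relative coordinates).
#' @export
class_discrimination_logo <- function(pos_seqs, neg_seqs,
                                      semantics = c("frequency_difference",
                                                    "information_content"),
                                      upstream = 249L) {
  semantics <- match.arg(semantics)
  if (nchar(pos_seqs[1L]) != nchar(neg_seqs[1L])) {
    stop("positive and negative sequences must have the same length")
  }
  fp <- base_frequencies(pos_seqs)
  fn <- base_frequencies(neg_seqs)
  M <- if (semantics == "frequency_difference") {
    fp - fn
  } else {
    ic_weight(fp) - ic_weight(fn)
  }
  L <- ncol(M)
  idx0 <- seq_len(L) - 1L
  rel <- ifelse(idx0 < upstream, idx0 - upstream, idx0 - upstream + 1L)
  structure(M, class = c("seq_logo_matrix", "matrix"),
            semantics = semantics, tss_relative = rel, upstream = upstream)
}

# information-content-weighted heights: freq * (2 + sum f log2 f), the
# standard logo height, in [0, 2] bits per position
ic_weight <- function(f) {
  ic <- apply(f, 2L, function(col) {
    p <- col[col > 0]
    2 + sum(p * log2(p))
  })
  sweep(f, 2L, ic, "*")
}

#' Information-content sequence logo of one set
#'
#' Column heights are `freq * IC` with per-position information content
#' `IC = 2 + sum(f log2 f)` bits, in `[0, 2]`.
#'
#' @param seqs Character vector of equal-length sequences.
#' @param upstream Upstream bases for the TSS-relative coordinates.
#' @return A `seq_logo_matrix` with `information_content` semantics.
#' @export
seq_logo <- function(seqs, upstream = 249L) {
  f <- ic_weight(base_frequencies(seqs))
  L <- ncol(f)
  idx0 <- seq_len(L) - 1L
  rel <- ifelse(idx0 < upstream, idx0 - upstream, idx0 - upstream + 1L)
  structure(f, class = c("seq_logo_matrix", "matrix"),
            semantics = "information_content", tss_relative = rel,
            upstream = upstream)
}

#' Write / read a logo matrix with its coordinate header
#'
#' Tab-separated: a comment header recording semantics and the TSS-relative
#' coordinate of every column, then one row per base.
#'
#' @param logo A `seq_logo_matrix`.
#' @param path Output path.
#' @return The path invisibly; `read_logo_matrix` returns the restored
#'   matrix.
#' @export
write_logo_matrix <- function(logo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# semantics=", attr(logo, "semantics"),
                    " upstream=", attr(logo, "upstream")), con)
  writeLines(paste0("# tss_relative=",
                    paste(attr(logo, "tss_relative"), collapse = ",")), con)
  utils::write.table(format(unclass(logo), digits = 12), con, sep = "\t",
                     quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_logo_matrix
#' @export
read_logo_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sem <- sub(".*semantics=(\\S+).*", "\\1", lines[1L])
  ups <- as.integer(sub(".*upstream=(\\d+).*", "\\1", lines[1L]))
  rel <- as.integer(strsplit(sub("# tss_relative=", "", lines[2L]),
                             ",")[[1]])
  body <- utils::read.table(text = lines[-(1:2)], sep = "\t",
                            row.names = 1L)
  M <- as.matrix(body)
  dimnames(M) <- list(rownames(body), NULL)
  structure(M, class = c("seq_logo_matrix", "matrix"), semantics = sem,
            tss_relative = rel, upstream = ups)
}

#' Slice every window of a dataset to a TSS-relative subrange
#'
#' Coordinates are TSS-relative (negative upstream, +1 = TSS base, no
#' position 0) and inclusive on both ends, so either reading of a motif
#' span is expressible. Tags and order are preserved; the slice coordinates
#' are recorded in the dataset source metadata.
#'
#' @param ds A [promoter_dataset()] of equal-length windows.
#' @param from_pos,to_pos TSS-relative inclusive bounds.
#' @param upstream Upstream bases in the window coordinate (default 249).
#' @return A [promoter_dataset()] of the sliced windows.
#' @export
subsequence_slice <- function(ds, from_pos, to_pos, upstream = 249L) {
  L <- nchar(ds$windows$sequence[1L])
  i0 <- tss_rel_to_index(from_pos, upstream)
  i1 <- tss_rel_to_index(to_pos, upstream)
  if (i0 > i1) stop("from_pos must not lie downstream of to_pos")
  if (i0 < 0L || i1 >= L) {
    stop("slice [", from_pos, ", ", to_pos, "] falls outside the ", L,
         "-base window")
  }
  w <- ds$windows
  w$sequence <- substring(w$sequence, i0 + 1L, i1 + 1L)
  promoter_dataset(w, ds$config,
                   c(ds$source, list(slice = c(from = from_pos,
                                               to = to_pos))))
}

#' Mean convolution-filter activation per window position
#'
#' For each convolution filter of the model, the mean linear activation
#' (sliding dot product plus bias) at every window position over the given
#' sequences, plus a combined map summing all filters for a global view.
#' Works for any family with a convolution stage, including frozen
#' JASPAR-filter models.
#'
#' @param model A `promoter_model` whose family has a convolution stage.
#' @param seqs Character vector of sequences of the model's input length.
#' @return List with `per_filter` (list, one numeric matrix `filters x
#'   positions` per conv bank) and `combined` (numeric vector, sum over all
#'   filters, padded to the longest bank's positions).
#' @export
filter_activation_map <- function(model, seqs) {
  spec <- model$spec
  if (is.null(model$params$conv)) stop("model has no convolution stage")
  bad <- which(nchar(seqs) != spec$input_length)
  if (length(bad)) {
    stop("sequence ", bad[1L], " does not match the model input length")
  }
  X <- encode_batch(seqs)
  B <- length(seqs)
  banks <- conv_banks(spec, model$filters)
  per_filter <- lapply(seq_along(banks), function(i) {
    cc <- conv_forward(X, model$params$conv[[i]]$W,
                       model$params$conv[[i]]$b, spec$input_length,
                       banks[[i]]$k)
    F_ <- ncol(model$params$conv[[i]]$W)
    arr <- array(cc$Z, c(B, cc$P, F_))
    m <- apply(arr, c(2L, 3L), mean)      # positions x filters
    t(m)                                   # filters x positions
  })
  maxP <- max(vapply(per_filter, ncol, 0L))
  combined <- rowSums(vapply(per_filter, function(m) {
    v <- colSums(m)
    c(v, numeric(maxP - length(v)))
  }, numeric(maxP)))
  list(per_filter = per_filter, combined = combined)
}
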