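# Architecture families and the uniform predict contract.
#
# Families:
#   cnnprom_nontata / cnnprom_tata  conv banks (lengths 15 and 21) -> max
#       pool -> ReLU -> dense -> head; the TATA variant uses fewer filters
#       and a smaller pool than the non-TATA variant.
#   icnnp       one conv bank (200 filters) plus a max-pooled full-sequence
#       context and one-hot element subsequences at fixed TSS-relative
#       offsets, concatenated -> dense -> head.
#   dprom       conv embedding -> max pool -> ReLU -> bidirectional LSTM ->
#       dense -> head.
#   jaspar_fixed  conv whose filters are imported position-weight matrices,
#       frozen during training -> max pool -> dense -> head.

FAMILIES <- c("cnnprom_tata", "cnnprom_nontata", "icnnp", "dprom",
              "jaspar_fixed")

#' Declarative architecture specification
#'
#' Only the published facts are fixed (the element-CNN's 200 filters, filter
#' lengths 15 and 21, the TATA CNN using fewer filters and a smaller pool
#' than the non-TATA CNN); remaining widths are configuration with the
#' defaults documented here.
#'
#' @param family One of `cnnprom_tata`, `cnnprom_nontata`, `icnnp`, `dprom`,
#'   `jaspar_fixed`.
#' @param input_length Input sequence length in bases (300 default; 251 for
#'   the classical TSS-anchored 200+1+50 region).
#' @param conv_filters Filters per filter length (defaults: non-TATA 200,
#'   TATA 100, element CNN 200, CNN-BiLSTM 64).
#' @param filter_lengths Convolution filter lengths (default `c(15, 21)`;
#'   the CNN-BiLSTM uses a single length-15 embedding bank).
#' @param pool_size Max-pool width (defaults: non-TATA 4, TATA 2,
#'   CNN-BiLSTM 6).
#' @param recurrent_units Hidden width per LSTM direction (`dprom` only,
#'   default 16).
#' @param hidden_units Dense hidden width before the output head (default 64).
#' @param output_head `"sigmoid"` (one score) or `"softmax"` (two scores
#'   summing to one; class order is fixed as non-promoter, promoter).
#' @param dropout Dropout rate on the pre-dense feature vector during
#'   training (default 0; 0.2 for the CNN-BiLSTM family).
#' @param element_profile An [element_profile()] (`icnnp` only).
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(family, input_length = 300L,
                              conv_filters = NULL, filter_lengths = NULL,
                              pool_size = NULL, recurrent_units = NULL,
                              hidden_units = 64L,
                              output_head = c("sigmoid", "softmax"),
                              dropout = 0, element_profile = NULL) {
  family <- match.arg(family, FAMILIES)
  output_head <- match.arg(output_head)
  defaults <- switch(family,
    cnnprom_nontata = list(conv_filters = 200L, filter_lengths = c(15L, 21L),
                           pool_size = 4L),
    cnnprom_tata = list(conv_filters = 100L, filter_lengths = c(15L, 21L),
                        pool_size = 2L),
    icnnp = list(conv_filters = 200L, filter_lengths = c(15L, 21L),
                 pool_size = 4L),
    dprom = list(conv_filters = 64L, filter_lengths = 15L, pool_size = 6L),
    jaspar_fixed = list(conv_filters = NA_integer_,
                        filter_lengths = NA_integer_, pool_size = 4L))
  if (missing(dropout) && family == "dprom") dropout <- 0.2
  conv_filters <- as.integer(conv_filters %||% defaults$conv_filters)
  filter_lengths <- as.integer(filter_lengths %||% defaults$filter_lengths)
  pool_size <- as.integer(pool_size %||% defaults$pool_size)
  input_length <- as.integer(input_length)
  if (family != "dprom" && !is.null(recurrent_units)) {
    stop("recurrent_units is only valid for the dprom family")
  }
  if (family == "dprom") {
    recurrent_units <- as.integer(recurrent_units %||% 16L)
    filter_lengths <- filter_lengths[1L]
  }
  if (family != "jaspar_fixed") {
    if (is.na(conv_filters) || conv_filters <= 0L) {
      stop("conv_filters must be positive")
    }
    if (input_length <= max(filter_lengths)) {
      stop("input_length must exceed the longest filter")
    }
  }
  if (family == "cnnprom_tata") {
    nt <- list(conv_filters = 200L, pool_size = 4L)
    if (conv_filters >= nt$conv_filters || pool_size >= nt$pool_size) {
      stop("cnnprom_tata must use fewer filters and a smaller pool than ",
           "cnnprom_nontata (", nt$conv_filters, " filters, pool ",
           nt$pool_size, ")")
    }
  }
  if (family == "icnnp" && is.null(element_profile)) {
    element_profile <- prombench::element_profile(window = input_length,
                                                  upstream = input_length - 51L)
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(family = family, input_length = input_length,
                 conv_filters = conv_filters,
                 filter_lengths = filter_lengths, pool_size = pool_size,
                 recurrent_units = recurrent_units,
                 hidden_units = as.integer(hidden_units),
                 output_head = output_head, dropout = dropout,
                 element_profile = element_profile),
            class = "architecture_spec")
}

n_out <- function(spec) if (spec$output_head == "softmax") 2L else 1L

#' Import JASPAR position frequency matrices as convolution filters
#'
#' Each motif's 4 x L count matrix (row order A, C, G, T) is normalized
#' per column to frequencies; in `log_odds` mode the frequencies (with a
#' pseudocount) are converted to log2 odds against a uniform background, so
#' a uniform column becomes exactly zero.
#'
#' @param pfm_file Path to a JASPAR-format PFM text file (header line per
#'   motif, then four count rows).
#' @param mode `"frequency"` or `"log_odds"`.
#' @param pseudocount Added to each count before log-odds conversion
#'   (default 0.5; unused in frequency mode).
#' @return List of `motif_filter` objects (`name`, `counts`, `weights`,
#'   `mode`).
#' @export
import_jaspar_filters <- function(pfm_file, mode = c("frequency", "log_odds"),
                                  pseudocount = 0.5) {
  mode <- match.arg(mode)
  lines <- readLines(pfm_file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L) stop("no motif headers ('>') found in ", pfm_file)
  out <- lapply(seq_along(hdr), function(i) {
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    rows <- lines[from:to]
    if (length(rows) != 4L) {
      stop("motif ", sub("^>\\s*", "", lines[hdr[i]]), " has ", length(rows),
           " count rows; expected 4 (A, C, G, T)")
    }
    counts <- lapply(rows, function(r) {
      nums <- regmatches(r, gregexpr("-?[0-9]*\\.?[0-9]+", r))[[1]]
      as.numeric(nums)
    })
    lens <- vapply(counts, length, 0L)
    if (length(unique(lens)) != 1L) {
      stop("motif ", sub("^>\\s*", "", lines[hdr[i]]),
           " has count rows of unequal length")
    }
    M <- do.call(rbind, counts)
    rownames(M) <- BASES
    if (any(M < 0)) {
      stop("motif ", sub("^>\\s*", "", lines[hdr[i]]),
           " contains negative counts")
    }
    W <- if (mode == "frequency") {
      sweep(M, 2L, colSums(M), "/")
    } else {
      Mp <- M + pseudocount
      freq <- sweep(Mp, 2L, colSums(Mp), "/")
      log2(freq / 0.25)
    }
    structure(list(name = sub("^>\\s*", "", lines[hdr[i]]), counts = M,
                   weights = W, mode = mode),
              class = "motif_filter")
  })
  out
}

#' Build an untrained model from an architecture specification
#'
#' Weights are seeded (Glorot-uniform) so an untrained model's scores are
#' reproducible. For `jaspar_fixed`, `filters` supplies the imported motifs;
#' their convolution weights are frozen and only the dense layers train.
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed for weight initialization.
#' @param filters List of `motif_filter` objects (required for
#'   `jaspar_fixed`).
#' @return An object of class `promoter_model`.
#' @export
build_model <- function(spec, seed = 1L, filters = NULL) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (spec$family == "jaspar_fixed") {
    if (is.null(filters) || length(filters) == 0L) {
      stop("jaspar_fixed requires imported motif filters")
    }
  } else if (!is.null(filters)) {
    stop("filters are only valid for the jaspar_fixed family")
  }
  params <- with_seed(seed, init_params(spec, filters))
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 filters = filters, trained = FALSE, history = NULL),
            class = "promoter_model")
}

#' @export
print.promoter_model <- function(x, ...) {
  cat(sprintf("<promoter_model> family=%s input=%d head=%s (%s)\n",
              x$spec$family, x$spec$input_length, x$spec$output_head,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# feature width after conv -> pool for one bank
bank_T <- function(L, k, p) ((L - k + 1L) %/% p)

# conv bank descriptors: for jaspar_fixed the banks are the distinct motif
# widths, one filter column per motif of that width.
conv_banks <- function(spec, filters = NULL) {
  if (spec$family == "jaspar_fixed") {
    widths <- vapply(filters, function(f) ncol(f$weights), 0L)
    lapply(sort(unique(widths)), function(k) {
      list(k = k, which = which(widths == k))
    })
  } else {
    lapply(spec$filter_lengths, function(k) list(k = k, nf = spec$conv_filters))
  }
}

init_params <- function(spec, filters = NULL) {
  L <- spec$input_length
  banks <- conv_banks(spec, filters)
  conv <- lapply(banks, function(bk) {
    if (spec$family == "jaspar_fixed") {
      W <- vapply(filters[bk$which],
                  function(f) as.vector(f$weights), numeric(4L * bk$k))
      W <- matrix(W, nrow = 4L * bk$k)
      list(W = W, b = numeric(ncol(W)))
    } else {
      list(W = glorot(4L * bk$k, bk$nf), b = numeric(bk$nf))
    }
  })
  feat_dim <- sum(vapply(seq_along(banks), function(i) {
    bank_T(L, banks[[i]]$k, spec$pool_size) * ncol(conv[[i]]$W)
  }, 0L))
  params <- list(conv = conv)
  if (spec$family == "dprom") {
    H <- spec$recurrent_units
    F_ <- spec$conv_filters
    mk_dir <- function() list(Wx = glorot(F_, 4L * H),
                              Wh = glorot(H, 4L * H),
                              b = c(numeric(H), rep(1, H), numeric(2L * H)))
    params$lstm <- list(fwd = mk_dir(), bwd = mk_dir())
    feat_dim <- 2L * H * bank_T(L, spec$filter_lengths[1L], spec$pool_size)
  }
  if (spec$family == "icnnp") {
    ep <- spec$element_profile
    feat_dim <- feat_dim + 4L * (spec$input_length %/% ep$pool_size) +
      4L * sum(ep$elements$end - ep$elements$start)
  }
  params$dense <- list(W = glorot(feat_dim, spec$hidden_units),
                       b = numeric(spec$hidden_units))
  params$out <- list(W = glorot(spec$hidden_units, n_out(spec)),
                     b = numeric(n_out(spec)))
  params
}

# icnnp auxiliary features straight from the batch encoding: element one-hot
# columns plus the max-pooled full-sequence context (no gradient needed —
# they are functions of the input only).
icnnp_aux <- function(X, spec) {
  ep <- spec$element_profile
  L <- spec$input_length
  el_cols <- unlist(lapply(seq_len(nrow(ep$elements)), function(i) {
    pos <- ep$elements$start[i]:(ep$elements$end[i] - 1L)
    as.vector(outer(1:4, pos * 4L, "+"))
  }))
  p <- ep$pool_size
  Tc <- L %/% p
  ctx <- X[, as.vector(outer(1:4, (seq(0L, by = p, length.out = Tc)) * 4L,
                             "+")), drop = FALSE]
  if (p > 1L) {
    for (i in 2:p) {
      ctx <- pmax(ctx, X[, as.vector(outer(
        1:4, (seq(i - 1L, by = p, length.out = Tc)) * 4L, "+")),
        drop = FALSE])
    }
  }
  cbind(X[, el_cols, drop = FALSE], ctx)
}

# full forward pass; returns probabilities plus every cache needed for the
# backward pass. dropout is applied (inverted) only when training.
nn_forward <- function(model, X, training = FALSE) {
  spec <- model$spec
  p <- model$params
  L <- spec$input_length
  B <- nrow(X)
  banks <- conv_banks(spec, model$filters)
  conv_caches <- list()
  pool_caches <- list()
  feats <- NULL
  for (i in seq_along(banks)) {
    k <- banks[[i]]$k
    cc <- conv_forward(X, p$conv[[i]]$W, p$conv[[i]]$b, L, k)
    pc <- pool_relu_forward(cc$Z, B, ncol(p$conv[[i]]$W), spec$pool_size)
    conv_caches[[i]] <- cc
    pool_caches[[i]] <- pc
    if (spec$family != "dprom") {
      feats <- cbind(feats, flat3(pc$act))
    }
  }
  lstm_cache <- NULL
  if (spec$family == "dprom") {
    pc <- pool_caches[[1L]]
    xs <- lapply(seq_len(pc$T_), function(t) pc$act[, t, , drop = TRUE])
    xs <- lapply(xs, function(x) if (is.null(dim(x))) matrix(x, nrow = B) else x)
    lstm_cache <- bilstm_forward(xs, p$lstm)
    feats <- lstm_cache$feat
  }
  if (spec$family == "icnnp") {
    feats <- cbind(feats, icnnp_aux(X, spec))
  }
  drop_mask <- NULL
  if (training && spec$dropout > 0) {
    drop_mask <- matrix(stats::rbinom(length(feats), 1L, 1 - spec$dropout) /
                          (1 - spec$dropout), nrow(feats), ncol(feats))
    feats <- feats * drop_mask
  }
  Zd <- dense_forward(feats, p$dense$W, p$dense$b)
  Hd <- pmax(Zd, 0)
  Zo <- dense_forward(Hd, p$out$W, p$out$b)
  prob <- if (spec$output_head == "sigmoid") {
    as.vector(sigmoid(Zo))
  } else {
    softmax_rows(Zo)
  }
  list(prob = prob,
       cache = list(X = X, conv = conv_caches, pool = pool_caches,
                    lstm = lstm_cache, feats = feats, drop_mask = drop_mask,
                    Zd = Zd, Hd = Hd, banks = banks))
}

# backward pass from the gradient on the output pre-activations
nn_backward <- function(model, cache, dZo) {
  spec <- model$spec
  p <- model$params
  g_out <- dense_backward(cache$Hd, p$out$W, dZo)
  dHd <- g_out$dX
  dHd[cache$Zd <= 0] <- 0
  g_dense <- dense_backward(cache$feats, p$dense$W, dHd)
  dfeats <- g_dense$dX
  if (!is.null(cache$drop_mask)) dfeats <- dfeats * cache$drop_mask
  grads <- list(conv = vector("list", length(cache$conv)),
                dense = g_dense[c("W", "b")], out = g_out[c("W", "b")])
  frozen <- spec$family == "jaspar_fixed"
  if (spec$family == "dprom") {
    B <- nrow(cache$X)
    bl <- bilstm_backward(cache$lstm, p$lstm, dfeats)
    grads$lstm <- bl$grads
    pc <- cache$pool[[1L]]
    dact <- array(0, c(B, pc$T_, pc$F_))
    for (t in seq_len(pc$T_)) dact[, t, ] <- bl$dxs[[t]]
    dZ <- pool_relu_backward(pc, dact)
    grads$conv[[1L]] <- conv_backward(cache$conv[[1L]], dZ)
  } else {
    off <- 0L
    for (i in seq_along(cache$conv)) {
      pc <- cache$pool[[i]]
      wdt <- pc$T_ * pc$F_
      if (frozen) {
        grads$conv[i] <- list(NULL)
      } else {
        dact <- dfeats[, off + seq_len(wdt), drop = FALSE]
        dim(dact) <- c(pc$B, pc$T_, pc$F_)
        dZ <- pool_relu_backward(pc, dact)
        grads$conv[[i]] <- conv_backward(cache$conv[[i]], dZ)
      }
      off <- off + wdt
    }
    # icnnp aux features and dropout columns beyond conv banks carry no
    # trainable parameters below them
  }
  grads
}

#' Predict promoter tags for a batch of sequences
#'
#' For a sigmoid head a sequence is tagged `I` iff its score is at least the
#' threshold (the 0.5 boundary is inclusive); for a softmax head the larger
#' class probability wins and the threshold is unused. Every sequence must
#' match the model's input length.
#'
#' @param object A `promoter_model`.
#' @param sequences Character vector of sequences.
#' @param threshold Sigmoid decision threshold (default 0.5).
#' @param chunk_size Sequences scored per internal batch (default 512), a
#'   memory/speed trade-off with no effect on the scores.
#' @param ... Unused.
#' @return Data frame with columns `tag` (`I`/`O`) and `score` (promoter
#'   probability).
#' @export
predict.promoter_model <- function(object, sequences, threshold = 0.5,
                                   chunk_size = 512L, ...) {
  L <- object$spec$input_length
  bad <- which(nchar(sequences) != L)
  if (length(bad)) {
    stop("sequence ", bad[1L], " has length ", nchar(sequences[bad[1L]]),
         "; model expects ", L)
  }
  starts <- seq(1L, length(sequences), by = chunk_size)
  parts <- lapply(starts, function(s) {
    idx <- s:min(s + chunk_size - 1L, length(sequences))
    fw <- nn_forward(object, encode_batch(sequences[idx]),
                     training = FALSE)
    if (object$spec$output_head == "sigmoid") {
      data.frame(tag = ifelse(fw$prob >= threshold, "I", "O"),
                 score = fw$prob, stringsAsFactors = FALSE)
    } else {
      data.frame(tag = ifelse(fw$prob[, 2L] >= fw$prob[, 1L], "I", "O"),
                 score = fw$prob[, 2L], stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a self-describing archive holding the architecture spec,
#' all weights, the training seed and any training history.
#'
#' @param model A `promoter_model`.
#' @param path Destination path.
#' @return `save_checkpoint` the path invisibly; `load_checkpoint` the
#'   restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(spec = model$spec, params = model$params, seed = model$seed,
               filters = model$filters, trained = model$trained,
               history = model$history,
               package_version = as.character(utils::packageVersion("prombench"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(list(spec = x$spec, params = x$params, seed = x$seed,
                 filters = x$filters, trained = x$trained,
                 history = x$history),
            class = "promoter_model")
}
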