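# Training loop, class-rebalancing samplers, confusion/metric computation,
# stratified k-fold cross-validation with Student-t confidence intervals,
# and the all-models-by-all-datasets cross-testing matrix.

#' Training configuration
#'
#' Defaults follow the benchmarking protocol: learning rate 0.001, at most
#' 50 epochs, early stopping after 5 epochs without improvement of the
#' validation MCC (computed on a stratified holdout carved from the training
#' data with the run seed), loss paired to the output head (binary
#' cross-entropy for sigmoid, cross-entropy for softmax).
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param max_epochs Epoch cap (default 50).
#' @param patience Epochs without validation-MCC improvement before stopping
#'   (default 5; must not exceed `max_epochs`).
#' @param batch_size Minibatch size (default 32). Batches are stratified:
#'   class proportions are preserved per batch within one example.
#' @param optimizer_name Only `"adam"` is provided.
#' @param sampling `"normal"`, `"oversample"` or `"undersample"`.
#' @param sampling_ratio Non-promoters per promoter for the non-normal modes
#'   (default 10).
#' @param validation_fraction Stratified holdout fraction used for early
#'   stopping (default 0.1).
#' @param checkpoint_dir Directory for best-model checkpoint files (`NULL`
#'   to keep checkpoints in memory only).
#' @param seed Integer seed driving initialization, batching, sampling and
#'   dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.001, max_epochs = 50L,
                            patience = 5L, batch_size = 32L,
                            optimizer_name = "adam",
                            sampling = c("normal", "oversample",
                                         "undersample"),
                            sampling_ratio = 10, validation_fraction = 0.1,
                            checkpoint_dir = NULL, seed = 1L) {
  sampling <- match.arg(sampling)
  stopifnot(learning_rate > 0, patience <= max_epochs, batch_size >= 1L)
  if (optimizer_name != "adam") stop("only the adam optimizer is provided")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 optimizer_name = optimizer_name, sampling = sampling,
                 sampling_ratio = sampling_ratio,
                 validation_fraction = validation_fraction,
                 checkpoint_dir = checkpoint_dir, seed = as.integer(seed)),
            class = "training_config")
}

#' Rebalance a dataset by over- or undersampling
#'
#' `normal` returns the dataset unchanged. `undersample` randomly discards
#' non-promoters until at most `ratio` remain per promoter. `oversample`
#' duplicates promoters (sampling with replacement, seeded) until the
#' non-promoter:promoter ratio is at most `ratio`, then shuffles the order
#' with the same seed. Oversampling never changes the set of distinct
#' non-promoter sequences; undersampling never touches promoters.
#'
#' @param ds A [promoter_dataset()] containing both classes.
#' @param strategy `"normal"`, `"oversample"` or `"undersample"`.
#' @param ratio Target non-promoters per promoter (default 10).
#' @param seed Integer seed.
#' @return A rebalanced [promoter_dataset()].
#' @export
apply_sampling <- function(ds, strategy = c("normal", "oversample",
                                            "undersample"),
                           ratio = 10, seed = 1L) {
  strategy <- match.arg(strategy)
  w <- ds$windows
  ii <- which(w$tag == "I"); io <- which(w$tag == "O")
  if (length(ii) == 0L) stop("dataset contains no promoter (I) windows")
  if (strategy == "normal") return(ds)
  with_seed(seed, {
    if (strategy == "undersample") {
      keep_o <- if (length(io) > ratio * length(ii)) {
        sort(sample(io, ratio * length(ii)))
      } else io
      idx <- sort(c(ii, keep_o))
    } else {
      target_i <- ceiling(length(io) / ratio)
      extra <- if (target_i > length(ii)) {
        sample(ii, target_i - length(ii), replace = TRUE)
      } else integer(0)
      idx <- sample(c(ii, extra, io))
    }
    promoter_dataset(w[idx, , drop = FALSE], ds$config,
                     c(ds$source, list(sampling = strategy, ratio = ratio,
                                       sampling_seed = seed)))
  })
}

# stratified order: examples sorted by within-class quantile rank, so any
# contiguous batch preserves class proportions within one example
stratified_order <- function(tags) {
  score <- numeric(length(tags))
  for (cl in unique(tags)) {
    idx <- which(tags == cl)
    score[idx] <- (sample(length(idx)) - 0.5) / length(idx)
  }
  order(score)
}

# stratified index split: fraction per class (at least 1 example when the
# class has >= 2)
stratified_holdout <- function(tags, fraction) {
  unlist(lapply(unique(tags), function(cl) {
    idx <- which(tags == cl)
    n <- max(1L, floor(fraction * length(idx)))
    if (length(idx) < 2L) return(integer(0))
    sample(idx, n)
  }))
}

#' Train a model
#'
#' Minibatch Adam with stratified batches, loss paired to the output head,
#' and early stopping on the validation MCC of a stratified holdout carved
#' from the training data. The best-scoring weights are retained (and
#' written as a checkpoint file when `checkpoint_dir` is set); the run log
#' records per-epoch loss and validation MCC.
#'
#' @param model An untrained `promoter_model` from [build_model()].
#' @param train_ds A [promoter_dataset()] with both classes present.
#' @param config A [training_config()].
#' @return The trained `promoter_model`, carrying `history` (per-epoch data
#'   frame) and `best_epoch`.
#' @export
train <- function(model, train_ds, config = training_config()) {
  stopifnot(inherits(model, "promoter_model"),
            inherits(config, "training_config"))
  w <- train_ds$windows
  if (nrow(w) == 0L) stop("training dataset is empty")
  with_seed(config$seed, {
    val_idx <- stratified_holdout(w$tag, config$validation_fraction)
    val <- w[val_idx, , drop = FALSE]
    tr <- w[setdiff(seq_len(nrow(w)), val_idx), , drop = FALSE]
    if (config$sampling != "normal") {
      tr_ds <- apply_sampling(
        promoter_dataset(tr, train_ds$config, train_ds$source),
        config$sampling, config$sampling_ratio,
        derive_seed(config$seed, 1L))
      tr <- tr_ds$windows
    }
    if (length(unique(tr$tag)) < 2L) {
      stop("both classes must be present in the training data after sampling")
    }
    Xtr <- encode_batch(tr$sequence)
    ytr <- as.numeric(tr$tag == "I")
    Xval <- encode_batch(val$sequence)
    yval <- val$tag
    params <- model$params
    opt <- adam_init(params)
    best_mcc <- -Inf
    best_params <- params
    best_epoch <- 0L
    since_best <- 0L
    hist <- list()
    for (epoch in seq_len(config$max_epochs)) {
      ord <- stratified_order(tr$tag)
      losses <- numeric(0)
      for (bs in seq(1L, length(ord), by = config$batch_size)) {
        bidx <- ord[bs:min(bs + config$batch_size - 1L, length(ord))]
        model$params <- params
        fw <- nn_forward(model, Xtr[bidx, , drop = FALSE], training = TRUE)
        y <- ytr[bidx]
        if (model$spec$output_head == "sigmoid") {
          pr <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
          loss <- -mean(y * log(pr) + (1 - y) * log(1 - pr))
          dZo <- matrix((fw$prob - y) / length(y), ncol = 1L)
        } else {
          pr <- pmax(fw$prob, 1e-12)
          loss <- -mean(log(pr[cbind(seq_along(y), y + 1)]))
          Y <- cbind(1 - y, y)
          dZo <- (fw$prob - Y) / length(y)
        }
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch,
               " (learning rate too high or degenerate input batch)")
        }
        losses <- c(losses, loss)
        grads <- nn_backward(model, fw$cache, dZo)
        st <- adam_step(params, grads, opt, config$learning_rate)
        params <- st$params
        opt <- st$opt
      }
      model$params <- params
      pred <- predict(model, val$sequence)
      mcc <- metrics(confusion(pred$tag, yval))$MCC
      improved <- mcc > best_mcc + 1e-9
      if (improved) {
        best_mcc <- mcc
        best_params <- params
        best_epoch <- epoch
        since_best <- 0L
        if (!is.null(config$checkpoint_dir)) {
          dir.create(config$checkpoint_dir, showWarnings = FALSE,
                     recursive = TRUE)
          model$trained <- TRUE
          save_checkpoint(model, file.path(
            config$checkpoint_dir,
            sprintf("%s_epoch%03d.rds", model$spec$family, epoch)))
        }
      } else {
        since_best <- since_best + 1L
      }
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = mean(losses),
                                  val_mcc = mcc, improved = improved)
      if (since_best >= config$patience) break
    }
    model$params <- best_params
    model$trained <- TRUE
    model$history <- do.call(rbind, hist)
    model$best_epoch <- best_epoch
    model$training_config <- config
    model
  })
}

#' Confusion counts with I as the positive class
#'
#' @param predicted,truth Character vectors of `I`/`O` tags, equal length.
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth have different lengths (", length(predicted),
         " vs ", length(truth), ")")
  }
  stopifnot(all(predicted %in% c("I", "O")), all(truth %in% c("I", "O")))
  structure(list(TP = sum(predicted == "I" & truth == "I"),
                 FP = sum(predicted == "I" & truth == "O"),
                 TN = sum(predicted == "O" & truth == "O"),
                 FN = sum(predicted == "O" & truth == "I")),
            class = "confusion_counts")
}

#' Classification metrics for promoter recognition
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, precision
#' `PPV = TP/(TP+FP)` and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Any metric
#' with a zero denominator is reported as 0 and listed in the `undefined`
#' field rather than propagating NaN.
#'
#' @param c A [confusion()] object (or list with `TP`, `FP`, `TN`, `FN`).
#' @return An object of class `metrics_report` with fields `Sn`, `Sp`,
#'   `PPV`, `MCC` and `undefined` (character vector of flagged metrics).
#' @export
metrics <- function(c) {
  TP <- as.numeric(c$TP); FP <- as.numeric(c$FP)
  TN <- as.numeric(c$TN); FN <- as.numeric(c$FN)
  undef <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undef <<- c(undef, name)
      0
    } else num / den
  }
  Sn <- ratio(TP, TP + FN, "Sn")
  Sp <- ratio(TN, TN + FP, "Sp")
  PPV <- ratio(TP, TP + FP, "PPV")
  den2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  MCC <- if (den2 == 0) {
    undef <- c(undef, "MCC")
    0
  } else {
    (TP * TN - FP * FN) / sqrt(den2)
  }
  structure(list(Sn = Sn, Sp = Sp, PPV = PPV, MCC = MCC, undefined = undef),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Sn=%.4f Sp=%.4f PPV=%.4f MCC=%.4f", x$Sn, x$Sp, x$PPV, x$MCC))
  if (length(x$undefined)) {
    cat("  [undefined: ", paste(x$undefined, collapse = ","), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by tag and seeded from the training config. Each
#' fold's model is built and trained from scratch on the remaining folds and
#' evaluated on the held-out fold. Confidence intervals are Student-t on the
#' fold scores with `k - 1` degrees of freedom at the 99% level (the CI
#' construction is recorded in the report so alternatives can be compared).
#'
#' @param spec An [architecture_spec()].
#' @param dataset A [promoter_dataset()].
#' @param k Number of folds (default 10, minimum 2).
#' @param config A [training_config()].
#' @param level Confidence level (default 0.99).
#' @return An object of class `cv_report`: per-fold metrics, per-metric
#'   means and confidence intervals.
#' @export
kfold_cv <- function(spec, dataset, k = 10L, config = training_config(),
                     level = 0.99) {
  stopifnot(k >= 2L)
  w <- dataset$windows
  counts <- table(w$tag)
  if (length(counts) < 2L || any(counts < k)) {
    stop("stratified ", k, "-fold CV needs at least ", k,
         " examples of each class")
  }
  folds <- integer(nrow(w))
  with_seed(derive_seed(config$seed, 99L), {
    for (cl in names(counts)) {
      idx <- which(w$tag == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  per_fold <- lapply(seq_len(k), function(f) {
    tr <- promoter_dataset(w[folds != f, , drop = FALSE], dataset$config,
                           dataset$source)
    te <- w[folds == f, , drop = FALSE]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, f)
    m <- train(build_model(spec, seed = cfg$seed), tr, cfg)
    pred <- predict(m, te$sequence)
    met <- metrics(confusion(pred$tag, te$tag))
    data.frame(fold = f, Sn = met$Sn, Sp = met$Sp, PPV = met$PPV,
               MCC = met$MCC)
  })
  folds_df <- do.call(rbind, per_fold)
  mets <- c("Sn", "Sp", "PPV", "MCC")
  mean_v <- vapply(mets, function(m) mean(folds_df[[m]]), 0)
  half <- vapply(mets, function(m) {
    s <- stats::sd(folds_df[[m]])
    if (is.na(s)) s <- 0
    stats::qt(1 - (1 - level) / 2, df = k - 1L) * s / sqrt(k)
  }, 0)
  structure(list(folds = folds_df, mean = mean_v,
                 ci = data.frame(metric = mets, lower = mean_v - half,
                                 upper = mean_v + half,
                                 stringsAsFactors = FALSE),
                 k = k, level = level, ci_method = "Student-t",
                 fold_assignment = folds),
            class = "cv_report")
}

#' Cross-test a set of trained models against a set of datasets
#'
#' Evaluates every model on the full contents of every dataset. Cells whose
#' window length does not match the model's input length are marked
#' incompatible rather than silently skipped.
#'
#' @param models Named list of trained `promoter_model`s.
#' @param datasets Named list of [promoter_dataset()]s.
#' @param threshold Sigmoid decision threshold (default 0.5).
#' @return Data frame with one row per (model, dataset) cell: metrics,
#'   evaluation size `n`, and a `compatible` flag.
#' @export
cross_test <- function(models, datasets, threshold = 0.5) {
  rows <- list()
  for (mn in names(models)) {
    for (dn in names(datasets)) {
      ds <- datasets[[dn]]
      L <- unique(nchar(ds$windows$sequence))
      if (length(L) != 1L || L != models[[mn]]$spec$input_length) {
        rows[[length(rows) + 1L]] <- data.frame(
          model = mn, dataset = dn, compatible = FALSE, n = nrow(ds$windows),
          Sn = NA_real_, Sp = NA_real_, PPV = NA_real_, MCC = NA_real_)
        next
      }
      pred <- predict(models[[mn]], ds$windows$sequence,
                      threshold = threshold)
      met <- metrics(confusion(pred$tag, ds$windows$tag))
      rows[[length(rows) + 1L]] <- data.frame(
        model = mn, dataset = dn, compatible = TRUE, n = nrow(ds$windows),
        Sn = met$Sn, Sp = met$Sp, PPV = met$PPV, MCC = met$MCC)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "provenance") <- list(
    models = lapply(models, function(m)
      list(family = m$spec$family, seed = m$seed,
           best_epoch = m$best_epoch)),
    datasets = lapply(datasets, function(d) d$source))
  out
}

#' Write a metrics table as TSV and JSON reports
#'
#' @param report A data frame (e.g. from [cross_test()]).
#' @param path Output path without extension; `.tsv` and `.json` files are
#'   written.
#' @return The two paths, invisibly.
#' @export
write_report <- function(report, path) {
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  utils::write.table(report, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report, js, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(c(tsv, js))
}
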