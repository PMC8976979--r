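test_that("architecture specs validate family constraints", {
  expect_error(architecture_spec("cnnprom_tata", recurrent_units = 8L),
               "recurrent_units")
  expect_error(architecture_spec("cnnprom_tata", conv_filters = 300L),
               "fewer filters")
  expect_error(architecture_spec("cnnprom_tata", pool_size = 4L),
               "fewer filters and a smaller pool")
  expect_error(architecture_spec("cnnprom_nontata", input_length = 20L),
               "input_length")
  expect_error(architecture_spec("cnnprom_nontata", conv_filters = 0L),
               "positive")
  sp <- architecture_spec("dprom")
  expect_equal(sp$recurrent_units, 16L)
  expect_equal(sp$filter_lengths, 15L)  # single embedding bank
  expect_error(build_model(architecture_spec("jaspar_fixed")),
               "motif filters")
  expect_error(build_model(tiny_cnn_spec(),
                           filters = list(structure(list(), class =
                                            "motif_filter"))),
               "jaspar_fixed")
})

test_that("output heads respect their ranges and normalization", {
  seqs <- rand_seqs(16L, 60L, 3L)
  for (head in c("sigmoid", "softmax")) {
    m <- build_model(tiny_cnn_spec(head = head), seed = 4L)
    fw <- prombench:::nn_forward(m, prombench:::encode_batch(seqs))
    if (head == "sigmoid") {
      expect_true(all(fw$prob >= 0 & fw$prob <= 1))
    } else {
      expect_equal(rowSums(fw$prob), rep(1, 16L), tolerance = 1e-6)
      expect_true(all(fw$prob >= 0))
    }
  }
})

test_that("untrained scores are byte-stable under a fixed seed", {
  seqs <- rand_seqs(8L, 60L, 5L)
  s1 <- predict(build_model(tiny_dprom_spec(), seed = 11L), seqs)$score
  s2 <- predict(build_model(tiny_dprom_spec(), seed = 11L), seqs)$score
  expect_identical(s1, s2)
  s3 <- predict(build_model(tiny_dprom_spec(), seed = 12L), seqs)$score
  expect_false(identical(s1, s3))
})

test_that("analytic gradients match finite differences for every family", {
  specs <- list(
    cnn = tiny_cnn_spec(),
    dprom = tiny_dprom_spec(head = "softmax"),
    icnnp = architecture_spec("icnnp", input_length = 60L,
                              conv_filters = 4L, filter_lengths = 5L,
                              pool_size = 2L, hidden_units = 6L,
                              element_profile = element_profile(
                                data.frame(name = "e1", from = -5L,
                                           to = -2L),
                                pool_size = 3L, window = 60L,
                                upstream = 30L)))
  y <- c(1, 0, 1, 0)
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    model <- build_model(spec, seed = 3L)
    X <- prombench:::encode_batch(rand_seqs(4L, 60L, 8L))
    loss_fn <- function(params) {
      model$params <- params
      fw <- prombench:::nn_forward(model, X)
      if (spec$output_head == "sigmoid") {
        pr <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
        -mean(y * log(pr) + (1 - y) * log(1 - pr))
      } else {
        -mean(log(pmax(fw$prob, 1e-12)[cbind(1:4, y + 1)]))
      }
    }
    fw <- prombench:::nn_forward(model, X)
    dZo <- if (spec$output_head == "sigmoid") {
      matrix((fw$prob - y) / 4, ncol = 1L)
    } else {
      (fw$prob - cbind(1 - y, y)) / 4
    }
    grads <- prombench:::nn_backward(model, fw$cache, dZo)
    eps <- 1e-5
    check_leaf <- function(path, p, g) {
      if (is.null(g)) return(invisible())
      if (is.list(p)) {
        for (i in seq_along(p)) check_leaf(c(path, list(i)), p[[i]], g[[i]])
        return(invisible())
      }
      idxs <- unique(round(seq(1L, length(p),
                               length.out = min(4L, length(p)))))
      for (ii in idxs) {
        setv <- function(obj, pth, delta) {
          if (length(pth) == 0L) {
            obj[ii] <- obj[ii] + delta
            return(obj)
          }
          obj[[pth[[1L]]]] <- setv(obj[[pth[[1L]]]], pth[-1L], delta)
          obj
        }
        ng <- (loss_fn(setv(model$params, path, +eps)) -
                 loss_fn(setv(model$params, path, -eps))) / (2 * eps)
        expect_equal(unname(g[ii]), unname(ng), tolerance = 1e-4,
                     info = paste(nm, paste(unlist(path), collapse = "/"),
                                  ii))
      }
    }
    for (top in names(model$params)) {
      check_leaf(list(top), model$params[[top]], grads[[top]])
    }
  }
})

test_that("JASPAR PFM import normalizes counts per column", {
  pure_a <- matrix(0, 4, 3); pure_a[1, ] <- 5
  unif <- matrix(2, 4, 4)
  f <- write_pfm_file(list(PURE_A = pure_a, UNIF = unif))
  filters <- import_jaspar_filters(f)
  expect_equal(filters[[1]]$weights[1, ], rep(1, 3))
  expect_equal(colSums(filters[[1]]$weights), rep(1, 3))
  expect_equal(filters[[2]]$weights, matrix(0.25, 4, 4,
                                            dimnames = list(c("A","C","G","T"), NULL)))
  lo <- import_jaspar_filters(f, mode = "log_odds")
  # uniform counts are exactly zero in log-odds mode
  expect_equal(unname(lo[[2]]$weights), matrix(0, 4, 4))

  shipped <- import_jaspar_filters(
    system.file("extdata", "synthetic_motifs.jaspar",
                package = "prombench"))
  expect_length(shipped, 2L)
  expect_equal(ncol(shipped[[1]]$weights), 6L)
  expect_equal(ncol(shipped[[2]]$weights), 7L)  # width equals PFM width
  expect_equal(colSums(shipped[[2]]$weights), rep(1, 7))

  bad <- tempfile()
  writeLines(c(">B", "A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]", "T [ 1 2 ]"), bad)
  expect_error(import_jaspar_filters(bad), "unequal length")
  writeLines(c(">B", "A [ 1 -2 ]", "C [ 1 2 ]", "G [ 1 2 ]", "T [ 1 2 ]"),
             bad)
  expect_error(import_jaspar_filters(bad), "negative")
})

test_that("frozen JASPAR filters survive training unchanged", {
  filters <- import_jaspar_filters(
    system.file("extdata", "synthetic_motifs.jaspar", package = "prombench"))
  spec <- architecture_spec("jaspar_fixed", input_length = 60L,
                            pool_size = 2L, hidden_units = 8L)
  m <- build_model(spec, seed = 2L, filters = filters)
  before <- m$params$conv
  ds <- tiny_planted_dataset(40L, 40L, 3L)
  tr <- train(m, ds, training_config(max_epochs = 3L, patience = 3L,
                                     seed = 2L))
  expect_identical(tr$params$conv, before)
  expect_false(identical(tr$params$dense, m$params$dense))
})

test_that("prediction applies the inclusive 0.5 boundary and class order", {
  m <- build_model(tiny_cnn_spec(), seed = 1L)
  m$params$out$W[] <- 0
  m$params$out$b[] <- 0   # sigmoid(0) = 0.5 exactly
  pred <- predict(m, rand_seqs(3L, 60L, 1L))
  expect_equal(pred$score, rep(0.5, 3L))
  expect_equal(pred$tag, rep("I", 3L))  # boundary inclusive

  ms <- build_model(tiny_cnn_spec(head = "softmax"), seed = 1L)
  ms$params$out$W[] <- 0
  ms$params$out$b <- log(c(0.4, 0.6))  # softmax -> (0.4, 0.6)
  ps <- predict(ms, rand_seqs(2L, 60L, 2L))
  expect_equal(ps$score, rep(0.6, 2L), tolerance = 1e-12)
  expect_equal(ps$tag, rep("I", 2L))  # promoter is the second class

  expect_error(predict(m, c(rand_seq(60L, 1L), rand_seq(59L, 2L))),
               "sequence 2")
})

test_that("checkpoints round-trip spec, weights and provenance", {
  m <- build_model(tiny_dprom_spec(), seed = 6L)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$spec$family, "dprom")
  expect_identical(predict(m2, rand_seqs(4L, 60L, 9L)),
                   predict(m, rand_seqs(4L, 60L, 9L)))
})
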