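test_that("promoter regions are extrapolated with strand-aware arithmetic", {
  tss <- tss_annotation("chr1", 1000L, "+", "g1")
  iv <- promoter_region_from_tss(tss, region_spec(249L, 50L))
  expect_equal(c(iv$start, iv$end), c(751L, 1051L))
  expect_equal(iv$end - iv$start, 300L)  # 249 + 1 + 50

  ivm <- promoter_region_from_tss(tss_annotation("chr1", 1000L, "-", "g1"),
                                  region_spec(249L, 50L))
  expect_equal(c(ivm$start, ivm$end), c(950L, 1250L))
  expect_equal(ivm$strand, "-")

  iv251 <- promoter_region_from_tss(tss, region_spec(200L, 50L))
  expect_equal(iv251$end - iv251$start, 251L)

  expect_error(
    promoter_region_from_tss(tss_annotation("chr1", 100L, "+", "edge"),
                             region_spec(249L, 50L)),
    "chromosome end.*edge")
  expect_error(
    promoter_region_from_tss(tss, region_spec(249L, 50L),
                             c(chr1 = 1000L)),
    "chromosome end")
})

test_that("window labeling enforces contiguous single-promoter overlap", {
  win <- interval("c", 0L, 300L)
  expect_equal(label_window(win, interval("c", 0L, 300L), 250L), "I")
  # intersection exactly 250 (boundary inclusive) and exactly 249
  expect_equal(label_window(win, interval("c", 50L, 350L), 250L), "I")
  expect_equal(label_window(win, interval("c", 51L, 351L), 250L), "O")
  # two promoters overlapping 150 + 150 disjointly never sum to an I
  two <- interval("c", c(0L, 150L), c(150L, 450L))
  expect_equal(label_window(win, two, 250L), "O")
  # empty promoter set
  empty <- interval("zzz", 1L, 2L)
  expect_equal(label_window(win, empty, 250L), "O")
})

test_that("labeling is monotone in min_overlap", {
  proms <- interval("c", c(100L, 700L), c(400L, 1000L))
  starts <- seq(0L, 700L, by = 50L)
  for (s in starts) {
    tags <- vapply(c(100L, 200L, 250L, 300L), function(mo) {
      label_window(interval("c", s, s + 300L), proms, mo)
    }, "")
    # raising the threshold can only turn I into O, never back
    expect_true(all(diff(tags == "I") <= 0))
  }
})

test_that("benchmark window grid, N-removal and tags match brute force", {
  g300 <- genome_seq("c", rand_seq(300L, 1L))
  ds300 <- build_benchmark(g300, interval("zzz", 1L, 2L))
  expect_equal(nrow(ds300$windows), 1L)

  g1000 <- genome_seq("c", rand_seq(1000L, 2L))
  ds1000 <- build_benchmark(g1000, interval("zzz", 1L, 2L))
  expect_equal(nrow(ds1000$windows), 15L)  # floor(700/50) + 1

  # planted 300-base promoter at offset 600 in a 1500-base genome
  g <- genome_seq("c", rand_seq(1500L, 3L))
  prom <- interval("c", 600L, 900L)
  ds <- build_benchmark(g, prom)
  i_starts <- ds$windows$start[ds$windows$tag == "I"]
  expect_equal(i_starts, c(550L, 600L, 650L))
  # full brute-force recount of every tag
  for (r in seq_len(nrow(ds$windows))) {
    bo <- oracle_best_overlap(ds$windows$start[r], ds$windows$end[r], prom)
    expect_equal(ds$windows$tag[r], if (bo >= 250L) "I" else "O")
  }

  # N windows are dropped when requested, kept otherwise
  bases <- rand_seq(1000L, 4L)
  substr(bases, 500L, 500L) <- "N"
  gn <- genome_seq("c", bases)
  dsn <- build_benchmark(gn, interval("zzz", 1L, 2L))
  expect_true(all(!grepl("N", dsn$windows$sequence)))
  affected <- sum(vapply(seq(0L, 700L, 50L), function(s) {
    s < 500L && s + 300L >= 500L
  }, TRUE))
  expect_equal(nrow(dsn$windows), 15L - affected)
  dsk <- build_benchmark(gn, interval("zzz", 1L, 2L),
                         benchmark_config(drop_n = FALSE))
  expect_equal(nrow(dsk$windows), 15L)

  # deterministic: identical inputs give byte-identical datasets
  expect_identical(build_benchmark(g, prom)$windows, ds$windows)

  # genome shorter than the window warns and yields an empty dataset
  expect_warning(tiny <- build_benchmark(genome_seq("c", "ACGT"),
                                         interval("zzz", 1L, 2L)),
                 "shorter")
  expect_equal(nrow(tiny$windows), 0L)
})

test_that("window-count closed form holds on N-free genomes", {
  for (L in c(300L, 1000L, 2513L)) {
    g <- genome_seq("c", rand_seq(L, L))
    ds <- build_benchmark(g, interval("zzz", 1L, 2L))
    expect_equal(nrow(ds$windows), (L - 300L) %/% 50L + 1L)
  }
})

test_that("deduplication keeps first occurrences and reports conflicts", {
  mk <- function(seqs, tags) promoter_dataset(
    data.frame(sequence = seqs, tag = tags, stringsAsFactors = FALSE))
  s1 <- rand_seq(300L, 1L); s2 <- rand_seq(300L, 2L)
  r <- deduplicate(mk(c(s1, s1, s2), c("I", "I", "O")))
  expect_equal(r$removed, 1L)
  expect_equal(r$dataset$windows$sequence, c(s1, s2))

  r2 <- deduplicate(mk(c(s1, s2), c("I", "O")))
  expect_equal(r2$removed, 0L)
  expect_identical(r2$dataset$windows$sequence, c(s1, s2))

  expect_warning(r3 <- deduplicate(mk(c(s1, s1), c("I", "O"))),
                 "conflict")
  expect_equal(r3$dataset$windows$tag, "I")  # first occurrence kept
  expect_equal(r3$tag_conflicts, 1L)
})

test_that("dataset stats are consistent, with a degenerate-empty flag", {
  ds <- promoter_dataset(data.frame(
    sequence = rand_seqs(10L, 20L, 1L),
    tag = c(rep("I", 2L), rep("O", 8L)), stringsAsFactors = FALSE))
  st <- dataset_stats(ds)
  expect_equal(st$total, 10L)
  expect_equal(st$n_promoter + st$n_nonpromoter, st$total)
  expect_equal(st$promoter_fraction, 0.2)
  empty <- dataset_stats(promoter_dataset(data.frame(
    sequence = character(0), tag = character(0))))
  expect_equal(empty$total, 0L)
  expect_equal(empty$promoter_fraction, 0)
  expect_true(empty$empty)
})

test_that("disjoint splits nest subsets in the master split and catch leaks", {
  seqs <- rand_seqs(140L, 30L, 5L)
  ds <- promoter_dataset(data.frame(
    sequence = seqs, tag = c(rep("I", 100L), rep("O", 40L)),
    stringsAsFactors = FALSE))
  req <- list(
    big = list(promoters = c(80L, 20L), nonpromoters = c(20L, 10L)),
    small = list(promoters = c(50L, 10L), nonpromoters = c(10L, 5L)))
  sp <- disjoint_split(ds, req, seed = 7L)
  big_tr_i <- subset(sp$big$train$windows, tag == "I")$sequence
  big_te_i <- subset(sp$big$test$windows, tag == "I")$sequence
  small_tr_i <- subset(sp$small$train$windows, tag == "I")$sequence
  small_te_i <- subset(sp$small$test$windows, tag == "I")$sequence
  expect_length(small_tr_i, 50L)
  expect_true(all(small_tr_i %in% big_tr_i))  # subset train in master train
  expect_true(all(small_te_i %in% big_te_i))
  expect_length(intersect(
    c(sp$big$train$windows$sequence, sp$small$train$windows$sequence),
    c(sp$big$test$windows$sequence, sp$small$test$windows$sequence)), 0L)

  # identical request reproduces the master split sizes exactly
  sp2 <- disjoint_split(ds, req["big"], seed = 7L)
  expect_equal(nrow(sp2$big$train$windows), 100L)
  expect_equal(nrow(sp2$big$test$windows), 30L)

  expect_error(disjoint_split(ds, list(
    x = list(promoters = c(90L, 20L), nonpromoters = c(10L, 5L))), 1L),
    "infeasible")

  # a deliberately planted leak trips the exhaustive verification
  leaked <- list(m = list(
    train = promoter_dataset(ds$windows[1:10, ]),
    test = promoter_dataset(ds$windows[c(5L, 120L), ])))
  expect_error(prombench:::verify_disjoint(leaked), "leak")
})

test_that("exact-match promoter mapping finds both strands", {
  g <- genome_seq("c", rand_seq(2000L, 11L))
  p_fwd <- substr(g$bases, 101L, 400L)
  hits <- map_promoters_by_exact_match(g, p_fwd)
  expect_true(any(hits$start == 100L & hits$end == 400L &
                    hits$strand == "+"))
  p_rev <- reverse_complement(p_fwd)
  hits_rev <- map_promoters_by_exact_match(g, p_rev)
  expect_true(any(hits_rev$start == 100L & hits_rev$end == 400L &
                    hits_rev$strand == "-"))
  none <- map_promoters_by_exact_match(g, strrep("ACGT", 80L))
  expect_equal(nrow(none), 0L)
})

test_that("dataset files round-trip with their construction recipe", {
  g <- genome_seq("c", rand_seq(1200L, 21L))
  ds <- build_benchmark(g, interval("c", 300L, 600L))
  f <- tempfile(fileext = ".tsv")
  write_dataset(ds, f)
  back <- read_dataset(f)
  expect_identical(back$windows$sequence, ds$windows$sequence)
  expect_identical(back$windows$tag, ds$windows$tag)
  expect_equal(back$config$window, 300L)
  expect_equal(back$config$min_overlap, 250L)
  # FASTA export carries the tag in the description
  ff <- tempfile(fileext = ".fa")
  write_dataset_fasta(ds, ff)
  lines <- readLines(ff)
  expect_equal(sum(startsWith(lines, ">")), nrow(ds$windows))
  expect_true(any(grepl(" I$", lines[startsWith(lines, ">")])))
})
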