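test_that("ppm filter reproduces the 750-read threshold at study scale", {
  counts <- as_count_table(data.frame(
    transcript_id = c("kept", "removed"),
    length_bp = c(500L, 500L),
    g = c(300L, 300L), f = c(250L, 249L), m = c(200L, 200L),
    stringsAsFactors = FALSE))
  out <- filter_by_ppm(counts, threshold_ppm = 5, grand_total = 1.5e8)
  info <- attr(out, "ppm_filter")
  expect_equal(info$absolute_threshold, 750)
  expect_identical(out$transcript_id, "kept")  # sum 749 removed, 750 kept
})

test_that("ppm filter arithmetic matches hand-derived toy thresholds", {
  counts <- as_count_table(data.frame(
    transcript_id = paste0("t", 1:4), length_bp = rep(100L, 4),
    a = c(5L, 50L, 500L, 5000L), b = c(5L, 50L, 500L, 5000L),
    stringsAsFactors = FALSE))  # sums 10, 100, 1000, 10000; grand 11110
  expect_equal(nrow(filter_by_ppm(counts, 0)), 4)  # identity at zero
  k100 <- filter_by_ppm(counts, 100)
  expect_equal(attr(k100, "ppm_filter")$absolute_threshold, 1.111)
  expect_equal(nrow(k100), 4)
  k1e4 <- filter_by_ppm(counts, 10000)
  expect_equal(attr(k1e4, "ppm_filter")$absolute_threshold, 111.1)
  expect_identical(k1e4$transcript_id, c("t3", "t4"))
  expect_error(filter_by_ppm(counts, 5, grand_total = 0), "positive")
})

test_that("raising the ppm threshold never adds transcripts", {
  set.seed(21)
  counts <- random_counts(200)
  kept <- lapply(c(0, 10, 100, 1000, 5000, 20000),
                 function(th) filter_by_ppm(counts, th)$transcript_id)
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
})

test_that("log2 ratios follow hand arithmetic under both zero policies", {
  expr <- data.frame(transcript_id = c("eq", "eight", "zero"),
                     g = c(3, 8, 0), f = c(3, 1, 4),
                     stringsAsFactors = FALSE)
  class(expr) <- c("expression_table", "data.frame")
  r <- log2_ratio(expr, "g", "f", floor_value = 0.25)
  expect_equal(as.numeric(r), c(0, 3, -4))  # log2(0.25/4) = -4
  expect_equal(attr(r, "pair"), c("g", "f"))

  dropped <- log2_ratio(expr, "g", "f", zero_policy = "drop")
  expect_named(dropped, c("eq", "eight"), ignore.order = TRUE)
  expect_equal(attr(dropped, "dropped"), "zero")
  expect_error(log2_ratio(expr, "g", "f", floor_value = 0), "positive")
  expect_error(log2_ratio(expr, "g", "brain"), "not present")
})

test_that("log2 ratio is antisymmetric under the floor policy", {
  set.seed(31)
  counts <- random_counts(100)
  counts$gill[1:5] <- 0L
  expr <- compute_fpkm(counts)
  ab <- log2_ratio(expr, "gill", "foot", floor_value = 0.01)
  ba <- log2_ratio(expr, "foot", "gill", floor_value = 0.01)
  expect_equal(as.numeric(ab), -as.numeric(ba))
})

test_that("ratio stats use the population SD and symmetric 2-SD cutoffs", {
  s <- ratio_stats(c(-2, 0, 2), pair = c("a", "b"))
  expect_equal(s$mean, 0)
  expect_equal(s$sd, sqrt(8 / 3), tolerance = 1e-12)  # 1.632993...
  expect_equal(s$upper_cutoff, 2 * sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(s$lower_cutoff, -2 * sqrt(8 / 3), tolerance = 1e-12)

  const <- ratio_stats(c(1.3, 1.3, 1.3))
  expect_equal(const$sd, 0)
  expect_equal(const$upper_cutoff, 1.3)
  expect_equal(const$lower_cutoff, 1.3)
  expect_error(ratio_stats(c(1)), "at least 2")

  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(sample(5:50, 1), mean = runif(1, -2, 2))
    st <- ratio_stats(x)
    expect_equal(st$upper_cutoff + st$lower_cutoff, 2 * st$mean)
  }
})

test_that("DE labels use strict inequality at the cutoffs", {
  stats <- pairwise_stats(mean = 0.05, sd = 5.09 / 2,
                          pair = c("gill", "foot"))
  ratios <- c(high = 6, at_mean = 0.05, at_upper = 5.14, at_lower = -5.04,
              low = -5.05)
  called <- call_de_pair(ratios, stats)
  expect_equal(unname(called$labels),
               c("gill", "not_DE", "not_DE", "not_DE", "foot"))
  expect_equal(unname(called$label_counts), c(1, 1, 3))
})

test_that("tissue dominance requires a high call in both relevant pairs", {
  gf <- fake_called_pair(c("gill", "foot"), c(x = "gill", y = "not_DE"))
  gm <- fake_called_pair(c("gill", "mantle"), c(x = "gill", y = "not_DE"))
  fm <- fake_called_pair(c("foot", "mantle"), c(x = "not_DE", y = "not_DE"))
  dom <- call_tissue_dominance(list(gf, gm, fm))
  expect_equal(dom$dominant_tissue[dom$transcript_id == "x"], "gill")
  expect_true(is.na(dom$dominant_tissue[dom$transcript_id == "y"]))

  expect_error(call_tissue_dominance(list(gf, gm)), "three")
  bad <- fake_called_pair(c("gill", "brain"), c(x = "not_DE"))
  expect_error(call_tissue_dominance(list(gf, gm, bad)), "triangle")
  expect_error(call_tissue_dominance(list(gf, gf, gm)), "triangle")
})

test_that("the pipeline wires filter, FPKM, calls and dominance together", {
  set.seed(51)
  cfg <- simulation_config(n_transcripts = 500, library_sizes = 1e5,
                           n_terms = 5, seed = 99)
  ds <- simulate_dataset(cfg)
  pipe <- run_dominance_pipeline(ds$counts)
  expect_named(pipe, c("expr", "filtered", "pairs", "dominance"))
  expect_length(pipe$pairs, 3)
  # library sizes come from the unfiltered table
  expect_equal(unname(library_sizes(pipe$expr)),
               unname(colSums(as.matrix(ds$counts[, cfg$tissues]))))
  # report writer emits one row per transcript in the dominance table
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_de_report(pipe, tsv, jsn)
  rep <- utils::read.delim(tsv)
  expect_equal(nrow(rep), nrow(pipe$dominance))
  summ <- jsonlite::read_json(jsn)
  expect_length(summ, 3)
  expect_equal(summ[[1]]$two_sd, 2 * pipe$pairs[[1]]$sd)
})
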