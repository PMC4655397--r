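test_that("dominant-fraction selection ranks by total expression", {
  set.seed(61)
  n <- 100
  expr <- data.frame(transcript_id = sprintf("t%03d", 1:n),
                     g = runif(n, 0, 50), f = runif(n, 0, 50),
                     m = runif(n, 0, 50), stringsAsFactors = FALSE)
  class(expr) <- c("expression_table", "data.frame")
  top5 <- select_dominant_fraction(expr, 0.05)
  expect_length(top5, 5)
  totals <- expr$g + expr$f + expr$m
  expect_setequal(top5,
                  expr$transcript_id[order(-totals)][1:5])  # sort oracle
  expect_setequal(select_dominant_fraction(expr, 1), expr$transcript_id)
  expect_error(select_dominant_fraction(expr, 0), "fraction")
  expect_error(select_dominant_fraction(expr, 1.2), "fraction")
})

test_that("boundary ties go to the lexicographically smaller id", {
  expr <- data.frame(transcript_id = c("b_tied", "a_tied", "top"),
                     g = c(5, 5, 9), stringsAsFactors = FALSE)
  class(expr) <- c("expression_table", "data.frame")
  # ceiling(0.5 * 3) = 2: "top" then one of the tied pair
  expect_identical(select_dominant_fraction(expr, 0.5),
                   c("top", "a_tied"))
})

test_that("upper-tail hypergeometric matches draw enumeration", {
  expect_identical(hypergeom_upper_tail(0, 5, 4, 10), 1)  # exact 1 at k=0
  # N=10, K=5, n=4, k=4: 5/210 by enumerating all 210 draws
  expect_equal(hypergeom_upper_tail(4, 5, 4, 10),
               enumerate_hyper_tail(4, 5, 4, 10), tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(4, 5, 4, 10), 5 / 210,
               tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(5, 8, 6, 20),
               enumerate_hyper_tail(5, 8, 6, 20), tolerance = 1e-12)
  expect_error(hypergeom_upper_tail(5, 4, 6, 20), "k <= min")
  expect_error(hypergeom_upper_tail(1, 4, 21, 20), "n <= N")
  expect_error(hypergeom_upper_tail(-1, 4, 6, 20), "nonnegative")
})

test_that("the upper tail is non-increasing in k", {
  for (case in list(c(K = 5, n = 4, N = 12), c(K = 8, n = 6, N = 20),
                    c(K = 3, n = 9, N = 15))) {
    ks <- 0:min(case["n"], case["K"])
    p <- hypergeom_upper_tail(ks, case["K"], case["n"], case["N"])
    expect_true(all(diff(p) <= 1e-15))
    expect_true(all(p > 0 & p <= 1))
  }
})

test_that("rich factor is the literal k over K", {
  expect_equal(rich_factor(12, 12), 1)
  expect_equal(rich_factor(3, 12), 0.25)
  expect_equal(rich_factor(0, 7), 0)
  expect_error(rich_factor(1, 0), "K must be")
  expect_error(rich_factor(5, 4), "k <= K")
})

test_that("enrichment rows carry exact single-term probabilities", {
  universe <- sprintf("u%03d", 1:100)
  lst <- universe[1:10]
  terms <- as_term_map(rbind(
    data.frame(transcript_id = lst, term_id = "planted",
               stringsAsFactors = FALSE),
    data.frame(transcript_id = universe, term_id = "everything",
               stringsAsFactors = FALSE),
    data.frame(transcript_id = universe[11:20], term_id = "absent",
               stringsAsFactors = FALSE)))
  res <- enrich_terms(lst, terms, universe = universe, p_threshold = 0.001)
  planted <- res[res$term_id == "planted", ]
  expect_equal(planted$k, 10)
  expect_equal(planted$K, 10)
  expect_equal(planted$n, 10)
  expect_equal(planted$N, 100)
  expect_equal(planted$p, 1 / choose(100, 10), tolerance = 1e-12)
  expect_true(planted$enriched)
  expect_equal(planted$rich_factor, 1)
  # k = 0 terms emit no row; rows sorted by p
  expect_false("absent" %in% res$term_id)
  expect_equal(res$term_id, res$term_id[order(res$p, res$term_id)])
  # BH column is supplementary and never gates the flag
  expect_true(all(res$enriched == (res$p <= 0.001)))
  expect_error(enrich_terms(c(lst, "other"), terms, universe = universe),
               "other")
})

test_that("the annotated universe defines n and N", {
  universe <- sprintf("u%02d", 1:20)
  terms <- as_term_map(data.frame(
    transcript_id = universe[1:8], term_id = "t1",
    stringsAsFactors = FALSE))
  # list of 5, only 3 annotated; universe of 20, only 8 annotated
  res <- enrich_terms(universe[c(1:3, 15:16)], terms, universe = universe)
  expect_equal(res$n, 3)
  expect_equal(res$N, 8)
  expect_equal(res$k, 3)
  expect_equal(res$K, 8)
  expect_equal(res$p, 1)
})

test_that("null lists are not systematically called enriched", {
  set.seed(71)
  universe <- sprintf("u%04d", 1:400)
  rows <- do.call(rbind, lapply(1:40, function(j) {
    data.frame(transcript_id = sample(universe, 30),
               term_id = sprintf("term%02d", j), stringsAsFactors = FALSE)
  }))
  terms <- as_term_map(rows)
  alpha <- 0.05
  hits <- 0; tested <- 0
  for (i in 1:30) {
    res <- enrich_terms(sample(universe, 40), terms, universe = universe,
                        p_threshold = alpha)
    tested <- tested + nrow(res)
    hits <- hits + sum(res$enriched)
  }
  # discrete tails are conservative; allow Monte-Carlo slack above alpha
  expect_lt(hits / tested, alpha + 3 * sqrt(alpha * (1 - alpha) / tested))
})

test_that("term maps read from two-column TSV and GMT agree", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tterm_id", "a\tT1", "b\tT1", "c\tT2"), tsv)
  tm <- read_term_map(tsv, namespace = "demo")
  expect_s3_class(tm, "term_map")
  expect_equal(attr(tm, "namespace"), "demo")
  expect_equal(nrow(tm), 3)

  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tfirst set\ta\tb", "T2\tsecond set\tc"), gmt)
  gm <- read_gmt(gmt)
  expect_equal(sort(gm$transcript_id[gm$term_id == "T1"]), c("a", "b"))
  expect_equal(attr(gm, "labels")[["T2"]], "second set")
  gm_sorted <- gm[order(gm$term_id, gm$transcript_id), ]
  tm_sorted <- tm[order(tm$term_id, tm$transcript_id), ]
  expect_equal(gm_sorted$transcript_id, tm_sorted$transcript_id)
  expect_equal(gm_sorted$term_id, tm_sorted$term_id)
  writeLines("T3\tno members", gmt)
  expect_error(read_gmt(gmt), ">=1 member")
})
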