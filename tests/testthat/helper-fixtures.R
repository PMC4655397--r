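# Shared fixtures and independent oracles.

toy_counts <- function() {
  as_count_table(data.frame(
    transcript_id = c("t1", "t2", "t3", "t4"),
    length_bp = c(1000L, 500L, 2000L, 750L),
    gill = c(100L, 0L, 40L, 8L),
    foot = c(50L, 20L, 40L, 0L),
    mantle = c(25L, 10L, 400L, 4L),
    stringsAsFactors = FALSE))
}

random_counts <- function(n, tissues = c("gill", "foot", "mantle")) {
  df <- data.frame(transcript_id = sprintf("r%04d", seq_len(n)),
                   length_bp = sample(200:2000, n, replace = TRUE),
                   stringsAsFactors = FALSE)
  for (t in tissues) df[[t]] <- rpois(n, 50)
  as_count_table(df)
}

# upper-tail hypergeometric by literal enumeration of all C(N, n) draws
enumerate_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K items carry the term
  mean(hits >= k)
}

# upper-tail hypergeometric as an exact combinatorial sum
hyper_sum_oracle <- function(k, K, n, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# N50 by explicit descending prefix sums
n50_oracle <- function(lengths) {
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(s)
  for (i in seq_along(s)) if (cs[i] >= sum(s) / 2) return(s[i])
}

# Cys-Xaa-Cys count by an explicit sliding window
cxc_oracle <- function(residues) {
  ch <- strsplit(residues, "")[[1]]
  n <- length(ch)
  if (n < 3) return(0L)
  sum(ch[1:(n - 2)] == "C" & ch[3:n] == "C")
}

# tissue dominance by direct restatement of the rule
dominance_oracle <- function(labels_by_pair, pairs, tissues) {
  for (x in tissues) {
    idx <- which(vapply(pairs, function(p) x %in% p, TRUE))
    if (all(vapply(idx, function(i) labels_by_pair[[i]] == x, TRUE))) {
      return(x)
    }
  }
  NA_character_
}

# fabricate a labeled pairwise_stats for dominance tests
fake_called_pair <- function(pair, labels) {
  s <- pairwise_stats(mean = 0, sd = 1, pair = pair, n = length(labels))
  s$labels <- labels
  s
}
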