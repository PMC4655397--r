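# Replicate-free differential expression: ppm abundance filter, pairwise
# log2 ratios, empirical mean +/- 2 SD cutoffs, and tissue-dominance calls.
#
# With one pooled library per tissue there is no within-group variance to
# model, so a transcript is called differentially expressed in a pairwise
# comparison when its log2 expression ratio lies more than two standard
# deviations from the comparison-wide mean ratio.

#' Filter transcripts by parts-per-million abundance
#'
#' Retains transcript i iff its summed count over all tissues is at least
#' `threshold_ppm * 1e-6 * grand_total`. At the study scale of three
#' libraries totalling 1.5e8 mapped reads, 5 ppm corresponds to an absolute
#' threshold of 750 reads; the absolute threshold is kept as a real number
#' and never rounded.
#'
#' @param counts A `count_table`.
#' @param threshold_ppm Abundance threshold in parts per million of the
#'   grand total (default 5). Zero keeps everything.
#' @param grand_total Total mapped reads across all tissues; defaults to the
#'   sum of all counts in the table. An override is useful when the table has
#'   already been subset.
#' @return The filtered `count_table`, with a `ppm_filter` attribute
#'   recording the threshold arithmetic and the number of transcripts
#'   removed.
#' @export
filter_by_ppm <- function(counts, threshold_ppm = 5, grand_total = NULL) {
  counts <- as_count_table(counts)
  if (!is.numeric(threshold_ppm) || length(threshold_ppm) != 1 ||
      !is.finite(threshold_ppm) || threshold_ppm < 0) {
    stop("threshold_ppm must be a single nonnegative number")
  }
  m <- count_matrix(counts)
  if (is.null(grand_total)) grand_total <- sum(m)
  if (!is.numeric(grand_total) || length(grand_total) != 1 ||
      !is.finite(grand_total) || grand_total <= 0) {
    stop("grand_total must be a single positive number")
  }
  absolute_threshold <- threshold_ppm * 1e-6 * grand_total
  keep <- rowSums(m) >= absolute_threshold
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ppm_filter") <- list(threshold_ppm = threshold_ppm,
                                  grand_total = grand_total,
                                  absolute_threshold = absolute_threshold,
                                  n_kept = sum(keep),
                                  n_removed = sum(!keep))
  out
}

#' Pairwise log2 expression ratios
#'
#' Computes log2(FPKM_A / FPKM_B) per transcript. Zeros make the ratio
#' undefined; two policies are offered. Under `"floor"` (default) zero FPKM
#' values are replaced by `floor_value` before taking the ratio — by default
#' half the smallest nonzero FPKM observed in the two tissues. Under
#' `"drop"` transcripts with a zero in either tissue are omitted and their
#' ids recorded in the `dropped` attribute.
#'
#' @param expr An `expression_table`.
#' @param tissue_a,tissue_b Tissue column names; the ratio is A over B.
#' @param zero_policy `"floor"` or `"drop"`.
#' @param floor_value Positive replacement for zero FPKM under the floor
#'   policy; default half the smallest nonzero FPKM in the pair.
#' @return Named numeric vector of log2 ratios with attribute `pair`
#'   (`c(tissue_a, tissue_b)`), and `dropped` under the drop policy.
#' @export
log2_ratio <- function(expr, tissue_a, tissue_b,
                       zero_policy = c("floor", "drop"), floor_value = NULL) {
  zero_policy <- match.arg(zero_policy)
  tissues <- tissue_names(expr)
  for (t in c(tissue_a, tissue_b)) {
    if (!t %in% tissues) stop("tissue '", t, "' not present in table")
  }
  a <- expr[[tissue_a]]
  b <- expr[[tissue_b]]
  ids <- expr$transcript_id
  if (zero_policy == "floor") {
    if (is.null(floor_value)) {
      nz <- c(a[a > 0], b[b > 0])
      if (length(nz) == 0) stop("all FPKM values are zero; cannot derive a floor")
      floor_value <- min(nz) / 2
    }
    if (!is.numeric(floor_value) || length(floor_value) != 1 ||
        !is.finite(floor_value) || floor_value <= 0) {
      stop("floor_value must be a single positive number")
    }
    a <- ifelse(a == 0, floor_value, a)
    b <- ifelse(b == 0, floor_value, b)
    ratios <- stats::setNames(log2(a / b), ids)
    dropped <- character(0)
  } else {
    keep <- a > 0 & b > 0
    ratios <- stats::setNames(log2(a[keep] / b[keep]), ids[keep])
    dropped <- ids[!keep]
  }
  attr(ratios, "pair") <- c(tissue_a, tissue_b)
  attr(ratios, "dropped") <- dropped
  ratios
}

#' Pairwise comparison statistics from mean and SD
#'
#' Low-level constructor: given the mean and standard deviation of a
#' log2-ratio distribution, derives the differential-expression cutoffs
#' `mean + 2*sd` (high in the first tissue) and `mean - 2*sd` (high in the
#' second). [ratio_stats()] builds this from a ratio vector.
#'
#' @param mean Mean log2 ratio.
#' @param sd Standard deviation of the log2 ratios (must be >= 0).
#' @param pair Optional character vector `c(tissue_a, tissue_b)`.
#' @param n Optional number of ratios summarised.
#' @return A `pairwise_stats` object: list with `pair`, `mean`, `sd`,
#'   `upper_cutoff`, `lower_cutoff`, `n`.
#' @export
pairwise_stats <- function(mean, sd, pair = NULL, n = NA_integer_) {
  if (!is.numeric(mean) || length(mean) != 1 || !is.finite(mean)) {
    stop("mean must be a single finite number")
  }
  if (!is.numeric(sd) || length(sd) != 1 || !is.finite(sd) || sd < 0) {
    stop("sd must be a single nonnegative number")
  }
  structure(list(pair = pair, mean = mean, sd = sd,
                 upper_cutoff = mean + 2 * sd,
                 lower_cutoff = mean - 2 * sd,
                 n = n),
            class = "pairwise_stats")
}

#' Empirical log2-ratio statistics for one tissue pair
#'
#' Computes the mean and population standard deviation (divide by n) of the
#' finite log2 ratios and the 2-SD differential-expression cutoffs. With
#' thousands of retained transcripts the population/sample distinction is
#' numerically irrelevant; the population form is used because it is
#' deterministic in its definition.
#'
#' @param ratios Named log2-ratio vector from [log2_ratio()].
#' @param pair Tissue pair; defaults to the `pair` attribute of `ratios`.
#' @return A `pairwise_stats` object.
#' @export
ratio_stats <- function(ratios, pair = attr(ratios, "pair")) {
  r <- ratios[is.finite(ratios)]
  if (length(r) < 2) stop("need at least 2 finite ratios")
  m <- mean(r)
  s <- sqrt(mean((r - m)^2))
  pairwise_stats(mean = m, sd = s, pair = pair, n = length(r))
}

#' @export
print.pairwise_stats <- function(x, ...) {
  pair <- if (is.null(x$pair)) "A vs B" else paste(x$pair, collapse = " vs ")
  cat(sprintf("Pairwise log2-ratio stats (%s): n=%s mean=%.4g sd=%.4g\n",
              pair, format(x$n), x$mean, x$sd))
  cat(sprintf("  cutoffs: high in %s > %.4g; high in %s < %.4g\n",
              if (is.null(x$pair)) "A" else x$pair[1], x$upper_cutoff,
              if (is.null(x$pair)) "B" else x$pair[2], x$lower_cutoff))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(names(x$label_counts), x$label_counts,
                           sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Call differential expression for one tissue pair
#'
#' Labels each transcript by strict comparison of its log2 ratio to the
#' 2-SD cutoffs: strictly above the upper cutoff is high in the first
#' tissue, strictly below the lower cutoff high in the second, anything
#' else (including ties at a cutoff) not differentially expressed.
#'
#' @param ratios Named log2-ratio vector the stats were computed from.
#' @param stats A `pairwise_stats` with a non-null `pair`.
#' @return `stats` augmented with `labels` (named character vector taking
#'   a tissue name or `"not_DE"`) and `label_counts`.
#' @export
call_de_pair <- function(ratios, stats) {
  if (!inherits(stats, "pairwise_stats")) stop("stats must be pairwise_stats")
  if (is.null(stats$pair) || length(stats$pair) != 2) {
    stop("stats must carry the tissue pair to label against")
  }
  r <- ratios[is.finite(ratios)]
  labels <- rep("not_DE", length(r))
  labels[r > stats$upper_cutoff] <- stats$pair[1]
  labels[r < stats$lower_cutoff] <- stats$pair[2]
  stats$ratio_values <- r
  stats$labels <- stats::setNames(labels, names(r))
  stats$label_counts <- c(
    stats::setNames(sum(labels == stats$pair[1]), stats$pair[1]),
    stats::setNames(sum(labels == stats$pair[2]), stats$pair[2]),
    not_DE = sum(labels == "not_DE"))
  stats
}

#' Classify tissue-dominant transcripts from three pairwise comparisons
#'
#' A transcript is dominant in tissue X iff it is labeled high-in-X in both
#' pairwise comparisons that involve X (e.g. gill-dominant means high in
#' gill in both gill-vs-mantle and gill-vs-foot). The label semantics make
#' more than one dominant tissue per transcript impossible.
#'
#' @param pair_results List of three labeled `pairwise_stats` (from
#'   [call_de_pair()]) whose pairs form a triangle over exactly three
#'   tissues.
#' @return data.frame with `transcript_id` and `dominant_tissue`
#'   (tissue name, or `NA` when no tissue dominates).
#' @export
call_tissue_dominance <- function(pair_results) {
  if (length(pair_results) != 3) stop("need exactly three pairwise results")
  pairs <- lapply(pair_results, function(s) {
    if (!inherits(s, "pairwise_stats") || is.null(s$labels)) {
      stop("each element must be a labeled pairwise_stats")
    }
    s$pair
  })
  tissues <- sort(unique(unlist(pairs)))
  if (length(tissues) != 3 ||
      anyDuplicated(vapply(pairs, function(p) paste(sort(p), collapse = "|"),
                           ""))) {
    stop("the three pairs must form a triangle over exactly three tissues")
  }
  ids <- sort(unique(unlist(lapply(pair_results, function(s) names(s$labels)))))
  label_of <- function(s, ids) {
    out <- s$labels[ids]
    out[is.na(out)] <- "not_DE"
    out
  }
  lab <- vapply(pair_results, label_of, character(length(ids)), ids = ids)
  if (length(ids) == 1) lab <- matrix(lab, nrow = 1)
  dominant <- rep(NA_character_, length(ids))
  for (x in tissues) {
    involves <- vapply(pairs, function(p) x %in% p, TRUE)
    hit <- rowSums(lab[, involves, drop = FALSE] == x) == 2
    dominant[hit] <- x
  }
  data.frame(transcript_id = ids, dominant_tissue = dominant,
             stringsAsFactors = FALSE)
}

#' Run the replicate-free tissue-dominance pipeline
#'
#' Convenience wrapper over the whole comparison: ppm filter (library sizes
#' taken from the unfiltered table so totals reflect all mapped reads),
#' FPKM, all three pairwise log2-ratio comparisons with 2-SD calls, and
#' tissue-dominance classification. Requires exactly three tissues.
#'
#' @param counts A `count_table` with three tissue columns.
#' @param threshold_ppm Abundance filter threshold in ppm (default 5).
#' @param zero_policy,floor_value Passed to [log2_ratio()].
#' @return List with `expr` (filtered expression table), `filtered` counts,
#'   `pairs` (named list of labeled `pairwise_stats`), and `dominance`.
#' @export
run_dominance_pipeline <- function(counts, threshold_ppm = 5,
                                   zero_policy = "floor", floor_value = NULL) {
  counts <- as_count_table(counts)
  tissues <- tissue_names(counts)
  if (length(tissues) != 3) stop("pipeline requires exactly three tissues")
  lib <- colSums(count_matrix(counts))
  filtered <- filter_by_ppm(counts, threshold_ppm = threshold_ppm)
  expr <- compute_fpkm(filtered, library_sizes = lib)
  combos <- utils::combn(tissues, 2, simplify = FALSE)
  pairs <- lapply(combos, function(p) {
    r <- log2_ratio(expr, p[1], p[2], zero_policy = zero_policy,
                    floor_value = floor_value)
    call_de_pair(r, ratio_stats(r))
  })
  names(pairs) <- vapply(combos, paste, "", collapse = "_vs_")
  list(expr = expr, filtered = filtered, pairs = pairs,
       dominance = call_tissue_dominance(pairs))
}

#' Write the differential-expression report
#'
#' Emits a per-transcript TSV (log2 ratio and label per pair, dominance
#' call) and, optionally, a JSON summary with each pair's mean, SD, cutoffs
#' and label counts.
#'
#' @param pipeline Result of [run_dominance_pipeline()] (or a list with
#'   `pairs` and `dominance`).
#' @param path Output TSV path.
#' @param json_path Optional JSON summary path.
#' @return `path`, invisibly.
#' @export
write_de_report <- function(pipeline, path, json_path = NULL) {
  dom <- pipeline$dominance
  out <- data.frame(transcript_id = dom$transcript_id,
                    stringsAsFactors = FALSE)
  for (nm in names(pipeline$pairs)) {
    s <- pipeline$pairs[[nm]]
    ids <- out$transcript_id
    out[[paste0("log2_", nm)]] <- unname(s$ratio_values[ids])
    out[[paste0("label_", nm)]] <- unname(s$labels[ids])
  }
  out$dominant_tissue <- dom$dominant_tissue
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!is.null(json_path)) {
    summ <- lapply(pipeline$pairs, function(s) {
      list(pair = s$pair, n = s$n, mean = s$mean, sd = s$sd,
           two_sd = 2 * s$sd, upper_cutoff = s$upper_cutoff,
           lower_cutoff = s$lower_cutoff,
           label_counts = as.list(s$label_counts))
    })
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
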