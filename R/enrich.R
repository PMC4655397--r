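# Term over-representation: dominant-list selection, upper-tail cumulative
# hypergeometric tests and rich factors.

#' Validate and classify a term-annotation map
#'
#' A term map is long-format: one row per (transcript_id, term_id) pair.
#' Terms with no members cannot be represented and duplicated pairs are
#' collapsed.
#'
#' @param df data.frame with columns `transcript_id` and `term_id`.
#' @param namespace Optional namespace tag (e.g. "KEGG-pathway", "GOBP").
#' @param labels Optional named character vector of term labels.
#' @return The validated data.frame with class `term_map` and attributes
#'   `namespace` and `labels`.
#' @export
as_term_map <- function(df, namespace = NA_character_, labels = NULL) {
  if (!is.data.frame(df) ||
      !all(c("transcript_id", "term_id") %in% names(df))) {
    stop("term map needs columns transcript_id and term_id")
  }
  df <- df[c("transcript_id", "term_id")]
  df$transcript_id <- as.character(df$transcript_id)
  df$term_id <- as.character(df$term_id)
  df <- unique(df)
  if (nrow(df) == 0) stop("term map is empty")
  rownames(df) <- NULL
  attr(df, "namespace") <- namespace
  attr(df, "labels") <- labels
  class(df) <- unique(c("term_map", class(df)))
  df
}

#' Read a two-column transcript/term TSV
#'
#' @param path Headered TSV with columns `transcript_id`, `term_id`; `#`
#'   comment lines ignored.
#' @param label_path Optional headered TSV with columns `term_id`, `label`.
#' @param namespace Optional namespace tag.
#' @return A `term_map`.
#' @export
read_term_map <- function(path, label_path = NULL,
                          namespace = NA_character_) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  labels <- NULL
  if (!is.null(label_path)) {
    lab <- utils::read.delim(label_path, comment.char = "#",
                             check.names = FALSE, stringsAsFactors = FALSE)
    labels <- stats::setNames(as.character(lab$label),
                              as.character(lab$term_id))
  }
  as_term_map(df, namespace = namespace, labels = labels)
}

#' Read a GMT gene-set file as a term map
#'
#' Standard GMT layout: one term per line, tab-separated
#' `term<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path Path to the GMT file.
#' @param namespace Optional namespace tag.
#' @return A `term_map` with descriptions kept as labels.
#' @export
read_gmt <- function(path, namespace = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 3
  if (any(bad)) stop("GMT lines must have term, description and >=1 member")
  term_ids <- vapply(parts, `[`, "", 1)
  labels <- stats::setNames(vapply(parts, `[`, "", 2), term_ids)
  df <- do.call(rbind, lapply(parts, function(p) {
    data.frame(transcript_id = p[-(1:2)], term_id = p[1],
               stringsAsFactors = FALSE)
  }))
  as_term_map(df, namespace = namespace, labels = labels)
}

#' Select the top fraction of transcripts by total expression
#'
#' Ranks transcripts by summed FPKM over all tissues (descending) and
#' returns the top `ceiling(fraction * N)`. Ties are broken by transcript
#' id ascending so the selection is deterministic.
#'
#' @param expr An `expression_table`.
#' @param fraction Fraction of transcripts to keep, in (0, 1]; default 0.05,
#'   i.e. the top 5% "dominant" transcripts.
#' @return Character vector of selected transcript ids, highest total first.
#' @export
select_dominant_fraction <- function(expr, fraction = 0.05) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      !is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  totals <- total_expression(expr)
  if (length(totals) == 0) stop("expression table is empty")
  ord <- order(-totals, names(totals))
  n_keep <- ceiling(fraction * length(totals))
  names(totals)[ord][seq_len(n_keep)]
}

#' Upper-tail cumulative hypergeometric probability
#'
#' P(X >= k) when drawing `n` transcripts without replacement from a
#' universe of `N` of which `K` carry the term:
#' sum over i = k..min(n, K) of C(K,i) C(N-K, n-i) / C(N, n).
#' `k = 0` returns exactly 1. Arguments are vectorized.
#'
#' @param k Observed annotated transcripts in the list.
#' @param K Universe transcripts carrying the term.
#' @param n List size.
#' @param N Universe size.
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  args <- cbind(k = k, K = K, n = n, N = N)
  k <- args[, "k"]; K <- args[, "K"]; n <- args[, "n"]; N <- args[, "N"]
  if (any(args < 0) || any(args != round(args))) {
    stop("k, K, n, N must be nonnegative integers")
  }
  if (any(K > N) || any(n > N) || any(k > pmin(n, K))) {
    stop("require k <= min(n, K), K <= N, n <= N")
  }
  unname(stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE))
}

#' Rich factor of an enriched term
#'
#' The number of transcripts carrying the term inside the list divided by
#' the total number of universe transcripts carrying the term (k / K). The
#' closer to 1, the higher the fold-enrichment.
#'
#' @param k In-list transcripts with the term.
#' @param K Universe transcripts with the term (>= 1).
#' @return k / K, in [0, 1]. Vectorized.
#' @export
rich_factor <- function(k, K) {
  if (any(K < 1)) stop("K must be >= 1")
  if (any(k < 0) || any(k > K)) stop("require 0 <= k <= K")
  k / K
}

#' Term over-representation test for a transcript list
#'
#' For each term with at least one member in the list, computes the k/K/n/N
#' contingency against the annotated universe, the upper-tail cumulative
#' hypergeometric P value and the rich factor. Only annotated transcripts
#' count: term members are intersected with `universe` first, `n` is the
#' number of list members with at least one term and `N` the number of
#' universe transcripts with at least one term. P values are thresholded
#' raw (no multiple-testing gate); a Benjamini-Hochberg column is provided
#' as supplementary output only.
#'
#' @param list Character vector of transcript ids (must be within
#'   `universe`).
#' @param terms A `term_map`.
#' @param universe Character vector of universe transcript ids; default all
#'   transcripts in `terms`.
#' @param p_threshold Raw P-value threshold for the `enriched` flag
#'   (0.001 for KEGG-style analyses, 0.0001 for GO Biological Process).
#' @return data.frame (class `enrichment_result`) with columns `term_id`,
#'   `label`, `k`, `n`, `K`, `N`, `p`, `bh_q`, `rich_factor`, `enriched`,
#'   sorted by `p` then `term_id`.
#' @export
enrich_terms <- function(list, terms, universe = NULL, p_threshold = 0.001) {
  if (!inherits(terms, "term_map")) terms <- as_term_map(terms)
  if (is.null(universe)) universe <- unique(terms$transcript_id)
  universe <- unique(as.character(universe))
  list <- unique(as.character(list))
  outside <- setdiff(list, universe)
  if (length(outside) > 0) {
    stop("list transcripts outside the universe: ",
         paste(utils::head(outside, 10), collapse = ", "),
         if (length(outside) > 10) ", ..." else "")
  }
  terms <- terms[terms$transcript_id %in% universe, , drop = FALSE]
  annotated <- unique(terms$transcript_id)
  N <- length(annotated)
  n <- length(intersect(list, annotated))
  if (N == 0) stop("no annotated transcripts in the universe")
  K_all <- table(terms$term_id)
  in_list <- terms[terms$transcript_id %in% list, , drop = FALSE]
  k_all <- table(in_list$term_id)
  term_ids <- names(k_all)
  if (length(term_ids) == 0) {
    res <- data.frame(term_id = character(0), label = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), bh_q = numeric(0),
                      rich_factor = numeric(0), enriched = logical(0),
                      stringsAsFactors = FALSE)
    class(res) <- unique(c("enrichment_result", class(res)))
    return(res)
  }
  k <- as.integer(k_all[term_ids])
  K <- as.integer(K_all[term_ids])
  p <- hypergeom_upper_tail(k, K, n, N)
  labels <- attr(terms, "labels")
  res <- data.frame(
    term_id = term_ids,
    label = if (is.null(labels)) NA_character_ else
      unname(labels[term_ids]),
    k = k, n = n, K = K, N = N, p = p,
    bh_q = stats::p.adjust(p, method = "BH"),
    rich_factor = rich_factor(k, K),
    enriched = p <= p_threshold,
    stringsAsFactors = FALSE)
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "p_threshold") <- p_threshold
  attr(res, "namespace") <- attr(terms, "namespace")
  class(res) <- unique(c("enrichment_result", class(res)))
  res
}

#' Write an enrichment report to TSV
#'
#' @param result An `enrichment_result` from [enrich_terms()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
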