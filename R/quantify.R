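# Count tables and FPKM quantification.
#
# A count table is a plain data.frame with columns `transcript_id`,
# `length_bp`, then one nonnegative integer read-count column per tissue.
# The tissue set is whatever columns remain after the two fixed ones.

RESERVED_COLUMNS <- c("transcript_id", "length_bp")

#' Tissue columns of a count or expression table
#'
#' @param x A `count_table` or `expression_table` (any data.frame with the
#'   standard `transcript_id` leading column).
#' @return Character vector of tissue column names.
#' @export
tissue_names <- function(x) {
  setdiff(names(x), RESERVED_COLUMNS)
}

#' Validate and classify a transcript-level count table
#'
#' Checks the count-table contract: unique transcript ids, integer lengths
#' of at least 1 bp, and nonnegative integral counts in every tissue column.
#'
#' @param df A data.frame with columns `transcript_id`, `length_bp`, and one
#'   count column per tissue.
#' @return The validated data.frame with class `count_table`.
#' @export
as_count_table <- function(df) {
  if (!is.data.frame(df)) stop("count table must be a data.frame")
  missing <- setdiff(RESERVED_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("count table is missing column(s): ", paste(missing, collapse = ", "))
  }
  tissues <- tissue_names(df)
  if (length(tissues) == 0) stop("count table has no tissue columns")
  if (anyDuplicated(df$transcript_id)) {
    stop("transcript ids must be unique")
  }
  df$transcript_id <- as.character(df$transcript_id)
  len <- df$length_bp
  if (!is.numeric(len) || any(!is.finite(len)) || any(len < 1) ||
      any(len != round(len))) {
    stop("length_bp must be integers >= 1")
  }
  for (t in tissues) {
    v <- df[[t]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) ||
        any(v != round(v))) {
      stop("counts for tissue '", t, "' must be nonnegative integers")
    }
  }
  class(df) <- unique(c("count_table", class(df)))
  df
}

#' Read a count table from TSV
#'
#' Expects a headered tab-separated file with columns `transcript_id`,
#' `length_bp`, then one column per tissue. Lines starting with `#` are
#' ignored.
#'
#' @param path Path to the TSV file.
#' @return A `count_table`.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  as_count_table(df)
}

#' Write a count table to TSV
#'
#' @param x A `count_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  x <- as_count_table(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

count_matrix <- function(counts) {
  m <- as.matrix(counts[, tissue_names(counts), drop = FALSE])
  rownames(m) <- counts$transcript_id
  storage.mode(m) <- "double"
  m
}

#' Convert read counts to FPKM
#'
#' FPKM(i, t) = C(i, t) * 1e9 / (L(i) * T(t)) where C is the mapped-read
#' count of transcript i in tissue t, L its length in bases and T the
#' library size (total mapped reads) of tissue t. Each mapped read is
#' treated as one fragment. When `library_sizes` is omitted the per-tissue
#' column sums of `counts` are used; an override is accepted because
#' sequencing totals commonly include reads mapping to transcripts absent
#' from a filtered table.
#'
#' @param counts A `count_table`.
#' @param library_sizes Optional named vector of positive totals, one per
#'   tissue of `counts`.
#' @return An `expression_table`: data.frame of `transcript_id` plus one
#'   FPKM column per tissue, with the library sizes kept in the
#'   `library_sizes` attribute.
#' @export
compute_fpkm <- function(counts, library_sizes = NULL) {
  counts <- as_count_table(counts)
  tissues <- tissue_names(counts)
  m <- count_matrix(counts)
  if (is.null(library_sizes)) {
    library_sizes <- colSums(m)
  } else {
    if (is.null(names(library_sizes))) {
      stop("library_sizes must be named by tissue")
    }
    unknown <- setdiff(names(library_sizes), tissues)
    if (length(unknown) > 0) {
      stop("library_sizes names unknown tissue(s): ",
           paste(unknown, collapse = ", "))
    }
    missing <- setdiff(tissues, names(library_sizes))
    if (length(missing) > 0) {
      stop("library_sizes missing tissue(s): ",
           paste(missing, collapse = ", "))
    }
    library_sizes <- library_sizes[tissues]
  }
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0)) {
    stop("every library size must be a positive finite number")
  }
  fpkm <- m * 1e9 / (counts$length_bp %o% as.numeric(library_sizes))
  out <- data.frame(transcript_id = counts$transcript_id, fpkm,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "library_sizes") <- stats::setNames(as.numeric(library_sizes),
                                                tissues)
  class(out) <- unique(c("expression_table", class(out)))
  out
}

#' Library sizes of an expression table
#'
#' @param expr An `expression_table`.
#' @return Named numeric vector of per-tissue total mapped reads.
#' @export
library_sizes <- function(expr) {
  attr(expr, "library_sizes")
}

fpkm_matrix <- function(expr) {
  m <- as.matrix(expr[, tissue_names(expr), drop = FALSE])
  rownames(m) <- expr$transcript_id
  m
}

#' Total expression per transcript
#'
#' Sums FPKM across all tissues, the ranking statistic used to pick
#' "dominant" transcripts.
#'
#' @param expr An `expression_table`.
#' @return Named numeric vector (by transcript id) of summed FPKM.
#' @export
total_expression <- function(expr) {
  m <- fpkm_matrix(expr)
  stats::setNames(rowSums(m), expr$transcript_id)
}

#' Write an expression table to TSV
#'
#' The library sizes travel in a `#library_sizes` comment line so the file
#' round-trips through [read_expression_table()].
#'
#' @param expr An `expression_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  ls <- library_sizes(expr)
  header <- paste0("#library_sizes\t",
                   paste(names(ls), ls, sep = "=", collapse = "\t"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(expr, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression table written by [write_expression_table()]
#'
#' @param path Path to the TSV file.
#' @return An `expression_table`.
#' @export
read_expression_table <- function(path) {
  lines <- readLines(path)
  ls_line <- grep("^#library_sizes\t", lines, value = TRUE)
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          check.names = FALSE, stringsAsFactors = FALSE)
  df$transcript_id <- as.character(df$transcript_id)
  if (length(ls_line) == 1) {
    kv <- strsplit(strsplit(ls_line, "\t")[[1]][-1], "=", fixed = TRUE)
    ls <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                          vapply(kv, `[`, "", 1))
    attr(df, "library_sizes") <- ls
  }
  class(df) <- unique(c("expression_table", class(df)))
  df
}
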