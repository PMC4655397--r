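# Relative quantification of qPCR Ct tables by the 2^-ddCt method and
# concordance with sequencing-based log2 ratios.

CT_COLUMNS <- c("gene_id", "role", "tissue", "biological_replicate",
                "technical_replicate", "ct")

#' Validate and classify a qPCR Ct table
#'
#' One row per well: target or reference gene, tissue, biological and
#' technical replicate, threshold cycle. Exactly one reference
#' (housekeeping) gene is allowed per experiment.
#'
#' @param df data.frame with columns `gene_id`, `role` (`target` or
#'   `reference`), `tissue`, `biological_replicate`,
#'   `technical_replicate`, `ct` (cycles, > 0).
#' @return The validated data.frame with class `ct_table`.
#' @export
as_ct_table <- function(df) {
  if (!is.data.frame(df)) stop("Ct table must be a data.frame")
  missing <- setdiff(CT_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("Ct table missing column(s): ", paste(missing, collapse = ", "))
  }
  df$gene_id <- as.character(df$gene_id)
  df$role <- as.character(df$role)
  df$tissue <- as.character(df$tissue)
  if (!all(df$role %in% c("target", "reference"))) {
    stop("role must be 'target' or 'reference'")
  }
  if (!is.numeric(df$ct) || any(!is.finite(df$ct)) || any(df$ct <= 0)) {
    stop("ct must be positive finite cycles")
  }
  refs <- unique(df$gene_id[df$role == "reference"])
  if (length(refs) != 1) {
    stop("exactly one reference gene required, found ", length(refs))
  }
  class(df) <- unique(c("ct_table", class(df)))
  df
}

#' Read a Ct table from TSV
#'
#' @param path Headered TSV with the [as_ct_table()] columns.
#' @return A `ct_table`.
#' @export
read_ct_table <- function(path) {
  as_ct_table(utils::read.delim(path, comment.char = "#",
                                check.names = FALSE,
                                stringsAsFactors = FALSE))
}

reference_gene <- function(ct) {
  unique(ct$gene_id[ct$role == "reference"])
}

# mean Ct over technical replicates for one gene/tissue, by biological rep
mean_ct_by_biorep <- function(ct, gene, tissue) {
  sub <- ct[ct$gene_id == gene & ct$tissue == tissue, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  tapply(sub$ct, sub$biological_replicate, mean)
}

#' Relative expression between two tissues by the 2^-ddCt method
#'
#' Per biological replicate: dCt in each tissue is the technical-replicate
#' mean Ct of the target minus that of the reference gene; ddCt is
#' dCt(tissue_a) - dCt(tissue_b); the replicate fold change is 2^-ddCt.
#' Replicates are combined by geometric mean, i.e. the log2 fold change is
#' the arithmetic mean of -ddCt. Amplification efficiency is fixed at 2.
#'
#' @param ct A `ct_table`.
#' @param target Target gene id.
#' @param tissue_a,tissue_b Tissues compared; the fold change is A over B.
#' @return List (class `ddct_result`) with `target`, `pair`,
#'   `fold_change`, `log2_fold_change` and `per_replicate` (data.frame of
#'   biological replicate, ddCt and fold change).
#' @export
ddct_fold_change <- function(ct, target, tissue_a, tissue_b) {
  ct <- as_ct_table(ct)
  ref <- reference_gene(ct)
  if (!target %in% ct$gene_id[ct$role == "target"]) {
    stop("target '", target, "' not present in Ct table")
  }
  dct <- function(tissue) {
    tgt <- mean_ct_by_biorep(ct, target, tissue)
    rf <- mean_ct_by_biorep(ct, ref, tissue)
    if (is.null(tgt)) {
      stop("target '", target, "' not measured in tissue '", tissue, "'")
    }
    unmatched <- setdiff(names(tgt), names(rf))
    if (is.null(rf) || length(unmatched) > 0) {
      stop("no reference measurement for tissue '", tissue,
           "', biological replicate(s): ",
           paste(unmatched, collapse = ", "))
    }
    tgt - rf[names(tgt)]
  }
  dct_a <- dct(tissue_a)
  dct_b <- dct(tissue_b)
  shared <- intersect(names(dct_a), names(dct_b))
  if (length(shared) == 0) {
    stop("no shared biological replicates between tissues")
  }
  ddct <- dct_a[shared] - dct_b[shared]
  log2_fc <- mean(-ddct)
  structure(list(
    target = target,
    pair = c(tissue_a, tissue_b),
    fold_change = 2^log2_fc,
    log2_fold_change = log2_fc,
    per_replicate = data.frame(biological_replicate = shared,
                               ddct = unname(ddct),
                               fold_change = unname(2^(-ddct)),
                               stringsAsFactors = FALSE)),
    class = "ddct_result")
}

#' qPCR log2 fold changes for every target gene
#'
#' Applies [ddct_fold_change()] to each target in the table.
#'
#' @param ct A `ct_table`.
#' @param tissue_a,tissue_b Tissues compared.
#' @return Named numeric vector of log2 fold changes (A over B) by target.
#' @export
qpcr_log2_ratios <- function(ct, tissue_a, tissue_b) {
  ct <- as_ct_table(ct)
  targets <- sort(unique(ct$gene_id[ct$role == "target"]))
  vapply(stats::setNames(targets, targets), function(g) {
    ddct_fold_change(ct, g, tissue_a, tissue_b)$log2_fold_change
  }, 0)
}

#' Concordance between qPCR and sequencing log2 ratios
#'
#' Pearson correlation (and its square) over the transcripts shared by the
#' two named vectors, mirroring the scatterplot comparison used to validate
#' replicate-free sequencing calls with qRT-PCR.
#'
#' @param qpcr_log2 Named vector of qPCR log2 fold changes.
#' @param seq_log2 Named vector of sequencing log2 ratios.
#' @param pair Optional label for the tissue pair.
#' @return List (class `concordance_result`) with `pair`, `n`,
#'   `pearson_r`, `r_squared` and `shared` (data.frame of the paired
#'   values, for audit and plotting).
#' @export
log2_concordance <- function(qpcr_log2, seq_log2, pair = NULL) {
  shared <- intersect(names(qpcr_log2), names(seq_log2))
  if (length(shared) < 3) {
    stop("need at least 3 shared transcripts, found ", length(shared))
  }
  x <- as.numeric(qpcr_log2[shared])
  y <- as.numeric(seq_log2[shared])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in one of the vectors")
  }
  r <- stats::cor(x, y)
  structure(list(pair = pair, n = length(shared), pearson_r = r,
                 r_squared = r^2,
                 shared = data.frame(transcript_id = shared, qpcr_log2 = x,
                                     seq_log2 = y,
                                     stringsAsFactors = FALSE)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  pair <- if (is.null(x$pair)) "" else paste0(" (", paste(x$pair, collapse = " vs "), ")")
  cat(sprintf("qPCR/sequencing concordance%s: n=%d r=%.4f R^2=%.4f\n",
              pair, x$n, x$pearson_r, x$r_squared))
  invisible(x)
}

#' Write concordance scatter data to TSV
#'
#' @param result A `concordance_result`.
#' @param path Output path for the (x, y) pairs.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(result, path) {
  utils::write.table(result$shared, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
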