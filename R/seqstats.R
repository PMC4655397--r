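# Transcriptome assembly summary statistics and cysteine-motif scanning.

#' Assembly summary statistics
#'
#' Computes the usual assembly report: sequence count, total bases, mean,
#' min, max and N50. N50 is the length of the sequence at which the
#' cumulative sum of lengths sorted in descending order first reaches half
#' the total (weighted-median convention).
#'
#' @param lengths Vector of positive integer sequence lengths.
#' @return List (class `assembly_stats`) with `n_sequences`, `total_bp`,
#'   `mean_length`, `n50`, `min_length`, `max_length`.
#' @export
assembly_stats <- function(lengths) {
  if (length(lengths) == 0) stop("lengths must be nonempty")
  if (!is.numeric(lengths) || any(!is.finite(lengths)) || any(lengths < 1) ||
      any(lengths != round(lengths))) {
    stop("lengths must be positive integers")
  }
  sorted <- sort(as.numeric(lengths), decreasing = TRUE)
  total <- sum(sorted)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1]]
  structure(list(n_sequences = length(lengths),
                 total_bp = total,
                 mean_length = total / length(lengths),
                 n50 = n50,
                 min_length = min(sorted),
                 max_length = max(sorted)),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  rows <- c("Total number of sequences" = format(x$n_sequences),
            "Total bases (bp)" = format(x$total_bp),
            "Mean length (bp)" = sprintf("%.1f", x$mean_length),
            "N50 (bp)" = format(x$n50),
            "Length range (bp)" = sprintf("%d-%d", x$min_length,
                                          x$max_length))
  w <- max(nchar(names(rows)))
  for (i in seq_along(rows)) {
    cat(sprintf("%-*s  %s\n", w, names(rows)[i], rows[i]))
  }
  invisible(x)
}

#' Write assembly statistics as JSON
#'
#' @param stats An `assembly_stats`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly_stats <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Sequence lengths of a FASTA file
#'
#' Reads both wrapped-line and single-line FASTA dialects.
#'
#' @param path Path to a (nucleotide or protein) FASTA file.
#' @return Named integer vector of sequence lengths.
#' @export
fasta_lengths <- function(path) {
  Biostrings::fasta.seqlengths(path)
}

#' Assembly statistics straight from a FASTA file
#'
#' @param path Path to the transcript FASTA.
#' @return An `assembly_stats`.
#' @export
assembly_stats_fasta <- function(path) {
  assembly_stats(fasta_lengths(path))
}

PROTEIN_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and checked against the 20-letter amino-acid
#' alphabet plus X; gap characters (or anything else) are rejected.
#'
#' @param path Path to a protein FASTA file.
#' @return Named character vector of residue strings.
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  for (i in seq_along(seqs)) {
    validate_protein(seqs[i], names(seqs)[i])
  }
  seqs
}

validate_protein <- function(residues, id = "<protein>") {
  if (!is.character(residues) || length(residues) != 1 ||
      is.na(residues) || nchar(residues) == 0) {
    stop("protein '", id, "' must be a nonempty residue string")
  }
  letters <- unique(strsplit(residues, "", fixed = TRUE)[[1]])
  bad <- setdiff(letters, PROTEIN_ALPHABET)
  if (length(bad) > 0) {
    stop("protein '", id, "' contains invalid residue(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(residues)
}

#' Count Cys-Xaa-Cys motifs in a protein
#'
#' Counts positions i with residue i and residue i+2 both cysteine; the
#' middle residue may be anything, including another cysteine, and
#' overlapping windows all count (so "CACAC" has 2 and "CCC" has 1). The
#' motif is the hallmark of metal-binding metallothionein-like proteins.
#'
#' @param residues Character vector of uppercase residue strings.
#' @return Integer vector of motif counts, one per input protein.
#' @export
count_cxc_motifs <- function(residues) {
  vapply(residues, function(s) {
    validate_protein(s)
    hits <- gregexpr("C(?=.C)", s, perl = TRUE)[[1]]
    if (hits[1] == -1L) 0L else length(hits)
  }, 0L, USE.NAMES = !is.null(names(residues)))
}
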