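# Synthetic three-tissue datasets with known tissue-dominant ground truth.
#
# The generator emulates the study design the pipeline targets: three
# tissue libraries sequenced without replication, negative-binomial
# transcript counts whose means scale with baseline expression, transcript
# length and library size, a minority of transcripts spiked with a large
# log2 effect in exactly one tissue, term annotations with an enriched term
# planted inside each spiked set, and qPCR Ct tables consistent with the
# simulated expression ratios plus measurement noise.

#' Simulation configuration
#'
#' Defaults echo the study scale: three tissues (gill, foot, mantle) at
#' 5e7 mapped reads each, log-normal transcript lengths with median 673 bp,
#' a 1% spike fraction per tissue at a log2 effect of 8, negative-binomial
#' dispersion 0.1, and a 10-transcripts-per-dominant-list qPCR design with
#' 3 biological x 2 technical replicates and 0.2-cycle Ct noise.
#'
#' @param n_transcripts Number of transcripts.
#' @param tissues Three tissue names.
#' @param library_sizes Per-tissue total mapped reads (scalar recycled).
#' @param length_meanlog,length_sdlog Log-normal transcript-length
#'   parameters (meanlog defaults to log(673)).
#' @param min_length Minimum transcript length in bp.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline mean-FPKM
#'   parameters.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param spike_fraction Fraction of transcripts spiked per tissue; spiked
#'   sets are disjoint across tissues.
#' @param spike_log2_effect log2 fold effect applied to a spiked transcript
#'   in its tissue only.
#' @param n_terms Number of background annotation terms.
#' @param term_size_meanlog,term_size_sdlog Log-normal term-size
#'   parameters (sizes clamped to [5, min(500, n_transcripts)]).
#' @param n_qpcr_per_list Spiked transcripts per tissue carried into the
#'   simulated qPCR assay.
#' @param n_bio_reps,n_tech_reps qPCR biological / technical replicates.
#' @param reference_ct Reference-gene Ct in cycles.
#' @param target_ct_offset Constant such that a target's expected Ct is
#'   `reference_ct + target_ct_offset - log2(FPKM)`; only ratios matter
#'   downstream.
#' @param ct_noise_sd Gaussian Ct measurement noise, in cycles.
#' @param seed Mandatory RNG seed; the same config and seed regenerate a
#'   bit-identical dataset.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_transcripts = 10000,
                              tissues = c("gill", "foot", "mantle"),
                              library_sizes = 5e7,
                              length_meanlog = log(673),
                              length_sdlog = 0.8,
                              min_length = 200,
                              baseline_meanlog = log(10),
                              baseline_sdlog = 1.5,
                              dispersion = 0.1,
                              spike_fraction = 0.01,
                              spike_log2_effect = 8,
                              n_terms = 100,
                              term_size_meanlog = log(30),
                              term_size_sdlog = 0.8,
                              n_qpcr_per_list = 10,
                              n_bio_reps = 3,
                              n_tech_reps = 2,
                              reference_ct = 15,
                              target_ct_offset = 30,
                              ct_noise_sd = 0.2,
                              seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 ||
      !is.finite(seed)) {
    stop("a numeric seed is mandatory for reproducibility")
  }
  if (length(tissues) != 3 || anyDuplicated(tissues)) {
    stop("exactly three distinct tissues required")
  }
  if (length(library_sizes) == 1) {
    library_sizes <- rep(library_sizes, 3)
  }
  if (length(library_sizes) != 3 || any(library_sizes < 1)) {
    stop("library_sizes must give one positive total per tissue")
  }
  library_sizes <- stats::setNames(as.numeric(library_sizes), tissues)
  if (n_transcripts < 1) stop("n_transcripts must be >= 1")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (spike_fraction < 0 || spike_fraction > 1) {
    stop("spike_fraction must be in [0, 1]")
  }
  if (3 * floor(spike_fraction * n_transcripts) > n_transcripts) {
    stop("spiked sets exceed the transcript count")
  }
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0")
  structure(list(n_transcripts = as.integer(n_transcripts),
                 tissues = tissues, library_sizes = library_sizes,
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 min_length = as.integer(min_length),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion,
                 spike_fraction = spike_fraction,
                 spike_log2_effect = spike_log2_effect,
                 n_terms = as.integer(n_terms),
                 term_size_meanlog = term_size_meanlog,
                 term_size_sdlog = term_size_sdlog,
                 n_qpcr_per_list = as.integer(n_qpcr_per_list),
                 n_bio_reps = as.integer(n_bio_reps),
                 n_tech_reps = as.integer(n_tech_reps),
                 reference_ct = reference_ct,
                 target_ct_offset = target_ct_offset,
                 ct_noise_sd = ct_noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a three-tissue dataset with planted tissue-dominant structure
#'
#' Counts are drawn per transcript and tissue from a negative-binomial
#' model with mean proportional to baseline FPKM x length x library size;
#' the per-tissue means are rescaled so each library's expected total
#' equals its configured size. Spiked transcripts have their mean
#' multiplied by `2^spike_log2_effect` in their tissue only. Background
#' terms annotate random transcripts; one planted term per spiked set
#' concentrates its members there. Ct values follow
#' `reference_ct + target_ct_offset - log2(true FPKM)` plus Gaussian
#' noise for a per-tissue sample of spiked transcripts.
#'
#' @param config A `simulation_config`.
#' @return List (class `synthetic_dataset`) with `counts` (a
#'   `count_table`), `terms` (a `term_map`), `ct` (a `ct_table`), `truth`
#'   (spiked sets, true effects, planted terms, and the full transcript id
#'   universe) and `config`.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must come from simulation_config()")
  }
  set.seed(config$seed)
  n <- config$n_transcripts
  tissues <- config$tissues
  ids <- sprintf("T%06d", seq_len(n))

  len <- pmax(config$min_length,
              round(stats::rlnorm(n, config$length_meanlog,
                                  config$length_sdlog)))
  base_fpkm <- stats::rlnorm(n, config$baseline_meanlog,
                             config$baseline_sdlog)

  # disjoint spiked sets, one per tissue
  n_spike <- floor(config$spike_fraction * n)
  pool <- ids
  spiked <- list()
  for (t in tissues) {
    s <- if (n_spike > 0) sort(sample(pool, n_spike)) else character(0)
    spiked[[t]] <- s
    pool <- setdiff(pool, s)
  }

  effect <- matrix(0, nrow = n, ncol = 3,
                   dimnames = list(ids, tissues))
  for (t in tissues) {
    effect[spiked[[t]], t] <- config$spike_log2_effect
  }

  # expected counts: proportional to baseline FPKM x length x library
  # size, with the scaling calibrated on the baseline mass so that a
  # spike multiplies its transcript's mean by exactly 2^effect
  mu0 <- base_fpkm * len
  mu <- 2^effect * ((mu0 / sum(mu0)) %o% as.numeric(config$library_sizes))
  counts_mat <- matrix(
    stats::rnbinom(n * 3, size = 1 / config$dispersion, mu = mu),
    nrow = n, dimnames = list(ids, tissues))
  counts <- as_count_table(data.frame(transcript_id = ids,
                                      length_bp = as.integer(len),
                                      counts_mat, check.names = FALSE,
                                      stringsAsFactors = FALSE))

  # true (noise-free) FPKM per tissue, used for Ct generation
  true_fpkm <- mu * 1e9 / (len %o% as.numeric(config$library_sizes))

  # background terms over random transcripts, one planted term per spiked set
  sizes <- pmin(pmax(round(stats::rlnorm(config$n_terms,
                                         config$term_size_meanlog,
                                         config$term_size_sdlog)), 5),
                min(500, n))
  term_rows <- vector("list", config$n_terms + 3)
  for (j in seq_len(config$n_terms)) {
    term_rows[[j]] <- data.frame(
      transcript_id = sample(ids, sizes[j]),
      term_id = sprintf("TERM%04d", j), stringsAsFactors = FALSE)
  }
  planted <- stats::setNames(rep(NA_character_, 3), tissues)
  for (i in seq_along(tissues)) {
    t <- tissues[i]
    if (length(spiked[[t]]) == 0) next
    tid <- sprintf("TERM_PLANTED_%s", t)
    planted[t] <- tid
    core <- sample(spiked[[t]], ceiling(0.8 * length(spiked[[t]])))
    background <- sample(setdiff(ids, spiked[[t]]),
                         min(5, n - length(spiked[[t]])))
    term_rows[[config$n_terms + i]] <- data.frame(
      transcript_id = c(core, background), term_id = tid,
      stringsAsFactors = FALSE)
  }
  terms <- as_term_map(do.call(rbind, term_rows), namespace = "synthetic")

  # qPCR design: a sample of spiked transcripts per tissue-dominant list
  qpcr_targets <- unlist(lapply(tissues, function(t) {
    if (length(spiked[[t]]) == 0) return(character(0))
    sort(sample(spiked[[t]], min(config$n_qpcr_per_list,
                                 length(spiked[[t]]))))
  }), use.names = FALSE)
  ct_rows <- list(data.frame(
    gene_id = "REF18S", role = "reference",
    tissue = rep(tissues, each = config$n_bio_reps * config$n_tech_reps),
    biological_replicate = rep(rep(seq_len(config$n_bio_reps),
                                   each = config$n_tech_reps), 3),
    technical_replicate = rep(seq_len(config$n_tech_reps),
                              3 * config$n_bio_reps),
    ct = config$reference_ct +
      stats::rnorm(3 * config$n_bio_reps * config$n_tech_reps,
                   sd = config$ct_noise_sd),
    stringsAsFactors = FALSE))
  for (g in qpcr_targets) {
    for (t in tissues) {
      expected_ct <- config$reference_ct + config$target_ct_offset -
        log2(true_fpkm[g, t])
      ct_rows[[length(ct_rows) + 1]] <- data.frame(
        gene_id = g, role = "target", tissue = t,
        biological_replicate = rep(seq_len(config$n_bio_reps),
                                   each = config$n_tech_reps),
        technical_replicate = rep(seq_len(config$n_tech_reps),
                                  config$n_bio_reps),
        ct = expected_ct +
          stats::rnorm(config$n_bio_reps * config$n_tech_reps,
                       sd = config$ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  ct <- as_ct_table(do.call(rbind, ct_rows))

  truth <- list(
    transcript_ids = ids,
    spiked = spiked,
    effects = lapply(stats::setNames(tissues, tissues), function(t) {
      stats::setNames(rep(config$spike_log2_effect,
                          length(spiked[[t]])), spiked[[t]])
    }),
    planted_terms = planted)

  structure(list(counts = counts, terms = terms, ct = ct, truth = truth,
                 config = config),
            class = "synthetic_dataset")
}

#' Score recovery of the planted truth
#'
#' Compares tissue-dominance calls (and optionally per-tissue enrichment
#' results) against the spiked sets and planted terms of a synthetic
#' dataset.
#'
#' @param truth The `truth` element of a `synthetic_dataset`.
#' @param dominance data.frame from [call_tissue_dominance()] run on the
#'   dataset carrying this truth.
#' @param enrichment Optional named list (by tissue) of
#'   `enrichment_result` data.frames for the tissue-dominant lists.
#' @return List (class `recovery_report`) with `per_tissue` (sensitivity
#'   and precision per tissue; precision is `NA` when nothing was called)
#'   and, when enrichment is supplied, `planted` with the planted term's P
#'   value and detection flags at thresholds 0.001 and 0.0001.
#' @export
evaluate_recovery <- function(truth, dominance, enrichment = NULL) {
  unknown <- setdiff(dominance$transcript_id, truth$transcript_ids)
  if (length(unknown) > 0) {
    stop("dominance calls reference transcripts outside the dataset: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  tissues <- names(truth$spiked)
  per_tissue <- do.call(rbind, lapply(tissues, function(t) {
    called <- dominance$transcript_id[!is.na(dominance$dominant_tissue) &
                                        dominance$dominant_tissue == t]
    spiked <- truth$spiked[[t]]
    tp <- length(intersect(called, spiked))
    data.frame(tissue = t, n_spiked = length(spiked),
               n_called = length(called), true_positives = tp,
               sensitivity = if (length(spiked) == 0) NA_real_ else
                 tp / length(spiked),
               precision = if (length(called) == 0) NA_real_ else
                 tp / length(called),
               stringsAsFactors = FALSE)
  }))
  out <- list(per_tissue = per_tissue)
  if (!is.null(enrichment)) {
    out$planted <- do.call(rbind, lapply(tissues, function(t) {
      tid <- truth$planted_terms[[t]]
      if (is.na(tid) || !t %in% names(enrichment)) return(NULL)
      e <- enrichment[[t]]
      p <- if (tid %in% e$term_id) e$p[e$term_id == tid] else NA_real_
      data.frame(tissue = t, term_id = tid, p = p,
                 detected_0.001 = !is.na(p) && p <= 0.001,
                 detected_0.0001 = !is.na(p) && p <= 0.0001,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(out, class = "recovery_report")
}

#' Write a synthetic dataset to a directory
#'
#' Writes `counts.tsv`, `terms.tsv`, `ct.tsv` and `truth.json` (the truth
#' carries a config echo). Regenerating with the same config and seed and
#' rewriting yields bit-identical files.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_table(dataset$counts, file.path(dir, "counts.tsv"))
  utils::write.table(as.data.frame(dataset$terms),
                     file.path(dir, "terms.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(dataset$ct), file.path(dir, "ct.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(truth = dataset$truth, config = unclass(dataset$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
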