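#' Run the msGBS quantification pipeline end to end
#'
#' Executes, in order: (1) demultiplexing and pair merging/joining,
#' (2) UMI deduplication, (3) dereplication of monoclonal reads
#' (`min_unique_size`), per-strain greedy clustering (`cluster_identity`),
#' the contaminant hook, and meta-reference assembly, (4) multi-mapping of
#' all samples' deduplicated reads with the alignment-score filter
#' (`score_min`), (5) homologous-cluster filtering from the monoclonal
#' mappings (three rules), exclusion of low-read mixed samples
#' (`min_sample_reads`), calibration-key estimation from the calibration
#' samples, and abundance estimation for the mock samples.
#'
#' @param reads pooled read pairs (`read_id`, `r1`, `r2`), e.g. from
#'   [simulate_msgbs_study()].
#' @param barcode_map named character vector sample_id -> barcode.
#' @param designs long-format design table.
#' @param max_barcode_mismatch demultiplexing mismatch tolerance.
#' @param min_overlap,max_mismatch_frac pair-merging thresholds.
#' @param min_unique_size dereplication multiplicity cutoff.
#' @param cluster_identity greedy clustering identity threshold.
#' @param contaminant_classifier optional hook for [contaminant_filter()].
#' @param score_min mapping score filter.
#' @param max_hits multi-mapping cap.
#' @param min_sample_reads low-read sample exclusion threshold.
#' @param min_target,ratio_max homologous-filter thresholds.
#' @param exhaustive use exhaustive (no k-mer prefilter) mapping.
#' @param calibrate use the calibration key (`FALSE` gives uncalibrated
#'   read-share abundances, for sensitivity analyses).
#' @return an `msgbs_run` list: `preprocess` (per-sample fractions),
#'   `reference` (meta-reference before homology filtering), `events`
#'   mapping attributes, `counts_raw` (all clusters), `homology` (stats),
#'   `filter` (three-rule report), `counts` (filtered clusters/samples),
#'   `excluded_samples`, `target_rates`, `strain_counts`, `key`,
#'   `abundance_gbs`, and bookkeeping (`excluded_strains`).
#' @export
#' @examples
#' \donttest{
#' study <- simulate_msgbs_study(seed = 1, reads_monoclonal = 3000,
#'                               reads_calibration = 1500, reads_mock = 1500)
#' run <- run_msgbs_pipeline(study$reads, study$barcode_map, study$designs,
#'                           min_sample_reads = 200)
#' head(run$abundance_gbs)
#' }
run_msgbs_pipeline <- function(reads, barcode_map, designs,
                               max_barcode_mismatch = 1L,
                               min_overlap = 20L, max_mismatch_frac = 0.10,
                               min_unique_size = 5L, cluster_identity = 0.95,
                               contaminant_classifier = NULL,
                               score_min = 0.8, max_hits = 50L,
                               min_sample_reads = 3000,
                               min_target = 8, ratio_max = 1 / 15,
                               exhaustive = FALSE, calibrate = TRUE) {
  # (1)-(2) demultiplex, merge/join, deduplicate
  demux <- demultiplex(reads, barcode_map, max_mismatch = max_barcode_mismatch)
  pp <- preprocess_samples(demux, min_overlap = min_overlap,
                           max_mismatch_frac = max_mismatch_frac)
  proc <- pp$reads

  # (3) meta-reference from monoclonal samples
  mono <- monoclonal_strain_map(designs)
  per_strain <- lapply(names(mono), function(sid) {
    seqs <- proc$sequence[proc$sample_id == sid]
    un <- if (length(seqs)) dereplicate(seqs, min_unique_size) else
      suppressWarnings(dereplicate(character(0), min_unique_size))
    cl <- cluster_sequences(un, identity = cluster_identity)
    contaminant_filter(cl, contaminant_classifier)
  })
  names(per_strain) <- unname(mono[names(mono)])
  reference <- build_meta_reference(per_strain)
  excluded_strains <- attr(reference, "excluded_strains")

  # (4) mapping with multi-mapping + score filter
  events <- map_reads(proc, reference, score_min = score_min,
                      max_hits = max_hits, exhaustive = exhaustive)
  counts_raw <- build_count_matrix(events, reference,
                                   samples = unique(designs$sample_id))

  # (5) homologous-cluster filter, sample exclusion, calibration, abundances
  homology <- compute_homology_stats(counts_raw, designs, reference)
  filt <- filter_homologous(homology, min_target = min_target,
                            ratio_max = ratio_max)
  counts_f <- subset_count_matrix(counts_raw, rows = filt$retained)
  excl <- exclude_low_read_samples(counts_f, designs,
                                   min_reads = min_sample_reads)
  counts_f <- excl$matrix
  target_rates <- target_mapping_rate(counts_f, designs)

  sc <- strain_counts(counts_f)
  roles <- design_roles(designs)
  key <- if (calibrate)
    build_calibration_key(sc, designs) else NULL
  mock_ids <- intersect(rownames(sc), names(roles)[roles == "mock"])
  abundance_gbs <- estimate_abundances(sc[mock_ids, , drop = FALSE], key)

  structure(list(
    preprocess = pp$summary,
    duplicate_fraction = pp$duplicate_fraction,
    unassigned_fraction = attr(demux, "unassigned_fraction"),
    reference = reference,
    excluded_strains = excluded_strains,
    mapping = list(n_reads = attr(events, "n_reads"),
                   n_events = nrow(events),
                   n_unmapped = attr(events, "n_unmapped"),
                   n_dropped = attr(events, "n_dropped")),
    counts_raw = counts_raw,
    homology = homology,
    filter = filt,
    counts = counts_f,
    excluded_samples = excl$excluded,
    target_rates = target_rates,
    strain_counts = sc,
    key = key,
    abundance_gbs = abundance_gbs), class = "msgbs_run")
}

#' @export
print.msgbs_run <- function(x, ...) {
  cat("msGBS run\n")
  cat("  reads processed:   ", x$mapping$n_reads,
      " (duplicate fraction ", round(x$duplicate_fraction, 3), ")\n", sep = "")
  cat("  meta-reference:    ", nrow(x$reference), " clusters",
      if (length(x$excluded_strains))
        paste0(" (excluded strains: ",
               paste(x$excluded_strains, collapse = ", "), ")"),
      "\n", sep = "")
  cat("  homology filter:   ", length(x$filter$retained), " clusters retained, ",
      nrow(x$filter$report), " removed\n", sep = "")
  cat("  samples excluded:  ", nrow(x$excluded_samples), "\n", sep = "")
  cat("  target map rates:  ",
      paste(sprintf("%.3f", x$target_rates), collapse = " "), "\n", sep = "")
  cat("  mock samples quantified: ", nrow(x$abundance_gbs), "\n", sep = "")
  invisible(x)
}
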