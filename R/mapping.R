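#' Map processed reads against the meta-reference
#'
#' Semi-global alignment with multi-mapping: for each read, every cluster
#' whose score (`matches / read length`, see [alignment_score()]) reaches
#' `score_min` *and* ties the read's maximum score is reported (tie tolerance
#' zero, decided on integer match counts). Joined reads are scored as two
#' pooled half-alignments across their `N` spacer; both read orientations are
#' tried. Reads tying more than `max_hits` clusters are discarded as
#' unmappable repeats and counted. By default candidate clusters are
#' shortlisted by shared k-mers; `exhaustive = TRUE` aligns every read
#' against every cluster and is the reference behaviour the shortlist must
#' reproduce.
#'
#' @param reads data.frame with columns `read_id`, `sample_id`, `sequence`.
#' @param reference a [build_meta_reference()] object.
#' @param score_min minimal retained alignment score (default 0.8).
#' @param max_hits maximal number of tied clusters per read.
#' @param exhaustive disable the k-mer prefilter.
#' @param kmer k-mer size of the prefilter.
#' @return data.frame of mapping events (`read_id`, `sample_id`,
#'   `cluster_id`, `score`, `n_hits`), one row per (read, tied cluster);
#'   attributes `n_unmapped`, `n_dropped` (multi-hit cap) and `n_reads`.
#' @export
map_reads <- function(reads, reference, score_min = 0.8, max_hits = 50L,
                      exhaustive = FALSE, kmer = 11L) {
  stopifnot(inherits(reference, "meta_reference"), nrow(reference) > 0)
  res <- cpp_map_reads(toupper(reads$sequence), reference$centroid,
                       score_min, as.integer(max_hits), exhaustive,
                       as.integer(kmer), spacer_len = 10L)
  nh <- lengths(res$hits)
  idx <- rep.int(seq_along(nh), nh)
  events <- data.frame(
    read_id = reads$read_id[idx],
    sample_id = reads$sample_id[idx],
    cluster_id = reference$cluster_id[unlist(res$hits)],
    score = res$score[idx],
    n_hits = nh[idx],
    stringsAsFactors = FALSE)
  attr(events, "n_unmapped") <- sum(nh == 0L & !res$dropped)
  attr(events, "n_dropped") <- sum(res$dropped)
  attr(events, "n_reads") <- nrow(reads)
  events
}

#' Build the cluster x sample count matrix from mapping events
#'
#' A read retained with `k` tied clusters contributes `1/k` to each
#' (fractional multi-mapping allocation), so each sample's column mass equals
#' its number of retained mapped reads. Raw (unweighted) event counts are
#' kept in attribute `"raw_events"`.
#'
#' @param events data.frame from [map_reads()].
#' @param reference the meta-reference (fixes the row set and order).
#' @param samples optional sample ids fixing the column set (defaults to the
#'   samples present in `events`).
#' @return a `count_matrix`: numeric matrix clusters x samples with a
#'   `"strain"` attribute mapping each row to its strain.
#' @export
build_count_matrix <- function(events, reference, samples = NULL) {
  samples <- samples %||% sort(unique(events$sample_id))
  m <- matrix(0, nrow = nrow(reference), ncol = length(samples),
              dimnames = list(reference$cluster_id, samples))
  raw <- m
  if (nrow(events)) {
    w <- 1 / events$n_hits
    i <- match(events$cluster_id, reference$cluster_id)
    j <- match(events$sample_id, samples)
    ok <- !is.na(i) & !is.na(j)
    li <- i[ok] + (j[ok] - 1L) * nrow(m)  # linear cell index
    ws <- rowsum(w[ok], li)
    m[as.integer(rownames(ws))] <- ws[, 1L]
    rs <- rowsum(rep(1, sum(ok)), li)
    raw[as.integer(rownames(rs))] <- rs[, 1L]
  }
  structure(m, strain = setNames(reference$strain_id, reference$cluster_id),
            raw_events = raw, class = c("count_matrix", class(m)))
}

#' Drop mixed samples with too few retained reads
#'
#' Mock and calibration samples whose retained column mass (mapped reads
#' after cluster filtering) is below `min_reads` are removed and reported,
#' mirroring the study's exclusion of low-read samples. Monoclonal samples
#' are never dropped here. If every calibration sample would be dropped the
#' run stops, because no calibration key could be computed.
#'
#' @param matrix a [build_count_matrix()] matrix (after cluster filtering).
#' @param designs long-format design table (for sample roles).
#' @param min_reads exclusion threshold (a sample is dropped when its mass is
#'   strictly below this; default 3000).
#' @return list with `matrix` (columns dropped) and `excluded` (data.frame
#'   `sample_id`, `role`, `reads`).
#' @export
exclude_low_read_samples <- function(matrix, designs, min_reads = 3000) {
  roles <- design_roles(designs)
  mass <- colSums(matrix)
  role <- roles[colnames(matrix)]
  drop <- role %in% c("mock", "calibration") & mass < min_reads
  excluded <- data.frame(sample_id = colnames(matrix)[drop],
                         role = unname(role[drop]),
                         reads = unname(mass[drop]),
                         stringsAsFactors = FALSE)
  kept <- subset_count_matrix(matrix, cols = colnames(matrix)[!drop])
  if (any(role == "calibration") &&
      !any(roles[colnames(kept)] == "calibration"))
    qc_failure("all calibration samples fell below the read threshold; no calibration key can be computed",
               data = excluded)
  list(matrix = kept, excluded = excluded)
}

# subset a count_matrix by rows/columns without losing its attributes
subset_count_matrix <- function(matrix, rows = NULL, cols = NULL) {
  strain <- attr(matrix, "strain")
  raw <- attr(matrix, "raw_events")
  rows <- rows %||% rownames(matrix)
  cols <- cols %||% colnames(matrix)
  out <- matrix[rows, cols, drop = FALSE]
  structure(out, strain = strain[rows],
            raw_events = if (!is.null(raw)) raw[rows, cols, drop = FALSE],
            class = c("count_matrix", "matrix", "array"))
}
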