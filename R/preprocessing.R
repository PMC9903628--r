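#' Demultiplex pooled read pairs by inline barcode
#'
#' Assigns each read pair to the sample whose barcode matches the start of R1
#' within `max_mismatch` Hamming mismatches, then strips the barcode and the
#' two per-adapter UMIs (start of R1 and of R2) from the sequences. The
#' barcode table is rejected up front when any two barcodes are within
#' `2 * max_mismatch` of each other, which would make assignments ambiguous.
#' Unassigned pairs are counted, not silently dropped.
#'
#' @param reads data.frame with columns `read_id`, `r1`, `r2` (R1 layout:
#'   barcode, UMI, genomic mate; R2 layout: UMI, genomic mate).
#' @param barcode_map named character vector, sample_id -> barcode (equal
#'   widths).
#' @param max_mismatch maximal Hamming mismatches tolerated in the barcode.
#' @param umi_length UMI length per adapter.
#' @return data.frame of assigned pairs with columns `read_id`, `sample_id`,
#'   `umi` (UMI1 + UMI2), `mate1`, `mate2`; attributes `n_unassigned` and
#'   `unassigned_fraction`.
#' @export
demultiplex <- function(reads, barcode_map, max_mismatch = 1L,
                        umi_length = 3L) {
  bw <- unique(nchar(barcode_map))
  if (length(bw) != 1L) stop("barcodes must share one width")
  nb <- length(barcode_map)
  if (nb > 1L) {
    for (i in seq_len(nb - 1L)) for (j in seq(i + 1L, nb)) {
      d <- sum(strsplit(barcode_map[[i]], "")[[1L]] !=
                 strsplit(barcode_map[[j]], "")[[1L]])
      if (d <= 2L * max_mismatch)
        stop("ambiguous barcode table: '", barcode_map[[i]], "' and '",
             barcode_map[[j]], "' are within ", 2L * max_mismatch,
             " mismatches")
    }
  }
  obs <- substr(reads$r1, 1L, bw)
  hit <- cpp_match_barcodes(obs, unname(barcode_map), as.integer(max_mismatch))
  assigned <- hit > 0L
  out <- data.frame(
    read_id = reads$read_id[assigned],
    sample_id = names(barcode_map)[hit[assigned]],
    umi = paste0(
      substr(reads$r1[assigned], bw + 1L, bw + umi_length),
      substr(reads$r2[assigned], 1L, umi_length)),
    mate1 = substring(reads$r1[assigned], bw + umi_length + 1L),
    mate2 = substring(reads$r2[assigned], umi_length + 1L),
    stringsAsFactors = FALSE)
  attr(out, "n_unassigned") <- sum(!assigned)
  attr(out, "unassigned_fraction") <-
    if (nrow(reads)) sum(!assigned) / nrow(reads) else 0
  out
}

#' Merge or join read pairs
#'
#' Reverse-complements mate 2 and searches for the longest suffix/prefix
#' overlap of at least `min_overlap` bp with a mismatch fraction of at most
#' `max_mismatch_frac`; ties on mismatch count go to the longer overlap. If
#' such an overlap exists the pair is merged into a consensus (mate 1 wins at
#' mismatching positions, length `len1 + len2 - overlap`); otherwise the pair
#' is joined as `mate1 + spacer + revcomp(mate2)`. The fixed `N` spacer keeps
#' merged and joined reads in one alphabet; downstream alignment treats `N`
#' as a mismatch.
#'
#' @param mate1,mate2 character vectors of mate sequences.
#' @param min_overlap minimal overlap length (bp).
#' @param max_mismatch_frac maximal mismatch fraction inside the overlap.
#' @param spacer joiner inserted between unmerged mates.
#' @return data.frame with columns `sequence` and `origin`
#'   (`"merged"`/`"joined"`).
#' @export
#' @examples
#' frag <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
#' merge_pairs(substr(frag, 1, 30), revcomp(substr(frag, 11, 40)),
#'             min_overlap = 10)
merge_pairs <- function(mate1, mate2, min_overlap = 20L,
                        max_mismatch_frac = 0.10, spacer = strrep("N", 10L)) {
  stopifnot(length(mate1) == length(mate2))
  if (any(!nzchar(mate1)) || any(!nzchar(mate2)))
    stop("mates must be non-empty")
  res <- cpp_merge_pairs(toupper(mate1), toupper(mate2),
                         as.integer(min_overlap), max_mismatch_frac, spacer)
  data.frame(sequence = res$sequence,
             origin = ifelse(res$merged, "merged", "joined"),
             stringsAsFactors = FALSE)
}

#' Remove PCR duplicates by UMI and sequence
#'
#' Reads identical in `(sample_id, umi, sequence)` are collapsed to a single
#' representative (the first occurrence). Identical sequences with different
#' UMIs are biological duplicates and are all retained. Deduplication here
#' runs before mapping, on the processed sequence, rather than on mapping
#' positions.
#'
#' @param reads data.frame with columns `sample_id`, `umi`, `sequence`
#'   (additional columns are carried along).
#' @return list with `reads` (deduplicated data.frame) and
#'   `duplicate_fraction` (overall), plus per-sample fractions in
#'   `per_sample`.
#' @export
deduplicate <- function(reads) {
  stopifnot(all(c("sample_id", "umi", "sequence") %in% names(reads)))
  key <- paste(reads$sample_id, reads$umi, reads$sequence, sep = "\r")
  dup <- duplicated(key)
  frac <- if (nrow(reads)) sum(dup) / nrow(reads) else 0
  per_sample <- if (nrow(reads))
    tapply(dup, reads$sample_id, mean) else numeric(0)
  list(reads = reads[!dup, , drop = FALSE],
       duplicate_fraction = frac,
       per_sample = per_sample)
}

#' Dereplicate reads into unique sequences with abundances
#'
#' Collapses exact-identical sequences, recording each unique sequence's
#' multiplicity (`size`), and discards unique sequences supported by fewer
#' than `min_unique_size` reads. Intended for monoclonal read sets feeding
#' the meta-reference.
#'
#' @param sequences character vector of processed read sequences.
#' @param min_unique_size minimal multiplicity retained (default 5).
#' @return data.frame with columns `sequence`, `size`, ordered by decreasing
#'   size then sequence; attribute `total_input` records the input read
#'   count (the sizes before the cut sum to it).
#' @export
dereplicate <- function(sequences, min_unique_size = 5L) {
  if (!length(sequences)) {
    warning("dereplicate: empty input")
    out <- data.frame(sequence = character(0), size = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "total_input") <- 0L
    return(out)
  }
  tab <- table(sequences)
  out <- data.frame(sequence = names(tab), size = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$size, out$sequence), , drop = FALSE]
  total <- sum(out$size)
  out <- out[out$size >= min_unique_size, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_input") <- total
  out
}

#' Preprocess demultiplexed pairs into mapped-ready reads
#'
#' Convenience wrapper: merges/joins each sample's pairs and removes PCR
#' duplicates, keeping per-sample merged/joined/duplicate fractions.
#'
#' @param demux output of [demultiplex()].
#' @inheritParams merge_pairs
#' @return list with `reads` (data.frame `read_id`, `sample_id`, `umi`,
#'   `sequence`, `origin`), `duplicate_fraction`, and `summary` (per-sample
#'   data.frame of merged/joined/duplicate fractions).
#' @export
preprocess_samples <- function(demux, min_overlap = 20L,
                               max_mismatch_frac = 0.10,
                               spacer = strrep("N", 10L)) {
  merged <- merge_pairs(demux$mate1, demux$mate2, min_overlap,
                        max_mismatch_frac, spacer)
  reads <- data.frame(read_id = demux$read_id, sample_id = demux$sample_id,
                      umi = demux$umi, sequence = merged$sequence,
                      origin = merged$origin, stringsAsFactors = FALSE)
  dd <- deduplicate(reads)
  merged_frac <- tapply(reads$origin == "merged", reads$sample_id, mean)
  summary <- data.frame(
    sample_id = names(merged_frac),
    merged_fraction = as.numeric(merged_frac),
    joined_fraction = 1 - as.numeric(merged_frac),
    duplicate_fraction = as.numeric(dd$per_sample[names(merged_frac)]),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(reads = dd$reads, duplicate_fraction = dd$duplicate_fraction,
       summary = summary)
}
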