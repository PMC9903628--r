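DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Characters outside `{A, C, G, T}` (in particular the `N` spacer used for
#' joined read pairs) complement to `N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AANT"))
revcomp <- function(x) {
  cpp_revcomp(toupper(as.character(x)))
}

#' Pairwise global sequence identity
#'
#' Identity is defined as `1 - d / max(nchar(a), nchar(b))` where `d` is the
#' unit-cost (Levenshtein) global alignment distance. For equal-length,
#' substitution-only pairs this equals matches divided by alignment length.
#' `N` never matches, including against another `N`.
#'
#' @param a,b single DNA sequences.
#' @return identity fraction in `[0, 1]`.
#' @export
#' @examples
#' seq_identity("ACGTACGT", "ACGTACGA")
seq_identity <- function(a, b) {
  cpp_seq_identity(toupper(as.character(a)), toupper(as.character(b)))
}

#' Semi-global alignment score of a read against a reference sequence
#'
#' The score is `matches / read length`, with `matches = read length - d`
#' and `d` the semi-global edit distance (the read aligns end to end, the
#' reference absorbs free flanking gaps). Joined reads carrying an internal
#' spacer of `spacer_len` or more `N`s are scored as two pooled half
#' alignments normalised by the non-spacer read length. Both orientations of
#' the read are tried and the better one is returned.
#'
#' @param read,ref single DNA sequences.
#' @param spacer_len minimal `N`-run length treated as a joined-read spacer.
#' @return score in `[0, 1]`.
#' @export
#' @examples
#' alignment_score("ACGTACGTAC", "TTTACGTACGTACTTT")
alignment_score <- function(read, ref, spacer_len = 10L) {
  read <- toupper(as.character(read))
  ref <- toupper(as.character(ref))
  res <- cpp_map_reads(read, ref, score_min = 0, max_hits = 1L,
                       exhaustive = TRUE, kmer = 11L,
                       spacer_len = as.integer(spacer_len))
  res$score[1L]
}

random_dna <- function(length) {
  paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
}

random_tags <- function(n, width) {
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# integer index -> fixed-width DNA tag (base-4 encoding), used by the
# deterministic simulator mode to hand out collision-free UMIs.
index_tag <- function(i, width) {
  out <- character(length(i))
  i <- (as.integer(i) - 1L) %% (4L^width)
  for (p in seq_len(width)) {
    out <- paste0(DNA_BASES[(i %% 4L) + 1L], out)
    i <- i %/% 4L
  }
  out
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

qc_failure <- function(msg, data = NULL) {
  stop(structure(class = c("gbsmix_qc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), data = data)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
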