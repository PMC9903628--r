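#' Write simulated read pairs as gzipped FASTQ
#'
#' R1 carries barcode + UMI inline (GBS convention); constant quality is
#' written since qualities are not modelled.
#'
#' @param reads data.frame with `read_id`, `r1`, `r2`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; files are `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz`.
#' @param quality_char constant quality character.
#' @return invisibly, the two file paths.
#' @export
write_fastq_pairs <- function(reads, dir, prefix = "reads",
                              quality_char = "I") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_R1", "_R2"), ".fastq.gz"))
  for (k in 1:2) {
    seqs <- if (k == 1L) reads$r1 else reads$r2
    con <- gzfile(paths[k], "w")
    writeLines(paste0("@", reads$read_id, "\n", seqs, "\n+\n",
                      strrep(quality_char, nchar(seqs))), con)
    close(con)
  }
  invisible(paths)
}

#' Read paired FASTQ files back into a read-pair table
#'
#' @param r1_path,r2_path FASTQ files (optionally gzipped).
#' @return data.frame with `read_id`, `r1`, `r2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  read_one <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    list(ids = sub("\\s.*$", "", names(x)), seqs = as.character(x))
  }
  a <- read_one(r1_path); b <- read_one(r2_path)
  if (!identical(a$ids, b$ids)) stop("R1/R2 read ids disagree")
  data.frame(read_id = a$ids, r1 = unname(a$seqs), r2 = unname(b$seqs),
             stringsAsFactors = FALSE)
}

#' Write processed (merged/deduplicated) reads as annotated gzipped FASTA
#'
#' One file per sample, headers `read_id;sample=<id>;umi=<tag>;origin=<o>`.
#'
#' @param reads processed read data.frame (`read_id`, `sample_id`, `umi`,
#'   `sequence`, `origin`).
#' @param dir output directory.
#' @return invisibly, the written file paths (named by sample).
#' @export
write_processed_fasta <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- unique(reads$sample_id)
  paths <- setNames(file.path(dir, paste0(samples, ".fasta.gz")), samples)
  for (sid in samples) {
    r <- reads[reads$sample_id == sid, ]
    con <- gzfile(paths[[sid]], "w")
    writeLines(paste0(">", r$read_id, ";sample=", sid, ";umi=", r$umi,
                      ";origin=", r$origin, "\n", r$sequence), con)
    close(con)
  }
  invisible(paths)
}

#' Write the meta-reference as FASTA
#'
#' Headers follow `strainID|clusterN|size=M`.
#'
#' @param reference a [build_meta_reference()] object.
#' @param path output file (plain or `.gz`).
#' @return invisibly, `path`.
#' @export
write_meta_reference <- function(reference, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(paste0(">", reference$cluster_id, "|size=",
                    reference$member_count, "\n", reference$centroid), con)
  close(con)
  invisible(path)
}

#' Read a meta-reference back from FASTA
#'
#' @param path FASTA file written by [write_meta_reference()].
#' @return a `meta_reference` data.frame.
#' @export
read_meta_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- names(x)
  seqs <- unname(as.character(x))
  parts <- strsplit(ids, "|", fixed = TRUE)
  out <- data.frame(
    cluster_id = vapply(parts, function(p) paste(p[1:2], collapse = "|"),
                        character(1)),
    strain_id = vapply(parts, `[`, character(1), 1L),
    centroid = seqs,
    member_count = as.integer(sub("^size=", "",
                                  vapply(parts, `[`, character(1), 3L))),
    stringsAsFactors = FALSE)
  class(out) <- c("meta_reference", "data.frame")
  attr(out, "excluded_strains") <- character(0)
  out
}

#' Write / read the long-format design table as TSV
#'
#' @param designs long-format design table.
#' @param path TSV path.
#' @return invisibly `path` (write) or the design data.frame (read).
#' @export
write_design_tsv <- function(designs, path) {
  utils::write.table(designs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write the cluster x sample count matrix
#'
#' Writes both a wide TSV (clusters x samples) and, when `long_csv` is given,
#' a long-format CSV (`cluster_id`, `strain_id`, `sample_id`, `weight`,
#' `raw_events`) mirroring a per-cluster mapping stats file.
#'
#' @param matrix a count matrix.
#' @param path TSV path for the wide table.
#' @param long_csv optional CSV path for the long table.
#' @return invisibly `path`.
#' @export
write_count_matrix <- function(matrix, path, long_csv = NULL) {
  wide <- data.frame(cluster_id = rownames(matrix),
                     strain_id = attr(matrix, "strain")[rownames(matrix)],
                     unclass(matrix), check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(long_csv)) {
    raw <- attr(matrix, "raw_events")
    long <- data.frame(
      cluster_id = rep(rownames(matrix), times = ncol(matrix)),
      strain_id = rep(attr(matrix, "strain")[rownames(matrix)],
                      times = ncol(matrix)),
      sample_id = rep(colnames(matrix), each = nrow(matrix)),
      weight = as.vector(unclass(matrix)),
      raw_events = if (!is.null(raw)) as.vector(raw) else NA,
      stringsAsFactors = FALSE)
    long <- long[long$weight > 0 | long$raw_events > 0, , drop = FALSE]
    utils::write.csv(long, long_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
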