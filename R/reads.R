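#' Generate paired-end GBS reads for one sample
#'
#' Emits 2 x `read_length` bp read pairs from the strains' restriction
#' fragments. The expected read count of strain *s* is proportional to
#' `cells(s) * yield_factor(s)`; within a strain, fragments are sampled
#' uniformly. Each template molecule carries one 3-nt UMI per adapter (so a
#' pair of UMIs per read pair), is sequenced from either fragment end with
#' equal probability, and receives per-base substitution errors at the bias
#' model's error rate. PCR duplicates are exact copies of finished molecules
#' (same UMIs and sequence). R1 is emitted as `barcode + UMI1 + mate1`, R2 as
#' `UMI2 + mate2`, following the GBS convention of inline barcodes.
#'
#' In `deterministic` mode the read count per strain is exactly
#' `round(cells * yield * reads_per_cell)`, reads are dealt round-robin over
#' fragments and orientations, UMI pairs are assigned without collisions, and
#' no duplicates or errors are produced; this mode realises the exact
#' "read yield = cells x yield" world used by the bias-cancellation checks.
#'
#' @param fragments data.frame from [digest_genome()] (all strains pooled).
#' @param design design rows of a single sample.
#' @param bias a [make_bias_model()] object covering the design's strains.
#' @param reads_per_cell expected reads per (cell x unit yield); ignored when
#'   `n_reads` is given.
#' @param barcode_map named character vector, sample_id -> barcode.
#' @param n_reads optional total read-pair count for the sample (multinomial
#'   across strains with probabilities proportional to `cells * yield`).
#' @param read_length mate length (bp); mates are truncated to the fragment
#'   length when shorter.
#' @param umi_length UMI length per adapter (nt).
#' @param deterministic see above.
#' @param seed optional RNG seed (falls back to `bias$seed`).
#' @return list with `reads` (data.frame `read_id`, `r1`, `r2`) and `truth`
#'   (data.frame `read_id`, `sample_id`, `strain_id`, `fragment_start`,
#'   `fragment_end`, `orientation`, `duplicate`).
#' @export
generate_reads <- function(fragments, design, bias, reads_per_cell = NULL,
                           barcode_map, n_reads = NULL, read_length = 150L,
                           umi_length = 3L, deterministic = FALSE,
                           seed = NULL) {
  stopifnot(length(unique(design$sample_id)) == 1L)
  sample_id <- design$sample_id[1L]
  if (!sample_id %in% names(barcode_map))
    stop("no barcode for sample ", sample_id)
  set_seed_if(seed %||% bias$seed)

  design <- design[design$cells > 0, , drop = FALSE]
  lambda <- design$cells * bias$yield_factor[design$strain_id]
  for (s in design$strain_id)
    if (!any(fragments$strain_id == s))
      stop("strain ", s, " has positive cells but no fragments")

  # reads per strain
  if (deterministic) {
    if (is.null(reads_per_cell))
      stop("deterministic mode needs reads_per_cell")
    n_s <- round(lambda * reads_per_cell)
  } else if (!is.null(n_reads)) {
    n_s <- as.integer(rmultinom(1L, n_reads, lambda / sum(lambda)))
  } else {
    if (is.null(reads_per_cell)) stop("give reads_per_cell or n_reads")
    n_s <- rpois(length(lambda), lambda * reads_per_cell)
  }

  mol <- list()
  for (k in seq_along(design$strain_id)) {
    s <- design$strain_id[k]
    n <- n_s[k]
    if (n == 0L) next
    fr <- fragments[fragments$strain_id == s, , drop = FALSE]
    if (deterministic) {
      n_unique <- n
      idx <- rep_len(seq_len(nrow(fr)), n_unique)
      orient <- rep_len(c("fwd", "rev"), n_unique)
      # collision-free UMI pairs within each (fragment, orientation) group,
      # so deduplication provably removes nothing in this mode
      grp <- paste(idx, orient)
      within <- stats::ave(seq_len(n_unique), grp, FUN = seq_along)
      if (max(within) > 4L^(2L * umi_length))
        stop("deterministic mode cannot hand out more than ",
             4L^(2L * umi_length), " distinct UMI pairs per fragment")
      umi_pair <- cbind(index_tag(within, umi_length),
                        index_tag(within %/% (4L^umi_length) + 1L,
                                  umi_length))
    } else {
      n_dup <- rbinom(1L, n, bias$duplicate_rate)
      n_unique <- max(1L, n - n_dup)
      n_dup <- n - n_unique
      idx <- sample.int(nrow(fr), n_unique, replace = TRUE)
      orient <- c("fwd", "rev")[rbinom(n_unique, 1L, 0.5) + 1L]
      umi_pair <- cbind(random_tags(n_unique, umi_length),
                        random_tags(n_unique, umi_length))
    }
    fl <- fr$length[idx]
    mlen <- pmin(read_length, fl)
    fseq <- fr$sequence[idx]
    fwd <- orient == "fwd"
    m1 <- character(n_unique); m2 <- character(n_unique)
    m1[fwd] <- substring(fseq[fwd], 1L, mlen[fwd])
    m2[fwd] <- as.character(revcomp(
      substring(fseq[fwd], fl[fwd] - mlen[fwd] + 1L, fl[fwd])))
    if (any(!fwd)) {
      rseq <- as.character(revcomp(fseq[!fwd]))
      m1[!fwd] <- substring(rseq, 1L, mlen[!fwd])
      m2[!fwd] <- as.character(revcomp(
        substring(rseq, fl[!fwd] - mlen[!fwd] + 1L, fl[!fwd])))
    }
    # sequencing errors on unique molecules (duplicates copy them verbatim)
    if (!deterministic && bias$error_rate > 0) {
      for (mate in 1:2) {
        seqs <- if (mate == 1L) m1 else m2
        total_bases <- sum(nchar(seqs))
        n_err <- rbinom(1L, total_bases, bias$error_rate)
        if (n_err > 0L) {
          offs <- sort(sample.int(total_bases, n_err))
          ends <- cumsum(nchar(seqs))
          row <- findInterval(offs - 1L, ends) + 1L
          pos <- offs - c(0L, ends)[row]
          for (e in seq_len(n_err)) {
            b <- substr(seqs[row[e]], pos[e], pos[e])
            substr(seqs[row[e]], pos[e], pos[e]) <-
              sample(setdiff(DNA_BASES, b), 1L)
          }
          if (mate == 1L) m1 <- seqs else m2 <- seqs
        }
      }
    }
    take <- seq_len(n_unique)
    if (!deterministic && n - n_unique > 0L)
      take <- c(take, sample.int(n_unique, n - n_unique, replace = TRUE))
    mol[[length(mol) + 1L]] <- data.frame(
      strain_id = s,
      fragment_start = fr$start[idx][take],
      fragment_end = fr$end[idx][take],
      orientation = orient[take],
      umi1 = umi_pair[take, 1L], umi2 = umi_pair[take, 2L],
      m1 = m1[take], m2 = m2[take],
      duplicate = c(rep(FALSE, n_unique), rep(TRUE, length(take) - n_unique)),
      stringsAsFactors = FALSE)
  }

  if (!length(mol)) {
    reads <- data.frame(read_id = character(0), r1 = character(0),
                        r2 = character(0), stringsAsFactors = FALSE)
    truth <- data.frame(read_id = character(0), sample_id = character(0),
                        strain_id = character(0), fragment_start = integer(0),
                        fragment_end = integer(0), orientation = character(0),
                        duplicate = logical(0), stringsAsFactors = FALSE)
    return(list(reads = reads, truth = truth))
  }
  mol <- do.call(rbind, mol)
  read_id <- sprintf("%s_read%06d", sample_id, seq_len(nrow(mol)))
  bc <- barcode_map[[sample_id]]
  list(
    reads = data.frame(
      read_id = read_id,
      r1 = paste0(bc, mol$umi1, mol$m1),
      r2 = paste0(mol$umi2, mol$m2),
      stringsAsFactors = FALSE),
    truth = data.frame(
      read_id = read_id, sample_id = sample_id, strain_id = mol$strain_id,
      fragment_start = mol$fragment_start, fragment_end = mol$fragment_end,
      orientation = mol$orientation, duplicate = mol$duplicate,
      stringsAsFactors = FALSE))
}

#' Simulate a complete msGBS mock-community study
#'
#' One-stop generator reproducing the benchmark's statistical structure:
#' six strain genomes in three lineages (one close clade of three strains and
#' one hybrid mosaic with its own divergence), PacI/NsiI double digestion with
#' > 150 bp size selection, per-strain yield biases spanning 32-fold, 3-nt
#' UMIs on both adapters, about 50% PCR duplicates, sequencing errors, the
#' 6 monoclonal / 5 calibration / 25 mock design, and light-microscopy valve
#' counts (200 valves per mock) drawn through a morphology confusion matrix.
#'
#' @param seed RNG seed for the whole study.
#' @param n_strains number of strains (the default topology expects 6).
#' @param genome_length genome length (bp).
#' @param divergences per-strain divergence from the parent; the default
#'   encodes lineage 1 (strain01), a close clade (strain02..04), a distant
#'   lineage (strain05) and the hybrid's own divergence (strain06).
#' @param reads_monoclonal,reads_calibration,reads_mock raw read pairs per
#'   sample by role.
#' @param bias optional [make_bias_model()]; default 32-fold yield spread,
#'   50% duplicates, 0.1% per-base errors.
#' @param confusion optional LM confusion matrix; default
#'   [lm_confusion_matrix()].
#' @param n_valves valves counted per mock sample.
#' @param plant_every spacing of planted PacI sites in the ancestor.
#' @return list with `genomes`, `fragments`, `designs`, `bias`,
#'   `barcode_map`, `reads` (pooled read pairs), `truth`, `lm_counts`
#'   (mock x strain matrix), `confusion`.
#' @export
#' @examples
#' \donttest{
#' study <- simulate_msgbs_study(seed = 1, reads_monoclonal = 2000,
#'                               reads_calibration = 1200, reads_mock = 1200)
#' }
simulate_msgbs_study <- function(seed = 1, n_strains = 6,
                                 genome_length = 1e5,
                                 divergences = c(0.05, 0.05, 0.015, 0.015,
                                                 0.08, 0.02),
                                 reads_monoclonal = 12000,
                                 reads_calibration = 7000,
                                 reads_mock = 7000,
                                 bias = NULL, confusion = NULL,
                                 n_valves = 200L, plant_every = 1500L) {
  set_seed_if(seed)
  strains <- sprintf("strain%02d", seq_len(n_strains))
  parents <- c("ancestor", "ancestor", "strain02", "strain02", "ancestor",
               "ancestor")[seq_len(n_strains)]
  genomes <- simulate_strain_genomes(
    n_strains, genome_length, divergences = divergences, parents = parents,
    hybrid_spec = if (n_strains >= 6) list(
      strain = strains[6], parents = strains[1:2],
      breakpoints = round(genome_length * c(0.25, 0.5, 0.75)),
      divergence = divergences[6]) else NULL,
    plant_site = "TTAATTAA", plant_every = plant_every)

  fragments <- do.call(rbind, lapply(genomes, digest_genome))
  rownames(fragments) <- NULL

  designs <- make_study_design(n_strains)
  if (is.null(bias)) bias <- make_bias_model(strains)
  sample_ids <- unique(designs$sample_id)
  barcode_map <- setNames(make_barcodes(length(sample_ids)), sample_ids)

  roles <- design_roles(designs)
  depth <- c(monoclonal = reads_monoclonal, calibration = reads_calibration,
             mock = reads_mock)
  reads <- list(); truth <- list()
  for (sid in sample_ids) {
    g <- generate_reads(fragments, designs[designs$sample_id == sid, ],
                        bias, barcode_map = barcode_map,
                        n_reads = depth[[roles[[sid]]]])
    reads[[sid]] <- g$reads
    truth[[sid]] <- g$truth
  }
  reads <- do.call(rbind, reads); rownames(reads) <- NULL
  truth <- do.call(rbind, truth); rownames(truth) <- NULL

  if (is.null(confusion)) confusion <- lm_confusion_matrix(strains)
  mock_ids <- names(roles)[roles == "mock"]
  lm_counts <- t(vapply(mock_ids, function(sid)
    simulate_lm_counts(designs[designs$sample_id == sid, ], confusion,
                       n_valves = n_valves),
    numeric(n_strains)))

  list(genomes = genomes, fragments = fragments, designs = designs,
       bias = bias, barcode_map = barcode_map, reads = reads, truth = truth,
       lm_counts = lm_counts, confusion = confusion)
}
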