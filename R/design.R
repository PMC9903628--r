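#' Build the benchmark sample design
#'
#' Reproduces the mock-community study layout: one monoclonal sample per
#' strain, five calibration samples containing all strains in equal
#' proportions (990,000 cells total by default, split evenly with rounding to
#' the nearest cell), and 25 mock mixtures of about one million cells each
#' (18 five-strain, 3 three-strain, 3 two-strain and 1 single-strain sample).
#' Mock proportions are drawn from a symmetric Dirichlet (`alpha`) over the
#' strains selected for each sample. Leave-one-out mixes (five strains out of
#' six) rotate the absent strain so every strain is absent equally often;
#' smaller mixes pick their strains at random.
#'
#' @param n_strains number of strains (>= 5).
#' @param seed optional RNG seed.
#' @param total_cells target total cells per mock sample.
#' @param calibration_cells total cells per calibration sample.
#' @param monoclonal_cells cells per monoclonal sample (not counted in the
#'   original protocol; only its relative magnitude matters here).
#' @param n_calibration number of calibration samples.
#' @param mix_sizes integer vector giving the number of strains in each mock
#'   sample; default `c(rep(5, 18), rep(3, 3), rep(2, 3), 1)`.
#' @param alpha Dirichlet concentration for mock proportions.
#' @return long-format data.frame with columns `sample_id`, `role`
#'   (`monoclonal`/`calibration`/`mock`) and `strain_id`, `cells`.
#' @export
#' @examples
#' d <- make_study_design(6, seed = 1)
#' table(unique(d[c("sample_id", "role")])$role)
make_study_design <- function(n_strains = 6, seed = NULL,
                              total_cells = 1e6, calibration_cells = 990000,
                              monoclonal_cells = 6e6, n_calibration = 5,
                              mix_sizes = c(rep(5L, 18L), rep(3L, 3L),
                                            rep(2L, 3L), 1L),
                              alpha = 2) {
  stopifnot(n_strains >= 5)
  set_seed_if(seed)
  strains <- sprintf("strain%02d", seq_len(n_strains))
  rows <- list()

  for (i in seq_len(n_strains))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("mono%02d", i), role = "monoclonal",
      strain_id = strains[i], cells = monoclonal_cells,
      stringsAsFactors = FALSE)

  cal_each <- round(calibration_cells / n_strains)
  for (i in seq_len(n_calibration))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("cal%02d", i), role = "calibration",
      strain_id = strains, cells = cal_each, stringsAsFactors = FALSE)

  n_left_out <- 0L
  for (i in seq_along(mix_sizes)) {
    k <- mix_sizes[i]
    if (k == n_strains - 1L) {
      # leave-one-out mixes rotate the absent strain so that absences (and
      # hence false-positive opportunities) are balanced across strains
      n_left_out <- n_left_out + 1L
      chosen <- strains[-(((n_left_out - 1L) %% n_strains) + 1L)]
    } else {
      chosen <- sort(sample(strains, k))
    }
    p <- rgamma(k, shape = alpha)
    p <- p / sum(p)
    cells <- round(p * total_cells)
    cells[which.max(cells)] <- cells[which.max(cells)] +
      (total_cells - sum(cells))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("mock%02d", i), role = "mock",
      strain_id = chosen, cells = cells, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-strain library bias model
#'
#' Captures the strain-specific read-yield biases observed in GBS libraries
#' (up to 32-fold between strains in the benchmark study), the PCR duplicate
#' rate (about half of all reads) and the per-base sequencing error rate.
#'
#' @param strain_ids strain labels.
#' @param yield_factor positive reads-per-cell multipliers, one per strain;
#'   the default spans 32-fold as `2^seq(0, 5, length.out = n)`.
#' @param duplicate_rate fraction of emitted reads that are PCR duplicates,
#'   in `[0, 1)`.
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed stored with the model (used by [generate_reads()]
#'   when no explicit seed is passed).
#' @return a `bias_model` list with fields `yield_factor` (named),
#'   `duplicate_rate`, `error_rate`, `seed` and `yield_spread`
#'   (max/min yield ratio).
#' @export
#' @examples
#' make_bias_model(sprintf("strain%02d", 1:6))$yield_spread
make_bias_model <- function(strain_ids, yield_factor = NULL,
                            duplicate_rate = 0.5, error_rate = 0.001,
                            seed = NULL) {
  n <- length(strain_ids)
  if (is.null(yield_factor)) yield_factor <- 2^seq(0, 5, length.out = n)
  yield_factor <- rep_len(as.numeric(yield_factor), n)
  if (any(yield_factor <= 0)) stop("yield factors must be positive")
  if (duplicate_rate < 0 || duplicate_rate >= 1)
    stop("duplicate_rate must be in [0, 1)")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  structure(list(
    yield_factor = setNames(yield_factor, strain_ids),
    duplicate_rate = duplicate_rate,
    error_rate = error_rate,
    seed = seed,
    yield_spread = max(yield_factor) / min(yield_factor)),
    class = "bias_model")
}

#' Generate sample barcodes
#'
#' Draws fixed-width barcodes with a minimal pairwise Hamming distance
#' (default 3, so single-mismatch demultiplexing stays unambiguous).
#'
#' @param n number of barcodes.
#' @param width barcode length in nt.
#' @param min_dist minimal pairwise Hamming distance.
#' @param seed optional RNG seed.
#' @return character vector of barcodes.
#' @export
make_barcodes <- function(n, width = 6L, min_dist = 3L, seed = NULL) {
  set_seed_if(seed)
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    cand <- random_tags(1L, width)
    ok <- all(vapply(out, function(b)
      sum(strsplit(cand, "")[[1L]] != strsplit(b, "")[[1L]]) >= min_dist,
      logical(1)))
    if (ok) out <- c(out, cand)
    tries <- tries + 1L
    if (tries > 20000L) stop("could not find ", n, " barcodes at distance ",
                             min_dist)
  }
  out
}

#' Default light-microscopy confusion matrix
#'
#' Encodes the misidentification structure expected from morphology when
#' phylogenetically close strains overlap in valve metrics: the members of
#' the close clade are confused with one another, and every strain leaks a
#' small fraction of identifications into the putative-hybrid analogue whose
#' teratological valves resemble several strains.
#'
#' @param strain_ids strain labels.
#' @param clade ids of the morphologically similar clade members.
#' @param hybrid id of the hybrid-analogue strain.
#' @param clade_leak identification probability leaked to each other clade
#'   member.
#' @param hybrid_leak identification probability leaked from every non-hybrid
#'   strain to the hybrid.
#' @return row-stochastic matrix `confusion[true, identified]`.
#' @export
lm_confusion_matrix <- function(strain_ids,
                                clade = strain_ids[c(2, 3, 4)],
                                hybrid = strain_ids[length(strain_ids)],
                                clade_leak = 0.08, hybrid_leak = 0.08) {
  n <- length(strain_ids)
  cm <- matrix(0, n, n, dimnames = list(strain_ids, strain_ids))
  diag(cm) <- 1
  for (s in clade) for (t in setdiff(clade, s)) {
    cm[s, t] <- cm[s, t] + clade_leak
    cm[s, s] <- cm[s, s] - clade_leak
  }
  for (s in setdiff(strain_ids, hybrid)) {
    cm[s, hybrid] <- cm[s, hybrid] + hybrid_leak
    cm[s, s] <- cm[s, s] - hybrid_leak
  }
  if (any(cm < 0)) stop("leak probabilities are too large")
  cm
}

#' Simulate light-microscopy valve counts for one sample
#'
#' Draws `n_valves` identifications from the sample's true cell proportions
#' pushed through a strain-by-strain confusion matrix, emulating expert
#' counting with morphology-driven misidentification.
#'
#' @param design design rows of a single sample (long format).
#' @param confusion row-stochastic confusion matrix
#'   `confusion[true, identified]` covering all strains.
#' @param n_valves number of valves counted.
#' @param seed optional RNG seed.
#' @return named integer vector of valve counts per strain (all strains of
#'   the confusion matrix, zeros included).
#' @export
simulate_lm_counts <- function(design, confusion, n_valves = 200L,
                               seed = NULL) {
  stopifnot(length(unique(design$sample_id)) == 1L)
  if (n_valves < 1L) stop("n_valves must be >= 1")
  strains <- rownames(confusion)
  if (is.null(strains) || !identical(strains, colnames(confusion)))
    stop("confusion must have matching strain row/col names")
  if (any(abs(rowSums(confusion) - 1) > 1e-8))
    stop("confusion rows must sum to 1")
  total <- sum(design$cells)
  if (total <= 0) stop("design has zero total cells")
  set_seed_if(seed)
  p_true <- setNames(numeric(length(strains)), strains)
  p_true[design$strain_id] <- design$cells / total
  p_obs <- as.numeric(p_true %*% confusion)
  counts <- as.integer(rmultinom(1L, n_valves, p_obs))
  setNames(counts, strains)
}

# role lookup helpers over the long-format design table
design_roles <- function(designs) {
  u <- unique(designs[c("sample_id", "role")])
  setNames(u$role, u$sample_id)
}

monoclonal_strain_map <- function(designs) {
  mono <- designs[designs$role == "monoclonal" & designs$cells > 0, ]
  if (any(duplicated(mono$sample_id)))
    stop("a monoclonal sample lists more than one strain")
  setNames(mono$strain_id, mono$sample_id)
}
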