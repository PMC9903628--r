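#' Aggregate cluster counts to strain x sample read weights
#'
#' Sums each sample's mapped-read weights over the retained clusters of each
#' strain.
#'
#' @param matrix a (filtered) count matrix.
#' @return numeric matrix samples x strains.
#' @export
strain_counts <- function(matrix) {
  strain_of <- attr(matrix, "strain")[rownames(matrix)]
  if (is.null(strain_of)) stop("matrix carries no strain annotation")
  t(rowsum(unclass(matrix), strain_of))
}

#' Learn the per-strain calibration key from equal-proportion samples
#'
#' For every calibration sample the per-strain read shares are computed
#' (strain weight / sample total); the calibration factor of a strain is the
#' arithmetic mean of its shares across calibration samples (factors sum
#' to 1), and the between-sample variance of the shares (on the percent
#' scale) is reported as a stability diagnostic.
#'
#' @param counts samples x strains matrix from [strain_counts()].
#' @param designs long-format design table (identifies calibration samples),
#'   or a character vector of calibration sample ids.
#' @return a `calibration_key` data.frame with columns `strain_id`, `factor`,
#'   `s2`; per-sample shares in attribute `"shares"`.
#' @export
build_calibration_key <- function(counts, designs) {
  cal_ids <- if (is.character(designs)) designs else {
    roles <- design_roles(designs)
    names(roles)[roles == "calibration"]
  }
  cal_ids <- intersect(cal_ids, rownames(counts))
  if (!length(cal_ids)) stop("no calibration sample available")
  shares <- counts[cal_ids, , drop = FALSE]
  tot <- rowSums(shares)
  if (any(tot == 0)) stop("calibration sample(s) with zero reads: ",
                          paste(cal_ids[tot == 0], collapse = ", "))
  shares <- shares / tot
  dead <- colSums(shares) == 0
  if (any(dead))
    stop("strain(s) with zero reads in every calibration sample cannot be calibrated: ",
         paste(colnames(shares)[dead], collapse = ", "))
  key <- data.frame(strain_id = colnames(shares),
                    factor = colMeans(shares),
                    s2 = apply(shares * 100, 2L, function(x)
                      if (length(x) > 1L) var(x) else 0),
                    stringsAsFactors = FALSE)
  rownames(key) <- NULL
  attr(key, "shares") <- shares
  class(key) <- c("calibration_key", "data.frame")
  key
}

#' Convert strain read counts to calibrated relative abundances
#'
#' Divides each strain's read weight by its calibration factor and
#' renormalises per sample:
#' `abundance(s, j) = (r_sj / f_s) / sum_t (r_tj / f_t)`.
#' Because the factors are the strains' mean read shares at equal cell
#' proportions, this inverts the strain-specific read-yield bias. Strains
#' with zero reads get abundance 0 (no pseudocount). Samples with zero total
#' reads are excluded and reported.
#'
#' @param counts samples x strains matrix (typically restricted to mock
#'   samples).
#' @param key a [build_calibration_key()] object, or `NULL` for the
#'   uncalibrated read-share estimate (uniform key).
#' @return an `abundance_table` (samples x strains matrix, rows summing
#'   to 1) with `method = "GBS"`; excluded samples in attribute
#'   `"excluded_samples"`.
#' @export
estimate_abundances <- function(counts, key) {
  f <- if (is.null(key)) {
    setNames(rep(1 / ncol(counts), ncol(counts)), colnames(counts))
  } else {
    missing <- setdiff(colnames(counts), key$strain_id)
    if (length(missing)) stop("calibration key lacks strain(s): ",
                              paste(missing, collapse = ", "))
    setNames(key$factor, key$strain_id)[colnames(counts)]
  }
  corrected <- sweep(counts, 2L, f, "/")
  tot <- rowSums(corrected)
  excluded <- rownames(counts)[tot == 0]
  corrected <- corrected[tot > 0, , drop = FALSE]
  ab <- corrected / rowSums(corrected)
  abundance_table(ab, method = "GBS", excluded_samples = excluded)
}

#' Expected abundances from the sample design
#'
#' Converts designed cell counts to expected relative abundances, after
#' removing any strains excluded from the analysis (for example a strain
#' whose monoclonal library failed) and renormalising the remaining cells.
#' Samples left empty by the exclusion are dropped and reported.
#'
#' @param designs long-format design table.
#' @param excluded_strains strain ids removed before renormalisation.
#' @param roles design roles to include (default `"mock"`).
#' @param strains optional strain set fixing the column order.
#' @return an `abundance_table` with `method = "expected"`.
#' @export
expected_abundances <- function(designs, excluded_strains = character(0),
                                roles = "mock", strains = NULL) {
  d <- designs[designs$role %in% roles &
                 !designs$strain_id %in% excluded_strains, ]
  strains <- strains %||%
    sort(setdiff(unique(designs$strain_id), excluded_strains))
  samples <- unique(designs$sample_id[designs$role %in% roles])
  m <- matrix(0, length(samples), length(strains),
              dimnames = list(samples, strains))
  m[cbind(match(d$sample_id, samples), match(d$strain_id, strains))] <- d$cells
  tot <- rowSums(m)
  dropped <- samples[tot == 0]
  m <- m[tot > 0, , drop = FALSE]
  abundance_table(m / rowSums(m), method = "expected",
                  excluded_samples = dropped)
}

#' Light-microscopy counts as an abundance table
#'
#' Converts valve counts to per-sample proportions, after removing excluded
#' strains' valves (mirroring the treatment of the expected table).
#'
#' @param lm_counts samples x strains matrix of valve counts.
#' @param excluded_strains strain ids whose valves are discarded.
#' @return an `abundance_table` with `method = "LM"`.
#' @export
lm_abundance_table <- function(lm_counts, excluded_strains = character(0)) {
  m <- lm_counts[, !colnames(lm_counts) %in% excluded_strains, drop = FALSE]
  tot <- rowSums(m)
  dropped <- rownames(m)[tot == 0]
  m <- m[tot > 0, , drop = FALSE]
  abundance_table(m / rowSums(m), method = "LM", excluded_samples = dropped)
}

#' Abundance table constructor
#'
#' A samples x strains matrix of relative abundances whose rows sum to one
#' (within 1e-9), tagged with the estimating method.
#'
#' @param m samples x strains matrix.
#' @param method method tag (`"GBS"`, `"LM"`, `"expected"`, ...).
#' @param excluded_samples sample ids dropped during construction.
#' @return the validated `abundance_table`.
#' @export
abundance_table <- function(m, method, excluded_samples = character(0)) {
  m <- as.matrix(m)
  if (nrow(m) && (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)))
    stop("abundance rows must be non-negative and sum to 1")
  structure(m, method = method, excluded_samples = excluded_samples,
            class = c("abundance_table", "matrix", "array"))
}
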