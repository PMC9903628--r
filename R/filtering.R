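#' Per-cluster homology statistics from monoclonal mappings
#'
#' For every cluster, `target_reads` is the mapped-read weight it received
#' from the monoclonal sample of its own strain, and the non-target weights
#' are those from every other strain's monoclonal sample. These statistics
#' drive the homologous-cluster filter.
#'
#' @param matrix a [build_count_matrix()] matrix including all monoclonal
#'   samples.
#' @param designs long-format design table.
#' @param reference the meta-reference the matrix was built against.
#' @return a `homology_stats` data.frame with columns `cluster_id`,
#'   `strain_id`, `target_reads`, `max_nontarget`, `sum_nontarget`,
#'   `max_nontarget_strain`; the full cluster x non-target-strain weight
#'   matrix is kept in attribute `"nontarget"`.
#' @export
compute_homology_stats <- function(matrix, designs, reference) {
  mono <- monoclonal_strain_map(designs)
  mono <- mono[names(mono) %in% colnames(matrix)]
  strains <- unique(reference$strain_id)
  missing <- setdiff(strains, mono)
  if (length(missing))
    stop("no monoclonal sample in the matrix for strain(s): ",
         paste(missing, collapse = ", "))
  strain_sample <- setNames(names(mono), mono)  # strain -> monoclonal sample
  cl <- intersect(reference$cluster_id, rownames(matrix))
  ref <- reference[match(cl, reference$cluster_id), ]
  mono_w <- matrix[cl, strain_sample[strains], drop = FALSE]
  colnames(mono_w) <- strains

  target <- mono_w[cbind(seq_along(cl), match(ref$strain_id, strains))]
  nt <- mono_w
  nt[cbind(seq_along(cl), match(ref$strain_id, strains))] <- NA
  sum_nt <- rowSums(nt, na.rm = TRUE)
  ntz <- nt
  ntz[is.na(ntz)] <- -Inf
  mi <- max.col(ntz, ties.method = "first")
  max_nt <- ntz[cbind(seq_along(cl), mi)]
  max_nt[!is.finite(max_nt)] <- 0
  which_nt <- colnames(nt)[mi]
  which_nt[max_nt == 0] <- NA_character_

  out <- data.frame(cluster_id = cl, strain_id = ref$strain_id,
                    target_reads = as.numeric(target),
                    max_nontarget = as.numeric(max_nt),
                    sum_nontarget = as.numeric(sum_nt),
                    max_nontarget_strain = which_nt,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "nontarget") <- nt
  class(out) <- c("homology_stats", "data.frame")
  out
}

#' Remove homologous clusters by the three-rule filter
#'
#' A cluster is removed iff any of three rules fires (evaluated in order for
#' attribution; the retained set depends only on their disjunction):
#' \enumerate{
#'   \item non-target reads exceed target reads
#'     (`max_nontarget > target_reads`),
#'   \item the target monoclonal support is insufficient
#'     (`target_reads < min_target`, default 8),
#'   \item the non-target/target ratio exceeds the threshold
#'     (`max_nontarget / target_reads > ratio_max`, default 1/15).
#' }
#' Non-target reads are aggregated as the maximum over non-target strains by
#' default; `aggregate = "sum"` pools them instead (a stricter variant).
#'
#' @param stats a [compute_homology_stats()] data.frame (or any data.frame
#'   with `cluster_id`, `strain_id`, `target_reads`, `max_nontarget`,
#'   and, for `aggregate = "sum"`, `sum_nontarget`).
#' @param min_target rule 2 threshold.
#' @param ratio_max rule 3 threshold.
#' @param aggregate `"max"` (default) or `"sum"` non-target aggregation.
#' @return list with `retained` (cluster ids), `report` (data.frame
#'   `cluster_id`, `strain_id`, `rule` for removed clusters) and `pairwise`
#'   (strain x strain removal counts: off-diagonal cells count clusters of
#'   the row strain removed with the column strain as strongest non-target
#'   attractor; the diagonal counts rule-2 removals with no non-target
#'   signal).
#' @export
filter_homologous <- function(stats, min_target = 8, ratio_max = 1 / 15,
                              aggregate = c("max", "sum")) {
  aggregate <- match.arg(aggregate)
  nt <- if (aggregate == "max") stats$max_nontarget else stats$sum_nontarget
  t_ <- stats$target_reads
  rule1 <- nt > t_
  rule2 <- t_ < min_target
  rule3 <- ifelse(t_ > 0, nt / t_ > ratio_max, nt > 0)
  removed <- rule1 | rule2 | rule3
  first_rule <- ifelse(rule1, 1L, ifelse(rule2, 2L, ifelse(rule3, 3L, NA)))

  report <- data.frame(cluster_id = stats$cluster_id[removed],
                       strain_id = stats$strain_id[removed],
                       rule = first_rule[removed],
                       stringsAsFactors = FALSE)
  strains <- sort(unique(c(stats$strain_id,
                           stats$max_nontarget_strain[
                             !is.na(stats$max_nontarget_strain)])))
  pw <- matrix(0L, length(strains), length(strains),
               dimnames = list(target = strains, nontarget = strains))
  if (any(removed)) {
    off <- stats$max_nontarget_strain[removed]
    tg <- stats$strain_id[removed]
    for (k in seq_along(tg)) {
      col <- if (is.na(off[k])) tg[k] else off[k]
      pw[tg[k], col] <- pw[tg[k], col] + 1L
    }
  }
  list(retained = stats$cluster_id[!removed], report = report, pairwise = pw)
}

#' Per-monoclonal-sample target mapping rate
#'
#' Fraction of each monoclonal sample's retained read mass that maps to
#' clusters of its own strain, a quality gate on the filtered
#' meta-reference's strain resolution.
#'
#' @param matrix filtered count matrix.
#' @param designs long-format design table.
#' @param min_rate optional QC threshold; when given, any monoclonal sample
#'   below it (or with no retained reads at all) raises a structured
#'   `gbsmix_qc_error`.
#' @return named numeric vector of rates per monoclonal sample (`NaN` when
#'   the sample has no retained reads).
#' @export
target_mapping_rate <- function(matrix, designs, min_rate = NULL) {
  mono <- monoclonal_strain_map(designs)
  mono <- mono[names(mono) %in% colnames(matrix)]
  strain_of <- attr(matrix, "strain")[rownames(matrix)]
  rates <- vapply(names(mono), function(sid) {
    col <- matrix[, sid]
    tot <- sum(col)
    if (tot == 0) return(NaN)
    sum(col[strain_of == mono[[sid]]]) / tot
  }, numeric(1))
  if (!is.null(min_rate)) {
    bad <- !is.finite(rates) | rates < min_rate
    if (any(bad))
      qc_failure(paste0("target mapping rate below ", min_rate,
                        " for monoclonal sample(s): ",
                        paste(names(rates)[bad], collapse = ", ")),
                 data = rates)
  }
  rates
}
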