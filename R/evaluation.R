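#' Align two abundance tables on common samples and strains
#'
#' @noRd
align_tables <- function(observed, expected) {
  miss_o <- setdiff(rownames(expected), rownames(observed))
  miss_e <- setdiff(rownames(observed), rownames(expected))
  if (length(miss_o) || length(miss_e))
    stop("sample sets differ: missing from observed {",
         paste(miss_o, collapse = ", "), "}; missing from expected {",
         paste(miss_e, collapse = ", "), "}")
  strains <- intersect(colnames(expected), colnames(observed))
  if (!length(strains)) stop("no common strains")
  samples <- rownames(expected)
  list(observed = observed[samples, strains, drop = FALSE],
       expected = expected[samples, strains, drop = FALSE])
}

#' Restrict two abundance tables to their common samples and strains
#'
#' Convenience for comparing tables whose sample sets differ (for example
#' when low-read samples were excluded from one method): both tables are
#' subset to the shared samples (and shared strains) in matching order.
#' Errors when no sample is shared. Note that rows are *not* renormalised;
#' strains should already agree up to exclusions handled by
#' [expected_abundances()] / [lm_abundance_table()].
#'
#' @param observed,expected `abundance_table`s.
#' @return list with elements `observed` and `expected`.
#' @export
intersect_tables <- function(observed, expected) {
  samples <- intersect(rownames(observed), rownames(expected))
  if (!length(samples)) stop("no common samples")
  strains <- intersect(colnames(observed), colnames(expected))
  if (!length(strains)) stop("no common strains")
  list(observed = abundance_table(
         unclass(observed)[samples, strains, drop = FALSE],
         attr(observed, "method")),
       expected = abundance_table(
         unclass(expected)[samples, strains, drop = FALSE],
         attr(expected, "method")))
}

#' False positive / false negative detection report
#'
#' A strain is "detected" in a sample when its estimated abundance exceeds
#' `presence_threshold` (default 0: any signal counts). Detections are
#' tallied against the expected table's presences: a false positive is a
#' detection where the strain is absent from the design, a false negative a
#' miss where it is present.
#'
#' @param observed,expected `abundance_table`s sharing samples.
#' @param presence_threshold abundance above which a strain counts as
#'   detected.
#' @return list with `summary` (data.frame `strain_id`, `fp`, `fn`,
#'   `n_present`, `n_absent`) and `detail` (long data.frame per sample and
#'   strain).
#' @export
detect_strains <- function(observed, expected, presence_threshold = 0) {
  al <- align_tables(observed, expected)
  present <- al$expected > 0
  detected <- al$observed > presence_threshold
  summary <- data.frame(
    strain_id = colnames(al$expected),
    fp = as.integer(colSums(detected & !present)),
    fn = as.integer(colSums(!detected & present)),
    n_present = as.integer(colSums(present)),
    n_absent = as.integer(colSums(!present)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  detail <- data.frame(
    sample_id = rep(rownames(al$expected), times = ncol(al$expected)),
    strain_id = rep(colnames(al$expected), each = nrow(al$expected)),
    expected = as.vector(al$expected),
    observed = as.vector(al$observed),
    status = as.vector(ifelse(detected & !present, "FP",
                              ifelse(!detected & present, "FN",
                                     ifelse(present, "TP", "TN")))),
    stringsAsFactors = FALSE)
  list(summary = summary, detail = detail)
}

#' Abundance mass assigned to absent strains
#'
#' Per sample, the total estimated abundance of strains absent from the
#' design (the false positive signal), and its mean over samples.
#'
#' @param observed,expected `abundance_table`s sharing samples.
#' @return list with `per_sample` (named numeric) and `mean`.
#' @export
false_signal_rate <- function(observed, expected) {
  al <- align_tables(observed, expected)
  fp_mass <- rowSums(al$observed * (al$expected == 0))
  list(per_sample = fp_mass, mean = mean(fp_mass))
}

#' Classify correlation strength
#'
#' Fixed cutpoints: strong when `r > 0.7`, moderate when `0.5 <= r <= 0.7`,
#' weak (or none) when `r < 0.5`.
#'
#' @param r numeric vector of Pearson correlations.
#' @return character vector of classes (`NA` stays `NA`).
#' @export
classify_correlation <- function(r) {
  ifelse(is.na(r), NA_character_,
         ifelse(r > 0.7, "strong", ifelse(r >= 0.5, "moderate", "weak")))
}

#' Pearson correlation and regression of observed vs expected abundances
#'
#' Per unit (sample row or strain column), computes the Pearson correlation,
#' the ordinary least squares regression `observed ~ expected` (slope,
#' intercept, R-squared, 95% t-based confidence interval on the slope) and
#' the strength class of [classify_correlation()]. Units with fewer than 3
#' pairs or zero variance on either axis are reported as not computable
#' (`r = NA`) rather than propagating `NaN`.
#'
#' @param observed,expected `abundance_table`s sharing samples.
#' @param unit `"sample"` (correlate each sample's composition) or
#'   `"strain"` (correlate each strain across samples).
#' @param nonzero_only drop pairs whose expected value is 0 (default keeps
#'   all pairs, including zero-expected strains).
#' @return data.frame with columns `unit`, `n`, `r`, `r2`, `slope`,
#'   `intercept`, `slope_lo`, `slope_hi`, `class`.
#' @export
correlate_abundances <- function(observed, expected,
                                 unit = c("sample", "strain"),
                                 nonzero_only = FALSE) {
  unit <- match.arg(unit)
  al <- align_tables(observed, expected)
  ids <- if (unit == "sample") rownames(al$expected) else colnames(al$expected)
  rows <- lapply(ids, function(id) {
    if (unit == "sample") {
      x <- al$expected[id, ]; y <- al$observed[id, ]
    } else {
      x <- al$expected[, id]; y <- al$observed[, id]
    }
    if (nonzero_only) {
      keep <- x > 0
      x <- x[keep]; y <- y[keep]
    }
    out <- data.frame(unit = id, n = length(x), r = NA_real_, r2 = NA_real_,
                      slope = NA_real_, intercept = NA_real_,
                      slope_lo = NA_real_, slope_hi = NA_real_,
                      class = NA_character_, stringsAsFactors = FALSE)
    if (length(x) < 3L || var(x) == 0 || var(y) == 0) return(out)
    out$r <- cor(x, y)
    fit <- lm(y ~ x)
    out$slope <- unname(coef(fit)[2L])
    out$intercept <- unname(coef(fit)[1L])
    ci <- tryCatch(suppressWarnings(confint(fit, "x", level = 0.95)),
                   error = function(e) c(NA_real_, NA_real_))
    out$slope_lo <- ci[1L]; out$slope_hi <- ci[2L]
    out$r2 <- out$r^2
    out$class <- classify_correlation(out$r)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two methods' correlations per unit
#'
#' Flags, per unit, the method with the higher Pearson correlation; exact
#' ties (and units not computable under both methods) are reported as ties.
#'
#' @param stats_a,stats_b data.frames from [correlate_abundances()] over the
#'   same units.
#' @param labels method names, used in the `winner` column.
#' @return data.frame `unit`, `r_a`, `r_b`, `winner`, with a named summary
#'   count vector in attribute `"summary"`.
#' @export
compare_methods <- function(stats_a, stats_b, labels = c("GBS", "LM")) {
  m <- merge(stats_a[c("unit", "r")], stats_b[c("unit", "r")],
             by = "unit", suffixes = c("_a", "_b"))
  winner <- ifelse(is.na(m$r_a) & is.na(m$r_b), "tie",
                   ifelse(is.na(m$r_b) | (!is.na(m$r_a) & m$r_a > m$r_b),
                          labels[1L],
                          ifelse(is.na(m$r_a) | m$r_b > m$r_a,
                                 labels[2L], "tie")))
  out <- data.frame(unit = m$unit, r_a = m$r_a, r_b = m$r_b,
                    winner = winner, stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("r_", labels)
  counts <- c(sum(winner == labels[1L]), sum(winner == labels[2L]),
              sum(winner == "tie"))
  attr(out, "summary") <- setNames(counts, c(labels, "tie"))
  out
}
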