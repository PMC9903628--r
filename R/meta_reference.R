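#' Greedy centroid clustering of dereplicated sequences
#'
#' Classic abundance-sorted greedy clustering: sequences are visited in
#' decreasing `size` order (ties broken lexicographically by sequence); each
#' sequence joins the first existing centroid whose global identity is at
#' least `identity`, otherwise it founds a new cluster. Identity is
#' `1 - d / max(length)` with `d` the unit-cost global alignment distance
#' (see [seq_identity()]); with `both_strands = TRUE` (the default) the
#' reverse complement is also tried, so the two orientations of the same
#' restriction fragment fall into one cluster.
#'
#' @param uniques data.frame from [dereplicate()] (columns `sequence`,
#'   `size`).
#' @param identity identity threshold in `(0, 1]`.
#' @param both_strands also compare against centroid reverse complements.
#' @return data.frame with columns `centroid` (the founding sequence) and
#'   `member_count` (sum of member sizes), in founding order.
#' @export
#' @examples
#' u <- data.frame(sequence = c("ACGTACGTAC", "ACGTACGTAT"), size = c(9, 5))
#' cluster_sequences(u, identity = 0.9)
cluster_sequences <- function(uniques, identity = 0.95, both_strands = TRUE) {
  if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]")
  if (!nrow(uniques))
    return(data.frame(centroid = character(0), member_count = integer(0),
                      stringsAsFactors = FALSE))
  ord <- order(-uniques$size, uniques$sequence)
  seqs <- toupper(uniques$sequence[ord])
  sizes <- uniques$size[ord]
  assign <- cpp_greedy_cluster(seqs, identity, both_strands)
  founders <- unique(assign)  # in founding order
  member_count <- vapply(founders, function(f)
    sum(sizes[assign == f]), numeric(1))
  data.frame(centroid = seqs[founders],
             member_count = as.integer(member_count),
             stringsAsFactors = FALSE)
}

#' Filter contaminant clusters through a pluggable classifier
#'
#' Stands in for taxonomic contaminant screening (e.g. BLAST-based removal of
#' non-target kingdoms) behind a hook: the classifier receives the centroid
#' sequences and returns a logical keep-vector. The default keeps everything,
#' appropriate for synthetic data with no contaminants.
#'
#' @param clusters data.frame from [cluster_sequences()].
#' @param classifier `function(centroids) -> logical` keep mask, or `NULL`.
#' @param reason label recorded for dropped clusters.
#' @return retained clusters, with the dropped rows (plus `reason`) in
#'   attribute `"dropped"`.
#' @export
contaminant_filter <- function(clusters, classifier = NULL,
                               reason = "contaminant") {
  if (is.null(classifier)) classifier <- function(centroids)
    rep(TRUE, length(centroids))
  keep <- classifier(clusters$centroid)
  if (!is.logical(keep) || length(keep) != nrow(clusters))
    stop("classifier must return one logical per cluster")
  dropped <- clusters[!keep, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- reason
  out <- clusters[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Concatenate per-strain clusters into a meta-reference
#'
#' Assigns strain-prefixed cluster ids and stacks all strains' clusters into
#' one reference. Strains contributing zero clusters (for instance a failed
#' monoclonal library) are excluded and reported rather than failing the
#' build; the build fails only when no strain has any cluster.
#'
#' @param per_strain_clusters named list (strain_id -> cluster data.frame).
#' @return a `meta_reference`: data.frame with columns `cluster_id`,
#'   `strain_id`, `centroid`, `member_count`; excluded strains in attribute
#'   `"excluded_strains"`.
#' @export
build_meta_reference <- function(per_strain_clusters) {
  if (is.null(names(per_strain_clusters)))
    stop("per_strain_clusters must be named by strain")
  n_clusters <- vapply(per_strain_clusters, nrow, integer(1))
  excluded <- names(per_strain_clusters)[n_clusters == 0L]
  kept <- per_strain_clusters[n_clusters > 0L]
  if (!length(kept))
    stop("every strain has zero clusters; no meta-reference can be built")
  if (length(excluded))
    message("excluding strain(s) with no clusters from the meta-reference: ",
            paste(excluded, collapse = ", "))
  parts <- lapply(names(kept), function(s) {
    cl <- kept[[s]]
    data.frame(cluster_id = sprintf("%s|cluster%d", s, seq_len(nrow(cl))),
               strain_id = s, centroid = cl$centroid,
               member_count = cl$member_count, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  if (anyDuplicated(out$cluster_id)) stop("duplicate cluster ids")
  class(out) <- c("meta_reference", "data.frame")
  attr(out, "excluded_strains") <- excluded
  out
}
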