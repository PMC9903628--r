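#' Simulate strain genomes with a controlled divergence structure
#'
#' Generates an ancestral genome and derives one genome per strain by
#' substituting each site with the requested per-site probability relative to
#' its parent (the ancestor by default, or an earlier strain to build
#' clade-like topologies). One strain may be declared a hybrid: its genome is
#' a mosaic alternating between two parental genomes at the given breakpoints,
#' optionally followed by its own substitutions.
#'
#' @param n_strains number of strains (>= 1).
#' @param genome_length genome length in bp (>= 1000).
#' @param divergences per-strain substitutions-per-site fraction from the
#'   parent, in `[0, 0.5)`; recycled if length 1.
#' @param parents optional character vector naming each strain's parent:
#'   `"ancestor"` (default) or the id of an earlier strain.
#' @param hybrid_spec optional list describing the hybrid strain:
#'   `strain` (id or index, default the last strain), `parents` (ids of the
#'   two parental strains, which must precede it), `breakpoints` (0-based
#'   positions where the mosaic switches parent; default a single midpoint
#'   breakpoint), and `divergence` (the hybrid's own substitution rate applied
#'   after the mosaic, default its entry in `divergences`).
#' @param seed optional RNG seed.
#' @param ancestor optional ancestral sequence; random if `NULL`.
#' @param plant_site optional recognition sequence planted into the ancestor
#'   at regular intervals (`plant_every`) so that sparse cutters still yield a
#'   usable number of restriction fragments in short simulated genomes.
#' @param plant_every spacing (bp) between planted sites.
#' @return a list of `strain_genome` objects (fields `strain_id`, `sequence`,
#'   `parent_id`, `divergence`, `is_hybrid`), named by strain id, with the
#'   ancestor sequence in attribute `"ancestor"`.
#' @export
#' @examples
#' g <- simulate_strain_genomes(2, 2000, divergences = 0.05, seed = 1)
#' sapply(g, function(x) x$strain_id)
simulate_strain_genomes <- function(n_strains, genome_length, divergences,
                                    parents = NULL, hybrid_spec = NULL,
                                    seed = NULL, ancestor = NULL,
                                    plant_site = NULL, plant_every = 1500L) {
  stopifnot(n_strains >= 1, genome_length >= 1000)
  divergences <- rep_len(as.numeric(divergences), n_strains)
  if (any(divergences < 0 | divergences >= 0.5))
    stop("divergences must lie in [0, 0.5)")
  set_seed_if(seed)

  ids <- sprintf("strain%02d", seq_len(n_strains))
  if (is.null(parents)) parents <- rep("ancestor", n_strains)
  parents <- rep_len(parents, n_strains)

  if (is.null(ancestor)) ancestor <- random_dna(genome_length)
  ancestor <- toupper(ancestor)
  if (nchar(ancestor) != genome_length)
    stop("ancestor length disagrees with genome_length")
  if (!is.null(plant_site)) {
    plant_site <- toupper(plant_site)
    w <- nchar(plant_site)
    at <- seq(from = max(1L, plant_every %/% 2L),
              to = genome_length - w, by = plant_every)
    for (p in at) substr(ancestor, p, p + w - 1L) <- plant_site
  }

  hybrid_id <- NULL
  if (!is.null(hybrid_spec)) {
    hs <- hybrid_spec
    if (is.null(hs$strain)) hs$strain <- ids[n_strains]
    if (is.numeric(hs$strain)) hs$strain <- ids[hs$strain]
    if (length(hs$parents) != 2L)
      stop("hybrid_spec$parents must name two strains")
    if (is.numeric(hs$parents)) hs$parents <- ids[hs$parents]
    if (is.null(hs$breakpoints)) hs$breakpoints <- genome_length %/% 2L
    hybrid_id <- hs$strain
    hybrid_spec <- hs
  }

  mutate <- function(seq, rate) {
    if (rate <= 0) return(seq)
    n_sub <- rbinom(1L, nchar(seq), rate)
    if (n_sub == 0L) return(seq)
    pos <- sample.int(nchar(seq), n_sub)
    new <- vapply(substring(seq, pos, pos), function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1), USE.NAMES = FALSE)
    cpp_substitute(seq, as.integer(pos), new)
  }

  genomes <- list()
  for (i in seq_len(n_strains)) {
    id <- ids[i]
    if (!is.null(hybrid_id) && id == hybrid_id) {
      pa <- hybrid_spec$parents
      if (!all(pa %in% names(genomes)))
        stop("hybrid parents must be simulated before the hybrid strain")
      bp <- sort(unique(as.integer(hybrid_spec$breakpoints)))
      if (any(bp <= 0L | bp >= genome_length))
        stop("hybrid breakpoints must fall strictly inside the genome")
      bounds <- c(0L, bp, genome_length)
      segs <- character(length(bounds) - 1L)
      for (s in seq_along(segs)) {
        src <- genomes[[pa[((s - 1L) %% 2L) + 1L]]]$sequence
        segs[s] <- substr(src, bounds[s] + 1L, bounds[s + 1L])
      }
      seqn <- paste(segs, collapse = "")
      own <- hybrid_spec$divergence %||% divergences[i]
      if (own < 0 || own >= 0.5) stop("hybrid divergence must lie in [0, 0.5)")
      seqn <- mutate(seqn, own)
      genomes[[id]] <- structure(
        list(strain_id = id, sequence = seqn, parent_id = pa,
             divergence = own, is_hybrid = TRUE),
        class = "strain_genome")
      next
    }
    parent_seq <- if (parents[i] == "ancestor") ancestor else {
      if (!parents[i] %in% names(genomes))
        stop("parent '", parents[i], "' must be simulated before '", id, "'")
      genomes[[parents[i]]]$sequence
    }
    genomes[[id]] <- structure(
      list(strain_id = id, sequence = mutate(parent_seq, divergences[i]),
           parent_id = parents[i], divergence = divergences[i],
           is_hybrid = FALSE),
      class = "strain_genome")
  }
  attr(genomes, "ancestor") <- ancestor
  genomes
}

#' Double restriction digest of a genome with size selection
#'
#' Cuts the genome at every occurrence of the two recognition sequences
#' (cut position = site start + cut offset; defaults model PacI `TTAAT|TAA`
#' and NsiI `ATGCA|T`) and retains only fragments flanked by one cut of each
#' enzyme with length strictly greater than `min_fragment`, mirroring
#' double-digest library construction with enzyme-specific adapters and
#' a > 150 bp size selection. Coordinates are 0-based, half-open. Sites are
#' searched on the given strand only.
#'
#' @param genome a `strain_genome` or a plain sequence string.
#' @param site_a,site_b recognition sequences of the two enzymes.
#' @param min_fragment retained fragments must be strictly longer than this.
#' @param cut_a,cut_b cut offset within each recognition site.
#' @param strain_id label used when `genome` is a plain string.
#' @return data.frame with columns `strain_id`, `start`, `end`, `left_site`,
#'   `right_site`, `length`, `sequence`. Zero rows when no fragment survives.
#' @export
#' @examples
#' g <- paste0(strrep("A", 200), "TTAATTAA", strrep("C", 300),
#'             "ATGCAT", strrep("G", 200))
#' digest_genome(g, strain_id = "toy")
digest_genome <- function(genome, site_a = "TTAATTAA", site_b = "ATGCAT",
                          min_fragment = 150L, cut_a = 5L, cut_b = 5L,
                          strain_id = NULL) {
  if (inherits(genome, "strain_genome")) {
    strain_id <- strain_id %||% genome$strain_id
    seqn <- genome$sequence
  } else {
    strain_id <- strain_id %||% "genome"
    seqn <- toupper(as.character(genome))
  }
  if (!nzchar(site_a) || !nzchar(site_b))
    stop("recognition sequences must be non-empty")

  find_cuts <- function(site, offset) {
    hits <- gregexpr(site, seqn, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(integer(0))
    as.integer(hits) - 1L + as.integer(offset)  # 0-based cut position
  }
  cuts <- data.frame(
    pos = c(find_cuts(toupper(site_a), cut_a),
            find_cuts(toupper(site_b), cut_b)),
    enzyme = rep(c("a", "b"),
                 c(length(find_cuts(toupper(site_a), cut_a)),
                   length(find_cuts(toupper(site_b), cut_b)))),
    stringsAsFactors = FALSE)
  empty <- data.frame(strain_id = character(0), start = integer(0),
                      end = integer(0), left_site = character(0),
                      right_site = character(0), length = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  if (nrow(cuts) < 2L) return(empty)
  cuts <- cuts[order(cuts$pos), ]
  n <- nrow(cuts)
  start <- cuts$pos[-n]
  end <- cuts$pos[-1L]
  left <- cuts$enzyme[-n]
  right <- cuts$enzyme[-1L]
  keep <- left != right & (end - start) > min_fragment
  if (!any(keep)) return(empty)
  start <- start[keep]; end <- end[keep]
  data.frame(
    strain_id = strain_id,
    start = start,
    end = end,
    left_site = ifelse(left[keep] == "a", "site_a", "site_b"),
    right_site = ifelse(right[keep] == "a", "site_a", "site_b"),
    length = end - start,
    sequence = substring(seqn, start + 1L, end),
    stringsAsFactors = FALSE)
}
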