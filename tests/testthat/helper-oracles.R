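# Independent oracles, deliberately written against base R (utils::adist,
# plain DP loops) so they share no code with the package's C++ paths.

rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, pos) {
  for (p in pos) {
    b <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }
  s
}

r_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# global identity oracle: Levenshtein via utils::adist
r_identity <- function(a, b) {
  1 - c(utils::adist(a, b)) / max(nchar(a), nchar(b))
}

# semi-global edit distance oracle (pattern end-to-end, free text flanks),
# N never matches
r_sg_distance <- function(p, t) {
  P <- strsplit(p, "")[[1L]]; T <- strsplit(t, "")[[1L]]
  n <- length(P); m <- length(T)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  if (m > 0) for (j in 2:(m + 1L)) {
    D[1L, j] <- 0L
    for (i in 2:(n + 1L)) {
      mm <- P[i - 1L] != T[j - 1L] || P[i - 1L] == "N" || T[j - 1L] == "N"
      D[i, j] <- min(D[i - 1L, j - 1L] + mm, D[i - 1L, j] + 1L,
                     D[i, j - 1L] + 1L)
    }
  }
  min(D[n + 1L, ])
}

# full mapping-score oracle: joined reads split on the 10-N spacer, halves
# pooled, both orientations tried
r_alignment_score <- function(read, ref) {
  score_one <- function(r) {
    parts <- strsplit(r, "N{10,}")[[1L]]
    parts <- parts[nzchar(parts)]
    len <- sum(nchar(parts))
    d <- sum(vapply(parts, r_sg_distance, numeric(1), t = ref))
    (len - d) / len
  }
  max(score_one(read), score_one(r_revcomp(read)))
}

# exhaustive mapping oracle: all refs scored, ties at the maximum reported
r_map_read <- function(read, refs, score_min = 0.8) {
  sc <- vapply(refs, r_alignment_score, numeric(1), read = read)
  best <- max(sc)
  if (best < score_min - 1e-12) return(integer(0))
  which(abs(sc - best) < 1e-12)
}

# greedy clustering oracle on size-sorted uniques
r_greedy_cluster <- function(seqs, identity, both_strands = TRUE) {
  centroids <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (c in centroids) {
      id <- r_identity(seqs[i], seqs[c])
      if (both_strands)
        id <- max(id, r_identity(seqs[i], r_revcomp(seqs[c])))
      if (id >= identity - 1e-12) { hit <- c; break }
    }
    if (hit) assign[i] <- hit
    else { centroids <- c(centroids, i); assign[i] <- i }
  }
  assign
}

# three-rule homologous-cluster filter oracle
r_filter_oracle <- function(target, nontarget_max, min_target = 8,
                            ratio_max = 1 / 15) {
  removed <- logical(length(target))
  for (i in seq_along(target)) {
    r1 <- nontarget_max[i] > target[i]
    r2 <- target[i] < min_target
    r3 <- if (target[i] > 0) nontarget_max[i] / target[i] > ratio_max
          else nontarget_max[i] > 0
    removed[i] <- r1 || r2 || r3
  }
  removed
}

# small genome with enough planted sites for a handful of fragments
toy_genomes <- function(n_strains = 3, genome_length = 30000,
                        divergences = 0.12, seed = 5, ...) {
  simulate_strain_genomes(n_strains, genome_length,
                          divergences = divergences, seed = seed,
                          plant_site = "TTAATTAA", plant_every = 1200, ...)
}
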