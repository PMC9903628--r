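make_ref <- function(centroids, strains = rep("s1", length(centroids))) {
  per <- split(centroids, strains)
  build_meta_reference(lapply(per, function(x)
    data.frame(centroid = x, member_count = rep(5L, length(x)),
               stringsAsFactors = FALSE)))
}

test_that("alignment scores follow the semi-global contract", {
  set.seed(9)
  ref <- rand_dna(300)
  # exact substring -> score 1.0
  expect_equal(alignment_score(substr(ref, 50, 199), ref), 1.0)
  # reverse complement of a substring -> score 1.0 (both strands tried)
  expect_equal(alignment_score(r_revcomp(substr(ref, 50, 199)), ref), 1.0)
  # 150-nt read with 35 substitutions -> 115/150 = 0.767
  read <- mutate_seq(substr(ref, 50, 199), sample(150, 35))
  expect_equal(alignment_score(read, ref), r_alignment_score(read, ref))
  expect_equal(r_alignment_score(read, ref), 115 / 150)
})

test_that("reads are assigned to all clusters tying the best score", {
  set.seed(16)
  homo1 <- rand_dna(200)
  # homolog differing at exactly 10 known positions inside the read window
  pos_read <- sort(sample(150, 10))            # read-relative positions
  homo2 <- mutate_seq(homo1, 10 + pos_read)    # window is homo1[11..160]
  other <- rand_dna(200)
  ref <- make_ref(c(homo1, homo2, other), c("a", "a", "b"))

  # flip 5 of the 10 diagnostic sites: the read is equidistant (score 145/150)
  read <- substr(homo1, 11, 160)
  for (p in pos_read[1:5])
    substr(read, p, p) <- substr(homo2, 10 + p, 10 + p)
  expect_equal(r_alignment_score(read, homo1), 145 / 150)
  expect_equal(r_alignment_score(read, homo2), 145 / 150)
  ev <- map_reads(data.frame(read_id = "r", sample_id = "s",
                             sequence = read), ref)
  expect_identical(sort(ev$cluster_id), sort(ref$cluster_id[1:2]))
  expect_identical(unique(ev$n_hits), 2L)

  # a read below the score threshold is unmapped
  bad <- mutate_seq(substr(homo1, 11, 160), sample(150, 40))
  ev2 <- map_reads(data.frame(read_id = "r", sample_id = "s",
                              sequence = bad), ref)
  expect_identical(nrow(ev2), 0L)
  expect_identical(attr(ev2, "n_unmapped"), 1L)
})

test_that("k-mer prefilter reproduces exhaustive mapping, which matches the oracle", {
  set.seed(27)
  # reference: 30 clusters in 3 families of near-duplicates
  fam <- replicate(10, rand_dna(120))
  centroids <- c(fam,
                 vapply(fam, function(f) mutate_seq(f, sample(120, 3)),
                        character(1)),
                 vapply(fam, function(f) mutate_seq(f, sample(120, 12)),
                        character(1)))
  ref <- make_ref(centroids)

  reads <- character(0)
  for (i in 1:120) {
    src <- sample(centroids, 1)
    start <- sample(1:40, 1)
    r <- substr(src, start, start + 79)
    nmut <- sample(0:12, 1)
    if (nmut) r <- mutate_seq(r, sample(nchar(r), nmut))
    if (runif(1) < 0.3) r <- r_revcomp(r)
    if (runif(1) < 0.2)  # joined form
      r <- paste0(substr(r, 1, 40), strrep("N", 10), substr(r, 41, 80))
    reads <- c(reads, r)
  }
  rd <- data.frame(read_id = sprintf("r%03d", seq_along(reads)),
                   sample_id = "s", sequence = reads,
                   stringsAsFactors = FALSE)

  ev_fast <- map_reads(rd, ref)
  ev_full <- map_reads(rd, ref, exhaustive = TRUE)
  expect_identical(ev_fast, ev_full)

  # independent oracle per read
  for (i in seq_along(reads)) {
    want <- sort(ref$cluster_id[r_map_read(reads[i], ref$centroid)])
    got <- sort(ev_full$cluster_id[ev_full$read_id == rd$read_id[i]])
    expect_identical(got, want)
  }
})

test_that("count matrix allocates fractionally and conserves column mass", {
  ref <- make_ref(c("AAAA", "CCCC", "GGGG"), c("a", "a", "b"))
  events <- data.frame(
    read_id = c("r1", "r2", "r2", "r3", "r3"),
    sample_id = c("s1", "s1", "s1", "s2", "s2"),
    cluster_id = c("a|cluster1", "a|cluster1", "a|cluster2",
                   "a|cluster1", "b|cluster1"),
    score = 1, n_hits = c(1L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE)
  m <- build_count_matrix(events, ref)
  expect_equal(m["a|cluster1", "s1"], 1.5)
  expect_equal(m["a|cluster2", "s1"], 0.5)
  expect_equal(unname(colSums(m)), c(2, 1))  # one read -> one unit of mass
  raw <- attr(m, "raw_events")
  expect_equal(raw["a|cluster1", "s1"], 2)

  # strain aggregation equals the hand-enumerated sums
  sc <- strain_counts(m)
  expect_equal(sc["s1", "a"], 2)
  expect_equal(sc["s2", "a"], 0.5)
  expect_equal(sc["s2", "b"], 0.5)
})

test_that("raising score_min never increases any matrix entry", {
  set.seed(31)
  centroids <- replicate(8, rand_dna(100))
  ref <- make_ref(centroids)
  reads <- vapply(1:60, function(i) {
    r <- substr(sample(centroids, 1), 1, 70)
    mutate_seq(r, sample(70, sample(0:15, 1)))
  }, character(1))
  rd <- data.frame(read_id = sprintf("r%02d", 1:60), sample_id = "s",
                   sequence = reads, stringsAsFactors = FALSE)
  m_low <- build_count_matrix(map_reads(rd, ref, score_min = 0.8), ref)
  m_high <- build_count_matrix(map_reads(rd, ref, score_min = 0.9), ref)
  expect_true(all(m_high <= m_low + 1e-12))
})

test_that("low-read mixed samples are excluded at the 3000-read boundary", {
  ref <- make_ref(c("AAAA", "CCCC"), c("a", "b"))
  designs <- data.frame(
    sample_id = c("mono01", "mock01", "mock02", "cal01"),
    role = c("monoclonal", "mock", "mock", "calibration"),
    strain_id = "a", cells = 10)
  m <- matrix(c(2999, 2999, 3000, 3500,
                0,    0,    0,    0), nrow = 2, byrow = TRUE,
              dimnames = list(ref$cluster_id, designs$sample_id))
  m <- structure(m, strain = setNames(ref$strain_id, ref$cluster_id),
                 class = c("count_matrix", "matrix", "array"))
  out <- exclude_low_read_samples(m, designs, min_reads = 3000)
  # 2999 reads -> excluded; 3000 -> retained; monoclonal never dropped
  expect_identical(out$excluded$sample_id, "mock01")
  expect_identical(colnames(out$matrix), c("mono01", "mock02", "cal01"))

  # all calibration samples below threshold is a structured failure
  m2 <- m; m2[1, "cal01"] <- 10
  expect_error(exclude_low_read_samples(m2, designs, min_reads = 3000),
               class = "gbsmix_qc_error")
})
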