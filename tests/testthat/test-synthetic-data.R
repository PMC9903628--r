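test_that("strain genomes honour requested divergence and reproducibility", {
  g0 <- simulate_strain_genomes(3, 5000, divergences = 0, seed = 1)
  anc <- attr(g0, "ancestor")
  for (g in g0) expect_identical(g$sequence, anc)

  L <- 100000
  g <- simulate_strain_genomes(2, L, divergences = 0.05, seed = 42)
  anc <- attr(g, "ancestor")
  diff_frac <- mean(strsplit(g$strain01$sequence, "")[[1L]] !=
                      strsplit(anc, "")[[1L]])
  tol <- 3 * sqrt(0.05 * 0.95 / L)
  expect_lt(abs(diff_frac - 0.05), tol)

  g2 <- simulate_strain_genomes(2, L, divergences = 0.05, seed = 42)
  expect_identical(g, g2)

  expect_error(simulate_strain_genomes(2, 5000, divergences = 0.6, seed = 1),
               "divergences")
  expect_error(simulate_strain_genomes(1, 500, divergences = 0, seed = 1))
})

test_that("hybrid genomes alternate parental segments at the breakpoints", {
  L <- 4000
  g <- simulate_strain_genomes(
    3, L, divergences = c(0.1, 0.1, 0), seed = 7,
    hybrid_spec = list(strain = "strain03", parents = c("strain01", "strain02"),
                       breakpoints = L / 2, divergence = 0))
  hyb <- g$strain03
  expect_true(hyb$is_hybrid)
  expect_identical(substr(hyb$sequence, 1, L / 2),
                   substr(g$strain01$sequence, 1, L / 2))
  expect_identical(substr(hyb$sequence, L / 2 + 1, L),
                   substr(g$strain02$sequence, L / 2 + 1, L))
})

test_that("double digest retains only hetero-flanked fragments above the size cut", {
  # no recognition sites at all
  expect_identical(nrow(digest_genome(strrep("A", 2000))), 0L)

  # one PacI cut at 200+5, one NsiI cut at 508+5: a single retained fragment
  g <- paste0(strrep("A", 200), "TTAATTAA", strrep("C", 300), "ATGCAT",
              strrep("G", 200))
  fr <- digest_genome(g, strain_id = "toy")
  expect_identical(nrow(fr), 1L)
  expect_identical(fr$start, 205L)
  expect_identical(fr$end, 513L)
  expect_identical(fr$length, 308L)
  expect_identical(fr$sequence, substr(g, 206, 513))

  # shrinking the spacer to 100 C's puts the fragment at 108 bp <= 150: gone
  g_short <- paste0(strrep("A", 200), "TTAATTAA", strrep("C", 100), "ATGCAT",
                    strrep("G", 200))
  expect_identical(nrow(digest_genome(g_short)), 0L)

  # fragment between two cuts of the same enzyme is discarded
  g_same <- paste0(strrep("A", 100), "TTAATTAA", strrep("C", 300), "TTAATTAA",
                   strrep("G", 100))
  expect_identical(nrow(digest_genome(g_same)), 0L)

  # boundary: a fragment of exactly min_fragment is not retained
  g_exact <- paste0(strrep("A", 100), "TTAATTAA", strrep("C", 142), "ATGCAT",
                    strrep("G", 100))
  fr <- digest_genome(g_exact)          # 5 + 142 + 3 = 150 exactly
  expect_identical(nrow(fr), 0L)
})

test_that("study design reproduces the benchmark layout", {
  d <- make_study_design(6, seed = 3)
  roles <- table(unique(d[c("sample_id", "role")])$role)
  expect_identical(as.integer(roles[c("monoclonal", "calibration", "mock")]),
                   c(6L, 5L, 25L))

  # mock composition counts: 18 five-strain, 3 three-strain, 3 two-strain, 1 single
  mocks <- d[d$role == "mock", ]
  sizes <- table(table(mocks$sample_id))
  expect_identical(as.integer(sizes[c("5", "3", "2", "1")]),
                   c(18L, 3L, 3L, 1L))
  expect_true(all(abs(tapply(mocks$cells, mocks$sample_id, sum) - 1e6) < 1))

  # calibration: all strains at 990000/6 cells
  cal <- d[d$role == "calibration", ]
  expect_true(all(cal$cells == round(990000 / 6)))
  expect_identical(length(unique(cal$sample_id)), 5L)

  # monoclonal: one strain each, all strains covered
  mono <- d[d$role == "monoclonal", ]
  expect_identical(sort(mono$strain_id), sprintf("strain%02d", 1:6))
  expect_identical(as.integer(table(mono$sample_id)), rep(1L, 6))
})

test_that("read generation respects yields, duplicates and truth tags", {
  set.seed(11)
  genomes <- toy_genomes(2)
  frags <- do.call(rbind, lapply(genomes, digest_genome))
  strains <- c("strain01", "strain02")
  bm <- setNames(make_barcodes(1, seed = 2), "mix01")
  design <- data.frame(sample_id = "mix01", role = "mock",
                       strain_id = strains, cells = c(1000, 1000))

  # no-noise case: every mate is an exact substring of its source fragment
  bias0 <- make_bias_model(strains, yield_factor = c(1, 1),
                           duplicate_rate = 0, error_rate = 0)
  g <- generate_reads(frags, design, bias0, barcode_map = bm, n_reads = 400,
                      seed = 31)
  expect_identical(nrow(g$reads), 400L)
  key <- paste(frags$strain_id, frags$start)
  for (i in sample(nrow(g$reads), 25)) {
    fr <- frags[match(paste(g$truth$strain_id[i], g$truth$fragment_start[i]),
                      key), ]
    m1 <- substring(g$reads$r1[i], 10)   # strip 6 nt barcode + 3 nt UMI
    m2 <- substring(g$reads$r2[i], 4)    # strip 3 nt UMI
    hit <- grepl(m1, fr$sequence, fixed = TRUE) ||
      grepl(m1, r_revcomp(fr$sequence), fixed = TRUE)
    expect_true(hit)
    hit2 <- grepl(m2, fr$sequence, fixed = TRUE) ||
      grepl(m2, r_revcomp(fr$sequence), fixed = TRUE)
    expect_true(hit2)
  }
  # conservation: truth rows match emitted reads one-to-one
  expect_identical(g$truth$read_id, g$reads$read_id)

  # yield factors 1 vs 4 at equal cells: read ratio within 3 sd of 1:4
  bias14 <- make_bias_model(strains, yield_factor = c(1, 4),
                            duplicate_rate = 0, error_rate = 0)
  n <- 100000
  g14 <- generate_reads(frags, design, bias14, barcode_map = bm, n_reads = n,
                        seed = 32)
  p <- 0.8   # expected share of strain02
  share <- mean(g14$truth$strain_id == "strain02")
  expect_lt(abs(share - p), 3 * sqrt(p * (1 - p) / n))

  # duplicate_rate 0.5: measured duplicate fraction close to 0.5
  bias_dup <- make_bias_model(strains, yield_factor = c(1, 1),
                              duplicate_rate = 0.5, error_rate = 0)
  gd <- generate_reads(frags, design, bias_dup, barcode_map = bm,
                       n_reads = 20000, seed = 33)
  expect_lt(abs(mean(gd$truth$duplicate) - 0.5), 0.02)

  # strain with cells but no fragments is a hard error naming the strain
  expect_error(
    generate_reads(frags[frags$strain_id == "strain01", ], design, bias0,
                   barcode_map = bm, n_reads = 100, seed = 34),
    "strain02")

  # reproducibility: same seed, byte-identical output (FASTQ text included)
  g_a <- generate_reads(frags, design, bias0, barcode_map = bm, n_reads = 500,
                        seed = 35)
  g_b <- generate_reads(frags, design, bias0, barcode_map = bm, n_reads = 500,
                        seed = 35)
  expect_identical(g_a, g_b)
  d1 <- withr::local_tempdir()
  p1 <- write_fastq_pairs(g_a$reads, d1, "a")
  p2 <- write_fastq_pairs(g_b$reads, d1, "b")
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  expect_identical(readLines(p1[2]), readLines(p2[2]))
})

test_that("LM count simulation pushes truth through the confusion matrix", {
  strains <- c("A", "B")
  design <- data.frame(sample_id = "m", role = "mock", strain_id = strains,
                       cells = c(500, 500))
  id <- diag(2); dimnames(id) <- list(strains, strains)

  # identity confusion: expected counts proportional to composition
  n <- 200000
  cnt <- simulate_lm_counts(design, id, n_valves = n, seed = 4)
  expect_lt(abs(cnt[["A"]] / n - 0.5), 3 * sqrt(0.25 / n))

  # complete swap keeps 50/50 in expectation (symmetry)
  swap <- matrix(c(0, 1, 1, 0), 2, dimnames = list(strains, strains))
  cs <- simulate_lm_counts(design, swap, n_valves = n, seed = 5)
  expect_lt(abs(cs[["A"]] / n - 0.5), 3 * sqrt(0.25 / n))

  # 10% leak from A into absent strain B: E[B share] = 0.10 of A's mass
  dA <- data.frame(sample_id = "m", role = "mock", strain_id = "A",
                   cells = 1000)
  leak <- matrix(c(0.9, 0.1, 0, 1), 2, byrow = TRUE,
                 dimnames = list(strains, strains))
  cl <- simulate_lm_counts(dA, leak, n_valves = n, seed = 6)
  expect_lt(abs(cl[["B"]] / n - 0.10), 3 * sqrt(0.1 * 0.9 / n))
  expect_gt(cl[["B"]], 0)

  expect_error(simulate_lm_counts(
    data.frame(sample_id = "m", role = "mock", strain_id = "A", cells = 0),
    id, n_valves = 10), "zero total cells")
})

test_that("read shares follow the cells-by-yield law across designs", {
  set.seed(21)
  genomes <- toy_genomes(3)
  frags <- do.call(rbind, lapply(genomes, digest_genome))
  strains <- sprintf("strain%02d", 1:3)
  bias <- make_bias_model(strains, yield_factor = c(1, 3, 9),
                          duplicate_rate = 0, error_rate = 0)
  bm <- setNames(make_barcodes(1, seed = 9), "s")
  xs <- c(); ys <- c()
  for (rep in 1:12) {
    cells <- sample(200:2000, 3)
    design <- data.frame(sample_id = "s", role = "mock",
                         strain_id = strains, cells = cells)
    g <- generate_reads(frags, design, bias, barcode_map = bm,
                        n_reads = 100000)
    share <- table(factor(g$truth$strain_id, levels = strains)) /
      nrow(g$truth)
    w <- cells * bias$yield_factor
    xs <- c(xs, log(w / sum(w)))
    ys <- c(ys, log(as.numeric(share)))
  }
  slope <- unname(coef(lm(ys ~ xs))[2])
  expect_lt(abs(slope - 1), 0.05)
})
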