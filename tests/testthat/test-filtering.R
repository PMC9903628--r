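toy_counts <- function() {
  # 2 strains, 2 clusters each, hand-built monoclonal cross-mapping
  ref <- build_meta_reference(list(
    a = data.frame(centroid = c("AAAA", "CCCC"), member_count = 5L),
    b = data.frame(centroid = c("GGGG", "TTTT"), member_count = 5L)))
  designs <- data.frame(
    sample_id = c("monoA", "monoB", "mock01"),
    role = c("monoclonal", "monoclonal", "mock"),
    strain_id = c("a", "b", "a"), cells = 10)
  m <- matrix(c(100,  3, 20,    # a|cluster1
                 50, 60,  5,    # a|cluster2 (cross-attracting)
                  0, 80, 10,    # b|cluster1
                  2, 40,  0),   # b|cluster2
              nrow = 4, byrow = TRUE,
              dimnames = list(ref$cluster_id,
                              c("monoA", "monoB", "mock01")))
  m <- structure(m, strain = setNames(ref$strain_id, ref$cluster_id),
                 class = c("count_matrix", "matrix", "array"))
  list(ref = ref, designs = designs, matrix = m)
}

test_that("homology stats take target and non-target weights from monoclonals", {
  tc <- toy_counts()
  st <- compute_homology_stats(tc$matrix, tc$designs, tc$ref)
  expect_identical(st$cluster_id, rownames(tc$matrix))
  expect_equal(st$target_reads, c(100, 50, 80, 40))
  expect_equal(st$max_nontarget, c(3, 60, 0, 2))
  expect_identical(st$max_nontarget_strain, c("b", "b", NA, "a"))

  # cluster with reads only from its own strain has zero non-target weight
  expect_equal(st$max_nontarget[3], 0)

  # a strain without a monoclonal sample is a hard error
  expect_error(
    compute_homology_stats(tc$matrix,
                           tc$designs[tc$designs$sample_id != "monoB", ],
                           tc$ref),
    "monoclonal")
})

test_that("the three filter rules fire on their boundaries", {
  st <- data.frame(
    cluster_id = sprintf("c%d", 1:6),
    strain_id = "a",
    target_reads   = c(7,   8, 150, 150, 150, 10),
    max_nontarget  = c(0,   0,  11,   9, 200,  0),
    sum_nontarget  = c(0,   0,  11,   9, 200,  0),
    max_nontarget_strain = c(NA, NA, "b", "b", "b", NA),
    stringsAsFactors = FALSE)
  out <- filter_homologous(st)
  # target 7 -> rule 2; target 8 clean -> retained
  expect_identical(out$report$rule[out$report$cluster_id == "c1"], 2L)
  expect_true("c2" %in% out$retained)
  # 11/150 > 1/15 -> rule 3; 9/150 = 0.06 <= 1/15 -> retained
  expect_identical(out$report$rule[out$report$cluster_id == "c3"], 3L)
  expect_true("c4" %in% out$retained)
  # non-target > target -> rule 1 (fires first)
  expect_identical(out$report$rule[out$report$cluster_id == "c5"], 1L)
  expect_true("c6" %in% out$retained)

  # ratio exactly 1/15 is retained (removal requires strictly greater)
  st_edge <- data.frame(cluster_id = "e", strain_id = "a",
                        target_reads = 15, max_nontarget = 1,
                        sum_nontarget = 1, max_nontarget_strain = "b")
  expect_identical(filter_homologous(st_edge)$retained, "e")
})

test_that("filter matches a brute-force oracle on random stats tables", {
  set.seed(41)
  n <- 3000
  st <- data.frame(
    cluster_id = sprintf("c%05d", seq_len(n)),
    strain_id = sample(c("a", "b", "c"), n, TRUE),
    target_reads = sample(c(0:20, seq(25, 500, by = 25)), n, TRUE),
    max_nontarget = sample(c(0:15, seq(20, 400, by = 20)), n, TRUE),
    stringsAsFactors = FALSE)
  st$sum_nontarget <- st$max_nontarget + sample(0:5, n, TRUE)
  st$max_nontarget_strain <- ifelse(st$max_nontarget > 0, "z", NA)
  # include exact boundary cases
  st$target_reads[1:4] <- c(7, 8, 15, 15)
  st$max_nontarget[1:4] <- c(0, 0, 1, 2)

  out <- filter_homologous(st)
  removed_oracle <- r_filter_oracle(st$target_reads, st$max_nontarget)
  expect_identical(sort(out$retained),
                   sort(st$cluster_id[!removed_oracle]))

  # retained set is order-invariant (disjunction), report attribution ordered
  perm <- sample(n)
  out_perm <- filter_homologous(st[perm, ])
  expect_identical(sort(out_perm$retained), sort(out$retained))
  rep_match <- merge(out$report, out_perm$report, by = "cluster_id")
  expect_identical(rep_match$rule.x, rep_match$rule.y)

  # decreasing ratio_max never grows the retained set
  tighter <- filter_homologous(st, ratio_max = 1 / 30)
  expect_true(all(tighter$retained %in% out$retained))

  # sum aggregation removes at least as much as max aggregation
  summed <- filter_homologous(st, aggregate = "sum")
  expect_true(all(summed$retained %in% out$retained))
})

test_that("pairwise removal table attributes clusters to their attractor", {
  tc <- toy_counts()
  st <- compute_homology_stats(tc$matrix, tc$designs, tc$ref)
  out <- filter_homologous(st)
  # a|cluster2: 60 non-target from b > 50 target -> rule 1, cell [a, b]
  expect_identical(out$pairwise["a", "b"], 1L)
  # b|cluster2: target 40, non-target 2 from a; 2/40 <= 1/15 -> retained
  expect_true("b|cluster2" %in% out$retained)
  expect_identical(sum(out$pairwise), 1L)
})

test_that("target mapping rates and the QC gate behave at the extremes", {
  tc <- toy_counts()
  st <- compute_homology_stats(tc$matrix, tc$designs, tc$ref)
  keep <- filter_homologous(st)$retained
  m <- tc$matrix[keep, , drop = FALSE]
  m <- structure(m, strain = attr(tc$matrix, "strain")[keep],
                 class = c("count_matrix", "matrix", "array"))
  rates <- target_mapping_rate(m, tc$designs)
  expect_equal(rates[["monoA"]], 100 / 102)
  expect_equal(rates[["monoB"]], 120 / 123)

  # single-strain reference: rate exactly 1
  ref1 <- build_meta_reference(list(
    a = data.frame(centroid = "AAAA", member_count = 5L)))
  m1 <- structure(matrix(10, 1, 1, dimnames = list("a|cluster1", "monoA")),
                  strain = c("a|cluster1" = "a"),
                  class = c("count_matrix", "matrix", "array"))
  d1 <- data.frame(sample_id = "monoA", role = "monoclonal",
                   strain_id = "a", cells = 1)
  expect_equal(unname(target_mapping_rate(m1, d1)), 1)

  # identical twin strains: every cluster removed, QC gate raises
  ref2 <- build_meta_reference(list(
    a = data.frame(centroid = "AAAA", member_count = 5L),
    b = data.frame(centroid = "AAAA", member_count = 5L)))
  d2 <- data.frame(sample_id = c("monoA", "monoB"),
                   role = "monoclonal", strain_id = c("a", "b"), cells = 1)
  m2 <- matrix(c(5, 5, 5, 5), 2, byrow = TRUE,
               dimnames = list(ref2$cluster_id, c("monoA", "monoB")))
  m2 <- structure(m2, strain = setNames(ref2$strain_id, ref2$cluster_id),
                  class = c("count_matrix", "matrix", "array"))
  st2 <- compute_homology_stats(m2, d2, ref2)
  out2 <- filter_homologous(st2)
  expect_identical(length(out2$retained), 0L)
  m2f <- m2[out2$retained, , drop = FALSE]
  m2f <- structure(m2f, strain = character(0),
                   class = c("count_matrix", "matrix", "array"))
  expect_error(target_mapping_rate(m2f, d2, min_rate = 0.9),
               class = "gbsmix_qc_error")
})
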