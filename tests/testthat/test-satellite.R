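test_that("monomer scanner annotates exact and reverse-complement arrays", {
  set.seed(61)
  cons <- random_dna_str(181)
  ann <- annotate_monomers(strrep(cons, 5), cons)
  expect_equal(nrow(ann), 5L)
  expect_true(all(ann$edit == 0L))
  expect_true(all(ann$strand == "+"))
  expect_equal(ann$start, (0:4) * 181L)
  expect_equal(ann$end, (1:5) * 181L)

  rc <- tandemfill:::revcomp(cons)
  ann2 <- annotate_monomers(strrep(rc, 3), cons)
  expect_equal(nrow(ann2), 3L)
  expect_true(all(ann2$strand == "-"))
})

test_that("random sequence yields no monomer calls", {
  set.seed(62)
  cons <- random_dna_str(181)
  hits <- vapply(1:10, function(i) {
    nrow(annotate_monomers(random_dna_str(1500), cons))
  }, 0L)
  expect_true(all(hits == 0L))
})

test_that("mutated copies are all annotated with their edit distances", {
  set.seed(63)
  cons <- random_dna_str(181)
  arr <- paste(vapply(1:8, function(i) {
    tandemfill:::point_mutate(cons, 0.05)
  }, ""), collapse = "")
  ann <- annotate_monomers(arr, cons)
  expect_equal(nrow(ann), 8L)
  expect_true(all(ann$edit <= 0.25 * 181))
  expect_true(all(ann$edit > 0L))
})

test_that("consensus building and the variant profile count columns", {
  set.seed(64)
  cons <- random_dna_str(100)
  mono <- rep(cons, 10)
  # plant one substitution at column 5 in a single monomer
  old <- substr(cons, 5, 5)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  mono[3] <- paste0(substr(cons, 1, 4), new, substr(cons, 6, 100))
  expect_equal(build_consensus(mono), cons)
  vp <- variant_profile(mono, cons)
  expect_equal(vp[5], 0.1)
  expect_equal(sum(vp[-5]), 0)
  # identical monomers: all zero
  expect_true(all(variant_profile(rep(cons, 5), cons) == 0))
  # even split at a column: frequency 0.5, majority tie to the earlier base
  half <- c(rep(cons, 2), rep(mono[3], 2))
  vph <- variant_profile(half, cons)
  expect_equal(vph[5], 0.5)
  bc <- build_consensus(half)
  expect_equal(substr(bc, 5, 5), min(old, new))
})

test_that("HOR detection matches the definition on frozen cases", {
  set.seed(65)
  m <- random_dna_str(80)
  # six identical monomers: one period-3 HOR with two repeats
  h <- detect_hors(rep(m, 6))
  expect_equal(nrow(h), 1L)
  expect_equal(h$start_index, 1L)
  expect_equal(h$period, 3L)
  expect_equal(h$repeats, 2L)
  # a 6-edit difference at the duplicated position kills the HOR
  m4 <- tandemfill:::point_mutate(m, 0)  # same
  mono <- rep(m, 6)
  bad <- m
  for (i in 1:6) {
    pos <- 10 * i
    old <- substr(bad, pos, pos)
    substr(bad, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  mono[4] <- bad
  h2 <- detect_hors(mono)
  expect_false(any(h2$period == 3L & h2$start_index == 1L))
  # five monomers cannot hold two period-3 repeats
  expect_equal(nrow(detect_hors(rep(m, 5))), 0L)
})

test_that("HOR detection equals exhaustive enumeration on random cases", {
  set.seed(66)
  for (case in 1:15) {
    base <- vapply(1:3, function(i) random_dna_str(60), "")
    n <- sample(9:20, 1)
    mono <- vapply(1:n, function(i) {
      tandemfill:::point_mutate(base[(i - 1) %% 3 + 1], runif(1, 0, 0.08))
    }, "")
    got <- detect_hors(mono)
    got <- got[order(got$period, got$start_index),
               c("start_index", "period", "repeats")]
    want <- brute_hors(mono)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                 label = paste("case", case))
  }
})

test_that("planted (ABC)xk arrays give a period-3 HOR spanning all blocks", {
  set.seed(67)
  abc <- vapply(1:3, function(i) random_dna_str(181), "")
  mono <- vapply(1:12, function(i) {
    mutate_bounded(abc[(i - 1) %% 3 + 1], 2L)  # at most 2 edits per copy
  }, "")
  h <- detect_hors(mono)
  expect_true(any(h$period == 3L & h$span_start == 1L & h$span_end == 12L))
})

test_that("HOR scores divide membership by the region total", {
  hors <- data.frame(start_index = c(1L, 3L), period = c(3L, 3L),
                     repeats = c(2L, 2L), span_start = c(1L, 3L),
                     span_end = c(6L, 8L))
  sc <- hor_scores(10L, hors)
  expect_equal(sc[4], 0.2)   # inside both spans
  expect_equal(sc[9], 0)     # in none
  expect_equal(sc[1], 0.1)
})

test_that("strand bias fractions sum to one", {
  ann <- data.frame(strand = c("+", "+", "+", "-"))
  expect_equal(strand_bias(ann), c(plus = 0.75, minus = 0.25))
  expect_equal(strand_bias(data.frame(strand = rep("+", 4))),
               c(plus = 1, minus = 0))
})

test_that("monomer-set similarity is Jaccard on strand-canonical sequences", {
  a <- c("ACGTACGTAC", "GGGTTTGGGA")
  expect_equal(monomer_set_similarity(a, a), 1)
  expect_equal(monomer_set_similarity(a, c("CCCCCCCCAA")), 0)
  # 2 shared of 8 distinct
  b <- c(a, "TTTTGGGGCA", "ATATATATGC")
  d <- c(a, "CAGGCAGGAA", "CTCTCTCTAG", "AAAACCCCGT", "ACCCGGGTTA")
  expect_equal(monomer_set_similarity(b, d), 0.25)
  # reverse complements are the same monomer
  expect_equal(monomer_set_similarity("ACGTACGTAC",
                                      tandemfill:::revcomp("ACGTACGTAC")), 1)
  expect_equal(monomer_set_similarity(character(0), character(0)), 0)
})

test_that("region-local drift makes intra similarity exceed inter", {
  regions <- simulate_monomer_population(seed = 5)
  ex <- similarity_experiment(regions, "subtelomere", n_trials = 100,
                              seed = 5)
  med <- tapply(ex$similarity, ex$type, median)
  expect_gt(med[["intra"]], med[["inter"]])
  pv <- wilcox.test(similarity ~ type, data = ex)$p.value
  expect_lt(pv, 0.01)
})

test_that("region-mode experiment groups whole regions by genome", {
  regions <- simulate_monomer_population(n_regions = 4, seed = 9)
  # regions 1/2 from one group; intra compares them, inter crosses groups
  ex <- similarity_experiment(regions, "region", n_trials = 20, seed = 9,
                              groups = c("g1", "g1", "g2", "g2"))
  expect_equal(nrow(ex), 40L)
  expect_true(all(ex$similarity >= 0 & ex$similarity <= 1))
})
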