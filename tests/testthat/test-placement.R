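mk_contig_aln <- function(cid, clen, qs, qe, ts, te, strand = "+",
                          target = "ref", tlen = 100000L) {
  data.frame(query_id = cid, query_len = clen, query_start = qs,
             query_end = qe, strand = strand, target_id = target,
             target_len = tlen, target_start = ts, target_end = te,
             n_match = qe - qs, block_len = qe - qs, mapq = 60L,
             stringsAsFactors = FALSE)
}

test_that("contig filtering applies both alignment-length rules", {
  lens <- c(c1 = 10000L, c2 = 10000L, c3 = 10000L)
  aln <- rbind(
    mk_contig_aln("c1", 10000L, 0L, 500L, 1000L, 1500L),          # < 10%
    mk_contig_aln("c2", 10000L, 0L, 3000L, 1000L, 4000L),         # 3 kb TOI
    mk_contig_aln("c2", 10000L, 4000L, 6000L, 60000L, 62000L),    # 2 kb off
    mk_contig_aln("c3", 10000L, 0L, 3000L, 1000L, 4000L),         # 3 kb TOI
    mk_contig_aln("c3", 10000L, 4000L, 5000L, 60000L, 61000L))    # 1 kb off
  kept <- filter_contigs(lens, aln, "ref", 0L, 50000L)
  expect_equal(kept, "c3")  # c1 fails rule 1, c2 fails rule 2 (3 < 2*2)
})

test_that("LMS dynamic program handles identity, disjoint and swap cases", {
  expect_equal(lms_score(4, 4, function(i, j) i == j), 4L)
  expect_equal(lms_score(3, 3, function(i, j) FALSE), 0L)
  # A = [e1,e2,e3], B = [e2,e1,e3]: best common order has length 2
  b_of <- c(2L, 1L, 3L)
  expect_equal(lms_score(3, 3, function(i, j) i == b_of[j]), 2L)
})

test_that("LIS length matches frozen values and brute force", {
  expect_equal(lis_score(c(3, 1, 2, 5, 4)), 3L)
  expect_equal(lis_score(1:7), 7L)
  expect_equal(lis_score(c(2, 2, 2)), 3L)  # non-decreasing admits ties
  expect_equal(lis_score(integer(0)), 0L)
  set.seed(13)
  for (i in 1:25) {
    L <- sample.int(6, sample(1:9, 1), replace = TRUE)
    expect_equal(lis_score(L), brute_lis(L))
  }
})

test_that("candidate enumeration anchors, scores, merges and caps windows", {
  # one full-length alignment: a single candidate scoring its element count
  aln <- rbind(mk_contig_aln("c", 4000L, 0L, 2000L, 10000L, 12000L),
               mk_contig_aln("c", 4000L, 2000L, 4000L, 12000L, 14000L))
  cand <- enumerate_candidates("c", 4000L, aln, 50000L)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$score, 2L)
  expect_equal(cand$start, 10000)
  expect_equal(cand$strand, "+")

  # first element aligned at 3 loci: at most 3 windows before merging
  aln3 <- rbind(mk_contig_aln("c", 4000L, 0L, 2000L, 10000L, 12000L),
                mk_contig_aln("c", 4000L, 0L, 2000L, 30000L, 32000L),
                mk_contig_aln("c", 4000L, 0L, 2000L, 45000L, 47000L))
  cand3 <- enumerate_candidates("c", 4000L, aln3, 60000L)
  expect_lte(nrow(cand3), 3L)
  expect_gte(nrow(cand3), 1L)

  expect_equal(nrow(enumerate_candidates("c", 4000L, empty_paf(), 50000L)), 0L)
})

test_that("window LIS score never exceeds the LMS oracle", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    ref_starts <- sort(sample(seq(0, 8000, by = 400), n))
    c_starts <- sample(seq(0, 3600, by = 300), n)
    aln <- do.call(rbind, lapply(seq_len(n), function(i) {
      mk_contig_aln("c", 4000L, c_starts[i], c_starts[i] + 300L,
                    ref_starts[i], ref_starts[i] + 300L, tlen = 20000L)
    }))
    cand <- enumerate_candidates("c", 4000L, aln, 12000L)
    if (nrow(cand) == 0L) next
    # oracle: exact LMS between contig-ordered and reference-ordered elements
    ord_c <- order(c_starts, ref_starts)
    for (w in seq_len(nrow(cand))) {
      mid <- (ref_starts + 150)
      inside <- which(mid >= cand$start[w] & mid < cand$end[w])
      if (length(inside) == 0L) next
      ord_r <- inside[order(ref_starts[inside], c_starts[inside])]
      lms <- lms_score(n, length(ord_r),
                       function(i, j) ord_c[i] == ord_r[j])
      expect_lte(cand$score[w], lms)
    }
  }
})

test_that("coverage profile books depth classes, gaps and distances", {
  pl1 <- data.frame(contig_id = "c1", start = 0, end = 1000, midpoint = 500)
  pr <- coverage_profile(pl1, 1000)
  expect_equal(unname(pr$l["l1"]), 1000)
  expect_equal(sum(pr$l[c("l0", "l2", "l_gt2", "l_neg")]), 0)

  # two same-component contigs with a 100 bp gap: the gap is l_neg
  pl2 <- data.frame(contig_id = c("a", "b"), start = c(0, 500),
                    end = c(400, 1000), midpoint = c(200, 750))
  comp <- c(a = 1L, b = 1L)
  pr2 <- coverage_profile(pl2, 1000, comp)
  expect_equal(unname(pr2$l["l_neg"]), 100)
  expect_equal(unname(pr2$l["l0"]), 0)
  # different components: same gap is plain l0
  pr2b <- coverage_profile(pl2, 1000, c(a = 1L, b = 2L))
  expect_equal(unname(pr2b$l["l_neg"]), 0)
  expect_equal(unname(pr2b$l["l0"]), 100)

  # overlap counts as depth 2
  pl3 <- data.frame(contig_id = c("a", "b"), start = c(0, 300),
                    end = c(600, 1000), midpoint = c(300, 650))
  pr3 <- coverage_profile(pl3, 1000, comp)
  expect_equal(unname(pr3$l["l2"]), 300)
  expect_equal(pr3$d_sum, 350)
})

test_that("depth-class lengths always partition the TOI", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(0:5, 1)
    toi <- 5000
    pl <- if (n == 0) {
      data.frame(contig_id = character(0), start = numeric(0),
                 end = numeric(0), midpoint = numeric(0))
    } else {
      s <- sample(0:4000, n); e <- pmin(s + sample(500:3000, n, TRUE), toi)
      data.frame(contig_id = paste0("c", 1:n), start = s, end = e,
                 midpoint = (s + e) / 2)
    }
    pr <- coverage_profile(pl, toi)
    expect_equal(unname(pr$l["l0"] + pr$l["l_neg"] + pr$l["l1"] +
                          pr$l["l_ge2"]), toi)
  }
})

test_that("adaptivity reproduces the printed objective by substitution", {
  L <- 10000
  full <- coverage_profile(
    data.frame(contig_id = "c", start = 0, end = L, midpoint = L / 2), L)
  expect_equal(adaptivity(full, 1), 2 * L)
  empty <- coverage_profile(
    data.frame(contig_id = character(0), start = numeric(0),
               end = numeric(0), midpoint = numeric(0)), L)
  expect_equal(adaptivity(empty, 1), -2 * L)
  # diploid, two disjoint single-copy contigs covering everything:
  # l1 = L, d12 = |mid1 - mid2| -> f = -L + d12/... (half of the double sum)
  two <- coverage_profile(
    data.frame(contig_id = c("a", "b"), start = c(0, L / 2), end = c(L / 2, L),
               midpoint = c(L / 4, 3 * L / 4)), L)
  expect_equal(adaptivity(two, 2), -L + (L / 2) / 2)
  expect_error(adaptivity(full, 3), "ploidy")
})

test_that("adaptivity is invariant under contig relabeling", {
  set.seed(23)
  s <- sample(0:3000, 4); e <- s + 1500
  pl <- data.frame(contig_id = c("a", "b", "c", "d"), start = s, end = e,
                   midpoint = (s + e) / 2)
  comp <- setNames(c(1L, 1L, 2L, 2L), pl$contig_id)
  f1 <- adaptivity(coverage_profile(pl, 5000, comp), 2)
  perm <- pl[sample(4), ]
  comp2 <- setNames(unname(comp[perm$contig_id]), c("w", "x", "y", "z"))
  perm$contig_id <- c("w", "x", "y", "z")
  f2 <- adaptivity(coverage_profile(perm, 5000, comp2), 2)
  expect_equal(f1, f2)
})

test_that("GA finds the single perfect placement and brute-force optima", {
  L <- 10000
  cands <- list(c1 = data.frame(contig_id = "c1", start = 0, end = L,
                                strand = "+", score = 5L, midpoint = L / 2))
  ga <- run_ga(cands, L, 1, seed = 1)
  expect_equal(ga$fitness, 2 * L)
  expect_equal(ga$placements$contig_id, "c1")

  for (s in 1:5) {
    inst <- rand_placement_instance(s)
    ex <- exhaustive_placement(inst$cands, inst$toi_len, inst$ploidy, inst$comp)
    ga <- run_ga(inst$cands, inst$toi_len, inst$ploidy, inst$comp, seed = s)
    expect_equal(ga$fitness, ex$fitness, tolerance = 1e-9)
  }
})

test_that("a doubly-overlapping candidate is dropped in haploid mode", {
  L <- 6000
  cands <- list(
    base = data.frame(contig_id = "base", start = 0, end = L, strand = "+",
                      score = 9L, midpoint = L / 2),
    extra = data.frame(contig_id = "extra", start = c(1000, 2000),
                       end = c(4000, 5000), strand = "+", score = c(4L, 3L),
                       midpoint = c(2500, 3500)))
  ga <- run_ga(cands, L, 1, seed = 3)
  expect_false("extra" %in% ga$placements$contig_id)
})
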