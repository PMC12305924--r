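test_that("homology coefficients capture containment and disjointness", {
  set.seed(41)
  a <- random_dna_str(400)
  b <- substr(a, 1, 200)          # k-mer set of b is a subset of a's
  d <- random_dna_str(400)
  hom <- homology_coefficients(c(a = a, b = b, d = d), k = 31L)
  expect_equal(hom$H["a", "a"], 1)
  expect_equal(hom$H["a", "b"], 1)  # denominator is the smaller set
  expect_lt(hom$H["a", "d"], 0.05)
  expect_true(isSymmetric(hom$H))
  # contig shorter than k has an empty set and zero coefficient
  hom2 <- homology_coefficients(c(a = a, tiny = "ACGT"), k = 31L)
  expect_equal(hom2$H["a", "tiny"], 0)
})

test_that("h_bar averages the non-zero off-diagonal coefficients", {
  set.seed(42)
  a <- random_dna_str(300)
  hom <- homology_coefficients(c(a = a, b = a, d = random_dna_str(300)), 31L)
  off <- hom$H[upper.tri(hom$H)]
  expect_equal(hom$h_bar, mean(off[off > 0]))
})

test_that("Hi-C pairs anchor by unique k-mers; ambiguity drops the pair", {
  set.seed(43)
  shore <- c(shoreM = random_dna_str(300))
  rep_unit <- random_dna_str(40)
  contigs <- c(
    cX = paste0(random_dna_str(150), strrep(rep_unit, 4)),
    cY = paste0(random_dna_str(150), strrep(rep_unit, 4)))
  pairs <- data.frame(
    read_id = c("p1", "p2", "p3"),
    seq1 = c(substr(shore[["shoreM"]], 50, 149),   # unique to shoreM
             substr(shore[["shoreM"]], 50, 149),
             paste0(substr(contigs[["cX"]], 50, 99),   # unique kmers of BOTH
                    substr(contigs[["cY"]], 50, 99))), # -> ambiguous end
    seq2 = c(substr(contigs[["cX"]], 30, 129),     # unique to cX
             strrep(rep_unit, 3),                  # repeat-only: unlocatable
             substr(contigs[["cX"]], 30, 129)),
    stringsAsFactors = FALSE)
  HIC <- unique_kmer_hic_signals(contigs, shore, pairs, k = 31L)
  expect_equal(HIC["shoreM", "cX"], 1L)   # p1 only
  expect_equal(HIC["cX", "shoreM"], 1L)
  expect_equal(sum(HIC), 2L)              # p2 and p3 dropped
})

test_that("HiFi links add one count per read and unordered contig pair", {
  aln <- data.frame(query_id = c("r1", "r1", "r2", "r3", "r3", "r3", "r1"),
                    target_id = c("c1", "c2", "c1", "c1", "c2", "c3", "c1"))
  HIFI <- hifi_link_signals(aln, c("c1", "c2", "c3"))
  expect_equal(HIFI["c1", "c2"], 2L)  # r1 and r3 (duplicate r1-c1 ignored)
  expect_equal(HIFI["c1", "c3"], 1L)
  expect_equal(HIFI["c2", "c3"], 1L)
  expect_true(isSymmetric(HIFI))
  expect_equal(sum(diag(HIFI)), 0L)
})

test_that("phasing objective matches an independent literal evaluation", {
  M <- rand_signal_matrices(7, n_contigs = 4L)
  literal <- function(state) {
    mat_c <- M$contig_ids[state %in% c(1, 3)]
    pat_c <- M$contig_ids[state %in% c(2, 3)]
    mat_s <- names(M$shore_hap)[M$shore_hap == "maternal"]
    pat_s <- names(M$shore_hap)[M$shore_hap == "paternal"]
    t1 <- 0
    for (i in mat_s) for (j in mat_c) {
      t1 <- t1 + M$HIC[i, j] / (M$L[i] * M$L[j] * M$D[i, j])
    }
    for (i in pat_s) for (j in pat_c) {
      t1 <- t1 + M$HIC[i, j] / (M$L[i] * M$L[j] * M$D[i, j])
    }
    t2 <- 0
    pair_sum <- function(set) {
      s <- 0
      if (length(set) > 1) {
        for (ii in 1:(length(set) - 1)) for (jj in (ii + 1):length(set)) {
          i <- set[ii]; j <- set[jj]
          s <- s + (M$h_bar - M$H[i, j]) * M$HIFI[i, j] / (M$L[i] * M$L[j])
        }
      }
      s
    }
    t2 <- pair_sum(mat_c) + pair_sum(pat_c)
    t3 <- abs(sum(M$L[mat_c]) - sum(M$L[pat_c])) / M$l_toi_ref
    unname(M$c1 * t1 + M$c2 * t2 - M$c3 * t3)
  }
  set.seed(44)
  for (i in 1:10) {
    st <- sample(0:3, 4, replace = TRUE)
    expect_equal(phasing_objective(st, M), literal(st), tolerance = 1e-12)
  }
})

test_that("objective degenerate cases follow from substitution", {
  M <- rand_signal_matrices(8, n_contigs = 3L)
  # everything discarded: empty sums and zero length difference
  expect_equal(phasing_objective(c(0L, 0L, 0L), M), 0)
  # no signals, one maternal contig: only the balance penalty remains
  M0 <- M
  M0$HIC[] <- 0L; M0$HIFI[] <- 0L
  st <- c(1L, 0L, 0L)
  expect_equal(phasing_objective(st, M0),
               -M0$c3 * M0$L[M0$contig_ids[1]] / M0$l_toi_ref,
               ignore_attr = TRUE)
  expect_error(phasing_objective(c(1L, 2L), M), "length")
})

test_that("objective is invariant under a global maternal/paternal swap", {
  M <- rand_signal_matrices(9)
  swap_M <- M
  swap_M$shore_hap <- c(shoreM = "paternal", shoreP = "maternal")
  set.seed(45)
  for (i in 1:10) {
    st <- sample(0:3, length(M$contig_ids), replace = TRUE)
    st_sw <- st
    st_sw[st == 1L] <- 2L
    st_sw[st == 2L] <- 1L
    expect_equal(phasing_objective(st, M), phasing_objective(st_sw, swap_M),
                 tolerance = 1e-12)
  }
})

test_that("single-contig annealing matches four-state enumeration", {
  M <- rand_signal_matrices(10, n_contigs = 1L)
  best <- which.max(vapply(0:3, function(s) phasing_objective(s, M), 0)) - 1L
  ann <- run_annealing(M, n_restarts = 50L, seed = 1)
  expect_equal(unname(ann$state), best)
})

test_that("annealing equals exhaustive search on small instances", {
  for (s in 1:4) {
    M <- rand_signal_matrices(s, n_contigs = 5L)
    ex <- exhaustive_phasing(M)
    ann <- run_annealing(M, n_restarts = 100L, seed = s)
    expect_equal(ann$objective, ex$objective, tolerance = 1e-9)
  }
})

test_that("scaffolds join placed contigs with Ns in reference order", {
  contigs <- c(a = "AAAA", b = "CCCC")
  pl <- data.frame(contig_id = c("a", "b"), start = c(0, 500), strand = "+")
  sc <- build_scaffolds(pl, c(a = 1L, b = 1L), contigs, gap_n = 2L)
  expect_equal(unname(sc["maternal"]), "AAAANNCCCC")
  expect_equal(unname(sc["paternal"]), "")
  # single contig is emitted as itself; reverse placements are revcomped
  sc2 <- build_scaffolds(pl[1, ], c(a = 2L), contigs, gap_n = 2L)
  expect_equal(unname(sc2["paternal"]), "AAAA")
  pl3 <- data.frame(contig_id = "b", start = 0, strand = "-")
  sc3 <- build_scaffolds(pl3, c(b = 1L), contigs, gap_n = 2L)
  expect_equal(unname(sc3["maternal"]), "GGGG")
  # collapsed contigs appear in both haplotypes
  sc4 <- build_scaffolds(pl, c(a = 3L, b = 1L), contigs, gap_n = 1L)
  expect_equal(unname(sc4["paternal"]), "AAAA")
  expect_equal(unname(sc4["maternal"]), "AAAANCCCC")
})

test_that("shore trimming removes exactly the terminal aligned blocks", {
  set.seed(46)
  core <- random_dna_str(2000)
  left <- random_dna_str(1000)
  right <- random_dna_str(800)
  scaffold <- paste0(left, core, right)
  n <- nchar(scaffold)
  aln <- data.frame(
    query_id = "scf", query_len = n,
    query_start = c(0L, 3000L), query_end = c(1000L, n),
    strand = "+", target_id = c("shoreL", "shoreR"),
    target_len = c(1000L, 800L), target_start = 0L,
    target_end = c(1000L, 800L),
    n_match = c(1000L, 800L), block_len = c(1000L, 800L), mapq = 60L)
  expect_equal(trim_shores(scaffold, aln), core)
  # no shore alignment: unchanged
  expect_equal(trim_shores(scaffold, aln[0, ]), scaffold)
  # internal-only alignment: unchanged
  internal <- transform(aln[1, ], query_start = 1500L, query_end = 2500L)
  expect_equal(trim_shores(scaffold, internal), scaffold)
  # low identity blocks are ignored
  weak <- transform(aln, n_match = as.integer(0.5 * n_match))
  expect_equal(trim_shores(scaffold, weak), scaffold)
})
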