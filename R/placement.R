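#' Filter spurious contigs by their reference alignments
#'
#' A contig assembled from wrongly recalled reads is discarded when either
#' (1) its TOI-aligned length is shorter than 10% of the contig length, or
#' (2) its total TOI-aligned length is less than twice its total aligned
#' length elsewhere on the reference genome.
#'
#' @param contig_lens Named integer vector of contig lengths.
#' @param alignments data.frame of contig-vs-reference alignments (whole
#'   genome, not just the TOI).
#' @param toi_chrom,toi_start,toi_end The reference TOI interval
#'   (0-based half-open). An alignment is TOI-aligned when its target
#'   midpoint falls inside this interval.
#' @param min_toi_frac Minimum TOI-aligned fraction of the contig length.
#' @param off_target_ratio Required ratio of TOI-aligned to off-TOI bp.
#' @return Character vector of retained contig ids.
#' @export
filter_contigs <- function(contig_lens, alignments, toi_chrom, toi_start,
                           toi_end, min_toi_frac = 0.10,
                           off_target_ratio = 2) {
  keep <- character(0)
  mid <- (alignments$target_start + alignments$target_end) / 2
  on_toi <- alignments$target_id == toi_chrom & mid >= toi_start & mid < toi_end
  qspan <- alignments$query_end - alignments$query_start
  for (cid in names(contig_lens)) {
    rows <- alignments$query_id == cid
    toi_bp <- sum(qspan[rows & on_toi])
    off_bp <- sum(qspan[rows & !on_toi])
    if (toi_bp >= min_toi_frac * contig_lens[[cid]] &&
        toi_bp >= off_target_ratio * off_bp) {
      keep <- c(keep, cid)
    }
  }
  keep
}

#' Exact longest matching subsequence (DP oracle)
#'
#' Quadratic dynamic program over two element sequences and an arbitrary
#' matching predicate; used as the exact oracle that the faster LIS
#' approximation is checked against.
#'
#' @param n_a,n_b Lengths of the two element sequences.
#' @param match_fn `function(i, j)` returning `TRUE` when element `i` of A
#'   matches element `j` of B.
#' @return Integer LMS length.
#' @export
lms_score <- function(n_a, n_b, match_fn) {
  if (n_a == 0L || n_b == 0L) return(0L)
  dp <- matrix(0L, n_a + 1L, n_b + 1L)
  for (i in seq_len(n_a)) {
    for (j in seq_len(n_b)) {
      best <- max(dp[i, j + 1L], dp[i + 1L, j])
      if (isTRUE(match_fn(i, j))) best <- max(best, dp[i, j] + 1L)
      dp[i + 1L, j + 1L] <- best
    }
  }
  dp[n_a + 1L, n_b + 1L]
}

#' Longest non-decreasing subsequence length
#'
#' Patience-sorting algorithm (binary search on the tails vector), `O(M log
#' M)`. Non-decreasing: ties extend the subsequence.
#'
#' @param L Integer vector (the coordinate sequence of chained elements).
#' @return Integer LIS length (`0` for empty input).
#' @export
lis_score <- function(L) {
  if (length(L) == 0L) return(0L)
  tails <- numeric(0)
  for (x in L) {
    # first tail strictly greater than x gets replaced (non-decreasing LIS)
    pos <- findInterval(x, tails) + 1L  # tails <= x count, then next slot
    if (pos > length(tails)) tails <- c(tails, x) else tails[pos] <- x
  }
  length(tails)
}

# Elements of one contig from its TOI alignments, in TOI-local coordinates.
# Minus-strand contig coordinates are mapped onto the reverse-complemented
# contig so that chain order is consistent for either orientation.
contig_elements <- function(alignments, contig_len, toi_start = 0L) {
  el <- data.frame(
    ref_start = alignments$target_start - toi_start,
    ref_end = alignments$target_end - toi_start,
    c_start = alignments$query_start,
    c_end = alignments$query_end,
    strand = alignments$strand,
    stringsAsFactors = FALSE
  )
  el$oc_start <- ifelse(el$strand == "+", el$c_start, contig_len - el$c_end)
  el$oc_end <- ifelse(el$strand == "+", el$c_end, contig_len - el$c_start)
  el$ref_mid <- (el$ref_start + el$ref_end) / 2
  el[order(el$oc_start, el$ref_start), , drop = FALSE]
}

# LIS chain score of the elements inside one candidate window, under the
# majority strand of those elements.
window_chain_score <- function(el, wstart, wend) {
  inside <- el$ref_mid >= wstart & el$ref_mid < wend
  win <- el[inside, , drop = FALSE]
  if (nrow(win) == 0L) return(list(score = 0L, strand = "+"))
  strand <- if (mean(win$strand == "+") >= 0.5) "+" else "-"
  # L_c rank: all contig elements ordered by oriented contig start
  ord_c <- order(el$oc_start, el$ref_start)
  rank_c <- match(seq_len(nrow(el)), ord_c)
  win_idx <- which(inside)
  ord_r <- order(win$ref_start, win$oc_start)
  L <- rank_c[win_idx][ord_r]
  list(score = lis_score(L), strand = strand)
}

#' Enumerate candidate placements for one contig
#'
#' Every element anchors a window of length equal to the contig length
#' (placed so the element aligns at its contig offset, clipped at the TOI
#' ends). Each window is scored by the longest non-decreasing chain (LIS) of
#' its elements ordered by reference position against the contig-order
#' ranks; windows overlapping more than `merge_frac` are merged keeping the
#' best, and the top `max_candidates` by score are returned (ties by
#' leftmost start).
#'
#' @param contig_id Contig identifier.
#' @param contig_len Contig length (bp).
#' @param alignments Contig-vs-reference-TOI alignments of this contig.
#' @param toi_len Length of the reference TOI.
#' @param toi_start Offset of the TOI on the alignment target (0 when the
#'   target is the TOI itself).
#' @param max_candidates Maximum number of candidate subregions kept.
#' @param merge_frac Windows overlapping more than this fraction of the
#'   contig length are considered the same locus.
#' @return data.frame of candidate placements: `contig_id, start, end,
#'   strand, score, midpoint`.
#' @export
enumerate_candidates <- function(contig_id, contig_len, alignments, toi_len,
                                 toi_start = 0L, max_candidates = 7L,
                                 merge_frac = 0.5) {
  empty <- data.frame(contig_id = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      score = integer(0), midpoint = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(alignments) == 0L) return(empty)
  el <- contig_elements(alignments, contig_len, toi_start)
  wlen <- min(contig_len, toi_len)
  anchors <- unique(pmin(pmax(el$ref_start - el$oc_start, 0), toi_len - wlen))
  cand <- lapply(anchors, function(ws) {
    sc <- window_chain_score(el, ws, ws + wlen)
    data.frame(contig_id = contig_id, start = ws, end = ws + wlen,
               strand = sc$strand, score = sc$score,
               midpoint = ws + wlen / 2, stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand)
  cand <- cand[cand$score > 0L, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(-cand$score, cand$start), , drop = FALSE]
  # merge windows that overlap > merge_frac of the window length: keep best
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ov <- FALSE
    for (j in kept) {
      inter <- min(cand$end[i], cand$end[j]) - max(cand$start[i], cand$start[j])
      if (inter > merge_frac * wlen) { ov <- TRUE; break }
    }
    if (!ov) kept <- c(kept, i)
    if (length(kept) >= max_candidates) break
  }
  out <- cand[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage profile of a set of placements on the reference TOI
#'
#' Computes the piecewise-constant depth of the placed windows, the total
#' length `l_t` at each depth, the split of zero-depth length into `l_0`
#' and `l_neg` (zero-depth stretches whose nearest placed neighbours on both
#' sides belong to the same contig-graph component, which should not exist
#' and are penalised harder), and the pairwise midpoint distances.
#'
#' @param placements data.frame with columns `contig_id, start, end,
#'   midpoint` (and optionally `component`).
#' @param toi_len Reference TOI length.
#' @param components Named vector mapping contig id to component label
#'   (used for the `l_neg` rule; unknown ids never match).
#' @return List with `l` (named vector of depth-class lengths: `l0, l1, l2,
#'   l_gt2, l_ge2, l_neg`), `d_sum` (sum of pairwise midpoint distances) and
#'   `n_placed`.
#' @export
coverage_profile <- function(placements, toi_len, components = NULL) {
  C <- nrow(placements)
  if (C == 0L) {
    return(list(l = c(l0 = toi_len, l1 = 0, l2 = 0, l_gt2 = 0, l_ge2 = 0,
                      l_neg = 0), d_sum = 0, n_placed = 0L))
  }
  s <- pmax(placements$start, 0)
  e <- pmin(placements$end, toi_len)
  bp <- sort(unique(c(0, toi_len, s, e)))
  seg_s <- head(bp, -1L); seg_e <- tail(bp, -1L)
  depth <- vapply(seq_along(seg_s), function(i) {
    sum(s <= seg_s[i] & e >= seg_e[i])
  }, 0L)
  seg_len <- seg_e - seg_s

  comp_of <- function(ids) {
    if (is.null(components)) return(rep(NA, length(ids)))
    unname(components[ids])
  }
  l_neg <- 0
  l0 <- 0
  for (i in which(depth == 0L)) {
    # nearest placed neighbours left and right of the zero-depth stretch
    lefts <- which(e <= seg_s[i])
    rights <- which(s >= seg_e[i])
    same_comp <- FALSE
    if (length(lefts) && length(rights)) {
      lmax <- max(e[lefts]); rmin <- min(s[rights])
      lc <- comp_of(placements$contig_id[lefts][e[lefts] == lmax])
      rc <- comp_of(placements$contig_id[rights][s[rights] == rmin])
      same_comp <- length(intersect(lc[!is.na(lc)], rc[!is.na(rc)])) > 0L
    }
    if (same_comp) l_neg <- l_neg + seg_len[i] else l0 <- l0 + seg_len[i]
  }
  l <- c(l0 = l0,
         l1 = sum(seg_len[depth == 1L]),
         l2 = sum(seg_len[depth == 2L]),
         l_gt2 = sum(seg_len[depth > 2L]),
         l_ge2 = sum(seg_len[depth >= 2L]),
         l_neg = l_neg)
  mids <- placements$midpoint
  d_sum <- if (C > 1L) sum(dist(mids)) else 0
  list(l = l, d_sum = d_sum, n_placed = C)
}

#' Adaptivity (fitness) of a placement set
#'
#' The genetic algorithm's objective: for a haploid target,
#' `2*(l1 - l0 - l_gt2) + l2 - 2.5*l_neg + d_sum/2`; for a diploid target,
#' `2*(l_ge2 - l0) - l1 - 2.5*l_neg + d_sum/2`. The coverage terms push the
#' placements to tile the TOI exactly `ploidy` times; the distance term
#' spreads the placed contigs apart.
#'
#' @param profile A coverage profile from [coverage_profile()].
#' @param ploidy 1 or 2.
#' @return Numeric fitness.
#' @export
adaptivity <- function(profile, ploidy) {
  l <- profile$l
  if (ploidy == 1) {
    2 * (l[["l1"]] - l[["l0"]] - l[["l_gt2"]]) + l[["l2"]] -
      2.5 * l[["l_neg"]] + profile$d_sum / 2
  } else if (ploidy == 2) {
    2 * (l[["l_ge2"]] - l[["l0"]]) - l[["l1"]] -
      2.5 * l[["l_neg"]] + profile$d_sum / 2
  } else {
    stop("ploidy must be 1 or 2")
  }
}

# Fitness of one GA assignment (integer vector over contigs; 0 = unplaced).
assignment_fitness <- function(assignment, candidates_by_contig, toi_len,
                               ploidy, components) {
  placed <- which(assignment > 0L)
  if (length(placed) == 0L) {
    return(adaptivity(coverage_profile(
      data.frame(contig_id = character(0), start = numeric(0),
                 end = numeric(0), midpoint = numeric(0)), toi_len,
      components), ploidy))
  }
  rows <- lapply(placed, function(i) {
    candidates_by_contig[[i]][assignment[i], , drop = FALSE]
  })
  pl <- do.call(rbind, rows)
  adaptivity(coverage_profile(pl, toi_len, components), ploidy)
}

#' Select contig placements with a genetic algorithm
#'
#' Individuals assign each contig either one of its candidate placements or
#' leave it unplaced. Each generation: fitness-proportional selection of
#' `n_select` parents (fitness shifted so the minimum maps to a small
#' positive weight), offspring produced by swapping the two parents'
#' alleles at one random shared locus until `n_offspring` exist, per-offspring
#' mutation with probability `p_mut` (delete a random placed contig or
#' insert a random unplaced one at a random candidate), and replenishment
#' with fresh random individuals back to `pop_size`. Terminates when the
#' `top_eq` best fitnesses coincide or after `max_gen` generations; the best
#' individual ever seen is returned.
#'
#' @param candidates_by_contig Named list (one entry per contig) of
#'   candidate data.frames from [enumerate_candidates()].
#' @param toi_len Reference TOI length.
#' @param ploidy 1 or 2.
#' @param components Named vector mapping contig id to component label.
#' @param seed Integer seed; the run is fully reproducible.
#' @param pop_size,n_select,n_offspring,p_mut,max_gen,top_eq GA parameters.
#' @return List with `assignment` (named integer vector; 0 = unplaced),
#'   `placements` (data.frame of the chosen candidates), `fitness`, and
#'   `generations` run.
#' @export
run_ga <- function(candidates_by_contig, toi_len, ploidy, components = NULL,
                   seed = 1L, pop_size = 500L, n_select = 60L,
                   n_offspring = 300L, p_mut = 0.05, max_gen = 200L,
                   top_eq = 10L) {
  n_cand <- vapply(candidates_by_contig, nrow, 0L)
  if (all(n_cand == 0L)) stop("no candidate placements for any contig")
  contigs <- names(candidates_by_contig)
  nc <- length(contigs)
  set.seed(seed)

  random_ind <- function() {
    vapply(seq_len(nc), function(i) sample.int(n_cand[i] + 1L, 1L) - 1L, 0L)
  }
  cache <- new.env(hash = TRUE, parent = emptyenv())
  fit_of <- function(a) {
    key <- paste(a, collapse = ",")
    f <- cache[[key]]
    if (is.null(f)) {
      f <- assignment_fitness(a, candidates_by_contig, toi_len, ploidy,
                              components)
      cache[[key]] <- f
    }
    f
  }

  pop <- replicate(pop_size, random_ind(), simplify = FALSE)
  best <- NULL; best_fit <- -Inf
  gen <- 0L
  repeat {
    gen <- gen + 1L
    fit <- vapply(pop, fit_of, 0)
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best <- pop[[which.max(fit)]]
    }
    top <- sort(fit, decreasing = TRUE)[seq_len(min(top_eq, length(fit)))]
    if ((length(top) >= top_eq && diff(range(top)) < 1e-9) || gen >= max_gen) break

    w <- fit - min(fit)
    w <- w + max(max(w), 1) * 1e-6
    parents <- pop[sample.int(length(pop), n_select, replace = TRUE, prob = w)]

    offspring <- vector("list", n_offspring)
    made <- 0L
    while (made < n_offspring) {
      pr <- sample.int(n_select, 2L, replace = FALSE)
      a <- parents[[pr[1]]]; b <- parents[[pr[2]]]
      locus <- sample.int(nc, 1L)
      tmp <- a[locus]; a[locus] <- b[locus]; b[locus] <- tmp
      for (child in list(a, b)) {
        if (made >= n_offspring) break
        if (runif(1) < p_mut) {
          placed <- which(child > 0L)
          unplaced <- which(child == 0L & n_cand > 0L)
          do_delete <- length(placed) > 0L &&
            (length(unplaced) == 0L || runif(1) < 0.5)
          if (do_delete) {
            child[placed[sample.int(length(placed), 1L)]] <- 0L
          } else if (length(unplaced) > 0L) {
            i <- unplaced[sample.int(length(unplaced), 1L)]
            child[i] <- sample.int(n_cand[i], 1L)
          }
        }
        made <- made + 1L
        offspring[[made]] <- child
      }
    }
    fresh <- replicate(pop_size - n_select - n_offspring, random_ind(),
                       simplify = FALSE)
    pop <- c(parents, offspring, fresh)
  }

  assignment <- setNames(best, contigs)
  placed <- which(assignment > 0L)
  placements <- if (length(placed)) {
    do.call(rbind, lapply(placed, function(i) {
      candidates_by_contig[[i]][assignment[i], , drop = FALSE]
    }))
  } else {
    data.frame(contig_id = character(0), start = numeric(0), end = numeric(0),
               strand = character(0), score = integer(0), midpoint = numeric(0))
  }
  rownames(placements) <- NULL
  list(assignment = assignment, placements = placements,
       fitness = best_fit, generations = gen)
}

#' Exhaustive search over all placement assignments
#'
#' Brute-force optimum for small instances; the oracle the genetic
#' algorithm is validated against.
#'
#' @inheritParams run_ga
#' @return List with `assignment` and `fitness` of the global optimum.
#' @export
exhaustive_placement <- function(candidates_by_contig, toi_len, ploidy,
                                 components = NULL) {
  n_cand <- vapply(candidates_by_contig, nrow, 0L)
  grid <- expand.grid(lapply(n_cand, function(k) 0:k))
  best <- NULL; best_fit <- -Inf
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    f <- assignment_fitness(a, candidates_by_contig, toi_len, ploidy,
                            components)
    if (f > best_fit) { best_fit <- f; best <- a }
  }
  list(assignment = setNames(best, names(candidates_by_contig)),
       fitness = best_fit)
}
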