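#' Pairwise homology coefficients between contigs
#'
#' `h_ij = |S_i intersect S_j| / min(|S_i|, |S_j|)` where `S_i` is the set
#' of distinct canonical k-mers of contig `i`. The global coefficient
#' `h_bar` is the mean of the non-zero off-diagonal values (0 if none).
#' Contigs shorter than `k` have an empty set and coefficient 0 against
#' everything.
#'
#' @param contigs Named character vector of contig sequences.
#' @param k k-mer length.
#' @return List with `H` (symmetric matrix, unit diagonal where defined) and
#'   `h_bar`.
#' @export
homology_coefficients <- function(contigs, k = 31L) {
  n <- length(contigs)
  stopifnot(n >= 2L)
  sets <- lapply(contigs, kmer_set, k = k)
  H <- matrix(0, n, n, dimnames = list(names(contigs), names(contigs)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      denom <- min(length(sets[[i]]), length(sets[[j]]))
      h <- if (denom == 0L) 0 else length(intersect(sets[[i]], sets[[j]])) / denom
      H[i, j] <- H[j, i] <- h
    }
  }
  off <- H[upper.tri(H)]
  h_bar <- if (any(off > 0)) mean(off[off > 0]) else 0
  list(H = H, h_bar = h_bar)
}

#' Hi-C signal matrix from unique k-mer anchoring
#'
#' Hi-C read ends are located on contigs and shores by their unique k-mers
#' (canonical k-mers occurring exactly once across all contigs and shores
#' combined) rather than by alignment. A pair contributes +1 to
#' `HIC[a, b]` iff one end contains unique k-mers of sequence `a` only and
#' the other of sequence `b` only; ends hitting unique k-mers of several
#' sequences (ambiguous) or none (unlocatable) drop the pair.
#'
#' @param contigs,shores Named character vectors (ids must be distinct).
#' @param hic_pairs data.frame with columns `seq1, seq2` (end sequences).
#' @param k k-mer length.
#' @return Symmetric integer matrix over shores and contigs.
#' @export
unique_kmer_hic_signals <- function(contigs, shores, hic_pairs, k = 31L) {
  seqs <- c(shores, contigs)
  if (anyDuplicated(names(seqs))) stop("contig and shore ids must be distinct")
  per_seq <- lapply(seqs, function(s) as.character(seq_kmers(s, k)))
  occ_km <- unlist(per_seq, use.names = FALSE)
  occ_owner <- rep.int(seq_along(seqs), lengths(per_seq))
  # unique k-mers: those occurring exactly once over all contigs and shores
  dup1 <- duplicated(occ_km)
  dup_any <- occ_km %in% occ_km[dup1]
  uniq_km <- occ_km[!dup_any]
  uniq_owner <- occ_owner[!dup_any]

  HIC <- matrix(0L, length(seqs), length(seqs),
                dimnames = list(names(seqs), names(seqs)))
  n_pairs <- nrow(hic_pairs)
  if (n_pairs == 0L) return(HIC)
  # locate all ends at once against the unique-k-mer index; the ends are
  # concatenated with N separators so one k-mer scan covers them all
  # (separator-spanning k-mers contain N and drop out)
  end_seqs <- c(hic_pairs$seq1, hic_pairs$seq2)
  concat <- paste(end_seqs, collapse = "N")
  km <- seq_kmers(concat, k)
  starts <- cumsum(c(1L, nchar(end_seqs[-length(end_seqs)]) + 1L))
  e_idx <- findInterval(attr(km, "pos"), starts)
  hit_owner <- uniq_owner[match(as.character(km), uniq_km)]
  ok <- !is.na(hit_owner)
  grp <- split(hit_owner[ok], e_idx[ok])
  own <- rep(NA_integer_, 2L * n_pairs)
  one <- vapply(grp, function(v) {
    if (all(v == v[1L])) v[1L] else NA_integer_   # ambiguous end -> drop
  }, 0L)
  own[as.integer(names(grp))] <- one
  a <- own[seq_len(n_pairs)]
  b <- own[n_pairs + seq_len(n_pairs)]
  keep <- which(!is.na(a) & !is.na(b))
  for (r in keep) {
    HIC[a[r], b[r]] <- HIC[a[r], b[r]] + 1L
    if (a[r] != b[r]) HIC[b[r], a[r]] <- HIC[b[r], a[r]] + 1L
  }
  HIC
}

#' HiFi linkage matrix between contigs
#'
#' A recalled read aligning to contigs `i` and `j` (`i != j`) adds +1 to
#' `HIFI[i, j]`, once per read and unordered pair.
#'
#' @param read_alignments data.frame of read-vs-contig alignments
#'   (`query_id` = read, `target_id` = contig).
#' @param contig_ids Character vector fixing the matrix dimensions.
#' @return Symmetric integer matrix over contigs.
#' @export
hifi_link_signals <- function(read_alignments, contig_ids) {
  HIFI <- matrix(0L, length(contig_ids), length(contig_ids),
                 dimnames = list(contig_ids, contig_ids))
  if (nrow(read_alignments) == 0L) return(HIFI)
  by_read <- split(read_alignments$target_id, read_alignments$query_id)
  for (tg in by_read) {
    tg <- unique(tg)
    tg <- tg[tg %in% contig_ids]
    if (length(tg) < 2L) next
    prs <- utils::combn(tg, 2L)
    for (c2 in seq_len(ncol(prs))) {
      i <- prs[1, c2]; j <- prs[2, c2]
      HIFI[i, j] <- HIFI[i, j] + 1L
      HIFI[j, i] <- HIFI[j, i] + 1L
    }
  }
  HIFI
}

#' Assemble the signal matrices that feed the phasing objective
#'
#' @param contigs Named character vector of contig sequences.
#' @param shores Named character vector of shore sequences.
#' @param shore_hap Named vector over shores with values `"maternal"` /
#'   `"paternal"`.
#' @param shore_pos Named numeric vector: inner boundary of each shore on
#'   reference-TOI coordinates (e.g. 0 for a left shore, TOI length for a
#'   right shore).
#' @param placements data.frame with `contig_id` and `midpoint` (reference
#'   TOI coordinates) for every contig.
#' @param hic_pairs Hi-C pairs (see [unique_kmer_hic_signals()]).
#' @param read_alignments Read-vs-contig alignments (see
#'   [hifi_link_signals()]).
#' @param l_toi_ref Reference TOI length (normalises the balance term).
#' @param k k-mer length for homology and Hi-C anchoring.
#' @param c1,c2,c3 Component weights of the objective.
#' @param pseudo_dist Distance pseudo-count (bp) keeping `D > 0`.
#' @return A `signal_matrices` list consumed by [phasing_objective()] and
#'   [run_annealing()].
#' @details Sequence lengths and shore-contig distances enter the objective
#'   in kilobases. With unit weights and raw base-pair units the
#'   signal terms are smaller than the length-balance term by about six
#'   orders of magnitude and the search degenerates; kilobase units put the
#'   three components on comparable scales for desk-sized loci.
#'
#'   The default homology-penalty weight is `c2 = 5`. The collapsed state
#'   costs nothing in the balance term and always gains whatever Hi-C
#'   signal links a contig to the wrong haplotype's shores, so the homology
#'   penalty is the only force keeping near-identical haplotype copies
#'   apart; its weight must at least offset the cis:trans contact-mass
#'   ratio (about 5:1 in typical phased Hi-C data) or the objective
#'   collapses shore-adjacent contigs.
#' @export
signal_matrices <- function(contigs, shores, shore_hap, shore_pos, placements,
                            hic_pairs, read_alignments, l_toi_ref, k = 31L,
                            c1 = 1, c2 = 5, c3 = 1, pseudo_dist = 1000) {
  contig_ids <- names(contigs)
  shore_ids <- names(shores)
  hom <- homology_coefficients(contigs, k)
  HIC <- unique_kmer_hic_signals(contigs, shores, hic_pairs, k)
  HIFI <- hifi_link_signals(read_alignments, contig_ids)
  L <- c(nchar(shores), nchar(contigs)) / 1000   # kb
  mid <- setNames(placements$midpoint, placements$contig_id)[contig_ids]
  D <- outer(shore_pos[shore_ids], mid,
             function(a, b) (abs(a - b) + pseudo_dist) / 1000)  # kb
  dimnames(D) <- list(shore_ids, contig_ids)
  structure(list(HIC = HIC, HIFI = HIFI, H = hom$H, h_bar = hom$h_bar,
                 D = D, L = L, l_toi_ref = l_toi_ref / 1000,
                 contig_ids = contig_ids, shore_ids = shore_ids,
                 shore_hap = shore_hap[shore_ids],
                 c1 = c1, c2 = c2, c3 = c3),
            class = "signal_matrices")
}

# Precompute the per-pair weight matrices so objective evaluation is a
# couple of submatrix sums (integer indices: this runs ~1e5 times per
# annealing run).
phasing_weights <- function(M) {
  sc <- M$shore_ids; cc <- M$contig_ids
  Ls <- M$L[sc]; Lc <- M$L[cc]
  W1 <- M$HIC[sc, cc, drop = FALSE] / (outer(Ls, Lc) * M$D[sc, cc, drop = FALSE])
  W2 <- (M$h_bar - M$H[cc, cc, drop = FALSE]) *
    M$HIFI[cc, cc, drop = FALSE] / outer(Lc, Lc)
  diag(W2) <- 0
  list(W1 = W1, W2 = W2, Lc = unname(Lc),
       mat_shore = which(M$shore_hap == "maternal"),
       pat_shore = which(M$shore_hap == "paternal"))
}

#' Phasing objective for a contig state vector
#'
#' States per contig: 0 discarded, 1 maternal, 2 paternal, 3 collapsed
#' (counted in both haplotypes). The objective rewards Hi-C contacts linking
#' shores to contigs of the same haplotype (distance- and length-normalised),
#' rewards HiFi links between low-homology same-haplotype contigs while
#' penalising links between high-homology pairs, and penalises maternal /
#' paternal length imbalance.
#'
#' @param state Integer vector in `{0,1,2,3}` over `M$contig_ids`.
#' @param M A `signal_matrices` object.
#' @param W Optional precomputed weights (internal use).
#' @return Numeric objective value.
#' @export
phasing_objective <- function(state, M, W = NULL) {
  if (length(state) != length(M$contig_ids)) {
    stop("state vector length does not match contig count")
  }
  if (is.null(W)) W <- phasing_weights(M)
  mat <- which(state == 1L | state == 3L)
  pat <- which(state == 2L | state == 3L)
  t1 <- 0
  if (length(W$mat_shore) && length(mat)) {
    t1 <- t1 + sum(W$W1[W$mat_shore, mat, drop = FALSE])
  }
  if (length(W$pat_shore) && length(pat)) {
    t1 <- t1 + sum(W$W1[W$pat_shore, pat, drop = FALSE])
  }
  t2 <- 0
  if (length(mat) > 1L) t2 <- t2 + sum(W$W2[mat, mat]) / 2
  if (length(pat) > 1L) t2 <- t2 + sum(W$W2[pat, pat]) / 2
  t3 <- abs(sum(W$Lc[mat]) - sum(W$Lc[pat])) / M$l_toi_ref
  M$c1 * t1 + M$c2 * t2 - M$c3 * t3
}

#' Phase contigs by restart hill climbing
#'
#' Random single-contig state changes are accepted only when they improve
#' the objective; a local optimum is declared after `plateau` consecutive
#' non-improving proposals. The best local optimum over `n_restarts` outer
#' iterations is returned, with a random perturbation of `perturb_frac` of
#' the contigs between restarts. Fully reproducible from `seed`.
#'
#' @param M A `signal_matrices` object.
#' @param n_restarts Outer iterations.
#' @param plateau Consecutive non-improving proposals declaring a local
#'   optimum.
#' @param perturb_frac Fraction of contigs randomised between restarts.
#' @param seed Integer seed.
#' @return List with `state` (named integer vector in `{0,1,2,3}`) and
#'   `objective`.
#' @export
run_annealing <- function(M, n_restarts = 1000L, plateau = 100L,
                          perturb_frac = 0.5, seed = 1L) {
  n <- length(M$contig_ids)
  stopifnot(n >= 1L)
  W <- phasing_weights(M)
  set.seed(seed)
  state <- sample(0:3, n, replace = TRUE)
  best_state <- state
  best_f <- -Inf
  for (outer in seq_len(n_restarts)) {
    cur_f <- phasing_objective(state, M, W)
    fails <- 0L
    while (fails < plateau) {
      i <- sample.int(n, 1L)
      new_s <- sample(setdiff(0:3, state[i]), 1L)
      cand <- state; cand[i] <- new_s
      f <- phasing_objective(cand, M, W)
      if (f > cur_f) {
        state <- cand; cur_f <- f; fails <- 0L
      } else {
        fails <- fails + 1L
      }
    }
    if (cur_f > best_f) { best_f <- cur_f; best_state <- state }
    idx <- sample.int(n, max(1L, round(perturb_frac * n)))
    state[idx] <- sample(0:3, length(idx), replace = TRUE)
  }
  list(state = setNames(best_state, M$contig_ids), objective = best_f)
}

#' Exhaustive search over all phasing states
#'
#' Brute-force optimum over the `4^n` state vectors; the oracle
#' [run_annealing()] is validated against on small instances.
#'
#' @param M A `signal_matrices` object.
#' @return List with `state` and `objective` of the global optimum.
#' @export
exhaustive_phasing <- function(M) {
  n <- length(M$contig_ids)
  stopifnot(n <= 12L)
  W <- phasing_weights(M)
  best <- NULL; best_f <- -Inf
  for (code in 0:(4^n - 1)) {
    state <- integer(n)
    c0 <- code
    for (i in seq_len(n)) { state[i] <- c0 %% 4; c0 <- c0 %/% 4 }
    f <- phasing_objective(state, M, W)
    if (f > best_f) { best_f <- f; best <- state }
  }
  list(state = setNames(best, M$contig_ids), objective = best_f)
}

#' Join placed contigs into per-haplotype scaffolds
#'
#' Contigs assigned to a haplotype (collapsed contigs to both) are oriented
#' by their placement strand, ordered by reference position, and joined with
#' a fixed number of `N`s.
#'
#' @param placements data.frame with `contig_id, start, strand`.
#' @param state Named state vector from [run_annealing()] (use
#'   `rep(1L, n)` for a haploid run).
#' @param contigs Named character vector of contig sequences.
#' @param gap_n Number of `N`s between consecutive contigs.
#' @return Named character vector with elements `maternal` and `paternal`
#'   (empty string, with a message, for an empty haplotype).
#' @export
build_scaffolds <- function(placements, state, contigs, gap_n = 100L) {
  one_hap <- function(ids) {
    ids <- ids[ids %in% placements$contig_id]
    if (length(ids) == 0L) {
      log_msg("no contigs assigned to a haplotype; emitting empty scaffold")
      return("")
    }
    pl <- placements[placements$contig_id %in% ids, , drop = FALSE]
    pl <- pl[order(pl$start, pl$contig_id), , drop = FALSE]
    seqs <- contigs[pl$contig_id]
    seqs <- ifelse(pl$strand == "+", seqs, revcomp(seqs))
    paste(seqs, collapse = strrep("N", gap_n))
  }
  cids <- names(state)
  c(maternal = one_hap(cids[state == 1L | state == 3L]),
    paternal = one_hap(cids[state == 2L | state == 3L]))
}

#' Trim shore overhangs off a scaffold
#'
#' Removes the scaffold prefix aligning to the left shore and the suffix
#' aligning to the right shore: the longest terminal aligned block with
#' identity at least `min_identity` that starts or ends within `end_slack`
#' bp of the scaffold end. Internal-only shore alignments leave the scaffold
#' unchanged (with a message).
#'
#' @param scaffold Single scaffold sequence.
#' @param shore_alignments data.frame of scaffold-vs-shore alignments with
#'   the scaffold on the query side.
#' @param min_identity Minimum `n_match / block_len`.
#' @param end_slack Maximum distance (bp) from the scaffold end for a block
#'   to count as terminal.
#' @return The trimmed scaffold string.
#' @export
trim_shores <- function(scaffold, shore_alignments, min_identity = 0.9,
                        end_slack = 100L) {
  n <- nchar(scaffold)
  if (nrow(shore_alignments) == 0L) return(scaffold)
  ident <- shore_alignments$n_match / shore_alignments$block_len
  ok <- shore_alignments[ident >= min_identity, , drop = FALSE]
  if (nrow(ok) == 0L) return(scaffold)
  left <- ok[ok$query_start <= end_slack, , drop = FALSE]
  right <- ok[ok$query_end >= n - end_slack, , drop = FALSE]
  if (nrow(left) == 0L && nrow(right) == 0L) {
    log_msg("shore alignment is internal only; scaffold left untrimmed")
    return(scaffold)
  }
  from <- if (nrow(left)) max(left$query_end) + 1L else 1L
  to <- if (nrow(right)) min(right$query_start) else n
  if (from > to) stop("shore trimming would remove the whole scaffold")
  substr(scaffold, from, to)
}
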