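edit_dist <- function(a, b) as.integer(adist(a, b))

# Fit `pattern` inside `subject` (pattern global, subject local) and return
# the edit distance and subject range of the best fit.
fit_monomer <- function(pattern, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(pattern, subject,
                                       type = "global-local",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1)
  rng <- Biostrings::subject(aln)
  list(edit = as.integer(-Biostrings::score(aln)),
       start = Biostrings::start(rng), end = Biostrings::end(rng))
}

#' Annotate tandem-repeat monomers along a sequence
#'
#' Greedy left-to-right scan: at each position the consensus and its
#' reverse complement are fitted into a local window (pattern-global,
#' window-local alignment with unit edit costs); the better fit is emitted
#' as a monomer when its edit distance is at most `max_edit_frac` times the
#' unit length, and the scan advances past it. Coordinates are 0-based
#' half-open.
#'
#' @param seq DNA string to annotate.
#' @param consensus Monomer consensus sequence (unit length >= 20).
#' @param max_edit_frac Maximum edit distance as a fraction of unit length.
#' @return data.frame with columns `index, start, end, strand, seq, edit`;
#'   zero rows when nothing matches.
#' @export
annotate_monomers <- function(seq, consensus, max_edit_frac = 0.25) {
  u <- nchar(consensus)
  stopifnot(u >= 20L)
  n <- nchar(seq)
  thr <- max_edit_frac * u
  cons_rc <- revcomp(consensus)
  # short window: only the unit at the cursor fits fully, so an adjacent
  # cleaner copy cannot outcompete it; wide window recovers after gaps
  win_short <- ceiling(1.35 * u)
  win_wide <- ceiling(2.2 * u)
  out <- list()
  p <- 1L
  while (p <= n - floor(0.8 * u) + 1L) {
    best_fit <- function(win) {
      subject <- substr(seq, p, min(n, p + win - 1L))
      fwd <- fit_monomer(consensus, subject)
      rev <- fit_monomer(cons_rc, subject)
      if (fwd$edit <= rev$edit) c(fwd, strand = "+") else c(rev, strand = "-")
    }
    hit <- best_fit(win_short)
    if (hit$edit > thr) hit <- best_fit(win_wide)
    if (hit$edit <= thr) {
      out[[length(out) + 1L]] <- data.frame(
        start = p + hit$start - 2L, end = p + hit$end - 1L,
        strand = hit$strand,
        seq = substr(seq, p + hit$start - 1L, p + hit$end - 1L),
        edit = hit$edit, stringsAsFactors = FALSE)
      p <- p + hit$end
    } else {
      p <- p + u  # no unit starts in this stretch; jump one unit ahead
    }
  }
  if (length(out) == 0L) {
    return(data.frame(index = integer(0), start = integer(0), end = integer(0),
                      strand = character(0), seq = character(0),
                      edit = integer(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- cbind(index = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

# Character matrix of monomers projected onto the consensus columns:
# same-length monomers map directly, others through a global alignment
# (insertions relative to the consensus are dropped, deletions become "-").
monomer_column_matrix <- function(monomers, consensus) {
  u <- nchar(consensus)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                  baseOnly = TRUE)
  rows <- lapply(monomers, function(m) {
    if (nchar(m) == u) return(strsplit(m, "")[[1]])
    aln <- Biostrings::pairwiseAlignment(m, consensus, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    p[s != "-"]
  })
  do.call(rbind, rows)
}

majority_base <- function(col) {
  counts <- table(factor(col, levels = c("A", "C", "G", "T")))
  names(counts)[which.max(counts)]  # ties: lexicographically first
}

#' Build a monomer consensus by majority vote
#'
#' Seeded by the column-wise majority over the monomers of the most common
#' length, then refined once by aligning every monomer to the seed and
#' re-voting each column.
#'
#' @param monomers Character vector of monomer sequences (>= 2).
#' @return Consensus DNA string.
#' @export
build_consensus <- function(monomers) {
  stopifnot(length(monomers) >= 2L)
  lens <- nchar(monomers)
  lmode <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  same <- monomers[lens == lmode]
  seed_mat <- do.call(rbind, strsplit(same, ""))
  seed <- paste(apply(seed_mat, 2L, majority_base), collapse = "")
  cm <- monomer_column_matrix(monomers, seed)
  paste(apply(cm, 2L, majority_base), collapse = "")
}

#' Per-position variant frequency of monomers against a consensus
#'
#' For each consensus column, the variant frequency is one minus the
#' frequency of the most frequent base (over all monomers; a deleted base
#' counts as a variant).
#'
#' @param monomers Character vector of monomer sequences.
#' @param consensus Consensus string the columns refer to.
#' @return Numeric vector of length `nchar(consensus)`.
#' @export
variant_profile <- function(monomers, consensus) {
  cm <- monomer_column_matrix(monomers, consensus)
  apply(cm, 2L, function(col) {
    counts <- table(factor(col, levels = c("A", "C", "G", "T")))
    1 - max(counts) / length(col)
  })
}

#' Detect higher-order repeats (HORs) in an ordered monomer sequence
#'
#' An HOR is a tandem duplication of at least `min_period` consecutive
#' monomers in which each duplicated monomer is within `max_edit`
#' (Levenshtein) of its counterpart in the preceding block. For every start
#' and period the number of whole duplicated blocks is counted; HORs whose
#' monomer span is contained in an equal-period longer HOR are suppressed.
#'
#' @param monomers Character vector of monomer sequences in positional order.
#' @param min_period Minimum monomers per block.
#' @param max_edit Maximum edit distance between duplicated monomers.
#' @param max_period Optional cap on the period (defaults to `n %/% 2`).
#' @return data.frame with columns `start_index, period, repeats,
#'   span_start, span_end` (1-based monomer indices, inclusive span).
#' @export
detect_hors <- function(monomers, min_period = 3L, max_edit = 5L,
                        max_period = NULL) {
  n <- length(monomers)
  max_period <- max_period %||% (n %/% 2L)
  out <- list()
  for (p in seq_len(max_period)) {
    if (p < min_period || n < 2L * p) next
    ok <- vapply(seq_len(n - p), function(t) {
      edit_dist(monomers[t], monomers[t + p]) <= max_edit
    }, TRUE)
    # run[t]: consecutive TRUEs starting at t
    run <- integer(length(ok))
    for (t in rev(seq_along(ok))) {
      run[t] <- if (ok[t]) 1L + (if (t < length(ok)) run[t + 1L] else 0L) else 0L
    }
    r <- run %/% p + 1L
    cand <- which(r >= 2L)
    if (length(cand) == 0L) next
    right <- cand + r[cand] * p - 1L
    # containment filter: drop spans inside an earlier-starting longer span
    keep <- right > cummax(c(0L, head(right, -1L)))
    cand <- cand[keep]; right <- right[keep]
    out[[length(out) + 1L]] <- data.frame(
      start_index = cand, period = p, repeats = r[cand],
      span_start = cand, span_end = right)
  }
  if (length(out) == 0L) {
    return(data.frame(start_index = integer(0), period = integer(0),
                      repeats = integer(0), span_start = integer(0),
                      span_end = integer(0)))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' HOR score per monomer
#'
#' The HOR score of a monomer is the number of detected HORs whose span
#' contains it, divided by the total number of monomers in its region.
#'
#' @param n_monomers Number of monomers in the region.
#' @param hors data.frame from [detect_hors()].
#' @return Numeric vector of length `n_monomers`.
#' @export
hor_scores <- function(n_monomers, hors) {
  score <- numeric(n_monomers)
  for (i in seq_len(nrow(hors))) {
    idx <- hors$span_start[i]:hors$span_end[i]
    score[idx] <- score[idx] + 1
  }
  score / n_monomers
}

#' Strand composition of annotated monomers
#'
#' @param annotations data.frame from [annotate_monomers()].
#' @return Named numeric vector `c(plus = ..., minus = ...)` summing to 1.
#' @export
strand_bias <- function(annotations) {
  n <- nrow(annotations)
  if (n == 0L) return(c(plus = NA_real_, minus = NA_real_))
  plus <- mean(annotations$strand == "+")
  c(plus = plus, minus = 1 - plus)
}

#' Similarity between two monomer sets
#'
#' Jaccard similarity on distinct strand-canonical monomer sequences:
#' shared distinct monomers divided by the distinct monomers in either set.
#'
#' @param a,b Character vectors of monomer sequences.
#' @return Numeric in `[0, 1]` (0 for an empty union).
#' @export
monomer_set_similarity <- function(a, b) {
  a <- unique(canonical_seq(a))
  b <- unique(canonical_seq(b))
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Random-sampling experiment over monomer-set similarities
#'
#' Draws `n_trials` intra and `n_trials` inter comparisons over a list of
#' monomer regions. In `"subtelomere"` mode each comparison uses a fraction
#' `frac` of a region's monomers: intra pairs are two disjoint fractions of
#' the same region, inter pairs one fraction from each of two regions. In
#' `"region"` mode whole regions are compared, with `groups` defining which
#' regions belong to the same genome/chromosome (intra = same group).
#'
#' @param regions List of character vectors of monomer sequences.
#' @param mode `"subtelomere"` or `"region"`.
#' @param n_trials Trials per comparison type.
#' @param seed Integer seed.
#' @param frac Fraction of monomers sampled per set in subtelomere mode.
#' @param groups Vector (same length as `regions`) of group labels,
#'   required for region mode.
#' @return data.frame with columns `type` (`intra`/`inter`) and
#'   `similarity`.
#' @export
similarity_experiment <- function(regions, mode = c("subtelomere", "region"),
                                  n_trials = 200L, seed = 1L, frac = 0.1,
                                  groups = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(regions) >= 2L)
  set.seed(seed)
  draw <- function(type) {
    if (mode == "subtelomere") {
      if (type == "intra") {
        r <- regions[[sample.int(length(regions), 1L)]]
        m <- max(1L, floor(frac * length(r)))
        idx <- sample.int(length(r), 2L * m)
        monomer_set_similarity(r[idx[seq_len(m)]], r[idx[m + seq_len(m)]])
      } else {
        ij <- sample.int(length(regions), 2L)
        a <- regions[[ij[1]]]; b <- regions[[ij[2]]]
        ma <- max(1L, floor(frac * length(a)))
        mb <- max(1L, floor(frac * length(b)))
        monomer_set_similarity(a[sample.int(length(a), ma)],
                               b[sample.int(length(b), mb)])
      }
    } else {
      if (is.null(groups)) stop("region mode requires groups")
      if (type == "intra") {
        g <- sample(unique(groups[duplicated(groups)]), 1L)
        ij <- sample(which(groups == g), 2L)
      } else {
        repeat {
          ij <- sample.int(length(regions), 2L)
          if (groups[ij[1]] != groups[ij[2]]) break
        }
      }
      monomer_set_similarity(regions[[ij[1]]], regions[[ij[2]]])
    }
  }
  data.frame(
    type = rep(c("intra", "inter"), each = n_trials),
    similarity = c(vapply(seq_len(n_trials), function(i) draw("intra"), 0),
                   vapply(seq_len(n_trials), function(i) draw("inter"), 0))
  )
}
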