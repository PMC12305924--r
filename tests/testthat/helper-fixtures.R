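# Shared fixture builders. Everything is generated in code; no data files.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small all-forward unitig graph from "X>Y" edge strings, with uniform
# edge support and degree/component annotations filled in.
mk_graph <- function(edges_chr, support = 1L, node_len = 10L) {
  nodes <- unique(unlist(strsplit(edges_chr, ">")))
  g <- structure(list(
    nodes = data.frame(id = nodes,
                       seq = vapply(nodes, function(x) random_dna_str(node_len), ""),
                       len = node_len, stringsAsFactors = FALSE),
    edges = do.call(rbind, lapply(strsplit(edges_chr, ">"), function(p) {
      data.frame(from = p[1], from_orient = "+", to = p[2], to_orient = "+",
                 overlap = 0L, support = support, stringsAsFactors = FALSE)
    }))), class = "unitig_graph")
  g$nodes$in_deg <- as.integer(table(factor(g$edges$to, g$nodes$id)))
  g$nodes$out_deg <- as.integer(table(factor(g$edges$from, g$nodes$id)))
  g$nodes$component <- tandemfill:::component_labels(g)
  g
}

contig_strings <- function(contigs) {
  sort(vapply(contigs, function(x) paste(x$node, collapse = ""), ""))
}

# Brute-force HOR enumeration: every (start, period, repeats) triple with
# whole duplicated blocks, then the same-period containment filter.
brute_hors <- function(monomers, min_period = 3L, max_edit = 5L) {
  n <- length(monomers)
  out <- list()
  if (n >= 2L * min_period) {
    for (p in min_period:(n %/% 2L)) {
      for (i in 1:(n - 2L * p + 1L)) {
        r <- 1L
        while (i + r * p + p - 1L <= n) {
          ok <- all(vapply(0:(p - 1L), function(j) {
            adist(monomers[i + j + (r - 1L) * p],
                  monomers[i + j + r * p]) <= max_edit
          }, TRUE))
          if (ok) r <- r + 1L else break
        }
        if (r >= 2L) out[[length(out) + 1L]] <- c(i, p, r)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start_index = integer(0), period = integer(0),
                      repeats = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("start_index", "period", "repeats")
  df$span_end <- df$start_index + df$repeats * df$period - 1L
  keep <- vapply(seq_len(nrow(df)), function(i) {
    !any(df$period == df$period[i] &
           df$start_index <= df$start_index[i] & df$span_end >= df$span_end[i] &
           (df$start_index < df$start_index[i] | df$span_end > df$span_end[i]))
  }, TRUE)
  df <- df[keep, c("start_index", "period", "repeats")]
  df[order(df$period, df$start_index), ]
}

# Brute-force longest non-decreasing subsequence by subset enumeration.
brute_lis <- function(L) {
  n <- length(L)
  if (n == 0L) return(0L)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) > best && !is.unsorted(L[idx])) best <- length(idx)
  }
  best
}

# Copy of a monomer with an exact bounded number of substitutions.
mutate_bounded <- function(seq, max_subs = 2L) {
  chars <- strsplit(seq, "")[[1]]
  k <- sample(0:max_subs, 1)
  for (i in sample(seq_along(chars), k)) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# Random placement instance for GA-vs-exhaustive comparison.
rand_placement_instance <- function(seed) {
  set.seed(seed)
  toi_len <- 10000
  nc <- sample(2:4, 1)
  cands <- lapply(seq_len(nc), function(i) {
    len <- sample(1500:4000, 1)
    k <- sample(1:3, 1)
    starts <- sample(0:(toi_len - len), k)
    data.frame(contig_id = paste0("c", i), start = starts, end = starts + len,
               strand = "+", score = sample(3:10, k, replace = TRUE),
               midpoint = starts + len / 2, stringsAsFactors = FALSE)
  })
  names(cands) <- paste0("c", seq_len(nc))
  list(cands = cands, toi_len = toi_len,
       comp = setNames(rep(1L, nc), names(cands)),
       ploidy = sample(1:2, 1))
}

# Planted 6-contig tiling over a 30 kb region plus decoy candidates.
planted_tiling_instance <- function(seed) {
  set.seed(seed)
  toi_len <- 30000; nc <- 6L; len <- 5000L
  cands <- lapply(seq_len(nc), function(i) {
    true_start <- (i - 1L) * len
    dec <- sample(setdiff(seq(0L, toi_len - len, by = 500L), true_start), 2L)
    starts <- c(true_start, dec)
    data.frame(contig_id = paste0("c", i), start = starts, end = starts + len,
               strand = "+", score = c(10L, 4L, 3L),
               midpoint = starts + len / 2, stringsAsFactors = FALSE)
  })
  names(cands) <- paste0("c", seq_len(nc))
  comp <- setNames(rep(1L, nc), names(cands))
  planted <- setNames(rep(1L, nc), names(cands))
  list(cands = cands, toi_len = toi_len, comp = comp, planted = planted)
}

# Random small signal-matrices object for annealing-vs-exhaustive tests.
rand_signal_matrices <- function(seed, n_contigs = 6L) {
  set.seed(seed)
  cid <- paste0("c", seq_len(n_contigs))
  sid <- c("shoreM", "shoreP")
  all_ids <- c(sid, cid)
  HIC <- matrix(0, length(all_ids), length(all_ids),
                dimnames = list(all_ids, all_ids))
  vals <- matrix(rpois(2 * n_contigs, 30), 2)
  HIC[sid, cid] <- vals
  HIC[cid, sid] <- t(vals)
  HIFI <- matrix(0L, n_contigs, n_contigs, dimnames = list(cid, cid))
  up <- which(upper.tri(HIFI))
  HIFI[up] <- rpois(length(up), 10)
  HIFI <- HIFI + t(HIFI)
  H <- matrix(runif(n_contigs^2, 0, 0.9), n_contigs,
              dimnames = list(cid, cid))
  H <- (H + t(H)) / 2; diag(H) <- 1
  off <- H[upper.tri(H)]
  structure(list(
    HIC = HIC, HIFI = HIFI, H = H,
    h_bar = mean(off[off > 0]),
    D = matrix(runif(2 * n_contigs, 2, 20), 2,
               dimnames = list(sid, cid)),
    L = setNames(runif(length(all_ids), 2, 8), all_ids),
    l_toi_ref = 30, contig_ids = cid, shore_ids = sid,
    shore_hap = c(shoreM = "maternal", shoreP = "paternal"),
    c1 = 1, c2 = 5, c3 = 1), class = "signal_matrices")
}
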