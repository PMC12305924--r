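BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# Substitutions only: coordinates are preserved.
point_mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  paste(chars, collapse = "")
}

# Mutate with substitutions, insertions and deletions (weights `w`).
# Returns the mutated sequence and `src`: for every base of the output, the
# 1-based coordinate of the input base it derives from (an inserted base
# inherits the coordinate of the base it precedes), so planted alignment
# coordinates stay exact through mutation.
mutate_seq <- function(seq, rate, w = c(sub = 2, ins = 1, del = 1)) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  pieces <- chars
  hit <- which(runif(n) < rate)
  if (length(hit)) {
    types <- sample(names(w), length(hit), replace = TRUE, prob = w)
    for (idx in seq_along(hit)) {
      i <- hit[idx]
      pieces[i] <- switch(types[idx],
        sub = sample(setdiff(BASES, chars[i]), 1L),
        ins = paste0(sample(BASES, 1L), chars[i]),
        del = "")
    }
  }
  src <- rep(seq_len(n), nchar(pieces))
  list(seq = paste(pieces, collapse = ""), src = src)
}

#' Configuration for the synthetic tandem-repeat generator
#'
#' Defaults describe a desk-scale diploid satellite locus: a 181 bp monomer
#' arrayed with period-3 higher-order structure, two haplotypes diverged at
#' 1% (substitutions and indels 8:1:1), 5 kb unique shores, 30x HiFi reads
#' of ~10 kb with 0.1% error (sub:ins:del = 2:1:1), and Hi-C pairs with
#' power-law contact decay and a configurable fraction of inter-haplotype
#' swaps.
#'
#' @param seed Integer seed; identical configuration and seed reproduce all
#'   outputs exactly.
#' @param monomer_len Repeat-unit length (bp).
#' @param n_monomers Monomers in the reference array.
#' @param hor_period Monomer classes cycling along the array.
#' @param class_divergence Substitution rate separating monomer classes.
#' @param monomer_mut_rate Per-copy substitution rate (private variants that
#'   make most k-mers locatable).
#' @param haplotype_divergence Per-base mutation rate between reference and
#'   each haplotype.
#' @param sv_spec Optional list of structural events, each
#'   `list(hap =, del_start =, del_n =)` deleting a monomer block.
#' @param shore_len Length of each flanking shore (bp).
#' @param ploidy 1 or 2 haplotypes.
#' @param hifi_depth,hifi_len_mean,hifi_err HiFi coverage, mean read length
#'   and per-base error rate.
#' @param hifi_aln_frag Alignment fragment length (bp): planted read
#'   alignments are split into pieces of about this size, as long-read
#'   aligners report fragmented alignments over tandem repeats.
#' @param hic_depth,hic_decay_exponent,inter_hap_noise Hi-C coverage,
#'   contact-distance decay exponent, and probability that a pair's second
#'   end is swapped to the other haplotype.
#' @param hic_end_len Hi-C end length (bp).
#' @param hic_min_dist Minimum end separation (bp); the decay law is
#'   truncated below this fragment-scale floor.
#' @param unitigs_per_hap Segments each haplotype array is chopped into for
#'   the truth unitig graph.
#' @param min_node_overlap Minimum read/node overlap (bp) for a read path to
#'   include a node.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, monomer_len = 181L, n_monomers = 200L,
                       hor_period = 3L, class_divergence = 0.05,
                       monomer_mut_rate = 0.02, haplotype_divergence = 0.01,
                       sv_spec = NULL, shore_len = 5000L, ploidy = 2L,
                       hifi_depth = 30, hifi_len_mean = 10000L,
                       hifi_err = 0.001, hifi_aln_frag = 3000L,
                       hic_depth = 20,
                       hic_decay_exponent = 1.5, inter_hap_noise = 0.05,
                       hic_end_len = 150L, hic_min_dist = 1000L,
                       unitigs_per_hap = 6L, min_node_overlap = 200L) {
  cfg <- as.list(environment())
  stopifnot(cfg$ploidy %in% c(1L, 2L),
            cfg$haplotype_divergence >= 0, cfg$haplotype_divergence < 1,
            cfg$hifi_err >= 0, cfg$hifi_err < 1,
            cfg$inter_hap_noise >= 0, cfg$inter_hap_noise < 1)
  structure(cfg, class = "sim_config")
}

#' Simulate a tandem-repeat region with truth annotations
#'
#' Builds a reference chromosome `shoreL + monomer array + shoreR`, the
#' reference TOI (the array), the truth monomer intervals, and `ploidy`
#' haplotypes derived from the array (and shores) by independent mutation
#' at the configured divergence plus optional monomer-block deletions. Each
#' haplotype carries a base-level `src` map back to reference-array
#' coordinates, which downstream simulators use to emit exact planted
#' alignments.
#'
#' @param cfg A `sim_config`.
#' @return A `sim_region` list: `cfg`, `classes`, `monomers`,
#'   `monomer_bed`, `reference` (named vector with `ref`), `toi`
#'   (`chrom,start,end`), and `haps` (per haplotype: `seq`, `src`,
#'   `shoreL`, `shoreR`, `chrom`, `kept` monomer indices).
#' @export
simulate_region <- function(cfg) {
  set.seed(cfg$seed)
  u <- cfg$monomer_len
  base <- random_dna(u)
  classes <- vapply(seq_len(cfg$hor_period), function(i) {
    point_mutate(base, cfg$class_divergence)
  }, "")
  monomers <- vapply(seq_len(cfg$n_monomers), function(i) {
    point_mutate(classes[(i - 1L) %% cfg$hor_period + 1L], cfg$monomer_mut_rate)
  }, "")
  ref_array <- paste(monomers, collapse = "")
  shoreL <- random_dna(cfg$shore_len)
  shoreR <- random_dna(cfg$shore_len)
  reference <- c(ref = paste0(shoreL, ref_array, shoreR))
  toi <- list(chrom = "ref", start = cfg$shore_len,
              end = cfg$shore_len + nchar(ref_array))
  monomer_bed <- data.frame(
    chrom = "ref",
    start = cfg$shore_len + (seq_len(cfg$n_monomers) - 1L) * u,
    end = cfg$shore_len + seq_len(cfg$n_monomers) * u,
    name = sprintf("monomer_%04d", seq_len(cfg$n_monomers)),
    strand = "+", stringsAsFactors = FALSE)

  haps <- lapply(seq_len(cfg$ploidy), function(h) {
    kept <- seq_len(cfg$n_monomers)
    for (sv in cfg$sv_spec %||% list()) {
      if (sv$hap == h) {
        kept <- setdiff(kept, sv$del_start:(sv$del_start + sv$del_n - 1L))
      }
    }
    template <- paste(monomers[kept], collapse = "")
    template_src <- unlist(lapply(kept, function(i) ((i - 1L) * u + 1L):(i * u)))
    mut <- mutate_seq(template, cfg$haplotype_divergence,
                      w = c(sub = 8, ins = 1, del = 1))
    sL <- point_mutate(shoreL, cfg$haplotype_divergence)
    sR <- point_mutate(shoreR, cfg$haplotype_divergence)
    list(seq = mut$seq, src = template_src[mut$src], shoreL = sL, shoreR = sR,
         chrom = paste0(sL, mut$seq, sR), kept = kept)
  })
  structure(list(cfg = cfg, classes = classes, monomers = monomers,
                 monomer_bed = monomer_bed, reference = reference, toi = toi,
                 haps = haps), class = "sim_region")
}

# Map a haplotype-chromosome position (1-based, over shoreL+array+shoreR)
# to the corresponding reference-chromosome position via the src map.
hap_to_ref_pos <- function(sim, h, pos) {
  hap <- sim$haps[[h]]
  lsh <- nchar(hap$shoreL)
  hlen <- nchar(hap$seq)
  ifelse(pos <= lsh, pos,
         ifelse(pos <= lsh + hlen,
                sim$cfg$shore_len + hap$src[pmax(1L, pos - lsh)],
                sim$cfg$shore_len + nchar(paste(sim$monomers, collapse = "")) +
                  (pos - lsh - hlen)))
}

#' Simulate HiFi reads with planted reference alignments
#'
#' Reads are sampled uniformly over each haplotype chromosome
#' (shore + array + shore) at `hifi_depth / ploidy` each, with lengths
#' `Normal(mean, 0.1 mean)` floored at 1 kb, random strand, and per-base
#' errors (sub:ins:del = 2:1:1) at `hifi_err`. Sampling across the repeat
#' boundaries matters: it keeps HiFi coverage flat at the array edges,
#' where boundary contigs otherwise lose linkage support. The planted
#' alignment of each read against the reference is emitted as PAF.
#'
#' @param sim A `sim_region`.
#' @return List with `reads` (named character vector), `paf`
#'   (read-vs-reference alignments) and `truth` (data.frame `read_id, hap,
#'   chrom_start, chrom_end, hap_start, hap_end, strand`; `hap_start/end`
#'   are 1-based inclusive coordinates on the haplotype array, NA for reads
#'   entirely within a shore).
#' @export
simulate_hifi <- function(sim) {
  cfg <- sim$cfg
  set.seed(cfg$seed + 1L)   # stage-specific stream: reproducible in isolation
  ref_len <- nchar(sim$reference[["ref"]])
  ids <- character(0); seqs <- character(0)
  hap_v <- integer(0); cs_v <- integer(0); ce_v <- integer(0)
  as_v <- integer(0); ae_v <- integer(0)
  strand_v <- character(0); qlen_v <- integer(0)
  rs_v <- integer(0); re_v <- integer(0)
  rid <- 0L
  for (h in seq_along(sim$haps)) {
    hap <- sim$haps[[h]]
    chrom <- hap$chrom
    clen <- nchar(chrom)
    lsh <- nchar(hap$shoreL)
    hlen <- nchar(hap$seq)
    n_reads <- ceiling(cfg$hifi_depth / length(sim$haps) * clen /
                         cfg$hifi_len_mean)
    for (i in seq_len(n_reads)) {
      len <- min(clen, max(1000L, round(rnorm(1, cfg$hifi_len_mean,
                                              0.1 * cfg$hifi_len_mean))))
      s <- sample.int(clen - len + 1L, 1L)
      e <- s + len - 1L
      err <- mutate_seq(substr(chrom, s, e), cfg$hifi_err)
      strand <- if (runif(1) < 0.5) "+" else "-"
      rid <- rid + 1L
      ids[rid] <- sprintf("read_%05d", rid)
      seqs[rid] <- if (strand == "+") err$seq else revcomp(err$seq)
      hap_v[rid] <- h; cs_v[rid] <- s; ce_v[rid] <- e
      a_s <- max(1L, s - lsh); a_e <- min(hlen, e - lsh)
      if (a_e < a_s) { a_s <- NA_integer_; a_e <- NA_integer_ }
      as_v[rid] <- a_s; ae_v[rid] <- a_e
      strand_v[rid] <- strand; qlen_v[rid] <- nchar(err$seq)
      rs_v[rid] <- hap_to_ref_pos(sim, h, s)
      re_v[rid] <- hap_to_ref_pos(sim, h, e)
    }
  }
  reads <- setNames(seqs, ids)
  # fragment each read's planted alignment, as an aligner would over repeats
  frag <- max(1000L, cfg$hifi_aln_frag)
  paf <- vector("list", rid)
  for (r in seq_len(rid)) {
    rlen <- ce_v[r] - cs_v[r] + 1L
    nfr <- max(1L, round(rlen / frag))
    cuts <- round(seq(0L, rlen, length.out = nfr + 1L))
    qlen <- qlen_v[r]
    qs <- qe <- ts <- te <- integer(nfr)
    for (fidx in seq_len(nfr)) {
      os <- cuts[fidx] + 1L; oe <- cuts[fidx + 1L]   # offsets in source orientation
      ts[fidx] <- hap_to_ref_pos(sim, hap_v[r], cs_v[r] + os - 1L)
      te[fidx] <- hap_to_ref_pos(sim, hap_v[r], cs_v[r] + oe - 1L)
      if (strand_v[r] == "+") {
        qs[fidx] <- min(os - 1L, qlen - 1L); qe[fidx] <- min(oe, qlen)
      } else {
        qs[fidx] <- max(0L, qlen - oe); qe[fidx] <- max(1L, qlen - os + 1L)
      }
    }
    blk <- pmax(qe - qs, 1L)
    paf[[r]] <- data.frame(
      query_id = ids[r], query_len = qlen, query_start = qs, query_end = qe,
      strand = strand_v[r], target_id = "ref", target_len = ref_len,
      target_start = ts - 1L, target_end = te,
      n_match = as.integer(round(0.98 * blk)), block_len = blk, mapq = 60L,
      stringsAsFactors = FALSE)
  }
  paf <- do.call(rbind, paf)
  truth <- data.frame(read_id = ids, hap = hap_v, chrom_start = cs_v,
                      chrom_end = ce_v, hap_start = as_v, hap_end = ae_v,
                      strand = strand_v, stringsAsFactors = FALSE)
  list(reads = reads, paf = paf, truth = truth)
}

#' Simulate decoy reads from a diverged off-target repeat
#'
#' A decoy array is derived from the reference array by substitution at
#' `divergence`; reads sampled from it carry planted alignments onto the
#' reference TOI at the corresponding coordinates (as a repeat-aware
#' aligner would place them), but share almost no rare k-mers with the
#' reference, so the recall test should reject them.
#'
#' @param sim A `sim_region`.
#' @param n_reads Number of decoy reads.
#' @param divergence Substitution rate of the decoy array.
#' @return List with `reads` and `paf` as in [simulate_hifi()].
#' @export
simulate_decoy_reads <- function(sim, n_reads, divergence = 0.15) {
  cfg <- sim$cfg
  set.seed(cfg$seed + 4L)
  ref_array <- paste(sim$monomers, collapse = "")
  decoy <- point_mutate(ref_array, divergence)
  dlen <- nchar(decoy)
  ref_len <- nchar(sim$reference[["ref"]])
  reads <- character(0); paf <- list()
  for (i in seq_len(n_reads)) {
    len <- min(dlen, max(1000L, round(rnorm(1, cfg$hifi_len_mean,
                                            0.1 * cfg$hifi_len_mean))))
    s <- sample.int(dlen - len + 1L, 1L)
    err <- mutate_seq(substr(decoy, s, s + len - 1L), cfg$hifi_err)
    id <- sprintf("decoy_%05d", i)
    reads[[id]] <- err$seq
    qlen <- nchar(err$seq)
    paf[[length(paf) + 1L]] <- data.frame(
      query_id = id, query_len = qlen, query_start = 0L, query_end = qlen,
      strand = "+", target_id = "ref", target_len = ref_len,
      target_start = cfg$shore_len + s - 1L,
      target_end = cfg$shore_len + s + len - 1L,
      n_match = round(0.85 * qlen), block_len = qlen, mapq = 10L,
      stringsAsFactors = FALSE)
  }
  list(reads = reads, paf = do.call(rbind, paf))
}

#' Simulate training observations from homologous trusted regions
#'
#' Emulates fitting the recall model on trusted assemblies of homologous
#' regions in a different individual: `n_individuals` independent
#' haplotypes of the reference array are generated at the configured
#' divergence, pseudo-reads are drawn from them, and each read's
#' rare-k-mer observation `(x, y)` against its planted reference alignment
#' is computed with [observe_alignment()]. Training across several regions
#' matters: the per-region rare-k-mer survival varies, and the fitted
#' variance must absorb that between-region spread for the downstream test
#' to be calibrated.
#'
#' @param sim A `sim_region`.
#' @param n_obs Number of training observations.
#' @param n_individuals Independent homologous templates the observations
#'   are spread over.
#' @param rare_set Rare canonical k-mers of the reference genome (computed
#'   from `sim$reference` when `NULL`).
#' @param k k-mer length.
#' @return data.frame with columns `read_id, x, y`.
#' @export
simulate_training_observations <- function(sim, n_obs = 150L,
                                           n_individuals = 5L,
                                           rare_set = NULL, k = 21L) {
  cfg <- sim$cfg
  set.seed(cfg$seed + 3L)
  if (is.null(rare_set)) {
    rare_set <- extract_rare_kmers(count_kmers(sim$reference, k), 3L)
  }
  template <- paste(sim$monomers, collapse = "")
  muts <- lapply(seq_len(n_individuals), function(i) {
    mutate_seq(template, cfg$haplotype_divergence,
               w = c(sub = 8, ins = 1, del = 1))
  })
  ref_len <- nchar(sim$reference[["ref"]])
  obs <- list()
  for (i in seq_len(n_obs)) {
    mut <- muts[[(i - 1L) %% n_individuals + 1L]]
    hlen <- nchar(mut$seq)
    len <- min(hlen, max(1000L, round(rnorm(1, cfg$hifi_len_mean,
                                            0.1 * cfg$hifi_len_mean))))
    s <- sample.int(hlen - len + 1L, 1L)
    err <- mutate_seq(substr(mut$seq, s, s + len - 1L), cfg$hifi_err)
    qlen <- nchar(err$seq)
    aln <- data.frame(
      query_id = sprintf("train_%04d", i), query_len = qlen,
      query_start = 0L, query_end = qlen, strand = "+",
      target_id = "ref", target_len = ref_len,
      target_start = cfg$shore_len + mut$src[s] - 1L,
      target_end = cfg$shore_len + mut$src[s + len - 1L],
      n_match = qlen, block_len = qlen, mapq = 60L, stringsAsFactors = FALSE)
    o <- observe_alignment(aln, sim$reference, err$seq, rare_set, k)
    obs[[i]] <- data.frame(read_id = o$read_id, x = o$x, y = o$y)
  }
  do.call(rbind, obs)
}

#' Simulate Hi-C pairs with contact-distance decay
#'
#' Pair end-1 positions are uniform over a haplotype chromosome
#' (shore + array + shore); the end separation is drawn from a truncated
#' power law `P(d) ~ (d+1)^-decay`; with probability `inter_hap_noise` the
#' second end is swapped to the other haplotype at the same position.
#'
#' @param sim A `sim_region`.
#' @param n_pairs Number of pairs (derived from `hic_depth` when `NULL`).
#' @return data.frame `read_id, seq1, seq2, hap1, hap2, pos1, pos2`
#'   (positions 1-based on the haplotype chromosome).
#' @export
simulate_hic <- function(sim, n_pairs = NULL) {
  cfg <- sim$cfg
  set.seed(cfg$seed + 2L)
  chroms <- vapply(sim$haps, `[[`, "", "chrom")
  lens <- nchar(chroms)
  el <- cfg$hic_end_len
  if (is.null(n_pairs)) {
    n_pairs <- round(cfg$hic_depth * sum(lens) / (2 * el))
  }
  if (n_pairs == 0L) {
    return(data.frame(read_id = character(0), seq1 = character(0),
                      seq2 = character(0), hap1 = integer(0),
                      hap2 = integer(0), pos1 = integer(0), pos2 = integer(0)))
  }
  a <- cfg$hic_decay_exponent
  d0 <- cfg$hic_min_dist
  h1 <- sample.int(length(chroms), n_pairs, replace = TRUE, prob = lens)
  L1 <- lens[h1]
  p1 <- 1L + floor(runif(n_pairs) * (L1 - el + 1L))
  # truncated power law on [d0, dmax]
  u <- runif(n_pairs)
  dmax <- L1 - el
  d <- if (abs(a - 1) < 1e-9) {
    d0 * (dmax / d0)^u
  } else {
    (d0^(1 - a) + u * (dmax^(1 - a) - d0^(1 - a)))^(1 / (1 - a))
  }
  d <- pmax(1L, pmin(dmax, round(d)))
  p2 <- ifelse(runif(n_pairs) < 0.5, p1 - d, p1 + d)
  p2 <- pmax(1L, pmin(L1 - el + 1L, p2))
  h2 <- h1
  if (length(chroms) > 1L) {
    # inter-haplotype (trans) contacts: random ligation, so the second end
    # is uniform on the other haplotype with no distance structure
    swap <- runif(n_pairs) < cfg$inter_hap_noise
    h2[swap] <- 3L - h1[swap]
    p2[swap] <- 1L + floor(runif(sum(swap)) * (lens[h2[swap]] - el + 1L))
    p2 <- pmin(p2, lens[h2] - el + 1L)
  }
  data.frame(
    read_id = sprintf("pair_%06d", seq_len(n_pairs)),
    seq1 = substring(chroms[h1], p1, p1 + el - 1L),
    seq2 = substring(chroms[h2], p2, p2 + el - 1L),
    hap1 = h1, hap2 = h2, pos1 = as.integer(p1), pos2 = as.integer(p2),
    stringsAsFactors = FALSE)
}

#' Build the planted-truth unitig graph and read paths
#'
#' Each haplotype array is chopped into `unitigs_per_hap` segments (the
#' planted junctions); nodes carry the segment sequences and edges the true
#' adjacencies. Optionally a decoy transitive edge skipping the second node
#' of each haplotype is added, supported by `decoy_support` chimeric read
#' paths, so that transitive-edge removal can be exercised against planted
#' structure. Simulated reads are threaded through the node layout to give
#' their paths.
#'
#' @param sim A `sim_region`.
#' @param hifi Output of [simulate_hifi()] (used for read threading); may
#'   be `NULL` for a graph without read paths.
#' @param decoy_transitive Add a decoy transitive edge per haplotype?
#' @param decoy_support Number of chimeric paths supporting each decoy edge.
#' @param isolated Omit the edges between consecutive segments, so every
#'   segment becomes its own contig (used to study placement and phasing of
#'   many fragments).
#' @param stagger Offset the segment grid of even haplotypes by half a
#'   segment, as real assemblies fragment the two haplotypes at unrelated
#'   positions (also avoids artificial one-to-one homologous segment pairs).
#' @return List with `graph` (a `unitig_graph`), `node_info` (data.frame
#'   `node, hap, hap_start, hap_end, ref_start, ref_end`, 1-based inclusive)
#'   and `paths` (read paths as from [parse_gaf()]).
#' @export
build_truth_graph <- function(sim, hifi = NULL, decoy_transitive = FALSE,
                              decoy_support = 2L, isolated = FALSE,
                              stagger = FALSE) {
  cfg <- sim$cfg
  nodes <- list(); edges <- list(); info <- list()
  for (h in seq_along(sim$haps)) {
    hap <- sim$haps[[h]]
    hlen <- nchar(hap$seq)
    nseg <- min(cfg$unitigs_per_hap, hlen)
    bounds <- round(seq(0L, hlen, length.out = nseg + 1L))
    if (stagger && h %% 2L == 0L && nseg >= 2L) {
      half <- round(hlen / nseg / 2)
      bounds[2:nseg] <- bounds[2:nseg] + half
    }
    bounds <- unique(pmin(bounds, hlen))
    ids <- sprintf("u%d_%02d", h, seq_len(length(bounds) - 1L))
    for (i in seq_along(ids)) {
      s <- bounds[i] + 1L; e <- bounds[i + 1L]
      nodes[[length(nodes) + 1L]] <- data.frame(
        id = ids[i], seq = substr(hap$seq, s, e), stringsAsFactors = FALSE)
      info[[length(info) + 1L]] <- data.frame(
        node = ids[i], hap = h, hap_start = s, hap_end = e,
        ref_start = hap$src[s], ref_end = hap$src[e], stringsAsFactors = FALSE)
      if (i > 1L && !isolated) {
        edges[[length(edges) + 1L]] <- data.frame(
          from = ids[i - 1L], from_orient = "+", to = ids[i], to_orient = "+",
          overlap = 0L, support = 0L, stringsAsFactors = FALSE)
      }
    }
    if (decoy_transitive && length(ids) >= 3L) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = ids[1], from_orient = "+", to = ids[3], to_orient = "+",
        overlap = 0L, support = 0L, stringsAsFactors = FALSE)
    }
  }
  nodes <- do.call(rbind, nodes)
  nodes$len <- nchar(nodes$seq)
  edges <- if (length(edges)) {
    do.call(rbind, edges)
  } else {
    data.frame(from = character(0), from_orient = character(0),
               to = character(0), to_orient = character(0),
               overlap = integer(0), support = integer(0),
               stringsAsFactors = FALSE)
  }
  graph <- structure(list(nodes = nodes, edges = edges), class = "unitig_graph")
  node_info <- do.call(rbind, info)

  paths <- list()
  if (!is.null(hifi)) {
    for (r in seq_len(nrow(hifi$truth))) {
      tr <- hifi$truth[r, ]
      if (is.na(tr$hap_start)) next
      ni <- node_info[node_info$hap == tr$hap, , drop = FALSE]
      ov <- pmin(ni$hap_end, tr$hap_end) - pmax(ni$hap_start, tr$hap_start) + 1L
      hit <- ni$node[ov >= cfg$min_node_overlap]
      if (length(hit) == 0L) next
      paths[[length(paths) + 1L]] <- list(
        read_id = tr$read_id, node = hit, orient = rep("+", length(hit)))
    }
  }
  if (decoy_transitive) {
    for (h in seq_along(sim$haps)) {
      ids <- node_info$node[node_info$hap == h]
      if (length(ids) < 3L) next
      for (j in seq_len(decoy_support)) {
        paths[[length(paths) + 1L]] <- list(
          read_id = sprintf("chimera_h%d_%02d", h, j),
          node = ids[c(1L, 3L)], orient = c("+", "+"))
      }
    }
  }
  list(graph = graph, node_info = node_info, paths = paths)
}

#' Planted fragmented alignments of contigs against the reference
#'
#' Stands in for a long-read aligner: each contig's node provenance is
#' projected through the haplotype `src` maps onto reference coordinates,
#' and every node span is fragmented into elements of about `frag_len` bp,
#' one PAF record each.
#'
#' @param contigs List of contigs from [dfs_contigs()].
#' @param contig_seqs Named character vector of contig sequences.
#' @param node_info Node provenance from [build_truth_graph()].
#' @param sim The `sim_region` the graph was built from.
#' @param frag_len Target element length (bp).
#' @return data.frame of PAF alignment records (contig on the query side,
#'   `ref` on the target side).
#' @export
simulate_contig_alignments <- function(contigs, contig_seqs, node_info, sim,
                                       frag_len = 2000L) {
  cfg <- sim$cfg
  ref_len <- nchar(sim$reference[["ref"]])
  rows <- list()
  for (ctg in contigs) {
    qlen <- nchar(contig_seqs[[ctg$id]])
    off <- 0L
    for (j in seq_along(ctg$node)) {
      ni <- node_info[node_info$node == ctg$node[j], , drop = FALSE]
      if (nrow(ni) == 0L) stop("unknown node in contig: ", ctg$node[j])
      if (ctg$orient[j] != "+") stop("planted graphs are forward-stranded")
      src <- sim$haps[[ni$hap]]$src
      nlen <- ni$hap_end - ni$hap_start + 1L
      cuts <- unique(c(seq(0L, nlen, by = frag_len), nlen))
      for (ci in seq_len(length(cuts) - 1L)) {
        a <- ni$hap_start + cuts[ci]          # 1-based haplotype coords
        b <- ni$hap_start + cuts[ci + 1L] - 1L
        elen <- b - a + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = ctg$id, query_len = qlen,
          query_start = off + cuts[ci], query_end = off + cuts[ci + 1L],
          strand = "+", target_id = "ref", target_len = ref_len,
          target_start = cfg$shore_len + src[a] - 1L,
          target_end = cfg$shore_len + src[b],
          n_match = round(0.98 * elen), block_len = elen, mapq = 60L,
          stringsAsFactors = FALSE)
      }
      off <- off + nlen
    }
  }
  if (length(rows) == 0L) return(empty_paf())
  do.call(rbind, rows)
}

#' Planted read-vs-contig alignments
#'
#' Stands in for aligning the recalled reads back to the contigs: a read is
#' reported as aligning to every contig whose reference span overlaps the
#' read's planted reference interval by at least `min_overlap` bp,
#' regardless of haplotype — near-identical haplotype contigs capture each
#' other's reads exactly as they do under a real aligner. This is the
#' cross-haplotype HiFi linkage the phasing objective's homology penalty
#' exists for.
#'
#' @param hifi Output of [simulate_hifi()].
#' @param contigs List of contigs from [dfs_contigs()].
#' @param node_info Node provenance from [build_truth_graph()].
#' @param sim The `sim_region`.
#' @param min_overlap Minimum reference-span overlap (bp).
#' @return data.frame with columns `query_id` (read) and `target_id`
#'   (contig), suitable for [hifi_link_signals()].
#' @export
simulate_read_contig_alignments <- function(hifi, contigs, node_info, sim,
                                            min_overlap = 500L) {
  spans <- do.call(rbind, lapply(contigs, function(ctg) {
    ni <- node_info[node_info$node %in% ctg$node, , drop = FALSE]
    data.frame(contig_id = ctg$id, ref_start = min(ni$ref_start),
               ref_end = max(ni$ref_end), stringsAsFactors = FALSE)
  }))
  tr <- hifi$truth[!is.na(hifi$truth$hap_start), , drop = FALSE]
  rs <- vapply(seq_len(nrow(tr)), function(i) {
    sim$haps[[tr$hap[i]]]$src[tr$hap_start[i]]
  }, 0L)
  re <- vapply(seq_len(nrow(tr)), function(i) {
    sim$haps[[tr$hap[i]]]$src[tr$hap_end[i]]
  }, 0L)
  ov <- outer(re, spans$ref_end, pmin) - outer(rs, spans$ref_start, pmax) + 1L
  idx <- which(ov >= min_overlap, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(query_id = character(0), target_id = character(0)))
  }
  data.frame(query_id = tr$read_id[idx[, 1]],
             target_id = spans$contig_id[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Simulate a complete diploid phasing instance
#'
#' Wires the generator end to end for phasing studies: a diploid region,
#' HiFi reads, the fragmented (isolated, staggered) truth graph, contigs,
#' Hi-C pairs, planted placements, and the signal matrices. The defaults
#' are the package's diploid study conditions: a ~29 kb array per
#' haplotype split into 8 contigs, 1% haplotype divergence, 30x HiFi,
#' 80x Hi-C with 5x intra-haplotype contact enrichment.
#'
#' @param seed Integer seed.
#' @param n_monomers,shore_len,hifi_len_mean,unitigs_per_hap,inter_hap_noise,hic_depth,hic_decay_exponent
#'   Passed to [sim_config()].
#' @param ... Further arguments to [sim_config()].
#' @return List with `sim`, `hifi`, `graph` (truth-graph list), `asm`
#'   (assembly), `M` (a `signal_matrices`), `placements`, `hap_of` (named
#'   truth haplotype per contig) and `truth_state` (the planted state
#'   vector, haplotype 1 = maternal).
#' @export
simulate_phasing_instance <- function(seed, n_monomers = 160L,
                                      shore_len = 3000L,
                                      hifi_len_mean = 6000L,
                                      unitigs_per_hap = 8L,
                                      inter_hap_noise = 1 / 6,
                                      hic_depth = 80,
                                      hic_decay_exponent = 1.0, ...) {
  cfg <- sim_config(seed = seed, n_monomers = n_monomers,
                    shore_len = shore_len, ploidy = 2L,
                    hifi_len_mean = hifi_len_mean,
                    unitigs_per_hap = unitigs_per_hap,
                    inter_hap_noise = inter_hap_noise, hic_depth = hic_depth,
                    hic_decay_exponent = hic_decay_exponent, ...)
  sim <- simulate_region(cfg)
  hifi <- simulate_hifi(sim)
  tg <- build_truth_graph(sim, hifi, isolated = TRUE, stagger = TRUE)
  asm <- assemble_contigs(tg$graph, tg$paths)
  hic <- simulate_hic(sim)
  toi_len <- sim$toi$end - sim$toi$start
  placements <- do.call(rbind, lapply(asm$contigs, function(ctg) {
    ni <- tg$node_info[tg$node_info$node %in% ctg$node, , drop = FALSE]
    data.frame(contig_id = ctg$id, start = min(ni$ref_start) - 1L,
               end = max(ni$ref_end), strand = "+",
               midpoint = (min(ni$ref_start) - 1L + max(ni$ref_end)) / 2,
               stringsAsFactors = FALSE)
  }))
  shores <- c(matL = sim$haps[[1]]$shoreL, matR = sim$haps[[1]]$shoreR,
              patL = sim$haps[[2]]$shoreL, patR = sim$haps[[2]]$shoreR)
  shore_hap <- c(matL = "maternal", matR = "maternal",
                 patL = "paternal", patR = "paternal")
  shore_pos <- c(matL = 0, matR = toi_len, patL = 0, patR = toi_len)
  links <- simulate_read_contig_alignments(hifi, asm$contigs, tg$node_info, sim)
  M <- signal_matrices(asm$seqs, shores, shore_hap, shore_pos, placements,
                       hic, links, toi_len)
  hap_of <- vapply(asm$contigs, function(ctg) {
    unique(tg$node_info$hap[tg$node_info$node %in% ctg$node])[1]
  }, 0L)
  names(hap_of) <- names(asm$seqs)
  truth_state <- setNames(ifelse(hap_of[M$contig_ids] == 1L, 1L, 2L),
                          M$contig_ids)
  list(sim = sim, hifi = hifi, graph = tg, asm = asm, M = M,
       placements = placements, hap_of = hap_of, truth_state = truth_state)
}

#' Accuracy of a phasing state against the planted haplotypes
#'
#' Fraction of contigs assigned to their planted haplotype, maximised over
#' the global maternal/paternal swap. Discarded and collapsed contigs count
#' as errors.
#'
#' @param state Named state vector from [run_annealing()].
#' @param hap_of Named truth haplotype (1 or 2) per contig.
#' @return Numeric accuracy in `[0, 1]`.
#' @export
phasing_accuracy <- function(state, hap_of) {
  hap <- hap_of[names(state)]
  direct <- mean((state == 1L & hap == 1L) | (state == 2L & hap == 2L))
  swapped <- mean((state == 1L & hap == 2L) | (state == 2L & hap == 1L))
  max(direct, swapped)
}

#' Simulate a monomer population with region-local drift
#'
#' Emulates the situation in which monomers within one region (e.g. one
#' subtelomere) derive from a region-private pool of variants: each region
#' gets its own drifted consensus and a pool of `pool_size` variants, from
#' which `n_monomers` monomers are drawn with replacement. Regions share no
#' pool, so intra-region monomer sets overlap far more than inter-region
#' ones.
#'
#' @param n_regions Number of regions.
#' @param n_monomers Monomers per region.
#' @param monomer_len Monomer length (bp).
#' @param pool_size Variants in each region's private pool.
#' @param drift Substitution rate from the global consensus to each
#'   region's consensus.
#' @param variant_rate Substitution rate from the region consensus to each
#'   pool variant.
#' @param seed Integer seed.
#' @return List of character vectors of monomer sequences, one per region.
#' @export
simulate_monomer_population <- function(n_regions = 5L, n_monomers = 200L,
                                        monomer_len = 181L, pool_size = 30L,
                                        drift = 0.05, variant_rate = 0.01,
                                        seed = 1L) {
  set.seed(seed)
  global <- random_dna(monomer_len)
  lapply(seq_len(n_regions), function(r) {
    cons <- point_mutate(global, drift)
    pool <- vapply(seq_len(pool_size), function(i) {
      point_mutate(cons, variant_rate)
    }, "")
    sample(pool, n_monomers, replace = TRUE)
  })
}
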