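# (read, contig) incidence derived from read paths: a read is linked to
# every contig sharing at least one graph node with its path.
read_contig_links <- function(read_paths, contigs) {
  rows <- list()
  node_sets <- lapply(contigs, `[[`, "node")
  ids <- vapply(contigs, `[[`, "", "id")
  for (p in read_paths) {
    hit <- ids[vapply(node_sets, function(ns) any(p$node %in% ns), TRUE)]
    for (cid in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = p$read_id, target_id = cid, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(query_id = character(0), target_id = character(0)))
  }
  do.call(rbind, rows)
}

#' Run the full gap-filling pipeline
#'
#' Recall -> contig generation -> placement -> (diploid) phasing ->
#' scaffolds. Alignment artifacts that external aligners would produce are
#' supplied as inputs or via the `align_contigs` callback, keeping the
#' pipeline free of external binaries.
#'
#' @param reads Named character vector of HiFi reads.
#' @param read_aln Read-vs-reference PAF records (whole genome; the
#'   pipeline restricts to TOI overlap).
#' @param graph A `unitig_graph` built on the reads.
#' @param read_paths Read paths on the graph (see [parse_gaf()]).
#' @param ref Named character vector holding the reference.
#' @param toi List `chrom, start, end`: the reference TOI.
#' @param model A `recall_model`.
#' @param ploidy 1 or 2.
#' @param align_contigs `function(contig_seqs, contigs)` returning
#'   contig-vs-reference PAF records.
#' @param shores,shore_hap,shore_pos Query shores for phasing (see
#'   [signal_matrices()]); required when `ploidy = 2`.
#' @param hic_pairs Hi-C pairs (required when `ploidy = 2`).
#' @param read_contig_aln Read-vs-contig alignments for the HiFi phasing
#'   signals: a data.frame (`query_id` read, `target_id` contig), or a
#'   function of the contig list returning one (contigs only exist after
#'   assembly). Derived from the graph read paths when `NULL` (note that
#'   path-derived links never cross haplotypes, unlike aligner output).
#' @param min_support Graph-edge support threshold.
#' @param seed Integer seed driving the genetic algorithm and phasing.
#' @param gap_n `N`s between scaffolded contigs.
#' @param k_phase k-mer length for phasing signals.
#' @param anneal_restarts Restart budget of the phasing search.
#' @return List with `recalled`, `asm`, `kept`, `contig_aln`, `candidates`,
#'   `ga`, `state`, `scaffolds`.
#' @export
fill_pipeline <- function(reads, read_aln, graph, read_paths, ref, toi, model,
                          ploidy, align_contigs, shores = NULL,
                          shore_hap = NULL, shore_pos = NULL,
                          hic_pairs = NULL, read_contig_aln = NULL,
                          min_support = 2L, seed = 1L,
                          gap_n = 100L, k_phase = 31L,
                          anneal_restarts = 200L) {
  on_toi <- read_aln$target_id == toi$chrom &
    read_aln$target_end > toi$start & read_aln$target_start < toi$end
  recalled <- recall_reads(read_aln[on_toi, , drop = FALSE], reads, ref, model)
  log_msg("recalled ", length(recalled), " of ",
          length(unique(read_aln$query_id)), " candidate reads")

  paths <- Filter(function(p) p$read_id %in% recalled, read_paths)
  asm <- assemble_contigs(graph, paths, min_support)
  log_msg("assembled ", length(asm$seqs), " contigs")

  contig_aln <- align_contigs(asm$seqs, asm$contigs)
  lens <- setNames(nchar(asm$seqs), names(asm$seqs))
  kept <- filter_contigs(lens, contig_aln, toi$chrom, toi$start, toi$end)
  toi_len <- toi$end - toi$start
  candidates <- lapply(kept, function(cid) {
    sub <- contig_aln[contig_aln$query_id == cid, , drop = FALSE]
    enumerate_candidates(cid, lens[[cid]], sub, toi_len, toi$start)
  })
  names(candidates) <- kept
  candidates <- candidates[vapply(candidates, nrow, 0L) > 0L]
  if (length(candidates) == 0L) stop("no placeable contigs after filtering")

  components <- setNames(
    vapply(asm$contigs, function(ctg) ctg$component %||% NA_integer_, 0L),
    vapply(asm$contigs, `[[`, "", "id"))
  ga <- run_ga(candidates, toi_len, ploidy, components, seed = seed)
  placed_ids <- ga$placements$contig_id

  if (ploidy == 1L) {
    state <- setNames(rep(1L, length(placed_ids)), placed_ids)
  } else {
    stopifnot(!is.null(shores), !is.null(shore_hap), !is.null(shore_pos),
              !is.null(hic_pairs))
    links <- if (is.function(read_contig_aln)) {
      read_contig_aln(asm$contigs)
    } else {
      read_contig_aln %||% read_contig_links(paths, asm$contigs)
    }
    M <- signal_matrices(asm$seqs[placed_ids], shores, shore_hap, shore_pos,
                         ga$placements, hic_pairs, links, toi_len, k = k_phase)
    ann <- run_annealing(M, n_restarts = anneal_restarts, seed = seed)
    state <- ann$state
  }
  scaffolds <- build_scaffolds(ga$placements, state, asm$seqs, gap_n)
  list(recalled = recalled, asm = asm, kept = kept, contig_aln = contig_aln,
       candidates = candidates, ga = ga, state = state, scaffolds = scaffolds)
}

#' Run the pipeline end to end on a simulated region and score it
#'
#' Generates a region with [simulate_region()] and friends, trains the
#' recall model on homologous templates, runs [fill_pipeline()], and scores
#' the result against the planted truth with [completeness_correctness()].
#' This is the package's self-contained validation run.
#'
#' @param seed Integer seed.
#' @param ploidy 1 or 2.
#' @param n_monomers Array size in monomers (default ~50 kb of 181 bp
#'   units).
#' @param ... Further arguments to [sim_config()].
#' @return List with `result` (the [fill_pipeline()] output), `sim`, and
#'   `quality`: a data.frame with one row per haplotype
#'   (`hap, completeness, correctness`).
#' @export
fill_simulated_region <- function(seed, ploidy, n_monomers = 276L, ...) {
  cfg <- sim_config(seed = seed, n_monomers = n_monomers, shore_len = 4000L,
                    ploidy = ploidy, hifi_depth = 30, hifi_len_mean = 8000L,
                    unitigs_per_hap = 6L, inter_hap_noise = 1 / 6,
                    hic_depth = 80, hic_decay_exponent = 1.0, ...)
  sim <- simulate_region(cfg)
  hifi <- simulate_hifi(sim)
  tg <- build_truth_graph(sim, hifi, isolated = (ploidy == 2L),
                          stagger = (ploidy == 2L))
  rare <- extract_rare_kmers(count_kmers(sim$reference, 21L), 3L)
  model <- fit_recall_model(
    simulate_training_observations(sim, n_obs = 120L, rare_set = rare))
  toi_len <- sim$toi$end - sim$toi$start
  args <- list(
    reads = hifi$reads, read_aln = hifi$paf, graph = tg$graph,
    read_paths = tg$paths, ref = sim$reference, toi = sim$toi, model = model,
    ploidy = ploidy, seed = seed,
    align_contigs = function(seqs, contigs) {
      simulate_contig_alignments(contigs, seqs, tg$node_info, sim)
    })
  if (ploidy == 2L) {
    args$shores <- c(matL = sim$haps[[1]]$shoreL, matR = sim$haps[[1]]$shoreR,
                     patL = sim$haps[[2]]$shoreL, patR = sim$haps[[2]]$shoreR)
    args$shore_hap <- c(matL = "maternal", matR = "maternal",
                        patL = "paternal", patR = "paternal")
    args$shore_pos <- c(matL = 0, matR = toi_len, patL = 0, patR = toi_len)
    args$hic_pairs <- simulate_hic(sim)
    args$read_contig_aln <- function(contigs) {
      simulate_read_contig_alignments(hifi, contigs, tg$node_info, sim)
    }
  }
  res <- do.call(fill_pipeline, args)
  quality <- do.call(rbind, lapply(seq_len(ploidy), function(h) {
    hap_ids <- if (ploidy == 1L) {
      res$ga$placements$contig_id
    } else {
      lab <- if (h == 1L) c(1L, 3L) else c(2L, 3L)
      names(res$state)[res$state %in% lab]
    }
    paf <- planted_asm_truth_paf(hap_ids, res$asm$contigs, res$asm$seqs,
                                 tg$node_info, sim, h)
    asm_len <- sum(nchar(res$asm$seqs[hap_ids]))
    if (nrow(paf) == 0L || asm_len == 0L) {
      return(data.frame(hap = h, completeness = 0, correctness = 0))
    }
    q <- completeness_correctness(paf, nchar(sim$haps[[h]]$seq), asm_len)
    data.frame(hap = h, completeness = q$completeness,
               correctness = q$correctness)
  }))
  list(result = res, sim = sim, quality = quality)
}

#' Planted assembly-vs-truth alignments for evaluation
#'
#' Projects each contig's reference span (from its node provenance) onto
#' one haplotype's coordinates through the inverse of the haplotype `src`
#' map, emitting one continuous alignment per contig. Stands in for the
#' assembly-vs-truth aligner of the evaluation stage.
#'
#' @param contig_ids Contigs to include (e.g. one haplotype's).
#' @param contigs Contig list from [dfs_contigs()].
#' @param contig_seqs Named character vector of contig sequences.
#' @param node_info Node provenance from [build_truth_graph()].
#' @param sim The `sim_region`.
#' @param hap Haplotype index of the truth being compared against.
#' @return data.frame of PAF records (contig query vs haplotype-array
#'   target).
#' @export
planted_asm_truth_paf <- function(contig_ids, contigs, contig_seqs,
                                  node_info, sim, hap) {
  hp <- sim$haps[[hap]]
  tlen <- nchar(hp$seq)
  array_len <- nchar(paste(sim$monomers, collapse = ""))
  inv <- rep(NA_integer_, array_len)
  inv[hp$src] <- seq_along(hp$src)
  fill_next <- function(pos) {
    while (pos <= array_len && is.na(inv[pos])) pos <- pos + 1L
    if (pos > array_len) NA_integer_ else inv[pos]
  }
  fill_prev <- function(pos) {
    while (pos >= 1L && is.na(inv[pos])) pos <- pos - 1L
    if (pos < 1L) NA_integer_ else inv[pos]
  }
  rows <- list()
  for (ctg in contigs) {
    if (!(ctg$id %in% contig_ids)) next
    ni <- node_info[node_info$node %in% ctg$node, , drop = FALSE]
    rs <- min(ni$ref_start); re <- max(ni$ref_end)
    ts <- fill_next(rs); te <- fill_prev(re)
    if (is.na(ts) || is.na(te) || te <= ts) next
    qlen <- nchar(contig_seqs[[ctg$id]])
    blk <- te - ts + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = ctg$id, query_len = qlen, query_start = 0L,
      query_end = qlen, strand = "+", target_id = sprintf("hap%d", hap),
      target_len = tlen, target_start = ts - 1L, target_end = te,
      n_match = round(0.98 * blk), block_len = blk, mapq = 60L,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty_paf())
  do.call(rbind, rows)
}
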