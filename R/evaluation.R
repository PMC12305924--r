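#' Completeness and correctness of an assembly against a ground truth
#'
#' Every continuously aligned block is a correct region. Aligned blocks are
#' merged (union, no double counting) independently on the truth side and
#' on the assembly side; completeness is the truth-side union divided by the
#' truth length, correctness the assembly-side union divided by the
#' assembly length.
#'
#' @param asm_vs_truth data.frame of assembly-vs-truth alignments with the
#'   assembly on the query side and the truth on the target side.
#' @param truth_len,asm_len Total lengths (bp) of truth and assembly.
#' @return List with `completeness`, `correctness`, `correct_bp_truth`,
#'   `correct_bp_asm`, `truth_len`, `asm_len`.
#' @export
completeness_correctness <- function(asm_vs_truth, truth_len, asm_len) {
  if (truth_len <= 0L || asm_len <= 0L) {
    stop("truth and assembly lengths must be positive")
  }
  union_bp <- function(ids, starts, ends) {
    if (length(starts) == 0L) return(0L)
    # merge per sequence: intervals on different sequences never overlap
    total <- 0L
    for (sub in split(seq_along(starts), ids)) {
      ir <- IRanges::reduce(IRanges::IRanges(start = starts[sub] + 1L,
                                             end = ends[sub]))
      total <- total + sum(IRanges::width(ir))
    }
    total
  }
  truth_bp <- union_bp(asm_vs_truth$target_id, asm_vs_truth$target_start,
                       asm_vs_truth$target_end)
  asm_bp <- union_bp(asm_vs_truth$query_id, asm_vs_truth$query_start,
                     asm_vs_truth$query_end)
  list(completeness = truth_bp / truth_len,
       correctness = asm_bp / asm_len,
       correct_bp_truth = truth_bp, correct_bp_asm = asm_bp,
       truth_len = truth_len, asm_len = asm_len)
}

#' LIS identity score between a truth and an assembly sequence
#'
#' Takes the canonical k-mers unique within the truth AND unique within the
#' assembly, orders the shared ones by assembly position, and computes the
#' longest non-decreasing subsequence of their truth positions. The score is
#' that LIS length divided by the number of unique k-mers in the assembly
#' (0 when the assembly has none).
#'
#' @param truth_seq,asm_seq DNA strings.
#' @param k k-mer length.
#' @return Numeric score in `[0, 1]`.
#' @export
lis_identity_score <- function(truth_seq, asm_seq, k = 31L) {
  stopifnot(nchar(truth_seq) > 0L, nchar(asm_seq) > 0L)
  tk <- seq_kmers(truth_seq, k)
  ak <- seq_kmers(asm_seq, k)
  t_tab <- table(tk)
  a_tab <- table(ak)
  t_uniq <- names(t_tab)[t_tab == 1L]
  a_uniq <- names(a_tab)[a_tab == 1L]
  n_asm_uniq <- length(a_uniq)
  if (n_asm_uniq == 0L) return(0)
  shared <- intersect(t_uniq, a_uniq)
  if (length(shared) == 0L) return(0)
  t_pos <- setNames(attr(tk, "pos")[match(shared, tk)], shared)
  a_pos <- setNames(attr(ak, "pos")[match(shared, ak)], shared)
  ord <- order(a_pos, t_pos)
  lis_score(unname(t_pos[ord])) / n_asm_uniq
}

#' Classify assembly improvement from reference-free quality scores
#'
#' Decision rules over regional/structural assembly-quality indices (R_AQI,
#' S_AQI, e.g. from CRAQ) and HiFi coverages of the original and new
#' assemblies. Strictly improved: `r_new > 1.1 * r_ori`. Loosely improved:
#' `r_new > r_ori`, or all of `r_new > r_ori / 1.6`, `s_new > s_ori`, and
#' the new coverage closer to the genome-wide coverage than the original.
#' Strict implies loose.
#'
#' @param r_aqi_ori,s_aqi_ori,r_aqi_new,s_aqi_new Quality indices.
#' @param cov_ori,cov_new,cov_whole HiFi coverages (original assembly, new
#'   assembly, genome-wide).
#' @return List with logicals `strict` and `loose` and a `label` in
#'   `c("strict", "loose", "none")`.
#' @export
classify_improvement <- function(r_aqi_ori, s_aqi_ori, r_aqi_new, s_aqi_new,
                                 cov_ori, cov_new, cov_whole) {
  stopifnot(is.finite(c(r_aqi_ori, s_aqi_ori, r_aqi_new, s_aqi_new,
                        cov_ori, cov_new, cov_whole)))
  strict <- r_aqi_new > 1.1 * r_aqi_ori
  loose <- r_aqi_new > r_aqi_ori ||
    (r_aqi_new > r_aqi_ori / 1.6 && s_aqi_new > s_aqi_ori &&
       abs(cov_whole - cov_new) < abs(cov_whole - cov_ori))
  loose <- loose || strict
  list(strict = strict, loose = loose,
       label = if (strict) "strict" else if (loose) "loose" else "none")
}
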