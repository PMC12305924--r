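#' Extract rare k-mers from a spectrum
#'
#' Rare k-mers are the canonical k-mers occurring at most `rare_max_count`
#' times in the reference genome (default 3, i.e. "fewer than 4"). Their
#' co-occurrence between a read and its aligned reference region drives the
#' read-recruitment hypothesis test.
#'
#' @param spectrum A `kmer_spectrum` from [count_kmers()].
#' @param rare_max_count Maximum count for a k-mer to be considered rare.
#' @return Character vector of rare canonical k-mers.
#' @export
extract_rare_kmers <- function(spectrum, rare_max_count = 3L) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  names(spectrum$counts)[spectrum$counts <= rare_max_count]
}

#' Observe rare-k-mer co-occurrence for one alignment
#'
#' For an alignment between reference region R and read region Q, `y` is the
#' number of distinct rare k-mers present in R and `x` the number of those
#' also present anywhere in Q. Membership is tested on canonical k-mer sets,
#' so strand and small indel shifts do not matter.
#'
#' @param aln One alignment record (a 1-row data.frame as from [parse_paf()]).
#' @param ref_seq Named character vector holding the alignment target.
#' @param read_seq The read sequence (single string).
#' @param rare_set Character vector of rare canonical k-mers (from
#'   [extract_rare_kmers()]).
#' @param k k-mer length.
#' @return List with `read_id`, `x` and `y` (`x = y = 0` when the aligned
#'   region is shorter than `k`).
#' @export
observe_alignment <- function(aln, ref_seq, read_seq, rare_set, k = 21L) {
  tgt <- ref_seq[[aln$target_id]]
  if (is.null(tgt) || is.na(tgt)) stop("alignment target not found: ", aln$target_id)
  R <- substr(tgt, aln$target_start + 1L, aln$target_end)
  Q <- substr(read_seq, aln$query_start + 1L, aln$query_end)
  if (nchar(R) < k || nchar(Q) < k) {
    return(list(read_id = aln$query_id, x = 0L, y = 0L))
  }
  r_km <- intersect(kmer_set(R, k), rare_set)
  q_km <- kmer_set(Q, k)
  list(read_id = aln$query_id, x = sum(r_km %in% q_km), y = length(r_km))
}

#' Fit the recall model by maximum likelihood
#'
#' Under the model `X ~ Normal(delta * y, sigma2)` for the number of rare
#' k-mers shared between homologous aligned regions, the maximum-likelihood
#' estimates from training observations `(x_i, y_i)` are
#' `delta = sum(y_i x_i) / sum(y_i^2)` and
#' `sigma2 = sum((x_i - delta y_i)^2) / N` (the usual residual variance of
#' the regression through the origin). `delta` is clamped to `[0, 1)` and
#' `sigma2` floored at a small positive epsilon.
#'
#' @param observations data.frame with numeric columns `x` and `y`.
#' @param alpha Two-sided significance level for the downstream test.
#' @param k Rare k-mer length the observations were made with.
#' @param rare_max_count Rarity cutoff the observations were made with.
#' @param eps Floor for `sigma2` and clamp margin for `delta`.
#' @return A `recall_model` with fields `delta`, `sigma2`, `alpha`,
#'   `z_half_alpha`, `k`, `rare_max_count`.
#' @export
fit_recall_model <- function(observations, alpha = 0.05, k = 21L,
                             rare_max_count = 3L, eps = 1e-8) {
  x <- as.numeric(observations$x)
  y <- as.numeric(observations$y)
  stopifnot(length(x) == length(y), all(x >= 0), all(x <= y))
  use <- y > 0
  if (sum(use) < 2L) stop("model fit needs at least 2 observations with y > 0")
  x <- x[use]; y <- y[use]
  delta <- sum(y * x) / sum(y^2)
  delta <- min(max(delta, 0), 1 - eps)
  sigma2 <- max(mean((x - delta * y)^2), eps)
  recall_model(delta, sigma2, alpha, k, rare_max_count)
}

#' Construct a recall model directly
#'
#' Used for the packaged fallback when no training observations from a
#' homologous trusted region are available; the fallback values
#' (`delta = 0.85`, `sigma2 = 25`) are logged when used.
#'
#' @inheritParams fit_recall_model
#' @param delta Linear coefficient relating reference rare-k-mer count `y` to
#'   the expected shared count, `0 <= delta < 1`.
#' @param sigma2 Variance of the shared count, `> 0`.
#' @return A `recall_model`.
#' @export
recall_model <- function(delta = 0.85, sigma2 = 25, alpha = 0.05,
                         k = 21L, rare_max_count = 3L) {
  stopifnot(delta >= 0, delta < 1, sigma2 > 0, alpha > 0, alpha < 1)
  structure(list(delta = delta, sigma2 = sigma2, alpha = alpha,
                 z_half_alpha = qnorm(1 - alpha / 2), k = as.integer(k),
                 rare_max_count = as.integer(rare_max_count)),
            class = "recall_model")
}

#' @export
print.recall_model <- function(x, ...) {
  cat(sprintf("recall_model: delta = %.4f, sigma2 = %.4f, alpha = %.3f (z = %.4f), k = %d, rare count <= %d\n",
              x$delta, x$sigma2, x$alpha, x$z_half_alpha, x$k, x$rare_max_count))
  invisible(x)
}

#' Two-sided rare-k-mer test for one observation
#'
#' Accepts the alignment iff
#' `x` lies in `[delta*y - z*sigma, delta*y + z*sigma]` (boundaries
#' inclusive), with `z` the standard-normal quantile at `alpha/2`.
#'
#' @param model A `recall_model`.
#' @param x,y Observation counts (vectorised).
#' @return Logical vector.
#' @export
test_alignment <- function(model, x, y) {
  stopifnot(inherits(model, "recall_model"))
  half <- model$z_half_alpha * sqrt(model$sigma2)
  abs(x - model$delta * y) <= half
}

#' Recall the reads belonging to the target region
#'
#' Every alignment of a candidate read against the reference TOI is scored
#' with [observe_alignment()] and tested with [test_alignment()]; a read is
#' recalled as soon as one of its alignments passes. Reads with no TOI
#' alignment are never recalled.
#'
#' @param alignments data.frame of read-vs-reference alignments, already
#'   restricted to those overlapping the reference TOI.
#' @param reads Named character vector of read sequences.
#' @param ref Named character vector with the reference sequence(s) the
#'   alignments target.
#' @param model A `recall_model`.
#' @param rare_set Rare canonical k-mers of the whole reference genome;
#'   computed from `ref` with the model's `k`/`rare_max_count` when `NULL`.
#' @return Character vector of recalled read ids.
#' @export
recall_reads <- function(alignments, reads, ref, model, rare_set = NULL) {
  stopifnot(inherits(model, "recall_model"))
  if (nrow(alignments) == 0L) return(character(0))
  missing_ids <- setdiff(unique(alignments$query_id), names(reads))
  if (length(missing_ids)) {
    stop("read id(s) in alignments absent from reads: ",
         paste(head(missing_ids, 5L), collapse = ", "))
  }
  if (is.null(rare_set)) {
    rare_set <- extract_rare_kmers(count_kmers(ref, model$k), model$rare_max_count)
  }
  recalled <- character(0)
  for (rid in unique(alignments$query_id)) {
    rows <- alignments[alignments$query_id == rid, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      obs <- observe_alignment(rows[i, , drop = FALSE], ref, reads[[rid]],
                               rare_set, model$k)
      if (test_alignment(model, obs$x, obs$y)) {
        recalled <- c(recalled, rid)
        break
      }
    }
  }
  recalled
}
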