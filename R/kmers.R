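#' Enumerate the k-mers of one sequence
#'
#' Returns every k-mer of `seq` in positional order. k-mers containing a
#' non-ACGT character are dropped (their positions too). With
#' `canonical = TRUE` each k-mer is replaced by the lexicographic minimum of
#' itself and its reverse complement, which is the representation used
#' throughout the package because tandem-repeat arrays carry units on both
#' strands.
#'
#' @param seq A single DNA string.
#' @param k Odd k-mer length, 3..31.
#' @param canonical Canonicalise against the reverse complement?
#' @return Character vector of k-mers with attribute `pos` (1-based start
#'   positions in `seq`). Empty when `nchar(seq) < k`.
#' @export
seq_kmers <- function(seq, k, canonical = TRUE) {
  stopifnot(length(seq) == 1L, k >= 3L, k <= 31L)
  n <- nchar(seq)
  if (n < k) return(structure(character(0), pos = integer(0)))
  starts <- seq_len(n - k + 1L)
  km <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", km)
  km <- km[ok]; starts <- starts[ok]
  if (canonical && length(km)) {
    rcseq <- revcomp(seq)
    # forward k-mer starting at i pairs with the revcomp k-mer at n-k+2-i
    rk <- substring(rcseq, n - k + 2L - starts, n + 1L - starts)
    km <- ifelse(km <= rk, km, rk)
  }
  structure(km, pos = starts)
}

#' Count canonical k-mers over a set of sequences
#'
#' An exact in-memory counter over canonical k-mers (lexicographic min of a
#' k-mer and its reverse complement). k-mers spanning an `N` (or any
#' non-ACGT character) are skipped.
#'
#' @param records Named character vector of DNA sequences.
#' @param k Odd k-mer length, 3..31.
#' @return A `kmer_spectrum`: list with `k` and `counts`, a named integer
#'   vector mapping canonical k-mer to occurrence count.
#' @export
count_kmers <- function(records, k) {
  stopifnot(k %% 2L == 1L, k >= 3L, k <= 31L)
  all_km <- unlist(lapply(records, seq_kmers, k = k, canonical = TRUE),
                   use.names = FALSE)
  if (length(all_km) == 0L) {
    counts <- setNames(integer(0), character(0))
  } else {
    dt <- data.table::data.table(km = all_km)
    agg <- dt[, .N, by = "km"]
    data.table::setorder(agg, km)
    counts <- setNames(agg$N, agg$km)
  }
  structure(list(k = k, counts = counts), class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("kmer_spectrum: k =", x$k, ",", length(x$counts), "distinct canonical k-mers\n")
  invisible(x)
}

# Distinct canonical k-mer set of one sequence (character vector, no positions).
kmer_set <- function(seq, k) unique(as.character(seq_kmers(seq, k)))
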