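#' @importFrom stats qnorm rnorm runif median setNames dist wilcox.test
#' @importFrom utils read.table write.table adist head tail
NULL

# let data.table syntax work inside this package
.datatable.aware <- TRUE

# Vectorised reverse complement of plain character DNA. Base R on purpose:
# this sits on hot paths (k-mer extraction over many thousands of short
# sequences) where per-call external allocations are too costly.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan", intToUtf8(rev(utf8ToInt(s))))
  }, "", USE.NAMES = FALSE)
}

# Strand-canonical form of a sequence: lexicographic min of seq and revcomp.
canonical_seq <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

flip_orient <- function(o) ifelse(o == "+", "-", "+")

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(..., verbose = getOption("tandemfill.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[tandemfill] ", ...)
}
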