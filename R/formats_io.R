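#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; multi-line records are joined. This is the
#' carrier type for reads, contigs, shores and reference sequences throughout
#' the package: a named character vector over the alphabet `{A,C,G,T,N}`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  recs <- toupper(as.character(ss))
  # keep only the first whitespace-delimited token of each header, as aligners do
  names(recs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(recs))) stop("duplicate sequence ids in ", path)
  recs
}

#' Write sequences to a FASTA file
#'
#' @param records Named character vector of DNA sequences.
#' @param path Destination path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(records, path, width = 80L) {
  ss <- Biostrings::DNAStringSet(unname(records))
  names(ss) <- names(records)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' Format is chosen by the first non-empty character (`>` = FASTA,
#' `@` = FASTQ). Qualities are discarded.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("read file not found: ", path)
  first <- substr(readLines(path, n = 1L), 1L, 1L)
  if (length(first) == 0L) return(setNames(character(0), character(0)))
  if (first == ">") return(read_fasta(path))
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  recs <- toupper(as.character(ss))
  names(recs) <- sub("\\s.*$", "", names(ss))
  recs
}

paf_cols <- c("query_id", "query_len", "query_start", "query_end", "strand",
              "target_id", "target_len", "target_start", "target_end",
              "n_match", "block_len", "mapq")

#' Parse a PAF alignment file
#'
#' Reads the 12 mandatory PAF columns; optional SAM-style tags are ignored.
#' All coordinates are 0-based half-open, as in the PAF specification.
#'
#' @param path Path to a PAF file.
#' @return A data.frame of alignment records with columns
#'   `query_id, query_len, query_start, query_end, strand, target_id,
#'   target_len, target_start, target_end, n_match, block_len, mapq`.
#' @export
parse_paf <- function(path) {
  if (!file.exists(path)) stop("PAF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_paf())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop("PAF line(s) with fewer than 12 columns: line ",
         paste(which(nf < 12L)[seq_len(min(3L, sum(nf < 12L)))], collapse = ", "))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  aln <- data.frame(
    query_id = m[, 1], query_len = as.integer(m[, 2]),
    query_start = as.integer(m[, 3]), query_end = as.integer(m[, 4]),
    strand = m[, 5],
    target_id = m[, 6], target_len = as.integer(m[, 7]),
    target_start = as.integer(m[, 8]), target_end = as.integer(m[, 9]),
    n_match = as.integer(m[, 10]), block_len = as.integer(m[, 11]),
    mapq = as.integer(m[, 12]),
    stringsAsFactors = FALSE
  )
  validate_paf(aln)
  aln
}

empty_paf <- function() {
  df <- data.frame(query_id = character(0), query_len = integer(0),
                   query_start = integer(0), query_end = integer(0),
                   strand = character(0), target_id = character(0),
                   target_len = integer(0), target_start = integer(0),
                   target_end = integer(0), n_match = integer(0),
                   block_len = integer(0), mapq = integer(0),
                   stringsAsFactors = FALSE)
  df
}

validate_paf <- function(aln) {
  bad <- with(aln, query_start < 0L | query_start >= query_end |
                query_end > query_len |
                target_start < 0L | target_start >= target_end |
                target_end > target_len |
                n_match > block_len |
                !(strand %in% c("+", "-")))
  if (any(bad)) {
    stop("invalid PAF record(s) for query id(s): ",
         paste(unique(aln$query_id[bad])[seq_len(min(5L, sum(bad)))],
               collapse = ", "))
  }
  invisible(aln)
}

#' Write alignment records to a PAF file
#'
#' @param aln A data.frame of alignment records (see [parse_paf()]).
#' @param path Destination path.
#' @export
write_paf <- function(aln, path) {
  write.table(aln[, paf_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a GFA1 unitig graph
#'
#' Reads `S` (segment) and `L` (link) lines. Each `L` line becomes one
#' bidirected edge with orientation flags on both endpoints; the overlap
#' length is taken from a trailing `<n>M` CIGAR (0 otherwise). Edge read
#' support is initialised to 0 and filled by [count_edge_support()].
#'
#' @param path Path to a GFA1 file.
#' @return A `unitig_graph`: list with `nodes` (data.frame `id, seq, len`)
#'   and `edges` (data.frame `from, from_orient, to, to_orient, overlap,
#'   support`).
#' @export
parse_gfa <- function(path) {
  if (!file.exists(path)) stop("GFA file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  type <- vapply(fields, `[`, "", 1L)

  sf <- fields[type == "S"]
  nodes <- data.frame(
    id = vapply(sf, `[`, "", 2L),
    seq = toupper(vapply(sf, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  nodes$len <- nchar(nodes$seq)
  if (anyDuplicated(nodes$id)) stop("duplicate segment ids in ", path)

  lf <- fields[type == "L"]
  if (length(lf)) {
    ov <- vapply(lf, function(f) {
      cig <- if (length(f) >= 6L) f[[6]] else "0M"
      if (grepl("^[0-9]+M$", cig)) as.integer(sub("M$", "", cig)) else 0L
    }, 0L)
    edges <- data.frame(
      from = vapply(lf, `[`, "", 2L), from_orient = vapply(lf, `[`, "", 3L),
      to = vapply(lf, `[`, "", 4L), to_orient = vapply(lf, `[`, "", 5L),
      overlap = ov, support = 0L,
      stringsAsFactors = FALSE
    )
    unknown <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(unknown)) {
      stop("GFA L line references unknown segment(s): ",
           paste(unknown, collapse = ", "))
    }
  } else {
    edges <- data.frame(from = character(0), from_orient = character(0),
                        to = character(0), to_orient = character(0),
                        overlap = integer(0), support = integer(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "unitig_graph")
}

#' @export
print.unitig_graph <- function(x, ...) {
  cat("unitig_graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Write a unitig graph to GFA1
#'
#' @param graph A `unitig_graph` (see [parse_gfa()]).
#' @param path Destination path.
#' @export
write_gfa <- function(graph, path) {
  s <- sprintf("S\t%s\t%s", graph$nodes$id, graph$nodes$seq)
  l <- character(0)
  if (nrow(graph$edges)) {
    l <- sprintf("L\t%s\t%s\t%s\t%s\t%dM",
                 graph$edges$from, graph$edges$from_orient,
                 graph$edges$to, graph$edges$to_orient, graph$edges$overlap)
  }
  writeLines(c("H\tVN:Z:1.0", s, l), path)
  invisible(path)
}

# Index of oriented edges for fast membership tests. An oriented step
# (a,oa) -> (b,ob) traverses a stored edge if either the edge itself or its
# bidirected complement (b,flip(ob)) -> (a,flip(oa)) is present.
edge_keys <- function(edges) {
  paste(edges$from, edges$from_orient, edges$to, edges$to_orient, sep = "\r")
}

# For steps (a,oa)->(b,ob): index of the stored edge matched (NA if absent).
match_edge <- function(graph, from, from_orient, to, to_orient) {
  keys <- edge_keys(graph$edges)
  fwd <- paste(from, from_orient, to, to_orient, sep = "\r")
  rev <- paste(to, flip_orient(to_orient), from, flip_orient(from_orient), sep = "\r")
  idx <- match(fwd, keys)
  miss <- is.na(idx)
  idx[miss] <- match(rev[miss], keys)
  idx
}

#' Parse a GAF file of read paths on a unitig graph
#'
#' Only the path column (orientation syntax `>seg` / `<seg`) is used. Each
#' path is validated against the graph: every consecutive oriented step must
#' correspond to a bidirected edge. Paths containing a non-edge step are
#' excluded (with a message) rather than failing the whole file.
#'
#' @param path Path to a GAF file.
#' @param graph A `unitig_graph`.
#' @return List of read paths; each element is a list with `read_id`,
#'   `node` (character vector) and `orient` (`+`/`-` vector).
#' @export
parse_gaf <- function(path, graph) {
  if (!file.exists(path)) stop("GAF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  keep <- logical(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 6L) stop("GAF line ", i, " has fewer than 6 columns")
    p <- parse_gaf_path(f[[6]])
    ok <- TRUE
    if (length(p$node) > 1L) {
      idx <- match_edge(graph, head(p$node, -1L), head(p$orient, -1L),
                        tail(p$node, -1L), tail(p$orient, -1L))
      ok <- !anyNA(idx)
    }
    if (!all(p$node %in% graph$nodes$id)) ok <- FALSE
    if (ok) {
      out[[i]] <- list(read_id = f[[1]], node = p$node, orient = p$orient)
      keep[i] <- TRUE
    } else {
      log_msg("GAF path for read ", f[[1]], " uses a non-edge step; excluded")
    }
  }
  out[keep]
}

parse_gaf_path <- function(s) {
  toks <- regmatches(s, gregexpr("[><][^><]+", s))[[1]]
  if (length(toks) == 0L) stop("malformed GAF path: ", s)
  list(node = substring(toks, 2L),
       orient = ifelse(substring(toks, 1L, 1L) == ">", "+", "-"))
}

#' Write read paths to a GAF file
#'
#' @param paths List of read paths (see [parse_gaf()]).
#' @param graph The `unitig_graph` the paths refer to.
#' @param path Destination path.
#' @export
write_gaf <- function(paths, graph, path) {
  node_len <- setNames(graph$nodes$len, graph$nodes$id)
  lines <- vapply(paths, function(p) {
    pl <- sum(node_len[p$node])
    pstr <- paste0(ifelse(p$orient == "+", ">", "<"), p$node, collapse = "")
    sprintf("%s\t%d\t0\t%d\t+\t%s\t%d\t0\t%d\t%d\t%d\t60",
            p$read_id, pl, pl, pstr, pl, pl, pl, pl)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path Path to a BED3+ file (0-based half-open).
#' @return data.frame with columns `chrom, start, end` (plus `name` if present).
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4] <- "name"
  if (any(df$start < 0L | df$end <= df$start)) stop("invalid BED interval in ", path)
  df
}

#' Write intervals to a BED file
#'
#' @param df data.frame with columns `chrom, start, end` (extra columns kept).
#' @param path Destination path.
#' @export
write_bed <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read Hi-C pairs from a tabular pair file
#'
#' A dependency-free alternative to paired FASTQ: a TSV with columns
#' `read_id, seq1, seq2` (one row per pair, both end sequences inline).
#'
#' @param path Path to the pair TSV.
#' @return data.frame with columns `read_id, seq1, seq2`.
#' @export
read_hic_pairs <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("read_id", "seq1", "seq2") %in% names(df))) {
    stop("Hi-C pair file must have columns read_id, seq1, seq2")
  }
  df$seq1 <- toupper(df$seq1); df$seq2 <- toupper(df$seq2)
  df
}

#' Write Hi-C pairs to a tabular pair file
#'
#' @param pairs data.frame with columns `read_id, seq1, seq2`.
#' @param path Destination path.
#' @export
write_hic_pairs <- function(pairs, path) {
  write.table(pairs[, c("read_id", "seq1", "seq2")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
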