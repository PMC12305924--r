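#' Count read support for every graph edge
#'
#' Each oriented adjacency in a read path contributes +1 to the support of
#' the bidirected edge it traverses (a path traversing an edge twice counts
#' twice). Node in/out-degrees and connected-component labels (on the
#' undirected skeleton) are attached for downstream traversal.
#'
#' @param graph A `unitig_graph` from [parse_gfa()].
#' @param read_paths List of read paths from [parse_gaf()].
#' @return The graph with `edges$support` filled and `nodes$in_deg`,
#'   `nodes$out_deg`, `nodes$component` added.
#' @export
count_edge_support <- function(graph, read_paths) {
  support <- integer(nrow(graph$edges))
  for (p in read_paths) {
    if (length(p$node) < 2L) next
    idx <- match_edge(graph, head(p$node, -1L), head(p$orient, -1L),
                      tail(p$node, -1L), tail(p$orient, -1L))
    idx <- idx[!is.na(idx)]
    for (i in idx) support[i] <- support[i] + 1L
  }
  graph$edges$support <- support
  graph$nodes$in_deg <- as.integer(table(factor(graph$edges$to, graph$nodes$id)))
  graph$nodes$out_deg <- as.integer(table(factor(graph$edges$from, graph$nodes$id)))
  graph$nodes$component <- component_labels(graph)
  graph
}

# Connected components of the undirected skeleton (label = integer per node).
component_labels <- function(graph) {
  ids <- graph$nodes$id
  lab <- setNames(rep(NA_integer_, length(ids)), ids)
  adj <- split(c(graph$edges$to, graph$edges$from),
               c(graph$edges$from, graph$edges$to))
  comp <- 0L
  for (v in ids) {
    if (!is.na(lab[[v]])) next
    comp <- comp + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      if (!is.na(lab[[u]])) next
      lab[[u]] <- comp
      queue <- c(queue, setdiff(adj[[u]], names(lab)[!is.na(lab)]))
    }
  }
  unname(lab[ids])
}

# Out-edge indices per node (list keyed by node id).
out_edges_by_node <- function(graph) {
  split(seq_len(nrow(graph$edges)), factor(graph$edges$from, graph$nodes$id))
}

# Is there an alternative supported path from v to w of >= 2 hops, avoiding
# the direct edge? Bounded depth-first search.
has_supported_detour <- function(graph, adj, v, w, min_support, max_hops,
                                 skip_edge) {
  # stack of (node, depth)
  stack <- list(list(node = v, depth = 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    if (top$depth >= max_hops) next
    for (ei in adj[[top$node]]) {
      if (ei == skip_edge) next
      if (graph$edges$support[ei] < min_support) next
      nxt <- graph$edges$to[ei]
      d <- top$depth + 1L
      if (nxt == w && d >= 2L) return(TRUE)
      if (nxt != w && d < max_hops) stack[[length(stack) + 1L]] <- list(node = nxt, depth = d)
    }
  }
  FALSE
}

#' Remove transitive edges from a supported graph
#'
#' An edge `v -> w` is transitive when a longer path `v -> o -> ... -> w`
#' exists with every edge (including `v -> w` itself) supported by at least
#' `min_support` reads; the direct edge is then removed and the contig is
#' generated from the longer path. The detour search is bounded to
#' `max_hops` edges.
#'
#' @param graph A supported `unitig_graph` (see [count_edge_support()]).
#' @param min_support Minimum read support for both the direct edge and
#'   every detour edge.
#' @param max_hops Bound on detour length.
#' @return The graph with transitive edges dropped.
#' @export
remove_transitive_edges <- function(graph, min_support = 2L, max_hops = 5L) {
  if (nrow(graph$edges) == 0L) return(graph)
  adj <- out_edges_by_node(graph)
  drop <- logical(nrow(graph$edges))
  for (ei in seq_len(nrow(graph$edges))) {
    if (graph$edges$support[ei] < min_support) next
    drop[ei] <- has_supported_detour(graph, adj, graph$edges$from[ei],
                                     graph$edges$to[ei], min_support,
                                     max_hops, ei)
  }
  graph$edges <- graph$edges[!drop, , drop = FALSE]
  rownames(graph$edges) <- NULL
  graph$nodes$in_deg <- as.integer(table(factor(graph$edges$to, graph$nodes$id)))
  graph$nodes$out_deg <- as.integer(table(factor(graph$edges$from, graph$nodes$id)))
  graph
}

# Visit budget: a node may be visited floor((id+od)/2) times, with a floor of
# one visit so isolated and degree-1 nodes are not orphaned.
visit_budget <- function(in_deg, out_deg) {
  pmax(1L, (in_deg + out_deg) %/% 2L)
}

#' Modified breadth-first traversal of the unitig graph
#'
#' BFS from all zero-indegree nodes (unvisited components are seeded from
#' their longest node). A node may be visited up to `floor((id+od)/2)` times.
#' At each visit of `v`: successors reachable through a supported longer
#' path are skipped as transitive; otherwise, if any remaining successor has
#' support at least `min_support`, only the single best-supported one is
#' followed (ties by node length then id); if none reaches `min_support`,
#' all remaining successors are followed. Every traversed edge and every
#' visit timestamp is recorded.
#'
#' @param graph A supported `unitig_graph`, ideally after
#'   [remove_transitive_edges()].
#' @param min_support Support threshold shared by the transitive-skip and
#'   best-successor rules.
#' @param max_hops Detour bound for the transitive-skip rule.
#' @return A `bfs_traversal`: list with the input `graph`, `visits`
#'   (data.frame `node, timestamp`), and `edges` (data.frame of traversed
#'   edges `from, from_orient, to, to_orient, overlap, support`).
#' @export
modified_bfs <- function(graph, min_support = 2L, max_hops = 5L) {
  nodes <- graph$nodes
  budget <- setNames(visit_budget(nodes$in_deg, nodes$out_deg), nodes$id)
  adj <- out_edges_by_node(graph)
  edge_traversed <- logical(nrow(graph$edges))
  visits <- list()
  ts <- 0L
  visit_count <- setNames(integer(nrow(nodes)), nodes$id)

  starts <- sort(nodes$id[nodes$in_deg == 0L])
  queue <- as.list(starts)
  repeat {
    if (length(queue) == 0L) {
      unvisited <- nodes$id[visit_count[nodes$id] == 0L]
      if (length(unvisited) == 0L) break
      # seed a leftover (cyclic) component at its longest node
      lens <- nodes$len[match(unvisited, nodes$id)]
      seed <- unvisited[order(-lens, unvisited)][1]
      queue <- list(seed)
    }
    v <- queue[[1]]; queue <- queue[-1]
    if (visit_count[[v]] >= budget[[v]]) next
    visit_count[[v]] <- visit_count[[v]] + 1L
    ts <- ts + 1L
    visits[[length(visits) + 1L]] <- list(node = v, timestamp = ts)

    cand <- adj[[v]]
    cand <- cand[!edge_traversed[cand]]
    if (length(cand) == 0L) next
    # rule 2: skip transitive successors for this visit
    transitive <- vapply(cand, function(ei) {
      has_supported_detour(graph, adj, v, graph$edges$to[ei], min_support,
                           max_hops, ei)
    }, TRUE)
    cand <- cand[!transitive]
    if (length(cand) == 0L) next
    sup <- graph$edges$support[cand]
    if (any(sup >= min_support)) {
      # rule 3: follow only the best-supported successor this visit
      tgt <- graph$edges$to[cand]
      tlen <- nodes$len[match(tgt, nodes$id)]
      best <- cand[order(-sup, -tlen, tgt)][1]
      chosen <- best
    } else {
      # rule 4: no successor has enough support -> follow all
      chosen <- cand
    }
    for (ei in chosen) {
      edge_traversed[ei] <- TRUE
      queue <- c(queue, graph$edges$to[ei])
    }
  }

  visits <- data.frame(node = vapply(visits, `[[`, "", "node"),
                       timestamp = vapply(visits, `[[`, 0L, "timestamp"),
                       stringsAsFactors = FALSE)
  structure(list(graph = graph,
                 visits = visits,
                 edges = graph$edges[edge_traversed, , drop = FALSE]),
            class = "bfs_traversal")
}

#' @export
print.bfs_traversal <- function(x, ...) {
  cat("bfs_traversal:", nrow(x$visits), "visits,", nrow(x$edges),
      "traversed edges\n")
  invisible(x)
}

#' Generate contigs from the BFS-traversal graph by timestamped DFS
#'
#' The traversal graph is walked depth-first; at a branching node the
#' not-exhausted successor with the earliest BFS timestamp is taken. Each
#' branching node carries a cut flag (one-in/many-out: cut outgoing;
#' many-in/one-out: cut incoming; many/many: cut all); when a walk revisits
#' a node and thereby closes a loop, the flag at that node is cleared (the
#' loop is solvable). After traversal, walks are severed at edges incident
#' to remaining flags and every maximal unsevered stretch becomes a contig.
#'
#' @param traversal A `bfs_traversal` from [modified_bfs()].
#' @return List of contigs; each is a list with `id`, `node`, `orient` and
#'   `component` (component label inherited from the supported graph).
#' @export
dfs_contigs <- function(traversal) {
  g <- traversal$graph
  te <- traversal$edges
  nodes <- g$nodes
  ids <- nodes$id
  in_deg <- as.integer(table(factor(te$to, ids)))
  out_deg <- as.integer(table(factor(te$from, ids)))
  names(in_deg) <- names(out_deg) <- ids
  budget <- setNames(visit_budget(in_deg, out_deg), ids)
  # earliest BFS timestamp per node (unvisited nodes sort last)
  first_ts <- vapply(ids, function(v) {
    t <- traversal$visits$timestamp[traversal$visits$node == v]
    if (length(t)) min(t) else .Machine$integer.max
  }, 0L)
  names(first_ts) <- ids

  cut_flag <- setNames(rep("none", length(ids)), ids)
  cut_flag[in_deg == 1L & out_deg > 1L] <- "out"
  cut_flag[in_deg > 1L & out_deg == 1L] <- "in"
  cut_flag[in_deg > 1L & out_deg > 1L] <- "all"

  adj <- split(seq_len(nrow(te)), factor(te$from, ids))
  edge_used <- logical(nrow(te))
  visits_left <- budget
  seen <- setNames(logical(length(ids)), ids)
  walks <- list()

  start_pool <- function() {
    cand <- ids[!seen[ids] & visits_left[ids] > 0L]
    if (length(cand) == 0L) return(character(0))
    zero_in <- cand[in_deg[cand] == 0L]
    pool <- if (length(zero_in)) zero_in else cand
    pool[order(first_ts[pool], pool)]
  }

  repeat {
    pool <- start_pool()
    if (length(pool) == 0L) break
    v <- pool[[1]]
    walk_nodes <- v
    # start orientation from the node's first unused out-edge, default '+'
    oe <- adj[[v]]; oe <- oe[!edge_used[oe]]
    walk_orients <- if (length(oe)) te$from_orient[oe[1]] else "+"
    walk_edges <- integer(0)
    visits_left[[v]] <- visits_left[[v]] - 1L
    seen[[v]] <- TRUE
    repeat {
      cur <- walk_nodes[length(walk_nodes)]
      cand <- adj[[cur]]
      cand <- cand[!edge_used[cand] & visits_left[te$to[cand]] > 0L]
      if (length(cand) == 0L) break
      tgt <- te$to[cand]
      ei <- cand[order(first_ts[tgt], tgt)][1]
      nxt <- te$to[ei]
      if (nxt %in% walk_nodes) cut_flag[[nxt]] <- "none"  # loop closed: solvable
      edge_used[ei] <- TRUE
      visits_left[[nxt]] <- visits_left[[nxt]] - 1L
      seen[[nxt]] <- TRUE
      walk_nodes <- c(walk_nodes, nxt)
      walk_orients <- c(walk_orients, te$to_orient[ei])
      walk_edges <- c(walk_edges, ei)
    }
    walks[[length(walks) + 1L]] <- list(node = walk_nodes,
                                        orient = walk_orients,
                                        edge = walk_edges)
  }

  # sever walks at edges incident to surviving cut flags
  contigs <- list()
  for (w in walks) {
    n <- length(w$node)
    if (n == 1L) {
      contigs[[length(contigs) + 1L]] <- list(node = w$node, orient = w$orient)
      next
    }
    sever <- vapply(seq_len(n - 1L), function(i) {
      f_from <- cut_flag[[w$node[i]]]
      f_to <- cut_flag[[w$node[i + 1L]]]
      f_from %in% c("out", "all") || f_to %in% c("in", "all")
    }, TRUE)
    piece_start <- 1L
    for (i in seq_len(n - 1L)) {
      if (sever[i]) {
        contigs[[length(contigs) + 1L]] <-
          list(node = w$node[piece_start:i], orient = w$orient[piece_start:i])
        piece_start <- i + 1L
      }
    }
    contigs[[length(contigs) + 1L]] <-
      list(node = w$node[piece_start:n], orient = w$orient[piece_start:n])
  }

  comp <- nodes$component %||% rep(NA_integer_, nrow(nodes))
  names(comp) <- ids
  lapply(seq_along(contigs), function(i) {
    ctg <- contigs[[i]]
    ctg$id <- sprintf("contig_%03d", i)
    ctg$component <- unname(comp[[ctg$node[1]]])
    ctg
  })
}

#' Build the DNA sequence of a contig
#'
#' Node sequences (reverse-complemented for `-` orientations) are
#' concatenated; the GFA overlap of each traversed edge is trimmed from the
#' start of the incoming node.
#'
#' @param contig A contig from [dfs_contigs()].
#' @param graph The `unitig_graph` carrying the node sequences.
#' @return Single DNA string, named by the contig id.
#' @export
contig_sequence <- function(contig, graph) {
  seqs <- graph$nodes$seq[match(contig$node, graph$nodes$id)]
  if (anyNA(seqs)) stop("contig references unknown node(s)")
  oriented <- ifelse(contig$orient == "+", seqs, revcomp(seqs))
  out <- oriented[1]
  if (length(oriented) > 1L) {
    for (i in 2:length(oriented)) {
      ei <- match_edge(graph, contig$node[i - 1L], contig$orient[i - 1L],
                       contig$node[i], contig$orient[i])
      ov <- if (is.na(ei)) 0L else graph$edges$overlap[ei]
      if (ov >= nchar(oriented[i])) stop("edge overlap longer than node sequence")
      out <- paste0(out, substr(oriented[i], ov + 1L, nchar(oriented[i])))
    }
  }
  setNames(out, contig$id)
}

#' Assemble contigs from a unitig graph and read paths
#'
#' Convenience wrapper running [count_edge_support()],
#' [remove_transitive_edges()], [modified_bfs()] and [dfs_contigs()], and
#' building contig sequences.
#'
#' @param graph A `unitig_graph`.
#' @param read_paths Read paths from [parse_gaf()].
#' @param min_support Support threshold used throughout.
#' @return List with `contigs` (see [dfs_contigs()]), `seqs` (named
#'   character vector) and the supported `graph`.
#' @export
assemble_contigs <- function(graph, read_paths, min_support = 2L) {
  graph <- count_edge_support(graph, read_paths)
  graph <- remove_transitive_edges(graph, min_support)
  trav <- modified_bfs(graph, min_support)
  contigs <- dfs_contigs(trav)
  seqs <- vapply(contigs, function(ctg) contig_sequence(ctg, graph), "")
  names(seqs) <- vapply(contigs, `[[`, "", "id")
  list(contigs = contigs, seqs = seqs, graph = graph)
}
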