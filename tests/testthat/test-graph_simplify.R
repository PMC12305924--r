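test_that("edge support counts path traversals with multiplicity", {
  g <- mk_graph(c("a>b", "b>c"))
  paths <- c(replicate(3, list(read_id = "r", node = c("a", "b"),
                               orient = c("+", "+")), simplify = FALSE),
             list(list(read_id = "r4", node = c("a", "b", "c"),
                       orient = c("+", "+", "+"))))
  sg <- count_edge_support(g, paths)
  expect_equal(sg$edges$support, c(4L, 1L))
  # no paths -> all zero
  expect_equal(count_edge_support(g, list())$edges$support, c(0L, 0L))
  # a path around a 2-cycle traverses a>b twice
  g2 <- mk_graph(c("a>b", "b>a"))
  p2 <- list(list(read_id = "r", node = c("a", "b", "a", "b"),
                  orient = rep("+", 4)))
  expect_equal(count_edge_support(g2, p2)$edges$support, c(2L, 1L))
})

test_that("transitive edges are removed only when the detour is supported", {
  g <- mk_graph(c("a>b", "a>c", "c>b"), support = 4L)
  out <- remove_transitive_edges(g, min_support = 2L)
  expect_equal(nrow(out$edges), 2L)
  expect_false(any(out$edges$from == "a" & out$edges$to == "b"))

  g2 <- mk_graph(c("a>b", "a>c", "c>b"), support = 4L)
  g2$edges$support[g2$edges$from == "a" & g2$edges$to == "c"] <- 1L
  out2 <- remove_transitive_edges(g2, min_support = 2L)
  expect_equal(nrow(out2$edges), 3L)  # unsupported detour keeps the edge

  g3 <- mk_graph(c("a>b", "b>c"), support = 4L)
  expect_equal(nrow(remove_transitive_edges(g3, 2L)$edges), 2L)
})

test_that("BFS follows the best-supported successor and defers the rest", {
  # M branches to O (support 5) and N (support 2)
  g <- mk_graph(c("M>O", "M>N", "P>M"))
  g$edges$support <- c(5L, 2L, 6L)
  trav <- modified_bfs(g, min_support = 2L)
  # M budget floor((1+2)/2) = 1: only M>O traversed
  expect_true(any(trav$edges$from == "M" & trav$edges$to == "O"))
  expect_false(any(trav$edges$from == "M" & trav$edges$to == "N"))
})

test_that("BFS takes all successors when none has enough support", {
  g <- mk_graph(c("D>E", "D>G"), support = 1L)
  trav <- modified_bfs(g, min_support = 2L)
  expect_equal(nrow(trav$edges), 2L)
})

test_that("a linear chain is traversed in order and yields one contig", {
  g <- mk_graph(c("a>b", "b>c"), support = 3L)
  trav <- modified_bfs(g, min_support = 2L)
  expect_equal(trav$visits$node, c("a", "b", "c"))
  ctgs <- dfs_contigs(trav)
  expect_length(ctgs, 1L)
  expect_equal(ctgs[[1]]$node, c("a", "b", "c"))
})

test_that("solvable loop produces the single worked contig", {
  g <- mk_graph(c("E>A", "A>B", "B>C", "C>A", "A>D"))
  ctgs <- dfs_contigs(modified_bfs(g, min_support = 2L))
  expect_equal(contig_strings(ctgs), "EABCAD")
})

test_that("unsolvable branch nested in a solvable loop gives three contigs", {
  g <- mk_graph(c("E>A", "A>B", "B>C", "B>F", "C>A", "A>D"))
  ctgs <- dfs_contigs(modified_bfs(g, min_support = 2L))
  expect_equal(contig_strings(ctgs), c("CAD", "EAB", "F"))
})

test_that("contig sequences concatenate with overlap trimming and strand", {
  g <- structure(list(
    nodes = data.frame(id = c("a", "b"), seq = c("ACGT", "GTAA"),
                       len = 4L, stringsAsFactors = FALSE),
    edges = data.frame(from = "a", from_orient = "+", to = "b",
                       to_orient = "+", overlap = 2L, support = 1L,
                       stringsAsFactors = FALSE)), class = "unitig_graph")
  ctg <- list(id = "c1", node = c("a", "b"), orient = c("+", "+"))
  expect_equal(unname(contig_sequence(ctg, g)), "ACGTAA")
  single <- list(id = "c2", node = "a", orient = "+")
  expect_equal(unname(contig_sequence(single, g)), "ACGT")
  minus <- list(id = "c3", node = "a", orient = "-")
  expect_equal(unname(contig_sequence(minus, g)), "ACGT")  # palindrome-free? revcomp(ACGT)=ACGT
  g$edges$overlap <- 5L
  expect_error(contig_sequence(ctg, g), "overlap")
})

test_that("reverse orientation emits the reverse complement", {
  g <- structure(list(
    nodes = data.frame(id = "a", seq = "AACCG", len = 5L,
                       stringsAsFactors = FALSE),
    edges = data.frame(from = character(0), from_orient = character(0),
                       to = character(0), to_orient = character(0),
                       overlap = integer(0), support = integer(0))),
    class = "unitig_graph")
  ctg <- list(id = "c", node = "a", orient = "-")
  expect_equal(unname(contig_sequence(ctg, g)), "CGGTT")
})

test_that("every node's sequence survives into at least one contig", {
  set.seed(5)
  for (i in 1:5) {
    n_edge <- sample(4:8, 1)
    nodes <- LETTERS[1:sample(5:8, 1)]
    edges <- unique(replicate(n_edge, paste(sample(nodes, 2), collapse = ">")))
    g <- try(mk_graph(edges, support = sample(1:4, 1)), silent = TRUE)
    if (inherits(g, "try-error")) next
    ctgs <- dfs_contigs(modified_bfs(g, min_support = 2L))
    covered <- unique(unlist(lapply(ctgs, `[[`, "node")))
    expect_setequal(covered, g$nodes$id)
  }
})

test_that("on in/out-degree-1 DAGs contigs equal the path components", {
  set.seed(9)
  for (i in 1:10) {
    # random disjoint chains
    nodes <- paste0("n", 1:10)
    perm <- sample(nodes)
    cuts <- sort(sample(1:9, sample(1:4, 1)))
    chains <- split(perm, findInterval(1:10, cuts + 1))
    edges <- unlist(lapply(chains, function(ch) {
      if (length(ch) < 2) return(character(0))
      paste(head(ch, -1), tail(ch, -1), sep = ">")
    }))
    singletons <- unlist(chains[lengths(chains) == 1])
    if (length(edges) == 0) next
    g <- mk_graph(edges, support = 3L)
    # add isolated nodes
    for (s in singletons) {
      g$nodes <- rbind(g$nodes,
                       data.frame(id = s, seq = random_dna_str(10), len = 10L,
                                  in_deg = 0L, out_deg = 0L,
                                  component = max(g$nodes$component) + 1L))
    }
    ctgs <- dfs_contigs(modified_bfs(g, min_support = 2L))
    got <- sort(vapply(ctgs, function(x) paste(x$node, collapse = ">"), ""))
    want <- sort(vapply(chains, function(ch) paste(ch, collapse = ">"), ""))
    expect_equal(got, unname(want))
  }
})

test_that("assembly is deterministic for identical inputs", {
  g <- mk_graph(c("E>A", "A>B", "B>C", "B>F", "C>A", "A>D"))
  paths <- list(list(read_id = "r1", node = c("E", "A"), orient = c("+", "+")),
                list(read_id = "r2", node = c("A", "B"), orient = c("+", "+")))
  a1 <- assemble_contigs(g, paths, 2L)
  a2 <- assemble_contigs(g, paths, 2L)
  expect_identical(a1$seqs, a2$seqs)
  expect_identical(lapply(a1$contigs, `[[`, "node"),
                   lapply(a2$contigs, `[[`, "node"))
})
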