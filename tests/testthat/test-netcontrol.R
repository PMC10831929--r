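chain_graph <- function(n) {
  igraph::graph_from_data_frame(
    data.frame(from = sprintf("v%d", seq_len(n - 1)),
               to = sprintf("v%d", seq_len(n - 1) + 1), sign = 1L),
    vertices = sprintf("v%d", seq_len(n)))
}

test_that("cycle nodes are SCC members plus self-loops", {
  # DAG -> empty
  expect_length(cycle_nodes(chain_graph(4)), 0L)
  # 3-cycle plus pendant
  g <- igraph::graph_from_data_frame(data.frame(
    from = c("a", "b", "c", "c"), to = c("b", "c", "a", "d")))
  expect_identical(cycle_nodes(g), c("a", "b", "c"))
  # self-loop counts as a cycle
  gl <- igraph::graph_from_data_frame(data.frame(from = c("x", "x"),
                                                 to = c("x", "y")))
  expect_identical(cycle_nodes(gl), "x")
})

test_that("is_fvs matches the definition on hand cases", {
  expect_true(is_fvs(chain_graph(3), character(0)))
  g2 <- igraph::graph_from_data_frame(data.frame(from = c("a", "b"),
                                                 to = c("b", "a")))
  expect_true(is_fvs(g2, "a"))
  expect_false(is_fvs(g2, character(0)))
  # a self-loop is only broken by removing its node
  gl <- igraph::graph_from_data_frame(data.frame(from = "x", to = "x"))
  expect_false(is_fvs(gl, character(0)))
  expect_true(is_fvs(gl, "x"))
})

test_that("two disjoint 2-cycles admit exactly the four cross pairs", {
  g <- igraph::graph_from_data_frame(data.frame(
    from = c("a", "b", "c", "d"), to = c("b", "a", "d", "c")))
  p <- enumerate_fvs_pairs(g)
  got <- paste(p$node1, p$node2)
  expect_setequal(got, c("a c", "a d", "b c", "b d"))
})

test_that("a single 2-cycle yields its one pair", {
  g <- igraph::graph_from_data_frame(data.frame(from = c("a", "b"),
                                                to = c("b", "a")))
  p <- enumerate_fvs_pairs(g)
  expect_identical(paste(p$node1, p$node2), "a b")
  expect_setequal(fvs_singletons(g), c("a", "b"))
})

test_that("pair enumeration agrees with the exhaustive oracle on random
           digraphs and every pair's removal leaves the graph acyclic", {
  for (seed in 1:40) {
    g <- make_random_digraph(8, 0.25, seed = seed)
    got <- enumerate_fvs_pairs(g)
    want <- oracle_fvs_pairs(g)
    expect_identical(got, want, info = paste("seed", seed))
    if (nrow(got)) {
      edges <- graph_edges(g)
      nodes <- igraph::V(g)$name
      for (i in seq_len(nrow(got))) {
        p <- c(got$node1[i], got$node2[i])
        sub <- edges[!(edges$from %in% p | edges$to %in% p), , drop = FALSE]
        expect_true(kahn_acyclic(sub, setdiff(nodes, p)))
      }
    }
  }
})

test_that("filter_druggable keeps both-druggable pairs and audits counts", {
  pairs <- data.frame(node1 = c("a", "a", "c"), node2 = c("b", "c", "d"),
                      stringsAsFactors = FALSE)
  ann <- c(a = TRUE, b = TRUE, c = FALSE, d = TRUE)
  out <- filter_druggable(pairs, ann)
  expect_identical(paste(out$node1, out$node2), "a b")
  expect_equal(attr(out, "counts"),
               c(n_total = 3L, n_with_nondruggable = 2L,
                 n_both_druggable = 1L))
  expect_identical(nrow(filter_druggable(pairs, ann & FALSE)), 0L)
  expect_identical(filter_druggable(pairs, ann | TRUE)[, 1:2], pairs)
  expect_error(filter_druggable(pairs, ann[1:2]), "unannotated")
})

test_that("PRINCE iteration equals the direct linear solve", {
  # 3-node path at alpha 0.5, then a larger random graph
  g3 <- chain_graph(3)
  for (case in list(list(g = g3, seeds = "v1", alpha = 0.5),
                    list(g = make_random_digraph(50, 0.06, seed = 31),
                         seeds = c("n03", "n17"), alpha = 0.85))) {
    f <- prince_scores(case$g, case$seeds, case$alpha)
    W <- boolpop:::.prince_W(case$g)
    Y <- as.numeric(igraph::V(case$g)$name %in% case$seeds)
    direct <- unname(solve(diag(nrow(W)) - case$alpha * W,
                           (1 - case$alpha) * Y))
    expect_equal(unname(f), direct, tolerance = 1e-7)
    expect_true(all(f >= 0))
  }
})

test_that("PRINCE limits: tiny alpha returns ~Y; symmetric seeds tie", {
  g <- igraph::graph_from_data_frame(data.frame(from = c("a", "b"),
                                                to = c("b", "a")))
  f <- prince_scores(g, c("a", "b"), alpha = 1e-8)
  expect_equal(unname(f), c(1, 1), tolerance = 1e-6)
  f2 <- prince_scores(g, c("a", "b"), alpha = 0.6)
  expect_equal(f2[["a"]], f2[["b"]])
})

test_that("modified PRINCE propagates along edges with decaying scores", {
  # no edges -> (1 - alpha) Y
  g0 <- igraph::make_empty_graph(3) |> igraph::set_vertex_attr("name",
                                                               value = c("a", "b", "c"))
  f0 <- modified_prince_scores(g0, "a", alpha = 0.85)
  expect_equal(unname(f0), c(0.15, 0, 0))
  # directed chain seeded at the head: geometric decay along the chain
  gc <- chain_graph(5)
  f <- modified_prince_scores(gc, "v1", alpha = 0.5)
  expect_true(all(diff(unname(f)) < 0))
  # closed form: score(v_k) = (1-alpha) alpha^(k-1) for a chain
  expect_equal(unname(f), 0.5 * 0.5^(0:4), tolerance = 1e-7)
  # on a bipartite toy, flipping every sign leaves magnitudes unchanged:
  # W^k connects across groups only for odd k, so the flip multiplies each
  # score by (-1)^(distance parity) when the seed sits in one group
  set.seed(15)
  grp_a <- c("a1", "a2", "a3")
  grp_b <- c("b1", "b2", "b3")
  cross <- expand.grid(from = grp_a, to = grp_b, stringsAsFactors = FALSE)
  cross <- rbind(cross, stats::setNames(rev(cross), c("from", "to")))
  cross <- cross[stats::runif(nrow(cross)) < 0.6, ]
  cross$sign <- sample(c(-1L, 1L), nrow(cross), replace = TRUE)
  gm <- igraph::graph_from_data_frame(cross, vertices = c(grp_a, grp_b))
  gflip <- igraph::set_edge_attr(gm, "sign", value = -igraph::E(gm)$sign)
  expect_equal(abs(modified_prince_scores(gm, "a1", 0.7)),
               abs(modified_prince_scores(gflip, "a1", 0.7)),
               tolerance = 1e-7)
})

test_that("CheiRank is PageRank on the reversed graph", {
  g <- make_random_digraph(20, 0.15, seed = 12)
  cr <- cheirank_scores(g, 0.85)
  expect_equal(sum(cr), 1)
  # double reversal recovers ordinary PageRank
  grr <- igraph::reverse_edges(igraph::reverse_edges(g))
  expect_equal(unname(cheirank_scores(igraph::reverse_edges(g), 0.85)),
               unname(igraph::page_rank(grr, damping = 0.85)$vector))
  # CheiRank scores outgoing influence: in a star whose hub feeds every
  # spoke, the hub is the sole in-neighbour of each node of the reversed
  # graph and takes the maximal score (analytic PageRank of a star)
  star <- igraph::graph_from_data_frame(data.frame(
    from = "hub", to = c("s1", "s2", "s3", "s4")))
  crs <- cheirank_scores(star, 0.85)
  expect_identical(names(which.max(crs)), "hub")
})

test_that("pair ranking is deterministic, complete and honours dominance", {
  # hub-and-spoke where one pair dominates all three metrics by symmetry:
  # two hubs in a 2-cycle, each feeding and fed by all spokes
  edges <- rbind(
    data.frame(from = "h1", to = "h2", sign = 1L),
    data.frame(from = "h2", to = "h1", sign = 1L),
    data.frame(from = rep(c("h1", "h2"), each = 3),
               to = rep(c("s1", "s2", "s3"), 2), sign = 1L),
    data.frame(from = rep(c("s1", "s2", "s3"), 2),
               to = rep(c("h1", "h2"), each = 3), sign = 1L))
  g <- igraph::graph_from_data_frame(edges)
  pairs <- enumerate_fvs_pairs(g)
  expect_true(any(pairs$node1 == "h1" & pairs$node2 == "h2"))
  rk <- rank_pairs(g, pairs, top_fraction = 0.3)
  top <- rk[rk$final_rank == 1, ]
  expect_identical(c(top$node1, top$node2), c("h1", "h2"))
  # ranks are permutations of 1..n_pairs (dense within metric, final total)
  expect_setequal(rk$final_rank, seq_len(nrow(rk)))
  # single pair -> rank 1
  g1 <- igraph::graph_from_data_frame(data.frame(from = c("a", "b"),
                                                 to = c("b", "a")))
  rk1 <- rank_pairs(g1, enumerate_fvs_pairs(g1))
  expect_equal(rk1$final_rank, 1L)
  expect_error(rank_pairs(g1, enumerate_fvs_pairs(chain_graph(3))),
               "no candidate")
})

test_that("ranking export writes a readable TSV", {
  g <- igraph::graph_from_data_frame(data.frame(
    from = c("a", "b", "c", "d", "a"), to = c("b", "a", "d", "c", "c"),
    sign = c(1L, -1L, 1L, 1L, 1L)))
  pairs <- enumerate_fvs_pairs(g)
  rk <- rank_pairs(g, pairs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranking(rk, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(rk))
  expect_true(all(c("prince", "modified_prince", "cheirank", "final_rank")
                  %in% names(back)))
})
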