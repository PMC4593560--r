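# Network loading, hub pruning, centralities and clustering.

edge_lines <- function(...) c("gene_a\tgene_b", ...)

test_that("edge loading deduplicates and drops self-loops", {
  net <- suppressMessages(load_edges(edge_lines("a\tb", "b\ta", "a\ta")))
  expect_equal(igraph::ecount(net), 1L)
  expect_setequal(igraph::V(net)$name, c("a", "b"))
  net2 <- suppressMessages(load_edges(edge_lines("a\tb", "a\tb", "b\tc")))
  expect_equal(igraph::ecount(net2), 2L)
  expect_error(suppressMessages(load_edges(edge_lines("a\ta"))), "no edges")
})

test_that("hub removal peels one node at a time until max degree <= cap", {
  # star with 201 leaves: center removed, no edges remain
  star <- igraph::make_star(202, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", sprintf("n%03d", 1:201))
  pruned <- remove_hubs(star, 200)
  expect_false("hub" %in% igraph::V(pruned)$name)
  expect_equal(igraph::ecount(pruned), 0L)
  # max degree exactly at the cap: untouched
  star200 <- igraph::make_star(201, mode = "undirected", center = 1)
  igraph::V(star200)$name <- c("hub", sprintf("n%03d", 1:200))
  expect_equal(igraph::vcount(remove_hubs(star200, 200)), 201L)
  # idempotence
  expect_identical(igraph::V(remove_hubs(pruned, 200))$name,
                   igraph::V(pruned)$name)
})

test_that("removing the larger of two overlapping hubs can spare the other", {
  # h1: 200 shared leaves + 20 own + edge to h2 (degree 221)
  # h2: the same 200 shared leaves + edge to h1 (degree 201)
  # removing h1 drops h2 to exactly 200, so only h1 goes
  shared <- sprintf("s%03d", 1:200)
  own1 <- sprintf("p%03d", 1:20)
  el <- rbind(cbind("h1", c(shared, own1, "h2")),
              cbind("h2", shared))
  net <- igraph::graph_from_edgelist(el, directed = FALSE)
  deg0 <- igraph::degree(net)
  expect_equal(deg0[["h1"]], 221); expect_equal(deg0[["h2"]], 201)
  pruned <- remove_hubs(net, 200)
  expect_false("h1" %in% igraph::V(pruned)$name)
  expect_true("h2" %in% igraph::V(pruned)$name)
  expect_equal(max(igraph::degree(pruned)), 200)
})

test_that("betweenness matches exhaustive shortest-path enumeration", {
  # path a-b-c
  path <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c")),
                                      directed = FALSE)
  bc <- betweenness_centrality(path)
  expect_equal(unname(bc[c("a", "b", "c")]), c(0, 1, 0))
  # complete graph on 4 nodes: all zero
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_true(all(betweenness_centrality(k4) == 0))
  # random graphs up to 7 nodes vs oracle
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(4:7, 1)
    nodes <- letters[seq_len(n)]
    pairs <- t(utils::combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.5
    if (sum(keep) == 0L) keep[1L] <- TRUE
    net <- igraph::graph_from_edgelist(pairs[keep, , drop = FALSE],
                                       directed = FALSE)
    net <- net + igraph::vertices(setdiff(nodes, igraph::V(net)$name))
    bc <- betweenness_centrality(net)
    oracle <- oracle_betweenness(igraph::V(net)$name,
                                 igraph::as_edgelist(net))
    expect_equal(bc[order(names(bc))], oracle[order(names(oracle))],
                 tolerance = 1e-10)
    expect_equal(sum(bc), sum(oracle), tolerance = 1e-10)
  }
})

test_that("participation coefficient matches closed forms", {
  # v with 4 neighbors: all one cluster -> 0; 2+2 across two -> 0.5
  el <- cbind("v", c("a", "b", "c", "d"))
  net <- igraph::graph_from_edgelist(el, directed = FALSE)
  one <- stats::setNames(c("x", "c1", "c1", "c1", "c1"),
                         c("v", "a", "b", "c", "d"))
  expect_equal(unname(participation_coefficient(net, one)["v"]), 0)
  two <- stats::setNames(c("x", "c1", "c1", "c2", "c2"),
                         c("v", "a", "b", "c", "d"))
  expect_equal(unname(participation_coefficient(net, two)["v"]), 0.5)
  # degree 3 split 1+1+1 -> 2/3
  el3 <- cbind("w", c("a", "b", "c"))
  net3 <- igraph::graph_from_edgelist(el3, directed = FALSE)
  three <- stats::setNames(c("x", "c1", "c2", "c3"), c("w", "a", "b", "c"))
  expect_equal(unname(participation_coefficient(net3, three)["w"]), 2 / 3)
})

test_that("participation is bounded, relabel-invariant and 0 for isolates", {
  sim <- gen_network(n_nodes = 60, n_modules = 3, p_within = 0.3,
                     p_between = 0.05, seed = 5)
  net <- sim$network + igraph::vertices("ISOLATE")
  cl <- c(sim$clusters, ISOLATE = "M01")
  p1 <- participation_coefficient(net, cl)
  expect_true(all(p1 >= 0 & p1 < 1))
  expect_equal(unname(p1["ISOLATE"]), 0)
  relabel <- stats::setNames(paste0("z_", cl), names(cl))
  expect_equal(participation_coefficient(net, relabel), p1)
  expect_error(participation_coefficient(net, cl[-1L]), "without cluster")
})

test_that("modularity evaluates Newman's Q and greedy clustering recovers cliques", {
  # whole graph as one cluster: Q = 0
  sim <- gen_network(n_nodes = 40, n_modules = 2, seed = 2)
  one <- stats::setNames(rep("c", 40), names(sim$clusters))
  expect_equal(network_modularity(sim$network, one), 0)
  # two disconnected triangles clustered as themselves: Q = 1/2
  tri2 <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("c", "a"),
          c("d", "e"), c("e", "f"), c("f", "d")), directed = FALSE)
  cl <- stats::setNames(rep(c("t1", "t2"), each = 3), letters[1:6])
  expect_equal(network_modularity(tri2, cl), 0.5)
  # greedy baseline on two disconnected cliques
  k5a <- t(utils::combn(sprintf("a%d", 1:5), 2))
  k5b <- t(utils::combn(sprintf("b%d", 1:5), 2))
  cliques <- igraph::graph_from_edgelist(rbind(k5a, k5b), directed = FALSE)
  part <- greedy_cluster(cliques, seed = 1)
  expect_equal(length(unique(part)), 2L)
  expect_equal(length(unique(part[sprintf("a%d", 1:5)])), 1L)
  expect_equal(length(unique(part[sprintf("b%d", 1:5)])), 1L)
  # and its Q beats the all-singletons partition
  singles <- stats::setNames(names(part), names(part))
  expect_gt(network_modularity(cliques, part),
            network_modularity(cliques, singles))
})

test_that("network_stats assembles per-gene measures over pruned graph", {
  sim <- gen_network(n_nodes = 50, n_modules = 2, p_within = 0.3,
                     p_between = 0.02, seed = 9)
  df <- network_stats(sim$network, sim$clusters)
  expect_setequal(df$gene, igraph::V(sim$network)$name)
  expect_true(all(df$degree >= 0))
  expect_true(all(df$participation >= 0 & df$participation < 1))
})
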