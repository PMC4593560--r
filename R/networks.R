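# Interaction networks: loading, hub pruning, centralities and
# pluggable clustering.

#' Load an interaction network from an edge-list TSV
#'
#' Two-column tab-separated file (`gene_a<TAB>gene_b`, optional third
#' `source` and fourth `throughput` columns, optional header). The
#' result is a simple undirected graph: self-loops are dropped and
#' duplicate edges collapsed, with counts reported via message. When
#' `directed_bait_prey = TRUE` the original column order is kept as
#' edge attributes `bait`/`prey` (the undirected topology is
#' unchanged), supporting bait-degree analyses.
#'
#' @param file Path or character vector of lines.
#' @param directed_bait_prey Keep bait/prey orientation metadata.
#' @return An `igraph` undirected simple graph.
#' @export
load_edges <- function(file, directed_bait_prey = FALSE) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file, warn = FALSE) else file
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0L && grepl("^gene_a\t", lines[1L])) lines <- lines[-1L]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 2L
  if (any(!ok)) warning("skipping ", sum(!ok), " malformed edge line(s)")
  fields <- fields[ok]
  if (length(fields) == 0L) stop("no edges in input")
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  loops <- a == b
  if (any(loops)) message("dropped ", sum(loops), " self-loop(s)")
  a <- a[!loops]; b <- b[!loops]
  if (length(a) == 0L) stop("no edges left after dropping self-loops")
  el <- cbind(a, b)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (directed_bait_prey) {
    igraph::E(g)$bait <- a
    igraph::E(g)$prey <- b
  }
  before <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = "first")
  if (igraph::ecount(g) < before)
    message("collapsed ", before - igraph::ecount(g), " duplicate edge(s)")
  g
}

#' Load a node-to-cluster assignment TSV
#'
#' @param file Two-column TSV (`gene<TAB>cluster`), optional header.
#' @return Named character vector: names are genes, values cluster
#'   labels.
#' @export
load_clusters <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file, warn = FALSE) else file
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0L && grepl("^gene\t", lines[1L])) lines <- lines[-1L]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- fields[lengths(fields) >= 2L]
  stats::setNames(vapply(fields, `[[`, character(1), 2L),
                  vapply(fields, `[[`, character(1), 1L))
}

#' Iteratively remove super-connected hubs
#'
#' Repeatedly removes the single highest-degree node whose degree
#' exceeds `max_degree` (ties broken lexicographically by node name),
#' recomputing degrees after every removal, until the maximum degree
#' is at most `max_degree`. Suppresses experimental-artifact
#' super-connectors before centrality analysis.
#'
#' @param net An `igraph` graph.
#' @param max_degree Degree cap (default 200).
#' @return The pruned graph.
#' @export
remove_hubs <- function(net, max_degree = 200) {
  stopifnot(max_degree >= 1)
  repeat {
    deg <- igraph::degree(net)
    over <- deg[deg > max_degree]
    if (length(over) == 0L) break
    victim <- sort(names(over)[over == max(over)])[1L]
    net <- igraph::delete_vertices(net, victim)
  }
  net
}

#' Node centralities
#'
#' `degree_centrality` is the interaction count per node.
#' `betweenness_centrality` is unweighted shortest-path betweenness
#' (each s-t pair contributes fractionally, inversely to the number
#' of distinct shortest s-t paths; endpoints excluded; unnormalized,
#' since only rank comparisons between gene groups are consumed).
#' Disconnected components are handled per component.
#'
#' @param net An `igraph` graph.
#' @return Named numeric vector over nodes.
#' @export
degree_centrality <- function(net) igraph::degree(net)

#' @rdname degree_centrality
#' @export
betweenness_centrality <- function(net) {
  igraph::betweenness(net, directed = FALSE, normalized = FALSE)
}

#' Participation coefficient
#'
#' For node v with degree k and k_i edges into cluster i,
#' P(v) = 1 - sum_i (k_i / k)^2. P is 0 when all edges of v stay in
#' one cluster and approaches 1 as edges spread evenly over many
#' clusters. Isolated nodes (k = 0) are assigned P = 0 so that
#' downstream rank statistics are total.
#'
#' @param net An `igraph` graph.
#' @param clusters Named vector mapping every node to a cluster
#'   label.
#' @return Named numeric vector of participation coefficients in
#'   [0, 1).
#' @export
participation_coefficient <- function(net, clusters) {
  vn <- igraph::V(net)$name
  missing <- setdiff(vn, names(clusters))
  if (length(missing) > 0L)
    stop("nodes without cluster assignment, e.g. ", missing[1L])
  vapply(vn, function(v) {
    nb <- igraph::neighbors(net, v)$name
    k <- length(nb)
    if (k == 0L) return(0)
    ki <- table(clusters[nb])
    1 - sum((ki / k)^2)
  }, numeric(1))
}

#' Newman's modularity of a partition
#'
#' @param net An `igraph` graph.
#' @param clusters Named cluster vector covering all nodes.
#' @return Modularity Q.
#' @export
network_modularity <- function(net, clusters) {
  vn <- igraph::V(net)$name
  igraph::modularity(net, membership = as.integer(factor(clusters[vn])))
}

#' Greedy modularity clustering baseline
#'
#' Deterministic greedy agglomerative clustering (fast-greedy
#' modularity optimization). A plumbing baseline: any external
#' cluster assignment (e.g. from a dedicated clustering tool) can be
#' supplied instead wherever a `clusters` vector is accepted.
#'
#' @param net An `igraph` graph.
#' @param seed Integer seed (the algorithm is deterministic; the seed
#'   is set for interface uniformity).
#' @return Named character vector node -> cluster label.
#' @export
greedy_cluster <- function(net, seed = 1) {
  set.seed(seed)
  cl <- igraph::cluster_fast_greedy(igraph::simplify(net))
  stats::setNames(as.character(igraph::membership(cl)), igraph::V(net)$name)
}

#' Per-gene network statistics table
#'
#' @param net An `igraph` graph.
#' @param clusters Optional named cluster vector; when `NULL`, a
#'   greedy modularity partition is computed.
#' @param max_degree Hub cap applied before measuring (default 200);
#'   `NULL` disables pruning.
#' @return data.frame with gene, degree, betweenness, participation,
#'   cluster.
#' @export
network_stats <- function(net, clusters = NULL, max_degree = 200) {
  if (!is.null(max_degree)) net <- remove_hubs(net, max_degree)
  if (is.null(clusters)) clusters <- greedy_cluster(net)
  vn <- igraph::V(net)$name
  data.frame(
    gene = vn,
    degree = as.numeric(degree_centrality(net)[vn]),
    betweenness = as.numeric(betweenness_centrality(net)[vn]),
    participation = as.numeric(participation_coefficient(net, clusters)[vn]),
    cluster = as.character(clusters[vn]),
    stringsAsFactors = FALSE
  )
}
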