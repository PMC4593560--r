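# Independent brute-force oracles used to validate the package
# implementations. These deliberately re-derive everything from
# first principles (Warshall reachability, explicit tail sums,
# exhaustive path and labeling enumeration).

# Boolean reachability matrix over term ids: R[x, y] TRUE iff y is a
# proper ancestor of x (reachable child -> parent).
oracle_reachability <- function(ids, parents) {
  n <- length(ids)
  R <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (t in ids) for (p in parents[[t]]) R[t, p] <- TRUE
  for (k in seq_len(n)) R <- R | outer(R[, k], R[k, ])
  R
}

# Hypergeometric upper tail by explicit log-binomial sum.
oracle_hyper_tail <- function(k, a, b, G) {
  if (k > min(a, b)) return(0)
  i <- k:min(a, b)
  sum(exp(lchoose(a, i) + lchoose(G - a, b - i) - lchoose(G, b)))
}

# Hypergeometric upper tail by literal enumeration of all draws of
# size b from a universe of G, counting overlap with a fixed set of
# size a. Feasible for G <= 12.
oracle_hyper_enumerate <- function(k, a, b, G) {
  draws <- utils::combn(G, b)
  mean(apply(draws, 2L, function(d) sum(d <= a)) >= k)
}

# Literal re-implementation of the detection definitions: propagated
# counts by per-record ancestor walks, level sets by definition scan,
# pair filters by reachability set algebra, co-annotation p by
# explicit tail sum, union over levels.
oracle_detect <- function(records, graph, root, M = 60, increment = 10,
                          alpha = 0.1, n_min = 10) {
  ids <- graph$ids
  R <- oracle_reachability(ids, graph$parents)
  anc <- function(t) ids[R[t, ]]
  desc <- function(t) ids[R[, t]]
  gsets <- stats::setNames(vector("list", length(ids)), ids)
  for (t in ids) gsets[[t]] <- character(0)
  for (i in seq_len(nrow(records))) {
    g <- records$gene[i]; t <- records$term[i]
    for (tt in c(t, anc(t))) gsets[[tt]] <- union(gsets[[tt]], g)
  }
  G <- length(unique(records$gene))
  mf <- character(0); bg <- character(0)
  evidence <- list()
  for (N in seq(n_min, M, by = increment)) {
    TN <- ids[vapply(ids, function(t) {
      ct <- length(gsets[[t]])
      ct >= N && ct < 2 * N &&
        all(vapply(desc(t), function(d) length(gsets[[d]]) < N, logical(1)))
    }, logical(1))]
    bg <- union(bg, unlist(gsets[TN], use.names = FALSE))
    if (length(TN) >= 2L) {
      TN <- sort(TN)
      for (i2 in seq_len(length(TN) - 1L)) for (j2 in seq(i2 + 1L, length(TN))) {
        t1 <- TN[i2]; t2 <- TN[j2]
        if (R[t1, t2] || R[t2, t1]) next
        if (length(setdiff(intersect(anc(t1), anc(t2)), root)) > 0L) next
        if (length(intersect(desc(t1), desc(t2))) > 0L) next
        ov <- intersect(gsets[[t1]], gsets[[t2]])
        p <- oracle_hyper_tail(length(ov), length(gsets[[t1]]),
                               length(gsets[[t2]]), G)
        if (p < alpha) next
        mf <- union(mf, ov)
        evidence[[length(evidence) + 1L]] <- list(N = N, t1 = t1, t2 = t2)
      }
    }
  }
  list(multifunctional = sort(mf), background = sort(bg),
       evidence = evidence)
}

# Exhaustive all-shortest-paths betweenness for tiny graphs.
# edges: 2-column character matrix, undirected.
oracle_betweenness <- function(nodes, edges) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0L) {
    A[edges] <- TRUE
    A[edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  D <- ifelse(A, 1, Inf); diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- min(D[i, j], D[i, k] + D[k, j])
  paths <- function(s, t) {
    if (s == t) return(list(s))
    out <- list()
    for (w in which(A[, t])) if (is.finite(D[s, w]) && D[s, w] + 1 == D[s, t])
      for (pp in paths(s, w)) out[[length(out) + 1L]] <- c(pp, t)
    out
  }
  bc <- stats::setNames(numeric(n), nodes)
  if (n >= 2L) for (s in seq_len(n - 1L)) for (t in seq(s + 1L, n)) {
    if (!is.finite(D[s, t])) next
    ps <- paths(s, t)
    for (pp in ps) {
      inner <- pp[-c(1L, length(pp))]
      bc[inner] <- bc[inner] + 1 / length(ps)
    }
  }
  bc
}

# Two-sided Mann-Whitney p by enumerating all group labelings,
# measuring distance of U from its mean (handles ties via midranks).
oracle_mw_enumerate <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- apply(idx, 2L, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Random DAG fixture for oracle-equivalence sweeps: a generated
# multi-branch ontology with within-branch diamonds plus random
# multi-term annotations (not planted).
rand_fixture <- function(seed) {
  set.seed(seed)
  nb <- sample(3:5, 1)
  dp <- sample(2:3, 1)
  g <- gen_ontology(n_branches = nb, depth = dp, fanout = 2,
                    seed = seed + 1000L, p_crosslink = 0.15)
  set.seed(seed)
  n_genes <- sample(120:250, 1)
  terms <- setdiff(g$ids, unlist(g$roots))
  gene <- character(0); term <- character(0)
  for (i in seq_len(n_genes)) {
    k <- sample(1:3, 1)
    gene <- c(gene, rep(sprintf("R%04d", i), k))
    term <- c(term, sample(terms, k))
  }
  records <- data.frame(gene = gene, term = term, evidence = "EXP",
                        qualifiers = "", aspect = NA_character_,
                        stringsAsFactors = FALSE)
  records <- records[!duplicated(records[, c("gene", "term")]), ]
  list(graph = g, records = records,
       root = unlist(g$roots, use.names = FALSE))
}
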