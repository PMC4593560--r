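# Ontology DAG: parsing, traversal and term-pair disjointness.

#' Load an OBO ontology as a directed acyclic term graph
#'
#' Parses an OBO 1.2/1.4 flat file into a term DAG. Only edges whose
#' relation label is in `relations` become traversal edges (child to
#' parent). Obsolete terms are kept as records for diagnostics but are
#' excluded from traversal, so they never appear among ancestors or
#' descendants of any term. `replaced_by` links are recorded.
#'
#' @param file Path to an OBO file, or a character vector of OBO lines.
#' @param relations Relation labels to traverse. `"is_a"` plus the
#'   labels of `relationship:` tags. Default `c("is_a", "part_of")`,
#'   the conventional true-path propagation set for GO.
#' @return An object of class `ontology_graph` with components
#'   `ids`, `name`, `namespace`, `obsolete`, `parents`, `children`,
#'   `roots` (a list, one character vector of root ids per namespace),
#'   `relations` and `replaced_by`.
#' @examples
#' obo <- c("[Term]", "id: T:1", "name: root", "namespace: bp",
#'          "", "[Term]", "id: T:2", "name: leaf", "namespace: bp",
#'          "is_a: T:1 ! root")
#' g <- load_obo(obo)
#' ancestors(g, "T:2")
#' @export
load_obo <- function(file, relations = c("is_a", "part_of")) {
  stopifnot(length(relations) >= 1L)
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file, warn = FALSE) else file

  # split into stanzas; only [Term] stanzas carry terms
  stanza_starts <- grep("^\\[", lines)
  if (length(stanza_starts) == 0L) stop("no stanzas found in OBO input")
  stanza_ends <- c(stanza_starts[-1L] - 1L, length(lines))
  term_ids <- character(0)
  nm <- character(0); ns <- character(0); obs <- logical(0)
  rep_by <- character(0)
  edge_child <- character(0); edge_parent <- character(0); edge_rel <- character(0)

  strip_comment <- function(x) sub("\\s*!.*$", "", x)

  for (s in seq_along(stanza_starts)) {
    if (lines[stanza_starts[s]] != "[Term]") next
    body <- lines[seq(stanza_starts[s] + 1L, stanza_ends[s])]
    body <- body[nzchar(body)]
    tag <- sub(":.*$", "", body)
    val <- trimws(sub("^[^:]+:\\s*", "", body))
    id <- val[tag == "id"][1L]
    if (is.na(id)) stop("OBO [Term] stanza without id (stanza ", s, ")")
    if (id %in% term_ids) stop("duplicate term id in OBO input: ", id)
    term_ids <- c(term_ids, id)
    nm[id] <- if (any(tag == "name")) val[tag == "name"][1L] else NA_character_
    ns[id] <- if (any(tag == "namespace")) val[tag == "namespace"][1L] else NA_character_
    obs[id] <- any(tag == "is_obsolete" & grepl("^true", val))
    if (any(tag == "replaced_by")) rep_by[id] <- strip_comment(val[tag == "replaced_by"][1L])
    # is_a edges
    for (v in val[tag == "is_a"]) {
      edge_child <- c(edge_child, id)
      edge_parent <- c(edge_parent, trimws(strip_comment(v)))
      edge_rel <- c(edge_rel, "is_a")
    }
    # relationship: <rel> <target>
    for (v in val[tag == "relationship"]) {
      pieces <- strsplit(trimws(strip_comment(v)), "\\s+")[[1L]]
      if (length(pieces) >= 2L) {
        edge_child <- c(edge_child, id)
        edge_parent <- c(edge_parent, pieces[2L])
        edge_rel <- c(edge_rel, pieces[1L])
      }
    }
  }

  keep <- edge_rel %in% relations
  edge_child <- edge_child[keep]; edge_parent <- edge_parent[keep]

  unknown <- setdiff(edge_parent, term_ids)
  if (length(unknown) > 0L)
    stop("edge references unknown parent term: ", unknown[1L])

  # obsolete terms carry no traversal edges in either direction
  live <- !obs[edge_child] & !obs[edge_parent]
  edge_child <- edge_child[live]; edge_parent <- edge_parent[live]

  parents <- split(edge_parent, factor(edge_child, levels = term_ids))
  children <- split(edge_child, factor(edge_parent, levels = term_ids))
  parents <- lapply(parents, unique)
  children <- lapply(children, unique)

  g <- structure(list(
    ids = term_ids, name = nm, namespace = ns, obsolete = obs,
    parents = parents, children = children,
    relations = relations, replaced_by = rep_by
  ), class = "ontology_graph")

  cyc <- .find_cycle_member(g)
  if (!is.null(cyc)) stop("ontology graph contains a cycle through term: ", cyc)

  active <- term_ids[!obs[term_ids]]
  is_root <- vapply(active, function(t) length(parents[[t]]) == 0L, logical(1))
  rt <- active[is_root]
  g$roots <- split(rt, factor(ns[rt], levels = unique(ns[rt])))
  g
}

# Kahn's algorithm; returns NULL if acyclic, else one member of a cycle.
.find_cycle_member <- function(g) {
  indeg <- vapply(g$ids, function(t) length(g$parents[[t]]), integer(1))
  # orient edges parent -> child for the peel: peel terms with no parents
  queue <- g$ids[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    t <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in g$children[[t]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(g$ids)) g$ids[indeg > 0L][1L] else NULL
}

#' @export
print.ontology_graph <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  cat("ontology_graph:", length(x$ids), "terms (",
      sum(x$obsolete), "obsolete ),", n_edges, "traversal edges\n")
  cat("relations:", paste(x$relations, collapse = ", "), "\n")
  for (nsn in names(x$roots))
    cat("namespace", nsn, "- roots:", paste(x$roots[[nsn]], collapse = ", "), "\n")
  invisible(x)
}

.check_term <- function(graph, t) {
  if (!t %in% graph$ids) stop("term not in ontology: ", t)
  if (isTRUE(graph$obsolete[[t]])) stop("term is obsolete: ", t)
}

#' Ancestors and descendants of a term
#'
#' All terms reachable from `t` along traversal edges (towards the
#' roots for `ancestors`, away from them for `descendants`),
#' excluding `t` itself.
#'
#' @param graph An `ontology_graph`.
#' @param t Term id.
#' @return Character vector of term ids (possibly empty).
#' @export
ancestors <- function(graph, t) {
  .check_term(graph, t)
  .reach(graph$parents, t)
}

#' @rdname ancestors
#' @export
descendants <- function(graph, t) {
  .check_term(graph, t)
  .reach(graph$children, t)
}

.reach <- function(adj, t) {
  out <- character(0)
  frontier <- adj[[t]]
  while (length(frontier) > 0L) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(adj[frontier], use.names = FALSE))
  }
  out
}

# Full reachability closure for every term, computed once in topological
# order. direction = "up" gives ancestor sets, "down" descendant sets.
.closure <- function(graph, direction = c("up", "down")) {
  direction <- match.arg(direction)
  adj <- if (direction == "up") graph$parents else graph$children
  rev_adj <- if (direction == "up") graph$children else graph$parents
  indeg <- vapply(graph$ids, function(t) length(adj[[t]]), integer(1))
  queue <- graph$ids[indeg == 0L]
  out <- stats::setNames(vector("list", length(graph$ids)), graph$ids)
  while (length(queue) > 0L) {
    t <- queue[1L]; queue <- queue[-1L]
    out[[t]] <- unique(c(adj[[t]],
                         unlist(out[adj[[t]]], use.names = FALSE)))
    for (ch in rev_adj[[t]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  out
}

#' Are two terms disjoint up to the namespace root?
#'
#' A term pair is disjoint when the terms share no common ancestor
#' other than the root (equivalently, their least common ancestor is
#' the root), share no common descendant, and neither is an ancestor
#' of the other.
#'
#' @param graph An `ontology_graph`.
#' @param t1,t2 Distinct term ids from the same namespace as `root`.
#' @param root The namespace root term id.
#' @param ancestor_only If `TRUE`, only the common-ancestor condition
#'   is checked (used for disease-ontology distinct-disease calls);
#'   the shared-descendant condition is skipped.
#' @return Logical scalar.
#' @export
is_disjoint_pair <- function(graph, t1, t2, root, ancestor_only = FALSE) {
  stopifnot(t1 != t2)
  .check_term(graph, t1); .check_term(graph, t2); .check_term(graph, root)
  ns <- graph$namespace[c(t1, t2, root)]
  if (length(unique(ns[!is.na(ns)])) > 1L)
    stop("terms from different namespaces: ", t1, ", ", t2)
  a1 <- ancestors(graph, t1); a2 <- ancestors(graph, t2)
  if (t1 %in% a2 || t2 %in% a1) return(FALSE)
  if (length(setdiff(intersect(a1, a2), root)) > 0L) return(FALSE)
  if (!ancestor_only) {
    d1 <- descendants(graph, t1)
    if (length(intersect(d1, descendants(graph, t2))) > 0L) return(FALSE)
  }
  TRUE
}
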