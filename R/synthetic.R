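# Seeded generators for ontologies, annotations, networks,
# orthologies and feature tables with planted ground truth.

.syn_id <- function(i) sprintf("SYN:%07d", i)

#' Generate a synthetic multi-branch ontology
#'
#' Builds a single-rooted DAG of `n_branches` mutually disjoint
#' subtrees: branch roots are the children of the root, and no edges
#' cross branches, so terms from different branches always have the
#' root as their only common ancestor. Each branch is a tree of
#' `depth` levels with `fanout` children per internal node;
#' `p_crosslink` adds random extra within-branch child-to-
#' grandparent-side edges (DAG diamonds) for traversal stress tests.
#'
#' @param n_branches Number of disjoint branches (>= 2).
#' @param depth Levels per branch (1 = branch root only).
#' @param fanout Children per internal node.
#' @param seed Integer seed.
#' @param p_crosslink Probability of an extra within-branch edge per
#'   eligible term (default 0).
#' @param namespace Namespace name (default "synthetic_process").
#' @return An `ontology_graph`.
#' @export
gen_ontology <- function(n_branches, depth, fanout, seed = 1,
                         p_crosslink = 0, namespace = "synthetic_process") {
  stopifnot(n_branches >= 2, depth >= 1, fanout >= 1)
  set.seed(seed)
  root <- .syn_id(1L)
  nodes <- root
  branch_of <- stats::setNames(NA_character_, root)
  level_of <- stats::setNames(0L, root)
  edges <- list()
  nxt <- 2L
  for (b in seq_len(n_branches)) {
    broot <- .syn_id(nxt); nxt <- nxt + 1L
    nodes <- c(nodes, broot)
    branch_of[broot] <- broot; level_of[broot] <- 1L
    edges[[length(edges) + 1L]] <- c(broot, root)
    frontier <- broot
    lvl <- 1L
    while (lvl < depth) {
      lvl <- lvl + 1L
      new_frontier <- character(0)
      for (parent in frontier) {
        for (f in seq_len(fanout)) {
          id <- .syn_id(nxt); nxt <- nxt + 1L
          nodes <- c(nodes, id)
          branch_of[id] <- broot; level_of[id] <- lvl
          edges[[length(edges) + 1L]] <- c(id, parent)
          new_frontier <- c(new_frontier, id)
        }
      }
      frontier <- new_frontier
    }
  }
  # optional within-branch diamonds: extra edge to another term at a
  # strictly shallower level of the same branch
  if (p_crosslink > 0) {
    for (t in nodes[-1L]) {
      if (stats::runif(1) >= p_crosslink) next
      cand <- nodes[!is.na(branch_of) & branch_of == branch_of[t] &
                      level_of < level_of[t]]
      cand <- setdiff(cand, t)
      if (length(cand) > 0L)
        edges[[length(edges) + 1L]] <- c(t, cand[sample.int(length(cand), 1L)])
    }
  }
  lines <- c("format-version: 1.2", "")
  for (t in nodes) {
    lines <- c(lines, "[Term]", paste0("id: ", t),
               paste0("name: synthetic term ", t),
               paste0("namespace: ", namespace))
    for (e in edges) if (e[1L] == t)
      lines <- c(lines, paste0("is_a: ", e[2L]))
    lines <- c(lines, "")
  }
  load_obo(lines)
}

#' Serialize an ontology graph to OBO
#'
#' @param graph An `ontology_graph`.
#' @param file Output path; omit to return the lines.
#' @return Invisibly, the OBO lines.
#' @export
write_obo <- function(graph, file = NULL) {
  lines <- c("format-version: 1.2", "")
  for (t in graph$ids) {
    lines <- c(lines, "[Term]", paste0("id: ", t))
    if (!is.na(graph$name[[t]])) lines <- c(lines, paste0("name: ", graph$name[[t]]))
    if (!is.na(graph$namespace[[t]]))
      lines <- c(lines, paste0("namespace: ", graph$namespace[[t]]))
    if (isTRUE(graph$obsolete[[t]])) lines <- c(lines, "is_obsolete: true")
    for (p in graph$parents[[t]]) lines <- c(lines, paste0("is_a: ", p))
    lines <- c(lines, "")
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Generate annotations with planted multifunctional genes
#'
#' Background genes are annotated to single leaf terms so that every
#' leaf's propagated count falls in one specificity window. Each
#' planted multifunctional gene is annotated to its own distinct
#' cross-branch pair of leaves, so no planted pair becomes
#' co-annotation enriched (each such pair shares exactly one gene).
#' When `coannotation_enrichment > 1`, a flagged decoy leaf pair
#' (cross-branch, never used by planted genes) is additionally
#' co-annotated by a block of shared genes, inflating its overlap to
#' about `coannotation_enrichment` times the chance expectation so
#' the hypergeometric filter is exercised.
#'
#' @param graph An `ontology_graph` from [gen_ontology()].
#' @param n_genes Total genes (default 220).
#' @param planted_mf Number of planted multifunctional genes
#'   (default 25).
#' @param coannotation_enrichment Overlap inflation factor for the
#'   decoy pair; values <= 1 disable the decoy (default 6, enough to
#'   drive the decoy pair's co-annotation p-value well below 0.1 at
#'   the default scale).
#' @param seed Integer seed.
#' @param max_pairs_per_leaf Cap on planted pairs touching one leaf
#'   (default 6), keeping leaf counts inside their window.
#' @return List with `records` (annotation data.frame) and `truth`
#'   (planted multifunctional genes, decoy pair and genes, leaf
#'   targets, parameters, seed).
#' @export
gen_annotations <- function(graph, n_genes = 220, planted_mf = 25,
                            coannotation_enrichment = 6, seed = 1,
                            max_pairs_per_leaf = 6) {
  set.seed(seed)
  root <- unlist(graph$roots, use.names = FALSE)
  stopifnot(length(root) == 1L)
  leaves <- sort(graph$ids[vapply(graph$ids, function(t)
    length(graph$children[[t]]) == 0L, logical(1))])
  leaves <- setdiff(leaves, root)
  branch_root <- function(t) {
    a <- c(t, ancestors(graph, t))
    a[a %in% graph$children[[root]]][1L]
  }
  br <- vapply(leaves, branch_root, character(1))
  if (length(unique(br)) < 2L) stop("need leaves in at least two branches")

  use_decoy <- coannotation_enrichment > 1 && length(leaves) >= 4L
  decoy_leaves <- character(0)
  if (use_decoy) {
    # last leaf of the two last branches
    bs <- sort(unique(br))
    decoy_leaves <- c(rev(leaves[br == bs[length(bs) - 1L]])[1L],
                      rev(leaves[br == bs[length(bs)]])[1L])
  }
  open_leaves <- setdiff(leaves, decoy_leaves)

  # distinct cross-branch planted pairs over open leaves, capped load
  planted_pairs <- NULL
  if (planted_mf > 0L) {
    all_pairs <- utils::combn(open_leaves, 2L)
    cross <- br[all_pairs[1L, ]] != br[all_pairs[2L, ]]
    all_pairs <- all_pairs[, cross, drop = FALSE]
    if (ncol(all_pairs) < planted_mf)
      stop("not enough distinct cross-branch leaf pairs for planted_mf")
    for (attempt in seq_len(200L)) {
      sel <- sample.int(ncol(all_pairs), planted_mf)
      load <- table(as.vector(all_pairs[, sel]))
      if (max(load) <= max_pairs_per_leaf) break
      sel <- NULL
    }
    if (is.null(sel))
      stop("could not place planted pairs under the per-leaf load cap; ",
           "reduce planted_mf or add branches")
    planted_pairs <- all_pairs[, sel, drop = FALSE]
  }

  mf_genes <- if (planted_mf > 0L) sprintf("MF%04d", seq_len(planted_mf)) else character(0)
  gene <- character(0); term <- character(0)
  for (i in seq_len(planted_mf)) {
    gene <- c(gene, mf_genes[i], mf_genes[i])
    term <- c(term, planted_pairs[1L, i], planted_pairs[2L, i])
  }

  # decoy block: shared genes co-annotated to both decoy leaves
  decoy_target <- 15L
  n_decoy <- 0L
  decoy_genes <- character(0)
  if (use_decoy) {
    n_decoy <- as.integer(ceiling(coannotation_enrichment *
                                    decoy_target^2 / n_genes))
    if (n_decoy >= decoy_target)
      stop("coannotation_enrichment too large for the fixture scale")
    decoy_genes <- sprintf("DY%04d", seq_len(n_decoy))
    for (g in decoy_genes) {
      gene <- c(gene, g, g)
      term <- c(term, decoy_leaves[1L], decoy_leaves[2L])
    }
  }

  # background genes: one leaf each, equalizing leaf counts
  n_bg <- n_genes - planted_mf - n_decoy
  if (n_bg < 0L) stop("n_genes too small for planted and decoy genes")
  planted_load <- table(factor(if (is.null(planted_pairs)) character(0)
                               else as.vector(planted_pairs),
                               levels = open_leaves))
  # decoy leaves are filled to the fixed decoy target
  bg_decoy <- if (use_decoy) pmax(0L, decoy_target - n_decoy) else integer(0)
  n_bg_open <- n_bg - sum(rep(bg_decoy, length(decoy_leaves)))
  if (n_bg_open < 0L) stop("n_genes too small for the decoy block")
  total_open <- n_bg_open + sum(planted_load)
  base <- total_open %/% length(open_leaves)
  extra <- total_open %% length(open_leaves)
  target <- stats::setNames(rep(base, length(open_leaves)), open_leaves)
  if (extra > 0L) {
    bump <- sample(open_leaves, extra)
    target[bump] <- target[bump] + 1L
  }
  if (any(target < 10L) || any(target >= 20L))
    stop("leaf annotation targets fall outside the [10, 20) specificity ",
         "window; adjust n_genes (", length(open_leaves), " open leaves, ",
         "targets ", min(target), "-", max(target), ")")
  if (any(target < planted_load[names(target)]))
    stop("planted load exceeds leaf target; lower max_pairs_per_leaf")
  bg_per_leaf <- target - as.integer(planted_load[names(target)])
  bg_genes <- sprintf("BG%04d", seq_len(n_bg))
  bg_assign <- c(rep(names(bg_per_leaf), bg_per_leaf),
                 rep(decoy_leaves, each = if (use_decoy) bg_decoy else 0L))
  stopifnot(length(bg_assign) == n_bg)
  bg_assign <- sample(bg_assign)  # shuffle gene-to-leaf pairing
  gene <- c(gene, bg_genes)
  term <- c(term, bg_assign)

  records <- data.frame(gene = gene, term = term, evidence = "EXP",
                        qualifiers = "", aspect = NA_character_,
                        stringsAsFactors = FALSE)
  truth <- list(
    planted_multifunctional = mf_genes,
    decoy_pair = if (use_decoy) sort(decoy_leaves) else NULL,
    decoy_genes = decoy_genes,
    background_genes = bg_genes,
    leaf_targets = as.list(target),
    parameters = list(n_genes = n_genes, planted_mf = planted_mf,
                      coannotation_enrichment = coannotation_enrichment,
                      seed = seed)
  )
  list(records = records, truth = truth)
}

#' Generate a clustered random network
#'
#' Stochastic block model: `n_modules` planted modules of near-equal
#' size with independent edge probability `p_within` inside modules
#' and `p_between` across.
#'
#' @param n_nodes Number of nodes (default 200).
#' @param n_modules Planted modules (default 4).
#' @param p_within,p_between Edge probabilities (defaults 0.15 and
#'   0.01).
#' @param seed Integer seed.
#' @return List with `network` (igraph) and `clusters` (named vector
#'   of planted module labels).
#' @export
gen_network <- function(n_nodes = 200, n_modules = 4, p_within = 0.15,
                        p_between = 0.01, seed = 1) {
  stopifnot(n_nodes >= n_modules, n_modules >= 1)
  set.seed(seed)
  sizes <- rep(n_nodes %/% n_modules, n_modules)
  sizes[seq_len(n_nodes %% n_modules)] <- sizes[seq_len(n_nodes %% n_modules)] + 1L
  pm <- matrix(p_between, n_modules, n_modules)
  diag(pm) <- p_within
  g <- igraph::sample_sbm(n_nodes, pref.matrix = pm, block.sizes = sizes)
  igraph::V(g)$name <- sprintf("G%04d", seq_len(n_nodes))
  clusters <- stats::setNames(rep(sprintf("M%02d", seq_len(n_modules)), sizes),
                              igraph::V(g)$name)
  list(network = g, clusters = clusters)
}

#' Generate one-to-one ortholog pairs with a planted excess
#'
#' Creates `n_pairs` one-to-one ortholog pairs between organisms A
#' and B, labels `f_mf_a` / `f_mf_b` fractions of each side's genes
#' multifunctional, and plants `excess` times the chance-expected
#' number of both-multifunctional pairs (`excess = 1` assigns labels
#' uniformly at random).
#'
#' @param n_pairs Number of pairs (default 400).
#' @param f_mf_a,f_mf_b Multifunctional fractions (defaults 0.3).
#' @param excess Planted excess factor (default 2).
#' @param seed Integer seed.
#' @return List with `pairs` (data.frame `a`, `b`), `mf_a`, `mf_b`
#'   (label sets) and `truth`.
#' @export
gen_orthology <- function(n_pairs = 400, f_mf_a = 0.3, f_mf_b = 0.3,
                          excess = 2, seed = 1) {
  stopifnot(n_pairs >= 2, f_mf_a > 0, f_mf_a < 1, f_mf_b > 0, f_mf_b < 1)
  set.seed(seed)
  ga <- sprintf("A%04d", seq_len(n_pairs))
  gb <- sprintf("B%04d", seq_len(n_pairs))
  n_a <- round(f_mf_a * n_pairs); n_b <- round(f_mf_b * n_pairs)
  if (excess == 1) {
    mf_a <- sample(ga, n_a)
    mf_b <- sample(gb, n_b)
  } else {
    both <- round(excess * n_pairs * (n_a / n_pairs) * (n_b / n_pairs))
    both <- min(both, n_a, n_b)
    if (n_pairs - both < (n_a - both) + (n_b - both))
      stop("excess too large for the requested fractions")
    idx <- sample.int(n_pairs)
    i_both <- idx[seq_len(both)]
    rest <- idx[-seq_len(both)]
    i_a <- rest[seq_len(n_a - both)]
    i_b <- rest[seq(n_a - both + 1L, length.out = n_b - both)]
    mf_a <- ga[c(i_both, i_a)]
    mf_b <- gb[c(i_both, i_b)]
  }
  list(
    pairs = data.frame(a = ga, b = gb, stringsAsFactors = FALSE),
    mf_a = sort(mf_a), mf_b = sort(mf_b),
    truth = list(excess = excess, n_pairs = n_pairs,
                 expected_null = n_pairs * (n_a / n_pairs) * (n_b / n_pairs),
                 seed = seed)
  )
}

#' Generate a per-gene feature table with planted group shifts
#'
#' Each feature is standard normal noise plus `effect_sizes[f]` added
#' for genes in the labelled group, emulating shifted feature
#' distributions between multifunctional and other genes.
#'
#' @param genes Character vector of gene ids.
#' @param group_labels Named logical vector over `genes` (TRUE =
#'   shifted group).
#' @param effect_sizes Named numeric vector, one entry per feature to
#'   generate.
#' @param seed Integer seed.
#' @return data.frame with `gene`, `group` and one column per
#'   feature.
#' @export
gen_features <- function(genes, group_labels,
                         effect_sizes = c(feature1 = 1, feature2 = 0),
                         seed = 1) {
  stopifnot(all(genes %in% names(group_labels)))
  set.seed(seed)
  out <- data.frame(gene = genes, group = unname(group_labels[genes]),
                    stringsAsFactors = FALSE)
  for (f in names(effect_sizes)) {
    out[[f]] <- stats::rnorm(length(genes)) +
      effect_sizes[[f]] * as.numeric(group_labels[genes])
  }
  out
}

#' Write annotation records as GAF 2.2 or plain TSV
#'
#' @param records Annotation data.frame (`gene`, `term`, `evidence`,
#'   `qualifiers`, `aspect`).
#' @param file Output path.
#' @param format `"tsv"` (two-column fixture dialect) or `"gaf"`.
#' @return Invisibly, `file`.
#' @export
write_annotations <- function(records, file, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(records[, c("gene", "term")], file, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
  } else {
    asp <- ifelse(is.na(records$aspect), "P", records$aspect)
    lines <- c("!gaf-version: 2.2",
               paste("SYNDB", records$gene, records$gene,
                     ifelse(nzchar(records$qualifiers), records$qualifiers,
                            "involved_in"),
                     records$term, "SYN_REF:0000001", records$evidence, "",
                     asp, "", "", "protein", "taxon:0001", "20260101",
                     "SYNDB", "", "", sep = "\t"))
    writeLines(lines, file)
  }
  invisible(file)
}

#' Write a network edge list as TSV
#' @param net An igraph graph.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_edges <- function(net, file) {
  el <- igraph::as_edgelist(net)
  utils::write.table(data.frame(gene_a = el[, 1L], gene_b = el[, 2L]),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
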