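# Core method: specificity-level term selection, distinct-pair
# filtering, and multifunctional gene calling as a union over levels.

#' Select terms at one specificity level
#'
#' The level-N term set contains every term that annotates at least N
#' but fewer than 2N genes and whose every descendant term annotates
#' fewer than N genes (terms with no descendants qualify). Counts are
#' true-path propagated. The namespace root receives no special
#' treatment: it is selected if and only if it satisfies the bounds.
#'
#' @param index A `gene_term_index`.
#' @param graph An `ontology_graph`.
#' @param N Positive integer gene-count threshold.
#' @return Character vector of selected term ids (sorted).
#' @export
select_terms <- function(index, graph, N) {
  stopifnot(N >= 1)
  if (length(index$universe) == 0L) stop("empty annotation index")
  desc <- .closure(graph, "down")
  .select_terms_closed(index, graph, N, desc)
}

.candidate_terms <- function(index, graph) {
  ts <- graph$ids[!graph$obsolete[graph$ids]]
  if (!is.null(index$namespace))
    ts <- ts[graph$namespace[ts] %in% index$namespace]
  ts
}

.select_terms_closed <- function(index, graph, N, desc) {
  ts <- .candidate_terms(index, graph)
  cnt <- term_count(index, ts)
  ok <- cnt >= N & cnt < 2L * N
  ts <- ts[ok]
  keep <- vapply(ts, function(t) {
    d <- desc[[t]]
    length(d) == 0L || all(term_count(index, d) < N)
  }, logical(1))
  sort(ts[keep])
}

#' Upper-tail hypergeometric co-annotation p-value
#'
#' Probability of observing at least `k` genes in common between two
#' gene sets of sizes `a` and `b` drawn from a universe of `G` genes:
#' P[X >= k] for X ~ Hypergeometric(G, a, b). Symmetric in (a, b).
#'
#' @param k Observed overlap.
#' @param a,b Sizes of the two gene sets.
#' @param G Universe size.
#' @return A probability.
#' @export
coannotation_pvalue <- function(k, a, b, G) {
  if (any(c(k, a, b, G) < 0) || a > G || b > G || k > min(a, b))
    stop("inconsistent hypergeometric counts (k=", k, ", a=", a,
         ", b=", b, ", G=", G, ")")
  stats::phyper(k - 1, a, G - a, b, lower.tail = FALSE)
}

#' Filter term pairs at one specificity level for distinctness
#'
#' From all unordered pairs of level terms, retains those that (i)
#' share no common ancestor other than the namespace root, (ii) share
#' no common descendant, (iii) are not ancestor/descendant of each
#' other, and (iv) do not co-annotate significantly overlapping gene
#' sets (upper-tail hypergeometric p-value below `alpha` removes the
#' pair; no multiple-testing correction, per-pair raw p-values).
#'
#' @param level_terms Character vector of term ids (a level set).
#' @param graph An `ontology_graph`.
#' @param index A `gene_term_index`.
#' @param root Namespace root term id.
#' @param alpha Co-annotation significance cutoff in (0,1); pairs
#'   with p >= alpha are retained.
#' @return data.frame with columns `term1`, `term2`, `overlap`, `p`
#'   (one row per retained pair; term1 < term2).
#' @export
filter_pairs <- function(level_terms, graph, index, root, alpha = 0.1) {
  stopifnot(alpha > 0, alpha < 1)
  anc <- .closure(graph, "up")
  desc <- .closure(graph, "down")
  .filter_pairs_closed(level_terms, index, root, alpha, anc, desc)
}

.filter_pairs_closed <- function(level_terms, index, root, alpha, anc, desc) {
  out <- list()
  G <- length(index$universe)
  ts <- sort(level_terms)
  n <- length(ts)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      t1 <- ts[i]; t2 <- ts[j]
      if (t1 %in% anc[[t2]] || t2 %in% anc[[t1]]) next
      if (length(setdiff(intersect(anc[[t1]], anc[[t2]]), root)) > 0L) next
      if (length(intersect(desc[[t1]], desc[[t2]])) > 0L) next
      g1 <- term_genes(index, t1); g2 <- term_genes(index, t2)
      k <- length(intersect(g1, g2))
      p <- coannotation_pvalue(k, length(g1), length(g2), G)
      if (p < alpha) next
      out[[length(out) + 1L]] <- data.frame(
        term1 = t1, term2 = t2, overlap = k, p = p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(term1 = character(0), term2 = character(0),
                      overlap = integer(0), p = numeric(0)))
  do.call(rbind, out)
}

#' Detect multifunctional genes
#'
#' The core caller. For each specificity level N on the grid
#' {10, 10+increment, ..., M}: selects the level term set, filters
#' term pairs for distinctness ([filter_pairs()]), and calls every
#' gene co-annotated by both members of a retained pair. The final
#' multifunctional set is the union of calls over all levels; the
#' background is every gene annotated by at least one selected term
#' at any level. Output ordering is deterministic (lexicographic by
#' gene, then level, then terms).
#'
#' @param index A `gene_term_index`.
#' @param graph An `ontology_graph`.
#' @param root Namespace root term id. Defaults to the single root of
#'   the index namespace when unambiguous.
#' @param M Largest specificity level (default 120).
#' @param increment Level grid step (default 10).
#' @param alpha Co-annotation cutoff (default 0.1).
#' @param n_min Smallest specificity level (default 10).
#' @return An object of class `multifun`: list with components
#'   `multifunctional` (sorted gene ids), `background` (sorted gene
#'   ids of all genes annotated by a selected term; contains
#'   `multifunctional`), `other` (background minus multifunctional),
#'   `evidence` (data.frame gene/N/term1/term2/overlap/p), `levels`
#'   (per-N list with `terms` and `pairs`), and `parameters`.
#' @examples
#' g <- gen_ontology(n_branches = 4, depth = 1, fanout = 1, seed = 1)
#' sim <- gen_annotations(g, n_genes = 80, planted_mf = 0, seed = 1)
#' idx <- build_index(sim$records, g)
#' fit <- detect_multifunctional(idx, g, M = 40)
#' summary(fit)
#' @export
detect_multifunctional <- function(index, graph, root = NULL, M = 120,
                                   increment = 10, alpha = 0.1, n_min = 10) {
  stopifnot(M >= n_min, increment >= 1)
  if (is.null(root)) {
    rts <- if (!is.null(index$namespace)) graph$roots[[index$namespace]]
           else unlist(graph$roots, use.names = FALSE)
    if (length(rts) != 1L)
      stop("namespace root is ambiguous; pass `root` explicitly")
    root <- rts
  }
  anc <- .closure(graph, "up")
  desc <- .closure(graph, "down")
  grid <- seq(n_min, M, by = increment)

  levels <- list()
  ev <- list()
  bg <- character(0)
  for (N in grid) {
    ts <- .select_terms_closed(index, graph, N, desc)
    pairs <- .filter_pairs_closed(ts, index, root, alpha, anc, desc)
    if (length(ts) > 0L)
      bg <- union(bg, unique(unlist(index$term_to_genes[ts], use.names = FALSE)))
    if (nrow(pairs) > 0L) {
      for (r in seq_len(nrow(pairs))) {
        shared <- intersect(term_genes(index, pairs$term1[r]),
                            term_genes(index, pairs$term2[r]))
        if (length(shared) > 0L)
          ev[[length(ev) + 1L]] <- data.frame(
            gene = shared, N = N,
            term1 = pairs$term1[r], term2 = pairs$term2[r],
            overlap = pairs$overlap[r], p = pairs$p[r],
            stringsAsFactors = FALSE)
      }
    }
    levels[[as.character(N)]] <- list(N = N, terms = ts, pairs = pairs)
  }
  if (all(vapply(levels, function(l) length(l$terms) == 0L, logical(1)))) {
    cnt <- term_count(index, .candidate_terms(index, graph))
    stop("no specificity level selected any term; propagated count ",
         "distribution: min=", min(cnt), " median=", stats::median(cnt),
         " max=", max(cnt))
  }
  evidence <- if (length(ev) > 0L) do.call(rbind, ev) else
    data.frame(gene = character(0), N = integer(0), term1 = character(0),
               term2 = character(0), overlap = integer(0), p = numeric(0))
  evidence <- evidence[order(evidence$gene, evidence$N,
                             evidence$term1, evidence$term2), , drop = FALSE]
  rownames(evidence) <- NULL
  mf <- sort(unique(evidence$gene))
  bg <- sort(bg)

  structure(list(
    multifunctional = mf,
    background = bg,
    other = setdiff(bg, mf),
    evidence = evidence,
    levels = levels,
    parameters = list(M = M, increment = increment, alpha = alpha,
                      n_min = n_min, root = root,
                      universe_size = length(index$universe))
  ), class = "multifun")
}

#' @export
print.multifun <- function(x, ...) {
  p <- x$parameters
  cat("Multifunctional gene detection (N grid ", p$n_min, "..", p$M,
      " step ", p$increment, ", alpha = ", p$alpha, ")\n", sep = "")
  cat("  multifunctional:", length(x$multifunctional), "genes\n")
  cat("  background (annotated by a selected term):",
      length(x$background), "genes\n")
  cat("  evidence pairs:", nrow(x$evidence), "\n")
  invisible(x)
}

#' @export
summary.multifun <- function(object, ...) {
  lv <- data.frame(
    N = vapply(object$levels, `[[`, numeric(1), "N"),
    n_terms = vapply(object$levels, function(l) length(l$terms), integer(1)),
    n_pairs = vapply(object$levels, function(l) nrow(l$pairs), integer(1))
  )
  rownames(lv) <- NULL
  out <- list(
    levels = lv,
    n_multifunctional = length(object$multifunctional),
    n_background = length(object$background),
    n_other = length(object$other),
    fraction_multifunctional =
      length(object$multifunctional) / max(1L, length(object$background)),
    parameters = object$parameters
  )
  class(out) <- "summary.multifun"
  out
}

#' @export
print.summary.multifun <- function(x, ...) {
  cat("Per-level term selection:\n")
  print(x$levels)
  cat("\nmultifunctional:", x$n_multifunctional,
      " background:", x$n_background,
      " fraction:", signif(x$fraction_multifunctional, 3), "\n")
  invisible(x)
}

#' Write detection outputs
#'
#' Writes `<prefix>.genes.tsv` (gene, is_multifunctional,
#' n_evidence_pairs), `<prefix>.evidence.tsv`, `<prefix>.terms.tsv`
#' (N, term, count) and `<prefix>.summary.json`.
#'
#' @param result A `multifun` object.
#' @param prefix Output path prefix.
#' @param index The `gene_term_index` used for the fit (for term
#'   counts in the terms table).
#' @return Invisibly, the vector of files written.
#' @export
write_detection <- function(result, prefix, index) {
  genes <- data.frame(
    gene = result$background,
    is_multifunctional = as.integer(result$background %in% result$multifunctional),
    n_evidence_pairs = as.integer(
      table(factor(result$evidence$gene, levels = result$background)))
  )
  f1 <- paste0(prefix, ".genes.tsv")
  utils::write.table(genes, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- paste0(prefix, ".evidence.tsv")
  utils::write.table(result$evidence, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  terms <- do.call(rbind, lapply(result$levels, function(l) {
    if (length(l$terms) == 0L) return(NULL)
    data.frame(N = l$N, term = l$terms,
               count = as.integer(term_count(index, l$terms)))
  }))
  f3 <- paste0(prefix, ".terms.tsv")
  utils::write.table(terms, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  f4 <- paste0(prefix, ".summary.json")
  s <- summary(result)
  jsonlite::write_json(list(
    parameters = result$parameters,
    n_multifunctional = s$n_multifunctional,
    n_background = s$n_background,
    levels = s$levels
  ), f4, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, f3, f4))
}
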