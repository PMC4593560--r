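# Gene annotation loading and true-path-propagated indices.

#' Evidence-code presets
#'
#' `evidence_default()` is the broad 14-code set used for the main
#' analysis; `evidence_strict()` is the 6-code experimentally reliable
#' subset (EXP, IDA, IMP, IEP, IC, TAS) used for sensitivity analyses.
#' @return Character vector of GAF evidence codes.
#' @export
evidence_default <- function() {
  c("EXP", "IDA", "IMP", "IGI", "IEP", "ISS", "ISO", "ISA", "ISM",
    "IGC", "IBA", "IC", "TAS", "NAS")
}

#' @rdname evidence_default
#' @export
evidence_strict <- function() c("EXP", "IDA", "IMP", "IEP", "IC", "TAS")

#' Load gene annotations from a GAF file
#'
#' Reads a GAF 2.x tab-separated file. Records whose evidence code is
#' not in `evidence_whitelist` are removed, as are records carrying
#' the qualifier `NOT`. Duplicate (gene, term) pairs are collapsed.
#' Malformed lines are skipped with a warning giving the line number.
#'
#' @param file Path to a GAF file, or a character vector of its lines.
#' @param evidence_whitelist Evidence codes to keep; default the broad
#'   14-code set of [evidence_default()].
#' @return A data.frame with columns `gene`, `term`, `evidence`,
#'   `qualifiers`, `aspect` (one row per surviving record).
#' @export
load_gaf <- function(file, evidence_whitelist = evidence_default()) {
  stopifnot(length(evidence_whitelist) >= 1L)
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file, warn = FALSE) else file
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad) > 0L) {
    warning("skipping ", length(bad), " malformed GAF line(s), first at line ",
            bad[1L])
    fields <- fields[-bad]
  }
  if (length(fields) == 0L) stop("no annotation records in GAF input")
  get <- function(i) vapply(fields, `[[`, character(1), i)
  rec <- data.frame(
    gene = get(2L), qualifiers = get(4L), term = get(5L),
    evidence = get(7L), aspect = get(9L), stringsAsFactors = FALSE
  )
  has_not <- vapply(strsplit(rec$qualifiers, "|", fixed = TRUE),
                    function(q) "NOT" %in% q, logical(1))
  rec <- rec[!has_not & rec$evidence %in% evidence_whitelist, , drop = FALSE]
  rec <- rec[!duplicated(rec[, c("gene", "term")]), , drop = FALSE]
  if (nrow(rec) == 0L) stop("no annotation records survive filtering")
  rownames(rec) <- NULL
  rec[, c("gene", "term", "evidence", "qualifiers", "aspect")]
}

#' Load annotations from a plain two-column gene/term TSV
#'
#' Fixture dialect: tab-separated `gene<TAB>term`, optional header
#' line `gene\tterm`, no evidence codes or qualifiers.
#'
#' @param file Path or character vector of lines.
#' @return A data.frame as returned by [load_gaf()], with evidence
#'   `"EXP"` and empty qualifiers.
#' @export
load_gene_term_tsv <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file, warn = FALSE) else file
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0L && grepl("^gene\tterm", lines[1L])) lines <- lines[-1L]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 2L
  if (any(!ok)) warning("skipping ", sum(!ok), " malformed line(s)")
  fields <- fields[ok]
  if (length(fields) == 0L) stop("no annotation records in TSV input")
  rec <- data.frame(
    gene = vapply(fields, `[[`, character(1), 1L),
    term = vapply(fields, `[[`, character(1), 2L),
    evidence = "EXP", qualifiers = "", aspect = NA_character_,
    stringsAsFactors = FALSE
  )
  rec[!duplicated(rec[, c("gene", "term")]), , drop = FALSE]
}

#' Build a true-path-propagated gene/term index
#'
#' Restricts annotation records to terms of one namespace of the
#' ontology and propagates every annotation to all ancestors of the
#' annotated term (the true-path rule), so that a term's gene set
#' always contains the gene sets of all its descendants.
#'
#' @param records Annotation data.frame from [load_gaf()] or
#'   [load_gene_term_tsv()].
#' @param graph An `ontology_graph`.
#' @param namespace Namespace name to restrict to; `NULL` keeps all
#'   terms (single-namespace ontologies).
#' @param propagate Propagate annotations to ancestors (default
#'   `TRUE`); `FALSE` gives direct-only counts for sensitivity
#'   analysis.
#' @return An object of class `gene_term_index`: list with
#'   `term_to_genes` (named list of character vectors),
#'   `gene_to_terms`, `universe` (all annotated genes) and
#'   `namespace`.
#' @export
build_index <- function(records, graph, namespace = NULL, propagate = TRUE) {
  known <- records$term %in% graph$ids
  if (any(!known)) {
    warning("skipping ", sum(!known),
            " record(s) with terms absent from the ontology")
    records <- records[known, , drop = FALSE]
  }
  obs <- graph$obsolete[records$term]
  if (any(obs)) {
    warning("discarding ", sum(obs), " annotation(s) to obsolete terms")
    records <- records[!obs, , drop = FALSE]
  }
  if (!is.null(namespace)) {
    records <- records[graph$namespace[records$term] %in% namespace, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no annotation records left for namespace")

  anc <- .closure(graph, "up")
  gene_direct <- split(records$term, records$gene)
  gene_to_terms <- lapply(gene_direct, function(ts) {
    ts <- unique(ts)
    unique(c(ts, unlist(anc[ts], use.names = FALSE)))
  })
  if (!propagate) gene_to_terms <- lapply(gene_direct, unique)

  pairs_gene <- rep(names(gene_to_terms), lengths(gene_to_terms))
  pairs_term <- unlist(gene_to_terms, use.names = FALSE)
  term_to_genes <- split(pairs_gene, pairs_term)

  structure(list(
    term_to_genes = term_to_genes,
    gene_to_terms = gene_to_terms,
    universe = sort(names(gene_to_terms)),
    namespace = namespace
  ), class = "gene_term_index")
}

#' @export
print.gene_term_index <- function(x, ...) {
  cat("gene_term_index:", length(x$universe), "genes,",
      length(x$term_to_genes), "terms with >=1 gene",
      if (!is.null(x$namespace)) paste0("(namespace ", x$namespace, ")"), "\n")
  invisible(x)
}

#' Number of genes annotated to a term (propagated)
#'
#' @param index A `gene_term_index`.
#' @param terms Term ids.
#' @return Integer vector of propagated annotation counts (0 for
#'   terms with no annotated genes).
#' @export
term_count <- function(index, terms) {
  n <- integer(length(terms))
  hit <- terms %in% names(index$term_to_genes)
  n[hit] <- lengths(index$term_to_genes[terms[hit]])
  stats::setNames(n, terms)
}

#' Genes annotated to a term (propagated)
#' @param index A `gene_term_index`.
#' @param term A term id.
#' @return Character vector of gene ids (empty if none).
#' @export
term_genes <- function(index, term) {
  g <- index$term_to_genes[[term]]
  if (is.null(g)) character(0) else g
}
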