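# Per-gene scalar feature derivation from raw isoform / residue /
# condition level inputs.

#' Longest protein isoform length per gene
#'
#' @param isoform_lengths Named list: gene -> numeric vector of
#'   isoform lengths (amino acids).
#' @return Named numeric vector of longest-isoform lengths.
#' @export
longest_isoform_length <- function(isoform_lengths) {
  if (any(lengths(isoform_lengths) == 0L))
    stop("gene with empty isoform length list: ",
         names(isoform_lengths)[lengths(isoform_lengths) == 0L][1L])
  vapply(isoform_lengths, function(x) max(as.numeric(x)), numeric(1))
}

#' Number of unique domain families per gene
#'
#' Multiple instances of the same domain family count once.
#'
#' @param domains Named list: gene -> character vector of domain
#'   family ids (one entry per domain instance; may be empty).
#' @return Named integer vector.
#' @export
unique_domain_count <- function(domains) {
  vapply(domains, function(d) length(unique(d)), integer(1))
}

#' Fraction of disordered residues
#'
#' Fraction of per-residue disorder scores strictly above the
#' disorder threshold (default 0.5, the conventional cutoff for
#' per-residue disorder predictors).
#'
#' @param scores Numeric vector of per-residue scores in [0, 1].
#' @param threshold Strict cutoff (default 0.5).
#' @return Fraction in [0, 1].
#' @export
disorder_fraction <- function(scores, threshold = 0.5) {
  stopifnot(length(scores) >= 1L, all(scores >= 0 & scores <= 1))
  mean(scores > threshold)
}

#' Gene conservation score from per-isoform nucleotide scores
#'
#' Per-nucleotide conservation scores are averaged within each
#' isoform, then the isoform means are averaged with equal weights
#' (isoforms are not weighted by length).
#'
#' @param per_isoform_scores List of numeric vectors, one per
#'   isoform, each the per-nucleotide scores over the isoform's
#'   exons.
#' @return Scalar conservation score.
#' @export
conservation_score <- function(per_isoform_scores) {
  stopifnot(length(per_isoform_scores) >= 1L,
            all(lengths(per_isoform_scores) >= 1L))
  mean(vapply(per_isoform_scores, function(x) mean(as.numeric(x)), numeric(1)))
}

#' Expression breadth: number of conditions a gene is present in
#'
#' Two presence rules: `"nonzero"` counts conditions with a nonzero
#' value (e.g. nonzero RPKM in a tissue); `"all_replicates_present"`
#' counts a condition only when the gene is flagged present (nonzero)
#' in all of its replicates, with replicate grouping given by
#' `replicate_of`.
#'
#' @param mat Numeric matrix, genes x conditions (columns are
#'   replicates when using the all-replicates rule).
#' @param rule `"nonzero"` or `"all_replicates_present"`.
#' @param replicate_of For the all-replicates rule, a vector mapping
#'   each column to its condition.
#' @return Named integer vector: per-gene count of conditions
#'   present.
#' @export
expression_breadth <- function(mat, rule = c("nonzero", "all_replicates_present"),
                               replicate_of = NULL) {
  rule <- match.arg(rule)
  if (rule == "nonzero")
    return(apply(mat, 1L, function(x) sum(x != 0)))
  if (is.null(replicate_of) || length(replicate_of) != ncol(mat))
    stop("all_replicates_present rule needs `replicate_of` over columns")
  conds <- unique(replicate_of)
  present <- vapply(conds, function(cd)
    apply(mat[, replicate_of == cd, drop = FALSE] != 0, 1L, all),
    logical(nrow(mat)))
  if (is.null(dim(present))) present <- matrix(present, nrow = nrow(mat))
  stats::setNames(as.integer(rowSums(present)), rownames(mat))
}

#' Number of conditions in which a deletion strain is essential
#'
#' Counts per-condition fitness p-values strictly below the
#' threshold.
#'
#' @param per_condition_pvalues Named list: gene -> numeric vector
#'   of per-condition p-values (may be empty).
#' @param threshold Significance cutoff (default 0.01).
#' @return Named integer vector of condition counts.
#' @export
condition_essentiality_count <- function(per_condition_pvalues,
                                         threshold = 0.01) {
  vapply(per_condition_pvalues, function(p) sum(as.numeric(p) < threshold),
         integer(1))
}

#' Genes associated with at least two distinct diseases
#'
#' A gene qualifies when at least one pair of its disease-ontology
#' terms has only the ontology root as a common ancestor. By default
#' only the common-ancestor condition is checked (two diseases in
#' separate root branches count as distinct even if some shared,
#' more specific term exists below both); set `full_criterion = TRUE`
#' to additionally require no shared descendants.
#'
#' @param disease_graph An `ontology_graph` over disease terms.
#' @param gene_to_terms Named list: gene -> character vector of
#'   disease term ids.
#' @param root Disease ontology root term id.
#' @param full_criterion Also require disjoint descendant sets.
#' @return Character vector of qualifying genes (sorted).
#' @export
multi_disease_genes <- function(disease_graph, gene_to_terms, root,
                                full_criterion = FALSE) {
  qualifies <- vapply(gene_to_terms, function(ts) {
    ts <- unique(ts[ts %in% disease_graph$ids])
    ts <- ts[!disease_graph$obsolete[ts]]
    ts <- setdiff(ts, root)
    if (length(ts) < 2L) return(FALSE)
    for (i in seq_len(length(ts) - 1L)) for (j in seq(i + 1L, length(ts))) {
      if (is_disjoint_pair(disease_graph, ts[i], ts[j], root,
                           ancestor_only = !full_criterion))
        return(TRUE)
    }
    FALSE
  }, logical(1))
  sort(names(gene_to_terms)[qualifies])
}

#' Assemble a per-gene feature table
#'
#' Merges any of the derived per-gene feature vectors into one
#' data.frame keyed by gene; missing values where a gene lacks a
#' feature.
#'
#' @param ... Named arguments, each a named vector (gene -> value).
#' @return data.frame with a `gene` column plus one column per
#'   feature.
#' @export
feature_table <- function(...) {
  feats <- list(...)
  stopifnot(length(feats) >= 1L, !is.null(names(feats)),
            all(nzchar(names(feats))))
  genes <- sort(unique(unlist(lapply(feats, names), use.names = FALSE)))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in names(feats)) out[[nm]] <- unname(feats[[nm]][genes])
  out
}
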