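# Cross-species conservation of multifunctionality.

#' Load ortholog pairs from TSV
#'
#' Two-column file (`geneA<TAB>geneB`, optional third `family`
#' column, optional header). Many-to-many family relationships may
#' list every cross-species pair; pairs are kept as listed (no
#' per-family collapsing), duplicates removed.
#'
#' @param file Path or character vector of lines.
#' @return data.frame with columns `a`, `b` (and `family` if given).
#' @export
load_ortholog_pairs <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file, warn = FALSE) else file
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0L && grepl("^gene_a\t|^geneA\t", lines[1L])) lines <- lines[-1L]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- fields[lengths(fields) >= 2L]
  if (length(fields) == 0L) stop("no ortholog pairs in input")
  df <- data.frame(
    a = vapply(fields, `[[`, character(1), 1L),
    b = vapply(fields, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  if (all(lengths(fields) >= 3L))
    df$family <- vapply(fields, `[[`, character(1), 3L)
  df[!duplicated(df[, c("a", "b")]), , drop = FALSE]
}

#' Count ortholog pairs multifunctional on both sides
#'
#' @param pairs data.frame with columns `a`, `b`.
#' @param mf_a,mf_b Multifunctional gene sets of organisms A and B.
#' @return Integer count of pairs with both members multifunctional.
#' @export
count_mf_pairs <- function(pairs, mf_a, mf_b) {
  sum(pairs$a %in% mf_a & pairs$b %in% mf_b)
}

#' Permutation test for conservation of multifunctionality
#'
#' Tests whether ortholog pairs connect multifunctional genes of two
#' organisms more often than chance. In each of `n_trials` random
#' trials the multifunctional/other labels are independently
#' reshuffled over the ortholog-involved genes of each organism
#' (label counts preserved; every gene gets one label per trial;
#' orthology relationships untouched) and the both-multifunctional
#' pair count is recomputed. The empirical p-value is
#' (exceedances + 1) / (n_trials + 1).
#'
#' @param pairs data.frame with columns `a`, `b`.
#' @param mf_a,mf_b Multifunctional gene sets (subsets of the genes
#'   appearing in `pairs`; genes outside the pair list are ignored
#'   with a message).
#' @param n_trials Number of random trials (default 1000).
#' @param seed Integer seed.
#' @return Object of class `mf_permutation`: `observed`, `null_mean`,
#'   `null_sd`, `null` (trial counts), `p`, `ratio`
#'   (observed / null_mean), `n_trials`, `seed`.
#' @export
permutation_test <- function(pairs, mf_a, mf_b, n_trials = 1000, seed = 1) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  genes_a <- sort(unique(pairs$a))
  genes_b <- sort(unique(pairs$b))
  drop_a <- setdiff(mf_a, genes_a); drop_b <- setdiff(mf_b, genes_b)
  if (length(drop_a) > 0L || length(drop_b) > 0L)
    message("ignoring ", length(drop_a) + length(drop_b),
            " multifunctional gene(s) not involved in orthology")
  lab_a <- genes_a %in% mf_a
  lab_b <- genes_b %in% mf_b
  ia <- match(pairs$a, genes_a)
  ib <- match(pairs$b, genes_b)
  observed <- sum(lab_a[ia] & lab_b[ib])

  set.seed(seed)
  null <- vapply(seq_len(n_trials), function(i) {
    pa <- sample(lab_a)
    pb <- sample(lab_b)
    sum(pa[ia] & pb[ib])
  }, numeric(1))

  p <- (sum(null >= observed) + 1) / (n_trials + 1)
  structure(list(
    observed = observed,
    null_mean = mean(null), null_sd = stats::sd(null), null = null,
    p = p, ratio = observed / mean(null),
    n_trials = n_trials, seed = seed,
    n_pairs = nrow(pairs),
    n_mf_a = sum(lab_a), n_mf_b = sum(lab_b)
  ), class = "mf_permutation")
}

#' @export
print.mf_permutation <- function(x, ...) {
  cat("Conservation-of-multifunctionality permutation test\n")
  cat(sprintf("  %d ortholog pairs; %d / %d multifunctional genes per side\n",
              x$n_pairs, x$n_mf_a, x$n_mf_b))
  cat(sprintf("  observed both-multifunctional pairs: %d\n", x$observed))
  cat(sprintf("  random expectation: %.1f +/- %.1f (%d trials)\n",
              x$null_mean, x$null_sd, x$n_trials))
  cat(sprintf("  ratio = %.2g, empirical p %s\n", x$ratio,
              if (x$p <= 1 / (x$n_trials + 1))
                sprintf("< %.3g", 1 / x$n_trials) else sprintf("= %.3g", x$p)))
  invisible(x)
}
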