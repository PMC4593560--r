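# Group-comparison and bias-control statistics.

#' Mann-Whitney U comparison of two groups
#'
#' Rank-sum comparison reporting the U statistic (number of (a, b)
#' pairs with a ranked above b, counting ties as half), group means
#' and medians, and a two-sided p-value. The p-value is exact when
#' n1*n2 <= 400: via the exact U distribution when there are no
#' ties, or full enumeration of group labelings when there are ties
#' and the enumeration is small; otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param a,b Numeric samples (each non-empty).
#' @param method `"auto"` (default), `"exact"` or `"approx"`.
#' @return Object of class `mf_comparison`: list with `n1`, `n2`,
#'   `mean1`, `mean2`, `median1`, `median2`, `U`, `p`, `direction`
#'   (`"first"`, `"second"` or `"none"`, by the rank-sum), `method`.
#' @export
mann_whitney <- function(a, b, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  mu <- n1 * n2 / 2

  use_exact <- switch(method,
    auto = n1 * n2 <= 400,
    exact = TRUE,
    approx = FALSE)

  used <- "approx"
  p <- NA_real_
  if (use_exact && !ties) {
    p_less <- stats::pwilcox(U, n1, n2)
    p_greater <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(p_less, p_greater))
    used <- "exact"
  } else if (use_exact && ties && choose(n1 + n2, n1) <= 5e4) {
    # enumerate all labelings; two-sided by distance of U from its mean
    idx <- utils::combn(n1 + n2, n1)
    u_all <- apply(idx, 2L, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    used <- "exact"
  }
  if (is.na(p)) {
    n <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    used <- "approx"
  }

  structure(list(
    n1 = n1, n2 = n2,
    mean1 = mean(a), mean2 = mean(b),
    median1 = stats::median(a), median2 = stats::median(b),
    U = U, p = max(p, .Machine$double.xmin),
    direction = if (U > mu) "first" else if (U < mu) "second" else "none",
    method = used
  ), class = "mf_comparison")
}

#' @export
print.mf_comparison <- function(x, ...) {
  cat("Mann-Whitney U comparison (", x$method, ")\n", sep = "")
  cat(sprintf("  n = %d vs %d; medians %.4g vs %.4g; means %.4g vs %.4g\n",
              x$n1, x$n2, x$median1, x$median2, x$mean1, x$mean2))
  cat(sprintf("  U = %.1f, two-sided p = %.4g (larger: %s group)\n",
              x$U, x$p,
              switch(x$direction, first = "first", second = "second",
                     none = "neither")))
  invisible(x)
}

#' Hypergeometric enrichment of a gene set
#'
#' Upper-tail probability of observing at least `hits_in_set` hits
#' within a set of `set_size` genes, when `hits_total` of the
#' `background` genes are hits. Shares its implementation with
#' [coannotation_pvalue()].
#'
#' @param hits_in_set Hits inside the set.
#' @param set_size Set size.
#' @param hits_total Hits in the whole background.
#' @param background Background size.
#' @return A probability.
#' @export
enrichment <- function(hits_in_set, set_size, hits_total, background) {
  coannotation_pvalue(hits_in_set, set_size, hits_total, background)
}

#' Spearman and partial Spearman correlation
#'
#' `spearman_cor` is the rank correlation. `partial_spearman`
#' controls for a covariate by correlating the residuals of linear
#' rank regressions of `x` and `y` on `control`.
#'
#' @param x,y,control Numeric vectors of equal length (>= 3).
#' @return Correlation in [-1, 1].
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rank correlation undefined")
  stats::cor(rank(x), rank(y))
}

#' @rdname spearman_cor
#' @export
partial_spearman <- function(x, y, control) {
  stopifnot(length(x) == length(y), length(x) == length(control),
            length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(control) == 0)
    stop("constant vector: rank correlation undefined")
  rx <- rank(x); ry <- rank(y); rc <- rank(control)
  ex <- stats::residuals(stats::lm(rx ~ rc))
  ey <- stats::residuals(stats::lm(ry ~ rc))
  stats::cor(ex, ey)
}

#' Stratified Mann-Whitney comparison
#'
#' Compares the two groups within each stratum separately (e.g.
#' expression breadth within isoform-count classes). Strata where
#' either group has fewer than 2 members are reported as skipped.
#'
#' @param values Named numeric vector (per gene).
#' @param groups Named vector with two levels (per gene).
#' @param strata Named vector of stratum labels (per gene).
#' @return data.frame with one row per stratum: `stratum`, `n1`,
#'   `n2`, `median1`, `median2`, `U`, `p`, `skipped`.
#' @export
stratified_compare <- function(values, groups, strata) {
  genes <- intersect(intersect(names(values), names(groups)), names(strata))
  if (length(genes) == 0L) stop("no genes shared across inputs")
  g <- factor(groups[genes])
  if (nlevels(g) != 2L) stop("groups must have exactly two levels")
  lv <- levels(g)
  out <- lapply(sort(unique(as.character(strata[genes]))), function(s) {
    sel <- genes[strata[genes] == s]
    a <- values[sel[groups[sel] == lv[1L]]]
    b <- values[sel[groups[sel] == lv[2L]]]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(stratum = s, n1 = length(a), n2 = length(b),
                        median1 = NA_real_, median2 = NA_real_,
                        U = NA_real_, p = NA_real_, skipped = TRUE))
    cmp <- mann_whitney(a, b)
    data.frame(stratum = s, n1 = cmp$n1, n2 = cmp$n2,
               median1 = cmp$median1, median2 = cmp$median2,
               U = cmp$U, p = cmp$p, skipped = FALSE)
  })
  res <- do.call(rbind, out)
  if (all(res$skipped)) stop("no stratum with >= 2 genes per group")
  res
}

#' Covariate-matched resampling null
#'
#' Draws `n_trials` random samples of candidate genes matched to the
#' covariate distribution of the target genes (e.g. publication- or
#' degree-matched samples of non-multifunctional genes), and compares
#' the observed response statistic of the targets with the null
#' distribution of the same statistic over matched samples. Matching
#' uses exact covariate values when the target covariate takes few
#' distinct integer values, otherwise quantile bins of the target
#' distribution.
#'
#' @param target_genes,candidate_genes Character vectors of gene ids.
#' @param covariate Named numeric vector (matching variable).
#' @param response Named numeric vector (compared variable).
#' @param n_trials Number of random samples (default 1000).
#' @param seed Integer seed.
#' @param n_bins Number of quantile bins (default 10).
#' @param statistic `"median"`, `"mean"` or `"proportion"` (mean of a
#'   0/1 response).
#' @param alternative `"greater"` (default), `"less"` or
#'   `"two.sided"`.
#' @return Object of class `matched_null`: `observed`, `null`
#'   (numeric vector), `p` (empirical, (r+1)/(n+1)), `ci` (2.5%-97.5%
#'   of the null), `n_trials`, `seed`, `binning`.
#' @export
matched_resample <- function(target_genes, candidate_genes, covariate,
                             response, n_trials = 1000, seed = 1,
                             n_bins = 10,
                             statistic = c("median", "mean", "proportion"),
                             alternative = c("greater", "less", "two.sided")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  stopifnot(n_trials >= 1)
  stat_fun <- if (statistic == "median") stats::median else mean

  tc <- covariate[target_genes]
  cc <- covariate[candidate_genes]
  if (anyNA(tc) || anyNA(cc)) stop("covariate missing for some genes")

  small_int <- all(tc == round(tc)) && length(unique(tc)) <= n_bins
  if (small_int) {
    tbin <- as.character(tc)
    cbin <- as.character(cc)
    binning <- "exact integer values"
  } else {
    brk <- unique(stats::quantile(tc, probs = seq(0, 1, length.out = n_bins + 1)))
    brk[1L] <- -Inf; brk[length(brk)] <- Inf
    tbin <- as.character(cut(tc, brk))
    cbin <- as.character(cut(cc, brk))
    binning <- paste0(length(brk) - 1L, " target-quantile bins")
  }
  need <- table(tbin)
  cand_by_bin <- split(candidate_genes, cbin)
  unmatched <- setdiff(names(need), names(cand_by_bin))
  if (length(unmatched) > 0L)
    stop("no candidate genes in covariate bin(s): ",
         paste(unmatched, collapse = ", "))

  observed <- stat_fun(response[target_genes])
  set.seed(seed)
  null <- vapply(seq_len(n_trials), function(i) {
    samp <- unlist(lapply(names(need), function(bn) {
      pool <- cand_by_bin[[bn]]
      pool[sample.int(length(pool), need[[bn]], replace = TRUE)]
    }), use.names = FALSE)
    stat_fun(response[samp])
  }, numeric(1))

  r <- switch(alternative,
    greater = sum(null >= observed),
    less = sum(null <= observed),
    two.sided = 2 * min(sum(null >= observed), sum(null <= observed)))
  p <- min(1, (r + 1) / (n_trials + 1))

  structure(list(
    observed = observed, null = null, p = p,
    ci = stats::quantile(null, c(0.025, 0.975), names = FALSE),
    n_trials = n_trials, seed = seed, binning = binning,
    statistic = statistic, alternative = alternative
  ), class = "matched_null")
}

#' @export
print.matched_null <- function(x, ...) {
  cat("Covariate-matched resampling (", x$n_trials, " trials, ",
      x$binning, ")\n", sep = "")
  cat(sprintf("  observed %s = %.4g; null mean %.4g [95%% CI %.4g, %.4g]\n",
              x$statistic, x$observed, mean(x$null), x$ci[1L], x$ci[2L]))
  cat(sprintf("  empirical p (%s) = %.4g\n", x$alternative, x$p))
  invisible(x)
}

#' Bootstrap percentile confidence interval for the median
#'
#' @param sample Numeric vector (length >= 2).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Numeric length-2 vector (lower, upper).
#' @export
bootstrap_median_ci <- function(sample, n_boot = 1000, seed = 1, conf = 0.95) {
  stopifnot(length(sample) >= 2L, n_boot >= 1)
  set.seed(seed)
  meds <- vapply(seq_len(n_boot), function(i)
    stats::median(sample[sample.int(length(sample), replace = TRUE)]),
    numeric(1))
  alpha <- (1 - conf) / 2
  stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE)
}
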