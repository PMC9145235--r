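## Population-level descriptive statistics: fold variation, Spearman
## correlation with hierarchical trait clustering, and one-way ANOVA with
## Duncan's multiple range test.

#' Per-trait variation summary
#'
#' Median, minimum, maximum and fold change (max/min) per trait over
#' non-missing values. Traits whose minimum is not strictly positive get
#' an undefined (NA) fold and are flagged.
#'
#' @param table Data.frame of trait values (numeric columns only; rows =
#'   lines).
#' @return Data.frame with columns `trait`, `n`, `median`, `min`, `max`,
#'   `fold`, `fold_defined`.
#' @export
#' @examples
#' variation_summary(data.frame(IZ_A = c(64.688, 108.220, 214.114)))
variation_summary <- function(table) {
  stopifnot(is.data.frame(table))
  rows <- lapply(names(table), function(tr) {
    v <- table[[tr]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) stopf("trait %s has no non-missing values", tr)
    defined <- min(v) > 0
    data.frame(trait = tr, n = length(v), median = stats::median(v),
               min = min(v), max = max(v),
               fold = if (defined) max(v) / min(v) else NA_real_,
               fold_defined = defined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlation matrix with trait clustering
#'
#' Pairwise Spearman correlations (tie-corrected ranks, pairwise-complete
#' observations) with two-sided p-values from the t approximation, and
#' average-linkage hierarchical clustering of the traits on the distance
#' `1 - rho`, cut into `k` groups.
#'
#' @param table Data.frame of trait values (numeric columns).
#' @param k Number of trait groups to cut the dendrogram into.
#' @param alpha Significance level for the flag matrix.
#' @return List with `rho` (correlation matrix), `p` (p-value matrix),
#'   `significant` (logical matrix at `alpha`), `groups` (named integer
#'   vector of cluster memberships) and `hclust` (the tree).
#' @export
spearman_cluster <- function(table, k = 4L, alpha = 0.05) {
  stopifnot(is.data.frame(table))
  m <- as.matrix(table)
  if (k > ncol(m)) stopf("k (%d) exceeds the number of traits (%d)", k, ncol(m))
  if (sum(stats::complete.cases(m)) < 3)
    stopf("need at least 3 complete rows")
  rho <- stats::cor(m, method = "spearman", use = "pairwise.complete.obs")
  nobs <- crossprod(!is.na(m))
  tstat <- rho * sqrt(pmax(nobs - 2, 0) / pmax(1 - rho^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = pmax(nobs - 2, 1))
  diag(p) <- 0
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "average")
  groups <- stats::cutree(hc, k = k)
  list(rho = rho, p = p, significant = p <= alpha, groups = groups,
       hclust = hc)
}

## Duncan critical range for a span of p means: studentized-range quantile
## at protection level 1 - (1-alpha)^(p-1), times the standard error of a
## mean.
duncan_critical_range <- function(p_span, df, mse, n_harm, alpha) {
  alpha_p <- 1 - (1 - alpha)^(p_span - 1)
  stats::qtukey(1 - alpha_p, p_span, df) * sqrt(mse / n_harm)
}

#' One-way ANOVA with Duncan's multiple range test
#'
#' Fixed-effects one-way ANOVA followed by Duncan's multiple range test:
#' means sorted descending, a range of `p` means declared non-significant
#' when its extreme difference is at most the studentized-range critical
#' value at protection level `1 - (1-alpha)^(p-1)`, letters assigned to
#' the maximal non-significant stretches (so letter groups are always
#' contiguous). Unequal group sizes use the harmonic mean of the sizes in
#' the standard error.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor or character vector of subgroup labels.
#' @param alpha Significance level.
#' @return A `duncan_result`: data.frame `groups` (subgroup, n, mean,
#'   letters), `F`, `p`, `df_resid`, `mse`, `alpha`.
#' @export
#' @examples
#' set.seed(1)
#' anova_duncan(c(rnorm(10), rnorm(10, 5)), rep(c("a", "b"), each = 10))
anova_duncan <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(as.character(groups))
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  ng <- nlevels(groups)
  if (ng < 2) stopf("need >= 2 subgroups")
  nn <- tabulate(groups)
  if (any(nn < 2)) stopf("every subgroup needs >= 2 observations")
  fit <- stats::aov(values ~ groups)
  an <- stats::anova(fit)
  Fst <- an[["F value"]][1]; pval <- an[["Pr(>F)"]][1]
  mse <- an[["Mean Sq"]][2]; dfr <- an[["Df"]][2]
  if (mse <= 0) stopf("zero residual variance: Duncan's test undefined")
  means <- tapply(values, groups, mean)
  ord <- order(means, decreasing = TRUE)
  ms <- means[ord]; ns <- nn[ord]
  n_harm <- ng / sum(1 / nn)
  ## maximal non-significant stretches over the sorted means
  stretches <- list()
  for (i in seq_len(ng)) {
    j <- i
    while (j < ng) {
      span <- j + 1 - i + 1
      crit <- duncan_critical_range(span, dfr, mse, n_harm, alpha)
      if (ms[i] - ms[j + 1] <= crit) j <- j + 1 else break
    }
    stretches[[i]] <- c(i, j)
  }
  ## drop stretches contained in an earlier one
  keep <- rep(TRUE, ng)
  for (i in seq_len(ng)) {
    for (h in seq_len(i - 1)) {
      if (keep[h] && stretches[[h]][1] <= stretches[[i]][1] &&
          stretches[[i]][2] <= stretches[[h]][2]) keep[i] <- FALSE
    }
  }
  lett <- rep("", ng)
  li <- 0L
  for (i in which(keep)) {
    li <- li + 1L
    rng <- stretches[[i]][1]:stretches[[i]][2]
    lett[rng] <- paste0(lett[rng], letters[li])
  }
  gtab <- data.frame(subgroup = names(ms), n = ns, mean = as.numeric(ms),
                     letters = lett, stringsAsFactors = FALSE)
  rownames(gtab) <- NULL
  structure(list(groups = gtab, F = Fst, p = pval, df_resid = dfr,
                 mse = mse, alpha = alpha),
            class = "duncan_result")
}

#' @export
print.duncan_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.3g (alpha = %g)\n",
              x$F, x$p, x$alpha))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
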