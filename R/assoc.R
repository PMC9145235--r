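## Marker QC, two-method genome-wide association, hit intersection,
## SNP-to-gene annotation, shared-gene summaries and hypergeometric
## enrichment. The association procedure mirrors the multi-method design:
## every method is thresholded separately and only the intersection of
## hits is retained.

#' Per-SNP minor-allele frequency and call rate
#'
#' MAF is computed over non-missing alleles; call rate is the non-missing
#' fraction of lines.
#'
#' @param G A `genotype_matrix` (see [generate_genotypes()]) or a dosage
#'   matrix (lines x SNPs, values 0/1/2/NA).
#' @return Data.frame with columns `id`, `maf`, `call_rate`.
#' @export
marker_stats <- function(G) {
  dos <- if (inherits(G, "genotype_matrix")) G$dosage else G
  nn <- colSums(!is.na(dos))
  f <- colSums(dos, na.rm = TRUE) / (2 * pmax(nn, 1))
  maf <- pmin(f, 1 - f)
  maf[nn == 0] <- NA_real_
  data.frame(id = colnames(dos), maf = maf,
             call_rate = nn / nrow(dos), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Filter markers on MAF and call rate
#'
#' Retains SNPs with call rate >= `callrate_min` and MAF >= `maf_min`
#' (both boundaries inclusive, matching removal of MAF < 0.05 and call
#' rate < 0.9). Removing every SNP yields a warning and an empty matrix,
#' not an error.
#'
#' @param G A `genotype_matrix`.
#' @param maf_min Minimum minor-allele frequency.
#' @param callrate_min Minimum call rate.
#' @return The filtered `genotype_matrix`.
#' @export
filter_markers <- function(G, maf_min = 0.05, callrate_min = 0.9) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (ncol(G$dosage) == 0L) stopf("empty genotype matrix")
  st <- marker_stats(G)
  keep <- !is.na(st$maf) & st$maf >= maf_min & st$call_rate >= callrate_min
  if (!any(keep)) warning("all SNPs removed by MAF/call-rate filtering")
  G$dosage <- G$dosage[, keep, drop = FALSE]
  G$snps <- G$snps[keep, , drop = FALSE]
  rownames(G$snps) <- NULL
  G
}

#' Genome-wide significance threshold
#'
#' The reciprocal-SNP-count threshold `p <= 1/N`.
#'
#' @param N Number of tested SNPs (>= 1).
#' @return The p-value cutoff `1/N`.
#' @export
#' @examples
#' signif(genomewide_threshold(797058), 3)  # 1.25e-06
genomewide_threshold <- function(N) {
  if (length(N) != 1L || is.na(N) || N < 1) stopf("N must be >= 1")
  1 / N
}

#' Genome-wide association scan
#'
#' Per-SNP single-marker regression of the trait on dosage. `"marginal"`
#' is a simple linear regression Wald test; `"pc_adjusted"` adds the top
#' `k` genotype principal components as covariates to absorb population
#' structure. Missing dosages are mean-imputed per SNP for testing only.
#' SNPs monomorphic after imputation get `p = 1` and are flagged.
#'
#' @param G A `genotype_matrix`.
#' @param y Trait vector, aligned with (or named by) the lines of `G`.
#' @param method `"marginal"` or `"pc_adjusted"`.
#' @param k Number of principal components for `"pc_adjusted"`.
#' @return Data.frame with columns `id`, `beta`, `p`, `monomorphic`, and
#'   attribute `method`.
#' @export
assoc_scan <- function(G, y, method = c("marginal", "pc_adjusted"),
                       k = 3L) {
  stopifnot(inherits(G, "genotype_matrix"))
  method <- match.arg(method)
  dos <- G$dosage
  if (!is.null(names(y))) {
    if (!all(G$lines %in% names(y)))
      stopf("y is missing values for some lines")
    y <- y[G$lines]
  }
  if (length(y) != nrow(dos)) stopf("y length does not match line count")
  n <- nrow(dos); m <- ncol(dos)
  ## per-SNP mean imputation (testing only)
  cm <- colMeans(dos, na.rm = TRUE)
  X <- dos
  miss <- which(is.na(X))
  if (length(miss)) X[miss] <- cm[((miss - 1L) %/% n) + 1L]
  covar <- matrix(1, n, 1)
  if (method == "pc_adjusted") {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    pc <- stats::prcomp(Xc, center = FALSE, rank. = k)
    covar <- cbind(covar, pc$x[, seq_len(min(k, ncol(pc$x))), drop = FALSE])
  }
  q <- qr(covar)
  yr <- qr.resid(q, y)
  Xr <- qr.resid(q, X)
  sx2 <- colSums(Xr^2)
  mono <- sx2 < 1e-12
  df <- n - ncol(covar) - 1L
  beta <- rep(NA_real_, m); pval <- rep(1, m)
  ok <- !mono
  sxy <- colSums(Xr[, ok, drop = FALSE] * yr)
  b <- sxy / sx2[ok]
  rss <- sum(yr^2) - b * sxy
  rss <- pmax(rss, 0)
  se2 <- rss / df / sx2[ok]
  tstat <- ifelse(se2 > 0, b / sqrt(se2), Inf)
  pv <- 2 * stats::pt(-abs(tstat), df)
  beta[ok] <- b
  pval[ok] <- pmax(pv, .Machine$double.xmin)
  out <- data.frame(id = colnames(dos), beta = beta, p = pval,
                    monomorphic = mono, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "method") <- method
  out
}

#' Hit set at a p-value threshold
#'
#' @param scan An [assoc_scan()] result.
#' @param threshold P-value cutoff (e.g. [genomewide_threshold()]).
#' @return A `hit_set`: list with `method`, `snps` (ids with
#'   `p <= threshold`), `threshold`.
#' @export
hit_set <- function(scan, threshold) {
  structure(list(method = attr(scan, "method"),
                 snps = scan$id[scan$p <= threshold],
                 threshold = threshold),
            class = "hit_set")
}

#' Intersection of hit sets across methods
#'
#' The consensus set of SNPs significant in every method — the
#' reliability filter of a multi-method association workflow. Empty
#' results are allowed.
#'
#' @param hitsets List of `hit_set` objects (or plain character vectors).
#' @return Character vector of consensus SNP ids.
#' @export
intersect_hits <- function(hitsets) {
  if (length(hitsets) == 0L) stopf("need at least one hit set")
  sets <- lapply(hitsets, function(h)
    if (inherits(h, "hit_set")) h$snps else as.character(h))
  sort(Reduce(intersect, sets))
}

#' Annotate SNPs with overlapping genes
#'
#' A gene is assigned to a SNP when the SNP position lies in
#' `[start - flank, end + flank]` on the same chromosome (1-based,
#' inclusive at both ends). SNPs on chromosomes absent from the
#' annotation are skipped with a warning.
#'
#' @param snps Data.frame with columns `id`, `chrom`, `pos`.
#' @param genes Data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param flank Symmetric flank in bp (default 0: SNP-in-gene).
#' @return Data.frame with columns `snp_id`, `gene_id`, one row per
#'   assignment.
#' @export
annotate_genes <- function(snps, genes, flank = 0) {
  stopifnot(all(c("id", "chrom", "pos") %in% names(snps)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$start > genes$end)) stopf("gene intervals must have start <= end")
  unknown <- !(snps$chrom %in% unique(genes$chrom))
  if (any(unknown)) {
    warning(sprintf("skipping %d SNP(s) on chromosomes absent from the annotation",
                    sum(unknown)))
    snps <- snps[!unknown, , drop = FALSE]
  }
  if (nrow(snps) == 0L)
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  gr_snp <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  gr_gene <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$start - flank), genes$end + flank))
  ov <- GenomicRanges::findOverlaps(gr_snp, gr_gene)
  out <- data.frame(snp_id = snps$id[S4Vectors::queryHits(ov)],
                    gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Unique and shared genes across traits
#'
#' From a trait-to-gene mapping, counts genes associated with exactly one
#' trait (unique) and with two or more traits (shared), and exports the
#' bipartite trait-gene network as an edge table.
#'
#' @param mapping Data.frame with columns `trait` and `gene_id`, or a
#'   named list of per-trait gene-id vectors.
#' @return List with `per_trait` (trait, n_genes, n_unique, n_shared),
#'   `n_unique`, `n_shared`, `gene_degree` (named integer vector) and
#'   `edges` (unique trait-gene pairs).
#' @export
shared_gene_summary <- function(mapping) {
  if (is.list(mapping) && !is.data.frame(mapping)) {
    mapping <- do.call(rbind, lapply(names(mapping), function(tr)
      if (length(mapping[[tr]]))
        data.frame(trait = tr, gene_id = unique(mapping[[tr]]),
                   stringsAsFactors = FALSE)))
  }
  if (is.null(mapping) || nrow(mapping) == 0L) stopf("empty mapping")
  edges <- unique(mapping[, c("trait", "gene_id")])
  deg <- table(edges$gene_id)
  uniq_genes <- names(deg)[deg == 1]
  shared_genes <- names(deg)[deg >= 2]
  per_trait <- do.call(rbind, lapply(split(edges, edges$trait), function(e)
    data.frame(trait = e$trait[1], n_genes = nrow(e),
               n_unique = sum(e$gene_id %in% uniq_genes),
               n_shared = sum(e$gene_id %in% shared_genes),
               stringsAsFactors = FALSE)))
  rownames(per_trait) <- NULL
  list(per_trait = per_trait, n_unique = length(uniq_genes),
       n_shared = length(shared_genes),
       gene_degree = stats::setNames(as.integer(deg), names(deg)),
       edges = edges)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric p-value for the overlap between a selected
#' gene set and each term's gene set within a finite universe:
#' `P(overlap >= observed)`.
#'
#' @param selected Character vector of selected genes (subset of
#'   `universe`).
#' @param terms Named list of term gene sets (each a subset of
#'   `universe`).
#' @param universe Character vector: the gene universe.
#' @return Data.frame with columns `term`, `overlap`, `term_size`,
#'   `selected_size`, `universe_size`, `p`.
#' @export
hypergeom_enrichment <- function(selected, terms, universe) {
  if (length(universe) == 0L) stopf("empty universe")
  universe <- unique(universe)
  selected <- unique(selected)
  if (!all(selected %in% universe))
    stopf("selected genes must be a subset of the universe")
  N <- length(universe); n <- length(selected)
  rows <- lapply(names(terms), function(tm) {
    tg <- unique(intersect(terms[[tm]], universe))
    K <- length(tg)
    k <- length(intersect(selected, tg))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, term_size = K,
               selected_size = n, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
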