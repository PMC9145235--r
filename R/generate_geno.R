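#' Simulate a genotype matrix with planted QTL
#'
#' Dosages are drawn per SNP under Hardy-Weinberg proportions at an allele
#' frequency sampled from `maf_range`; columns whose realized minor-allele
#' frequency falls outside `maf_range` are redrawn, so every SNP respects
#' the range before missingness is applied. The phenotype is the sum of
#' QTL effects times (complete) dosage plus Gaussian noise scaled so the
#' planted QTL jointly explain `h2_marker` of the phenotypic variance.
#'
#' @param spec A [geno_sim_spec()].
#' @param seed Integer seed.
#' @return A list with `geno` (class `genotype_matrix`: `dosage` matrix
#'   lines x SNPs with NA for missing, `snps` metadata data.frame, `lines`
#'   ids), `phenotype` (numeric, one value per line) and `truth` (QTL
#'   table, complete dosage of QTL columns, realized h2).
#' @export
#' @examples
#' g <- generate_genotypes(geno_sim_spec(n_lines = 50, m_snps = 100), seed = 1)
#' dim(g$geno$dosage)
generate_genotypes <- function(spec, seed) {
  stopifnot(inherits(spec, "geno_sim_spec"))
  n <- spec$n_lines; m <- spec$m_snps
  withr::with_seed(seed, {
    ## draw all SNP columns at once; redraw the few whose realized MAF
    ## falls outside the requested range
    draw <- function(k) {
      p <- stats::runif(k, spec$maf_range[1], spec$maf_range[2])
      matrix(stats::rbinom(n * k, 2L, rep(p, each = n)), n, k)
    }
    dos <- draw(m)
    for (att in 1:100) {
      f <- colMeans(dos) / 2
      maf <- pmin(f, 1 - f)
      bad <- which(maf < spec$maf_range[1] | maf > spec$maf_range[2])
      if (length(bad) == 0L) break
      if (att == 100)
        stopf("could not realize MAF in range for SNP %d", bad[1])
      dos[, bad] <- draw(length(bad))
    }
    complete <- dos
    ## phenotype from complete dosages
    if (!is.null(spec$qtl) && nrow(spec$qtl) > 0 && spec$h2_marker > 0) {
      gval <- as.numeric(complete[, spec$qtl$snp, drop = FALSE] %*%
                           spec$qtl$effect)
      vg <- stats::var(gval)
      ve <- vg * (1 - spec$h2_marker) / spec$h2_marker
      y <- gval + stats::rnorm(n, 0, sqrt(ve))
    } else {
      gval <- rep(0, n)
      y <- stats::rnorm(n, 0, 1)
    }
    if (spec$missing_rate > 0) {
      miss <- stats::runif(n * m) < spec$missing_rate
      dos[miss] <- NA_integer_
    }
  })
  chrom <- rep(seq_len(spec$n_chrom), length.out = m)
  pos <- integer(m)
  for (cc in seq_len(spec$n_chrom)) {
    k <- sum(chrom == cc)
    pos[chrom == cc] <- seq_len(k) * 1000L
  }
  snps <- data.frame(id = sprintf("snp%05d", seq_len(m)),
                     chrom = sprintf("chr%d", chrom), pos = pos,
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  lines <- sprintf("L%03d", seq_len(n))
  dimnames(dos) <- list(lines, snps$id)
  geno <- structure(list(dosage = dos, snps = snps, lines = lines),
                    class = "genotype_matrix")
  r2 <- if (stats::var(gval) > 0) stats::cor(gval, y)^2 else 0
  truth <- list(qtl = spec$qtl, qtl_dosage = if (!is.null(spec$qtl))
    complete[, spec$qtl$snp, drop = FALSE] else NULL,
    realized_h2 = r2, seed = seed)
  list(geno = geno, phenotype = stats::setNames(y, lines), truth = truth)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d lines x %d SNPs (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}
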