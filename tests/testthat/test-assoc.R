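# Marker QC, association scans, hit intersection, gene annotation and
# enrichment.

toy_geno <- function(dosage, chrom = "chr1", pos = NULL) {
  m <- ncol(dosage); n <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  ids <- sprintf("s%03d", seq_len(m))
  colnames(dosage) <- ids
  rownames(dosage) <- sprintf("L%03d", seq_len(n))
  structure(list(dosage = dosage,
                 snps = data.frame(id = ids, chrom = chrom, pos = pos,
                                   ref = "A", alt = "T",
                                   stringsAsFactors = FALSE),
                 lines = rownames(dosage)),
            class = "genotype_matrix")
}

test_that("MAF/call-rate filtering follows its definitions", {
  # call rate 0.8 < 0.9: removed
  g1 <- toy_geno(cbind(c(0, 0, 1, 2, NA)))
  expect_warning(f1 <- filter_markers(g1), "all SNPs removed")
  expect_equal(ncol(f1$dosage), 0)
  # MAF 1/8 with full call rate: retained
  g2 <- toy_geno(cbind(c(0, 0, 0, 1)))
  f2 <- filter_markers(g2)
  expect_equal(ncol(f2$dosage), 1)
  st <- marker_stats(g2)
  expect_equal(st$maf, 0.125)
  expect_equal(st$call_rate, 1.0)
})

test_that("filtering matches a per-column oracle and is idempotent", {
  set.seed(31)
  dos <- matrix(rbinom(20 * 50, 2, runif(50, 0.02, 0.5)[rep(1:50, each = 20)]),
                20, 50)
  dos[sample(length(dos), 120)] <- NA
  G <- toy_geno(dos)
  f <- filter_markers(G)
  keep_oracle <- vapply(seq_len(50), function(j) {
    col <- dos[, j]
    nn <- sum(!is.na(col))
    if (nn / 20 < 0.9) return(FALSE)
    fr <- sum(col, na.rm = TRUE) / (2 * nn)
    min(fr, 1 - fr) >= 0.05
  }, TRUE)
  expect_equal(f$snps$id, G$snps$id[keep_oracle])
  f2 <- filter_markers(f)
  expect_identical(f2$dosage, f$dosage)
})

test_that("the genome-wide threshold is the reciprocal SNP count", {
  expect_equal(signif(genomewide_threshold(797058), 3), 1.25e-6)
  expect_equal(genomewide_threshold(1), 1.0)
  expect_equal(genomewide_threshold(1e6), 1e-6)
  expect_error(genomewide_threshold(0), "N must be")
})

test_that("null scans are calibrated and monomorphic SNPs are flagged", {
  # tests that share one permuted response are positively correlated, so
  # the empirical rate is averaged over independent permutations before
  # the binomial check
  g <- generate_genotypes(geno_sim_spec(n_lines = 202, m_snps = 10000),
                          seed = 1)
  rates <- sapply(1:5, function(k) {
    y <- withr::with_seed(k, sample(unname(g$phenotype)))
    mean(assoc_scan(g$geno, y)$p <= 0.01)
  })
  rate <- mean(rates)
  ci <- 0.01 + c(-1, 1) * 1.96 * sqrt(0.01 * 0.99 / (5 * 10000))
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])

  # monomorphic SNP: p = 1 by convention
  dos <- cbind(rep(1L, 30), rbinom(30, 2, 0.4))
  G <- toy_geno(dos)
  sc2 <- assoc_scan(G, rnorm(30))
  expect_true(sc2$monomorphic[1])
  expect_equal(sc2$p[1], 1)
  expect_false(sc2$monomorphic[2])

  # joint reordering of lines leaves p-values unchanged
  g3 <- generate_genotypes(geno_sim_spec(n_lines = 60, m_snps = 40),
                           seed = 2)
  y3 <- g3$phenotype
  perm <- withr::with_seed(2, sample(60))
  G3p <- g3$geno
  G3p$dosage <- G3p$dosage[perm, ]
  G3p$lines <- g3$geno$lines[perm]
  expect_equal(assoc_scan(g3$geno, y3)$p, assoc_scan(G3p, y3[perm])$p,
               tolerance = 1e-12)
})

test_that("planted QTL are detected by both methods", {
  hits <- sapply(1:25, function(s) {
    gs <- generate_genotypes(geno_sim_spec(
      n_lines = 202, m_snps = 500,
      qtl = data.frame(snp = 250, effect = 1), h2_marker = 0.2),
      seed = 700 + s)
    thr <- genomewide_threshold(500)
    c(assoc_scan(gs$geno, gs$phenotype)$p[250] <= thr,
      assoc_scan(gs$geno, gs$phenotype, method = "pc_adjusted")$p[250] <= thr)
  })
  expect_gte(mean(hits[1, ]), 0.8)
  expect_gte(mean(hits[2, ]), 0.8)
})

test_that("PC adjustment deflates stratification-driven null signal", {
  set.seed(33)
  n <- 200; m <- 1000
  pop <- rep(0:1, each = n / 2)
  p1 <- runif(m, 0.1, 0.5)
  p2 <- pmin(0.95, pmax(0.02, p1 + rnorm(m, 0, 0.15)))
  dos <- sapply(seq_len(m), function(j)
    rbinom(n, 2, ifelse(pop == 1, p2[j], p1[j])))
  G <- toy_geno(dos)
  y <- 2 * pop + rnorm(n)
  pm <- assoc_scan(G, y)$p
  pa <- assoc_scan(G, y, method = "pc_adjusted")$p
  expect_lt(median(-log10(pa)), median(-log10(pm)))
  expect_lt(median(-log10(pa)), 0.5)  # near the null median after adjustment
})

test_that("hit intersection is a commutative, shrinking set operation", {
  a <- structure(list(method = "m1", snps = c("a", "b"), threshold = 0.01),
                 class = "hit_set")
  b <- structure(list(method = "m2", snps = c("b", "c"), threshold = 0.01),
                 class = "hit_set")
  expect_equal(intersect_hits(list(a, b)), "b")
  expect_equal(intersect_hits(list(a, a)), sort(a$snps))
  expect_equal(intersect_hits(list(a, list(method = "x", snps = "z",
                                           threshold = 1) |>
                                     structure(class = "hit_set"))),
               character(0))
  expect_equal(intersect_hits(list(a, b)), intersect_hits(list(b, a)))
  cons <- intersect_hits(list(a, b))
  expect_true(all(cons %in% a$snps) && all(cons %in% b$snps))
})

test_that("gene annotation is boundary-inclusive and matches the oracle", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(100, 300), end = c(200, 400),
                      strand = "+")
  snps <- data.frame(id = c("s1", "s2", "s3"), chrom = "chr1",
                     pos = c(100, 250, 400))
  ann <- annotate_genes(snps, genes)
  expect_equal(ann$gene_id[ann$snp_id == "s1"], "g1")  # start boundary
  expect_false("s2" %in% ann$snp_id)                   # between genes
  expect_equal(ann$gene_id[ann$snp_id == "s3"], "g2")  # end boundary

  # randomized toy genome vs all-pairs containment oracle
  set.seed(34)
  genes2 <- data.frame(gene_id = sprintf("g%02d", 1:20),
                       chrom = sample(c("chr1", "chr2"), 20, TRUE),
                       start = sample.int(10000, 20))
  genes2$end <- genes2$start + sample.int(500, 20)
  snps2 <- data.frame(id = sprintf("s%03d", 1:200),
                      chrom = sample(c("chr1", "chr2"), 200, TRUE),
                      pos = sample.int(11000, 200))
  for (flank in c(0, 50)) {
    ann2 <- annotate_genes(snps2, genes2, flank = flank)
    oracle <- do.call(rbind, lapply(seq_len(200), function(i) {
      hit <- genes2$chrom == snps2$chrom[i] &
        snps2$pos[i] >= genes2$start - flank &
        snps2$pos[i] <= genes2$end + flank
      if (any(hit)) data.frame(snp_id = snps2$id[i],
                               gene_id = genes2$gene_id[hit])
    }))
    key <- function(d) sort(paste(d$snp_id, d$gene_id))
    expect_equal(key(ann2), key(oracle))
  }
  # flank monotonicity: smaller flank mapping nested in the larger
  a0 <- annotate_genes(snps2, genes2, flank = 0)
  a100 <- annotate_genes(snps2, genes2, flank = 100)
  expect_true(all(paste(a0$snp_id, a0$gene_id) %in%
                    paste(a100$snp_id, a100$gene_id)))

  # unknown chromosome: warned and skipped
  snps3 <- data.frame(id = "sX", chrom = "chrZ", pos = 1)
  expect_warning(annX <- annotate_genes(snps3, genes), "absent")
  expect_equal(nrow(annX), 0)
})

test_that("shared-gene summaries partition genes by degree", {
  s <- shared_gene_summary(list(T1 = c("g1", "g2"), T2 = "g2"))
  expect_equal(s$n_unique, 1)
  expect_equal(s$n_shared, 1)
  expect_equal(unname(s$gene_degree["g2"]), 2L)

  one <- shared_gene_summary(list(T1 = c("g1", "g2", "g3")))
  expect_equal(one$n_unique, 3)
  expect_equal(one$n_shared, 0)

  set.seed(35)
  mp <- data.frame(trait = sample(LETTERS[1:5], 60, TRUE),
                   gene_id = sample(sprintf("g%02d", 1:25), 60, TRUE))
  sm <- shared_gene_summary(mp)
  expect_equal(sm$n_unique + sm$n_shared,
               length(unique(mp$gene_id)))
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  u <- letters[1:10]
  e1 <- hypergeom_enrichment(letters[1:5], list(all = u), u)
  expect_equal(e1$p, 1)
  e2 <- hypergeom_enrichment(letters[1:5], list(disj = letters[6:9]), u)
  expect_equal(e2$p, 1)  # overlap 0: upper tail mass at 0 is 1
  # universe 10, term 4, selected 5, overlap 4: exact enumeration
  e3 <- hypergeom_enrichment(letters[1:5], list(t = letters[1:4]), u)
  cnt <- sum(combn(10, 5, function(ix) sum(ix <= 4) >= 4))
  expect_equal(e3$p, cnt / choose(10, 5), tolerance = 1e-12)
  expect_error(hypergeom_enrichment("a", list(t = "a"), character(0)),
               "empty universe")
  expect_error(hypergeom_enrichment("zz", list(t = "a"), u), "subset")
})
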