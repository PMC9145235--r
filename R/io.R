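## File interfaces: 8-bit PNG images, ground-truth JSON, trait CSV with a
## units sidecar, dosage TSV, minimal VCF (unphased GT) and GFF3 gene
## annotation.

#' Write a section image as 8-bit grayscale PNG
#'
#' @param image A [section_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_section_png <- function(image, path) {
  stopifnot(inherits(image, "section_image"))
  ## PNG rows = y, columns = x: transpose from the [x, y] matrix
  png::writePNG(t(image$pixels) / 255, path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG as a section image
#'
#' @param path PNG file path.
#' @param resolution Pixel size, micrometres per pixel.
#' @return A [section_image()].
#' @export
read_section_png <- function(path, resolution) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  section_image(t(matrix(as.integer(round(a * 255)), nrow(a), ncol(a))),
                resolution)
}

#' Write synthetic ground truth as JSON
#'
#' Stores the per-bundle records, planted zone boundary depths, section
#' area and seed (the raster mask itself is not serialized; regenerate it
#' from the seed when needed).
#'
#' @param truth A `section_truth` (see [generate_cross_section()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "section_truth"))
  obj <- list(bundles = truth$bundles,
              ez_depth_mm = truth$ez_depth_mm,
              pz_depth_mm = truth$pz_depth_mm,
              section_area_px = truth$section_area_px,
              resolution = truth$resolution,
              seed = truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read synthetic ground truth from JSON
#' @param path JSON file path.
#' @return List mirroring [write_ground_truth_json()]'s fields.
#' @export
read_ground_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a trait table as CSV with a units sidecar
#'
#' One row per section, 36 columns named by the registry abbreviations;
#' the sidecar JSON (same path with extension `.schema.json`) records the
#' category, unit and description of every column.
#'
#' @param traits Data.frame or matrix of trait rows (columns named as in
#'   [trait_names()]); an `id` column is allowed and preserved.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  df <- as.data.frame(traits)
  utils::write.csv(df, path, row.names = FALSE)
  schema <- trait_registry()
  jsonlite::write_json(schema, sub("\\.csv$", ".schema.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a bundle region table as CSV
#'
#' Columns `id`, `centroid_x_px`, `centroid_y_px`, `area_px`, `zone`;
#' centroid coordinates are 0-based continuous pixel positions.
#'
#' @param bundles A `bundle_set`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(bundles, path) {
  stopifnot(inherits(bundles, "bundle_set"))
  r <- bundles$regions
  utils::write.csv(data.frame(id = r$id,
                              centroid_x_px = r$x_px,
                              centroid_y_px = r$y_px,
                              area_px = r$area_px, zone = r$zone),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write/read a dosage matrix as TSV
#'
#' Dialect: rows = lines, columns = SNPs, header row of SNP ids, first
#' column `line`, missing as `NA`.
#'
#' @param G A `genotype_matrix`.
#' @param path TSV path.
#' @return `path` (write) / a `genotype_matrix` without SNP coordinates
#'   (read).
#' @export
write_dosage_tsv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  df <- data.frame(line = G$lines, G$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  lines <- df[[1]]
  dos <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(dos) <- "integer"
  rownames(dos) <- lines
  snps <- data.frame(id = colnames(dos), chrom = NA_character_,
                     pos = NA_integer_, ref = NA_character_,
                     alt = NA_character_, stringsAsFactors = FALSE)
  structure(list(dosage = dos, snps = snps, lines = lines),
            class = "genotype_matrix")
}

#' Write a genotype matrix as minimal VCF
#'
#' VCFv4.2, GT-only FORMAT, unphased genotypes (`0/0`, `0/1`, `1/1`),
#' missing as `./.`.
#'
#' @param G A `genotype_matrix` with SNP coordinates.
#' @param path VCF output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", G$lines),
                     collapse = "\t")), con)
  m <- ncol(G$dosage)
  for (j in seq_len(m)) {
    d <- G$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_codes[d + 1L])
    writeLines(paste(c(G$snps$chrom[j], G$snps$pos[j], G$snps$id[j],
                       G$snps$ref[j], G$snps$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Uses the GT field only; unphased or phased separators are accepted and
#' `./.` is missing.
#'
#' @param path VCF file path.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", ".|.", "."), NA_integer_,
           vapply(strsplit(x, "[/|]"), function(a)
             sum(as.integer(a)), 0L))
  }
  dos <- t(apply(gt, 1, count_alt))
  if (ncol(v@gt) == 2L) dos <- matrix(dos, ncol = 1,
                                      dimnames = list(rownames(gt), NULL))
  dos <- t(dos)  # lines x SNPs
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snps <- data.frame(id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF,
                     alt = fix$ALT, stringsAsFactors = FALSE)
  colnames(dos) <- snps$id
  structure(list(dosage = dos, snps = snps, lines = rownames(dos)),
            class = "genotype_matrix")
}

#' Read gene features from GFF3
#'
#' @param path GFF3 file path.
#' @param feature_type Feature type to keep (default `"gene"`).
#' @return Data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @export
read_gene_gff3 <- function(path, feature_type = "gene") {
  g <- rtracklayer::import(path, format = "gff3")
  g <- g[g$type == feature_type]
  ids <- if (!is.null(g$ID)) g$ID else g$Name
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g),
             end = GenomicRanges::end(g),
             strand = as.character(GenomicRanges::strand(g)),
             stringsAsFactors = FALSE)
}

#' Write gene features as GFF3
#'
#' @param genes Data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end` and optionally `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, path) {
  strand <- if ("strand" %in% names(genes)) genes$strand else "+"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(paste(genes$chrom, "shankvb", "gene", genes$start, genes$end,
                   ".", strand, ".", paste0("ID=", genes$gene_id),
                   sep = "\t"), con)
  invisible(path)
}
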