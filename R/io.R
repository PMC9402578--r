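# File readers/writers for the formats the pipeline consumes and emits.
# Established parsers are used where they exist (VariantAnnotation for VCF,
# rtracklayer for BED); matrices and the small tabular formats go through
# data.table.

#' Read a VCF into a genotype dosage matrix
#'
#' Biallelic records only; the GT field is converted to an alt-allele dosage
#' in \{0, 1, 2\}. Missing genotypes are mean-imputed per variant (with a
#' message reporting how many). Empirical MAF is recomputed from the
#' observed dosages.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return A `GenotypeMatrix`: list with `variants` (a `data.table`:
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `maf`) and `dosages`
#'   (numeric matrix, samples x variants).
#' @export
read_vcf_dosages <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(rr$ALT))
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  counts <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
              "1|0" = 1, "1/1" = 2, "1|1" = 2)
  for (j in seq_len(nrow(gt))) dos[, j] <- unname(counts[gt[j, ]])
  n_missing <- sum(is.na(dos))
  if (n_missing > 0L) {
    message("mean-imputing ", n_missing, " missing genotype(s)")
    for (j in seq_len(ncol(dos))) {
      nas <- is.na(dos[, j])
      if (any(nas)) dos[nas, j] <- mean(dos[!nas, j])
    }
  }
  af <- colMeans(dos) / 2
  variants <- data.table(
    variant_id = rownames(gt),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = alt,
    maf = pmin(af, 1 - af)
  )
  new_genotype_matrix(variants, dos)
}

new_genotype_matrix <- function(variants, dosages) {
  stopifnot(ncol(dosages) == nrow(variants))
  colnames(dosages) <- variants$variant_id
  structure(list(variants = variants, dosages = dosages),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", nrow(x$dosages), "samples x",
      nrow(x$variants), "variants\n")
  invisible(x)
}

#' Write a genotype matrix as a minimal VCF (GT field only)
#'
#' @param genotypes a `GenotypeMatrix` (dosages must be integral).
#' @param path output path.
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  d <- genotypes$dosages
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j], v$alt[j],
            ".", "PASS", ".", "GT", gt_codes[round(d[, j]) + 1L]),
          collapse = "\t")
  }, "")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t"),
    body), path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' BED is 0-based half-open on disk; intervals are converted to 1-based
#' inclusive coordinates at this boundary, matching the GTF convention used
#' internally.
#'
#' @param path BED file.
#' @return `data.table` with `chrom`, `start`, `end` (1-based inclusive) and
#'   `name` when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr))
  if (!is.null(gr$name)) dt[, name := gr$name]
  dt
}

#' Write intervals to BED (converting to 0-based half-open)
#'
#' @param dt `data.table` with 1-based inclusive `chrom`, `start`, `end`,
#'   optional `name`.
#' @param path output path.
#' @export
write_bed <- function(dt, path) {
  stopifnot(all(dt$start <= dt$end))
  cols <- data.table(dt$chrom, dt$start - 1L, dt$end)
  if (!is.null(dt$name)) cols <- cbind(cols, dt$name)
  fwrite(cols, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#' @param path GMT file (set name, description, then member genes, tab-sep).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read a feature-by-sample expression matrix from TSV
#' @param path TSV with a feature-id first column and sample-id header.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- fread(path, header = TRUE)
  m <- as.matrix(dt[, -1L])
  rownames(m) <- dt[[1L]]
  m
}

#' Write a feature-by-sample matrix to TSV
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_col name for the feature-id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  dt <- data.table(feature_id = rownames(m))
  setnames(dt, "feature_id", id_col)
  fwrite(cbind(dt, as.data.table(m)), path, sep = "\t")
  invisible(path)
}

#' @importFrom data.table as.data.table setnames
NULL
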