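# Phenotype construction: expression filters, CDS-group integration, ratio
# phenotypes, and the normalization cascade
# (quantile -> inverse-normal -> latent-factor removal).

#' Filter genes on a minimum FPKM in every sample
#'
#' Retains genes with expression strictly above `threshold` in all samples.
#'
#' @param gene_expr numeric matrix, genes x samples (FPKM).
#' @param threshold strict lower bound (default 0.1).
#' @return the filtered matrix.
#' @export
filter_genes <- function(gene_expr, threshold = 0.1) {
  stopifnot(is.matrix(gene_expr), all(gene_expr >= 0))
  keep <- apply(gene_expr > threshold, 1L, all)
  if (!any(keep)) warning("no genes pass the FPKM filter")
  gene_expr[keep, , drop = FALSE]
}

#' Filter isoforms of retained genes on FPKM in a sample fraction
#'
#' Retains isoforms whose parent gene survived [filter_genes()] and whose
#' expression exceeds `threshold` in at least `ceiling(frac * n_samples)`
#' samples.
#'
#' @param iso_expr numeric matrix, isoforms x samples.
#' @param retained_genes character vector of gene ids that passed the gene
#'   filter.
#' @param gene_of named character vector mapping isoform id -> gene id.
#' @param threshold strict FPKM bound (default 1).
#' @param frac minimum fraction of samples (default 0.05).
#' @return the filtered matrix.
#' @export
filter_isoforms <- function(iso_expr, retained_genes, gene_of,
                            threshold = 1, frac = 0.05) {
  n_min <- ceiling(frac * ncol(iso_expr))
  parent_ok <- gene_of[rownames(iso_expr)] %in% retained_genes
  expr_ok <- rowSums(iso_expr > threshold) >= n_min
  iso_expr[parent_ok & expr_ok, , drop = FALSE]
}

#' Sum expression of isoforms sharing a CDS group
#'
#' One output row per group; the value is the per-sample sum over member
#' isoforms (group members absent from the matrix contribute zero and are
#' reported in a message). Singleton groups pass through unchanged under
#' the group id.
#'
#' @param iso_expr numeric matrix, isoforms x samples.
#' @param groups a `CdsGroupSet` from [build_cds_groups()].
#' @return numeric matrix, groups x samples; only groups with at least one
#'   member present are emitted.
#' @export
integrate_isoforms <- function(iso_expr, groups) {
  present <- rownames(iso_expr)
  out <- list()
  n_absent <- 0L
  for (gid in names(groups$groups)) {
    members <- groups$groups[[gid]]
    here <- intersect(members, present)
    n_absent <- n_absent + length(members) - length(here)
    if (!length(here)) next
    out[[gid]] <- colSums(iso_expr[here, , drop = FALSE])
  }
  if (n_absent > 0L) message(n_absent, " group member(s) absent from matrix, treated as 0")
  do.call(rbind, out)
}

#' Compute isoform-over-gene expression ratios
#'
#' The ratio of each feature's FPKM to its gene's total (summed over the
#' features present in the matrix). Samples where the gene total is zero
#' yield missing ratios for every feature of that gene.
#'
#' @param expr numeric matrix, features x samples (isoforms or integrated
#'   isoforms).
#' @param gene_of named character vector mapping feature id -> gene id.
#' @return list with `ratios` (features x samples, values in \[0,1\] or NA)
#'   and `gene_of` (the mapping restricted to the matrix rows).
#' @export
compute_ratios <- function(expr, gene_of) {
  gene_of <- gene_of[rownames(expr)]
  stopifnot(!anyNA(gene_of))
  ratios <- expr
  for (g in unique(gene_of)) {
    rows <- which(gene_of == g)
    tot <- colSums(expr[rows, , drop = FALSE])
    r <- sweep(expr[rows, , drop = FALSE], 2, tot, `/`)
    r[, tot == 0] <- NA_real_
    ratios[rows, ] <- r
  }
  structure(list(ratios = ratios, gene_of = gene_of), class = "RatioMatrix")
}

#' @export
print.RatioMatrix <- function(x, ...) {
  cat("RatioMatrix:", nrow(x$ratios), "features x", ncol(x$ratios),
      "samples;", sum(is.na(x$ratios)), "missing entries\n")
  invisible(x)
}

#' Drop high-missingness features and mean-impute the rest
#'
#' Features missing in more than `max_missing_frac` of samples are dropped;
#' remaining missing entries are imputed with the feature's non-missing
#' mean (neutral under the later rank transform).
#'
#' @param m numeric matrix with possible NAs.
#' @param max_missing_frac tolerated missing fraction per feature
#'   (default 0.05).
#' @return complete numeric matrix.
#' @export
impute_missing <- function(m, max_missing_frac = 0.05) {
  miss <- rowMeans(is.na(m))
  m <- m[miss <= max_missing_frac, , drop = FALSE]
  for (i in which(rowSums(is.na(m)) > 0L)) {
    row <- m[i, ]
    m[i, is.na(row)] <- mean(row, na.rm = TRUE)
  }
  m
}

#' Quantile normalization across samples
#'
#' Forces every sample column onto a common distribution: the mean of order
#' statistics across columns, with ties receiving the mean of the tied
#' targets (delegated to `limma::normalizeQuantiles`).
#'
#' @param m complete numeric matrix, features x samples.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  stopifnot(!anyNA(m))
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Rank-based inverse normal transform (Blom offsets), per feature
#'
#' Each feature row is mapped to `qnorm((rank - 3/8) / (n + 1/4))` with
#' average ranks on ties. Zero-variance features are dropped with a
#' warning.
#'
#' @param m complete numeric matrix, features x samples.
#' @param offset Blom offset (default 3/8).
#' @return matrix with the surviving features.
#' @export
inverse_normal_transform <- function(m, offset = 3 / 8) {
  keep <- apply(m, 1L, function(x) var(x) > 0)
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance feature(s) dropped before INT")
    m <- m[keep, , drop = FALSE]
  }
  n <- ncol(m)
  t(apply(m, 1L, function(x) qnorm((rank(x) - offset) / (n + 1 - 2 * offset))))
}

#' Remove latent expression factors by PCA residualization
#'
#' A deterministic stand-in for PEER: each feature is residualized on the
#' top-`k` principal components of the feature-standardized matrix
#' (computed by SVD in sample space). `k = 0` returns the centered input
#' unchanged apart from centering already implied by the inverse-normal
#' transform.
#'
#' @param m numeric matrix, features x samples (typically INT output).
#' @param k number of latent factors to remove (default 15).
#' @return residual matrix of the same shape.
#' @export
remove_latent_factors <- function(m, k = 15) {
  if (k == 0) return(m)
  if (k >= ncol(m)) stop("k must be smaller than the number of samples")
  k <- min(k, nrow(m))
  center <- rowMeans(m)
  xc <- m - center
  sds <- sqrt(rowSums(xc^2) / (ncol(m) - 1))
  sds[sds == 0] <- 1
  s <- xc / sds
  v <- svd(s, nu = 0, nv = k)$v  # sample-space factor scores, orthonormal
  xc - (xc %*% v) %*% t(v)
}

#' Full phenotype normalization cascade
#'
#' Imputation (ratios only) -> quantile normalization across samples ->
#' inverse normal transform per feature -> latent-factor removal. The
#' fixed order matches standard QTL phenotype preparation.
#'
#' @param m numeric matrix, features x samples; may contain NAs.
#' @param n_factors latent factors to remove (default 15).
#' @param max_missing_frac passed to [impute_missing()].
#' @return normalized phenotype matrix.
#' @export
normalize_phenotypes <- function(m, n_factors = 15, max_missing_frac = 0.05) {
  m <- impute_missing(m, max_missing_frac)
  m <- quantile_normalize(m)
  m <- inverse_normal_transform(m)
  remove_latent_factors(m, k = n_factors)
}

#' Build phenotype matrices for one analysis mode
#'
#' Applies the filter -> (integrate) -> ratio -> normalize cascade and
#' returns the phenotype matrix plus the gene anchor of each phenotype.
#'
#' @param gene_fpkm genes x samples FPKM matrix.
#' @param iso_fpkm isoforms x samples FPKM matrix.
#' @param catalog an `IsoformCatalog`.
#' @param mode one of `gene_eqtl`, `i_eqtl`, `i_rqtl`, `i2_eqtl`,
#'   `i2_rqtl`.
#' @param groups a `CdsGroupSet`; required for the `i2_*` modes.
#' @param gene_fpkm_min,iso_fpkm_min,iso_frac,n_factors filter and
#'   normalization knobs (defaults 0.1, 1, 0.05, 15).
#' @param cdsi_only restrict isoform-level phenotypes to CDS-incomplete
#'   isoforms.
#' @return list with `phenotypes` (features x samples), `gene_of` (named
#'   vector) and `anchors` (`data.table`: `phenotype_id`, `gene_id`,
#'   `chrom`, `tss`, `tes`, `strand`, from the union of the gene's
#'   isoforms).
#' @export
build_phenotypes <- function(gene_fpkm, iso_fpkm, catalog,
                             mode = c("gene_eqtl", "i_eqtl", "i_rqtl",
                                      "i2_eqtl", "i2_rqtl"),
                             groups = NULL, gene_fpkm_min = 0.1,
                             iso_fpkm_min = 1, iso_frac = 0.05,
                             n_factors = 15, cdsi_only = FALSE) {
  mode <- match.arg(mode)
  iso <- catalog$isoforms
  gene_of_iso <- setNames(iso$gene_id, iso$isoform_id)
  genes_kept <- rownames(filter_genes(gene_fpkm, gene_fpkm_min))
  if (mode == "gene_eqtl") {
    m <- gene_fpkm[genes_kept, , drop = FALSE]
    gene_of <- setNames(genes_kept, genes_kept)
  } else {
    m <- filter_isoforms(iso_fpkm, genes_kept, gene_of_iso,
                         iso_fpkm_min, iso_frac)
    if (cdsi_only) {
      m <- m[rownames(m) %in% classify_cdsi(catalog), , drop = FALSE]
    }
    gene_of <- gene_of_iso[rownames(m)]
    if (mode %in% c("i2_eqtl", "i2_rqtl")) {
      stopifnot(!is.null(groups))
      m <- integrate_isoforms(m, groups)
      gene_of <- setNames(sub("::.*$", "", rownames(m)), rownames(m))
    }
    if (mode %in% c("i_rqtl", "i2_rqtl")) {
      m <- compute_ratios(m, gene_of)$ratios
    }
  }
  pheno <- normalize_phenotypes(m, n_factors = n_factors)
  gene_of <- gene_of[rownames(pheno)]
  anchors <- gene_anchors(catalog)[match(gene_of, gene_id)]
  anchors <- data.table(phenotype_id = rownames(pheno), anchors)
  list(phenotypes = pheno, gene_of = gene_of, anchors = anchors)
}

#' Gene-level anchor coordinates (TSS/TES span over all isoforms)
#' @param catalog an `IsoformCatalog`.
#' @return `data.table`: `gene_id`, `chrom`, `strand`, `tss`, `tes` with
#'   tss/tes the strand-aware extremes over the gene's isoforms.
#' @export
gene_anchors <- function(catalog) {
  iso <- catalog$isoforms
  iso[, {
    lo <- min(vapply(exons, function(e) min(e[, 1L]), 0))
    hi <- max(vapply(exons, function(e) max(e[, 2L]), 0))
    if (strand[1L] == "+") list(chrom = chrom[1L], strand = strand[1L],
                                tss = lo, tes = hi)
    else list(chrom = chrom[1L], strand = strand[1L], tss = hi, tes = lo)
  }, by = gene_id]
}
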