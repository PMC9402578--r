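# Trans-eQTL effects of sQTL lead variants: genome-wide correlation scan
# with cis exclusions, QQ-based enrichment comparison between variant
# classes, and GSEA with a continuous isoform-ratio phenotype label
# (Pearson-weighted running-sum statistic).

#' Trans-eQTL scan of one variant against distal gene expression
#'
#' Pearson r and two-sided p per gene. Genes within `cis_margin` of the
#' variant (same chromosome) are excluded with reason `cis_window`; genes
#' carrying a cis-eQTL (caller-supplied set, e.g. FDR <= 0.05 genes) with
#' reason `cis_eqtl_gene`.
#'
#' @param dosage variant dosage vector.
#' @param variant list/row with `chrom`, `pos`.
#' @param expr genes x samples phenotype matrix (normalized FPKM).
#' @param gene_coords `data.table` with `gene_id`, `chrom`, `tss`, `tes`.
#' @param cis_eqtl_genes character vector of genes to exclude.
#' @param cis_margin distal threshold in bp (default 1 Mb; with the cis
#'   window this makes cis/trans a partition).
#' @return `data.table`: `gene_id`, `r`, `p`, `excluded_reason` (`none`,
#'   `cis_window`, `cis_eqtl_gene`; excluded genes carry NA statistics).
#' @export
trans_scan <- function(dosage, variant, expr, gene_coords,
                       cis_eqtl_genes = character(0), cis_margin = 1e6) {
  n <- length(dosage)
  stopifnot(n == ncol(expr))
  gc <- gene_coords[match(rownames(expr), gene_id)]
  near <- gc$chrom == variant$chrom &
    pmin(abs(gc$tss - variant$pos), abs(gc$tes - variant$pos)) <= cis_margin
  reason <- rep("none", nrow(expr))
  reason[near] <- "cis_window"
  reason[rownames(expr) %in% cis_eqtl_genes] <- "cis_eqtl_gene"
  r <- rep(NA_real_, nrow(expr))
  p <- rep(NA_real_, nrow(expr))
  ok <- reason == "none"
  if (any(ok)) {
    r[ok] <- as.vector(cor(dosage, t(expr[ok, , drop = FALSE])))
    p[ok] <- cor_to_p(r[ok], n)
  }
  data.table(gene_id = rownames(expr), r = r, p = p, excluded_reason = reason)
}

#' QQ-style enrichment comparison of two p-value classes
#'
#' Builds observed-vs-expected quantile tables of -log10 p for each class
#' against the uniform expectation, and summarizes enrichment as the ratio
#' of class medians of -log10 p (optionally relative to a background
#' class).
#'
#' @param p_class_a,p_class_b numeric p-value vectors (non-empty).
#' @param background optional background p-values for reference lambda.
#' @param n_quantiles points per QQ curve (default 100).
#' @return list with `qq` (long `data.table`: `class`, `expected`,
#'   `observed` in -log10 units) and `median_ratio`
#'   (median(-log10 p_a) / median(-log10 p_b)).
#' @export
qq_compare <- function(p_class_a, p_class_b, background = NULL,
                       n_quantiles = 100L) {
  stopifnot(length(p_class_a) > 0, length(p_class_b) > 0)
  one <- function(p, label) {
    p <- sort(p)
    probs <- seq(0.5 / n_quantiles, 1 - 0.5 / n_quantiles,
                 length.out = n_quantiles)
    data.table(class = label,
               expected = -log10(quantile(seq_along(p) / (length(p) + 1),
                                          probs, names = FALSE)),
               observed = -log10(quantile(p, probs, names = FALSE)))
  }
  qq <- rbind(one(p_class_a, "a"), one(p_class_b, "b"),
              if (!is.null(background)) one(background, "background"))
  list(qq = qq,
       median_ratio = median(-log10(p_class_a)) / median(-log10(p_class_b)))
}

#' Rank genes by Pearson correlation with a continuous phenotype label
#'
#' @param expr genes x samples matrix.
#' @param label continuous phenotype vector (non-constant), e.g. a
#'   normalized isoform ratio.
#' @return `data.table` sorted by `r` descending (ties by gene id):
#'   `gene_id`, `r`. Zero-variance genes get r = 0 with a message.
#' @export
rank_genes_by_metric <- function(expr, label) {
  stopifnot(sd(label) > 0, ncol(expr) == length(label))
  sds <- apply(expr, 1L, sd)
  r <- rep(0, nrow(expr))
  if (any(sds == 0)) message(sum(sds == 0), " zero-variance gene(s): metric 0")
  ok <- sds > 0
  r[ok] <- as.vector(cor(label, t(expr[ok, , drop = FALSE])))
  data.table(gene_id = rownames(expr), r = r)[order(-r, gene_id)]
}

#' GSEA enrichment score (weighted Kolmogorov-Smirnov running sum)
#'
#' Walking down the ranked list, set members ("hits") add
#' `|r|^weight_p / sum_hits |r|^weight_p` and non-members subtract
#' `1 / (N - N_hits)`. The enrichment score is the signed maximum
#' deviation of the running sum; the leading edge is the set members at or
#' before the maximum (at or after it for negative scores).
#'
#' @param ranked `data.table` from [rank_genes_by_metric()] (`gene_id`,
#'   `r`, already ordered).
#' @param gene_set character vector (must intersect the ranked genes).
#' @param weight_p metric weight exponent (default 1; 0 gives the
#'   classical unweighted KS statistic).
#' @return list with `es`, `leading_edge`, `running` (numeric running
#'   sum).
#' @export
gsea_es <- function(ranked, gene_set, weight_p = 1) {
  hit <- ranked$gene_id %in% gene_set
  if (!any(hit)) stop("gene set has no overlap with the ranked list")
  n <- nrow(ranked)
  w <- abs(ranked$r)^weight_p
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  if (all(hit)) {
    running <- cumsum(inc)
  } else {
    dec <- ifelse(hit, 0, 1 / (n - sum(hit)))
    running <- cumsum(inc - dec)
  }
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading <- if (es >= 0) ranked$gene_id[seq_len(i_max)][hit[seq_len(i_max)]]
             else ranked$gene_id[i_max:n][hit[i_max:n]]
  list(es = es, leading_edge = leading, running = running)
}

#' GSEA with sample-label permutation significance
#'
#' Permutes the continuous phenotype label across samples (preserving
#' inter-gene correlation), recomputing the metric ranking and enrichment
#' score each time. `p = (1 + #\{|es_perm| >= |es_obs|\}) / (1 + n_perm)`;
#' the normalized score divides by the mean |es| of sign-matched
#' permutations.
#'
#' @param expr genes x samples matrix.
#' @param label continuous phenotype vector.
#' @param gene_set character vector of member genes.
#' @param weight_p metric weight exponent (default 1).
#' @param n_perm permutations (>= 100).
#' @param seed integer seed.
#' @return `GseaResult` list: `es`, `nes`, `p`, `leading_edge`,
#'   `weight_exponent`.
#' @export
gsea_permutation_p <- function(expr, label, gene_set, weight_p = 1,
                               n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 100L)
  obs <- gsea_es(rank_genes_by_metric(expr, label), gene_set, weight_p)
  set.seed(seed)
  es_perm <- vapply(seq_len(n_perm), function(b) {
    gsea_es(rank_genes_by_metric(expr, sample(label)), gene_set, weight_p)$es
  }, 0)
  if (sd(es_perm) == 0) warning("degenerate permutation distribution")
  same_sign <- es_perm[sign(es_perm) == sign(obs$es)]
  nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
  list(es = obs$es, nes = nes,
       p = (1 + sum(abs(es_perm) >= abs(obs$es))) / (1 + n_perm),
       leading_edge = obs$leading_edge, weight_exponent = weight_p)
}
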