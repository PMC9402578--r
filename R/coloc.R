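# Colocalization of QTL and GWAS signals: LD r-squared, the regulatory
# trait concordance (RTC) score within recombination intervals, and the
# dual-evidence curation of sQTL signals against a junction-QTL table.

#' Squared dosage correlation (composite LD r-squared) between two variants
#' @param g1,g2 dosage vectors over the same samples.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  if (sd(g1) == 0 || sd(g2) == 0) stop("monomorphic variant: LD undefined")
  cor(g1, g2)^2
}

#' RTC score of a GWAS variant against a QTL signal within one interval
#'
#' For every variant k in the interval, the phenotype is residualized on
#' k's dosage and the QTL variant re-associated against the residuals,
#' giving `p_k`. Variants are ranked by `p_k` in decreasing order (the
#' variant whose removal most annihilates the QTL signal gets rank 0; ties
#' broken by genomic position). With N interval variants and the GWAS
#' variant at rank `rank`, `RTC = (N - rank) / N`: 1 means the GWAS variant
#' fully explains the QTL association.
#'
#' @param y phenotype vector.
#' @param genotypes a `GenotypeMatrix` restricted (or restrictable) to the
#'   interval; only `variant_idx` columns are used.
#' @param variant_idx column indices of the interval's variants.
#' @param gwas_variant,qtl_variant variant ids, both within the interval.
#' @return one-row `data.table`: `gwas_variant_id`, `qtl_variant_id`,
#'   `n_variants`, `rank`, `rtc`, `r2`.
#' @export
rtc_score <- function(y, genotypes, variant_idx, gwas_variant, qtl_variant) {
  v <- genotypes$variants[variant_idx]
  stopifnot(gwas_variant %in% v$variant_id, qtl_variant %in% v$variant_id,
            length(variant_idx) >= 2L)
  g <- genotypes$dosages[, variant_idx, drop = FALSE]
  n <- length(y)
  gq <- g[, which(v$variant_id == qtl_variant)]
  if (sd(gq) == 0) stop("QTL variant monomorphic")
  p_k <- vapply(seq_len(ncol(g)), function(k) {
    gk <- g[, k]
    if (sd(gk) == 0) return(NA_real_)
    res <- y - mean(y) - cov(y, gk) / var(gk) * (gk - mean(gk))
    if (sd(res) == 0) return(1)  # signal fully removed
    cor_to_p(cor(gq, res), n)
  }, 0)
  ord <- order(-p_k, v$pos, v$variant_id, na.last = TRUE)
  rank0 <- which(v$variant_id[ord] == gwas_variant) - 1L
  n_var <- length(variant_idx)
  data.table(gwas_variant_id = gwas_variant, qtl_variant_id = qtl_variant,
             n_variants = n_var, rank = rank0,
             rtc = (n_var - rank0) / n_var,
             r2 = ld_r2(g[, which(v$variant_id == gwas_variant)], gq))
}

#' Score every (significant QTL, GWAS variant) pair sharing an interval
#'
#' QTL lead variants are assigned to the recombination interval containing
#' them; each GWAS catalog variant in the same interval is RTC-scored
#' against the QTL signal. A pair passes at `rtc >= rtc_min` and
#' `r2 >= r2_min`. Leads outside every interval are skipped with a message.
#'
#' @param qtl_results `CisQtlResult` table (uses `phenotype_id`,
#'   `lead_variant_id`, `qvalue`).
#' @param phenotypes phenotype matrix (rows must cover the QTL phenotypes).
#' @param genotypes a `GenotypeMatrix`.
#' @param gwas `data.table` with `trait`, `variant_id`.
#' @param intervals `data.table` with `chrom`, `start`, `end`, `name`
#'   (1-based inclusive, e.g. from [read_bed()]).
#' @param q_max significance cutoff on `qvalue` (default 0.05).
#' @param rtc_min,r2_min pass thresholds (default 0.8 both).
#' @return `RtcRecord` `data.table`: `interval_id`, `trait`,
#'   `phenotype_id`, `gwas_variant_id`, `qtl_variant_id`, `n_variants`,
#'   `rank`, `rtc`, `r2`, `pass`, plus `best` marking the max-RTC record
#'   per (trait, phenotype).
#' @export
colocalize_catalog <- function(qtl_results, phenotypes, genotypes, gwas,
                               intervals, q_max = 0.05, rtc_min = 0.8,
                               r2_min = 0.8) {
  v <- genotypes$variants
  sig <- qtl_results[qvalue <= q_max]
  out <- list()
  for (i in seq_len(nrow(sig))) {
    lead <- sig$lead_variant_id[i]
    lv <- v[variant_id == lead]
    hit <- intervals[chrom == lv$chrom & start <= lv$pos & end >= lv$pos]
    if (nrow(hit) == 0L) {
      message("lead variant ", lead, " in no interval; skipped")
      next
    }
    hit <- hit[1L]
    vidx <- which(v$chrom == hit$chrom & v$pos >= hit$start & v$pos <= hit$end)
    in_iv <- gwas[variant_id %in% v$variant_id[vidx]]
    if (!nrow(in_iv)) next
    y <- phenotypes[sig$phenotype_id[i], ]
    for (j in seq_len(nrow(in_iv))) {
      rec <- rtc_score(y, genotypes, vidx, in_iv$variant_id[j], lead)
      out[[length(out) + 1L]] <- data.table(
        interval_id = hit$name, trait = in_iv$trait[j],
        phenotype_id = sig$phenotype_id[i], rec)
    }
  }
  if (!length(out)) return(data.table())
  res <- rbindlist(out)
  res[, pass := rtc >= rtc_min & r2 >= r2_min]
  res[, best := rtc == max(rtc), by = .(trait, phenotype_id)]
  res[]
}

#' Curate isoform-ratio QTLs against junction-level evidence
#'
#' Keeps i-rQTL / i2-rQTL records that (1) are significant at
#' `qtl_fdr_max`, (2) have a matched junction-QTL record significant at
#' `junction_fdr_max`, and (3) agree in effect direction (`sign(slope)`)
#' with every matched junction record. Integrated phenotypes match if any
#' member isoform matches.
#'
#' @param irqtl `CisQtlResult` table (needs `phenotype_id`, `slope`,
#'   `qvalue`).
#' @param junction_qtl `data.table` with `junction_id`, `isoform_id`, `p`,
#'   `q`, `slope`.
#' @param qtl_fdr_max,junction_fdr_max FDR cutoffs (default 0.05).
#' @param require_direction_concordance default TRUE.
#' @return the curated subset of `irqtl`, with an added
#'   `n_junctions_matched` column; an attribute `n_unmatched` counts
#'   significant records excluded for lack of junction evidence.
#' @export
curate_signals <- function(irqtl, junction_qtl, qtl_fdr_max = 0.05,
                           junction_fdr_max = 0.05,
                           require_direction_concordance = TRUE) {
  sig <- irqtl[qvalue <= qtl_fdr_max]
  keep <- logical(nrow(sig))
  nj <- integer(nrow(sig))
  n_unmatched <- 0L
  for (i in seq_len(nrow(sig))) {
    members <- strsplit(sub("^.*::", "", sig$phenotype_id[i]), "+",
                        fixed = TRUE)[[1L]]
    jr <- junction_qtl[isoform_id %in% members & q <= junction_fdr_max]
    if (!nrow(jr)) { n_unmatched <- n_unmatched + 1L; next }
    nj[i] <- nrow(jr)
    keep[i] <- !require_direction_concordance ||
      all(sign(jr$slope) == sign(sig$slope[i]))
  }
  out <- sig[keep]
  out[, n_junctions_matched := nj[keep]]
  setattr(out, "n_unmatched", n_unmatched)
  out[]
}
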