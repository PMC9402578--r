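# Cis-window association mapping: nominal Pearson scan, a permutation pass
# yielding gene-level empirical and beta-approximated adjusted p-values,
# and Storey-Tibshirani q-values across phenotypes.

cor_to_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(tstat, df = n - 2, lower.tail = FALSE)
}

cis_window_variants <- function(genotypes, anchor, window = 1e6,
                                maf_min = 0.05) {
  v <- genotypes$variants
  lo <- min(anchor$tss, anchor$tes) - window
  hi <- max(anchor$tss, anchor$tes) + window
  which(v$chrom == anchor$chrom & v$pos >= lo & v$pos <= hi & v$maf >= maf_min)
}

#' Nominal cis-window association scan for one phenotype
#'
#' Pearson correlation, least-squares slope and two-sided p-value
#' (`t = r sqrt((n-2)/(1-r^2))`, n-2 df) of the phenotype against every
#' variant with `maf >= maf_min` within `window` bp of the gene body
#' (`[min(tss,tes) - window, max(tss,tes) + window]`). Zero-variance
#' variants are skipped.
#'
#' @param y numeric phenotype vector (one row of a phenotype matrix).
#' @param genotypes a `GenotypeMatrix`.
#' @param anchor list/row with `chrom`, `tss`, `tes`.
#' @param window cis window in bp (default 1e6).
#' @param maf_min minimum MAF (default 0.05).
#' @return `data.table`: `variant_id`, `pos`, `r`, `slope`, `p`.
#' @export
nominal_scan <- function(y, genotypes, anchor, window = 1e6, maf_min = 0.05) {
  stopifnot(sd(y) > 0)
  idx <- cis_window_variants(genotypes, anchor, window, maf_min)
  if (!length(idx)) return(data.table(variant_id = character(0), pos = integer(0),
                                      r = numeric(0), slope = numeric(0),
                                      p = numeric(0)))
  g <- genotypes$dosages[, idx, drop = FALSE]
  sds <- apply(g, 2L, sd)
  poly <- sds > 0
  if (any(!poly)) message(sum(!poly), " monomorphic variant(s) skipped")
  g <- g[, poly, drop = FALSE]
  idx <- idx[poly]
  r <- as.vector(cor(y, g))
  n <- length(y)
  data.table(variant_id = genotypes$variants$variant_id[idx],
             pos = genotypes$variants$pos[idx],
             r = r, slope = r * sd(y) / sds[poly],
             p = cor_to_p(r, n))
}

select_lead <- function(scan) {
  scan[order(p, pos, variant_id)][1L]
}

#' Maximum-likelihood Beta fit to permutation minimum p-values
#'
#' Fits `Beta(shape1, shape2)` to the permutation null of the minimum
#' cis-window p-value, giving a smooth adjusted p-value
#' `pbeta(observed_min_p, shape1, shape2)`. Falls back to the empirical
#' permutation p-value when the minima are degenerate or the fit fails.
#'
#' @param perm_minima numeric vector of permutation minimum p-values (>= 100
#'   recommended).
#' @return list with `shape1`, `shape2`, `adjust` (function of an observed
#'   minimum p) and `ok` (FALSE when the fallback applies).
#' @export
fit_beta_approx <- function(perm_minima) {
  x <- pmin(pmax(perm_minima, 1e-300), 1 - 1e-16)
  if (length(x) < 100L) warning("fewer than 100 permutation minima; beta fit unstable")
  if (sd(x) == 0) {
    return(list(shape1 = NA_real_, shape2 = NA_real_, adjust = NULL, ok = FALSE))
  }
  m <- mean(x); v <- var(x)
  common <- m * (1 - m) / v - 1
  init <- log(pmax(c(m * common, (1 - m) * common), 1e-3))
  nll <- function(par) {
    a <- exp(par[1L]); b <- exp(par[2L])
    -sum((a - 1) * log(x) + (b - 1) * log1p(-x)) + length(x) * lbeta(a, b)
  }
  fit <- tryCatch(optim(init, nll, method = "Nelder-Mead"),
                  error = function(e) NULL)
  if (is.null(fit)) {
    return(list(shape1 = NA_real_, shape2 = NA_real_, adjust = NULL, ok = FALSE))
  }
  a <- exp(fit$par[1L]); b <- exp(fit$par[2L])
  list(shape1 = a, shape2 = b,
       adjust = function(p_obs) pmax(pbeta(p_obs, a, b), 1e-300),
       ok = TRUE)
}

#' Permutation pass for one phenotype
#'
#' The observed statistic is the minimum nominal p over the cis window.
#' The phenotype is permuted across samples `B` times (one permutation per
#' replicate shared by all variants, preserving LD) and the minimum p
#' recorded each time. The empirical permutation p is
#' `(1 + #\{perm min <= observed\}) / (B + 1)`; a Beta fit to the minima
#' supplies the smoothed adjusted p.
#'
#' @param y phenotype vector.
#' @param genotypes a `GenotypeMatrix`.
#' @param anchor list/row with `chrom`, `tss`, `tes`.
#' @param window,maf_min as in [nominal_scan()].
#' @param B number of permutations (default 1000; < 100 warns).
#' @param seed integer seed for the permutations.
#' @param perms optional precomputed permutation matrix (n x B of sample
#'   indices); when supplied, `seed`/`B` are taken from it. Sharing one
#'   matrix across the phenotypes of a run makes results independent of
#'   phenotype ordering.
#' @return one-row `data.table`: `lead_variant_id`, `nominal_p`, `slope`,
#'   `r`, `perm_p`, `beta_shape1`, `beta_shape2`, `adjusted_p`.
#' @export
permutation_pass <- function(y, genotypes, anchor, window = 1e6,
                             maf_min = 0.05, B = 1000, seed = 1L,
                             perms = NULL) {
  if (!is.null(perms)) B <- ncol(perms)
  if (B < 100) warning("B < 100 permutations: adjusted p-values are coarse")
  scan <- nominal_scan(y, genotypes, anchor, window, maf_min)
  if (!nrow(scan)) stop("no variants in cis window")
  lead <- select_lead(scan)
  idx <- cis_window_variants(genotypes, anchor, window, maf_min)
  g <- genotypes$dosages[, idx, drop = FALSE]
  g <- g[, apply(g, 2L, sd) > 0, drop = FALSE]
  n <- length(y)
  gs <- scale(g)                      # n x p standardized
  if (is.null(perms)) {
    set.seed(seed)
    perms <- replicate(B, sample.int(n))
  }
  ys <- as.vector(scale(y))
  yperm <- matrix(ys[perms], n, B)    # each column a permuted phenotype
  rmat <- crossprod(gs, yperm) / (n - 1)   # p x B correlations
  max_abs_r <- apply(abs(rmat), 2L, max)
  perm_min_p <- cor_to_p(max_abs_r, n)
  perm_p <- (1 + sum(perm_min_p <= lead$p)) / (B + 1)
  bf <- fit_beta_approx(perm_min_p)
  adjusted <- if (bf$ok) bf$adjust(lead$p) else perm_p
  data.table(lead_variant_id = lead$variant_id, nominal_p = lead$p,
             slope = lead$slope, r = lead$r, perm_p = perm_p,
             beta_shape1 = if (bf$ok) bf$shape1 else NA_real_,
             beta_shape2 = if (bf$ok) bf$shape2 else NA_real_,
             adjusted_p = min(max(adjusted, .Machine$double.xmin), 1))
}

#' Storey-Tibshirani q-values
#'
#' `pi0` is estimated on the lambda grid 0.05-0.95 (step 0.05) with a cubic
#' smoothing-spline extrapolation at the largest lambda, clipped to (0, 1].
#' q-values follow the usual step-up: `q_i = min over p_j >= p_i of
#' pi0 * m * p_j / rank(p_j)`, returned in input order. With fewer than 20
#' p-values `pi0` is fixed at 1 (Benjamini-Hochberg-equivalent) with a
#' warning.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param lambda grid for the pi0 estimate.
#' @param pi0 optionally force pi0 (e.g. `pi0 = 1` for BH).
#' @return numeric vector of q-values, same order as `p`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, 0.05), pi0 = NULL) {
  stopifnot(all(p > 0 & p <= 1))
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 20L) {
      warning("fewer than 20 p-values: fixing pi0 = 1")
      pi0 <- 1
    } else {
      pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      fit <- smooth.spline(lambda, pi0_lambda, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / rank(p[o], ties.method = "max")
  q <- pmin(cummin(q), 1)
  q[ro]
}

#' Map cis-QTLs for every phenotype of a matrix
#'
#' Runs the permutation pass per phenotype and appends Storey q-values
#' computed on the adjusted p-values across phenotypes.
#'
#' @param phenotypes features x samples matrix (normalized).
#' @param genotypes a `GenotypeMatrix` (samples must match columns).
#' @param anchors `data.table` with `phenotype_id`, `chrom`, `tss`, `tes`
#'   (one row per phenotype, e.g. from [build_phenotypes()]).
#' @param window,maf_min,B as in [permutation_pass()].
#' @param seed integer seed; one permutation set is drawn up front and
#'   shared by every phenotype (preserving LD and making results invariant
#'   to phenotype ordering).
#' @return `CisQtlResult` `data.table`: `phenotype_id`, `lead_variant_id`,
#'   `nominal_p`, `slope`, `r`, `perm_p`, `beta_shape1`, `beta_shape2`,
#'   `adjusted_p`, `qvalue`.
#' @export
map_cis_qtl <- function(phenotypes, genotypes, anchors, window = 1e6,
                        maf_min = 0.05, B = 1000, seed = 1L) {
  stopifnot(ncol(phenotypes) == nrow(genotypes$dosages))
  ids <- rownames(phenotypes)
  set.seed(seed)
  perms <- replicate(B, sample.int(ncol(phenotypes)))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    anc <- anchors[phenotype_id == ids[i]]
    if (nrow(anc) != 1L) stop("no unique anchor for phenotype ", ids[i])
    res <- permutation_pass(phenotypes[i, ], genotypes, anc,
                            window = window, maf_min = maf_min,
                            perms = perms)
    rows[[i]] <- data.table(phenotype_id = ids[i], res)
  }
  out <- rbindlist(rows)
  out[, qvalue := storey_qvalues(adjusted_p)]
  out[]
}
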