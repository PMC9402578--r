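# Characterization of lead variants: position on a standardized gene body,
# Silverman's multimodality test, and cell-type specificity classes.

#' Map a variant position onto a standardized gene-body axis
#'
#' The gene body is rescaled to `body_scale` bp (0 at TSS, `body_scale` at
#' TES); flanks stay in raw bp: upstream of the TSS is negative, downstream
#' of the TES is `body_scale + distance`. Minus-strand genes are mirrored
#' so upstream always means 5'.
#'
#' @param pos variant genomic position.
#' @param tss,tes gene anchor positions (strand-aware: `tss` is the 5'
#'   end, so `tss > tes` on the minus strand).
#' @param body_scale standardized gene-body length (default 30000 bp, the
#'   average isoform length the axis emulates).
#' @return numeric coordinate on the standardized axis.
#' @export
relative_position <- function(pos, tss, tes, body_scale = 30000) {
  if (tss == tes) stop("zero-length gene")
  signed <- if (tss < tes) pos - tss else tss - pos  # 5'->3' distance
  len <- abs(tes - tss)
  if (signed < 0) return(signed)                      # upstream flank, raw bp
  if (signed > len) return(body_scale + (signed - len))
  body_scale * signed / len
}

count_modes <- function(x, h, n_grid = 1024L) {
  d <- density(x, bw = h, n = n_grid, from = min(x) - 3 * h,
               to = max(x) + 3 * h)
  dy <- diff(d$y)
  sum(dy[-length(dy)] > 0 & dy[-1L] <= 0)
}

#' Silverman's bootstrap test for the number of modes
#'
#' Finds the critical bandwidth `h_crit`, the smallest Gaussian-kernel
#' bandwidth at which the KDE has at most `k_null` modes (binary search;
#' modes counted as local maxima on a 1024-point grid spanning the data
#' range plus 3 bandwidths). Significance is assessed by the smoothed
#' bootstrap with variance rescaling: resample the data, add
#' `Normal(0, h_crit)` noise, shrink to the original sample variance, and
#' count modes at `h_crit`; the p-value is the fraction of resamples
#' showing more than `k_null` modes.
#'
#' @param values numeric data (n >= 20, non-constant).
#' @param k_null null number of modes (1 tests unimodality).
#' @param n_boot bootstrap resamples (default 500).
#' @param seed integer seed.
#' @param tol relative tolerance of the bandwidth search (default 1e-3).
#' @return list with `h_crit` and `p`.
#' @export
silverman_test <- function(values, k_null = 1L, n_boot = 500L, seed = 1L,
                           tol = 1e-3) {
  x <- values[is.finite(values)]
  if (length(x) < 20L) stop("need at least 20 observations")
  if (sd(x) == 0) stop("constant input")
  hi <- 2 * diff(range(x))
  while (count_modes(x, hi) > k_null) hi <- hi * 2
  lo <- hi / 1e4
  while (count_modes(x, lo) <= k_null && lo > hi * 1e-12) lo <- lo / 2
  while ((hi - lo) / hi > tol) {
    mid <- (hi + lo) / 2
    if (count_modes(x, mid) <= k_null) hi <- mid else lo <- mid
  }
  h_crit <- hi
  set.seed(seed)
  n <- length(x)
  s2 <- var(x)
  shrink <- 1 / sqrt(1 + h_crit^2 / s2)
  xbar <- mean(x)
  exceed <- 0L
  for (b in seq_len(n_boot)) {
    xs <- x[sample.int(n, replace = TRUE)]
    ys <- xbar + shrink * (xs - xbar + rnorm(n, 0, h_crit))
    if (count_modes(ys, h_crit) > k_null) exceed <- exceed + 1L
  }
  list(h_crit = h_crit, p = exceed / n_boot)
}

#' Classify cell-type specificity of QTL effects across five subsets
#'
#' Restricted to features expressed (i.e. present as phenotypes) in all
#' five subsets; counts the subsets where the feature is significant at
#' `q_max` and classes the counts as `specific-1` (1 subset),
#' `intermediate-2-3` (2-3) or `shared-4-5` (4-5). Features significant
#' nowhere are reported unclassified (`none`).
#'
#' @param results_per_subset named list (length 5) of `CisQtlResult`
#'   tables.
#' @param expressed_per_subset named list (length 5) of character vectors:
#'   the features that passed the phenotype filters in each subset.
#' @param q_max significance cutoff (default 0.05).
#' @return `data.table`: `feature_id`, `n_expressed_subsets`,
#'   `n_significant_subsets`, `class`; one row per feature expressed in
#'   all five subsets. An attribute `n_excluded` counts features expressed
#'   in fewer than five.
#' @export
classify_specificity <- function(results_per_subset, expressed_per_subset,
                                 q_max = 0.05) {
  stopifnot(length(results_per_subset) == 5L,
            length(expressed_per_subset) == 5L)
  all_feats <- sort(unique(unlist(expressed_per_subset)))
  n_expr <- vapply(all_feats, function(f) {
    sum(vapply(expressed_per_subset, function(e) f %in% e, TRUE))
  }, 0L)
  common <- all_feats[n_expr == 5L]
  n_sig <- vapply(common, function(f) {
    sum(vapply(results_per_subset, function(r) {
      nrow(r[phenotype_id == f & qvalue <= q_max]) > 0L
    }, TRUE))
  }, 0L)
  cls <- ifelse(n_sig == 0L, "none",
         ifelse(n_sig == 1L, "specific-1",
         ifelse(n_sig <= 3L, "intermediate-2-3", "shared-4-5")))
  out <- data.table(feature_id = common, n_expressed_subsets = 5L,
                    n_significant_subsets = n_sig, class = cls)
  setattr(out, "n_excluded", sum(n_expr < 5L))
  out[]
}
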