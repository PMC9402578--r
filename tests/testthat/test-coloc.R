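test_that("LD r2 basics: identity, repulsion, monomorphic error", {
  g <- c(0, 1, 2, 1, 0, 2, 1, 1)
  expect_equal(ld_r2(g, g), 1)
  expect_equal(ld_r2(g, 2 - g), 1)        # |r| = 1 either sign
  expect_error(ld_r2(g, rep(1, 8)), "monomorphic")
})

test_that("independent LD blocks show near-zero r2", {
  cfg <- sim_config(seed = 13L, n_samples = 500L, n_genes = 1L,
                    n_variants_per_locus = 40L, ld_block_size = 10L)
  gt <- simulate_genotypes(cfg)
  v <- gt$variants
  pairs <- expand.grid(a = which(v$block == 1), b = which(v$block == 3))
  r2 <- mapply(function(a, b) ld_r2(gt$dosages[, a], gt$dosages[, b]),
               pairs$a, pairs$b)
  expect_gte(mean(r2 < 0.05), 0.95)
})

test_that("RTC self-correction identity: gwas = qtl variant gives rtc 1", {
  gt <- toy_genotypes(n = 80, p = 20)
  set.seed(6)
  y <- gt$dosages[, 7] + rnorm(80, 0, 0.5)
  rec <- rtc_score(y, gt, 1:20, gwas_variant = "var07", qtl_variant = "var07")
  expect_equal(rec$rank, 0L)
  expect_equal(rec$rtc, 1)
  expect_equal(rec$n_variants, 20L)
})

test_that("rtc is within [1/N, 1] and invariant to affine phenotype scaling", {
  gt <- toy_genotypes(n = 60, p = 15)
  set.seed(7)
  y <- gt$dosages[, 2] + rnorm(60, 0, 0.8)
  r1 <- rtc_score(y, gt, 1:15, "var09", "var02")
  r2 <- rtc_score(3 * y - 7, gt, 1:15, "var09", "var02")
  expect_equal(r1$rtc, r2$rtc)
  expect_gte(r1$rtc, 1 / 15)
  expect_lte(r1$rtc, 1)
})

test_that("null rtc is roughly uniform; shared causal beats independent", {
  cfg <- sim_config(seed = 14L, n_samples = 200L, n_genes = 10L,
                    n_variants_per_locus = 50L, ld_flip_prob = 0.01)
  gt <- simulate_genotypes(cfg)
  v <- gt$variants
  set.seed(99)
  null_rtc <- c(); shared_rtc <- c()
  for (rep in 1:100) {
    l <- sample(10, 1)
    vidx <- which(v$locus == l)
    causal <- sample(vidx, 1)
    y <- gt$dosages[, causal] + rnorm(200, 0, 0.5)
    lead <- cdsqtl:::select_lead(
      nominal_scan(y, gt, list(chrom = "chrS", tss = min(v$pos[vidx]),
                               tes = max(v$pos[vidx])), window = 0))
    # shared: GWAS variant = high-LD block mate of the causal variant
    mates <- setdiff(which(v$locus == l & v$block == v$block[causal]), causal)
    r2s <- vapply(mates, function(m) ld_r2(gt$dosages[, m],
                                           gt$dosages[, causal]), 0)
    mate <- mates[which.max(r2s)]
    shared_rtc <- c(shared_rtc,
                    rtc_score(y, gt, vidx, v$variant_id[mate],
                              lead$variant_id)$rtc)
    # independent: GWAS variant from a different block
    other <- sample(which(v$locus == l & v$block != v$block[causal]), 1)
    null_rtc <- c(null_rtc,
                  rtc_score(y, gt, vidx, v$variant_id[other],
                            lead$variant_id)$rtc)
  }
  expect_gt(mean(shared_rtc >= 0.8), 0.8)
  expect_lt(wilcox.test(null_rtc, shared_rtc, alternative = "less")$p.value,
            0.01)
  expect_lt(abs(mean(null_rtc) - 0.51), 0.1)
})

test_that("colocalize_catalog applies RTC and r2 thresholds per interval", {
  cfg <- sim_config(seed = 15L, n_genes = 6L, frac_low_expressed = 0)
  gt <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  effects <- setNames(c(rep("gene_eqtl", 3), rep("none", 3)),
                      names(ann$catalog$genes))
  ex <- simulate_expression(gt, ann, cfg, effects = effects)
  aux <- simulate_aux(gt, ann, ex$truth, cfg)
  sim <- list(genotypes = gt, annotation = list(catalog = ann$catalog),
              expression = ex, aux = aux)
  ph <- build_phenotypes(ex$gene_fpkm, ex$iso_fpkm, ann$catalog,
                         mode = "gene_eqtl", n_factors = 0)
  res <- suppressWarnings(
    map_cis_qtl(ph$phenotypes, sim$genotypes, ph$anchors, B = 300, seed = 1L))
  recs <- colocalize_catalog(res, ph$phenotypes, sim$genotypes,
                             sim$aux$gwas, sim$aux$intervals)
  planted <- sim$expression$truth[effect_type == "gene_eqtl"]
  expect_gt(nrow(planted), 0L)
  expect_gt(nrow(recs), 0L)
  hit <- recs[phenotype_id %in% planted$phenotype_id &
              gwas_variant_id %in% planted$causal_variant_id]
  expect_gt(nrow(hit), 0L)
  # positive-control GWAS variants colocalize with their own QTL
  expect_true(all(hit$pass))
  expect_true(all(recs$rtc >= 1 / recs$n_variants & recs$rtc <= 1))
})

test_that("pass thresholds are boundary-faithful", {
  rec <- data.table(rtc = c(0.85, 0.79, 0.8), r2 = c(0.9, 0.95, 0.8))
  rec[, pass := rtc >= 0.8 & r2 >= 0.8]
  expect_equal(rec$pass, c(TRUE, FALSE, TRUE))
})

test_that("curation enforces FDR on both sides and direction concordance", {
  irqtl <- data.table(
    phenotype_id = c("isoA", "isoB", "isoC", "isoD"),
    slope = c(1.2, 0.8, -0.5, 0.7),
    qvalue = c(0.04, 0.04, 0.04, 0.06))
  jq <- data.table(
    junction_id = paste0("J", 1:4),
    isoform_id = c("isoA", "isoB", "isoC", "isoD"),
    p = 1e-6, q = c(0.04, 0.04, 0.01, 0.01),
    slope = c(0.9, -0.3, -0.2, 0.5))
  out <- curate_signals(irqtl, jq)
  expect_equal(out$phenotype_id, c("isoA", "isoC"))  # B flips sign, D fails FDR
  # junction q above threshold excludes
  jq2 <- copy(jq)[isoform_id == "isoA", q := 0.2]
  out2 <- curate_signals(irqtl, jq2)
  expect_false("isoA" %in% out2$phenotype_id)
  expect_equal(attr(out2, "n_unmatched"), 1L)
  # integrated ids match through their members
  irqtl3 <- data.table(phenotype_id = "G::isoA+isoX", slope = 1, qvalue = 0.01)
  expect_equal(nrow(curate_signals(irqtl3, jq)), 1L)
})
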