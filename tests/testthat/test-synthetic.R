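test_that("generators are fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5L, n_genes = 4L, n_variants_per_locus = 20L)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_all(cfg, dir = d1)
  simulate_all(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("ld_flip_prob = 0 gives perfect within-block LD", {
  cfg <- sim_config(seed = 2L, n_genes = 2L, n_variants_per_locus = 20L,
                    ld_block_size = 5L, ld_flip_prob = 0)
  gt <- simulate_genotypes(cfg)
  v <- gt$variants
  for (l in unique(v$locus)) for (b in unique(v[locus == l, block])) {
    idx <- which(v$locus == l & v$block == b)
    d <- gt$dosages[, idx, drop = FALSE]
    r2 <- cor(d)^2
    expect_true(all(abs(r2 - 1) < 1e-12))
  }
})

test_that("empirical MAF concentrates near the configured frequency", {
  # binomial bound: at n = 500 (1000 alleles) the frequency estimate has
  # sd ~ 0.015, so +/- 0.05 holds for essentially all variants
  cfg <- sim_config(seed = 3L, n_samples = 500L, n_genes = 4L,
                    n_variants_per_locus = 25L, maf_range = c(0.3, 0.3))
  gt <- simulate_genotypes(cfg)
  expect_gte(mean(abs(gt$variants$maf - 0.3) <= 0.05), 0.95)
  expect_true(all(gt$variants$maf >= 0.3))  # rejection-enforced floor
})

test_that("annotation truths are recovered by the annotation module", {
  cfg <- sim_config(seed = 4L, n_genes = 10L, frac_shared_cds = 1,
                    frac_cdsi = 0, isoforms_per_gene = c(2L, 2L))
  ann <- simulate_annotation(cfg)
  g <- build_cds_groups(ann$catalog)
  multi <- g$groups[lengths(g$groups) >= 2L]
  # every gene contributes exactly one group of size 2
  expect_length(multi, 10L)
  expect_true(all(lengths(multi) == 2L))
  expect_identical(classify_cdsi(ann$catalog), character(0))

  cfg2 <- sim_config(seed = 4L, n_genes = 10L, frac_cdsi = 0.5)
  ann2 <- simulate_annotation(cfg2)
  expect_identical(classify_cdsi(ann2$catalog), ann2$cdsi_truth)
})

test_that("emitted GTF re-read equals the in-memory catalog", {
  cfg <- sim_config(seed = 6L, n_genes = 5L)
  ann <- simulate_annotation(cfg)
  path <- tempfile(fileext = ".gtf")
  write_annotation_gtf(ann$catalog, path)
  cat2 <- read_annotation(path)
  expect_equal(cat2$isoforms$tss, ann$catalog$isoforms$tss)
  expect_equal(cat2$isoforms$exons, ann$catalog$isoforms$exons)
  expect_equal(cat2$isoforms$cds_incomplete_start,
               ann$catalog$isoforms$cds_incomplete_start)
})

test_that("isoform FPKM sums to the gene FPKM by construction", {
  cfg <- sim_config(seed = 7L, n_genes = 6L)
  sim <- simulate_all(cfg)
  iso_gene <- sim$annotation$catalog$isoforms$gene_id
  sums <- rowsum(sim$expression$iso_fpkm, iso_gene)
  expect_equal(sums[rownames(sim$expression$gene_fpkm), ],
               sim$expression$gene_fpkm, tolerance = 1e-10)
})

test_that("a planted ratio effect makes the target ratio increase in dosage", {
  cfg <- sim_config(seed = 8L, n_samples = 1000L, n_genes = 2L,
                    frac_low_expressed = 0)
  gt <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  ex <- simulate_expression(gt, ann, cfg,
                            effects = c(GENE01 = "i_rqtl", GENE02 = "none"))
  tr <- ex$truth[effect_type == "i_rqtl"]
  iso <- tr$phenotype_id
  gene <- tr$gene_id
  ids <- ann$catalog$genes[[gene]]
  ratio <- ex$iso_fpkm[iso, ] / colSums(ex$iso_fpkm[ids, , drop = FALSE])
  d <- gt$dosages[, tr$causal_variant_id]
  means <- tapply(ratio, d, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
})

test_that("the within-group switch leaves gene and group totals flat", {
  cfg <- sim_config(seed = 9L, n_genes = 4L, frac_shared_cds = 1,
                    frac_cdsi = 0, isoforms_per_gene = c(3L, 3L),
                    frac_low_expressed = 0)
  gt <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  genes <- names(ann$catalog$genes)
  ex <- simulate_expression(gt, ann, cfg,
                            effects = setNames(rep("within_group_switch",
                                                   length(genes)), genes))
  tr <- ex$truth[effect_type == "within_group_switch"][1]
  pair <- ann$cds_groups_truth[[grep(tr$gene_id,
                                     names(ann$cds_groups_truth))[1]]]
  pair_tot <- colSums(ex$iso_fpkm[pair, ])
  gene_tot <- ex$gene_fpkm[tr$gene_id, ]
  d <- gt$dosages[, tr$causal_variant_id]
  # group share of the gene total uncorrelated with dosage, but the member
  # ratio strongly dosage-dependent
  expect_lt(abs(cor(pair_tot / gene_tot, d)), 0.2)
  member_ratio <- ex$iso_fpkm[pair[1], ] / pair_tot
  expect_gt(abs(cor(member_ratio, d)), 0.5)
})

test_that("aux files respect their format contracts", {
  cfg <- sim_config(seed = 10L, n_genes = 6L)
  sim <- simulate_all(cfg, dir = (d <- tempfile()))
  bed <- data.table::fread(file.path(d, "intervals.bed"), header = FALSE)
  expect_true(all(bed$V2 < bed$V3))  # 0-based half-open
  gmt <- readLines(file.path(d, "gene_sets.gmt"))
  expect_length(gmt, length(sim$aux$gene_sets))
  # GWAS positive controls sit at planted causal variants
  cis <- sim$expression$truth[effect_type %in% c("gene_eqtl", "i_rqtl", "i2_rqtl")]
  pos <- sim$aux$gwas[grepl("^trait_", trait)]
  expect_setequal(pos$variant_id, cis$causal_variant_id)
})

test_that("tiny cohorts are refused", {
  expect_error(sim_config(n_samples = 5), "n_samples")
})
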