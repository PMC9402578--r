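anchor1 <- list(chrom = "chr1", tss = 1000L, tes = 10000L)

test_that("nominal scan matches the closed-form t oracle", {
  gt <- toy_genotypes(n = 6, p = 3)
  y <- c(0.3, -1.2, 0.8, 1.9, -0.4, 0.1)
  scan <- nominal_scan(y, gt, anchor1)
  for (j in seq_len(nrow(scan))) {
    g <- gt$dosages[, scan$variant_id[j]]
    r <- cor(y, g)
    tval <- r * sqrt(4 / (1 - r^2))
    expect_equal(scan$r[j], r)
    expect_equal(scan$p[j], 2 * pt(abs(tval), df = 4, lower.tail = FALSE))
    expect_equal(scan$slope[j], unname(coef(lm(y ~ g))[2]), tolerance = 1e-10)
  }
})

test_that("perfect fit and orthogonal phenotypes hit the r extremes", {
  gt <- toy_genotypes(n = 40, p = 4)
  g1 <- gt$dosages[, 1]
  scan <- nominal_scan(2 * g1, gt, anchor1)
  expect_equal(scan[variant_id == "var01", r], 1)
  expect_lt(scan[variant_id == "var01", p], 1e-100)
  # residual of random noise on g1 is exactly orthogonal to g1
  set.seed(3)
  y <- resid(lm(rnorm(40) ~ g1))
  scan2 <- nominal_scan(y, gt, anchor1)
  expect_equal(scan2[variant_id == "var01", r], 0, tolerance = 1e-12)
  expect_equal(scan2[variant_id == "var01", p], 1, tolerance = 1e-10)
})

test_that("window and MAF exclusions apply", {
  gt <- toy_genotypes(n = 50, p = 10, pos = c(seq(1000, 8000, length.out = 9),
                                              5e6))
  y <- rnorm(50)
  scan <- nominal_scan(y, gt, anchor1, window = 1e6)
  expect_false("var10" %in% scan$variant_id)   # outside the window
  scan2 <- nominal_scan(y, gt, anchor1, maf_min = 0.9)
  expect_equal(nrow(scan2), 0L)
})

test_that("lead selection is deterministic and order-invariant", {
  gt <- toy_genotypes(n = 30, p = 6)
  # duplicate a variant so nominal p ties exactly; tie broken by position
  gt$dosages[, 5] <- gt$dosages[, 2]
  set.seed(4)
  y <- gt$dosages[, 2] + rnorm(30, 0, 0.5)
  lead <- cdsqtl:::select_lead(nominal_scan(y, gt, anchor1))
  expect_equal(lead$variant_id, "var02")
  # permute variant order: same lead
  perm <- c(4, 6, 2, 5, 1, 3)
  gt2 <- cdsqtl:::new_genotype_matrix(gt$variants[perm],
                                      gt$dosages[, perm])
  lead2 <- cdsqtl:::select_lead(nominal_scan(y, gt2, anchor1))
  expect_equal(lead2$variant_id, "var02")
})

test_that("permutation p follows the (1 + k)/(B + 1) formula and its bound", {
  gt <- toy_genotypes(n = 60, p = 8)
  y <- gt$dosages[, 3] + rnorm(60, 0, 0.3)
  res <- suppressWarnings(
    permutation_pass(y, gt, anchor1, B = 999, seed = 2L))
  expect_equal(res$perm_p, 1 / 1000)  # observed beats all 999 permutations
  expect_gte(res$perm_p, 1 / 1000)    # bound holds by construction
  set.seed(8)
  res2 <- permutation_pass(rnorm(60), gt, anchor1, B = 199, seed = 2L)
  expect_lte(res2$perm_p, 1)
  expect_warning(permutation_pass(y, gt, anchor1, B = 50, seed = 1L),
                 "B < 100")
})

test_that("null permutation p-values are uniform", {
  gt <- toy_genotypes(n = 50, p = 10)
  set.seed(31)
  pp <- replicate(400, {
    y <- rnorm(50)
    suppressWarnings(permutation_pass(y, gt, anchor1, B = 99, seed =
                                        sample.int(1e6, 1)))$perm_p
  })
  # perm_p lives on the lattice k/100; de-discretize before the KS check
  jitter <- runif(length(pp), 0, 1 / 100)
  expect_gt(suppressWarnings(ks.test(pp - jitter, "punif"))$p.value, 0.01)
})

test_that("beta fit recovers the min-of-uniforms law", {
  set.seed(17)
  minima <- apply(matrix(runif(10 * 10000), ncol = 10), 1, min)
  fit <- fit_beta_approx(minima)
  expect_true(fit$ok)
  expect_lt(abs(fit$shape1 - 1) / 1, 0.15)
  expect_lt(abs(fit$shape2 - 10) / 10, 0.15)
  # m = 1: plain uniform
  fit1 <- fit_beta_approx(runif(5000))
  expect_lt(abs(fit1$shape1 - 1), 0.15)
  expect_lt(abs(fit1$shape2 - 1), 0.15)
  # adjusted p is a CDF: monotone increasing
  grid <- seq(0.001, 0.5, length.out = 50)
  expect_true(all(diff(fit$adjust(grid)) > 0))
  # degenerate minima fall back
  expect_false(fit_beta_approx(rep(0.2, 500))$ok)
})

test_that("Storey q-values reduce to BH at pi0 = 1 and respect ordering", {
  set.seed(23)
  p <- runif(1000)
  q1 <- storey_qvalues(p, pi0 = 1)
  expect_equal(q1, p.adjust(p, "BH"))
  q <- storey_qvalues(p)
  pi0_hat <- q[which.max(p)] / max(p.adjust(p, "BH"))
  # uniform p: pi0 estimate near 1, q-values no larger than BH
  expect_true(all(q <= q1 + 1e-12))
  expect_gte(min(q / q1), 0.85)
  # non-decreasing in p
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # all-identical p with pi0 = 1: q = p (rank/m cancels)
  expect_equal(storey_qvalues(rep(0.05, 30), pi0 = 1), rep(0.05, 30))
  expect_warning(storey_qvalues(runif(10)), "fewer than 20")
})

test_that("q <= 0.05 under a global null controls empirical FDR", {
  set.seed(77)
  false_pos <- replicate(200, {
    p <- runif(200)
    sum(storey_qvalues(p) <= 0.05)
  })
  # FDR control at the global null: discoveries are rare
  expect_lte(mean(false_pos > 0), 0.10)
})

test_that("map_cis_qtl recovers a planted association end to end", {
  gt <- toy_genotypes(n = 80, p = 10)
  set.seed(5)
  pheno <- rbind(hit = gt$dosages[, 4] + rnorm(80, 0, 0.5),
                 null = rnorm(80))
  colnames(pheno) <- rownames(gt$dosages)
  anchors <- data.table(phenotype_id = c("hit", "null"), chrom = "chr1",
                        tss = 1000L, tes = 10000L)
  res <- suppressWarnings(
    map_cis_qtl(pheno, gt, anchors, B = 500, seed = 9L))
  expect_equal(res[phenotype_id == "hit", lead_variant_id], "var04")
  expect_lt(res[phenotype_id == "hit", adjusted_p], 0.01)
  expect_gt(res[phenotype_id == "null", adjusted_p], 0.05)
})
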