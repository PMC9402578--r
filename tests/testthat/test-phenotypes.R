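test_that("gene filter is strict and requires all samples", {
  m <- rbind(keep = c(0.2, 0.2, 0.2), dip = c(0.5, 0.05, 0.5),
             boundary = c(0.1, 0.2, 0.2))
  out <- filter_genes(m, 0.1)
  expect_equal(rownames(out), "keep")   # 0.05 dip and exact 0.1 both drop
})

test_that("isoform filter uses ceil(frac n) and the parent-gene gate", {
  n <- 100
  iso <- rbind(a = c(rep(2, 5), rep(0, n - 5)),    # >1 in exactly 5 samples
               b = c(rep(2, 4), rep(0, n - 4)),    # only 4
               c = rep(2, n))                      # parent gene filtered out
  colnames(iso) <- sprintf("s%d", 1:n)
  gene_of <- c(a = "G1", b = "G1", c = "G2")
  out <- filter_isoforms(iso, retained_genes = "G1", gene_of = gene_of)
  expect_equal(rownames(out), "a")
})

test_that("filters are idempotent", {
  set.seed(1)
  m <- matrix(runif(200, 0, 3), 20, 10,
              dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
  f1 <- filter_genes(m)
  expect_identical(filter_genes(f1), f1)
})

test_that("integration adds member rows and conserves column sums", {
  iso <- rbind(i1 = c(2.0, 1.0), i2 = c(1.5, 0.5), i3 = c(4, 4))
  colnames(iso) <- c("s1", "s2")
  groups <- structure(list(groups = list("G::i1+i2" = c("i1", "i2"),
                                         "G2::i3" = "i3"),
                           membership = c(i1 = "G::i1+i2", i2 = "G::i1+i2",
                                          i3 = "G2::i3"),
                           unkeyed = character(0)), class = "CdsGroupSet")
  out <- integrate_isoforms(iso, groups)
  expect_equal(out["G::i1+i2", ], c(s1 = 3.5, s2 = 1.5))
  expect_equal(out["G2::i3", ], iso["i3", ])          # singleton identity
  expect_equal(colSums(out), colSums(iso))            # partition sum
})

test_that("ratios follow the definition and 0/0 becomes missing", {
  expr <- rbind(i1 = c(3, 0), i2 = c(1, 0))
  colnames(expr) <- c("s1", "s2")
  rm <- compute_ratios(expr, c(i1 = "G", i2 = "G"))
  expect_equal(rm$ratios[, "s1"], c(i1 = 0.75, i2 = 0.25))
  expect_true(all(is.na(rm$ratios[, "s2"])))
  # per-gene sums are 1 where defined
  expect_equal(sum(rm$ratios[, "s1"]), 1, tolerance = 1e-9)
})

test_that("single-isoform genes give constant ratio 1 (dropped downstream)", {
  expr <- rbind(solo = c(2, 5, 1))
  colnames(expr) <- c("s1", "s2", "s3")
  rm <- compute_ratios(expr, c(solo = "G"))
  expect_equal(unname(rm$ratios["solo", ]), c(1, 1, 1))
  expect_warning(inverse_normal_transform(rm$ratios), "zero-variance")
})

test_that("quantile normalization matches the sort-average-map oracle", {
  m <- cbind(A = c(1, 2), B = c(2, 4))
  rownames(m) <- c("f1", "f2")
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "A"]), c(1.5, 3))
  expect_equal(unname(out[, "B"]), c(1.5, 3))
  # fixed point: identical columns unchanged
  m2 <- cbind(A = c(5, 1, 3), B = c(5, 1, 3))
  expect_equal(quantile_normalize(m2), m2)
  # column-permutation equivariance
  m3 <- matrix(rnorm(30), 5, 6, dimnames = list(NULL, sprintf("s%d", 1:6)))
  perm <- c(3, 1, 2, 6, 5, 4)
  expect_equal(quantile_normalize(m3)[, perm],
               quantile_normalize(m3[, perm]))
})

test_that("inverse normal transform follows the Blom formula", {
  m <- rbind(f = c(10, 2, 7))  # ranks 3, 1, 2 of n = 3
  colnames(m) <- sprintf("s%d", 1:3)
  out <- inverse_normal_transform(m)
  expect_equal(out["f", "s3"], 0)  # middle rank: (2 - 3/8)/3.25 = 0.5 exactly
  expect_equal(unname(out["f", ]), qnorm((c(3, 1, 2) - 3 / 8) / 3.25))
  # monotone in ranks
  expect_equal(order(out["f", ]), order(m["f", ]))
  # near-symmetry at n = 100
  set.seed(9)
  big <- matrix(rexp(100), 1, 100, dimnames = list("f", sprintf("s%d", 1:100)))
  tb <- inverse_normal_transform(big)
  expect_lt(abs(mean(tb)), 1e-9)
  expect_lt(abs(mean(tb^3)), 0.01)  # skewness ~ 0
})

test_that("latent-factor removal: identity at k = 0, annihilates rank-1", {
  set.seed(11)
  m <- matrix(rnorm(200), 10, 20)
  expect_identical(remove_latent_factors(m, k = 0), m)
  expect_error(remove_latent_factors(m, k = 20), "smaller")
  # single latent factor drives all features -> residuals ~ 0
  f <- rnorm(20)
  loadings <- rnorm(10)
  r1 <- outer(loadings, f)
  resid <- remove_latent_factors(r1, k = 1)
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("missingness handling drops high-missing features and imputes rest", {
  m <- rbind(ok = c(1, 2, NA, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16,
                    17, 18, 19, 20),
             bad = c(rep(NA, 5), rnorm(15)))
  colnames(m) <- sprintf("s%d", 1:20)
  out <- impute_missing(m, max_missing_frac = 0.05)
  expect_equal(rownames(out), "ok")
  expect_equal(out["ok", "s3"], mean(m["ok", ], na.rm = TRUE))
})

test_that("ratio phenotypes sum to one per gene after both i and i2 builds", {
  cfg <- sim_config(seed = 12L, n_genes = 8L, frac_low_expressed = 0)
  sim <- simulate_all(cfg)
  groups <- build_cds_groups(sim$annotation$catalog)
  iso <- sim$expression$iso_fpkm
  gene_of <- setNames(sim$annotation$catalog$isoforms$gene_id,
                      sim$annotation$catalog$isoforms$isoform_id)
  for (mode in c("i", "i2")) {
    m <- if (mode == "i2") integrate_isoforms(iso, groups) else iso
    gof <- if (mode == "i2") setNames(sub("::.*$", "", rownames(m)),
                                      rownames(m)) else gene_of[rownames(m)]
    rm <- compute_ratios(m, gof)
    sums <- rowsum(rm$ratios, gof[rownames(rm$ratios)])
    expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9), info = mode)
  }
})
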