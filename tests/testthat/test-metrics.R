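test_that("condition means average collapsed observations", {
  ds <- toy_dataset(cbind(c(2, 7, 1), c(4, 7, 5)), cbind(c(1, 0, 2), c(3, 0, 2)))
  cp <- condition_profile(ds, "A")
  expect_equal(unname(cp$E), c(3, 7, 3))
  # constant gene keeps its value
  expect_equal(unname(cp$E[2]), 7)
  expect_error(condition_profile(ds, "C"), "unknown condition")

  # 5-gene fixture against an independent per-row loop
  set.seed(1)
  va <- matrix(rnorm(20), 5, 4)
  ds2 <- toy_dataset(va, matrix(rnorm(10), 5, 2))
  expected <- sapply(seq_len(5), function(i) sum(va[i, ]) / 4)
  expect_equal(unname(condition_profile(ds2, "A")$E), expected)
})

test_that("replicates are averaged within time points before profiling", {
  vals <- matrix(c(1, 3, 2, 4, 10, 10, 8, 12), nrow = 2, byrow = TRUE)
  rownames(vals) <- c("g1", "g2")
  colnames(vals) <- paste0("s", 1:4)
  design <- data.frame(sample = paste0("s", 1:4), condition = "A",
                       time = c(1, 1, 2, 2), replicate = c(1, 2, 1, 2))
  ds <- expression_dataset(vals, design)
  cp <- condition_profile(ds, "A")
  expect_equal(dim(cp$profile), c(2L, 2L))
  expect_equal(unname(cp$profile["g1", ]), c(2, 3))   # (1,3) and (2,4) averaged
  expect_equal(unname(cp$profile["g2", ]), c(10, 10))
  # opting out keeps every sample as an observation
  expect_equal(ncol(condition_profile(ds, "A", collapse_replicates = FALSE)$profile), 4L)
})

test_that("differential expression subtracts condition means and is antisymmetric", {
  ds <- toy_dataset(cbind(c(5, 2), c(5, 2)), cbind(c(3, 2), c(3, 2)))
  de <- differential_expression(ds, "A", "B")
  expect_equal(unname(de), c(2, 0))
  expect_equal(differential_expression(ds, "B", "A"), -de)
  expect_error(differential_expression(ds, "A", "A"), "differ")
})

test_that("co-expression matches rank-based oracles and flags flat genes", {
  up <- c(1, 2, 3, 4, 5)
  ds <- toy_dataset(rbind(up, up * 2 + 1, -up, c(3, 1, 2, 5, 4), rep(2, 5)),
                    matrix(rnorm(15), 5, 3),
                    genes = c("inc", "inc2", "dec", "perm", "flat"))
  cm <- coexpression(ds, "A")
  expect_equal(cm$values["inc", "inc2"], 1)
  expect_equal(cm$values["inc", "dec"], -1)
  expect_equal(cm$values["inc", "perm"], naive_spearman(up, c(3, 1, 2, 5, 4)))
  expect_true(isSymmetric(cm$values))
  expect_equal(unname(diag(cm$values)), rep(1, 5))
  expect_true(all(abs(cm$values) <= 1))
  # zero-variance gene: correlations forced to 0 and recorded
  expect_equal(cm$undefined, "flat")
  expect_equal(unname(cm$values["flat", c("inc", "perm")]), c(0, 0))
  # ties handled by average ranks
  ds_tie <- toy_dataset(rbind(c(1, 1, 2, 3), c(4, 5, 6, 7)),
                        matrix(rnorm(8), 2, 4), genes = c("t1", "t2"))
  cmt <- coexpression(ds_tie, "A")
  expect_equal(cmt$values["t1", "t2"], naive_spearman(c(1, 1, 2, 3), 4:7))
})

test_that("differential co-expression reproduces the sign-flip worked example", {
  r_a <- matrix(c(1, 0.76, 0.76, 1), 2, dimnames = list(c("reg", "tgt"), c("reg", "tgt")))
  r_b <- matrix(c(1, -0.34, -0.34, 1), 2, dimnames = dimnames(r_a))
  dc <- differential_coexpression(as_cormat(r_a, "A"), as_cormat(r_b, "B"))
  expect_equal(dc$values["reg", "tgt"], 1.1)
  expect_equal(unname(diag(dc$values)), c(0, 0))
  # identical matrices difference out
  expect_true(all(differential_coexpression(as_cormat(r_a), as_cormat(r_a))$values == 0))
  # the theoretical extreme: +1 vs -1 gives the maximum of 2
  e_a <- matrix(c(1, 1, 1, 1), 2, dimnames = dimnames(r_a))
  e_b <- matrix(c(1, -1, -1, 1), 2, dimnames = dimnames(r_a))
  dmax <- differential_coexpression(as_cormat(e_a), as_cormat(e_b))
  expect_equal(dmax$values["reg", "tgt"], 2)
  expect_error(differential_coexpression(as_cormat(r_a),
                                         as_cormat(r_a[2:1, 2:1])),
               "gene sets")
})

test_that("dC is antisymmetric in condition order and bounded", {
  set.seed(42)
  for (i in 1:10) {
    ra <- as_cormat(random_cormat(8), "A")
    rb <- as_cormat(random_cormat(8), "B")
    d1 <- differential_coexpression(ra, rb)$values
    d2 <- differential_coexpression(rb, ra)$values
    expect_equal(d1, -d2)
    expect_true(all(abs(d1) <= 2))
  }
})

test_that("co-differential expression correlates dE-over-time profiles", {
  # two conditions x 4 time points, single replicate
  tt <- 1:4
  build <- function(a, b) {
    vals <- rbind(a, b)
    rownames(vals) <- c("g1", "g2")
    vals
  }
  # dE profiles: g1 rises (1,2,3,4), g2 falls (4,3,2,1) -> CdE = -1
  va <- build(5 + c(1, 2, 3, 4), 5 + c(4, 3, 2, 1))
  vb <- build(rep(5, 4), rep(5, 4))
  vals <- cbind(va, vb)
  colnames(vals) <- paste0("s", 1:8)
  design <- data.frame(sample = colnames(vals),
                       condition = rep(c("A", "B"), each = 4),
                       time = rep(tt, 2))
  ds <- expression_dataset(vals, design)
  cde <- co_differential_expression(ds, "A", "B")
  expect_equal(cde$values["g1", "g2"], -1)
  expect_equal(cde$values["g1", "g1"], 1)
  expect_equal(unname(cde$de_profiles["g1", ]), c(1, 2, 3, 4))

  # independent two-step oracle on an arbitrary 4-time-point toy
  set.seed(3)
  v2 <- matrix(rnorm(16), 2, 8,
               dimnames = list(c("g1", "g2"), paste0("s", 1:8)))
  ds2 <- expression_dataset(v2, design)
  p1 <- (v2[1, 1:4] - v2[1, 5:8])
  p2 <- (v2[2, 1:4] - v2[2, 5:8])
  expect_equal(co_differential_expression(ds2, "A", "B")$values["g1", "g2"],
               naive_spearman(p1, p2))

  # no time annotation is an error
  ds3 <- toy_dataset(matrix(rnorm(8), 2), matrix(rnorm(8), 2))
  expect_error(co_differential_expression(ds3, "A", "B"), "time")
})

test_that("PIF is abundance-weighted dE and invariant to sample relabeling", {
  ds <- toy_dataset(cbind(c(2, 3), c(2, 3)), cbind(c(4, 3), c(4, 3)))
  met <- pif(ds, "A", "B")
  expect_equal(met$A[1], 3)
  expect_equal(met$dE[1], -2)
  expect_equal(met$PIF[1], -6)
  expect_equal(met$PIF[2], 0)          # dE = 0 kills PIF regardless of abundance
  expect_equal(met$A, (met$E_A + met$E_B) / 2)
  expect_equal(met$PIF, met$A * met$dE)

  set.seed(8)
  va <- matrix(rnorm(40, 6), 10, 4)
  vb <- matrix(rnorm(40, 5), 10, 4)
  ds2 <- toy_dataset(va, vb)
  met2 <- pif(ds2, "A", "B")
  # brute-force elementwise product
  expect_equal(met2$PIF,
               (rowMeans(va) + rowMeans(vb)) / 2 * (rowMeans(va) - rowMeans(vb)))
  # permuting samples within a condition changes nothing
  ds3 <- toy_dataset(va[, c(3, 1, 4, 2)], vb, genes = met2$gene)
  expect_equal(pif(ds3, "A", "B")$PIF, met2$PIF)
  # ranking helper returns the top-|PIF| genes
  expect_equal(select_de_genes(met2, 3),
               met2$gene[order(-abs(met2$PIF))][1:3])
})

test_that("RIF matches an explicit double-loop computation", {
  sim <- simulate_dataset(simulation_spec(n_genes = 30, n_regulators = 6,
                                          n_de_targets = 8, n_modules = 3,
                                          seed = 21))
  regs <- sim$truth$regulators
  de <- sim$truth$de_genes
  res <- rif(sim$dataset, "A", "B", regulators = regs, de_genes = de)
  ref <- naive_rif(sim$dataset, regs, de, "A", "B")
  expect_equal(res$RIF1_raw, ref$rif1, tolerance = 1e-10)
  expect_equal(res$RIF2_raw, ref$rif2, tolerance = 1e-10)
  # z-scores standardize and preserve the RIF1 order
  expect_equal(mean(res$RIF1_z), 0, tolerance = 1e-12)
  expect_equal(sd(res$RIF1_z), 1, tolerance = 1e-12)
  expect_equal(order(-res$RIF1_raw), order(-res$RIF1_z))
  expect_setequal(res$RIF1_rank, seq_along(regs))
  expect_setequal(res$RIF2_rank, seq_along(regs))
})

test_that("a regulator that is itself a DE gene skips its self-pair", {
  sim <- simulate_dataset(simulation_spec(n_genes = 20, n_regulators = 4,
                                          n_de_targets = 5, n_modules = 2,
                                          seed = 5))
  regs <- sim$truth$regulators
  de <- c(sim$truth$de_genes, regs[2])   # overlap
  res <- rif(sim$dataset, "A", "B", regulators = regs, de_genes = de)
  ref <- naive_rif(sim$dataset, regs, de, "A", "B")  # oracle drops self too
  expect_equal(res$RIF1_raw, ref$rif1, tolerance = 1e-10)
  expect_equal(res$RIF2_raw, ref$rif2, tolerance = 1e-10)
})

test_that("RIF1 averages, so cloned DE genes do not inflate it", {
  # three DE genes carrying identical values equal one of them
  set.seed(11)
  base_a <- matrix(rnorm(20, 6), 5, 4)
  base_b <- matrix(rnorm(20, 5), 5, 4)
  va <- rbind(base_a, base_a[5, ], base_a[5, ])
  vb <- rbind(base_b, base_b[5, ], base_b[5, ])
  genes <- c(paste0("g", 1:5), "g5copy1", "g5copy2")
  ds <- toy_dataset(va, vb, genes = genes)
  one <- rif(ds, "A", "B", regulators = "g1", de_genes = "g5")
  three <- rif(ds, "A", "B", regulators = "g1",
               de_genes = c("g5", "g5copy1", "g5copy2"))
  expect_equal(three$RIF1_raw, one$RIF1_raw, tolerance = 1e-12)
  expect_equal(three$RIF2_raw, one$RIF2_raw, tolerance = 1e-12)
})

test_that("an exact sign flip at equal abundance is invisible to RIF2", {
  # target: r = +1 in A, -1 in B, with E_A = E_B = 2
  reg_a <- c(1, 2, 3); reg_b <- c(1, 2, 3)
  tgt_a <- c(1, 2, 3); tgt_b <- c(3, 2, 1)
  ds <- toy_dataset(rbind(reg_a, tgt_a), rbind(reg_b, tgt_b),
                    genes = c("reg", "tgt"))
  res <- rif(ds, "A", "B", regulators = "reg", de_genes = "tgt")
  expect_equal(res$RIF2_raw, 0)
  # the e_r2 variant sees it even less: E r^2 identical across conditions
  res2 <- rif(ds, "A", "B", regulators = "reg", de_genes = "tgt",
              rif2_form = "e_r2")
  expect_equal(res2$RIF2_raw, 0)
})

test_that("RIF input validation rejects broken gene lists", {
  sim <- simulate_dataset(simulation_spec(n_genes = 15, n_regulators = 3,
                                          n_de_targets = 4, n_modules = 2,
                                          seed = 2))
  expect_error(rif(sim$dataset, "A", "B", regulators = "nope",
                   de_genes = sim$truth$de_genes), "absent")
  expect_error(rif(sim$dataset, "A", "B", regulators = sim$truth$regulators,
                   de_genes = "missing_gene"), "absent")
  expect_error(rif(sim$dataset, "A", "B", regulators = character(),
                   de_genes = sim$truth$de_genes), "empty")
  expect_warning(rif(sim$dataset, "A", "B", de_genes = sim$truth$de_genes),
                 "all genes")
})
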