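test_that("the regulator catalogue partitions 21 genes into 8/11/2 roles", {
  reg <- m6a_regulators()
  expect_equal(nrow(reg), 21L)
  expect_equal(sum(reg$role == "writer"), 8L)
  expect_equal(sum(reg$role == "reader"), 11L)
  expect_equal(sum(reg$role == "eraser"), 2L)
  expect_true(all(c("METTL3", "YTHDF3", "FTO", "ALKBH5", "VIRMA") %in% reg$gene))
})

test_that("pearson r and p match first-principles oracles", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  x6 <- c(1, 2, 3, 4, 5, 6); y6 <- c(1, 2, 3, 4, 5, 7)
  expect_equal(pearson_r(x6, y6), pearson_oracle(x6, y6), tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")

  expect_equal(pearson_p(0, 10), 1)
  expect_equal(pearson_p(1, 6), 0)
  # r = 0.95 at n = 6: t = 6.085 on 4 df
  p95 <- pearson_p(0.95, 6)
  expect_lt(p95, 0.01)
  expect_equal(p95, 2 * pt(-0.95 * sqrt(4 / (1 - 0.95^2)), 4), tolerance = 1e-12)
  expect_error(pearson_p(0.5, 2), "n >= 3")

  set.seed(13)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    r <- pearson_r(a, b)
    expect_equal(r, pearson_oracle(a, b), tolerance = 1e-10)
    t <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(pearson_p(r, n), 2 * (1 - pt(abs(t), n - 2)), tolerance = 1e-10)
  }
})

test_that("the m6A screen retains the planted pair and rejects decoys", {
  params <- simulation_params(seed = 53L)
  sim <- simulate_discovery_profile(params)
  # DELs = the paired lncRNAs plus 20 non-differential decoy lncRNAs,
  # which are independent of every regulator
  decoys <- setdiff(rownames(sim$profile$values)[
    sim$profile$feature_class == "lncRNA"], sim$truth$de_lncrna$id)[1:20]
  dels <- data.frame(feature_id = c(sim$truth$m6a_pairs$lncrna, decoys),
                     feature_class = "lncRNA", trend = "up")
  res <- screen_m6a_lncrnas(sim$profile, dels, m6a_regulators(),
                            threshold_config(), retain_only = FALSE)
  for (i in seq_len(nrow(sim$truth$m6a_pairs))) {
    expect_true(any(res$pass & res$lncrna == sim$truth$m6a_pairs$lncrna[i] &
                      res$regulator == sim$truth$m6a_pairs$regulator[i]))
  }
  # decoy x regulator pairs are null; their joint pass rate stays at the
  # nominal 1% (20 decoys x 21 regulators = 420 null tests, so a handful
  # of chance passes is expected, not zero)
  n_null <- sum(res$lncrna %in% decoys)
  n_pass <- sum(res$pass & res$lncrna %in% decoys)
  expect_lte(n_pass, qbinom(0.999, n_null, 0.01))
})

test_that("pass/fail is invariant under affine rescaling of a row", {
  params <- simulation_params(seed = 59L)
  sim <- simulate_discovery_profile(params)
  dels <- data.frame(feature_id = sim$truth$m6a_pairs$lncrna,
                     feature_class = "lncRNA", trend = "up")
  base <- screen_m6a_lncrnas(sim$profile, dels, m6a_regulators(),
                             threshold_config(), retain_only = FALSE)
  scaled <- sim$profile
  l1 <- dels$feature_id[1]
  scaled$values[l1, ] <- 7.3 * scaled$values[l1, ] + 2.1
  res <- screen_m6a_lncrnas(scaled, dels, m6a_regulators(),
                            threshold_config(), retain_only = FALSE)
  expect_equal(res$pass, base$pass)
  expect_equal(res$pcc, base$pcc, tolerance = 1e-9)
})

test_that("strict cutoffs exclude a pair at exactly |PCC| = 0.9", {
  cfg <- threshold_config()
  expect_false(0.9 > cfg$pcc_cut)
  # and a constant regulator is skipped without error
  vals <- matrix(c(1, 2, 3, 4, 5, 6,
                   2, 4, 6, 8, 10, 12,
                   5, 5, 5, 5, 5, 5), nrow = 3, byrow = TRUE,
                 dimnames = list(c("L1", "YTHDF3", "METTL3"), paste0("s", 1:6)))
  p <- expression_profile(
    vals, c(L1 = "lncRNA", YTHDF3 = "m6A-regulator", METTL3 = "m6A-regulator"),
    setNames(c(rep("case", 3), rep("control", 3)), paste0("s", 1:6)))
  dels <- data.frame(feature_id = "L1", feature_class = "lncRNA", trend = "up")
  warns <- capture_warnings(
    res <- screen_m6a_lncrnas(p, dels, m6a_regulators(), threshold_config()))
  expect_true(any(grepl("METTL3", warns)))
  expect_equal(res$lncrna, "L1")
  expect_equal(res$regulator, "YTHDF3")
  expect_equal(res$pcc, 1)
})

test_that("the joint 0.9/0.01 screen is calibrated under the null", {
  # ~10,000 independent (lncRNA, regulator) pairs at n = 6
  params <- simulation_params(n_lncrna = 477L, n_mrna = 0L, n_de_each = 0L,
                              n_m6a_pairs = 0L, n_triangles = 0L, seed = 61L)
  sim <- simulate_discovery_profile(params)
  dels <- data.frame(
    feature_id = rownames(sim$profile$values)[
      sim$profile$feature_class == "lncRNA"],
    feature_class = "lncRNA", trend = "up")
  res <- screen_m6a_lncrnas(sim$profile, dels, m6a_regulators(),
                            threshold_config(), retain_only = FALSE)
  expect_gte(nrow(res), 10000L)
  frac <- mean(res$pass)
  # nominal pass probability is 0.01; allow binomial sampling error
  # (upper 99.9% quantile of Binom(n, 0.01)/n)
  bound <- qbinom(0.999, nrow(res), 0.01) / nrow(res)
  expect_lte(frac, bound)
})

test_that("module extraction returns the planted four-node configuration", {
  # hand-built fixture mirroring the published module geometry: one
  # m6A-correlated lncRNA with ceRNA degree 5, one gene with PPI degree 36,
  # exactly one shared miRNA
  dels <- data.frame(feature_id = c("LINC1", "LINC2"), feature_class = "lncRNA",
                     trend = "up")
  demis <- data.frame(feature_id = paste0("mir", 1:5), feature_class = "miRNA",
                      trend = "down")
  dems <- data.frame(feature_id = paste0("G", 1:6), feature_class = "mRNA",
                     trend = "up")
  inter <- rbind(
    data.frame(mirna = paste0("mir", 1:5), target = "LINC1",
               target_class = "lncRNA", source = "x"),
    data.frame(mirna = "mir1", target = "LINC2", target_class = "lncRNA",
               source = "x"),
    data.frame(mirna = paste0("mir", 1:5), target = paste0("G", 2:6),
               target_class = "mRNA", source = "x"),
    data.frame(mirna = "mir1", target = "G1", target_class = "mRNA",
               source = "x"))
  net <- assemble_cerna(dels, demis, dems, inter)
  expect_equal(unname(m6acerna:::cerna_degrees(net)["LINC1"]), 5L)
  ppi_deg <- data.frame(gene = paste0("G", 1:6), degree = c(36L, rep(3L, 5)))
  cors <- data.frame(lncrna = c("LINC1", "LINC1"),
                     regulator = c("YTHDF3", "METTL3"),
                     pcc = c(0.95, 0.92), p_value = c(0.004, 0.009), n = 6)
  mod <- extract_m6a_module(net, ppi_deg, cors)
  expect_equal(mod$lncrna, "LINC1")
  expect_equal(mod$mrna, "G1")
  expect_equal(mod$mirna, "mir1")
  expect_equal(mod$regulator, "YTHDF3")   # maximal |PCC|
  expect_equal(mod$pcc, 0.95)
  expect_equal(mod$lncrna_cerna_degree, 5L)
  expect_equal(mod$mrna_ppi_degree, 36L)

  # eligibility: if the top-degree lncRNA is not m6A-related, the top
  # m6A-related one is chosen instead
  cors2 <- data.frame(lncrna = "LINC2", regulator = "FTO", pcc = 0.93,
                      p_value = 0.007, n = 6)
  mod2 <- extract_m6a_module(net, ppi_deg, cors2)
  expect_equal(mod2$lncrna, "LINC2")
  expect_equal(mod2$mirna, "mir1")

  # determinism: identical inputs give identical modules
  expect_identical(extract_m6a_module(net, ppi_deg, cors),
                   extract_m6a_module(net, ppi_deg, cors))
})

test_that("shared-miRNA ties break lexicographically and absence is an error", {
  dels <- data.frame(feature_id = "L1", feature_class = "lncRNA", trend = "up")
  demis <- data.frame(feature_id = c("mA", "mB"), feature_class = "miRNA",
                      trend = "down")
  dems <- data.frame(feature_id = "G1", feature_class = "mRNA", trend = "up")
  inter <- data.frame(mirna = c("mA", "mB", "mA", "mB"),
                      target = c("L1", "L1", "G1", "G1"),
                      target_class = c("lncRNA", "lncRNA", "mRNA", "mRNA"),
                      source = "x")
  net <- assemble_cerna(dels, demis, dems, inter)
  ppi_deg <- data.frame(gene = "G1", degree = 10L)
  cors <- data.frame(lncrna = "L1", regulator = "WTAP", pcc = 0.99,
                     p_value = 1e-4, n = 6)
  mod <- extract_m6a_module(net, ppi_deg, cors)
  expect_equal(mod$mirna, "mA")

  # two disjoint motifs: chosen lncRNA and top-PPI mRNA share no miRNA
  dels2 <- data.frame(feature_id = c("L1", "L2"), feature_class = "lncRNA",
                      trend = "up")
  dems2 <- data.frame(feature_id = c("G1", "G2"), feature_class = "mRNA",
                      trend = "up")
  inter2 <- data.frame(mirna = c("mA", "mA", "mB", "mB"),
                       target = c("L1", "G1", "L2", "G2"),
                       target_class = c("lncRNA", "mRNA", "lncRNA", "mRNA"),
                       source = "x")
  net2 <- assemble_cerna(dels2, demis, dems2, inter2)
  ppi_deg2 <- data.frame(gene = c("G1", "G2"), degree = c(1L, 30L))
  expect_error(extract_m6a_module(net2, ppi_deg2, cors), "no miRNA shared")
})

test_that("attach_regulators adds typed nodes with correlated edges", {
  net <- minimal_motif()
  cors <- data.frame(lncrna = c("L1", "L1"), regulator = c("YTHDF3", "FTO"),
                     pcc = c(0.95, -0.93), p_value = c(0.004, 0.006), n = 6)
  ann <- attach_regulators(net, cors)
  regs <- ann$nodes[ann$nodes$type == "m6A-regulator", ]
  expect_equal(nrow(regs), 2L)
  ce <- ann$edges[ann$edges$label == "correlated", ]
  expect_equal(nrow(ce), 2L)
  expect_setequal(ce$pcc, c(0.95, -0.93))
  # no retained pair for the seed: network unchanged
  none <- attach_regulators(net, cors[0, ])
  expect_equal(none$nodes, net$nodes)
})
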