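test_that("log2 fold change follows the ratio-of-means definition", {
  expect_equal(log2_fold_change(c(8, 8), c(2, 2), pseudocount = 0), 2)
  expect_equal(log2_fold_change(c(5, 5), c(5, 5), pseudocount = 0), 0)
  expect_equal(log2_fold_change(c(0, 0), c(3, 5), pseudocount = 1), log2(1 / 5))
  expect_error(log2_fold_change(numeric(0), c(1, 2)), "non-empty")
})

test_that("BH adjustment matches the step-up oracle exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("adjusted values never fall below raw values and stay in [0,1]", {
  set.seed(11)
  for (i in 1:20) {
    p <- runif(15)
    a <- bh_adjust(p)
    expect_true(all(a >= p - 1e-12))
    expect_true(all(a <= 1))
  }
})

test_that("the screen recovers a planted 3-log2 shift at 3 vs 3", {
  # 50 planted among 500 null mRNAs, within-group sd 0.2 on the log2 scale
  params <- simulation_params(n_lncrna = 0L, n_mrna = 550L, n_de_each = 50L,
                              noise_sd = 0.2, n_m6a_pairs = 0L,
                              n_triangles = 0L, seed = 101L)
  sim <- simulate_discovery_profile(params)
  de <- screen_differential(sim$profile, threshold_config())
  planted <- sim$truth$de_mrna$id
  recovered <- intersect(de$feature_id, planted)
  false_pos <- setdiff(de$feature_id, planted)
  expect_gte(length(recovered), 45L)
  expect_lte(length(false_pos), 5L)
  # trends match the planted direction
  tr <- merge(de, sim$truth$de_mrna, by.x = "feature_id", by.y = "id")
  expect_true(all(tr$trend.x == tr$trend.y))
})

test_that("identical groups yield an empty screen and boundary is strict", {
  vals <- matrix(rep(c(4, 4, 4, 4), each = 5), nrow = 5,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  p <- expression_profile(vals, setNames(rep("mRNA", 5), rownames(vals)),
                          setNames(c("case", "case", "control", "control"),
                                   colnames(vals)))
  expect_equal(nrow(screen_differential(p)), 0L)
  all_stats <- screen_differential(p, retain_only = FALSE)
  expect_true(all(all_stats$p_raw == 1))  # degenerate equal-mean rule

  # |log2FC| exactly 1 with tiny P must be excluded: ratio of means 2 exactly
  eps <- 2^-20  # dyadic offset keeps the group means exactly 8 and 4
  vals2 <- matrix(c(8 - eps, 8 + eps, 4 - eps, 4 + eps), 1, 4,
                  dimnames = list("exact", paste0("s", 1:4)))
  p2 <- expression_profile(vals2, c(exact = "mRNA"),
                           setNames(c("case", "case", "control", "control"),
                                    paste0("s", 1:4)))
  res <- screen_differential(p2, threshold_config(), pseudocount = 0,
                             retain_only = FALSE)
  expect_identical(res$log2fc, 1)
  expect_false(res$retained[1])
})

test_that("welch p values agree with stats::t.test on non-degenerate rows", {
  set.seed(3)
  case <- matrix(rnorm(30, 5), 10, 3)
  ctrl <- matrix(rnorm(30, 5), 10, 3)
  mine <- m6acerna:::welch_row_p(case, ctrl)
  ref <- vapply(1:10, function(i) t.test(case[i, ], ctrl[i, ])$p.value,
                numeric(1))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("a pure-null screen keeps false positives under BH control", {
  fps <- vapply(1:5, function(s) {
    params <- simulation_params(n_lncrna = 0L, n_mrna = 1000L, n_de_each = 0L,
                                n_m6a_pairs = 0L, n_triangles = 0L,
                                seed = 200L + s)
    sim <- simulate_discovery_profile(params)
    nrow(screen_differential(sim$profile))
  }, numeric(1))
  # with no true effects BH controls the expected FP fraction at alpha
  expect_lte(mean(fps) / 1000, 0.05)
})

test_that("miRNA evidence pooling applies support and contradiction rules", {
  ev <- data.frame(
    mirna = c("miR-A", "miR-A", "miR-B", "miR-B", "miR-C"),
    study = c("S1", "S2", "S1", "S2", "S1"),
    location = "placenta",
    trend = c("up", "up", "up", "down", "down"))
  out <- pool_mirna_evidence(ev, threshold_config(min_support = 2))
  expect_equal(out$feature_id, "miR-A")
  expect_equal(out$trend, "up")
  expect_equal(out$n_support, 2L)
  # retained trends never contradict any retained input record
  for (id in out$feature_id) {
    expect_true(all(ev$trend[ev$mirna == id] == out$trend[out$feature_id == id]))
  }
  out1 <- pool_mirna_evidence(ev, threshold_config(min_support = 1))
  expect_setequal(out1$feature_id, c("miR-A", "miR-C"))  # miR-B contradictory
})

test_that("the packaged literature evidence table pools to its printed trends", {
  ev <- gdm_mirna_evidence()
  expect_true(all(c("mirna", "study", "location", "trend") %in% names(ev)))
  out <- pool_mirna_evidence(ev, threshold_config(min_support = 1))
  # every miRNA in the table is reported by a single study, so none is
  # contradictory and all are retained at min_support = 1
  expect_setequal(out$feature_id, unique(ev$mirna))
  expect_equal(out$trend[out$feature_id == "miR-33a"], "down")
  expect_equal(out$trend[out$feature_id == "miR-503"], "up")
  expect_equal(out$trend[out$feature_id == "miR-210-3p"], "up")
  expect_equal(out$trend[out$feature_id == "miR-210-5p"], "down")
})

test_that("ddCt fold change reproduces hand-computed values and inverts", {
  expect_equal(ddct_fold_change(11, 10, 12, 10), 2)   # dCt 1 vs 2
  expect_equal(ddct_fold_change(10, 8, 12, 10), 1)    # identical dCt
  expect_equal(ddct_fold_change(20, 15, 24, 16), 8)   # 2^-(5-8)
  expect_error(ddct_fold_change(Inf, 10, 12, 10), "finite")
  set.seed(5)
  for (i in 1:20) {
    ct <- runif(4, 10, 30)
    fwd <- ddct_fold_change(ct[1], ct[2], ct[3], ct[4])
    rev <- ddct_fold_change(ct[3], ct[4], ct[1], ct[2])
    expect_equal(fwd * rev, 1, tolerance = 1e-12)
  }
})
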