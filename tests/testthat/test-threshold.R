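sweep_fixture <- function(n_sites = 2000, fp_per_kb = 2, seed = 101) {
  iv <- interval_set("chr1", 0, 400000)
  truth <- gen_truth_callset(n_sites, iv, snv_frac = 1, seed = seed)
  test <- corrupt(truth, confusion_model(p_miss = 0.02,
                                         fp_per_kb = fp_per_kb),
                  scores = score_model(), intervals = iv, seed = seed + 1)
  list(iv = iv, truth = truth, test = test)
}

test_that("sweep endpoints: no threshold removes nothing, +Inf removes all", {
  fx <- sweep_fixture(400, fp_per_kb = 0.5)
  lo <- min(fx$test$vqslod) - 1
  hi <- max(fx$test$vqslod) + 1
  pc <- pr_sweep(fx$test, fx$truth, fx$iv, vtype = "SNV",
                 thresholds = c(lo, hi))
  expect_equal(pc$n_pass[1], nrow(fx$test))
  # at -Inf the sweep equals the unfiltered comparison
  unfiltered <- compare_callsets(fx$truth, fx$test, fx$iv,
                                 truth_exhaustive = TRUE)
  expect_equal(pc$nrc[1], unfiltered$nrc)
  expect_equal(pc$precision[1], unfiltered$precision)
  # above the max score: nothing passes
  expect_equal(pc$n_pass[2], 0L)
  expect_equal(pc$nrc[2], 0)
  expect_true(is.na(pc$precision[2]))
})

test_that("n_pass and nrc are monotone along every sweep", {
  for (s in c(103, 104, 105)) {
    fx <- sweep_fixture(800, seed = s)
    pc <- pr_sweep(fx$test, fx$truth, fx$iv, vtype = "SNV")
    expect_true(all(diff(pc$threshold) > 0))
    expect_true(all(diff(pc$n_pass) <= 0))
    expect_true(all(diff(pc$nrc) <= 1e-12))
    expect_lte(nrow(pc), 200)
  }
})

test_that("empirical curve tracks the closed-form score-mixture ROC", {
  sm <- score_model(true_mean = 4, true_sd = 1.5,
                    artifact_mean = -2, artifact_sd = 1.5)
  fx <- sweep_fixture(4000, fp_per_kb = 10, seed = 107)
  thr <- seq(-6, 8, by = 0.5)
  pc <- pr_sweep(fx$test, fx$truth, fx$iv, vtype = "SNV", thresholds = thr)
  latent <- attr(fx$test, "latent")
  n_true <- sum(latent$status %in% c("kept", "gterr", "filtered"))
  n_fp <- sum(latent$status == "fp")
  roc <- score_model_roc(sm, thr, n_true, n_fp)
  n_truth <- nrow(fx$truth)
  # NRC(t) = P(score_true >= t) * (called fraction); envelope ~ KS bound
  env <- 1.5 * sqrt(log(2 / 0.01) / (2 * n_truth))
  expect_lt(max(abs(pc$nrc - roc$pass_true_frac * n_true / n_truth)), env)
  ok <- !is.na(pc$precision)
  expect_lt(max(abs(pc$precision[ok] - roc$precision[ok])), 0.05)
})

test_that("perfectly separated scores attain precision 1 at maximal nrc", {
  truth <- mk_callset(1:50)
  df <- tibble::as_tibble(truth)[, c("chrom", "pos", "ref", "alt", "gclass",
                                     "filter")]
  df <- rbind(df, data.frame(chrom = "chr1", pos = 1001:1010, ref = "A",
                             alt = "G", gclass = "HET", filter = "PASS"))
  df$vqslod <- c(rep(10, 50), rep(-10, 10))
  test <- callset(df, sample = "S1")
  pc <- pr_sweep(test, truth, thresholds = c(-20, 0, 20))
  expect_equal(pc$precision[2], 1)
  expect_equal(pc$nrc[2], 1)
})

test_that("operating point reflects the stored FILTER and lies on the curve", {
  truth <- mk_callset(1:40)
  df <- tibble::as_tibble(truth)[, c("chrom", "pos", "ref", "alt", "gclass",
                                     "filter")]
  df$vqslod <- seq(-4, 4, length.out = 40)
  df$filter <- ifelse(df$vqslod >= 0, "PASS", "LowQual")  # pure score cut
  test <- callset(df, sample = "S1")
  pc <- pr_sweep(test, truth, thresholds = seq(-5, 5, by = 1))
  op <- attr(pc, "operating_point")
  expect_equal(op$n_pass, sum(df$vqslod >= 0))
  expect_true(op$nrc <= max(pc$nrc) && op$nrc >= min(pc$nrc))
  i <- findInterval(0, pc$threshold)
  expect_true(op$n_pass <= pc$n_pass[i] && op$n_pass >= pc$n_pass[i + 1])
})

test_that("marginal ratio flags the density crossing of the mixture", {
  # symmetric equal-sd mixture: densities cross midway between the means
  fx <- sweep_fixture(5000, fp_per_kb = 13, seed = 109)
  # equal expected counts of true and artifact calls make the crossing
  # sit near (4 + -2)/2 = 1
  pc <- pr_sweep(fx$test, fx$truth, fx$iv, vtype = "SNV",
                 thresholds = seq(-6, 8, by = 0.7))
  mr <- marginal_ratio(pc)
  expect_equal(nrow(mr), nrow(pc) - 1)
  flagged <- mr[mr$brackets_unity, ]
  expect_equal(nrow(flagged), 1)
  mid <- (flagged$threshold_lo + flagged$threshold_hi) / 2
  expect_lt(abs(mid - 1), 1.5)
})

test_that("all-agreeing sweeps have infinite marginal ratio", {
  truth <- mk_callset(1:30)
  df <- tibble::as_tibble(truth)[, c("chrom", "pos", "ref", "alt", "gclass",
                                     "filter")]
  df$vqslod <- seq_len(30)
  test <- callset(df, sample = "S1")
  pc <- pr_sweep(test, truth, thresholds = c(0, 10, 20))
  mr <- marginal_ratio(pc)
  expect_true(all(mr$ratio[mr$delta_tp > 0] == Inf))
  # single-point curve -> empty table
  pc1 <- pr_sweep(test, truth, thresholds = 5)
  expect_equal(nrow(marginal_ratio(pc1)), 0)
})

test_that("score-missing calls are excluded and counted", {
  truth <- mk_callset(1:10)
  df <- tibble::as_tibble(truth)[, c("chrom", "pos", "ref", "alt", "gclass",
                                     "filter")]
  df$vqslod <- c(rnorm(7), NA, NA, NA)
  test <- callset(df, sample = "S1")
  pc <- pr_sweep(test, truth, thresholds = -10)
  expect_equal(attr(pc, "n_unscored"), 3L)
  expect_equal(pc$n_pass, 7L)
  df$vqslod <- NA_real_
  expect_error(pr_sweep(callset(df, sample = "S1"), truth),
               "no scored")
})
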