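panel_truth <- function(n_nonref, n_refconf = 0) {
  n <- n_nonref + n_refconf
  callset(tibble::tibble(
    chrom = "chr1", pos = seq_len(n) * 10L, ref = "A", alt = "G",
    gclass = c(rep("HET", n_nonref), rep("HOMREF", n_refconf)),
    status = c(rep("nonref", n_nonref), rep("ref-confirmed", n_refconf))),
    replicate_id = "panel", sample = "NA12878", assay = "panel")
}

panel_test <- function(truth, call_idx, diff_idx = integer(),
                       extra_pos = integer(), gt_swap_idx = integer()) {
  keep <- tibble::as_tibble(truth)[call_idx, c("chrom", "pos", "ref", "alt",
                                               "gclass", "filter")]
  keep$alt[match(diff_idx, call_idx)] <- "T"
  sw <- match(gt_swap_idx, call_idx)
  keep$gclass[sw] <- "HOMALT"
  if (length(extra_pos)) {
    keep <- rbind(keep, data.frame(chrom = "chr1", pos = extra_pos,
                                   ref = "A", alt = "C", gclass = "HET",
                                   filter = "PASS"))
  }
  callset(keep, replicate_id = "test", sample = "NA12878")
}

test_that("site categories partition the truth set and tallies reconcile", {
  truth <- panel_truth(10, n_refconf = 2)
  # 6 exact, 1 different allele, 3 missed; 1 FP at a ref-confirmed site,
  # 1 FP elsewhere
  test <- panel_test(truth, call_idx = 1:7, diff_idx = 7,
                     extra_pos = c(110L, 555L))
  tal <- site_eval(truth, test)
  expect_equal(tal$tp, 6)
  expect_equal(tal$diff_allele, 1)
  expect_equal(tal$fn, 3)
  expect_equal(tal$tn, 1)
  expect_equal(tal$fp_ep, 2)
  # SiteTally invariants
  expect_equal(tal$tp + tal$fn + tal$diff_allele, 10)
  expect_equal(tal$n_variants, tal$tp + tal$fp_ep + tal$diff_allele)
  expect_equal(tal$sensitivity, 7 / 10)
  expect_equal(tal$specificity, 1 / 2)
  # each truth site in exactly one category
  sites <- attr(tal, "sites")
  expect_equal(nrow(sites), 12)
  expect_true(all(table(sites$category)[c("tp", "diff_allele", "fn",
                                          "tn")] == c(6, 1, 3, 1),
                  na.rm = TRUE))
})

test_that("sensitivity >= NRC and genotype errors hit only NRC", {
  truth <- panel_truth(10)
  test <- panel_test(truth, call_idx = 1:9, gt_swap_idx = c(8, 9))
  tal <- site_eval(truth, test)
  expect_equal(tal$sensitivity, 9 / 10)
  expect_equal(tal$nrc, 7 / 10)
  expect_gte(tal$sensitivity, tal$nrc)
  # empty test callset
  empty <- callset(tibble::tibble(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  gclass = character()), sample = "NA12878")
  tal0 <- site_eval(truth, empty)
  expect_equal(tal0$fn, 10)
  expect_equal(tal0$sensitivity, 0)
})

test_that("FILTERED test calls count as not called at panel sites", {
  truth <- panel_truth(3)
  test <- callset(tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L),
                                 ref = "A", alt = "G", gclass = "HET",
                                 filter = c("PASS", "LowQual", "PASS")),
                  sample = "NA12878")
  tal <- site_eval(truth, test)
  expect_equal(tal$tp, 2)
  expect_equal(tal$fn, 1)
})

test_that("printed panel sensitivities follow from the count columns", {
  # exome and genome replicate rows: (tp, fn, diff) -> printed %
  rows <- list(
    list(40, 3, 0, 93.0), list(37, 6, 0, 86.0), list(39, 4, 0, 90.7),
    list(54, 8, 1, 87.3), list(55, 7, 1, 88.9), list(52, 10, 1, 84.1),
    list(53, 9, 1, 85.7))
  for (r in rows) {
    expect_equal(round(100 * site_sensitivity(r[[1]], r[[2]], r[[3]]), 1),
                 r[[4]])
  }
})

test_that("fn_report annotates homopolymers and per-replicate recovery", {
  ctx <- gen_reference_context(400, homopolymer_spec = data.frame(
    at = 99, base = "A", len = 10), seed = 5)
  anchor <- substr(ctx$seq, 99, 99)
  snv_ref <- substr(ctx$seq, 200, 200)
  snv_alt <- setdiff(c("A", "C", "G", "T"), snv_ref)[1]
  truth <- callset(tibble::tibble(
    chrom = "chr1", pos = c(99L, 200L),
    ref = c(paste0(anchor, "A"), snv_ref),
    alt = c(anchor, snv_alt), gclass = "HET", status = "nonref"),
    sample = "NA12878", assay = "panel")
  # replicate 1 calls the SNV only; replicates 2-3 call nothing
  rep1 <- callset(tibble::as_tibble(truth)[2, c("chrom", "pos", "ref",
                                                "alt", "gclass", "filter")],
                  replicate_id = "r1", sample = "NA12878")
  empty <- callset(tibble::tibble(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  gclass = character()),
                   replicate_id = "r2", sample = "NA12878")
  tal <- site_eval(truth, empty)
  rep_list <- list(rep1, empty, empty)
  fr <- fn_report(tal, ctx, replicates = rep_list)
  expect_equal(nrow(fr), 2)
  del <- fr[fr$pos == 99, ]
  expect_equal(del$hp_len, 10L)
  expect_true(del$homopolymer)
  expect_equal(del$called_in, "0/3")
  snv <- fr[fr$pos == 200, ]
  expect_false(snv$homopolymer)
  expect_equal(snv$called_in, "1/3")
})

test_that("truth records without a status are rejected", {
  truth <- mk_callset(1:3)
  expect_error(site_eval(truth, mk_callset(1:2)), "status")
})
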