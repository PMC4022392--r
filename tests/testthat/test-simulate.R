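test_that("reference context generator honors tract specs and determinism", {
  spec <- data.frame(at = 50, base = "A", len = 13)
  ctx <- gen_reference_context(200, spec, seed = 11)
  bases <- strsplit(ctx$seq, "")[[1]]
  expect_true(all(bases[51:63] == "A"))
  expect_true(bases[50] != "A" && bases[64] != "A")
  # empty spec: background runs stay below the flag threshold
  ctx2 <- gen_reference_context(50000, seed = 12)
  expect_lt(max(rle(strsplit(ctx2$seq, "")[[1]])$lengths), 10)
  # determinism
  expect_identical(gen_reference_context(500, spec, seed = 13)$seq,
                   gen_reference_context(500, spec, seed = 13)$seq)
  expect_error(gen_reference_context(100, data.frame(
    at = c(10, 15), base = "A", len = c(10, 10)), seed = 1), "overlap")
  expect_error(gen_reference_context(20, data.frame(
    at = 15, base = "A", len = 10), seed = 1), "outside")
})

test_that("truth generator delivers requested composition", {
  iv <- interval_set("chr1", 0, 60000)
  cs <- gen_truth_callset(100, iv, snv_frac = 1, seed = 15)
  expect_equal(nrow(cs), 100)
  expect_true(all(cs$vclass == "SNV"))
  all_het <- gen_truth_callset(50, iv, snv_frac = 1,
                               genotype_mix = c(HET = 1, HOMALT = 0),
                               seed = 16)
  expect_true(all(all_het$gclass == "HET"))
  # genotype mix is recovered within binomial error at larger n
  big <- gen_truth_callset(20000, iv, snv_frac = 1,
                           genotype_mix = c(HET = 0.6, HOMALT = 0.4),
                           seed = 17)
  p_het <- mean(big$gclass == "HET")
  se <- sqrt(0.6 * 0.4 / 20000)
  expect_lt(abs(p_het - 0.6), 3 * se)
  # positions inside intervals, alleles match the generating context
  ctx <- attr(big, "context")
  expect_true(all(positions_in_intervals(big$chrom, big$pos, iv)))
  snv <- big[big$vclass == "SNV", ]
  expect_true(all(substring(ctx$seq, snv$pos, snv$pos) == snv$ref))
  expect_error(gen_truth_callset(1e6, interval_set("chr1", 0, 100)),
               "too small")
})

test_that("indel-bearing truth callsets come out normalized", {
  iv <- interval_set("chr1", 0, 80000)
  cs <- gen_truth_callset(1500, iv, snv_frac = 0.5, seed = 19)
  ctx <- attr(cs, "context")
  expect_equal(nrow(cs), 1500)
  indels <- which(cs$vclass == "INDEL")
  expect_gt(length(indels), 400)
  for (i in sample(indels, 40)) {
    v <- left_align(cs$pos[i], cs$ref[i], cs$alt[i], ctx)
    expect_equal(list(pos = cs$pos[i], ref = cs$ref[i], alt = cs$alt[i]), v)
  }
})

test_that("a no-op confusion model reproduces the truth exactly", {
  iv <- interval_set("chr1", 0, 30000)
  truth <- gen_truth_callset(300, iv, snv_frac = 0.8, seed = 23)
  test <- corrupt(truth, confusion_model(p_miss = 0), seed = 24)
  r <- compare_callsets(truth, test, iv, truth_exhaustive = TRUE)
  expect_equal(unlist(r[c("concordance", "nrs", "nrc", "precision")]),
               c(concordance = 1, nrs = 1, nrc = 1, precision = 1))
  expect_true(all(attr(test, "latent")$status == "kept"))
})

test_that("corruption rates land within binomial error of their targets", {
  iv <- interval_set("chr1", 0, 500000)
  truth <- gen_truth_callset(20000, iv, snv_frac = 1, seed = 25)
  m <- confusion_model(p_miss = 0.05, p_filtered = 0.03, p_gterr = 0.02,
                       p_diffallele = 0.01, fp_per_kb = 0.2)
  test <- corrupt(truth, m, scores = score_model(), intervals = iv,
                  seed = 26)
  lat <- attr(test, "latent")
  n <- nrow(truth)
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(lat$status == "missed") - 0.05), 3 * se(0.05))
  r <- compare_callsets(truth, test, iv, truth_exhaustive = TRUE)
  nrs_expect <- (1 - 0.05) * (1 - 0.03) * (1 - 0.01)
  nrc_expect <- nrs_expect * (1 - 0.02)
  expect_lt(abs(r$nrs - nrs_expect), 3 * se(nrs_expect))
  expect_lt(abs(r$nrc - nrc_expect), 3 * se(nrc_expect))
  # latent sidecar supports exact accounting: every emitted call labelled
  key <- paste(test$chrom, test$pos, test$ref, test$alt, sep = ":")
  expect_true(all(key %in% lat$key))
  expect_equal(sum(lat$status %in% c("fp", "diffallele")),
               sum(!key %in% paste(truth$chrom, truth$pos, truth$ref,
                                   truth$alt, sep = ":")))
})

test_that("homopolymer dropout suppresses indels inside long runs", {
  spec <- data.frame(at = seq(100, 59000, by = 600), base = "A", len = 12)
  ctx <- gen_reference_context(60000, spec, seed = 27)
  # one single-base deletion inside every tract
  anchors <- spec$at       # pinned non-A base right before each tract
  truth <- callset(tibble::tibble(
    chrom = "chr1", pos = as.integer(anchors),
    ref = paste0(substr(ctx$seq, anchors, anchors), "A"),
    alt = substr(ctx$seq, anchors, anchors),
    gclass = "HET"), sample = "SYNTH1")
  truth <- annotate_homopolymers(truth, ctx)
  expect_true(all(truth$hp_len >= 12))
  withr::with_seed(28, {
    recovered <- purrr::map_int(1:120, function(i) {
      te <- corrupt(truth, confusion_model(p_miss = 0.05, hp_dropout = 0.9))
      nrow(te)
    })
  })
  rate <- mean(recovered) / nrow(truth)
  expect_equal(rate, 0.1 * 0.95, tolerance = 0.12)
})

test_that("coverage generator applies patches and stays deterministic", {
  iv <- interval_set("chr1", 0, 1000)
  trk <- gen_coverage(iv, base_depth = 30,
                      low_patches = data.frame(chrom = "chr1", start = 100,
                                               end = 150, depth = 5),
                      mapq0_patches = data.frame(chrom = "chr1",
                                                 start = 300, end = 350,
                                                 frac = 0.2))
  cr <- callable_regions(trk, iv)
  gaps <- subtract_intervals(iv, cr)
  expect_equal(as.data.frame(gaps),
               data.frame(chrom = c("chr1", "chr1"),
                          start = c(100L, 300L), end = c(150L, 350L)))
  # a 20% MAPQ0 patch survives a 25% tolerance
  cr2 <- callable_regions(trk, iv, max_mapq0_frac = 0.25)
  expect_equal(as.data.frame(subtract_intervals(iv, cr2)),
               data.frame(chrom = "chr1", start = 100L, end = 150L))
  expect_identical(gen_coverage(iv, 30, seed = 31),
                   gen_coverage(iv, 30, seed = 31))
  expect_error(gen_coverage(iv, 30, low_patches = data.frame(
    chrom = "chr1", start = c(0, 5), end = c(10, 15), depth = 1)),
    "overlap")
})

test_that("replicate families reproduce their additive model", {
  mdl0 <- batch_effect_model(deltas = c(inter_library = 0), noise_sd = 0)
  fam0 <- gen_replicate_family(mdl0, seed = 33)
  expect_true(all(fam0$pairs$concordance == 0.99))
  fam_a <- gen_replicate_family(seed = 34)
  fam_b <- gen_replicate_family(seed = 34)
  expect_identical(fam_a$pairs, fam_b$pairs)
  mdl <- batch_effect_model(deltas = c(inter_library = 0.0006),
                            noise_sd = 0)
  fam <- gen_replicate_family(mdl, seed = 35)
  expect_equal(fam$pairs$concordance,
               ifelse(fam$pairs$inter_library, 0.99 - 0.0006, 0.99))
})

test_that("generators are pure functions of parameters and seed", {
  iv <- interval_set("chr1", 0, 20000)
  a <- gen_truth_callset(200, iv, seed = 37)
  b <- gen_truth_callset(200, iv, seed = 37)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  ca <- corrupt(a, confusion_model(p_miss = 0.2), seed = 38)
  cb <- corrupt(b, confusion_model(p_miss = 0.2), seed = 38)
  expect_identical(tibble::as_tibble(ca), tibble::as_tibble(cb))
})
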