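# Independent brute-force oracles and tiny fixture builders shared across
# the suite. Everything here is deliberately written against definitions
# (set loops, string diffs), not against the package's own code paths.

# quick single-sample callset from parallel vectors
mk_callset <- function(pos, gclass = "HET", ref = "A", alt = "G",
                       filter = "PASS", chrom = "chr1", id = "test",
                       sample = "S1", ...) {
  callset(tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         gclass = gclass, filter = filter),
          replicate_id = id, sample = sample, ...)
}

# random small callset pair sharing a key universe, for oracle comparisons
rand_pair <- function(n_universe = 120, p_in = 0.7) {
  pos <- sample.int(100000, n_universe)
  alt <- sample(c("G", "T", "C"), n_universe, replace = TRUE)
  draw <- function(id) {
    keep <- runif(n_universe) < p_in
    mk_callset(pos[keep], alt = alt[keep],
               gclass = sample(c("HOMREF", "HET", "HOMALT", "NOCALL"),
                               sum(keep), replace = TRUE,
                               prob = c(.1, .45, .35, .1)),
               filter = sample(c("PASS", "LowQual"), sum(keep),
                               replace = TRUE, prob = c(.85, .15)),
               id = id)
  }
  list(truth = draw("A"), test = draw("B"))
}

# set-based concordance oracle: loops over the union of keys and tallies
# classes by definition; exhaustive-precision convention
oracle_metrics <- function(truth, test) {
  cls <- function(cs) {
    eff <- ifelse(cs$filter_status == "FILTERED", "NOCALL", cs$gclass)
    stats::setNames(eff, paste(cs$chrom, cs$pos, cs$ref, cs$alt, sep = ":"))
  }
  a <- cls(truth); b <- cls(test)
  keys <- union(names(a), names(b))
  lv <- c("HOMREF", "HET", "HOMALT", "NOCALL", "ABSENT")
  counts <- matrix(0L, 5, 5, dimnames = list(truth = lv, test = lv))
  for (k in keys) {
    ta <- if (k %in% names(a)) a[[k]] else "ABSENT"
    tb <- if (k %in% names(b)) b[[k]] else "ABSENT"
    counts[ta, tb] <- counts[ta, tb] + 1L
  }
  g <- lv[1:3]; nr <- lv[2:3]
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    counts = counts,
    total = sum(counts),
    concordance = rat(sum(diag(counts[g, g])), sum(counts[g, g])),
    nrs = rat(sum(counts[nr, nr]), sum(counts[nr, ])),
    nrc = rat(counts["HET", "HET"] + counts["HOMALT", "HOMALT"],
              sum(counts[nr, ])),
    precision = rat(counts["HET", "HET"] + counts["HOMALT", "HOMALT"],
                    sum(counts[, nr]))
  )
}

# string-diff normalization oracle: trim the longest shared suffix, then
# the shared prefix down to one anchor base; independent of the shifting
# algorithm under test
oracle_left_align <- function(pos, ref, alt, ctx) {
  lo <- ctx$offset
  i <- pos - lo + 1L
  stopifnot(substr(ctx$seq, i, i + nchar(ref) - 1L) == ref)
  hap <- paste0(substr(ctx$seq, 1, i - 1L), alt,
                substring(ctx$seq, i + nchar(ref)))
  s <- strsplit(ctx$seq, "")[[1]]
  h <- strsplit(hap, "")[[1]]
  ns <- length(s); nh <- length(h)
  # longest common suffix leaving >=1 base on each side
  k <- 0
  while (k < min(ns, nh) - 1 && s[ns - k] == h[nh - k]) k <- k + 1
  s2 <- s[seq_len(ns - k)]; h2 <- h[seq_len(nh - k)]
  # shared prefix, keeping at least one base in each allele
  p <- 0
  while (length(s2) - p > 1 && length(h2) - p > 1 &&
         s2[p + 1] == h2[p + 1]) p <- p + 1
  list(pos = lo + p,
       ref = paste(s2[(p + 1):length(s2)], collapse = ""),
       alt = paste(h2[(p + 1):length(h2)], collapse = ""))
}

# panel truth/test pair with exact tp / fn / different-allele composition
make_panel_fixture <- function(n_truth, n_match, n_miss, n_diff, seed = 1) {
  stopifnot(n_match + n_miss + n_diff == n_truth)
  withr::with_seed(seed, {
    iv <- interval_set("chr1", 0, 50 * n_truth + 1000)
    truth <- gen_truth_callset(n_truth, iv, snv_frac = 1)
    calls <- tibble::as_tibble(truth)
    calls$status <- "nonref"
    truth <- callset(calls, replicate_id = "panel", sample = "NA12878",
                     assay = "panel")
    shuffled <- sample.int(n_truth)
    miss_i <- shuffled[seq_len(n_miss)]
    diff_i <- shuffled[n_miss + seq_len(n_diff)]
    test <- calls[setdiff(seq_len(n_truth), miss_i),
                  c("chrom", "pos", "ref", "alt", "gclass", "filter")]
    for (p in calls$pos[diff_i]) {
      j <- which(test$pos == p)
      test$alt[j] <- sample(setdiff(c("A", "C", "G", "T"),
                                    c(test$ref[j], test$alt[j])), 1)
    }
    list(truth = truth,
         test = callset(test, replicate_id = "test", sample = "NA12878"))
  })
}

# replicate family whose miss rate rises outside the callable tiers
# (mirrors coverage-driven dropout): high-confidence best, callable next,
# the rest worst. Returns the replicates plus the nested interval tiers.
make_tiered_replicates <- function(n_reps = 3, n_sites = 900, seed = 1234) {
  withr::with_seed(seed, {
    iv <- interval_set("chr1", 0, 120000)
    high_conf <- interval_set("chr1", 0, 40000)
    callable <- interval_set("chr1", 0, 80000)
    truth <- gen_truth_callset(n_sites, iv, snv_frac = 1)
    tiers <- list(
      list(r = high_conf, p = 0.02),
      list(r = subtract_intervals(callable, high_conf), p = 0.12),
      list(r = subtract_intervals(iv, callable), p = 0.45))
    reps <- purrr::map(seq_len(n_reps), function(i) {
      parts <- purrr::map(tiers, function(tier) {
        part <- restrict_callset(truth, tier$r)
        tibble::as_tibble(corrupt(part, confusion_model(p_miss = tier$p)))
      })
      callset(dplyr::bind_rows(parts)[, c("chrom", "pos", "ref", "alt",
                                          "gclass", "filter")],
              replicate_id = paste0("SYNTH1/r", i), sample = "SYNTH1")
    })
    list(reps = reps, callable = callable, high_conf = high_conf)
  })
}

# every interval-set base as (chrom, pos) strings, for per-base set oracles
bases_of <- function(iv) {
  iv <- as_interval_set(iv)
  if (nrow(iv) == 0) return(character())
  unlist(purrr::pmap(iv, function(chrom, start, end) {
    paste(chrom, seq.int(start + 1L, end), sep = ":")
  }))
}

# matrix comparison helper: keep only dim/dimnames
strip_attrs <- function(m) {
  m <- unclass(m)
  array(as.integer(m), dim = dim(m), dimnames = dimnames(m))
}

variant_cols <- function(x) {
  tibble::tibble(chrom = unname(x$chrom), pos = unname(x$pos),
                 ref = unname(x$ref), alt = unname(x$alt))
}

context_slice_public <- function(ctx, from, to) {
  substr(ctx$seq, from - ctx$offset + 1, to - ctx$offset + 1)
}
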