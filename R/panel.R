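#' Site-level evaluation against a validated panel truth set
#'
#' Evaluates a test callset against a gene-panel truth set whose records
#' carry a per-site `status` of `"nonref"` (a validated variant) or
#' `"ref-confirmed"` (a site validated as reference). Both callsets must
#' be normalized and left-aligned; joining is by strict variant equality,
#' with site-level matching by (`chrom`, `pos`). FILTERED test calls are
#' treated as not called. Each truth site falls in exactly one category:
#'
#' * **tp** — non-ref truth site called with the matching alt allele
#'   (genotype-exact matches tracked separately for NRC);
#' * **diff_allele** — non-ref truth site where the test calls only a
#'   different alt allele (detected at the site level, discordant at the
#'   allele level);
#' * **fn** — non-ref truth site with no test call at the position;
#' * **tn** — ref-confirmed truth site with no test call.
#'
#' Test calls matching no truth variant are false or "excess" positives
#' (`fp_ep`; the two are not distinguished computationally).
#'
#' Site-level sensitivity counts different-allele sites as detected:
#' `(tp + diff_allele) / (tp + fn + diff_allele)`. NRC is the
#' genotype-exact fraction over the same denominator, and specificity is
#' `tn / (tn + fp at ref-confirmed sites)`.
#'
#' @param truth A `callset` with a `status` column (`"nonref"` or
#'   `"ref-confirmed"`).
#' @param test A `callset`.
#' @param intervals Optional `interval_set` (panel targets).
#' @return A one-row tibble of class `site_tally`: `n_variants`, `tp`,
#'   `tp_gt_exact`, `fp_ep`, `fn`, `tn`, `diff_allele`, `sensitivity`,
#'   `nrc`, `specificity`; per-site category labels are in
#'   `attr(x, "sites")`.
#' @export
site_eval <- function(truth, test, intervals = NULL) {
  stopifnot(inherits(truth, "callset"), inherits(test, "callset"))
  if (!"status" %in% names(truth)) {
    stop("site_eval: truth callset must carry a 'status' column ",
         "(nonref | ref-confirmed)", call. = FALSE)
  }
  bad <- setdiff(unique(truth$status), c("nonref", "ref-confirmed"))
  if (length(bad) || anyNA(truth$status)) {
    stop("site_eval: invalid truth status values: ",
         paste(c(bad, if (anyNA(truth$status)) "NA"), collapse = ", "),
         call. = FALSE)
  }
  truth <- restrict_callset(truth, intervals)
  test <- restrict_callset(test, intervals)
  test_pass <- test[test$filter_status == "PASS" &
                      test$gclass %in% NONREF, , drop = FALSE]

  t_key <- variant_key(truth)
  s_key <- variant_key(test_pass)
  t_site <- paste(truth$chrom, truth$pos, sep = ":")
  s_site <- paste(test_pass$chrom, test_pass$pos, sep = ":")

  nonref <- truth$status == "nonref"
  exact <- t_key %in% s_key
  site_hit <- t_site %in% s_site
  gt_exact <- exact & truth$gclass == test_pass$gclass[match(t_key, s_key)]

  category <- dplyr::case_when(
    nonref & exact ~ "tp",
    nonref & site_hit ~ "diff_allele",
    nonref ~ "fn",
    !nonref & !site_hit ~ "tn",
    TRUE ~ "fp_site"   # ref-confirmed site with a test call
  )
  sites <- tibble::tibble(
    chrom = truth$chrom, pos = truth$pos, ref = truth$ref, alt = truth$alt,
    status = truth$status, gclass = truth$gclass,
    category = category, gt_exact = gt_exact & category == "tp"
  )

  # test-call side: calls matching no truth variant are FP/EP
  s_match_variant <- s_key %in% t_key[nonref]
  s_at_nonref_site <- s_site %in% t_site[nonref]
  fp_ep <- sum(!s_match_variant & !s_at_nonref_site)
  fp_at_refconf <- sum(!s_match_variant & !s_at_nonref_site &
                         s_site %in% t_site[!nonref])

  tp <- sum(category == "tp")
  fn <- sum(category == "fn")
  tn <- sum(category == "tn")
  diff_allele <- sum(category == "diff_allele")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- tibble::tibble(
    n_variants = nrow(test_pass),
    tp = tp, tp_gt_exact = sum(sites$gt_exact), fp_ep = fp_ep,
    fn = fn, tn = tn, diff_allele = diff_allele,
    sensitivity = site_sensitivity(tp, fn, diff_allele),
    nrc = ratio(sum(sites$gt_exact), tp + fn + diff_allele),
    specificity = ratio(tn, tn + fp_at_refconf)
  )
  structure(tibble::new_tibble(out, class = "site_tally"), sites = sites)
}

#' Site-level sensitivity from category counts
#'
#' Different-allele sites count as detected in both numerator and
#' denominator: `(tp + diff_allele) / (tp + fn + diff_allele)`.
#'
#' @param tp,fn,diff_allele Counts (vectorized).
#' @return Sensitivity as a fraction in `[0, 1]` (`NA` on an empty
#'   denominator).
#' @examples
#' site_sensitivity(40, 3, 0)  # 0.930
#' site_sensitivity(54, 8, 1)  # 0.873
#' @export
site_sensitivity <- function(tp, fn, diff_allele = 0) {
  den <- tp + fn + diff_allele
  ifelse(den > 0, (tp + diff_allele) / den, NA_real_)
}

#' Describe false-negative and different-allele sites
#'
#' One row per missed (FN) or different-allele truth site: position,
#' alleles, truth genotype, how many of the supplied replicates call the
#' exact variant (PASSing), and the homopolymer run length at the site.
#' Single-base indels inside long homopolymer tracts are the dominant
#' false-negative class in clinical panel comparisons; runs of at least
#' `run_min` bases are flagged.
#'
#' @param tally A `site_tally` from [site_eval()].
#' @param context A [ref_context()] (or list of them) covering the sites.
#' @param replicates Optional list of `callset`s for the called-in count.
#' @param run_min Homopolymer flag threshold in bases (default 10).
#' @return A tibble: `chrom`, `pos`, `ref`, `alt`, `truth_gclass`,
#'   `category`, `called_in` (e.g. `"3/6"`, `NA` without replicates),
#'   `hp_len`, `homopolymer` (logical).
#' @export
fn_report <- function(tally, context, replicates = NULL, run_min = 10) {
  stopifnot(inherits(tally, "site_tally"))
  sites <- attr(tally, "sites")
  miss <- sites[sites$category %in% c("fn", "diff_allele"), , drop = FALSE]
  if (nrow(miss) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          truth_gclass = character(), category = character(),
                          called_in = character(), hp_len = integer(),
                          homopolymer = logical()))
  }
  ctxs <- if (inherits(context, "ref_context")) list(context) else context
  hp <- purrr::map2_int(miss$pos, seq_len(nrow(miss)), function(p, i) {
    ctx <- ctx_for(ctxs, miss$chrom[i], p)
    if (is.null(ctx)) return(NA_integer_)
    homopolymer_run(ctx, p, miss$ref[i], miss$alt[i])
  })
  called_in <- if (is.null(replicates)) {
    rep(NA_character_, nrow(miss))
  } else {
    n <- length(replicates)
    keys <- paste(miss$chrom, miss$pos, miss$ref, miss$alt, sep = ":")
    k <- purrr::map_int(keys, function(key) {
      sum(purrr::map_lgl(replicates, function(cs) {
        any(variant_key(cs) == key & cs$filter_status == "PASS")
      }))
    })
    sprintf("%d/%d", k, n)
  }
  tibble::tibble(
    chrom = miss$chrom, pos = miss$pos, ref = miss$ref, alt = miss$alt,
    truth_gclass = miss$gclass, category = miss$category,
    called_in = called_in, hp_len = hp,
    homopolymer = !is.na(hp) & hp >= run_min
  )
}

ctx_for <- function(ctxs, chrom, pos) {
  for (ctx in ctxs) {
    if (ctx$chrom == chrom && pos >= ctx$offset &&
        pos <= ctx$offset + nchar(ctx$seq) - 1L) {
      return(ctx)
    }
  }
  NULL
}

#' Longest single-base run overlapping a variant
#'
#' @param ctx A [ref_context()].
#' @param pos,ref,alt The variant; the scanned span is the reference bases
#'   the variant touches plus one base of right flank (so an insertion
#'   inside a tract picks the tract up).
#' @return Integer run length.
#' @export
homopolymer_run <- function(ctx, pos, ref, alt) {
  span_lo <- pos
  span_hi <- min(pos + nchar(ref), ctx$offset + nchar(ctx$seq) - 1L)
  bases <- strsplit(ctx$seq, "", fixed = TRUE)[[1]]
  r <- rle(bases)
  ends <- cumsum(r$lengths) + ctx$offset - 1L
  starts <- ends - r$lengths + 1L
  overlap <- starts <= span_hi & ends >= span_lo
  if (!any(overlap)) return(0L)
  as.integer(max(r$lengths[overlap]))
}
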