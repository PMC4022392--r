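GCLASSES <- c("HOMREF", "HET", "HOMALT", "NOCALL", "ABSENT")
GENOTYPED <- c("HOMREF", "HET", "HOMALT")
NONREF <- c("HET", "HOMALT")

#' Join two callsets into a truth-by-test genotype count matrix
#'
#' Callsets are joined under strict variant equality (chromosome, position,
#' reference and alternate allele). Every variant key present in either
#' callset (within the evaluation intervals) contributes to exactly one
#' cell of a 5x5 table over the classes HOMREF, HET, HOMALT, NOCALL and
#' ABSENT. FILTERED calls are counted as NOCALL; a key absent from one
#' side falls in that side's ABSENT class. All four concordance metrics
#' derive from this matrix via [concordance_metrics()].
#'
#' @param truth,test Normalized `callset` objects.
#' @param intervals Optional `interval_set` restricting the comparison.
#' @return An object of class `concordance_matrix`: an integer 5x5 matrix
#'   (truth rows, test columns) with attributes `truth_id`, `test_id`,
#'   `interval_bases`, and `truth_exhaustive` (from the truth callset).
#' @export
join_callsets <- function(truth, test, intervals = NULL) {
  stopifnot(inherits(truth, "callset"), inherits(test, "callset"))
  truth <- restrict_callset(truth, intervals)
  test <- restrict_callset(test, intervals)
  tr <- effective_class(truth)
  te <- effective_class(test)
  key_t <- variant_key(truth)
  key_s <- variant_key(test)
  i <- match(key_t, key_s)
  truth_class <- factor(tr, levels = GCLASSES)
  test_class <- factor(ifelse(is.na(i), "ABSENT", te[i]), levels = GCLASSES)
  only_s <- !(key_s %in% key_t)
  counts <- table(truth_class, test_class) +
    table(factor(rep("ABSENT", sum(only_s)), levels = GCLASSES),
          factor(te[only_s], levels = GCLASSES))
  counts <- unclass(counts)
  dimnames(counts) <- list(truth = GCLASSES, test = GCLASSES)
  structure(counts,
            class = c("concordance_matrix", "matrix"),
            truth_id = attr(truth, "replicate_id"),
            test_id = attr(test, "replicate_id"),
            interval_bases = if (is.null(intervals)) NA_integer_ else
              total_bases(intervals),
            truth_exhaustive = isTRUE(attr(truth, "exhaustive")))
}

# gclass with the filter-to-no-call rule applied
effective_class <- function(x) {
  ifelse(x$filter_status == "FILTERED", "NOCALL", x$gclass)
}

#' Concordance metrics from a genotype count matrix
#'
#' Computes the four validation metrics from a [join_callsets()] matrix:
#'
#' * **concordance** — matching genotype classes among sites genotyped in
#'   both callsets: `sum(diag)` over HOMREF/HET/HOMALT divided by the total
#'   of the 3x3 genotyped block.
#' * **nrs** (non-reference sensitivity) — truth non-ref sites at which the
#'   test calls the same variant non-ref, over all truth non-ref sites.
#' * **nrc** (non-reference genotype concordance; genotype-aware recall) —
#'   truth non-ref sites with the exactly matching genotype, over all truth
#'   non-ref sites.
#' * **precision** — test non-ref calls exactly matching the truth
#'   genotype, over evaluable test non-ref calls. When the truth callset
#'   is exhaustive over the intervals (arrays, panels, high-confidence
#'   reference sets, and replicate-vs-replicate comparisons), test-only
#'   keys count against precision; otherwise they are excluded and
#'   reported as `n_unevaluable`.
#'
#' Ratios with empty denominators are `NA`, never 0 or 1.
#'
#' @param x A `concordance_matrix`.
#' @param truth_exhaustive Override the matrix's stored exhaustiveness flag.
#' @return A one-row tibble of class `concordance_report`: `truth_id`,
#'   `test_id`, `n_joint`, `n_truth_nonref`, `n_test_nonref`,
#'   `n_unevaluable`, `concordance`, `nrs`, `nrc`, `precision`.
#' @export
concordance_metrics <- function(x, truth_exhaustive = NULL) {
  stopifnot(inherits(x, "concordance_matrix"))
  if (is.null(truth_exhaustive)) truth_exhaustive <- attr(x, "truth_exhaustive")
  m <- unclass(x)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  diag3 <- sum(diag(m[GENOTYPED, GENOTYPED]))
  diag_nr <- m["HET", "HET"] + m["HOMALT", "HOMALT"]
  n_truth_nonref <- sum(m[NONREF, ])
  n_test_nonref <- sum(m[, NONREF])
  n_unevaluable <- if (truth_exhaustive) 0L else sum(m["ABSENT", NONREF])
  prec_den <- if (truth_exhaustive) n_test_nonref else
    sum(m[setdiff(GCLASSES, "ABSENT"), NONREF])
  tibble::tibble(
    truth_id = attr(x, "truth_id") %||% NA_character_,
    test_id = attr(x, "test_id") %||% NA_character_,
    n_joint = sum(m[GENOTYPED, GENOTYPED]),
    n_truth_nonref = n_truth_nonref,
    n_test_nonref = n_test_nonref,
    n_unevaluable = n_unevaluable,
    concordance = ratio(diag3, sum(m[GENOTYPED, GENOTYPED])),
    nrs = ratio(sum(m[NONREF, NONREF]), n_truth_nonref),
    nrc = ratio(diag_nr, n_truth_nonref),
    precision = ratio(diag_nr, prec_den)
  )
}

#' Compare a truth and a test callset in one call
#'
#' Convenience wrapper: [join_callsets()] then [concordance_metrics()].
#'
#' @inheritParams join_callsets
#' @inheritParams concordance_metrics
#' @return A one-row `concordance_report` tibble.
#' @export
compare_callsets <- function(truth, test, intervals = NULL,
                             truth_exhaustive = NULL) {
  concordance_metrics(join_callsets(truth, test, intervals),
                      truth_exhaustive = truth_exhaustive)
}

#' All pairwise replicate comparisons of a sample
#'
#' For every unordered pair of same-sample callsets, runs the concordance
#' analysis twice, treating each callset alternately as truth and test
#' (concordance is symmetric by construction; NRS, NRC and precision
#' generally are not). Pairs with mismatched sample names are skipped with
#' a warning. Because replicates are compared against each other (no
#' external truth), test-only keys always count against precision, which
#' makes `precision(A,B) == nrc(B,A)` hold exactly.
#'
#' @param callsets A list of `callset` objects.
#' @param intervals Optional `interval_set` restriction.
#' @param design Optional replicate design table (see [build_design()]);
#'   when supplied, each row is annotated with the pair's comparison kinds.
#' @return A tibble with one row per ordered direction of each pair:
#'   the `concordance_report` columns plus, when `design` is given,
#'   `kinds` and `primary_label`.
#' @export
pairwise_replicates <- function(callsets, intervals = NULL, design = NULL) {
  stopifnot(is.list(callsets), length(callsets) >= 2)
  ids <- purrr::map_chr(callsets, replicate_id)
  samples <- purrr::map_chr(callsets, sample_id)
  pair_design <- if (!is.null(design)) build_design(design) else NULL
  out <- list()
  for (a in seq_along(callsets)) {
    for (b in seq_along(callsets)) {
      if (a >= b) next
      if (samples[a] != samples[b]) {
        warning("pairwise_replicates: skipping cross-sample pair ",
                ids[a], " vs ", ids[b], call. = FALSE)
        next
      }
      mat_ab <- join_callsets(callsets[[a]], callsets[[b]], intervals)
      mat_ba <- join_callsets(callsets[[b]], callsets[[a]], intervals)
      rep2 <- dplyr::bind_rows(
        concordance_metrics(mat_ab, truth_exhaustive = TRUE),
        concordance_metrics(mat_ba, truth_exhaustive = TRUE)
      )
      if (!is.null(pair_design)) {
        hit <- pair_design[
          (pair_design$replicate_a == ids[a] &
             pair_design$replicate_b == ids[b]) |
            (pair_design$replicate_a == ids[b] &
               pair_design$replicate_b == ids[a]), , drop = FALSE]
        rep2$kinds <- if (nrow(hit)) hit$kinds[1] else NA_character_
        rep2$primary_label <- if (nrow(hit)) hit$primary_label[1] else
          NA_character_
      }
      out[[length(out) + 1]] <- rep2
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat("Genotype concordance matrix: truth =", attr(x, "truth_id"),
      "| test =", attr(x, "test_id"), "\n")
  print(unclass(x))
  invisible(x)
}

#' @export
tidy.concordance_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    truth_class = rep(rownames(m), times = ncol(m)),
    test_class = rep(colnames(m), each = nrow(m)),
    n = as.vector(m)
  )
}
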