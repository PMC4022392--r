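#' Precision/NRC curve over a variant-quality threshold sweep
#'
#' Sweeps a quality-score threshold (VQSLOD by convention) over a test
#' callset compared against a truth callset: at each threshold `t`, calls
#' with score `>= t` are treated as PASS and all others as no-calls, then
#' precision and NRC are computed via [concordance_metrics()]. The
#' callset's own FILTER field gives the operating point — where the
#' production filter (e.g. the VQSR tranche cut capturing 99.5% of known
#' true positives) actually sits on the curve. Sweeps are per variant
#' class: SNVs and indels carry separately trained scores.
#'
#' Calls lacking the score are excluded from the sweep and counted in the
#' `n_unscored` attribute.
#'
#' @param test,truth Normalized `callset` objects.
#' @param intervals Optional `interval_set` restriction.
#' @param vtype `"SNV"` or `"INDEL"`.
#' @param thresholds Numeric vector of thresholds, or `"auto"`: the sorted
#'   distinct observed scores, thinned deterministically to at most
#'   `max_points` by quantile sampling.
#' @param score Name of the score column (default `"vqslod"`).
#' @param truth_exhaustive Whether test-only keys count against precision;
#'   defaults to the truth callset's flag.
#' @param max_points Cap on `"auto"` thresholds (default 200).
#' @return A tibble of class `pr_curve` with columns `threshold`,
#'   `n_pass`, `precision`, `nrc` (thresholds strictly increasing; `n_pass`
#'   and `nrc` non-increasing), and attributes `operating_point` (one-row
#'   tibble at the stored FILTER), `vtype`, `truth_scope`, `n_unscored`.
#' @export
pr_sweep <- function(test, truth, intervals = NULL,
                     vtype = c("SNV", "INDEL"), thresholds = "auto",
                     score = "vqslod", truth_exhaustive = NULL,
                     max_points = 200) {
  vtype <- match.arg(vtype)
  stopifnot(inherits(test, "callset"), inherits(truth, "callset"))
  if (is.null(truth_exhaustive)) truth_exhaustive <-
      isTRUE(attr(truth, "exhaustive"))
  truth <- restrict_callset(truth, intervals)
  test <- restrict_callset(test, intervals)
  truth <- truth[truth$vclass == vtype, , drop = FALSE]
  test <- test[test$vclass == vtype, , drop = FALSE]
  if (!score %in% names(test)) {
    stop("pr_sweep: test callset has no '", score, "' column", call. = FALSE)
  }
  scored <- !is.na(test[[score]])
  n_unscored <- sum(!scored)
  test_s <- test[scored, , drop = FALSE]
  if (nrow(test_s) == 0) {
    stop("pr_sweep: no scored ", vtype, " calls to sweep", call. = FALSE)
  }

  t_key <- variant_key(truth)
  s_key <- variant_key(test_s)
  truth_nonref <- truth$gclass %in% NONREF
  i <- match(s_key, t_key)
  # per scored test call: does it exactly match a truth non-ref genotype?
  call_nonref <- test_s$gclass %in% NONREF
  call_match <- !is.na(i) & call_nonref &
    test_s$gclass == ifelse(is.na(i), NA, truth$gclass[i])
  call_evaluable <- if (truth_exhaustive) call_nonref else
    (call_nonref & !is.na(i))
  sc <- test_s[[score]]
  n_truth_nonref <- sum(truth_nonref)

  if (identical(thresholds, "auto")) {
    u <- sort(unique(sc))
    thresholds <- if (length(u) > max_points) {
      sort(unique(stats::quantile(u, probs = seq(0, 1, length.out =
                                                   max_points), type = 1)))
    } else u
  } else {
    thresholds <- sort(unique(as.numeric(thresholds)))
  }

  point_at <- function(pass) {
    tp <- sum(call_match & pass)
    den <- sum(call_evaluable & pass)
    tibble::tibble(
      n_pass = sum(pass),
      precision = if (den > 0) tp / den else NA_real_,
      nrc = if (n_truth_nonref > 0) tp / n_truth_nonref else NA_real_
    )
  }
  points <- purrr::map_dfr(thresholds, function(t) point_at(sc >= t))
  points <- dplyr::bind_cols(tibble::tibble(threshold = thresholds), points)
  op <- point_at(test_s$filter_status == "PASS")

  structure(
    tibble::new_tibble(points, class = "pr_curve"),
    operating_point = op,
    vtype = vtype,
    truth_scope = if (truth_exhaustive) "exhaustive" else "non-exhaustive",
    n_unscored = n_unscored,
    sweep_calls = tibble::tibble(score = sc, match = call_match,
                                 evaluable = call_evaluable,
                                 nonref = call_nonref)
  )
}

#' Marginal true/false positives between sweep thresholds
#'
#' Relaxing a variant-quality threshold admits a mix of additional true
#' and false calls; production filters are effectively set at the
#' inflection point where relaxing further admits more false positives
#' than true positives (a marginal ratio near 1:1). Between each pair of
#' consecutive sweep thresholds this reports the newly admitted agreeing
#' calls (`delta_tp`), the newly admitted disagreeing or absent-in-truth
#' calls (`delta_fp`), their ratio, and flags the interval bracketing
#' ratio = 1.
#'
#' @param curve A `pr_curve` from [pr_sweep()].
#' @return A tibble: `threshold_lo`, `threshold_hi`, `delta_tp`,
#'   `delta_fp`, `ratio` (`Inf` when `delta_fp` is 0), `brackets_unity`.
#'   Empty for single-point curves.
#' @export
marginal_ratio <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  calls <- attr(curve, "sweep_calls")
  th <- curve$threshold
  if (length(th) < 2) {
    return(tibble::tibble(threshold_lo = numeric(), threshold_hi = numeric(),
                          delta_tp = integer(), delta_fp = integer(),
                          ratio = numeric(), brackets_unity = logical()))
  }
  out <- purrr::map_dfr(seq_len(length(th) - 1), function(k) {
    admitted <- calls$score >= th[k] & calls$score < th[k + 1]
    dtp <- sum(admitted & calls$match)
    dfp <- sum(admitted & calls$nonref & !calls$match)
    tibble::tibble(threshold_lo = th[k], threshold_hi = th[k + 1],
                   delta_tp = dtp, delta_fp = dfp,
                   ratio = if (dfp > 0) dtp / dfp else Inf)
  })
  r <- out$ratio[is.finite(out$ratio) | out$ratio == Inf]
  out$brackets_unity <- FALSE
  fin <- which(out$delta_tp + out$delta_fp > 0)
  if (length(fin) >= 2) {
    rr <- out$ratio[fin]
    cross <- which((rr[-length(rr)] - 1) * (rr[-1] - 1) <= 0)
    if (length(cross)) out$brackets_unity[fin[cross[1]]] <- TRUE
  }
  out
}

#' @export
autoplot.pr_curve <- function(object, ...) {
  op <- attr(object, "operating_point")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$nrc, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = op, colour = "red", size = 2) +
    ggplot2::labs(
      x = "Non-reference genotype concordance (NRC)",
      y = "Precision",
      title = paste0(attr(object, "vtype"),
                     " precision vs NRC over the quality-score sweep"),
      subtitle = "Point: operating point at the stored PASS filter"
    )
}
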