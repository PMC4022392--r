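KIND_NAMES <- c("intra_run", "inter_run", "inter_machine", "inter_mode",
                "inter_library")

#' Call uniformity across technical replicates
#'
#' Partitions the union of variant keys observed across same-sample
#' replicates by the number of replicates `k` in which each key appears.
#' Site-level presence deliberately ignores FILTER: a variant called
#' PASSing or not PASSing both count as called (this differs from the
#' concordance metrics, where a FILTERED call is a no-call). Optionally
#' restricted to an interval set, e.g. the squared-off callable
#' intersection or its further intersection with high-confidence regions;
#' on such nested restrictions the fraction of sites seen in all
#' replicates can only improve.
#'
#' @param callsets List of two or more same-sample `callset`s.
#' @param vtype `"SNV"` or `"INDEL"`.
#' @param restriction Optional `interval_set`.
#' @return An object of class `uniformity` — a list with:
#'   * `by_k`: tibble `sample`, `vtype`, `n_replicates`, `k`, `n_sites`,
#'     `pct` (percentages sum to 100);
#'   * `private`: tibble `replicate_id`, `n_unique` (sites seen only in
#'     that replicate).
#' @export
uniformity <- function(callsets, vtype = c("SNV", "INDEL"),
                       restriction = NULL) {
  vtype <- match.arg(vtype)
  stopifnot(is.list(callsets), length(callsets) >= 2)
  samples <- unique(purrr::map_chr(callsets, sample_id))
  if (length(samples) != 1) {
    stop("uniformity: callsets mix samples: ",
         paste(samples, collapse = ", "), call. = FALSE)
  }
  n <- length(callsets)
  keysets <- purrr::map(callsets, function(cs) {
    cs <- restrict_callset(cs, restriction)
    unique(variant_key(cs[cs$vclass == vtype, , drop = FALSE]))
  })
  all_keys <- unlist(keysets, use.names = FALSE)
  counts <- table(all_keys)
  k_of_key <- as.integer(counts)
  by_k <- tibble::tibble(
    sample = samples, vtype = vtype, n_replicates = n, k = seq_len(n),
    n_sites = purrr::map_int(seq_len(n), ~ sum(k_of_key == .x))
  )
  total <- sum(by_k$n_sites)
  by_k$pct <- if (total > 0) 100 * by_k$n_sites / total else NA_real_
  singles <- names(counts)[k_of_key == 1]
  private <- tibble::tibble(
    replicate_id = purrr::map_chr(callsets, replicate_id),
    n_unique = purrr::map_int(keysets, ~ sum(.x %in% singles))
  )
  structure(list(by_k = by_k, private = private), class = "uniformity")
}

#' @export
print.uniformity <- function(x, ...) {
  cat("Call uniformity across", x$by_k$n_replicates[1], "replicates of",
      x$by_k$sample[1], "(", x$by_k$vtype[1], ")\n")
  print(x$by_k)
  cat("Private (uniquely observed) sites per replicate:\n")
  print(x$private)
  invisible(x)
}

#' @export
tidy.uniformity <- function(x, ...) x$by_k

#' @export
autoplot.uniformity <- function(object, ...) {
  ggplot2::ggplot(object$by_k,
                  ggplot2::aes(x = factor(.data$k), y = .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Called in k replicates", y = "% of union of sites",
                  title = paste0(object$by_k$sample[1], " ",
                                 object$by_k$vtype[1], " call uniformity"))
}

#' Classify all same-sample replicate pairs by comparison kind
#'
#' Derives, for every unordered pair of same-sample (and same-assay)
#' replicates, which comparison kinds the pair represents, from the
#' replicate provenance:
#'
#' * same run and machine — `intra_run`
#' * same machine, different run — `inter_run`
#' * different machine — `inter_machine`
#' * different mode (high-throughput vs rapid) — `inter_mode`
#' * different library preparation — `inter_library`
#'
#' A pair may carry several kinds; `primary_label` is the single kind when
#' exactly one applies, else `"other"` (a display convention only — the
#' indicator columns carry the analysis).
#'
#' @param design Data frame with columns `replicate_id`, `sample`,
#'   `library`, `run`, `machine`, `mode` (and optionally `assay`).
#' @param samples Optional character vector restricting to some samples.
#' @return A tibble of class `comparison_design`, one row per pair:
#'   `replicate_a`, `replicate_b`, `sample`, logical indicator columns
#'   `intra_run` .. `inter_library`, `kinds` (comma-separated),
#'   `primary_label`.
#' @export
build_design <- function(design, samples = NULL) {
  design <- tibble::as_tibble(design)
  needed <- c("replicate_id", "sample", "library", "run", "machine", "mode")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols)) {
    stop("build_design: design table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("library", "run", "machine", "mode")) {
    if (anyNA(design[[col]])) {
      stop("build_design: missing '", col, "' for replicate ",
           design$replicate_id[which(is.na(design[[col]]))[1]],
           call. = FALSE)
    }
  }
  if (!is.null(samples)) design <- design[design$sample %in% samples, ,
                                          drop = FALSE]
  if (!"assay" %in% names(design)) design$assay <- "NA"
  groups <- split(design, paste(design$sample, design$assay))
  rows <- purrr::map_dfr(groups, function(g) {
    if (nrow(g) < 2) return(NULL)
    idx <- utils::combn(nrow(g), 2)
    purrr::map_dfr(seq_len(ncol(idx)), function(j) {
      a <- g[idx[1, j], ]; b <- g[idx[2, j], ]
      flags <- c(
        intra_run = a$run == b$run && a$machine == b$machine,
        inter_run = a$machine == b$machine && a$run != b$run,
        inter_machine = a$machine != b$machine,
        inter_mode = a$mode != b$mode,
        inter_library = a$library != b$library
      )
      tibble::tibble(
        replicate_a = a$replicate_id, replicate_b = b$replicate_id,
        sample = a$sample, assay = a$assay,
        intra_run = flags[["intra_run"]], inter_run = flags[["inter_run"]],
        inter_machine = flags[["inter_machine"]],
        inter_mode = flags[["inter_mode"]],
        inter_library = flags[["inter_library"]],
        kinds = paste(KIND_NAMES[flags], collapse = ","),
        primary_label = if (sum(flags) == 1) KIND_NAMES[flags] else "other"
      )
    })
  })
  tibble::new_tibble(rows, class = "comparison_design")
}

#' Read a replicate-design table
#'
#' TSV with header `replicate_id`, `sample`, `library`, `run`, `machine`,
#' `mode`, `assay`. Lines starting with `#` are comments.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_design <- function(path) {
  readr::read_tsv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()))
}

#' Regress pairwise concordance on comparison-kind indicators
#'
#' Quantifies whether any replicate comparison kind shifts the
#' (direction-symmetric) pairwise concordance, with the sample id as a
#' control covariate when more than one sample is present. Two layers:
#'
#' * the **overall** test fits all varying kind indicators jointly and
#'   compares against the sample-only null with a nested F-test (rank
#'   deficiency from logically dependent indicators — every pair is
#'   exactly one of intra-run / inter-run / inter-machine — is handled by
#'   the fit's rank);
#' * each varying kind is then **analyzed individually** (OLS of
#'   concordance on that kind plus the sample control), and its
#'   coefficient t-test is Bonferroni-corrected at
#'   `alpha_overall / n kinds tested`. A kind's coefficient is the
#'   additive change in concordance associated with that comparison kind.
#'
#' Kinds constant across all pairs carry no information and are dropped
#' with a warning.
#'
#' @param pairs A `comparison_design` (or compatible tibble) with a
#'   `concordance` column, one value per pair.
#' @param alpha_overall Overall significance level (default 0.05).
#' @return An object of class `concordance_regression`: list with `model`
#'   (the joint `lm` fit), `coefficients` (tibble of per-kind individual
#'   fits: term, estimate, std.error, statistic, p.value, significant),
#'   `overall_p`, `n_pairs`, `kinds_tested`, `kinds_dropped`,
#'   `alpha_overall`, `alpha_perkind`.
#' @export
regress_concordance <- function(pairs, alpha_overall = 0.05) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot("concordance" %in% names(pairs))
  kinds <- intersect(KIND_NAMES, names(pairs))
  varying <- kinds[purrr::map_lgl(kinds, ~ dplyr::n_distinct(pairs[[.x]]) > 1)]
  dropped <- setdiff(kinds, varying)
  if (length(dropped)) {
    warning("regress_concordance: dropping constant comparison kinds: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (!length(varying)) {
    stop("regress_concordance: no comparison kind varies across pairs",
         call. = FALSE)
  }
  with_sample <- "sample" %in% names(pairs) &&
    dplyr::n_distinct(pairs$sample) > 1
  df <- pairs[, c("concordance", varying,
                  if (with_sample) "sample"), drop = FALSE]
  df[varying] <- lapply(df[varying], as.numeric)
  ctrl <- if (with_sample) " + sample" else ""
  fit <- stats::lm(stats::as.formula(
    paste("concordance ~", paste(varying, collapse = " + "), ctrl)),
    data = df)
  null_fit <- stats::lm(
    if (with_sample) concordance ~ sample else concordance ~ 1, data = df)
  an <- stats::anova(null_fit, fit)
  overall_p <- an[["Pr(>F)"]][2]
  coefs <- purrr::map_dfr(varying, function(k) {
    f1 <- stats::lm(stats::as.formula(paste("concordance ~", k, ctrl)),
                    data = df)
    cs <- summary(f1)$coefficients
    tibble::tibble(term = k, estimate = cs[k, "Estimate"],
                   std.error = cs[k, "Std. Error"],
                   statistic = cs[k, "t value"],
                   p.value = cs[k, "Pr(>|t|)"])
  })
  alpha_perkind <- alpha_overall / length(varying)
  coefs$significant <- coefs$p.value < alpha_perkind
  structure(list(
    model = fit, coefficients = coefs, overall_p = overall_p,
    n_pairs = nrow(df), kinds_tested = varying, kinds_dropped = dropped,
    alpha_overall = alpha_overall, alpha_perkind = alpha_perkind
  ), class = "concordance_regression")
}

#' @export
print.concordance_regression <- function(x, ...) {
  cat("OLS of pairwise concordance on comparison kinds (",
      x$n_pairs, " pairs)\n", sep = "")
  cat("Overall model-vs-null p-value:", format.pval(x$overall_p),
      "(alpha =", x$alpha_overall, ")\n")
  cat("Per-kind alpha (Bonferroni over", length(x$kinds_tested),
      "kinds):", x$alpha_perkind, "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.concordance_regression <- function(x, ...) x$coefficients

#' @export
glance.concordance_regression <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma, overall_p = x$overall_p, n_pairs = x$n_pairs,
    n_kinds_tested = length(x$kinds_tested),
    alpha_perkind = x$alpha_perkind
  )
}

#' Concordance by comparison kind
#'
#' Scatter of pairwise concordance reports by primary comparison label,
#' the visual companion to [regress_concordance()].
#'
#' @param reports Tibble from [pairwise_replicates()] (needs
#'   `primary_label` and `concordance`).
#' @return A ggplot object.
#' @export
plot_pairwise_concordance <- function(reports) {
  stopifnot(all(c("primary_label", "concordance") %in% names(reports)))
  ggplot2::ggplot(reports, ggplot2::aes(x = .data$primary_label,
                                        y = .data$concordance)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.7) +
    ggplot2::labs(x = "Comparison kind", y = "Genotype concordance",
                  title = "Pairwise replicate concordance by comparison kind")
}
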