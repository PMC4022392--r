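#' Generate a reference context with controlled homopolymer structure
#'
#' Random A/C/G/T sequence in which single-base runs are capped at
#' `run_cap` bases everywhere except the explicitly requested homopolymer
#' tracts, so that a run reaching the annotation threshold exists exactly
#' where asked. Deterministic for a given seed.
#'
#' @param length Window length in bases.
#' @param homopolymer_spec Optional data frame with columns `at` (0-based
#'   offset of the tract within the window), `base`, `len`. Tracts must
#'   not overlap.
#' @param seed Optional integer seed.
#' @param chrom,offset Window placement (see [ref_context()]).
#' @param run_cap Maximum background run length (default 9, one below the
#'   homopolymer flag threshold).
#' @return A [ref_context()].
#' @export
gen_reference_context <- function(length, homopolymer_spec = NULL,
                                  seed = NULL, chrom = "chr1", offset = 1L,
                                  run_cap = 9L) {
  if (!is.null(seed)) withr::local_seed(seed)
  bases <- c("A", "C", "G", "T")
  x <- sample(bases, length, replace = TRUE)
  # break background runs longer than run_cap
  repeat {
    r <- rle(x)
    long <- which(r$lengths > run_cap)
    if (!length(long)) break
    ends <- cumsum(r$lengths)
    for (i in long) {
      run_start <- ends[i] - r$lengths[i] + 1L
      brk <- seq(run_start + run_cap, ends[i], by = run_cap + 1L)
      x[brk] <- sample(setdiff(bases, r$values[i]), length(brk),
                       replace = TRUE)
    }
  }
  if (!is.null(homopolymer_spec)) {
    hs <- tibble::as_tibble(homopolymer_spec)
    stopifnot(all(c("at", "base", "len") %in% names(hs)))
    if (any(hs$at + hs$len > length) || any(hs$at < 0)) {
      stop("gen_reference_context: homopolymer tract outside window",
           call. = FALSE)
    }
    if (nrow(hs) > 1) {
      o <- order(hs$at)
      if (any(hs$at[o][-1] < (hs$at + hs$len)[o][-nrow(hs)])) {
        stop("gen_reference_context: overlapping homopolymer tracts",
             call. = FALSE)
      }
    }
    for (i in seq_len(nrow(hs))) {
      span <- (hs$at[i] + 1L):(hs$at[i] + hs$len[i])
      x[span] <- hs$base[i]
      # pin flanking bases so the run length is exactly as requested
      for (p in c(hs$at[i], hs$at[i] + hs$len[i] + 1L)) {
        if (p >= 1 && p <= length && x[p] == hs$base[i]) {
          x[p] <- sample(setdiff(bases, hs$base[i]), 1)
        }
      }
    }
  }
  ref_context(paste(x, collapse = ""), offset = offset, chrom = chrom)
}

#' Annotate calls with homopolymer run length
#'
#' Adds an `hp_len` column: the longest single-base reference run
#' overlapping each variant (computed once per context, vectorized).
#'
#' @param x A `callset` whose calls are covered by `context`.
#' @param context A [ref_context()].
#' @return The `callset` with an `hp_len` integer column.
#' @export
annotate_homopolymers <- function(x, context) {
  stopifnot(inherits(x, "callset"), inherits(context, "ref_context"))
  bases <- strsplit(context$seq, "", fixed = TRUE)[[1]]
  r <- rle(bases)
  runlen_at <- rep(r$lengths, r$lengths)
  calls <- tibble::as_tibble(x)
  idx <- calls$pos - context$offset + 1L
  n <- base::length(runlen_at)
  hp <- runlen_at[pmin(pmax(idx, 1L), n)]
  span <- nchar(calls$ref)
  for (k in seq_len(max(c(span, 1)))) {
    j <- pmin(pmax(idx + k, 1L), n)
    hp <- ifelse(span >= k | k == 1L, pmax(hp, runlen_at[j]), hp)
  }
  calls$hp_len <- as.integer(hp)
  rebuild_callset(calls, x)
}

#' Generate a truth callset with known composition
#'
#' Sites are placed at distinct positions inside the target intervals
#' (indel-bearing callsets use spaced positions so that left-alignment
#' cannot collide two sites), with alleles consistent with a reference
#' context and genotype classes drawn from the requested HET/HOMALT mix.
#' Indels are 1-3 bp insertions or deletions, left-aligned at generation.
#'
#' @param n_sites Number of variant sites.
#' @param intervals Target `interval_set`.
#' @param snv_frac Expected fraction of SNVs (the rest are indels).
#' @param genotype_mix Named vector `c(HET=, HOMALT=)` of proportions.
#' @param context Optional [ref_context()] covering the intervals; one is
#'   generated (capped-run background) if omitted.
#' @param seed Optional integer seed.
#' @param sample,replicate_id,assay Provenance of the emitted callset.
#' @return A `callset` (with `hp_len` annotation); the generating context
#'   is attached as `attr(x, "context")`.
#' @export
gen_truth_callset <- function(n_sites, intervals, snv_frac = 0.8,
                              genotype_mix = c(HET = 2 / 3, HOMALT = 1 / 3),
                              context = NULL, seed = NULL,
                              sample = "SYNTH1", replicate_id = "SYNTH1/truth",
                              assay = "reference") {
  if (!is.null(seed)) withr::local_seed(seed)
  intervals <- as_interval_set(intervals)
  stopifnot(nrow(intervals) > 0, n_sites >= 1)
  chroms <- unique(intervals$chrom)
  if (length(chroms) != 1) {
    stop("gen_truth_callset: single-chromosome intervals expected",
         call. = FALSE)
  }
  if (is.null(context)) {
    context <- gen_reference_context(max(intervals$end) + 16L,
                                     chrom = chroms, offset = 1L)
  }
  all_pos <- unlist(purrr::map2(intervals$start, intervals$end,
                                ~ seq.int(.x + 1L, .y)))
  spacing <- if (snv_frac < 1) 12L else 1L
  candidates <- all_pos[seq.int(1L, base::length(all_pos), by = spacing)]
  # keep indel room inside the context window
  candidates <- candidates[candidates + 8L <=
                             context$offset + nchar(context$seq) - 1L &
                             candidates > context$offset]
  if (n_sites > base::length(candidates)) {
    stop("gen_truth_callset: intervals too small for ", n_sites, " sites",
         call. = FALSE)
  }
  pos <- sort(sample(candidates, n_sites))
  is_snv <- stats::runif(n_sites) < snv_frac
  ref_base <- context_base_vec(context, pos)
  alt <- character(n_sites)
  ref <- character(n_sites)
  other <- c("A", "C", "G", "T")
  for (i in seq_len(n_sites)) {
    if (is_snv[i]) {
      ref[i] <- ref_base[i]
      alt[i] <- sample(setdiff(other, ref_base[i]), 1)
    } else if (stats::runif(1) < 0.5) {   # deletion of 1-3 bases
      len <- sample(1:3, 1)
      ref[i] <- context_slice(context, pos[i], pos[i] + len)
      alt[i] <- ref_base[i]
    } else {                              # insertion of 1-3 bases
      len <- sample(1:3, 1)
      ref[i] <- ref_base[i]
      alt[i] <- paste0(ref_base[i],
                       paste(sample(other, len, replace = TRUE),
                             collapse = ""))
    }
  }
  gmix <- genotype_mix / sum(genotype_mix)
  gclass <- sample(names(gmix), n_sites, replace = TRUE, prob = gmix)
  cs <- callset(
    tibble::tibble(chrom = chroms, pos = pos, ref = ref, alt = alt,
                   gclass = gclass, filter = "PASS"),
    replicate_id = replicate_id, sample = sample, assay = assay
  )
  cs <- normalize_calls(cs, context)
  cs <- annotate_homopolymers(cs, context)
  attr(cs, "context") <- context
  cs
}

context_base_vec <- function(ctx, pos) {
  i <- pos - ctx$offset + 1L
  substring(ctx$seq, i, i)
}

#' Genotype-confusion model
#'
#' Parameters of the error process applied by [corrupt()], each an
#' independent per-site probability. Events are applied in a fixed order
#' (miss, then different-allele, then genotype error, then filter) so the
#' analytic expectations are well defined: downstream of a corruption with
#' no overlapping extras, `NRS = (1 - p_miss)(1 - p_filtered)
#' (1 - p_diffallele)` and `NRC = NRS * (1 - p_gterr)`.
#'
#' @param p_miss Probability a truth site is absent from the test set.
#' @param p_filtered Probability a called site is FILTERED.
#' @param p_gterr Probability a called site's genotype class is perturbed
#'   (HET and HOMALT swap).
#' @param p_diffallele Probability a called site carries a different alt.
#' @param fp_per_kb Rate of test-only calls per kilobase of interval.
#' @param hp_dropout Extra miss probability for indels inside homopolymer
#'   runs of at least `hp_run_min` bases (dominant real-data FN class).
#' @param hp_run_min Run threshold in bases (default 10).
#' @return A list of class `confusion_model`.
#' @export
confusion_model <- function(p_miss = 0.05, p_filtered = 0, p_gterr = 0,
                            p_diffallele = 0, fp_per_kb = 0,
                            hp_dropout = 0, hp_run_min = 10) {
  probs <- c(p_miss = p_miss, p_filtered = p_filtered, p_gterr = p_gterr,
             p_diffallele = p_diffallele, hp_dropout = hp_dropout)
  if (any(probs < 0 | probs > 1)) {
    stop("confusion_model: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (fp_per_kb < 0) stop("confusion_model: fp_per_kb must be >= 0",
                          call. = FALSE)
  structure(list(p_miss = p_miss, p_filtered = p_filtered,
                 p_gterr = p_gterr, p_diffallele = p_diffallele,
                 fp_per_kb = fp_per_kb, hp_dropout = hp_dropout,
                 hp_run_min = hp_run_min),
            class = "confusion_model")
}

#' Quality-score mixture model
#'
#' Scores attached to test calls by latent truth status: calls derived
#' from real truth sites draw from the "true" normal distribution,
#' artifactual calls (false positives and different-allele errors) from
#' the "artifact" one. The closed-form operating characteristics of the
#' mixture are available from [score_model_roc()], the oracle for
#' threshold sweeps.
#'
#' @param true_mean,true_sd Location/scale of true-call scores.
#' @param artifact_mean,artifact_sd Location/scale of artifact scores.
#' @return A list of class `score_model`.
#' @export
score_model <- function(true_mean = 4, true_sd = 1.5,
                        artifact_mean = -2, artifact_sd = 1.5) {
  stopifnot(true_sd > 0, artifact_sd > 0)
  structure(list(true_mean = true_mean, true_sd = true_sd,
                 artifact_mean = artifact_mean, artifact_sd = artifact_sd),
            class = "score_model")
}

#' Closed-form score-threshold characteristics
#'
#' For each threshold `t` (calls with score `>= t` pass): the expected
#' fractions of true and artifact calls passing, and the expected
#' precision given the mixture weights.
#'
#' @param model A [score_model()].
#' @param thresholds Numeric thresholds.
#' @param n_true,n_artifact Expected counts of true and artifact calls.
#' @return Tibble: `threshold`, `pass_true_frac`, `pass_artifact_frac`,
#'   `precision`.
#' @export
score_model_roc <- function(model, thresholds, n_true, n_artifact) {
  s1 <- stats::pnorm(thresholds, model$true_mean, model$true_sd,
                     lower.tail = FALSE)
  s0 <- stats::pnorm(thresholds, model$artifact_mean, model$artifact_sd,
                     lower.tail = FALSE)
  tibble::tibble(
    threshold = thresholds,
    pass_true_frac = s1,
    pass_artifact_frac = s0,
    precision = (n_true * s1) / (n_true * s1 + n_artifact * s0)
  )
}

#' Corrupt a truth callset into a synthetic test callset
#'
#' Applies the [confusion_model()] error processes independently per site,
#' in the order miss, different-allele, genotype error, filter; then adds
#' false-positive calls uniformly over interval bases not occupied by
#' truth sites, and attaches quality scores by latent status when a
#' [score_model()] is given. The latent per-site labels are recorded in
#' `attr(x, "latent")` so tests can do exact TP/FP/FN accounting.
#'
#' @param truth A `callset` (ideally from [gen_truth_callset()], whose
#'   context and `hp_len` annotation enable the homopolymer dropout and
#'   context-consistent false positives).
#' @param model A [confusion_model()].
#' @param scores Optional [score_model()].
#' @param intervals `interval_set` used for false-positive placement
#'   (required when `fp_per_kb > 0`).
#' @param seed Optional integer seed.
#' @param replicate_id Identifier of the emitted test callset.
#' @return A `callset` with attribute `latent`: tibble `key`, `status`
#'   (`kept`, `gterr`, `filtered`, `diffallele`, `missed`, `fp`).
#' @export
corrupt <- function(truth, model = confusion_model(), scores = NULL,
                    intervals = NULL, seed = NULL,
                    replicate_id = "SYNTH1/test") {
  stopifnot(inherits(truth, "callset"), inherits(model, "confusion_model"))
  if (!is.null(seed)) withr::local_seed(seed)
  calls <- tibble::as_tibble(truth)
  n <- nrow(calls)
  hp_len <- calls$hp_len %||% rep(0L, n)
  p_miss_i <- 1 - (1 - model$p_miss) *
    (1 - ifelse(calls$vclass == "INDEL" & hp_len >= model$hp_run_min,
                model$hp_dropout, 0))
  missed <- stats::runif(n) < p_miss_i
  diffa <- !missed & stats::runif(n) < model$p_diffallele
  gterr <- !missed & !diffa & stats::runif(n) < model$p_gterr
  filt <- !missed & stats::runif(n) < model$p_filtered

  out <- calls[!missed, , drop = FALSE]
  st <- rep("kept", nrow(out))
  st[diffa[!missed]] <- "diffallele"
  st[gterr[!missed]] <- "gterr"
  # different alt allele at the same site
  for (i in which(diffa[!missed])) {
    da <- different_allele(out$ref[i], out$alt[i])
    out$ref[i] <- da$ref
    out$alt[i] <- da$alt
  }
  sw <- gterr[!missed] & out$gclass %in% c("HET", "HOMALT")
  out$gclass[sw] <- ifelse(out$gclass[sw] == "HET", "HOMALT", "HET")
  out$filter[filt[!missed]] <- "LowQual"
  st[filt[!missed]] <- ifelse(st[filt[!missed]] == "kept", "filtered",
                              st[filt[!missed]])

  # latent labels use the *emitted* keys (different-allele calls carry
  # their mutated alleles) plus the missed truth keys
  latent <- dplyr::bind_rows(
    tibble::tibble(key = variant_key(calls)[missed], status = "missed"),
    tibble::tibble(key = paste(out$chrom, out$pos, out$ref, out$alt,
                               sep = ":"), status = st))

  # false positives at unoccupied interval positions
  fp <- NULL
  if (model$fp_per_kb > 0) {
    if (is.null(intervals)) {
      stop("corrupt: intervals required when fp_per_kb > 0", call. = FALSE)
    }
    intervals <- as_interval_set(intervals)
    n_fp <- stats::rpois(1, model$fp_per_kb * total_bases(intervals) / 1000)
    if (n_fp > 0) {
      all_pos <- unlist(purrr::map2(intervals$start, intervals$end,
                                    ~ seq.int(.x + 1L, .y)))
      free <- setdiff(all_pos, calls$pos)
      n_fp <- min(n_fp, base::length(free))
      fpos <- sort(sample(free, n_fp))
      ctx <- attr(truth, "context")
      rb <- if (!is.null(ctx)) context_base_vec(ctx, fpos) else
        sample(c("A", "C", "G", "T"), n_fp, replace = TRUE)
      ab <- purrr::map_chr(rb, ~ sample(setdiff(c("A", "C", "G", "T"), .x), 1))
      fp <- tibble::tibble(chrom = intervals$chrom[1], pos = fpos,
                           ref = rb, alt = ab, gclass = "HET",
                           filter = "PASS")
      latent <- dplyr::bind_rows(
        latent,
        tibble::tibble(key = paste(fp$chrom, fp$pos, fp$ref, fp$alt,
                                   sep = ":"), status = "fp"))
    }
  }
  keep_cols <- intersect(c("chrom", "pos", "ref", "alt", "gclass", "filter",
                           "hp_len"), names(out))
  out <- dplyr::bind_rows(out[keep_cols], fp)
  dup <- duplicated(paste(out$chrom, out$pos, out$ref, out$alt))
  out <- out[!dup, , drop = FALSE]
  if (!is.null(scores)) {
    stopifnot(inherits(scores, "score_model"))
    key_out <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
    status_out <- latent$status[match(key_out, latent$key)]
    is_artifact <- status_out %in% c("fp", "diffallele")
    out$vqslod <- ifelse(
      is_artifact,
      stats::rnorm(nrow(out), scores$artifact_mean, scores$artifact_sd),
      stats::rnorm(nrow(out), scores$true_mean, scores$true_sd))
  }
  res <- callset(out, replicate_id = replicate_id,
                 sample = attr(truth, "sample"), assay = "WGS")
  attr(res, "latent") <- latent
  attr(res, "context") <- attr(truth, "context")
  res
}

# a same-class, different alt at the same site (no context needed)
different_allele <- function(ref, alt) {
  bases <- c("A", "C", "G", "T")
  if (nchar(ref) == 1 && nchar(alt) == 1) {          # SNV: swap the base
    list(ref = ref, alt = sample(setdiff(bases, c(ref, alt)), 1))
  } else if (nchar(alt) > nchar(ref)) {              # insertion: new insert
    ins <- substring(alt, 2)
    last <- substring(ins, nchar(ins), nchar(ins))
    new_ins <- paste0(substr(ins, 1, nchar(ins) - 1),
                      sample(setdiff(bases, last), 1))
    list(ref = ref, alt = paste0(ref, new_ins))
  } else {                                           # deletion: call an
    anchor <- substring(ref, 1, 1)                   # insertion instead
    list(ref = anchor, alt = paste0(anchor, sample(bases, 1)))
  }
}

#' Generate a synthetic per-base coverage track
#'
#' Constant base depth over the intervals, with optional low-depth and
#' MAPQ0-excess patches and optional Poisson depth jitter.
#'
#' @param intervals Target `interval_set`.
#' @param base_depth Depth outside patches (default 30).
#' @param low_patches Optional data frame `chrom`, `start`, `end`, `depth`.
#' @param mapq0_patches Optional data frame `chrom`, `start`, `end`,
#'   `frac` (MAPQ0 read fraction; counts are rounded up so the fraction is
#'   at least `frac`).
#' @param jitter Poisson-jitter the depth (default off).
#' @param seed Optional integer seed.
#' @return A `coverage_track`.
#' @export
gen_coverage <- function(intervals, base_depth = 30, low_patches = NULL,
                         mapq0_patches = NULL, jitter = FALSE, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  intervals <- as_interval_set(intervals)
  pos <- unlist(purrr::map2(intervals$start, intervals$end,
                            ~ seq.int(.x + 1L, .y)))
  chrom <- rep(intervals$chrom, intervals$end - intervals$start)
  n <- base::length(pos)
  depth <- if (jitter) stats::rpois(n, base_depth) else
    rep(as.integer(base_depth), n)
  apply_patches <- function(patches, what) {
    check_patch_overlap(patches, what)
    for (i in seq_len(nrow(patches))) {
      hit <- chrom == patches$chrom[i] & pos > patches$start[i] &
        pos <= patches$end[i]
      if (what == "depth") {
        depth[hit] <<- as.integer(patches$depth[i])
      } else {
        mapq0[hit] <<- pmin(depth[hit],
                            as.integer(ceiling(patches$frac[i] * depth[hit])))
      }
    }
  }
  mapq0 <- rep(0L, n)
  if (!is.null(low_patches)) apply_patches(tibble::as_tibble(low_patches),
                                           "depth")
  if (!is.null(mapq0_patches)) apply_patches(tibble::as_tibble(mapq0_patches),
                                             "mapq0")
  coverage_track(tibble::tibble(chrom = chrom, pos = pos, depth = depth,
                                mapq0 = mapq0))
}

check_patch_overlap <- function(patches, what) {
  if (nrow(patches) < 2) return(invisible())
  for (ch in unique(patches$chrom)) {
    p <- patches[patches$chrom == ch, ]
    p <- p[order(p$start), ]
    if (any(p$start[-1] < p$end[-nrow(p)])) {
      stop("gen_coverage: overlapping ", what, " patches on ", ch,
           call. = FALSE)
    }
  }
  invisible()
}

#' Batch-effect model for replicate families
#'
#' Additive model of pairwise concordance across a replicate family:
#' `concordance = base - sum(active kind decrements) + noise`, clipped to
#' `[0, 1]`. The default design is the shipped WGS replicate metadata,
#' whose NA12878 (6 replicates) and NA18507 (3 replicates) families give
#' 18 same-sample pairs.
#'
#' @param base Baseline concordance (default 0.99).
#' @param deltas Named vector of per-kind concordance decrements over
#'   `intra_run`, `inter_run`, `inter_machine`, `inter_mode`,
#'   `inter_library`.
#' @param noise_sd Gaussian pair noise standard deviation.
#' @param design Replicate metadata (see [read_design()]); default
#'   [wgs_replicate_design()].
#' @return A list of class `batch_effect_model`.
#' @export
batch_effect_model <- function(base = 0.99,
                               deltas = c(intra_run = 0, inter_run = 0,
                                          inter_machine = 0, inter_mode = 0,
                                          inter_library = 0.0006),
                               noise_sd = 0.0002, design = NULL) {
  d <- stats::setNames(rep(0, base::length(KIND_NAMES)), KIND_NAMES)
  d[names(deltas)] <- deltas
  if (is.null(design)) design <- wgs_replicate_design()
  structure(list(base = base, deltas = d, noise_sd = noise_sd,
                 design = design),
            class = "batch_effect_model")
}

#' Generate a replicate family with known batch effects
#'
#' Classifies all same-sample pairs of the template's metadata
#' ([build_design()]) and draws each pair's concordance from the additive
#' [batch_effect_model()]. The output feeds [regress_concordance()]
#' directly, making the model's decrements the known quantities a
#' regression should recover.
#'
#' @param template A [batch_effect_model()].
#' @param seed Optional integer seed.
#' @return List: `design` (the metadata) and `pairs` (a
#'   `comparison_design` with a `concordance` column).
#' @export
gen_replicate_family <- function(template = batch_effect_model(),
                                 seed = NULL) {
  stopifnot(inherits(template, "batch_effect_model"))
  if (!is.null(seed)) withr::local_seed(seed)
  pairs <- build_design(template$design)
  ind <- as.matrix(as.data.frame(lapply(pairs[KIND_NAMES], as.numeric)))
  mu <- template$base - as.vector(ind %*% template$deltas[KIND_NAMES])
  pairs$concordance <- pmin(pmax(
    mu + stats::rnorm(nrow(pairs), 0, template$noise_sd), 0), 1)
  list(design = template$design, pairs = pairs)
}

#' Shipped replicate-design tables
#'
#' Replicate metadata for the WES and WGS validation families. Replicates
#' are named *sample/run-machine-slot*; run, machine, slot and mode derive
#' from the naming scheme (WES run 4 is the rapid-run mode). The library
#' assignments are a synthetic reconstruction consistent with the
#' experiment design (inter-machine pairs share a preparation; some
#' same-run and cross-run pairs differ in preparation) — see the shipped
#' TSV headers.
#'
#' @return A tibble with columns `replicate_id`, `sample`, `library`,
#'   `run`, `machine`, `mode`, `assay`.
#' @export
wes_replicate_design <- function() {
  read_design(system.file("extdata", "wes_replicate_design.tsv",
                          package = "concordare", mustWork = TRUE))
}

#' @rdname wes_replicate_design
#' @export
wgs_replicate_design <- function() {
  read_design(system.file("extdata", "wgs_replicate_design.tsv",
                          package = "concordare", mustWork = TRUE))
}
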