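#' Per-base coverage tracks
#'
#' A coverage track is a tibble with columns `chrom`, `pos` (1-based),
#' `depth` (reads) and `mapq0` (reads with mapping quality 0). Positions
#' absent from the track have depth 0. `mapq0 <= depth` everywhere.
#'
#' @param path TSV file (optionally gzipped) with a header line
#'   `chrom pos depth mapq0`.
#' @return A tibble of class `coverage_track`.
#' @export
read_coverage <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    depth = readr::col_integer(), mapq0 = readr::col_integer()
  ))
  coverage_track(df)
}

#' @rdname read_coverage
#' @param df Data frame with columns `chrom`, `pos`, `depth`, `mapq0`.
#' @export
coverage_track <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("chrom", "pos", "depth", "mapq0") %in% names(df)))
  if (any(df$depth < 0) || any(df$mapq0 > df$depth)) {
    stop("coverage_track: need 0 <= mapq0 <= depth at every position",
         call. = FALSE)
  }
  tibble::new_tibble(df, class = "coverage_track")
}

#' @rdname read_coverage
#' @param x A `coverage_track`.
#' @export
write_coverage <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

callable_predicate <- function(depth, mapq0, min_depth, max_mapq0_frac) {
  depth >= min_depth & mapq0 <= max_mapq0_frac * depth
}

#' Callable regions from depth and MAPQ0
#'
#' A base is confidently callable iff its depth is at least `min_depth`
#' (default 20-fold) and the fraction of MAPQ0 (ambiguously mapped) reads
#' is at most `max_mapq0_frac` (default 10%; a fraction of exactly 0.10 is
#' callable). Bases absent from the track have depth 0 and are never
#' callable. Maximal runs of callable bases are returned intersected with
#' the target intervals.
#'
#' @param track A `coverage_track`.
#' @param intervals Target `interval_set`.
#' @param min_depth Minimum depth (fold); default 20.
#' @param max_mapq0_frac Maximum MAPQ0 read fraction; default 0.10.
#' @return An `interval_set` of callable regions.
#' @export
callable_regions <- function(track, intervals, min_depth = 20,
                             max_mapq0_frac = 0.10) {
  stopifnot(min_depth > 0, max_mapq0_frac >= 0)
  intervals <- as_interval_set(intervals)
  keep <- positions_in_intervals(track$chrom, track$pos, intervals) &
    callable_predicate(track$depth, track$mapq0, min_depth, max_mapq0_frac)
  if (!any(keep)) {
    return(interval_set(tibble::tibble(chrom = character(),
                                       start = integer(), end = integer())))
  }
  pts <- track[keep, c("chrom", "pos")]
  lev <- chrom_levels(pts$chrom)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    factor(pts$chrom, lev), IRanges::IRanges(pts$pos, pts$pos)))
  new_interval_set(granges_to_tbl(gr))
}

#' Coverage summary over target intervals
#'
#' Mean depth and the percentage of target bases at or above 1-, 10-, 20-
#' and 30-fold coverage are computed over the **un-flanked** statistics
#' intervals (bases with no track record count as depth 0, including in
#' the mean). The percentage of coding bases confidently callable is
#' computed from callable regions over the statistics intervals expanded
#' by `flank_bp`, intersected with the coding-exon intervals.
#'
#' @param track A `coverage_track`.
#' @param stat_intervals Capture-target `interval_set` (un-flanked).
#' @param coding_intervals Coding-exon `interval_set`.
#' @param flank_bp Flank added to `stat_intervals` for the callable-coding
#'   computation; default 100.
#' @param min_depth,max_mapq0_frac Callable thresholds (see
#'   [callable_regions()]).
#' @return A one-row tibble: `mean_depth`, `pct_ge_1x`, `pct_ge_10x`,
#'   `pct_ge_20x`, `pct_ge_30x`, `pct_callable_coding`. Percentages are in
#'   0-100, full precision.
#' @export
coverage_summary <- function(track, stat_intervals, coding_intervals,
                             flank_bp = 100, min_depth = 20,
                             max_mapq0_frac = 0.10) {
  stat_intervals <- as_interval_set(stat_intervals)
  coding_intervals <- as_interval_set(coding_intervals)
  stopifnot(nrow(stat_intervals) > 0, nrow(coding_intervals) > 0)
  n_bases <- total_bases(stat_intervals)
  inside <- positions_in_intervals(track$chrom, track$pos, stat_intervals)
  depth <- track$depth[inside]
  pct <- function(thr) 100 * sum(depth >= thr) / n_bases
  callable <- callable_regions(track,
                               expand_intervals(stat_intervals, flank_bp),
                               min_depth, max_mapq0_frac)
  callable_coding <- intersect_intervals(callable, coding_intervals)
  tibble::tibble(
    mean_depth = sum(depth) / n_bases,
    pct_ge_1x = pct(1), pct_ge_10x = pct(10),
    pct_ge_20x = pct(20), pct_ge_30x = pct(30),
    pct_callable_coding = 100 * total_bases(callable_coding) /
      total_bases(coding_intervals)
  )
}

#' Squared-off callable intersection across replicates
#'
#' The per-base AND of confidently callable regions across all replicates
#' of a sample: the region over which every replicate could call variants.
#'
#' @param tracks List of two or more `coverage_track`s.
#' @param intervals Target `interval_set`.
#' @inheritParams callable_regions
#' @return An `interval_set`, a subset of every per-replicate callable set.
#' @export
squared_off_callable <- function(tracks, intervals, min_depth = 20,
                                 max_mapq0_frac = 0.10) {
  stopifnot(is.list(tracks), length(tracks) >= 2)
  sets <- purrr::map(tracks, callable_regions, intervals = intervals,
                     min_depth = min_depth, max_mapq0_frac = max_mapq0_frac)
  purrr::reduce(sets, intersect_intervals)
}
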