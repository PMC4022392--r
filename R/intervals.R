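#' Genomic interval sets
#'
#' An `interval_set` is a tibble with columns `chrom`, `start` and `end`
#' describing 0-based, half-open intervals (BED convention). Construction
#' canonicalizes the input: intervals are merged where they overlap or abut,
#' and sorted by chromosome (natural human order, `chr1`..`chr22`, `chrX`,
#' `chrY`, `chrM`, unknown contigs lexicographically after) then start.
#'
#' @param chrom Character vector of chromosome names, or a data frame with
#'   columns `chrom`, `start`, `end`.
#' @param start,end Integer vectors; 0-based inclusive start, exclusive end.
#' @return A tibble of class `interval_set` with columns `chrom`, `start`,
#'   `end`, canonical (sorted, disjoint, `start < end`).
#' @examples
#' interval_set("chr1", c(100, 150), c(200, 250))
#' @export
interval_set <- function(chrom, start = NULL, end = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  } else {
    df <- tibble::tibble(chrom = chrom, start = start, end = end)
  }
  if (nrow(df) == 0) {
    return(new_interval_set(tibble::tibble(
      chrom = character(), start = integer(), end = integer()
    )))
  }
  if (any(df$end <= df$start)) {
    stop("interval_set: every interval must satisfy start < end", call. = FALSE)
  }
  gr <- GenomicRanges::reduce(as_granges(df))
  new_interval_set(granges_to_tbl(gr))
}

new_interval_set <- function(df) {
  tibble::new_tibble(df, class = "interval_set")
}

#' @export
as_interval_set <- function(x) {
  if (inherits(x, "interval_set")) x else interval_set(x)
}

# natural human chromosome order; unknown contigs lexicographic after
chrom_levels <- function(chroms) {
  canonical <- c(paste0("chr", 1:22), "chrX", "chrY", "chrM")
  extra <- sort(setdiff(unique(chroms), canonical))
  c(canonical, extra)
}

as_granges <- function(df) {
  lev <- chrom_levels(df$chrom)
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = lev),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

granges_to_tbl <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Total bases covered by an interval set
#'
#' @param x An `interval_set`.
#' @return Integer; the sum of interval widths.
#' @export
total_bases <- function(x) {
  x <- as_interval_set(x)
  sum(x$end - x$start)
}

#' Interval-set algebra
#'
#' Set operations on canonical interval sets: intersection, union,
#' subtraction, and symmetric expansion by a flank. Expansion adds
#' `flank_bp` bases on each side of every interval, then re-merges
#' (overlapping flanked targets are merged). All outputs are canonical.
#'
#' @param a,b `interval_set` objects (or data frames coercible to one).
#' @param flank_bp Non-negative number of bases added to each side.
#' @return An `interval_set`.
#' @examples
#' a <- interval_set("chr1", 0, 10)
#' b <- interval_set("chr1", 5, 15)
#' intersect_intervals(a, b) # chr1:5-10
#' expand_intervals(interval_set("chr1", 200, 300), 100) # chr1:100-400
#' @name interval-algebra
NULL

#' @rdname interval-algebra
#' @export
intersect_intervals <- function(a, b) {
  gr <- suppressWarnings(
    GenomicRanges::intersect(as_granges(as_interval_set(a)),
                             as_granges(as_interval_set(b)))
  )
  new_interval_set(granges_to_tbl(gr))
}

#' @rdname interval-algebra
#' @export
union_intervals <- function(a, b) {
  gr <- suppressWarnings(
    GenomicRanges::union(as_granges(as_interval_set(a)),
                         as_granges(as_interval_set(b)))
  )
  new_interval_set(granges_to_tbl(gr))
}

#' @rdname interval-algebra
#' @export
subtract_intervals <- function(a, b) {
  gr <- suppressWarnings(
    GenomicRanges::setdiff(as_granges(as_interval_set(a)),
                           as_granges(as_interval_set(b)))
  )
  new_interval_set(granges_to_tbl(gr))
}

#' @rdname interval-algebra
#' @export
expand_intervals <- function(a, flank_bp) {
  if (length(flank_bp) != 1 || is.na(flank_bp) || flank_bp < 0) {
    stop("expand_intervals: flank_bp must be a single non-negative number",
         call. = FALSE)
  }
  a <- as_interval_set(a)
  if (nrow(a) == 0) return(a)
  interval_set(a$chrom, pmax(a$start - as.integer(flank_bp), 0L),
               a$end + as.integer(flank_bp))
}

#' Apply a named interval operation
#'
#' Thin dispatcher over the interval-algebra verbs, convenient for
#' programmatic use.
#'
#' @param a,b Interval sets (`b` ignored for `expand`).
#' @param op One of `"intersect"`, `"union"`, `"subtract"`, `"expand"`.
#' @param flank_bp Flank size for `op = "expand"`.
#' @return An `interval_set`.
#' @export
interval_ops <- function(a, b = NULL, op = c("intersect", "union", "subtract",
                                             "expand"), flank_bp = 0) {
  op <- match.arg(op)
  switch(op,
    intersect = intersect_intervals(a, b),
    union = union_intervals(a, b),
    subtract = subtract_intervals(a, b),
    expand = expand_intervals(a, flank_bp)
  )
}

#' Read and write BED interval files
#'
#' BED files are 0-based half-open; columns beyond the first three are
#' ignored on read. Reading canonicalizes (merges and sorts) the result.
#'
#' @param path Path to a BED file.
#' @return `read_bed()` returns an `interval_set`; `write_bed()` returns
#'   `path` invisibly.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  interval_set(tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ))
}

#' @rdname read_bed
#' @param x An `interval_set`.
#' @export
write_bed <- function(x, path) {
  x <- as_interval_set(x)
  rtracklayer::export(as_granges(x), path, format = "BED")
  invisible(path)
}

# membership of 1-based positions in an interval set (pos-1 in [start, end))
positions_in_intervals <- function(chrom, pos, intervals) {
  intervals <- as_interval_set(intervals)
  if (nrow(intervals) == 0 || length(pos) == 0) {
    return(rep(FALSE, length(pos)))
  }
  lev <- chrom_levels(c(chrom, intervals$chrom))
  q <- GenomicRanges::GRanges(factor(chrom, lev), IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(factor(intervals$chrom, lev),
                              IRanges::IRanges(intervals$start + 1L,
                                               intervals$end))
  GenomicRanges::countOverlaps(q, s) > 0
}
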