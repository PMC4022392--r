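#' Reference context windows
#'
#' A `ref_context` is a window of reference sequence with its 1-based
#' genomic offset, sufficient for left-aligning indels without full-genome
#' FASTA handling.
#'
#' @param seq A single character string of A/C/G/T bases.
#' @param offset 1-based genomic position of the first base of `seq`.
#' @param chrom Chromosome the window belongs to.
#' @return A list of class `ref_context` with elements `seq`, `offset`,
#'   `chrom`.
#' @export
ref_context <- function(seq, offset = 1L, chrom = "chr1") {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) >= 1)
  structure(list(seq = toupper(seq), offset = as.integer(offset),
                 chrom = chrom),
            class = "ref_context")
}

context_base <- function(ctx, pos) {
  i <- pos - ctx$offset + 1L
  if (any(i < 1 | i > nchar(ctx$seq))) {
    stop("position outside context window", call. = FALSE)
  }
  substring(ctx$seq, i, i)
}

context_slice <- function(ctx, from, to) {
  i <- from - ctx$offset + 1L
  j <- to - ctx$offset + 1L
  if (i < 1 || j > nchar(ctx$seq) || j < i - 1) {
    stop("requested slice outside context window", call. = FALSE)
  }
  substr(ctx$seq, i, j)
}

# replace ref allele at pos with alt within the window; used by the
# haplotype-preservation oracle and tests
apply_variant <- function(ctx, pos, ref, alt) {
  i <- pos - ctx$offset + 1L
  if (context_slice(ctx, pos, pos + nchar(ref) - 1L) != ref) {
    stop("ref allele does not match context", call. = FALSE)
  }
  paste0(substr(ctx$seq, 1, i - 1L), alt,
         substring(ctx$seq, i + nchar(ref)))
}

#' Left-align and trim a variant to canonical parsimonious form
#'
#' Applies the standard normalization algorithm: shared trailing bases are
#' trimmed (extending leftward through the reference when an allele would
#' become empty, which is what shifts indels left through tandem repeats),
#' then shared leading bases are trimmed down to the single required anchor
#' base. The returned variant applied to the reference yields the same
#' haplotype as the input, and the operation is idempotent. SNVs are
#' returned unchanged.
#'
#' @param pos,ref,alt Variant to normalize (1-based `pos`).
#' @param context A [ref_context()] covering the variant plus enough left
#'   flank to prove the left-shift fixpoint (at least one repeat unit).
#' @return A list with elements `pos`, `ref`, `alt`.
#' @examples
#' ctx <- ref_context("GCACACAT", offset = 100)
#' # deletion of CA written at the right end of the CACACA tract
#' left_align(104, "ACA", "A", ctx)  # shifts to pos 100, GCA > G
#' @export
left_align <- function(pos, ref, alt, context) {
  stopifnot(inherits(context, "ref_context"))
  pos <- as.integer(pos)
  if (ref == alt) stop("left_align: ref and alt are identical", call. = FALSE)
  if (context_slice(context, pos, pos + nchar(ref) - 1L) != ref) {
    stop("left_align: ref allele does not match reference context",
         call. = FALSE)
  }
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    last_r <- substring(ref, nr, nr)
    last_a <- substring(alt, na, na)
    if (nr > 0 && na > 0 && last_r == last_a) {
      ref <- substr(ref, 1, nr - 1L)
      alt <- substr(alt, 1, na - 1L)
      if (nchar(ref) == 0 || nchar(alt) == 0) {
        if (pos - 1L < context$offset) {
          stop("left_align: context window too small to left-align; ",
               "supply a larger left flank", call. = FALSE)
        }
        pos <- pos - 1L
        b <- context_base(context, pos)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      }
      next
    }
    if (nchar(ref) > 1 && nchar(alt) > 1 &&
        substring(ref, 1, 1) == substring(alt, 1, 1)) {
      ref <- substring(ref, 2)
      alt <- substring(alt, 2)
      pos <- pos + 1L
      next
    }
    break
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize every call in a callset against a reference context
#'
#' Runs [left_align()] over each call (SNVs pass through unchanged) and
#' re-validates the callset; a normalization that collapses two records
#' onto the same variant key is an error.
#'
#' @param x A `callset` on a single chromosome covered by `context`.
#' @param context A [ref_context()].
#' @return The normalized `callset`.
#' @export
normalize_calls <- function(x, context) {
  stopifnot(inherits(x, "callset"))
  if (nrow(x) == 0) return(x)
  calls <- tibble::as_tibble(x)
  needs <- which(!(nchar(calls$ref) == 1 & nchar(calls$alt) == 1))
  for (i in needs) {
    v <- left_align(calls$pos[i], calls$ref[i], calls$alt[i], context)
    calls$pos[i] <- v$pos
    calls$ref[i] <- v$ref
    calls$alt[i] <- v$alt
  }
  rebuild_callset(calls, x)
}
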