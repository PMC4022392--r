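#' Variant callsets
#'
#' A `callset` is a tibble of normalized, bi-allelic genotype calls for one
#' replicate of one sample, with one row per variant key
#' (`chrom`, `pos`, `ref`, `alt`). Columns:
#'
#' * `chrom`, `pos` — chromosome and 1-based position of the first reference
#'   base; `ref`, `alt` — reference and single alternate allele strings.
#' * `vclass` — `"SNV"` (both alleles length 1), `"INDEL"` (lengths differ,
#'   shorter is the 1-base anchor), or `"OTHER"` (e.g. MNPs).
#' * `gclass` — genotype class of this record's alt allele: `"HOMALT"`
#'   (2 copies), `"HET"` (1), `"HOMREF"` (0), `"NOCALL"` (missing).
#'   Haploid calls map alt to HOMALT and ref to HOMREF.
#' * `filter` — the raw FILTER string; `filter_status` — `"PASS"` for
#'   `PASS`/`.`, otherwise `"FILTERED"`.
#' * optional numeric annotation columns (`vqslod`, `qd`, `mq`, `dp`).
#'
#' Provenance (replicate id in *sample/run-machine-slot* form, sample,
#' library, run, machine, mode, assay) travels as attributes. Truth-type
#' callsets (array, panel, reference) are flagged `exhaustive`: within their
#' target intervals they are taken to report every variant, so test-only
#' calls count against precision.
#'
#' @param calls Data frame with at least `chrom`, `pos`, `ref`, `alt`,
#'   `gclass`; `filter` defaults to `"PASS"`.
#' @param replicate_id,sample Identifiers; `replicate_id` conventionally
#'   `sample/run-machine-slot`.
#' @param library,run,machine,mode,assay Provenance attributes (see
#'   [build_design()]); `mode` is `"high-throughput"` or `"rapid"`, `assay`
#'   one of `"WES"`, `"WGS"`, `"array"`, `"panel"`, `"reference"`.
#' @param exhaustive Logical; defaults to `TRUE` for array/panel/reference
#'   assays, `FALSE` otherwise.
#' @return A tibble of class `callset`, sorted by chromosome (natural
#'   order) and position, with at most one row per variant key.
#' @export
callset <- function(calls, replicate_id = "test", sample = "sample",
                    library = NA_character_, run = NA_character_,
                    machine = NA_character_, mode = NA_character_,
                    assay = NA_character_, exhaustive = NULL) {
  calls <- tibble::as_tibble(calls)
  needed <- c("chrom", "pos", "ref", "alt", "gclass")
  missing_cols <- setdiff(needed, names(calls))
  if (length(missing_cols)) {
    stop("callset: missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"filter" %in% names(calls)) calls$filter <- "PASS"
  calls$pos <- as.integer(calls$pos)
  calls$vclass <- classify_variant(calls$ref, calls$alt)
  calls$filter_status <- filter_status(calls$filter)
  if (any(calls$ref == calls$alt | nchar(calls$ref) == 0 |
            nchar(calls$alt) == 0)) {
    stop("callset: ref and alt must be non-empty and distinct",
         call. = FALSE)
  }
  bad_g <- setdiff(unique(calls$gclass),
                   c("HOMREF", "HET", "HOMALT", "NOCALL"))
  if (length(bad_g)) {
    stop("callset: invalid gclass values: ", paste(bad_g, collapse = ", "),
         call. = FALSE)
  }
  key <- variant_key(calls)
  if (anyDuplicated(key)) {
    stop("callset: duplicate variant keys (is the callset decomposed?): ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "),
         call. = FALSE)
  }
  lev <- chrom_levels(calls$chrom)
  ord <- order(match(calls$chrom, lev), calls$pos, calls$ref, calls$alt)
  calls <- calls[ord, , drop = FALSE]
  if (is.null(exhaustive)) {
    exhaustive <- isTRUE(assay %in% c("array", "panel", "reference"))
  }
  structure(
    tibble::new_tibble(calls, class = "callset"),
    replicate_id = replicate_id,
    sample = sample,
    provenance = list(library = library, run = run, machine = machine,
                      mode = mode, assay = assay),
    exhaustive = exhaustive
  )
}

#' @export
replicate_id <- function(x) attr(x, "replicate_id")

#' @export
sample_id <- function(x) attr(x, "sample")

variant_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Classify ref/alt allele pairs
#'
#' @param ref,alt Allele strings.
#' @return `"SNV"`, `"INDEL"` or `"OTHER"` per pair.
#' @export
classify_variant <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  dplyr::case_when(
    nr == 1 & na == 1 ~ "SNV",
    nr != na & pmin(nr, na) == 1 ~ "INDEL",
    TRUE ~ "OTHER"
  )
}

filter_status <- function(filter) {
  ifelse(is.na(filter) | filter %in% c("PASS", "."), "PASS", "FILTERED")
}

# carry a callset's identity onto a modified calls table
rebuild_callset <- function(calls, template) {
  prov <- attr(template, "provenance")
  callset(calls,
          replicate_id = attr(template, "replicate_id"),
          sample = attr(template, "sample"),
          library = prov$library, run = prov$run, machine = prov$machine,
          mode = prov$mode, assay = prov$assay,
          exhaustive = attr(template, "exhaustive"))
}

#' Decompose a (possibly multi-allelic) VCF genotype into bi-allelic calls
#'
#' Each alternate allele of a site becomes its own record. The genotype
#' class of each record is derived only from the copy count of its own alt
#' allele (2 copies HOMALT, 1 HET, 0 HOMREF); copies of *other* alt alleles
#' count as non-alt, so `GT=1/2` yields HET for both records. Any missing
#' allele (`./.`, `0/.`) yields NOCALL. Haploid genotypes map alt to HOMALT
#' and ref to HOMREF. Symbolic alleles (`<DEL>`, `*`) are dropped, with the
#' number dropped recorded in the `n_symbolic` attribute of the result.
#'
#' @param chrom,pos,ref Site coordinates and reference allele.
#' @param alt Comma-separated alternate allele string (e.g. `"G,T"`).
#' @param gt GT string, `/` or `|` separated allele indexes.
#' @param filter FILTER string (applies to every decomposed record).
#' @return Tibble with one row per non-symbolic alt allele, in alt order:
#'   columns `chrom`, `pos`, `ref`, `alt`, `gclass`, `filter`.
#' @examples
#' decompose_site("chr1", 100, "A", "G,T", "1/2")
#' @export
decompose_site <- function(chrom, pos, ref, alt, gt, filter = "PASS") {
  chrom <- unname(chrom); pos <- unname(pos); ref <- unname(ref)
  filter <- unname(filter)
  alts <- strsplit(unname(alt), ",", fixed = TRUE)[[1]]
  if (length(alts) < 1) stop("decompose_site: site has no alt allele",
                             call. = FALSE)
  symbolic <- grepl("^<.*>$", alts) | alts == "*"
  alleles <- strsplit(gt, "[/|]")[[1]]
  nocall <- any(alleles == ".") || gt == "." || length(alleles) == 0
  out <- purrr::imap_dfr(alts[!symbolic], function(a, j) {
    i <- which(alts == a)[1]
    gclass <- if (nocall) {
      "NOCALL"
    } else {
      copies <- sum(alleles == as.character(i))
      if (length(alleles) == 1) {               # haploid
        if (copies >= 1) "HOMALT" else "HOMREF"
      } else {
        c("HOMREF", "HET", "HOMALT")[min(copies, 2) + 1]
      }
    }
    tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = a,
                   gclass = gclass, filter = filter)
  })
  attr(out, "n_symbolic") <- sum(symbolic)
  out
}

#' Read a VCF callset
#'
#' Reads one sample's calls from a VCF v4.x file, decomposes multi-allelic
#' sites into bi-allelic records ([decompose_site()]), and harvests the
#' `VQSLOD`, `QD`, `MQ` and `DP` INFO annotations where the header declares
#' them. FILTER values other than `PASS`/`.` give `filter_status =
#' "FILTERED"` (downstream concordance treats these as no-calls).
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample Sample name; may be omitted for single-sample files.
#' @param ... Passed to [callset()] (provenance attributes).
#' @return A `callset`. The number of symbolic alt alleles dropped is
#'   available as `attr(x, "n_symbolic")`.
#' @export
read_vcf <- function(path, sample = NULL, ...) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1]
  if (is.null(sample)) {
    if (length(samples) != 1) {
      stop("read_vcf: multiple samples present, specify one of: ",
           paste(samples, collapse = ", "), call. = FALSE)
    }
    sample <- samples
  }
  if (!sample %in% samples) {
    stop("read_vcf: sample '", sample, "' not in file; available: ",
         paste(samples, collapse = ", "), call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")[, sample]
  n <- nrow(fix)
  info_keys <- c(vqslod = "VQSLOD", qd = "QD", mq = "MQ", dp = "DP")
  declared <- vcfR::queryMETA(vcf)
  info <- purrr::map(info_keys, function(k) {
    if (any(grepl(paste0("INFO=ID=", k, "($|,)"), declared))) {
      suppressWarnings(vcfR::extract.info(vcf, element = k, as.numeric = TRUE))
    } else NULL
  })
  info <- info[!purrr::map_lgl(info, is.null)]

  n_symbolic <- 0L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- tryCatch(
      decompose_site(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                     fix[i, "REF"], fix[i, "ALT"],
                     gt = ifelse(is.na(gt[i]), ".", gt[i]),
                     filter = ifelse(is.na(fix[i, "FILTER"]), ".",
                                     fix[i, "FILTER"])),
      error = function(e) {
        stop("read_vcf: malformed record at line (data row) ", i, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    n_symbolic <- n_symbolic + attr(rec, "n_symbolic")
    for (k in names(info)) rec[[k]] <- unname(info[[k]][i])
    rows[[i]] <- rec
  }
  calls <- dplyr::bind_rows(rows)
  out <- callset(calls, sample = sample, ...)
  attr(out, "n_symbolic") <- n_symbolic
  out
}

#' Write a callset as a single-sample VCF
#'
#' Serializes a normalized bi-allelic callset in chromosome/position order.
#' Round-trips through [read_vcf()] for (`chrom`,`pos`,`ref`,`alt`,`GT`,
#' `FILTER`). Annotation columns present in the callset are written as
#' INFO fields.
#'
#' @param x A `callset`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "callset"))
  ann <- intersect(c("vqslod", "qd", "mq", "dp"), names(x))
  ann_ids <- c(vqslod = "VQSLOD", qd = "QD", mq = "MQ", dp = "DP")[ann]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=LowQual,Description=\"Filtered call\">",
    purrr::map_chr(ann_ids, ~ sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", .x, .x)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           attr(x, "sample"))
  )
  gt <- c(HOMREF = "0/0", HET = "0/1", HOMALT = "1/1", NOCALL = "./.")
  info <- if (length(ann)) {
    apply(as.data.frame(x)[, ann, drop = FALSE], 1, function(v) {
      keep <- !is.na(v)
      if (!any(keep)) "." else
        paste(paste0(ann_ids[keep], "=", format(v[keep], trim = TRUE)),
              collapse = ";")
    })
  } else rep(".", nrow(x))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tGT\t%s",
                  x$chrom, x$pos, x$ref, x$alt, x$filter, info,
                  gt[x$gclass])
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Restrict a callset to target intervals
#'
#' Retains exactly the calls whose 1-based position lies inside an interval
#' (`pos - 1` in `[start, end)`). Provenance is unchanged.
#'
#' @param x A `callset`.
#' @param intervals An `interval_set` (or `NULL` for no restriction).
#' @return The restricted `callset`.
#' @export
restrict_callset <- function(x, intervals) {
  stopifnot(inherits(x, "callset"))
  if (is.null(intervals)) return(x)
  keep <- positions_in_intervals(x$chrom, x$pos, intervals)
  rebuild_callset(x[keep, , drop = FALSE], x)
}
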