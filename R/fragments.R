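#' Cell-free DNA fragments as a sorted tibble
#'
#' A fragment is an aligned cfDNA molecule represented as a genomic interval
#' in BED convention: 0-based, half-open `[start, end)`. A fragment table
#' (class `cf_fragments`) is a tibble with columns `chrom`, `start`, `end`
#' and `length`, sorted by `(chrom, start, end)`. Fragment endpoints are the
#' genomic positions `start` and `end - 1`; these are the objects counted by
#' the windowed protection score.
#'
#' Strand is deliberately not stored: nuclease protection is strand-agnostic.
#' Strand enters the analysis only through region orientation when
#' aggregating around transcription start sites (see [aggregate_wps()]).
#'
#' @param x A data frame with columns `chrom`, `start`, `end` (integer
#'   coordinates, `start < end`). Extra columns are dropped.
#' @return A `cf_fragments` tibble with columns `chrom`, `start`, `end`,
#'   `length`, sorted by `(chrom, start, end)`.
#' @examples
#' frags <- as_fragments(data.frame(
#'   chrom = "chr1", start = c(100, 50), end = c(270, 220)
#' ))
#' frags
#' @export
as_fragments <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("fragment table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    chrom = as.character(x$chrom),
    start = as.integer(x$start),
    end = as.integer(x$end)
  )
  bad <- which(!is.finite(out$start) | !is.finite(out$end) |
                 out$start < 0 | out$start >= out$end |
                 is.na(out$chrom) | out$chrom == "")
  if (length(bad) > 0) {
    abort(paste0(length(bad), " fragment(s) violate 0 <= start < end ",
                 "(first offending row: ", bad[1], ")"))
  }
  out$length <- out$end - out$start
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$end)
  class(out) <- c("cf_fragments", class(tibble()))
  out
}

#' Read aligned cfDNA fragments from a BED3+ file
#'
#' Reads tab-separated `chrom`, `start`, `end` (extra columns ignored),
#' validates coordinates and returns a sorted fragment table. Rows with
#' `start >= end` are rejected, and the numbers of accepted and rejected rows
#' are reported via a message. When a chromosome-size table is supplied,
#' fragments on chromosomes absent from it are an error.
#'
#' @param path Path to a BED3+ file (no header).
#' @param genome Optional two-column data frame or TSV path
#'   (`chrom`, `size`) restricting valid chromosome names.
#' @return A `cf_fragments` tibble (see [as_fragments()]), with attributes
#'   `n_accepted` and `n_rejected`.
#' @export
read_fragments <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    out <- as_fragments(tibble(chrom = character(), start = integer(), end = integer()))
    attr(out, "n_accepted") <- 0L
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  if (ncol(raw) < 3) abort(paste0(path, ": BED3+ requires >= 3 tab-separated columns"))
  start <- suppressWarnings(as.integer(raw[[2]]))
  end <- suppressWarnings(as.integer(raw[[3]]))
  malformed <- which(is.na(start) | is.na(end) | start < 0 | end < 0 | is.na(raw[[1]]))
  if (length(malformed) > 0) {
    abort(paste0(path, ": malformed row at line ", malformed[1],
                 " (non-negative integer coordinates required)"))
  }
  if (!is.null(genome)) {
    if (is.character(genome)) {
      genome <- readr::read_tsv(genome, col_names = c("chrom", "size"),
                                col_types = "ci", progress = FALSE)
    }
    unknown <- setdiff(unique(raw[[1]]), as.character(genome[[1]]))
    if (length(unknown) > 0) {
      abort(paste0(path, ": chromosome(s) absent from genome table: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  keep <- start < end
  out <- as_fragments(tibble(chrom = raw[[1]][keep], start = start[keep], end = end[keep]))
  attr(out, "n_accepted") <- sum(keep)
  attr(out, "n_rejected") <- sum(!keep)
  if (any(!keep)) {
    inform(paste0(path, ": accepted ", sum(keep), " fragment(s), rejected ",
                  sum(!keep), " with start >= end"))
  }
  out
}

#' Write fragments to a BED3 file
#'
#' @param fragments A `cf_fragments` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  readr::write_tsv(fragments[, c("chrom", "start", "end")], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Fragment length classes
#'
#' Named half-open length intervals `[min_len, max_len)` in bases. The two
#' named classes follow the convention that medium-length cfDNA fragments run
#' from 140 bp up to 200 bp and long fragments from 200 bp up to 500 bp; the
#' shared 200 bp boundary belongs to the long class, so the two classes
#' partition lengths in `[140, 501)`.
#'
#' @param label One of `"medium"` (140-199 bp), `"long"` (200-500 bp),
#'   `"all"`, or `"custom"`.
#' @param min_len,max_len Required for `"custom"`: half-open bounds in bases.
#' @return A list with `label`, `min_len` (inclusive), `max_len` (exclusive).
#' @examples
#' length_class("medium")
#' length_class("custom", 100, 180)
#' @export
length_class <- function(label = c("medium", "long", "all", "custom"),
                         min_len = NULL, max_len = NULL) {
  label <- match.arg(label)
  cls <- switch(label,
    medium = list(label = "medium", min_len = 140L, max_len = 200L),
    long = list(label = "long", min_len = 200L, max_len = 501L),
    all = list(label = "all", min_len = 1L, max_len = .Machine$integer.max),
    custom = {
      if (is.null(min_len) || is.null(max_len)) {
        abort("custom length class requires min_len and max_len")
      }
      list(label = "custom", min_len = as.integer(min_len), max_len = as.integer(max_len))
    }
  )
  if (cls$min_len >= cls$max_len) abort("length class requires min_len < max_len")
  cls
}

#' Filter fragments by length class
#'
#' Retains exactly the fragments with `min_len <= length < max_len`
#' (half-open). Order is preserved.
#'
#' @param fragments A `cf_fragments` tibble.
#' @param cls A [length_class()] list, or a label accepted by it.
#' @return A `cf_fragments` tibble.
#' @examples
#' frags <- as_fragments(data.frame(chrom = "chr1", start = 0, end = c(170, 200, 350)))
#' filter_by_length(frags, "medium")
#' @export
filter_by_length <- function(fragments, cls = "medium") {
  if (is.character(cls)) cls <- length_class(cls)
  out <- fragments[fragments$length >= cls$min_len & fragments$length < cls$max_len, ]
  class(out) <- class(fragments)
  out
}

#' Fragments overlapping a genomic region
#'
#' Returns every fragment with at least 1 bp of overlap with the half-open
#' region `[start, end)`: `frag.start < end` and `frag.end > start`. The
#' count of returned fragments is the normalization denominator used by
#' [normalize_by_count()] for that region. An unknown chromosome yields an
#' empty result, not an error.
#'
#' @param fragments A `cf_fragments` tibble.
#' @param chrom Chromosome name.
#' @param start,end Region bounds, 0-based half-open, `start < end`.
#' @return A `cf_fragments` tibble of overlapping fragments.
#' @export
fragments_in_region <- function(fragments, chrom, start, end) {
  if (start >= end) abort("region requires start < end")
  out <- fragments[fragments$chrom == chrom &
                     fragments$start < end & fragments$end > start, ]
  class(out) <- class(fragments)
  out
}

#' Uniform fragment subsampling without replacement
#'
#' Draws exactly `target` fragments uniformly at random without replacement.
#' The same seed always yields the same subset, and because fragment tables
#' are canonically sorted, the draw is invariant to the input order of the
#' original file.
#'
#' @param fragments A `cf_fragments` tibble.
#' @param target Number of fragments to keep, `0 <= target <= nrow(fragments)`.
#' @param seed Integer seed.
#' @return A `cf_fragments` tibble with `target` rows, sorted.
#' @export
subsample_fragments <- function(fragments, target, seed) {
  n <- nrow(fragments)
  if (target < 0 || target > n) {
    abort(paste0("target (", target, ") must be between 0 and the number of fragments (", n, ")"))
  }
  if (target == n) return(fragments)
  idx <- withr::with_seed(as.integer(seed), sample.int(n, size = target))
  out <- fragments[sort(idx), ]
  class(out) <- class(fragments)
  out
}
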