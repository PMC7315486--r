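#' Windowed protection score (WPS) for a genomic region
#'
#' For every position `p` of the half-open region `[region_start,
#' region_end)`, the raw WPS with window size `n` (`window`) counts
#' fragments over the window `W(p) = [p - n/2, p + n/2)`:
#'
#' \deqn{WPS_n(p) = \#\{\mathrm{spanning}\ W(p)\} - \#\{\ge 1\ \mathrm{endpoint\ in}\ W(p)\}}
#'
#' Fragment endpoints are the positions `start` and `end - 1`. A fragment
#' contributes -1 if at least one endpoint lies inside `W(p)` (once per
#' fragment, not per endpoint), and +1 if it covers the window strictly
#' beyond both edges (`start < p - n/2` and `end > p + n/2`). A fragment
#' whose endpoint falls exactly on a window edge position is an endpoint
#' fragment, never a spanning one, so the two sets are disjoint by
#' construction. The sign convention is protection-positive: nucleosome-
#' protected positions score high, nuclease-accessible positions score low.
#'
#' Fragments outside the region still contribute to scores near the region
#' edges whenever they reach a window; pass every fragment overlapping
#' `[region_start - n/2 - 1, region_end + n/2)` for exact edge scores.
#'
#' @param fragments A `cf_fragments` tibble (may be empty). Fragments on
#'   other chromosomes are ignored.
#' @param chrom Chromosome of the region.
#' @param region_start,region_end Region bounds, 0-based half-open.
#' @param window Window size `n` in bases; must be even and positive.
#'   120 suits libraries with a mononucleosomal ~167 bp fragment peak;
#'   200 suits long-fragment analyses.
#' @return A `wps_track` tibble with columns `chrom`, `pos`, `score`, and
#'   attributes `stage = "raw"`, `window`, `region` and
#'   `n_fragments_in_region` (fragments overlapping the region itself, the
#'   depth-normalization denominator).
#' @examples
#' frags <- as_fragments(data.frame(chrom = "chr1", start = 100, end = 270))
#' tr <- raw_wps(frags, "chr1", 0, 400, window = 120)
#' tr$score[tr$pos == 185] # +1: spans the window [125,245)
#' tr$score[tr$pos == 130] # -1: start 100 lies in the window [70,190)
#' @export
raw_wps <- function(fragments, chrom, region_start, region_end, window = 120) {
  if (window <= 0 || window %% 2 != 0) abort("window must be even and > 0")
  region_start <- as.integer(region_start)
  region_end <- as.integer(region_end)
  if (region_end - region_start < 1) abort("region must be at least 1 bp")
  h <- window %/% 2L
  L <- region_end - region_start
  f <- fragments[fragments$chrom == chrom, ]

  delta <- numeric(L + 1L)
  add_intervals <- function(delta, a, b, w) {
    # add w to positions a..b (genomic), clipped to the region
    a <- pmax(a, region_start)
    b <- pmin(b, region_end - 1L)
    keep <- a <= b
    if (!any(keep)) return(delta)
    ia <- a[keep] - region_start + 1L
    ib <- b[keep] - region_start + 2L
    delta + w * (tabulate(ia, nbins = L + 1L) - tabulate(ib, nbins = L + 1L))
  }

  if (nrow(f) > 0) {
    s <- f$start
    e <- f$end
    t <- e - 1L
    # endpoint-in-window: position p has s in W(p) iff p in [s-h+1, s+h],
    # likewise for t; one fragment counts once even if both endpoints hit.
    near <- (t - s) <= (window - 1L)
    delta <- add_intervals(delta, s[near] - h + 1L, t[near] + h, -1)
    delta <- add_intervals(delta, s[!near] - h + 1L, s[!near] + h, -1)
    delta <- add_intervals(delta, t[!near] - h + 1L, t[!near] + h, -1)
    # strict spanning: s < p-h and e > p+h  <=>  p in [s+h+1, e-h-1]
    delta <- add_intervals(delta, s + h + 1L, e - h - 1L, +1)
  }
  score <- cumsum(delta[seq_len(L)])

  n_in_region <- sum(f$start < region_end & f$end > region_start)
  new_wps_track(
    tibble(chrom = chrom, pos = seq.int(region_start, region_end - 1L), score = score),
    stage = "raw", window = window,
    region = c(start = region_start, end = region_end),
    n_fragments_in_region = n_in_region
  )
}

new_wps_track <- function(df, stage, window, region, n_fragments_in_region) {
  structure(df,
    class = c("wps_track", class(tibble())),
    stage = stage, window = window, region = region,
    n_fragments_in_region = n_fragments_in_region
  )
}

#' @export
print.wps_track <- function(x, ...) {
  cat("<wps_track> stage=", attr(x, "stage"),
      " window=", attr(x, "window"),
      " n_fragments_in_region=", attr(x, "n_fragments_in_region"), "\n", sep = "")
  NextMethod()
}

wps_stage <- function(track) attr(track, "stage")

#' Normalize a raw WPS track to the fragment count of its region
#'
#' Divides every raw score by the number of fragments overlapping the
#' analyzed region, controlling for sequencing-depth differences between
#' regions and samples. With zero fragments in the region the output is an
#' all-zero track and a warning is issued.
#'
#' @param track A `wps_track` at stage `"raw"`.
#' @param n_fragments_in_region Denominator; defaults to the count recorded
#'   by [raw_wps()].
#' @return A `wps_track` at stage `"count_normalized"`.
#' @export
normalize_by_count <- function(track, n_fragments_in_region = NULL) {
  if (!inherits(track, "wps_track") || wps_stage(track) != "raw") {
    abort("normalize_by_count() expects a wps_track at stage 'raw'")
  }
  n <- n_fragments_in_region %||% attr(track, "n_fragments_in_region")
  if (n == 0) {
    warn("no fragments in region; count-normalized track is all zeros")
    score <- rep(0, nrow(track))
  } else {
    score <- track$score / n
  }
  out <- track
  out$score <- score
  attr(out, "stage") <- "count_normalized"
  attr(out, "n_fragments_in_region") <- n
  out
}

running_mean_center <- function(score, half_width) {
  L <- length(score)
  cs <- cumsum(c(0, score))
  i <- seq_len(L)
  lo <- pmax(i - half_width, 1L)
  hi <- pmin(i + half_width, L)
  score - (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Center a WPS track on its running 1-kb mean
#'
#' Subtracts from each position the mean score within `half_width` bases on
#' either side (window truncated at the region edges), so the track has a
#' running local mean of zero. This removes broad coverage trends and leaves
#' the nucleosome-scale oscillation that the peak caller consumes.
#'
#' @param track A `wps_track` at stage `"count_normalized"`, or a
#'   `wps_aggregate`.
#' @param half_width Half window in bases; default 500 (a 1-kb running mean).
#' @return The same type of object, stage `"mean_centered"`.
#' @export
subtract_running_mean <- function(track, half_width = 500) {
  if (half_width <= 0) abort("half_width must be > 0")
  if (inherits(track, "wps_aggregate")) {
    track$score <- running_mean_center(track$score, as.integer(half_width))
    attr(track, "stage") <- "mean_centered"
    return(track)
  }
  if (!inherits(track, "wps_track") || wps_stage(track) != "count_normalized") {
    abort("subtract_running_mean() expects stage 'count_normalized' (or a wps_aggregate)")
  }
  out <- track
  out$score <- running_mean_center(track$score, as.integer(half_width))
  attr(out, "stage") <- "mean_centered"
  out
}

#' Strand-aware aggregate WPS around anchor coordinates
#'
#' For each anchor (typically a transcription start site), computes the raw
#' WPS over `[pos - flank, pos + flank)`, count-normalizes it to the number
#' of fragments overlapping that window, orients it so that positive offsets
#' point downstream of transcription (minus-strand tracks are reversed), and
#' averages the tracks position-wise with equal weight. The running-mean
#' centering is applied to the merged average.
#'
#' @param fragments A `cf_fragments` tibble (length-filter first if a
#'   specific fragment class is wanted).
#' @param anchors A data frame with columns `chrom`, `pos`, `strand`
#'   (`"+"` or `"-"`).
#' @param window WPS window size (even), default 120.
#' @param flank Bases on each side of the anchor, default 5000. The
#'   aggregate covers transcription-strand offsets `-flank .. flank - 1`.
#' @param half_width Running-mean half window passed to
#'   [subtract_running_mean()]; set `NULL` to skip centering.
#' @param chrom_sizes Optional data frame (`chrom`, `size`); anchors whose
#'   window exceeds chromosome bounds are skipped with a warning.
#' @return A `wps_aggregate` tibble with columns `offset`, `score` and
#'   attributes `n_regions`, `window`, `flank`, `stage`.
#' @export
aggregate_wps <- function(fragments, anchors, window = 120, flank = 5000,
                          half_width = 500, chrom_sizes = NULL) {
  if (nrow(anchors) == 0) abort("anchor list is empty")
  if (!all(anchors$strand %in% c("+", "-"))) abort("anchor strand must be '+' or '-'")
  flank <- as.integer(flank)
  h <- window %/% 2L

  ok <- anchors$pos - flank - 1L >= 0
  if (!is.null(chrom_sizes)) {
    sizes <- stats::setNames(chrom_sizes$size, chrom_sizes$chrom)
    ok <- ok & (anchors$pos + flank + 1L <= sizes[anchors$chrom])
  }
  if (any(!ok | is.na(ok))) {
    warn(paste0(sum(!ok | is.na(ok)), " anchor(s) exceed chromosome bounds; skipped"))
    anchors <- anchors[which(ok), ]
    if (nrow(anchors) == 0) abort("no usable anchors remain")
  }

  acc <- numeric(2L * flank)
  for (i in seq_len(nrow(anchors))) {
    pos <- as.integer(anchors$pos[i])
    chrom <- anchors$chrom[i]
    minus <- anchors$strand[i] == "-"
    # genomic window whose reversal gives offsets -flank..flank-1 on '-'
    rs <- if (minus) pos - flank + 1L else pos - flank
    re <- rs + 2L * flank
    near <- fragments_in_region(fragments, chrom, rs - h - 1L, re + h)
    tr <- raw_wps(near, chrom, rs, re, window = window)
    n <- sum(near$start < re & near$end > rs)
    sc <- if (n > 0) tr$score / n else rep(0, length(tr$score))
    if (minus) sc <- rev(sc)
    acc <- acc + sc
  }
  score <- acc / nrow(anchors)

  agg <- structure(
    tibble(offset = seq.int(-flank, flank - 1L), score = score),
    class = c("wps_aggregate", class(tibble())),
    n_regions = nrow(anchors), window = window, flank = flank,
    stage = "count_normalized"
  )
  if (!is.null(half_width)) agg <- subtract_running_mean(agg, half_width)
  agg
}

#' @export
print.wps_aggregate <- function(x, ...) {
  cat("<wps_aggregate> n_regions=", attr(x, "n_regions"),
      " window=", attr(x, "window"),
      " stage=", attr(x, "stage"), "\n", sep = "")
  NextMethod()
}

#' Write a WPS track as bedGraph
#'
#' @param track A `wps_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wps_bedgraph <- function(track, path) {
  df <- tibble(chrom = track$chrom, start = track$pos, end = track$pos + 1L,
               score = track$score)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
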