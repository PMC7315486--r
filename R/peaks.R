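#' Call nucleosome peaks on a normalized WPS track
#'
#' Candidate segments are maximal runs of positions with positive score in
#' which interior runs of at most `max_neg_gap` consecutive non-positive
#' scores do not break the segment (a fifth consecutive non-positive value
#' terminates it). Segments are retained when their genomic span, gap
#' positions included, is between `min_run` and `max_run` bases. Within each
#' retained segment the median of the segment's scores is computed, the
#' contiguous run of scores at or above that median with the largest score
#' sum is selected (leftmost run on ties), and the peak is the middle
#' position of that run (lower middle for even run lengths).
#'
#' @param track A `wps_track` at stage `"mean_centered"` (count-normalized
#'   then centered on the running mean), or a `wps_aggregate` at that stage.
#' @param min_run,max_run Retained segment span bounds in bases
#'   (defaults 50 and 450, about the footprints of one to two nucleosomes).
#' @param max_neg_gap Longest interior run of non-positive scores that does
#'   not break a segment (default 4).
#' @return A `peak_set` tibble with columns `pos` (peak position or offset),
#'   `segment_start`, `segment_end` (inclusive segment extent) and
#'   `segment_span`; attributes `params` and `source`.
#' @examples
#' fr <- simulate_phased_fragments(0, 3000, n_fragments = 5000,
#'                                 dyad_jitter_sd = 5, seed = 1)
#' tr <- raw_wps(fr, "chr1", 0, 3000) |>
#'   normalize_by_count() |>
#'   subtract_running_mean()
#' call_peaks(tr)
#' @export
call_peaks <- function(track, min_run = 50, max_run = 450, max_neg_gap = 4) {
  if (!attr(track, "stage") %in% "mean_centered") {
    abort("call_peaks() expects a normalized (mean_centered) track")
  }
  coord <- if (inherits(track, "wps_aggregate")) track$offset else track$pos
  score <- track$score

  segs <- find_segments(score, max_neg_gap)
  keep <- (segs$end - segs$start + 1L) >= min_run & (segs$end - segs$start + 1L) <= max_run
  segs <- segs[keep, , drop = FALSE]

  peak_idx <- integer(nrow(segs))
  for (k in seq_len(nrow(segs))) {
    idx <- segs$start[k]:segs$end[k]
    v <- score[idx]
    med <- median(v)
    runs <- runs_at_least(v, med)
    sums <- vapply(seq_len(nrow(runs)),
                   function(r) sum(v[runs$start[r]:runs$end[r]]), numeric(1))
    best <- which.max(sums) # which.max returns the leftmost maximum
    a <- runs$start[best]
    b <- runs$end[best]
    peak_idx[k] <- idx[a + (b - a) %/% 2L] # lower middle for even length
  }

  structure(
    tibble(
      pos = coord[peak_idx],
      segment_start = coord[segs$start],
      segment_end = coord[segs$end],
      segment_span = segs$end - segs$start + 1L
    ),
    class = c("peak_set", class(tibble())),
    params = list(min_run = min_run, max_run = max_run, max_neg_gap = max_neg_gap),
    source = attr(track, "region") %||% "aggregate"
  )
}

# maximal positive segments tolerating interior non-positive gaps <= max_gap;
# returns index tibble (1-based start/end of each segment extent)
find_segments <- function(score, max_gap) {
  posi <- which(score > 0)
  if (length(posi) == 0) return(tibble(start = integer(), end = integer()))
  gap <- diff(posi) - 1L
  brk <- which(gap > max_gap)
  seg_first <- posi[c(1L, brk + 1L)]
  seg_last <- posi[c(brk, length(posi))]
  tibble(start = seg_first, end = seg_last)
}

# contiguous runs of v >= threshold, as 1-based index bounds
runs_at_least <- function(v, threshold) {
  ok <- v >= threshold
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(start = starts[r$values], end = ends[r$values])
}

#' Interpeak distances (IPDs)
#'
#' Distances in bases between consecutive called peaks; distances above
#' `max_distance` (default 1 kb) are discarded, since peaks that far apart
#' are not adjacent nucleosomes.
#'
#' @param peaks A `peak_set` tibble (or any data frame with a `pos` column).
#' @param max_distance Largest tabulated distance, default 1000.
#' @return A tibble with a single column `distance`.
#' @export
interpeak_distances <- function(peaks, max_distance = 1000) {
  p <- sort(peaks$pos)
  d <- diff(p)
  tibble(distance = as.integer(d[d <= max_distance]))
}

#' Wilcoxon rank-sum (Mann-Whitney U) test for two IPD samples
#'
#' Computes the Mann-Whitney U statistic for the first sample using
#' midranks for ties. The two-sided p value is obtained by exact enumeration
#' of all rank assignments when `n1 + n2 <= 12` and there are no ties, and
#' otherwise by the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y Numeric vectors (e.g. two IPD distributions); both non-empty.
#' @return A one-row tibble: `statistic` (U for `x`), `p.value`, `method`
#'   (`"exact"` or `"normal approximation"`), `n1`, `n2`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(all_v))

  if (n1 + n2 <= 12 && !ties) {
    # exact: U distribution over all C(n1+n2, n1) rank assignments
    rk <- seq_len(n1 + n2)
    combos <- combn(n1 + n2, n1)
    u_all <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u), mean(u_all >= u)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    t_tab <- table(all_v)
    tie_term <- sum(t_tab^3 - t_tab) / (nn * (nn - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((nn + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sigma # continuity correction
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  tibble(statistic = u, p.value = p, method = method, n1 = n1, n2 = n2)
}
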