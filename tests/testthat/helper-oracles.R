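# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition (per-position loops, all-pairs
# scans) and share no code with the package implementations they check.

# windowed protection score by direct evaluation of the definition at each
# position: -1 if >= 1 fragment endpoint (start or end-1) lies in
# W(p) = [p - n/2, p + n/2); +1 if the fragment strictly covers the window
# (start < p - n/2 and end > p + n/2). Endpoint fragments never span.
oracle_wps <- function(fragments, chrom, region_start, region_end, window) {
  h <- window / 2
  f <- fragments[fragments$chrom == chrom, ]
  vapply(region_start:(region_end - 1), function(p) {
    lo <- p - h
    hi <- p + h
    ep <- (f$start >= lo & f$start < hi) | (f$end - 1 >= lo & f$end - 1 < hi)
    sp <- !ep & f$start < lo & f$end > hi
    sum(sp) - sum(ep)
  }, numeric(1))
}

# region overlap by all-pairs scan
oracle_overlap <- function(fragments, chrom, start, end) {
  keep <- logical(nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    keep[i] <- fragments$chrom[i] == chrom &&
      fragments$start[i] < end && fragments$end[i] > start
  }
  fragments[keep, ]
}

# truncated running mean, direct O(n * w)
oracle_running_mean_center <- function(score, half_width) {
  n <- length(score)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1, i - half_width):min(n, i + half_width)
    out[i] <- score[i] - mean(score[idx])
  }
  out
}

# locus methylation by all-pairs overlap of CpG records and locus intervals
oracle_locus_methylation <- function(calls, loci, min_cov = 1) {
  res <- data.frame(locus_id = as.character(loci$locus_id),
                    meth_fraction = NA_real_, coverage = 0L)
  cpg <- calls[calls$context == "CpG", ]
  for (k in seq_len(nrow(loci))) {
    m <- 0L; u <- 0L
    for (i in seq_len(nrow(cpg))) {
      if (cpg$chrom[i] == loci$chrom[k] &&
          cpg$pos[i] >= loci$start[k] && cpg$pos[i] < loci$end[k]) {
        m <- m + cpg$count_meth[i]
        u <- u + cpg$count_unmeth[i]
      }
    }
    res$coverage[k] <- m + u
    if (m + u >= min_cov) res$meth_fraction[k] <- m / (m + u)
  }
  res
}

# random fragment table on one chromosome
random_fragments <- function(n, region_max = 2000, len_max = 400, seed) {
  withr::with_seed(seed, {
    start <- sample.int(region_max, n, replace = TRUE) - 1L
    len <- sample.int(len_max, n, replace = TRUE)
    as_fragments(data.frame(chrom = "chr1", start = start, end = start + len))
  })
}

# mean-centered synthetic track wrapper used by peak-caller tests
as_centered_track <- function(score, start = 0L, chrom = "chrT") {
  fr <- as_fragments(data.frame(chrom = chrom, start = 0, end = 2))
  tr <- raw_wps(fr, chrom, start, start + length(score), window = 2)
  tr$score <- as.numeric(score)
  attr(tr, "stage") <- "mean_centered"
  tr
}

# single synthetic TSS layout shared by NPS tests and the acceptance suite:
# anchor at 2000 (+ strand), nucleosome-free region [1900, 2080), first
# downstream dyad at +160 (position 2160), 190-bp repeat
synth_tss_fragments <- function(n_fragments, jitter_sd, seed) {
  simulate_phased_fragments(
    0, 4000, n_fragments = n_fragments, dyad_spacing = 190,
    dyad_jitter_sd = jitter_sd, nfr = c(1900, 2080), dyad_offset = 70,
    seed = seed
  )
}
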