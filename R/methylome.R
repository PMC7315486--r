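#' Per-cytosine methylation calls as a tibble
#'
#' A methylation call set (class `meth_calls`) is a tibble with one row per
#' cytosine: `chrom`, `pos` (0-based), `strand` (`"+"`, `"-"` or `"*"` when
#' unknown), `context` (`"CpG"`, `"CHG"` or `"CHH"`), `count_meth`,
#' `count_unmeth`. Coverage is `count_meth + count_unmeth`.
#'
#' @param x A data frame with those columns (`strand` and `context` optional;
#'   defaults `"*"` and `"CpG"`).
#' @return A sorted `meth_calls` tibble.
#' @export
as_meth_calls <- function(x) {
  stopifnot(is.data.frame(x))
  out <- tibble(
    chrom = as.character(x$chrom),
    pos = as.integer(x$pos),
    strand = if ("strand" %in% names(x)) as.character(x$strand) else "*",
    context = if ("context" %in% names(x)) as.character(x$context) else "CpG",
    count_meth = as.integer(x$count_meth),
    count_unmeth = as.integer(x$count_unmeth)
  )
  if (any(out$count_meth < 0 | out$count_unmeth < 0)) abort("negative counts")
  if (!all(out$context %in% c("CpG", "CHG", "CHH"))) {
    abort("context must be one of CpG, CHG, CHH")
  }
  out <- dplyr::arrange(out, .data$chrom, .data$pos, .data$strand)
  class(out) <- c("meth_calls", class(tibble()))
  out
}

#' Read per-cytosine methylation calls (coverage or cytosine-report dialect)
#'
#' Auto-detects the two common extractor output dialects:
#' * coverage (`.cov`): `chrom, start, end, pct_methylated, count_meth,
#'   count_unmeth`, 1-based positions, CpG context, strand unknown;
#' * cytosine report: `chrom, pos, strand, count_meth, count_unmeth,
#'   context, tricontext`, 1-based positions.
#'
#' Positions are normalized to 0-based. In the coverage dialect a reported
#' percentage differing from the counts by more than one percentage point
#' draws a warning; malformed rows are an error naming the line.
#'
#' @param path Path to a tab-separated file without header.
#' @return A `meth_calls` tibble (see [as_meth_calls()]).
#' @export
read_methylation_calls <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"), progress = FALSE)
  if (nrow(raw) == 0) {
    return(as_meth_calls(tibble(chrom = character(), pos = integer(),
                                count_meth = integer(), count_unmeth = integer())))
  }
  is_report <- ncol(raw) >= 6 && all(raw[[3]] %in% c("+", "-"))
  if (is_report) {
    pos <- suppressWarnings(as.integer(raw[[2]]))
    cm <- suppressWarnings(as.integer(raw[[4]]))
    cu <- suppressWarnings(as.integer(raw[[5]]))
    bad <- which(is.na(pos) | is.na(cm) | is.na(cu))
    if (length(bad) > 0) abort(paste0(path, ": malformed row at line ", bad[1]))
    calls <- tibble(chrom = raw[[1]], pos = pos - 1L, strand = raw[[3]],
                    context = sub("^CG$", "CpG", raw[[6]]),
                    count_meth = cm, count_unmeth = cu)
  } else {
    if (ncol(raw) < 6) abort(paste0(path, ": coverage dialect requires 6 columns"))
    pos <- suppressWarnings(as.integer(raw[[2]]))
    pct <- suppressWarnings(as.numeric(raw[[4]]))
    cm <- suppressWarnings(as.integer(raw[[5]]))
    cu <- suppressWarnings(as.integer(raw[[6]]))
    bad <- which(is.na(pos) | is.na(pct) | is.na(cm) | is.na(cu))
    if (length(bad) > 0) abort(paste0(path, ": malformed row at line ", bad[1]))
    cov <- cm + cu
    implied <- ifelse(cov > 0, 100 * cm / cov, 0)
    off <- abs(implied - pct) > 1
    if (any(off)) {
      warn(paste0(path, ": ", sum(off),
                  " row(s) with >1 percentage-point discrepancy between pct and counts"))
    }
    calls <- tibble(chrom = raw[[1]], pos = pos - 1L, strand = "*",
                    context = "CpG", count_meth = cm, count_unmeth = cu)
  }
  as_meth_calls(calls)
}

#' Write methylation calls in the coverage dialect
#'
#' @param calls A `meth_calls` tibble.
#' @param path Output path (1-based start/end, CpG rows only are not
#'   enforced; all rows are written).
#' @return `path`, invisibly.
#' @export
write_methylation_coverage <- function(calls, path) {
  cov <- calls$count_meth + calls$count_unmeth
  df <- tibble(
    chrom = calls$chrom, start = calls$pos + 1L, end = calls$pos + 1L,
    pct = ifelse(cov > 0, 100 * calls$count_meth / cov, 0),
    count_meth = calls$count_meth, count_unmeth = calls$count_unmeth
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Pooled methylation level per target locus
#'
#' For each target locus, pools the counts of all CpG-context records whose
#' position falls inside the locus interval `[start, end)` (both strands of
#' a CpG dyad pool naturally) and reports the coverage-weighted methylated
#' fraction `sum(count_meth) / sum(coverage)`. Loci below `min_cov` total
#' coverage are emitted with `meth_fraction = NA` so that downstream
#' deconvolution can drop them pairwise.
#'
#' @param calls A `meth_calls` tibble.
#' @param loci A data frame `locus_id`, `chrom`, `start`, `end` (0-based,
#'   half-open; a single-CpG locus has `end = start + 1`). Ids must be
#'   unique.
#' @param min_cov Minimum pooled coverage for a locus to be reported,
#'   default 1.
#' @return A tibble `locus_id`, `meth_fraction`, `coverage`, one row per
#'   locus in input order.
#' @export
locus_methylation <- function(calls, loci, min_cov = 1) {
  if (anyDuplicated(loci$locus_id)) abort("locus ids must be unique")
  if (any(loci$start >= loci$end)) abort("loci require start < end")
  cpg <- calls[calls$context == "CpG", ]
  hits <- dplyr::inner_join(
    tibble(chrom = cpg$chrom, pos = cpg$pos,
           count_meth = cpg$count_meth, count_unmeth = cpg$count_unmeth),
    tibble(locus_id = as.character(loci$locus_id), chrom = loci$chrom,
           start = loci$start, end = loci$end),
    by = "chrom", relationship = "many-to-many"
  )
  hits <- hits[hits$pos >= hits$start & hits$pos < hits$end, ]
  agg <- dplyr::summarise(
    dplyr::group_by(hits, .data$locus_id),
    meth = sum(.data$count_meth),
    cov = sum(.data$count_meth) + sum(.data$count_unmeth),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble(locus_id = as.character(loci$locus_id)), agg,
                          by = "locus_id")
  out$cov[is.na(out$cov)] <- 0L
  tibble(
    locus_id = out$locus_id,
    meth_fraction = ifelse(out$cov >= min_cov, out$meth / out$cov, NA_real_),
    coverage = as.integer(out$cov)
  )
}

#' Global and windowed methylation summaries by context
#'
#' Without a window, reports for each sequence context the genome-wide
#' pooled methylated fraction. With a window size, additionally reports the
#' same per tiling window (windows tiled from position 0, half-open). Window
#' counts sum exactly to the global counts.
#'
#' @param calls A `meth_calls` tibble.
#' @param window Optional window size in bases (e.g. 1000).
#' @return A list with `global` (tibble `context`, `count_meth`,
#'   `count_unmeth`, `fraction`) and, when windowed, `windows` (tibble
#'   `chrom`, `window_start`, `context`, counts and `fraction`).
#' @export
methylation_summary <- function(calls, window = NULL) {
  glob <- dplyr::summarise(
    dplyr::group_by(as_tibble(calls), .data$context),
    count_meth = sum(.data$count_meth),
    count_unmeth = sum(.data$count_unmeth),
    .groups = "drop"
  )
  glob$fraction <- with(glob, ifelse(count_meth + count_unmeth > 0,
                                     count_meth / (count_meth + count_unmeth), NA_real_))
  out <- list(global = glob)
  if (!is.null(window)) {
    w <- dplyr::mutate(as_tibble(calls),
                       window_start = (.data$pos %/% as.integer(window)) * as.integer(window))
    w <- dplyr::summarise(
      dplyr::group_by(w, .data$chrom, .data$window_start, .data$context),
      count_meth = sum(.data$count_meth),
      count_unmeth = sum(.data$count_unmeth),
      .groups = "drop"
    )
    w$fraction <- with(w, ifelse(count_meth + count_unmeth > 0,
                                 count_meth / (count_meth + count_unmeth), NA_real_))
    out$windows <- w
  }
  out
}

#' Cytosine-conversion QC from spike-in controls
#'
#' Unmethylated lambda phage DNA measures conversion efficiency (any
#' methylated call on lambda is a conversion failure), and fully methylated
#' pUC19 DNA measures methylation retention (over-conversion erodes it).
#'
#' @param calls_lambda `meth_calls` over the unmethylated lambda control;
#'   all cytosine contexts are used.
#' @param calls_puc19 `meth_calls` over the fully methylated pUC19 control;
#'   CpG-context records are used.
#' @return A one-row tibble `conversion_efficiency`,
#'   `methylation_retention`, `lambda_cytosines`, `puc19_cpgs`.
#' @examples
#' lam <- as_meth_calls(data.frame(chrom = "lambda", pos = 0:9,
#'                                 count_meth = c(1, rep(0, 9)),
#'                                 count_unmeth = rep(99, 10)))
#' puc <- as_meth_calls(data.frame(chrom = "pUC19", pos = 0:9,
#'                                 count_meth = rep(95, 10),
#'                                 count_unmeth = rep(5, 10)))
#' conversion_qc(lam, puc)
#' @export
conversion_qc <- function(calls_lambda, calls_puc19) {
  if (nrow(calls_lambda) == 0 || nrow(calls_puc19) == 0) {
    abort("both control call sets must be non-empty")
  }
  lam_m <- sum(calls_lambda$count_meth)
  lam_t <- lam_m + sum(calls_lambda$count_unmeth)
  puc <- calls_puc19[calls_puc19$context == "CpG", ]
  if (nrow(puc) == 0) abort("pUC19 control has no CpG-context records")
  puc_m <- sum(puc$count_meth)
  puc_t <- puc_m + sum(puc$count_unmeth)
  tibble(
    conversion_efficiency = 1 - lam_m / lam_t,
    methylation_retention = puc_m / puc_t,
    lambda_cytosines = nrow(calls_lambda),
    puc19_cpgs = nrow(puc)
  )
}

#' CpG coverage summary
#'
#' @param calls A `meth_calls` tibble.
#' @return A one-row tibble `n_cpgs_covered` (CpG records with coverage >=
#'   1), `mean_depth` (0 when nothing is covered), with the depth histogram
#'   (tibble `depth`, `n`) in attribute `"histogram"`.
#' @export
cpg_coverage_summary <- function(calls) {
  cpg <- calls[calls$context == "CpG", ]
  depth <- cpg$count_meth + cpg$count_unmeth
  depth <- depth[depth >= 1]
  hist <- dplyr::count(tibble(depth = depth), .data$depth, name = "n")
  structure(
    tibble(n_cpgs_covered = length(depth),
           mean_depth = if (length(depth) > 0) mean(depth) else 0),
    histogram = hist
  )
}
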