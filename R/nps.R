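#' Bin genes by descending expression in a tissue
#'
#' Genes are sorted by expression in the chosen tissue (descending), with
#' mean expression across all tissue columns as the secondary key for exact
#' ties (descending) and gene id as the final tie-break (ascending), then
#' chunked into bins of `bin_size` genes (the last bin may be smaller). The
#' sort key is total, so bin assignment is a deterministic function of the
#' table. Genes with zero expression in the tissue can be split out into a
#' separate zero-expression group (`bin = NA`, `zero_expression = TRUE`),
#' mirroring the common practice of ranking only expressed genes.
#'
#' @param expr A data frame: column `gene_id` plus one numeric TPM column
#'   per tissue.
#' @param tissue Name of the tissue column to rank by.
#' @param bin_size Genes per bin, default 1000.
#' @param split_zero Separate zero-expression genes from the ranked bins
#'   (default TRUE).
#' @return A tibble `gene_id`, `expression`, `global_mean`, `bin` (1 = most
#'   expressed; `NA` for the zero-expression group), `zero_expression`.
#' @export
bin_genes_by_expression <- function(expr, tissue, bin_size = 1000,
                                    split_zero = TRUE) {
  check_tissue_column(expr, tissue)
  tissue_cols <- setdiff(names(expr), "gene_id")
  out <- tibble(
    gene_id = as.character(expr$gene_id),
    expression = as.numeric(expr[[tissue]]),
    global_mean = rowMeans(as.matrix(expr[, tissue_cols, drop = FALSE]))
  )
  if (any(out$expression < 0)) abort("TPM values must be non-negative")
  out <- dplyr::arrange(out, dplyr::desc(.data$expression),
                        dplyr::desc(.data$global_mean), .data$gene_id)
  out$zero_expression <- split_zero & out$expression == 0
  ranked <- which(!out$zero_expression)
  out$bin <- NA_integer_
  out$bin[ranked] <- as.integer((seq_along(ranked) - 1L) %/% bin_size + 1L)
  out
}

check_tissue_column <- function(expr, tissue) {
  if (!"gene_id" %in% names(expr)) abort("expression table needs a gene_id column")
  if (!tissue %in% names(expr)) {
    abort(paste0("unknown tissue column: ", tissue))
  }
  invisible(TRUE)
}

#' Bin tissue-enriched genes with low whole-blood expression
#'
#' Restricts the table to genes expressed below `blood_max_tpm` (strictly)
#' in whole blood, then bins the remainder by descending expression in the
#' tissue of interest exactly as [bin_genes_by_expression()] does. Used to
#' build gene sets whose transcription-start-site footprint should be
#' visible in urine- but not blood-derived cfDNA.
#'
#' @inheritParams bin_genes_by_expression
#' @param blood_tissue Name of the whole-blood column.
#' @param blood_max_tpm Strict upper TPM bound in whole blood, default 0.5.
#' @return As [bin_genes_by_expression()], over the filtered gene set.
#' @export
tissue_enriched_bins <- function(expr, tissue, blood_tissue = "whole_blood",
                                 blood_max_tpm = 0.5, bin_size = 1000,
                                 split_zero = TRUE) {
  check_tissue_column(expr, tissue)
  check_tissue_column(expr, blood_tissue)
  low_blood <- expr[as.numeric(expr[[blood_tissue]]) < blood_max_tpm, ]
  bin_genes_by_expression(low_blood, tissue, bin_size = bin_size,
                          split_zero = split_zero)
}

#' Nucleosome positioning signal (NPS) at the TSS
#'
#' Amplitude statistic of the TSS footprint computed on a normalized
#' aggregate WPS track:
#'
#' \deqn{NPS = \sum_{i=135}^{185} s(i) - \sum_{i=10}^{60} s(i)}
#'
#' i.e. the summed score over the +1 nucleosome window (inclusive offsets
#' +135..+185 downstream of the TSS for a 120-bp WPS window) minus the
#' summed score over the nucleosome-free-region window (+10..+60). Both
#' windows contain 51 integer offsets. High values indicate strongly
#' organized nucleosomes at the TSS; unphased or random loci score close to
#' zero. Different offsets must be chosen for other WPS window sizes.
#'
#' @param agg A `wps_aggregate` (offsets must cover both windows).
#' @param nfr_window Inclusive offset bounds of the nucleosome-free window,
#'   default `c(10, 60)`.
#' @param plus_one_window Inclusive offset bounds of the +1 nucleosome
#'   window, default `c(135, 185)`.
#' @return A single number.
#' @export
nps_score <- function(agg, nfr_window = c(10, 60), plus_one_window = c(135, 185)) {
  need <- c(nfr_window[1]:nfr_window[2], plus_one_window[1]:plus_one_window[2])
  if (!all(need %in% agg$offset)) {
    abort("aggregate does not cover the NPS offset windows")
  }
  s <- stats::setNames(agg$score, agg$offset)
  sum(s[as.character(plus_one_window[1]:plus_one_window[2])]) -
    sum(s[as.character(nfr_window[1]:nfr_window[2])])
}

#' NPS per expression bin, with correlation against bin rank
#'
#' For each gene bin, aggregates the WPS around the bin genes' TSS anchors
#' ([aggregate_wps()]) and computes the nucleosome positioning signal
#' ([nps_score()]). Reports Pearson and Spearman correlations of NPS against
#' bin rank; with a real TSS footprint these are strongly negative
#' (organization decays with decreasing expression).
#'
#' @param fragments A `cf_fragments` tibble (already length-filtered if a
#'   fragment class is studied).
#' @param bins Output of [bin_genes_by_expression()] or
#'   [tissue_enriched_bins()].
#' @param tss A data frame `gene_id`, `chrom`, `pos`, `strand` of TSS
#'   anchors.
#' @param window,flank,half_width Passed to [aggregate_wps()].
#' @param nfr_window,plus_one_window Passed to [nps_score()].
#' @return An `nps_by_bin` object: a tibble `bin`, `n_genes`, `nps`, with a
#'   `correlation` attribute (tibble `method`, `estimate`). [glance()]
#'   returns the correlations; bins without any anchored gene are skipped
#'   with a warning.
#' @export
nps_by_bin <- function(fragments, bins, tss, window = 120, flank = 5000,
                       half_width = 500, nfr_window = c(10, 60),
                       plus_one_window = c(135, 185)) {
  ranked <- bins[!is.na(bins$bin), ]
  out <- purrr::map_dfr(sort(unique(ranked$bin)), function(b) {
    genes <- ranked$gene_id[ranked$bin == b]
    anchors <- tss[tss$gene_id %in% genes, c("chrom", "pos", "strand")]
    if (nrow(anchors) == 0) {
      warn(paste0("bin ", b, " has no anchored genes; skipped"))
      return(NULL)
    }
    agg <- aggregate_wps(fragments, anchors, window = window, flank = flank,
                         half_width = half_width)
    tibble(bin = b, n_genes = nrow(anchors),
           nps = nps_score(agg, nfr_window, plus_one_window))
  })
  corr <- if (nrow(out) >= 3) {
    tibble(
      method = c("pearson", "spearman"),
      estimate = c(cor(out$bin, out$nps, method = "pearson"),
                   cor(out$bin, out$nps, method = "spearman"))
    )
  } else {
    tibble(method = c("pearson", "spearman"), estimate = c(NA_real_, NA_real_))
  }
  structure(out, class = c("nps_by_bin", class(tibble())), correlation = corr)
}

#' @method glance nps_by_bin
#' @export
glance.nps_by_bin <- function(x, ...) {
  corr <- attr(x, "correlation")
  tibble(
    n_bins = nrow(x),
    pearson = corr$estimate[corr$method == "pearson"],
    spearman = corr$estimate[corr$method == "spearman"]
  )
}

#' Random genomic anchors for an NPS null control
#'
#' Draws uniform anchor positions (random strand) across the supplied
#' chromosome sizes, optionally avoiding gap intervals. Aggregates over such
#' anchors have no common footprint, so their NPS is close to zero; they are
#' the negative control for [nps_by_bin()].
#'
#' @param n Number of anchors.
#' @param chrom_sizes Data frame `chrom`, `size`.
#' @param flank Keep anchors at least `flank` bases from chromosome ends.
#' @param gaps Optional data frame `chrom`, `start`, `end` of intervals to
#'   avoid (assembly gaps).
#' @param seed Integer seed.
#' @return An anchor tibble `chrom`, `pos`, `strand`.
#' @export
random_anchors <- function(n, chrom_sizes, flank = 5000, gaps = NULL, seed) {
  withr::with_seed(as.integer(seed), {
    sizes <- chrom_sizes[chrom_sizes$size > 2 * flank + 2, ]
    if (nrow(sizes) == 0) abort("no chromosome is long enough for the flank")
    out <- NULL
    while (is.null(out) || nrow(out) < n) {
      i <- sample.int(nrow(sizes), n, replace = TRUE,
                      prob = sizes$size - 2 * flank)
      pos <- flank + 1L + floor(runif(n) * (sizes$size[i] - 2 * flank - 1))
      cand <- tibble(chrom = sizes$chrom[i], pos = as.integer(pos),
                     strand = sample(c("+", "-"), n, replace = TRUE))
      if (!is.null(gaps)) {
        in_gap <- purrr::map_lgl(seq_len(nrow(cand)), function(k) {
          g <- gaps[gaps$chrom == cand$chrom[k], ]
          any(cand$pos[k] >= g$start & cand$pos[k] < g$end)
        })
        cand <- cand[!in_gap, ]
      }
      out <- rbind(out, cand)
    }
    out[seq_len(n), ]
  })
}
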