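#' Plot a WPS track
#'
#' @param object A `wps_track`.
#' @param peaks Optional `peak_set` to mark on the track.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot wps_track
#' @export
autoplot.wps_track <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$pos, y = .data$score)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "genomic position (bp)",
                  y = paste0("WPS (", attr(object, "stage"), ")"),
                  title = paste0(object$chrom[1], " WPS", attr(object, "window"))) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_vline(data = as_tibble(peaks),
                                 ggplot2::aes(xintercept = .data$pos),
                                 colour = "firebrick", alpha = 0.5)
  }
  p
}

#' Plot an aggregate WPS around anchors
#'
#' Shades the nucleosome-free-region and +1 nucleosome windows used by
#' [nps_score()].
#'
#' @param object A `wps_aggregate`.
#' @param nps_windows Show the NPS offset windows (default TRUE).
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot wps_aggregate
#' @export
autoplot.wps_aggregate <- function(object, nps_windows = TRUE, ...) {
  p <- ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$offset, y = .data$score))
  if (nps_windows) {
    shade <- tibble(xmin = c(10, 135), xmax = c(60, 185),
                    window = c("NFR (+10..+60)", "+1 nucleosome (+135..+185)"))
    p <- p + ggplot2::geom_rect(data = shade, inherit.aes = FALSE,
                                ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                             ymin = -Inf, ymax = Inf,
                                             fill = .data$window), alpha = 0.2)
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "offset from anchor (bp, transcription strand)",
                  y = paste0("mean normalized WPS", attr(object, "window")),
                  fill = NULL,
                  subtitle = paste0(attr(object, "n_regions"), " region(s)")) +
    ggplot2::theme_minimal()
}

#' Histogram of interpeak distances
#'
#' @param ipd Output of [interpeak_distances()] (tibble with `distance`).
#' @param binwidth Histogram bin width in bases, default 10.
#' @return A ggplot.
#' @export
plot_ipd_histogram <- function(ipd, binwidth = 10) {
  ggplot2::ggplot(as_tibble(ipd), ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::labs(x = "interpeak distance (bp)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot a tissue composition
#'
#' @param object A `tissue_composition`.
#' @param min_coefficient Hide tissues below this coefficient, default 0.001.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot tissue_composition
#' @export
autoplot.tissue_composition <- function(object, min_coefficient = 0.001, ...) {
  df <- dplyr::bind_rows(
    object$coefficients,
    tibble(tissue = "(unknown)", coefficient = object$unknown_fraction)
  )
  df <- df[df$coefficient >= min_coefficient, ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$tissue, .data$coefficient),
                                   y = .data$coefficient)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "cfDNA fraction") +
    ggplot2::theme_minimal()
}

#' Plot NPS against expression bin rank
#'
#' @param object An `nps_by_bin` result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot nps_by_bin
#' @export
autoplot.nps_by_bin <- function(object, ...) {
  corr <- attr(object, "correlation")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$bin, y = .data$nps)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "expression bin (1 = most expressed)",
                  y = "nucleosome positioning signal",
                  subtitle = paste0("Pearson R = ",
                                    round(corr$estimate[corr$method == "pearson"], 3))) +
    ggplot2::theme_minimal()
}
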