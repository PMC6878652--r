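# ggplot2 views of profiles and calls.

#' Plot sample profiles with optional call overlay
#'
#' Scatter of per-probe log2 ratios along the genome, faceted by
#' chromosome, with called intervals shaded.
#'
#' @param object a `cgh_profiles` tibble.
#' @param sample sample id to plot (defaults to the first).
#' @param chroms chromosomes to show (defaults to all with probes).
#' @param calls optional `cgh_calls` tibble to overlay.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cgh_profiles
#' @export
autoplot.cgh_profiles <- function(object, sample = NULL, chroms = NULL,
                                  calls = NULL, ...) {
  if (is.null(sample)) sample <- object$sample_id[1]
  dat <- object[object$sample_id == sample, ]
  if (!is.null(chroms)) dat <- dat[dat$chrom %in% chroms, ]
  dat$chrom <- chrom_factor(dat$chrom)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$start / 1e6,
                                         y = .data$log2ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "log2 ratio", title = sample)
  if (!is.null(calls)) {
    cc <- calls[calls$sample_id == sample, ]
    if (!is.null(chroms)) cc <- cc[cc$chrom %in% chroms, ]
    if (nrow(cc) > 0) {
      cc$chrom <- chrom_factor(cc$chrom)
      p <- p + ggplot2::geom_rect(
        data = cc,
        ggplot2::aes(xmin = .data$inner_start / 1e6,
                     xmax = .data$inner_end / 1e6,
                     ymin = -Inf, ymax = Inf, fill = .data$type),
        alpha = 0.25, inherit.aes = FALSE) +
        ggplot2::scale_fill_manual(values = c(gain = "#2166ac",
                                              loss = "#b2182b"))
    }
  }
  p
}

#' Plot call sizes and amplitudes across a cohort
#'
#' @param object a `cgh_calls` tibble.
#' @param ... unused.
#' @return a ggplot object: MALR vs probe count, coloured by type.
#' @method autoplot cgh_calls
#' @export
autoplot.cgh_calls <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$probe_count, y = .data$malr,
                                       colour = .data$type)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(gain = "#2166ac",
                                            loss = "#b2182b")) +
    ggplot2::labs(x = "probes per call", y = "MALR")
}
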