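#' Plot relative sequence read coverage along the genome
#'
#' The standard dosage-screen visual: per-bin RSRC scattered along each
#' chromosome, one colour per sample, horizontal reference lines at the
#' integer dosage states 1..ploidy+1, and called events shaded. A control
#' plotted against itself shows a flat band at the ploidy; a single-copy
#' deletion appears as a step down to ploidy - 1 across the affected bins.
#'
#' @param dosage A dosage tibble from [rsrc()], or a list of them (plotted
#'   together, distinguished by `sample_id`).
#' @param events Optional event tibble; event spans are shaded.
#' @param chroms Optional character vector restricting the plotted
#'   chromosomes.
#' @param ploidy Baseline ploidy for the reference lines; defaults to the
#'   dosage table's attribute.
#' @return A ggplot object; the underlying data are in `$data`, so
#'   rendering is exactly reproducible from the tables.
#' @export
plot_rsrc <- function(dosage, events = NULL, chroms = NULL, ploidy = NULL) {
  if (is.data.frame(dosage)) dosage <- list(dosage)
  if (is.null(ploidy)) ploidy <- attr(dosage[[1]], "ploidy")
  if (is.null(ploidy)) ploidy <- 3L
  dat <- purrr::map_dfr(dosage, function(d) {
    tibble::tibble(sample_id = d$sample_id, chrom = d$chrom,
                   pos_mbp = (d$start + d$end) / 2 / 1e6, rsrc = d$rsrc)
  })
  if (!is.null(chroms)) {
    dat <- dat[dat$chrom %in% chroms, ]
    if (!is.null(events)) events <- events[events$chrom %in% chroms, ]
  }
  dat$chrom <- factor(dat$chrom, levels = unique(dat$chrom))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos_mbp, y = .data$rsrc,
                                         colour = .data$sample_id)) +
    ggplot2::geom_hline(yintercept = seq_len(ploidy + 1),
                        linetype = "dashed", colour = "grey70",
                        linewidth = 0.3) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::coord_cartesian(ylim = c(0, ploidy + 2)) +
    ggplot2::labs(x = "Position (Mbp)", y = "Relative sequence read coverage",
                  colour = "Sample") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    shade <- tibble::tibble(
      chrom = factor(events$chrom, levels = levels(dat$chrom)),
      xmin = events$start / 1e6, xmax = events$end / 1e6
    )
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, fill = "red", alpha = 0.12,
      inherit.aes = FALSE
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.dosage_tbl <- function(object, ...) {
  plot_rsrc(object, ...)
}

#' @export
autoplot.cnv_screen <- function(object, ...) {
  dts <- purrr::flatten(object$dosage)
  plot_rsrc(dts, events = object$events, ploidy = object$ploidy, ...)
}
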