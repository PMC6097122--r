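#' Relative sequence read coverage (RSRC) against a control
#'
#' The central statistic of bin-based dosage analysis. Per-bin counts are
#' first turned into within-sample fractions (so library size cancels),
#' then each bin's fraction is divided by the control's fraction and
#' scaled by the ploidy:
#'
#'   rsrc_b = ploidy * (m_b / M) / (c_b / C)
#'
#' with `m_b`, `c_b` the bin counts of sample and control and `M`, `C`
#' their totals. A control compared against itself sits at exactly
#' `ploidy` in every bin; a single-copy deletion in a triploid drops the
#' affected bins to ~2, a single-copy insertion lifts them to ~4. Because
#' per-bin coverage biases (GC, mappability) are properties of the genome
#' shared by sample and control, they cancel in the ratio. Bins where the
#' control has zero reads are masked invalid (`valid = FALSE`, `rsrc = NA`)
#' and later break runs in the event caller.
#'
#' @param sample,control Bin-count tibbles from [bin_counts()], on the
#'   same grid.
#' @param ploidy Copy number assigned to the control (default 3).
#' @return A dosage tibble: `sample_id`, `control_id`, `chrom`, `bin`,
#'   `start`, `end`, `rsrc`, `valid`, carrying `ploidy` and `bin_size`
#'   attributes, with class `dosage_tbl`.
#' @examples
#' layout <- genome_layout("chr1", 1e6)
#' cfg <- sim_config(layout, seed = 7)
#' ctrl <- bin_counts(simulate_sample(cfg, stream = 0), layout, "ctrl")
#' mut <- bin_counts(simulate_sample(cfg, stream = 1), layout, "mut")
#' rsrc(mut, ctrl) # ~3.0 everywhere: no events injected
#' @export
rsrc <- function(sample, control, ploidy = 3L) {
  check_same_grid(sample, control)
  M <- sum(sample$count)
  C <- sum(control$count)
  if (M <= 0) rlang::abort("sample has zero total count")
  if (C <= 0) rlang::abort("control has zero total count")
  valid <- control$count > 0
  values <- ifelse(valid,
                   ploidy * (sample$count / M) / (control$count / C),
                   NA_real_)
  out <- tibble::tibble(
    sample_id = sample$sample_id[1],
    control_id = control$sample_id[1],
    chrom = sample$chrom, bin = sample$bin,
    start = sample$start, end = sample$end,
    rsrc = values, valid = valid
  )
  attr(out, "ploidy") <- as.integer(ploidy)
  attr(out, "bin_size") <- attr(sample, "bin_size")
  class(out) <- c("dosage_tbl", class(out))
  out
}

check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(a$chrom, b$chrom) || !identical(a$bin, b$bin)) {
    rlang::abort("sample and control are not on the same bin grid")
  }
  invisible(TRUE)
}

#' Pseudo-control from the mean of several samples
#'
#' The alternative control mode for screens without a designated untreated
#' reference: the per-bin fraction profile is the mean, over samples, of
#' each sample's own count fractions, so every individual contributes
#' equally regardless of library size. The result plugs into [rsrc()] in
#' place of a real control (its `count` column is fractional).
#'
#' @param samples A list of bin-count tibbles on a common grid (>= 2), or a
#'   single long tibble with a `sample_id` column.
#' @return A bin-count-shaped tibble with `sample_id = "mean-of-samples"`.
#' @export
control_from_mean <- function(samples) {
  if (is.data.frame(samples)) {
    samples <- split(samples, samples$sample_id)
    samples <- purrr::map(samples, tibble::as_tibble)
  }
  if (length(samples) < 2) {
    rlang::abort("mean-of-samples control needs at least 2 samples")
  }
  ref <- samples[[1]]
  fracs <- purrr::map(samples, function(s) {
    check_same_grid(ref, s)
    if (sum(s$count) <= 0) rlang::abort("sample has zero total count")
    s$count / sum(s$count)
  })
  out <- ref
  out$count <- purrr::reduce(fracs, `+`) / length(fracs)
  out$sample_id <- "mean-of-samples"
  attr(out, "bin_size") <- attr(ref, "bin_size")
  out
}

#' Write / read a dosage table as TSV
#'
#' One row per bin: `chrom`, `start`, `end`, `rsrc`, `valid`.
#'
#' @param dosage A dosage tibble from [rsrc()].
#' @param path File path.
#' @param layout A [genome_layout()] used to rebuild the grid on read.
#' @param ploidy,sample_id,control_id Metadata to attach on read.
#' @return `write_dosage()` returns `path` invisibly; `read_dosage()` a
#'   dosage tibble.
#' @export
write_dosage <- function(dosage, path) {
  readr::write_tsv(dosage[, c("chrom", "start", "end", "rsrc", "valid")],
                   path)
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path, layout, ploidy = 3L, sample_id = "sample",
                        control_id = "control") {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "d", end = "d", rsrc = "d", valid = "l"))
  grid <- make_bins(layout)
  merged <- dplyr::left_join(grid, tab, by = c("chrom", "start", "end"))
  out <- tibble::tibble(
    sample_id = sample_id, control_id = control_id,
    chrom = merged$chrom, bin = merged$bin,
    start = merged$start, end = merged$end,
    rsrc = merged$rsrc, valid = dplyr::coalesce(merged$valid, FALSE)
  )
  attr(out, "ploidy") <- as.integer(ploidy)
  attr(out, "bin_size") <- bin_size(layout)
  class(out) <- c("dosage_tbl", class(out))
  out
}
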