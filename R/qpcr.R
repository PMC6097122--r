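#' Relative copy number from qPCR concentrations
#'
#' Implements the ratio arithmetic used to validate CNV calls by
#' quantitative PCR. For each sample, the concentrations measured at the
#' unaffected flanking regions (labels in `flank_labels`, typically left
#' and right of the predicted event) are averaged into that sample's own
#' baseline; each region's ratio is its mean concentration over the
#' baseline. In a triploid, a region ratio of ~2/3 (a ~33% reduction)
#' indicates a single-copy deletion; ~1 indicates no change.
#'
#' @param measurements Tibble with columns `sample`, `region_label`,
#'   `replicate`, `concentration` (e.g. from [simulate_qpcr()] or
#'   [read_qpcr()]).
#' @param flank_labels Character vector of region labels treated as
#'   unaffected (e.g. `c("CL", "CR")`).
#' @param ploidy Baseline ploidy (default 3).
#' @return A tibble, one row per sample x region: `sample`,
#'   `region_label`, `ratio`, `est_copies` (`ratio * ploidy`),
#'   `pct_reduction` (`(1 - ratio) * 100`), and `sd` of the per-replicate
#'   ratios (NA with a single replicate).
#' @examples
#' m <- simulate_qpcr(c(CL = 3, CNV1 = 2, CR = 3), noise_cv = 0)
#' qpcr_dosage(m, flank_labels = c("CL", "CR"))
#' @export
qpcr_dosage <- function(measurements, flank_labels, ploidy = 3) {
  if (any(measurements$concentration <= 0)) {
    rlang::abort("concentrations must be positive")
  }
  per_sample <- split(measurements, measurements$sample)
  purrr::map_dfr(per_sample, function(m) {
    fl <- m$concentration[m$region_label %in% flank_labels]
    if (length(fl) == 0) {
      rlang::abort(sprintf(
        "sample '%s' has no measurements at flank labels (%s)",
        m$sample[1], paste(flank_labels, collapse = ", ")))
    }
    baseline <- mean(fl)
    if (baseline <= 0) {
      rlang::abort(sprintf("zero flank baseline for sample '%s'",
                           m$sample[1]))
    }
    m |>
      dplyr::group_by(.data$sample, .data$region_label) |>
      dplyr::summarise(
        ratio = mean(.data$concentration) / baseline,
        sd = stats::sd(.data$concentration / baseline),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        est_copies = .data$ratio * ploidy,
        pct_reduction = (1 - .data$ratio) * 100
      ) |>
      dplyr::select("sample", "region_label", "ratio", "est_copies",
                    "pct_reduction", "sd")
  })
}

#' Read / write qPCR measurement tables
#'
#' TSV with columns `sample`, `region_label`, `replicate`,
#' `concentration`.
#'
#' @param path File path.
#' @param measurements Measurement tibble.
#' @return `read_qpcr()` a measurement tibble; `write_qpcr()` the path,
#'   invisibly.
#' @export
read_qpcr <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample = "c", region_label = "c", replicate = "i", concentration = "d"))
}

#' @rdname read_qpcr
#' @export
write_qpcr <- function(measurements, path) {
  readr::write_tsv(measurements, path)
  invisible(path)
}
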