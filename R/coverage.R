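#' Load aligned read placements from SAM or BED
#'
#' Reads a file of positioned alignments and yields one placement — a
#' `(chrom, pos)` pair with `pos` the 1-based leftmost aligned base — per
#' usable record. For SAM, unmapped, secondary and supplementary records
#' and records below `mapq_min` are skipped; the skip count is recorded in
#' the `n_skipped` attribute. SAM parsing goes through Rsamtools (the file
#' is converted to a temporary BAM and filtered with standard flag/MAPQ
#' filters). BED input is 0-based half-open; interval starts are converted
#' to 1-based positions and no quality filter applies.
#'
#' @param path Path to a `.sam` or `.bed` file.
#' @param format `"auto"` (by extension), `"sam"` or `"bed"`.
#' @param mapq_min Minimum mapping quality for SAM records (default 20).
#' @param layout Optional [genome_layout()]; when given, placements on
#'   chromosomes absent from the layout raise an error naming the
#'   chromosome.
#' @return A tibble `chrom`, `pos` with attributes `n_records` (records
#'   inspected) and `n_skipped` (records filtered out).
#' @export
load_placements <- function(path, format = c("auto", "sam", "bed"),
                            mapq_min = 20, layout = NULL) {
  format <- rlang::arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "sam"
  }
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: '%s'", path))
  }
  if (format == "sam") {
    out <- load_placements_sam(path, mapq_min)
  } else {
    out <- load_placements_bed(path)
  }
  if (!is.null(layout)) {
    bad <- setdiff(unique(out$chrom), layout$chrom)
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "placements on chromosome(s) absent from layout: %s",
        paste(bad, collapse = ", ")))
    }
  }
  out
}

load_placements_sam <- function(path, mapq_min) {
  bam <- tryCatch(
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE),
    error = function(e) {
      rlang::abort(sprintf("malformed SAM file '%s': %s", path,
                           conditionMessage(e)))
    }
  )
  on.exit(unlink(bam), add = TRUE)
  n_records <- Rsamtools::countBam(bam)$records
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    mapqFilter = mapq_min,
    what = c("rname", "pos")
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  out <- tibble::tibble(chrom = as.character(rec$rname), pos = rec$pos)
  attr(out, "n_records") <- n_records
  attr(out, "n_skipped") <- n_records - nrow(out)
  out
}

load_placements_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                        pos = GenomicRanges::start(gr))
  attr(out, "n_records") <- length(gr)
  attr(out, "n_skipped") <- 0L
  out
}

#' Count read placements per bin
#'
#' Each placement increments exactly the bin containing its leftmost
#' aligned position; the sum over all bins equals the number of accepted
#' placements. The count unit is the read, not per-base depth — at 100-kb
#' bins and megabase-scale events the downstream coverage ratio is
#' insensitive to the distinction.
#'
#' @param placements Tibble with `chrom` and `pos` columns (e.g. from
#'   [load_placements()] or [simulate_sample()]).
#' @param layout A [genome_layout()].
#' @param sample_id Sample label carried into the output.
#' @return A bin-count tibble: `sample_id`, `chrom`, `bin`, `start`, `end`,
#'   `count`, one row per bin of the layout grid in global bin order.
#' @export
bin_counts <- function(placements, layout, sample_id = "sample") {
  stopifnot(inherits(layout, "genome_layout"))
  grid <- make_bins(layout)
  bs <- bin_size(layout)

  bad_chrom <- setdiff(unique(placements$chrom), layout$chrom)
  if (length(bad_chrom) > 0) {
    rlang::abort(sprintf("placements on unknown chromosome(s): %s",
                         paste(bad_chrom, collapse = ", ")))
  }
  chrom_len <- layout$length[match(placements$chrom, layout$chrom)]
  if (nrow(placements) > 0 &&
      (any(placements$pos < 1) || any(placements$pos > chrom_len))) {
    rlang::abort("placement position outside chromosome bounds")
  }

  tallied <- placements |>
    dplyr::mutate(bin = bin_index(.data$pos, bs)) |>
    dplyr::count(.data$chrom, .data$bin, name = "count")
  out <- grid |>
    dplyr::left_join(tallied, by = c("chrom", "bin")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  sample_id = sample_id) |>
    dplyr::select("sample_id", "chrom", "bin", "start", "end", "count")
  attr(out, "bin_size") <- bs
  out
}

#' Summarize coverage of a binned sample
#'
#' @param counts A bin-count tibble from [bin_counts()].
#' @param layout The [genome_layout()] the counts were made on.
#' @param read_length Read length in bp.
#' @return A one-row tibble: `sample_id`, `mapped_reads`,
#'   `mean_fold_coverage` (`mapped_reads * read_length / genome length`)
#'   and `zero_bins`.
#' @export
coverage_summary <- function(counts, layout, read_length = 300) {
  if (read_length <= 0) rlang::abort("`read_length` must be positive")
  tibble::tibble(
    sample_id = counts$sample_id[1],
    mapped_reads = sum(counts$count),
    mean_fold_coverage = sum(counts$count) * read_length / sum(layout$length),
    zero_bins = sum(counts$count == 0)
  )
}

#' Write / read bin counts as TSV
#'
#' One row per bin: `chrom`, `start`, `end`, `count`.
#'
#' @param counts A bin-count tibble.
#' @param path File path.
#' @param layout A [genome_layout()] used to rebuild the grid on read.
#' @param sample_id Sample label to attach on read.
#' @return `write_bin_counts()` returns `path` invisibly;
#'   `read_bin_counts()` a bin-count tibble.
#' @export
write_bin_counts <- function(counts, path) {
  readr::write_tsv(counts[, c("chrom", "start", "end", "count")], path)
  invisible(path)
}

#' @rdname write_bin_counts
#' @export
read_bin_counts <- function(path, layout, sample_id = "sample") {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "d", end = "d", count = "d"))
  grid <- make_bins(layout)
  merged <- dplyr::left_join(grid, tab, by = c("chrom", "start", "end"))
  if (anyNA(merged$count)) {
    rlang::abort("bin-count file does not cover the layout's bin grid")
  }
  out <- dplyr::mutate(merged, sample_id = sample_id,
                       count = as.integer(.data$count)) |>
    dplyr::select("sample_id", "chrom", "bin", "start", "end", "count")
  attr(out, "bin_size") <- bin_size(layout)
  out
}
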