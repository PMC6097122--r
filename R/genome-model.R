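#' Define a genome layout
#'
#' A genome layout is the coordinate backbone of a dosage analysis: an
#' ordered set of chromosomes with their lengths, plus the fixed bin size
#' used to aggregate read coverage. All other tables in the package (bin
#' grids, bin counts, dosage tables, CNV events) are aligned to a layout.
#'
#' Coordinates throughout the package are 1-based and inclusive; conversion
#' to 0-based half-open happens only at format boundaries (BED writers and
#' readers).
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Integer vector of chromosome lengths in base pairs.
#' @param bin_size Bin width in base pairs (default 100 kb, the resolution
#'   at which megabase-scale dosage changes are visually and statistically
#'   unambiguous at ~3x coverage).
#' @return A tibble with columns `chrom` and `length`, ordered as given,
#'   carrying the bin size as the `bin_size` attribute.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(3e6, 2.5e6))
#' @export
genome_layout <- function(chrom, length, bin_size = 100000L) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) {
    rlang::abort("chromosome names must be unique")
  }
  if (length(chrom) != length(length)) {
    rlang::abort("`chrom` and `length` must have the same length")
  }
  if (any(length <= 0)) {
    rlang::abort("chromosome lengths must be positive")
  }
  if (bin_size <= 0) {
    rlang::abort("`bin_size` must be positive")
  }
  out <- tibble::tibble(chrom = chrom, length = length)
  attr(out, "bin_size") <- as.numeric(bin_size)
  class(out) <- c("genome_layout", class(out))
  out
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("Genome layout: ", nrow(x), " chromosomes, ",
      format(sum(x$length), big.mark = ","), " bp, bin size ",
      format(bin_size(x), big.mark = ","), " bp\n", sep = "")
  NextMethod()
}

#' Bin size of a layout or grid
#'
#' @param x A `genome_layout` or any table produced on its bin grid.
#' @return The bin width in base pairs.
#' @export
bin_size <- function(x) {
  bs <- attr(x, "bin_size")
  if (is.null(bs)) {
    rlang::abort("object carries no `bin_size` attribute")
  }
  bs
}

#' Tile a genome layout into fixed-size bins
#'
#' Each chromosome is tiled left to right with non-overlapping bins of
#' `bin_size(layout)` base pairs. The final bin of a chromosome may be
#' shorter; it is retained, not dropped, because downstream dosage values
#' are ratios of per-bin count fractions between samples on the same grid,
#' in which bin length cancels.
#'
#' @param layout A [genome_layout()].
#' @return A tibble with one row per bin: `chrom`, `bin` (0-based index
#'   within the chromosome), `start`, `end` (1-based inclusive). Rows are
#'   ordered by layout chromosome order, then by bin index; this global
#'   order is shared by every per-sample table in the package.
#' @examples
#' make_bins(genome_layout("chr1", 250000, bin_size = 100000))
#' @export
make_bins <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  bs <- bin_size(layout)
  grid <- purrr::map2_dfr(layout$chrom, layout$length, function(ch, len) {
    n <- ceiling(len / bs)
    idx <- seq_len(n) - 1L
    tibble::tibble(
      chrom = ch,
      bin = idx,
      start = idx * bs + 1,
      end = pmin((idx + 1) * bs, len)
    )
  })
  grid$chrom <- factor(grid$chrom, levels = layout$chrom)
  grid$chrom <- as.character(grid$chrom) # keep plain, order is row order
  attr(grid, "bin_size") <- bs
  grid
}

#' Count bins overlapped by a genomic interval
#'
#' The number of fixed-size bins a 1-based inclusive interval touches:
#' `floor((end - 1) / bin_size) - floor((start - 1) / bin_size) + 1`.
#' This is the "number of 100-kb bins" column of a CNV report when
#' `bin_size` is 100 kb.
#'
#' @param start,end 1-based inclusive interval bounds (vectorized).
#' @param bin_size Bin width in bp.
#' @return Integer vector of bin counts.
#' @examples
#' bins_spanned(24400001, 28200000) # 38 bins = 3.8 Mbp at 100-kb bins
#' @export
bins_spanned <- function(start, end, bin_size = 100000) {
  if (any(start > end)) {
    rlang::abort("`start` must be <= `end`")
  }
  if (any(start < 1)) {
    rlang::abort("coordinates are 1-based; `start` must be >= 1")
  }
  as.integer(floor((end - 1) / bin_size) - floor((start - 1) / bin_size) + 1)
}

# 0-based bin index of a 1-based position
bin_index <- function(pos, bin_size) {
  floor((pos - 1) / bin_size)
}

#' Read a genome layout from a two-column TSV
#'
#' Expects columns `chrom` and `length` (header optional; the first two
#' columns are used).
#'
#' @param path Path to a TSV file.
#' @inheritParams genome_layout
#' @return A [genome_layout()].
#' @export
read_layout <- function(path, bin_size = 100000L) {
  tab <- readr::read_tsv(path, col_names = c("chrom", "length"),
                         col_types = "cd", comment = "#")
  # tolerate a header row
  if (is.na(suppressWarnings(as.numeric(tab$length[1])))) {
    tab <- tab[-1, ]
    tab$length <- as.numeric(tab$length)
  }
  genome_layout(tab$chrom, tab$length, bin_size = bin_size)
}

#' Write a genome layout to TSV
#'
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  readr::write_tsv(tibble::tibble(chrom = layout$chrom,
                                  length = layout$length),
                   path, col_names = FALSE)
  invisible(path)
}

#' Infer a genome layout from a SAM header
#'
#' Reads the `@SQ` lines (`SN`/`LN`) of a SAM file.
#'
#' @param path Path to a SAM file.
#' @inheritParams genome_layout
#' @return A [genome_layout()].
#' @export
layout_from_sam <- function(path, bin_size = 100000L) {
  lines <- readLines(path, n = 10000L)
  sq <- grep("^@SQ\t", lines, value = TRUE)
  if (length(sq) == 0) {
    rlang::abort(sprintf("no @SQ lines found in SAM header of '%s'", path))
  }
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.numeric(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  genome_layout(sn, ln, bin_size = bin_size)
}

#' Read gene models from GFF3
#'
#' Imports features of type `gene` and returns them as a tidy table. The
#' `ID` attribute is used as the gene identifier.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  ids <- gr$ID
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  tibble::tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write gene models to GFF3
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end` and
#'   optionally `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  strand <- if ("strand" %in% names(genes)) genes$strand else "*"
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$source <- "bindosage"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
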